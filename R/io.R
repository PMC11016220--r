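## Codebook describing each survey_dataset column: type, levels, units, role.
survey_codebook <- function(data) {
  role_of <- function(v) {
    if (v %in% c("stratum", "cluster", "weight")) return("design")
    if (grepl("^y_", v)) return("outcome")
    if (grepl("bmi|wc|height|weight_", v) || v == "exam") return("exposure")
    if (v == "id") return("id")
    "covariate"
  }
  unit_of <- function(v) {
    if (grepl("bmi", v)) "kg/m2"
    else if (grepl("height|wc", v)) "cm"
    else if (grepl("^weight_", v)) "kg"
    else if (v == "age") "years"
    else if (v == "black_carbon") "ug/m3"
    else if (v == "vegetation") "fraction"
    else ""
  }
  lapply(setNames(names(data), names(data)), function(v) {
    x <- data[[v]]
    tp <- if (is.factor(x)) "categorical"
      else if (all(stats::na.omit(x) %in% c(0, 1)) && !grepl("weight|bmi", v)) "binary"
      else if (is.integer(x)) "integer" else "numeric"
    cb <- list(type = tp, role = role_of(v), units = unit_of(v))
    if (is.factor(x)) cb$levels <- levels(x)
    cb
  })
}

#' Read and write survey datasets as CSV plus a YAML codebook
#'
#' The CSV stores missing values as empty fields; the YAML codebook records
#' each variable's type, levels, units and role (covariate, exposure, outcome,
#' design), so the dataset round-trips with factor levels and types intact.
#'
#' @param data a `survey_dataset`.
#' @param csv_path,codebook_path file paths.
#' @return `write_survey_csv` returns `csv_path` invisibly; `read_survey_csv`
#'   the reconstructed `survey_dataset`.
#' @export
write_survey_csv <- function(data, csv_path, codebook_path) {
  write.csv(data, csv_path, row.names = FALSE, na = "")
  yaml::write_yaml(survey_codebook(data), codebook_path)
  invisible(csv_path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(csv_path, codebook_path) {
  cb <- yaml::read_yaml(codebook_path)
  cls <- vapply(cb, function(e) switch(e$type, categorical = "character",
                                       integer = "integer",
                                       binary = "integer", "numeric"),
                character(1))
  d <- read.csv(csv_path, colClasses = cls, na.strings = "")
  for (v in names(cb)) {
    if (cb[[v]]$type == "categorical") {
      d[[v]] <- factor(d[[v]], levels = unlist(cb[[v]]$levels))
    }
  }
  class(d) <- c("survey_dataset", "data.frame")
  d
}

#' Serialize a population specification to YAML
#'
#' @param spec a `population_spec`.
#' @param path file path.
#' @return `write_population_spec` returns `path` invisibly;
#'   `read_population_spec` the validated `population_spec`.
#' @export
write_population_spec <- function(spec, path) {
  validate_population_spec(spec)
  # named atomic vectors become YAML maps, so names survive the round trip
  as_maps <- function(x) {
    if (is.list(x)) lapply(x, as_maps)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(as_maps(unclass(spec)), path, precision = 15)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  loaded <- yaml::read_yaml(path)
  # YAML reads vectors back as lists; rebuild the spec shape against the
  # default specification, so atomic leaves become atomic again
  merge_shape <- function(default, x) {
    if (is.null(x)) return(default)
    if (!is.list(default)) {
      v <- unlist(x)
      if (!is.null(v) && is.null(names(v)) && !is.null(names(default)) &&
          length(v) == length(default)) {
        names(v) <- names(default)
      }
      return(v)
    }
    out <- default
    for (nm in names(x)) {
      out[[nm]] <- if (!is.null(default[[nm]])) {
        merge_shape(default[[nm]], x[[nm]])
      } else if (is.list(x[[nm]]) &&
                 all(vapply(x[[nm]], function(e) is.numeric(e) &&
                              length(e) == 1, logical(1)))) {
        unlist(x[[nm]])
      } else x[[nm]]
    }
    out
  }
  spec <- merge_shape(unclass(default_population_spec()), loaded)
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

#' Persist completed datasets as CSV files plus a JSON chain trace
#'
#' @param completed a `completed_datasets` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_completed_datasets <- function(completed, dir) {
  stopifnot(inherits(completed, "completed_datasets"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (j in seq_along(completed$datasets)) {
    p <- file.path(dir, sprintf("imputation_%02d.csv", j))
    cbp <- file.path(dir, sprintf("imputation_%02d.codebook.yaml", j))
    write_survey_csv(completed$datasets[[j]], p, cbp)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "chain_trace.json")
  jsonlite::write_json(completed$trace, tp, digits = NA, dataframe = "columns")
  invisible(c(paths, tp))
}
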