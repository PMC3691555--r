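# Plain-text serialization for patterns, sweeps and configs. Patterns and
# weight matrices travel as CSV (one column per unit; a commented header
# records population metadata and seed), experiment configs as YAML or JSON.

#' Write a pattern ensemble to CSV
#'
#' One pattern per row, one column per unit. Metadata (population id, seed,
#' any named extras) is stored in `#`-prefixed header comment lines so the
#' file round-trips through [read_patterns_csv()].
#'
#' @param patterns matrix (one pattern per row) or numeric vector.
#' @param path output file path.
#' @param population_id label for the population.
#' @param seed integer seed that generated the ensemble, if any.
#' @param extra named list of additional scalar metadata.
#' @return `path`, invisibly.
#' @export
write_patterns_csv <- function(patterns, path, population_id = "pop",
                               seed = NULL, extra = list()) {
  patterns <- as_pattern_matrix(patterns)
  meta <- c(population_id = population_id,
            seed = if (is.null(seed)) "NA" else as.character(seed),
            vapply(extra, as.character, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(patterns, con, sep = ",", row.names = FALSE,
                     col.names = paste0("u", seq_len(ncol(patterns))))
  invisible(path)
}

#' Read a pattern ensemble written by [write_patterns_csv()]
#'
#' @param path CSV file path.
#' @return matrix with attributes `population_id` and `seed`.
#' @export
read_patterns_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  m <- as.matrix(utils::read.csv(text = lines[-hdr], check.names = FALSE))
  dimnames(m) <- NULL
  attr(m, "population_id") <- meta$population_id
  attr(m, "seed") <- if (identical(meta$seed, "NA")) NA_integer_ else
    as.integer(meta$seed)
  m
}

#' Read an experiment configuration file
#'
#' YAML (preferred) with JSON fallback; the file holds named fields that are
#' passed to [object_place_config()] or other constructors by the caller.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is required to read JSON configs")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file")
  }
}
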