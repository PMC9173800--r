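#' Read and write ERG traces as CSV with JSON sidecars
#'
#' A trace file is a plain two-column CSV (`time_ms`, `voltage_uV`); its
#' metadata (stimulus label, subject id, eye, sweep index, component tag,
#' seed, ...) lives in a JSON sidecar with the same path plus `.json`.
#'
#' @param trace An `erg_trace`.
#' @param path Output CSV path (sidecar written to `<path>.json`).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` an
#'   `erg_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "erg_trace"))
  utils::write.csv(data.frame(time_ms = sprintf("%.17g", trace$time),
                              voltage_uV = sprintf("%.17g", trace$voltage)),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trace$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  erg_trace(d$time_ms, d$voltage_uV, meta)
}

#' Read and write cohort tables and kinship matrices
#'
#' The cohort table is a CSV with columns `subject_id`, `family_id`,
#' `zygosity`, `age`, `sex`, `dosage`.  The kinship matrix is a dense CSV
#' with subject ids in the header row and first column.
#'
#' @param subjects Cohort data frame.
#' @param K Kinship matrix with subject-id dimnames.
#' @param path File path.
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @export
write_cohort <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_cohort
#' @export
write_kinship <- function(K, path) {
  d <- data.frame(subject_id = rownames(K), K, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_kinship <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  K <- as.matrix(d[, -1, drop = FALSE])
  rownames(K) <- d[[1]]
  storage.mode(K) <- "double"
  K
}

# small FNV-1a-style hash of a serialized object, for provenance stamping
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  b <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (v in b) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(v))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
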