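# Plain-text interchange: sweep sets as delimited text (one column per trial,
# header lines carrying rate/onset/level), cohort tables as CSV with fixed
# column names.

#' Write a sweep set to a delimited-text file
#'
#' One tab-separated block per level: comment header lines (`# key=value`) with
#' sampling rate, onset, stimulus duration, kind and level, then one column per
#' trial. Blocks are concatenated in level order and separated by a `# level=`
#' header, so a single file holds a whole protocol.
#'
#' @param ss A [sweep_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_set <- function(ss, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ss$levels)) {
    tr <- ss$sweeps[[i]]
    t0 <- tr[[1L]]
    writeLines(c(
      sprintf("# level=%.10g", ss$levels[i]),
      sprintf("# rate_hz=%.10g", t0$rate_hz),
      sprintf("# onset_ms=%.10g", t0$onset_ms),
      sprintf("# dur_ms=%.10g", t0$dur_ms),
      sprintf("# kind=%s", t0$kind),
      sprintf("# cell_id=%s", t0$cell_id),
      sprintf("# trials=%d", length(tr))
    ), con)
    mat <- vapply(tr, function(s) s$v, numeric(length(t0$v)))
    utils::write.table(format(mat, digits = 8, trim = TRUE), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a sweep set written by [write_sweep_set()]
#' @param path File path.
#' @return A [sweep_set()].
#' @export
read_sweep_set <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^# level=", lines)
  if (length(hdr_idx) == 0L) stop("no level headers found in ", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  by_level <- list()
  for (b in seq_along(hdr_idx)) {
    block <- lines[bounds[b]:(bounds[b + 1L] - 1L)]
    meta_lines <- grep("^# ", block, value = TRUE)
    meta <- list()
    for (m in meta_lines) {
      kv <- strsplit(sub("^# ", "", m), "=", fixed = TRUE)[[1L]]
      meta[[kv[1L]]] <- kv[2L]
    }
    dat <- utils::read.table(text = block[!grepl("^# ", block)], sep = "\t")
    trials <- lapply(seq_len(ncol(dat)), function(j) {
      voltage_trace(dat[[j]],
                    rate_hz = as.numeric(meta$rate_hz),
                    onset_ms = as.numeric(meta$onset_ms),
                    dur_ms = as.numeric(meta$dur_ms),
                    kind = meta$kind,
                    level = as.numeric(meta$level),
                    cell_id = meta$cell_id)
    })
    by_level[[meta$level]] <- trials
  }
  sweep_set(by_level)
}

.cohort_columns <- c("cell_id", "type", "layer", "depth_norm", "solution",
                     "nucleus", "responsive")

#' Write / read a cohort table as CSV
#'
#' The cohort CSV carries at least the fixed per-cell record columns
#' `cell_id, type, layer, depth_norm, solution, nucleus, responsive`; extra
#' analysis columns (intrinsic properties, threshold-response metrics,
#' predicted subtype) are appended as produced.
#'
#' @param cohort A data frame of per-cell records.
#' @param path CSV file path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols))
    stop("file lacks required columns: ", paste(missing_cols, collapse = ", "))
  df$responsive <- as.logical(df$responsive)
  df
}
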