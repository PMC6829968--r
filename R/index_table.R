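#' Write per-trial index records to TSV
#'
#' One row per trial with columns \code{subject_id}, \code{group},
#' \code{sias_level}, \code{motion}, \code{trial_index}, \code{esb},
#' \code{mcs}. An undefined MCS (degenerate coefficient vector) is serialized
#' as \code{NA}.
#'
#' @param records data.frame of index records (as produced by
#'   \code{\link{session_indexes}}).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_index_table <- function(records, path) {
  cols <- c("subject_id", "group", "sias_level", "motion", "trial_index",
            "esb", "mcs")
  if (is.null(records) || nrow(records) == 0L)
    stop("no index records to write")
  if (!all(cols %in% names(records)))
    stop("records need columns: ", paste(cols, collapse = ", "))
  out <- records[, cols]
  # full double precision so a roundtrip preserves values
  out$esb <- sprintf("%.15g", out$esb)
  out$mcs <- ifelse(is.na(records$mcs), "NA",
                    sprintf("%.15g", records$mcs))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$esb <- as.numeric(df$esb)
  df$mcs <- as.numeric(df$mcs)
  df$sias_level <- as.integer(df$sias_level)
  df
}
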