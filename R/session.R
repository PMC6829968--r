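#' Subject metadata
#'
#' Describes one participant. Stroke subjects carry a SIAS level (1--5, lower
#' is more severe) and a paretic side; healthy subjects carry a dominant side
#' and no SIAS level.
#'
#' @param subject_id Character identifier.
#' @param group One of \code{"healthy_young"}, \code{"healthy_elder"},
#'   \code{"stroke"}.
#' @param sias_level Integer 1--5 (stroke only), otherwise \code{NA}.
#' @param paretic_side \code{"left"}/\code{"right"} (stroke only), else \code{NA}.
#' @param dominant_side \code{"left"}/\code{"right"} (healthy), else \code{NA}.
#' @return An object of class \code{subject_meta}.
#' @export
subject_meta <- function(subject_id, group,
                         sias_level = NA_integer_,
                         paretic_side = NA_character_,
                         dominant_side = NA_character_) {
  group <- match.arg(group, c("healthy_young", "healthy_elder", "stroke"))
  if (group == "stroke") {
    if (is.na(sias_level) || !(sias_level %in% 1:5))
      stop("stroke subjects require sias_level in 1..5")
    if (is.na(paretic_side) || !(paretic_side %in% emg_sides))
      stop("stroke subjects require paretic_side ('left' or 'right')")
  } else {
    if (!is.na(sias_level))
      stop("sias_level applies only to stroke subjects")
    if (is.na(dominant_side) || !(dominant_side %in% emg_sides))
      stop("healthy subjects require dominant_side ('left' or 'right')")
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 sias_level = as.integer(sias_level),
                 paretic_side = as.character(paretic_side),
                 dominant_side = as.character(dominant_side)),
            class = "subject_meta")
}

#' Multichannel sEMG recording session
#'
#' Holds one subject's recording: a channel-by-time sample matrix, the channel
#' labels, the sampling rate, subject metadata, and trial annotations marking
#' the motion windows within the continuous recording.
#'
#' @param samples Numeric matrix, channels in rows, time in columns. Row names
#'   must be (or are set to) the canonical channel labels.
#' @param channels Character vector of channel labels (canonicalized).
#' @param sample_rate Sampling frequency in Hz (positive). The protocol value
#'   is 1000 Hz but any positive rate is accepted.
#' @param meta A \code{subject_meta}.
#' @param annotations data.frame with columns \code{motion}
#'   (\code{"elbow_flexion"} or \code{"steering"}), \code{start_sample},
#'   \code{end_sample} (1-based, inclusive, non-overlapping).
#' @return An object of class \code{emg_session}. The logical field
#'   \code{montage_complete} is \code{FALSE} when fewer than the 18 montage
#'   channels are present.
#' @export
emg_session <- function(samples, channels, sample_rate, meta,
                        annotations = NULL) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar (Hz)")
  if (!inherits(meta, "subject_meta")) stop("meta must be a subject_meta")
  parsed <- parse_channel_label(channels)
  if (anyNA(parsed$label))
    stop("unrecognized channel label(s): ",
         paste(channels[is.na(parsed$label)], collapse = ", "))
  if (anyDuplicated(parsed$label))
    stop("duplicate channel labels")
  if (nrow(samples) != nrow(parsed))
    stop("channel count does not match sample matrix rows")
  rownames(samples) <- parsed$label
  annotations <- validate_annotations(annotations, ncol(samples))
  structure(list(meta = meta, sample_rate = sample_rate,
                 channels = parsed$label, samples = samples,
                 annotations = annotations,
                 montage_complete = setequal(parsed$label, full_montage())),
            class = "emg_session")
}

validate_annotations <- function(annotations, n_samples) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(data.frame(motion = character(), start_sample = integer(),
                      end_sample = integer(), stringsAsFactors = FALSE))
  req <- c("motion", "start_sample", "end_sample")
  if (!all(req %in% names(annotations)))
    stop("annotations need columns: ", paste(req, collapse = ", "))
  ann <- annotations[order(annotations$start_sample), req, drop = FALSE]
  if (!all(ann$motion %in% c("elbow_flexion", "steering")))
    stop("unknown motion label(s): ",
         paste(setdiff(ann$motion, c("elbow_flexion", "steering")), collapse = ", "))
  if (any(ann$start_sample < 1L) || any(ann$end_sample > n_samples) ||
      any(ann$start_sample >= ann$end_sample))
    stop("annotation window out of range (need 1 <= start < end <= ", n_samples, ")")
  if (nrow(ann) > 1L && any(ann$start_sample[-1L] <= ann$end_sample[-nrow(ann)]))
    stop("annotations overlap")
  rownames(ann) <- NULL
  ann
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("emg_session: subject %s (%s), %d channels x %d samples @ %g Hz, %d trial(s)%s\n",
              x$meta$subject_id, x$meta$group, nrow(x$samples), ncol(x$samples),
              x$sample_rate, nrow(x$annotations),
              if (x$montage_complete) "" else " [montage incomplete]"))
  invisible(x)
}

#' Extract one annotated trial from a session
#'
#' @param session An \code{emg_session}.
#' @param trial Row index into \code{session$annotations}.
#' @return A \code{trial_segment}: the sample window of that trial with its
#'   motion label and the session's metadata. Segments shorter than the
#'   nominal 20 s are accepted and flagged (\code{short = TRUE}).
#' @export
trial_segment <- function(session, trial) {
  stopifnot(inherits(session, "emg_session"))
  ann <- session$annotations
  if (trial < 1L || trial > nrow(ann)) stop("no such trial: ", trial)
  idx <- seq.int(ann$start_sample[trial], ann$end_sample[trial])
  new_trial_segment(session$samples[, idx, drop = FALSE], session$channels,
                    session$sample_rate, session$meta,
                    motion = ann$motion[trial], trial_index = trial,
                    preprocessed = isTRUE(session$preprocessed))
}

new_trial_segment <- function(samples, channels, sample_rate, meta, motion,
                              trial_index = NA_integer_, preprocessed = FALSE) {
  dur <- ncol(samples) / sample_rate
  structure(list(motion = motion, samples = samples, channels = channels,
                 sample_rate = sample_rate, meta = meta,
                 trial_index = as.integer(trial_index),
                 preprocessed = preprocessed,
                 short = dur < 20 - 1e-9),
            class = "trial_segment")
}

#' @export
print.trial_segment <- function(x, ...) {
  cat(sprintf("trial_segment: %s, %d ch x %.2f s @ %g Hz%s%s\n",
              x$motion, nrow(x$samples), ncol(x$samples) / x$sample_rate,
              x$sample_rate,
              if (x$preprocessed) " [preprocessed]" else " [raw]",
              if (x$short) " [short]" else ""))
  invisible(x)
}

#' Read a session from a wide-format CSV (plus optional sidecar)
#'
#' The CSV has one column per channel, named by the channel label
#' (case-insensitive \code{"<MUSCLE>_<SIDE>"}); an optional leading time/index
#' column (any name not parseable as a channel label) is validated against
#' \code{sample_rate} when it looks like time in seconds, then discarded.
#'
#' Metadata and annotations come either from the arguments or from a YAML
#' sidecar file \code{<path>.meta.yaml} written by \code{\link{write_session}}.
#'
#' @param path CSV file path.
#' @param meta A \code{subject_meta}; if \code{NULL}, read from the sidecar.
#' @param annotations Trial annotation data.frame; if \code{NULL}, taken from
#'   the sidecar (if any).
#' @param sample_rate Hz; if \code{NULL}, taken from the sidecar, else 1000.
#' @return An \code{emg_session}. A warning is issued when the montage is
#'   incomplete (fewer than 18 recognized channels).
#' @export
read_session <- function(path, meta = NULL, annotations = NULL,
                         sample_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- sidecar_path(path)
  side <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  if (is.null(meta)) {
    if (is.null(side)) stop("no metadata given and no sidecar found at ", sidecar)
    meta <- meta_from_sidecar(side)
  }
  if (is.null(annotations) && !is.null(side$trials))
    annotations <- do.call(rbind, lapply(side$trials, function(tr)
      data.frame(motion = tr$motion, start_sample = tr$start_sample,
                 end_sample = tr$end_sample, stringsAsFactors = FALSE)))
  if (is.null(sample_rate))
    sample_rate <- if (!is.null(side$sample_rate)) side$sample_rate else 1000

  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE),
    error = function(e) stop("parse error reading ", path, ": ", conditionMessage(e)))
  if (ncol(dt) == 0L || nrow(dt) == 0L) stop("empty session file: ", path)
  parsed <- parse_channel_label(names(dt))
  is_chan <- !is.na(parsed$label)
  non_chan <- which(!is_chan)
  # at most one leading non-channel (time/index) column is tolerated
  if (length(non_chan) > 1L || (length(non_chan) == 1L && non_chan != 1L))
    stop("unrecognized channel column(s): ",
         paste(names(dt)[setdiff(non_chan, 1L)], collapse = ", "))
  if (length(non_chan) == 1L) {
    tcol <- dt[[1L]]
    if (is.numeric(tcol) && length(tcol) > 2L) {
      dtv <- diff(tcol)
      # looks like a time axis in seconds -> must be uniform at 1/sample_rate
      if (abs(stats::median(dtv) - 1 / sample_rate) < 0.5 / sample_rate &&
          (max(dtv) - min(dtv)) > 1e-6 * abs(stats::median(dtv)))
        stop("time column is not uniform at the stated sample rate")
    }
    dt <- dt[, -1L, drop = FALSE]
    parsed <- parsed[-1L, , drop = FALSE]
  }
  if (!all(vapply(dt, is.numeric, TRUE)))
    stop("non-numeric values in channel column(s): ",
         paste(names(dt)[!vapply(dt, is.numeric, TRUE)], collapse = ", "))
  samples <- t(as.matrix(dt))
  sess <- emg_session(samples, parsed$label, sample_rate, meta, annotations)
  if (!sess$montage_complete)
    warning("incomplete montage: ", nrow(samples), " of 18 channels present")
  sess
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.yaml")

meta_from_sidecar <- function(side) {
  subject_meta(subject_id = side$subject_id, group = side$group,
               sias_level = if (is.null(side$sias_level)) NA_integer_ else as.integer(side$sias_level),
               paretic_side = if (is.null(side$paretic_side)) NA_character_ else side$paretic_side,
               dominant_side = if (is.null(side$dominant_side)) NA_character_ else side$dominant_side)
}

#' Write a session to CSV plus YAML sidecar
#'
#' Writes the sample matrix as a wide CSV (canonical uppercase channel-label
#' header, no time column) and the metadata/annotations to
#' \code{<path>.meta.yaml}, the format \code{\link{read_session}} reads back.
#'
#' @param session An \code{emg_session}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "emg_session"))
  df <- as.data.frame(t(session$samples))
  names(df) <- session$channels
  data.table::fwrite(df, path, sep = ",")
  m <- session$meta
  side <- list(subject_id = m$subject_id, group = m$group,
               sample_rate = session$sample_rate)
  if (!is.na(m$sias_level)) side$sias_level <- m$sias_level
  if (!is.na(m$paretic_side)) side$paretic_side <- m$paretic_side
  if (!is.na(m$dominant_side)) side$dominant_side <- m$dominant_side
  if (nrow(session$annotations) > 0L)
    side$trials <- lapply(seq_len(nrow(session$annotations)), function(i)
      as.list(session$annotations[i, ]))
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}
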