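#' Per-second RMS of an envelope
#'
#' Electrical power per second is quantized as the root-mean-square of the
#' rectified signal over consecutive, non-overlapping 1-second windows; a
#' trailing partial second is dropped.
#'
#' @param x Numeric vector (envelope samples).
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric vector of per-second RMS values, length
#'   \code{floor(length(x)/sample_rate)}.
#' @export
rms_per_second <- function(x, sample_rate) {
  w <- as.integer(round(sample_rate))
  n <- length(x) %/% w
  if (n < 1L)
    stop("segment shorter than one second (", length(x), " samples at ",
         sample_rate, " Hz)")
  m <- matrix(x[seq_len(n * w)]^2, nrow = w)
  sqrt(colMeans(m))
}

#' Per-muscle electrical power of a trial
#'
#' For each of the 18 montage channels, the trial power P_i is the mean of
#' the per-second RMS values over the motion window (edge-trimmed to exclude
#' filter transients). Side totals P_r and P_l are the sums over the nine
#' muscles of each side.
#'
#' @param segment A preprocessed \code{trial_segment} carrying the full
#'   montage. A raw segment is preprocessed first.
#' @param config An \code{\link{emg_config}} (controls the edge trim).
#' @return An object of class \code{muscle_powers}: data.frame
#'   \code{powers} (muscle, side, power) in canonical muscle order, plus
#'   \code{total_right}, \code{total_left}, \code{n_muscles}.
#' @export
trial_powers <- function(segment, config = emg_config()) {
  stopifnot(inherits(segment, "trial_segment"))
  if (!segment$preprocessed) segment <- preprocess_trial(segment, config)
  montage <- full_montage()
  missing <- setdiff(montage, segment$channels)
  if (length(missing) > 0L)
    stop("montage incomplete, missing channel(s): ",
         paste(missing, collapse = ", "))
  trim <- as.integer(round(config$edge_trim_s * segment$sample_rate))
  nt <- ncol(segment$samples)
  if (nt - 2L * trim < segment$sample_rate)
    stop("trial too short: less than one second remains after edge trim")
  idx <- seq.int(trim + 1L, nt - trim)
  p <- vapply(montage, function(ch)
    mean(rms_per_second(segment$samples[ch, idx], segment$sample_rate)),
    numeric(1))
  parsed <- parse_channel_label(montage)
  powers <- data.frame(muscle = factor(parsed$muscle, levels = emg_muscles),
                       side = parsed$side, power = unname(p),
                       stringsAsFactors = FALSE)
  structure(list(powers = powers,
                 total_right = sum(powers$power[powers$side == "right"]),
                 total_left = sum(powers$power[powers$side == "left"]),
                 n_muscles = length(emg_muscles)),
            class = "muscle_powers")
}

#' Construct a muscle_powers object from per-side power vectors
#'
#' Mostly useful for analysis of externally computed powers and for
#' property checks; \code{\link{trial_powers}} builds the same object from
#' a trial segment.
#'
#' @param right,left Nonnegative length-9 vectors of per-muscle powers in
#'   canonical muscle order (names, if present, must match
#'   \code{emg_muscles}).
#' @return A \code{muscle_powers} object.
#' @export
muscle_powers <- function(right, left) {
  for (v in list(right, left)) {
    if (length(v) != length(emg_muscles) || any(v < 0) || anyNA(v))
      stop("each side needs ", length(emg_muscles),
           " nonnegative power values")
    if (!is.null(names(v)) && !identical(names(v), emg_muscles))
      stop("power names must match canonical muscle order")
  }
  powers <- data.frame(muscle = factor(rep(emg_muscles, 2L), levels = emg_muscles),
                       side = rep(c("right", "left"), each = length(emg_muscles)),
                       power = c(unname(right), unname(left)),
                       stringsAsFactors = FALSE)
  structure(list(powers = powers, total_right = sum(right),
                 total_left = sum(left), n_muscles = length(emg_muscles)),
            class = "muscle_powers")
}

#' Coordination coefficients of a trial
#'
#' Each muscle's power is re-expressed as its fraction of the side total:
#' a_i = P_i / P_r for the right side, b_i = P_i / P_l for the left. Each
#' vector is nonnegative and sums to 1, describing how the side's total
#' electrical power is divided among its muscles.
#'
#' @param powers A \code{muscle_powers} object.
#' @return An object of class \code{coordination_coefficients} with fields
#'   \code{a} (right) and \code{b} (left), each a named length-9 vector in
#'   canonical muscle order.
#' @export
coordination_coefficients <- function(powers) {
  stopifnot(inherits(powers, "muscle_powers"))
  if (powers$total_right <= 0 || powers$total_left <= 0) {
    bad <- c("right", "left")[c(powers$total_right <= 0, powers$total_left <= 0)]
    stop("degenerate side (zero total power): ", paste(bad, collapse = ", "),
         "; coordination coefficients undefined")
  }
  pw <- powers$powers
  ord_r <- pw$side == "right"
  a <- stats::setNames(pw$power[ord_r], as.character(pw$muscle[ord_r]))[emg_muscles]
  b_raw <- stats::setNames(pw$power[!ord_r], as.character(pw$muscle[!ord_r]))[emg_muscles]
  structure(list(a = a / powers$total_right, b = b_raw / powers$total_left,
                 muscles = emg_muscles),
            class = "coordination_coefficients")
}

#' Effective Strength Balance (ESB)
#'
#' Normalized difference of the total electrical power of the two sides:
#' \code{(P_r - P_l) / (P_r + P_l)}, in [-1, 1]. 0 means equal power on both
#' sides; +1/-1 means total dominance of the right/left side.
#'
#' @param p_r,p_l Nonnegative side totals, not both zero.
#' @return ESB value in \code{[-1, 1]}.
#' @examples
#' effective_strength_balance(3, 1)   # right side dominant: 0.5
#' effective_strength_balance(2, 2)   # balanced: 0
#' @export
effective_strength_balance <- function(p_r, p_l) {
  if (p_r < 0 || p_l < 0) stop("side powers must be nonnegative")
  if (p_r + p_l <= 0) stop("both side powers are zero: ESB undefined")
  (p_r - p_l) / (p_r + p_l)
}

#' Muscle Coordination Similarity (MCS)
#'
#' Pearson product-moment correlation between the two sides' coordination
#' coefficient vectors, evaluated in its summation form over the n muscle
#' pairs:
#' \deqn{MCS = \frac{n\sum a_i b_i - \sum a_i \sum b_i}{
#'   \sqrt{n\sum a_i^2 - (\sum a_i)^2}\sqrt{n\sum b_i^2 - (\sum b_i)^2}}}
#' MCS = 1 is perfect muscle mirroring; 0 a loss of between-side correlation;
#' negative values mean symmetric muscles have switched roles.
#'
#' @param a,b Equal-length (n >= 3) coefficient vectors, or a single
#'   \code{coordination_coefficients} object passed as \code{a}.
#' @return MCS in \code{[-1, 1]}, or \code{NA} (with a warning) when either
#'   vector has zero variance, in which case the correlation is undefined.
#' @examples
#' a <- c(0.5, 0.3, 0.2)
#' muscle_coordination_similarity(a, a)       # perfect mirroring: 1
#' muscle_coordination_similarity(a, rev(a))  # reversed roles: -13/14
#' @export
muscle_coordination_similarity <- function(a, b = NULL) {
  if (inherits(a, "coordination_coefficients")) {
    b <- a$b
    a <- a$a
  }
  if (length(a) != length(b))
    stop("coefficient vectors differ in length (", length(a), " vs ",
         length(b), ")")
  n <- length(a)
  if (n < 3L) stop("need at least 3 muscle pairs")
  den_a <- n * sum(a^2) - sum(a)^2
  den_b <- n * sum(b^2) - sum(b)^2
  # tolerance relative to the squared scale of the vector: constant vectors
  # make the correlation undefined
  if (den_a <= 1e-14 * max(sum(a^2), 1e-300) ||
      den_b <= 1e-14 * max(sum(b^2), 1e-300)) {
    warning("zero variance in a coefficient vector: MCS undefined")
    return(NA_real_)
  }
  mcs <- (n * sum(a * b) - sum(a) * sum(b)) / (sqrt(den_a) * sqrt(den_b))
  # guard against floating-point overshoot of the Cauchy-Schwarz bound
  min(1, max(-1, mcs))
}

#' Per-trial symmetry indexes
#'
#' Composes \code{\link{trial_powers}}, \code{\link{coordination_coefficients}}
#' and both indexes into one record. When one side has zero total power the
#' trial is still scored: ESB is exactly +1 or -1 and MCS is undefined
#' (\code{NA}); when both sides are zero the trial is rejected.
#'
#' @param segment A \code{trial_segment} (preprocessed or raw).
#' @param config An \code{\link{emg_config}}.
#' @return One-row data.frame: \code{subject_id}, \code{group},
#'   \code{sias_level}, \code{motion}, \code{trial_index}, \code{esb},
#'   \code{mcs}.
#' @export
trial_indexes <- function(segment, config = emg_config()) {
  pw <- trial_powers(segment, config)
  if (pw$total_right <= 0 && pw$total_left <= 0)
    stop("trial rejected: zero power on both sides (subject ",
         segment$meta$subject_id, ", ", segment$motion, ")")
  esb <- effective_strength_balance(pw$total_right, pw$total_left)
  if (pw$total_right <= 0 || pw$total_left <= 0) {
    mcs <- NA_real_
  } else {
    mcs <- muscle_coordination_similarity(coordination_coefficients(pw))
  }
  m <- segment$meta
  data.frame(subject_id = m$subject_id, group = m$group,
             sias_level = m$sias_level, motion = segment$motion,
             trial_index = segment$trial_index, esb = esb, mcs = mcs,
             stringsAsFactors = FALSE)
}

#' Index records for every annotated trial of a session
#'
#' Preprocesses the session (if raw) and scores each annotated trial.
#' Trial indexes are numbered per motion in annotation order.
#'
#' @param session An \code{emg_session}.
#' @param config An \code{\link{emg_config}}.
#' @return data.frame of per-trial index records.
#' @export
session_indexes <- function(session, config = emg_config()) {
  stopifnot(inherits(session, "emg_session"))
  if (nrow(session$annotations) == 0L) stop("session has no trial annotations")
  session <- preprocess_session(session, config)
  recs <- lapply(seq_len(nrow(session$annotations)), function(i)
    trial_indexes(trial_segment(session, i), config))
  out <- do.call(rbind, recs)
  out$trial_index <- stats::ave(seq_len(nrow(out)), out$motion, FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Coordination coefficients for every annotated trial, long format
#'
#' @param session An \code{emg_session}.
#' @param config An \code{\link{emg_config}}.
#' @return data.frame with one row per (trial, muscle, side): columns
#'   \code{subject_id}, \code{group}, \code{sias_level}, \code{motion},
#'   \code{trial_index}, \code{muscle}, \code{side}, \code{side_role},
#'   \code{coefficient}. Trials with a zero-power side are skipped with a
#'   warning. Side roles follow \code{\link{side_role_map}}.
#' @export
session_coefficients <- function(session, config = emg_config()) {
  stopifnot(inherits(session, "emg_session"))
  session <- preprocess_session(session, config)
  roles <- side_role_map(session$meta)
  recs <- list()
  for (i in seq_len(nrow(session$annotations))) {
    seg <- trial_segment(session, i)
    pw <- trial_powers(seg, config)
    if (pw$total_right <= 0 || pw$total_left <= 0) {
      warning("skipping trial ", i, ": zero-power side")
      next
    }
    cc <- coordination_coefficients(pw)
    m <- session$meta
    recs[[length(recs) + 1L]] <- data.frame(
      subject_id = m$subject_id, group = m$group, sias_level = m$sias_level,
      motion = seg$motion, trial_index = i,
      muscle = rep(emg_muscles, 2L),
      side = rep(c("right", "left"), each = length(emg_muscles)),
      side_role = rep(c(roles[["right"]], roles[["left"]]),
                      each = length(emg_muscles)),
      coefficient = c(cc$a, cc$b), stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) stop("no scoreable trials in session")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Map body sides to analysis roles
#'
#' Healthy subjects' sides are labelled dominant/non-dominant; stroke
#' patients' sides non-paretic/paretic, so that the affected (or
#' non-dominant) arm is comparable across groups.
#'
#' @param meta A \code{subject_meta}.
#' @return Named character vector mapping \code{"right"} and \code{"left"}
#'   to their role for this subject.
#' @export
side_role_map <- function(meta) {
  stopifnot(inherits(meta, "subject_meta"))
  if (meta$group == "stroke") {
    if (meta$paretic_side == "right") c(right = "paretic", left = "non_paretic")
    else c(right = "non_paretic", left = "paretic")
  } else {
    if (meta$dominant_side == "right") c(right = "dominant", left = "non_dominant")
    else c(right = "non_dominant", left = "dominant")
  }
}
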