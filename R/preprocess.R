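#' Preprocessing configuration
#'
#' Parameters of the sEMG conditioning chain. Defaults follow the protocol:
#' 20 Hz high-pass to remove motion artifacts, full-wave rectification, 32 Hz
#' low-pass to retain the contraction envelope, both as fifth-order
#' Butterworth filters, followed by division of the whole session by the
#' pooled median of the envelope over all channels and samples.
#'
#' @param hp_cutoff_hz High-pass cutoff (Hz), default 20.
#' @param lp_cutoff_hz Low-pass cutoff (Hz), default 32.
#' @param filter_order Butterworth order for both stages, default 5.
#' @param zero_phase Apply each filter forward and backward (no group delay;
#'   attenuation doubled in dB). Default \code{TRUE}: envelope timing symmetry
#'   between body sides matters for power integration.
#' @param standardization_mode \code{"pooled"} (one session-global median) or
#'   \code{"per_channel"} (sensitivity-analysis mode; erases between-muscle
#'   power ratios, so coefficients become uninformative).
#' @param standardize_stage \code{"envelope"} (after the low-pass, default) or
#'   \code{"rectified"} (before it).
#' @param edge_trim_s Seconds excluded at each end of a trial before power
#'   integration, to drop filter edge transients. Default 1.
#' @return A list of class \code{emg_config}.
#' @export
emg_config <- function(hp_cutoff_hz = 20, lp_cutoff_hz = 32, filter_order = 5,
                       zero_phase = TRUE,
                       standardization_mode = c("pooled", "per_channel"),
                       standardize_stage = c("envelope", "rectified"),
                       edge_trim_s = 1.0) {
  structure(list(hp_cutoff_hz = hp_cutoff_hz, lp_cutoff_hz = lp_cutoff_hz,
                 filter_order = filter_order, zero_phase = zero_phase,
                 standardization_mode = match.arg(standardization_mode),
                 standardize_stage = match.arg(standardize_stage),
                 edge_trim_s = edge_trim_s),
            class = "emg_config")
}

#' Butterworth filter specification
#'
#' @param kind \code{"highpass"} or \code{"lowpass"}.
#' @param cutoff Cutoff frequency in Hz (0 < cutoff < Nyquist).
#' @param order Filter order (>= 1), default 5.
#' @param zero_phase Forward-backward application, default \code{TRUE}.
#' @return A list of class \code{filter_spec}.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass"), cutoff, order = 5L,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive (Hz)")
  if (order < 1) stop("order must be >= 1")
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply a Butterworth filter to a 1-D signal
#'
#' Single-pass filtering has the standard monotonic Butterworth magnitude
#' response (-3 dB at the cutoff); with \code{zero_phase} the filter runs
#' forward and backward, giving zero phase distortion and doubled attenuation
#' in dB.
#'
#' @param x Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param spec A \code{\link{filter_spec}}.
#' @return Filtered vector, same length as \code{x}.
#' @export
butterworth_filter <- function(x, sample_rate, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- sample_rate / 2
  if (spec$cutoff >= nyq)
    stop("cutoff (", spec$cutoff, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  if (length(x) <= 3L * spec$order)
    stop("signal too short for order-", spec$order, " filtering (need > ",
         3L * spec$order, " samples)")
  bf <- signal::butter(spec$order, spec$cutoff / nyq,
                       type = if (spec$kind == "highpass") "high" else "low")
  if (spec$zero_phase) as.numeric(signal::filtfilt(bf, x))
  else as.numeric(signal::filter(bf, x))
}

#' Full-wave rectification
#'
#' @param x Numeric vector.
#' @return \code{abs(x)}.
#' @export
rectify <- function(x) abs(x)

envelope_chain <- function(x, sample_rate, config) {
  hp <- filter_spec("highpass", config$hp_cutoff_hz, config$filter_order,
                    config$zero_phase)
  lp <- filter_spec("lowpass", config$lp_cutoff_hz, config$filter_order,
                    config$zero_phase)
  env <- butterworth_filter(rectify(butterworth_filter(x, sample_rate, hp)),
                            sample_rate, lp)
  # the low-pass of a rectified signal can overshoot below zero near sharp
  # transients; powers must be nonnegative
  pmax(env, 0)
}

#' Preprocess one trial segment
#'
#' Per channel: high-pass, rectify, low-pass, clip negative low-pass
#' overshoot to zero. Channel count and length are unchanged. Session-level
#' standardization is a separate step (\code{\link{preprocess_session}});
#' it cancels in the symmetry indexes, so per-trial analysis may skip it.
#'
#' @param segment A raw \code{trial_segment}.
#' @param config An \code{\link{emg_config}}.
#' @return The segment with envelope samples and \code{preprocessed = TRUE}.
#' @export
preprocess_trial <- function(segment, config = emg_config()) {
  stopifnot(inherits(segment, "trial_segment"))
  if (segment$preprocessed) return(segment)
  segment$samples <- t(apply(segment$samples, 1L, envelope_chain,
                             sample_rate = segment$sample_rate,
                             config = config))
  segment$preprocessed <- TRUE
  segment
}

#' Standardize a session of envelopes by its median amplitude
#'
#' Divides every channel by one session-global scalar: the median of the
#' pooled envelope samples over all channels and all time points. A pooled
#' (not per-channel) median preserves the between-muscle power ratios on
#' which the coordination coefficients depend.
#'
#' @param envelopes Numeric matrix, channels x time (nonnegative envelopes).
#' @param mode \code{"pooled"} or \code{"per_channel"}.
#' @return List with \code{samples} (scaled matrix) and \code{scale} (the
#'   divisor; a vector of per-channel medians in per-channel mode).
#' @export
standardize_session <- function(envelopes, mode = c("pooled", "per_channel")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(envelopes), is.numeric(envelopes))
  if (all(envelopes == 0)) stop("all-zero session: standardization scale undefined")
  if (mode == "pooled") {
    scale <- stats::median(envelopes)
    if (scale <= 0) stop("pooled median is zero: standardization scale undefined")
    list(samples = envelopes / scale, scale = scale)
  } else {
    scale <- apply(envelopes, 1L, stats::median)
    if (any(scale <= 0)) stop("zero per-channel median: scale undefined")
    list(samples = envelopes / scale, scale = scale)
  }
}

#' Preprocess a whole session
#'
#' Runs the envelope chain over every channel of the continuous recording,
#' then standardizes by the session median. Trial segments extracted
#' afterwards are already preprocessed.
#'
#' @param session An \code{emg_session} with raw samples.
#' @param config An \code{\link{emg_config}}.
#' @return The session with envelope samples; the standardization scalar is
#'   stored as attribute \code{"standardization_scale"} and
#'   \code{session$preprocessed} is set.
#' @export
preprocess_session <- function(session, config = emg_config()) {
  stopifnot(inherits(session, "emg_session"))
  if (isTRUE(session$preprocessed)) return(session)
  env <- t(apply(session$samples, 1L, envelope_chain,
                 sample_rate = session$sample_rate, config = config))
  if (config$standardize_stage == "rectified") {
    # standardize the rectified (pre-LP) amplitudes instead of the envelope
    hp <- filter_spec("highpass", config$hp_cutoff_hz, config$filter_order,
                      config$zero_phase)
    rect <- t(apply(session$samples, 1L, function(x)
      rectify(butterworth_filter(x, session$sample_rate, hp))))
    ref <- standardize_session(rect, config$standardization_mode)$scale
    std <- list(samples = env / ref, scale = ref)
  } else {
    std <- standardize_session(env, config$standardization_mode)
  }
  session$samples <- std$samples
  rownames(session$samples) <- session$channels
  session$preprocessed <- TRUE
  attr(session, "standardization_scale") <- std$scale
  session
}
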