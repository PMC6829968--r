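#' Ground-truth coordination presets for the two motions
#'
#' Length-9 weight vectors (canonical muscle order, summing to 1) describing
#' how each motion distributes power among the nine muscles of one side:
#' elbow flexion loads the elbow flexors (brachioradialis, biceps), steering
#' loads the shoulder girdle (deltoids, pectoralis).
#'
#' @param motion \code{"elbow_flexion"} or \code{"steering"}.
#' @return Named numeric vector of length 9 summing to 1.
#' @export
motion_coordination <- function(motion = c("elbow_flexion", "steering")) {
  motion <- match.arg(motion)
  w <- switch(motion,
    elbow_flexion = c(BR = 0.20, PT = 0.10, B = 0.25, T = 0.05, AD = 0.12,
                      PD = 0.05, PEC = 0.08, IS = 0.08, ES = 0.07),
    steering = c(BR = 0.08, PT = 0.08, B = 0.10, T = 0.12, AD = 0.18,
                 PD = 0.12, PEC = 0.12, IS = 0.10, ES = 0.10))
  w[emg_muscles]
}

#' Specification of one synthetic bimanual trial
#'
#' Each channel of side s is amplitude-modulated band-limited Gaussian noise:
#' \code{gain_s * w_i * E(t) * G_i(t) + floor * G'_i(t)}, where \code{w_i} is
#' the side's coordination weight for muscle i, \code{E(t)} a smooth
#' raised-cosine burst envelope repeating at the motion frequency (shared by
#' all channels: it is the motion itself), and \code{G}, \code{G'} are
#' independent zero-mean unit-variance noise carriers band-limited to
#' 20--450 Hz. The baseline-noise amplitude \code{floor} is
#' \code{noise_floor} times the amplitude of a unit-gain channel of average
#' weight (\code{mean(weights)}, i.e. 1/9): baseline noise models the
#' acquisition chain and does not scale with contraction strength.
#'
#' @param motion Motion label, sets the default coordination vectors.
#' @param motion_freq Burst repetition frequency in Hz, default 0.25 (one
#'   cycle per 4 s).
#' @param duration Trial duration in seconds, default 20.
#' @param sample_rate Hz, default 1000.
#' @param coordination_right,coordination_left Length-9 nonnegative vectors
#'   summing to 1 (ground-truth a and b).
#' @param gain_right,gain_left Positive side amplitude scalars.
#' @param burst_duty Active fraction of each cycle, in (0, 1], default 0.5.
#' @param noise_floor Baseline noise amplitude relative to the mean active
#'   channel amplitude, default 0.05.
#' @param jitter_sd Burst-onset timing jitter (s), default 0.05.
#' @param seed Integer seed; same seed gives bit-identical trials.
#' @return A list of class \code{trial_spec}.
#' @examples
#' # a short trial with the right side driven at twice the left gain
#' seg <- generate_trial(trial_spec(seed = 1, duration = 4,
#'                                  sample_rate = 250, gain_right = 2))
#' trial_indexes(seg)[, c("esb", "mcs")]
#' @export
trial_spec <- function(motion = "elbow_flexion", motion_freq = 0.25,
                       duration = 20, sample_rate = 1000,
                       coordination_right = motion_coordination(motion),
                       coordination_left = motion_coordination(motion),
                       gain_right = 1, gain_left = 1, burst_duty = 0.5,
                       noise_floor = 0.05, jitter_sd = 0.05, seed = 1L) {
  check_coord <- function(w, name) {
    if (length(w) != length(emg_muscles) || any(w < 0) ||
        abs(sum(w) - 1) > 1e-8)
      stop(name, " must be a nonnegative length-", length(emg_muscles),
           " vector summing to 1")
  }
  check_coord(coordination_right, "coordination_right")
  check_coord(coordination_left, "coordination_left")
  if (gain_right <= 0 || gain_left <= 0) stop("gains must be positive")
  if (burst_duty <= 0 || burst_duty > 1) stop("burst_duty must be in (0, 1]")
  if (motion_freq <= 0 || duration <= 0 || sample_rate <= 0)
    stop("motion_freq, duration and sample_rate must be positive")
  if (noise_floor < 0 || jitter_sd < 0)
    stop("noise_floor and jitter_sd must be nonnegative")
  structure(list(motion = match.arg(motion, c("elbow_flexion", "steering")),
                 motion_freq = motion_freq, duration = duration,
                 sample_rate = sample_rate,
                 coordination_right = unname(coordination_right),
                 coordination_left = unname(coordination_left),
                 gain_right = gain_right, gain_left = gain_left,
                 burst_duty = burst_duty, noise_floor = noise_floor,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "trial_spec")
}

# raised-cosine burst train: one smooth pulse per motion cycle, onsets
# jittered; shared by every channel of a trial
burst_envelope <- function(n, sample_rate, freq, duty, jitter_sd) {
  t <- (seq_len(n) - 1L) / sample_rate
  period <- 1 / freq
  width <- duty * period
  onsets <- seq(0, t[n], by = period)
  onsets <- onsets + stats::rnorm(length(onsets), 0, jitter_sd)
  env <- numeric(n)
  for (on in onsets) {
    i0 <- max(1L, ceiling(on * sample_rate) + 1L)
    i1 <- min(n, floor((on + width) * sample_rate) + 1L)
    if (i1 < i0) next
    ph <- (t[i0:i1] - on) / width
    env[i0:i1] <- env[i0:i1] + 0.5 * (1 - cos(2 * pi * ph))
  }
  env
}

# band-limited (20-450 Hz, capped below Nyquist) unit-variance Gaussian
# noise carrier, synthesized spectrally: white Gaussian noise with all
# Fourier bins outside the band zeroed (ideal band limitation)
bandlimited_noise <- function(n, sample_rate, band = c(20, 450)) {
  hi <- min(band[2], 0.45 * sample_rate)
  if (hi <= band[1]) stop("sample rate too low for the 20 Hz noise band")
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * sample_rate / n
  X[f < band[1] | f > hi] <- 0+0i
  g <- Re(stats::fft(X, inverse = TRUE)) / n
  g / stats::sd(g)
}

#' Generate one synthetic raw trial
#'
#' @param spec A \code{\link{trial_spec}}.
#' @param meta Optional \code{subject_meta} attached to the segment (default
#'   a placeholder healthy subject).
#' @return A raw \code{trial_segment} with the full 18-channel montage; the
#'   generating parameters are attached as attribute \code{"ground_truth"}
#'   (list: \code{coordination_right}, \code{coordination_left},
#'   \code{gain_right}, \code{gain_left}).
#' @export
generate_trial <- function(spec, meta = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  if (is.null(meta))
    meta <- subject_meta("SYN", "healthy_young", dominant_side = "right")
  set.seed(spec$seed)
  seg <- generate_trial_samples(spec, meta)
  seg
}

# generation body, using the current RNG state (callers control seeding)
generate_trial_samples <- function(spec, meta, trial_index = NA_integer_) {
  n <- as.integer(round(spec$duration * spec$sample_rate))
  env <- burst_envelope(n, spec$sample_rate, spec$motion_freq,
                        spec$burst_duty, spec$jitter_sd)
  weights <- rbind(right = spec$coordination_right,
                   left = spec$coordination_left)
  gains <- c(right = spec$gain_right, left = spec$gain_left)
  # baseline noise is a property of the acquisition chain, independent of
  # contraction strength: referenced to a unit-gain active channel
  floor_amp <- spec$noise_floor * mean(weights)
  montage <- full_montage()
  samples <- matrix(0, nrow = length(montage), ncol = n,
                    dimnames = list(montage, NULL))
  for (side in emg_sides) {
    for (i in seq_along(emg_muscles)) {
      ch <- channel_label(emg_muscles[i], side)
      carrier <- bandlimited_noise(n, spec$sample_rate)
      floor_noise <- bandlimited_noise(n, spec$sample_rate)
      samples[ch, ] <- gains[side] * weights[side, i] * env * carrier +
        floor_amp * floor_noise
    }
  }
  seg <- new_trial_segment(samples, montage, spec$sample_rate, meta,
                           motion = spec$motion, trial_index = trial_index)
  attr(seg, "ground_truth") <- list(
    coordination_right = spec$coordination_right,
    coordination_left = spec$coordination_left,
    gain_right = spec$gain_right, gain_left = spec$gain_left)
  seg
}

#' Impairment profile for cohort simulation
#'
#' Operationalizes severity along the two axes the indexes are designed to
#' dissociate: a coordination perturbation (additive Gaussian noise on the
#' affected side's weight vector, floored at 0 and renormalized) and a
#' strength deficit (paretic/non-paretic amplitude gain ratio, drawn once
#' per subject).
#'
#' @param label \code{"healthy"} or an integer SIAS-like level 1--5 (lower =
#'   more severe).
#' @param coordination_noise_sd SD of the per-trial additive perturbation of
#'   the affected side's coordination vector.
#' @param strength_ratio_mean,strength_ratio_sd Median and log-scale SD of
#'   the subject-level affected/unaffected gain ratio, drawn from a
#'   lognormal (a strictly positive amplitude ratio whose spread grows
#'   multiplicatively with severity).
#' @return A list of class \code{impairment_profile}.
#' @export
impairment_profile <- function(label, coordination_noise_sd,
                               strength_ratio_mean, strength_ratio_sd) {
  if (coordination_noise_sd < 0 || strength_ratio_sd < 0 ||
      strength_ratio_mean <= 0)
    stop("invalid impairment profile parameters")
  structure(list(label = label,
                 coordination_noise_sd = coordination_noise_sd,
                 strength_ratio_mean = strength_ratio_mean,
                 strength_ratio_sd = strength_ratio_sd),
            class = "impairment_profile")
}

#' Default cohort profiles
#'
#' Illustrative severity ladder: healthy subjects have near-symmetric gains
#' and minimal coordination noise; SIAS levels 5 down to 1 have progressively
#' larger coordination perturbations and gain ratios progressively further
#' below 1, with progressively larger between-subject spread. No quantitative
#' per-level effect sizes are available to calibrate against, so the ladder
#' encodes only the qualitative ordering (severity monotonicity).
#'
#' @return Named list of \code{\link{impairment_profile}} objects:
#'   \code{healthy_young}, \code{healthy_elder}, \code{sias_5} .. \code{sias_1}.
#' @export
default_profiles <- function() {
  list(
    healthy_young = impairment_profile("healthy", 0.010, 0.95, 0.03),
    healthy_elder = impairment_profile("healthy", 0.012, 0.94, 0.04),
    sias_5 = impairment_profile(5L, 0.02, 0.85, 0.08),
    sias_4 = impairment_profile(4L, 0.04, 0.70, 0.14),
    sias_3 = impairment_profile(3L, 0.07, 0.55, 0.24),
    sias_2 = impairment_profile(2L, 0.12, 0.40, 0.40),
    sias_1 = impairment_profile(1L, 0.22, 0.25, 0.70))
}

#' Perturb a coordination vector
#'
#' Adds iid Gaussian noise to each weight, floors at zero and renormalizes
#' to sum 1 (keeping the vector a valid coefficient vector).
#'
#' @param w Nonnegative weight vector summing to 1.
#' @param sd Perturbation SD.
#' @return Perturbed vector of the same length, summing to 1.
#' @export
perturb_coordination <- function(w, sd) {
  if (sd == 0) return(w)
  v <- pmax(w + stats::rnorm(length(w), 0, sd), 0)
  if (sum(v) <= 0) v <- rep(1 / length(w), length(w))
  v / sum(v)
}

#' Generate a synthetic cohort of sessions
#'
#' For each group, draws per-subject parameters once (gain ratio, paretic or
#' dominant side) and generates fresh per-trial noise: each trial perturbs
#' the affected side's coordination vector by the profile's SD (the
#' unaffected side by a small physiological baseline of 0.01) and jitters
#' both gains by a small per-trial coefficient of variation. Trials of the
#' requested motions are interleaved in randomized order and separated by
#' rest periods containing only baseline noise. Subject-level draws and
#' sample-level noise use separate derived seeds, so the cohort structure is
#' reproducible independent of trial count.
#'
#' @param profiles Named list: group name -> list(n_subjects, n_trials
#'   (per motion), profile = \code{\link{impairment_profile}}). Group names
#'   must start with \code{healthy_young}, \code{healthy_elder} or
#'   \code{sias_<level>} (the latter become stroke subjects).
#' @param seed Integer master seed.
#' @param motions Motions each subject performs.
#' @param duration,sample_rate,rest_s Trial length, sampling rate, and rest
#'   between trials (seconds); protocol defaults 20 s / 1000 Hz / 20 s.
#' @param noise_floor,burst_duty,jitter_sd Passed to \code{\link{trial_spec}}.
#' @param trial_gain_cv Per-trial multiplicative gain jitter (lognormal CV),
#'   default 0.03.
#' @return List of \code{emg_session} objects, each carrying a ground-truth
#'   attribute (per-trial true coordination vectors and gains).
#' @export
generate_cohort <- function(profiles, seed = 1L,
                            motions = c("elbow_flexion", "steering"),
                            duration = 20, sample_rate = 1000, rest_s = 20,
                            noise_floor = 0.05, burst_duty = 0.5,
                            jitter_sd = 0.05, trial_gain_cv = 0.03) {
  if (length(profiles) == 0L) stop("empty profile map")
  motions <- match.arg(motions, several.ok = TRUE)
  set.seed(seed)
  sessions <- list()
  for (gname in names(profiles)) {
    gp <- profiles[[gname]]
    if (is.null(gp$n_subjects) || gp$n_subjects < 1L)
      stop("profile '", gname, "' needs n_subjects >= 1")
    prof <- gp$profile
    stopifnot(inherits(prof, "impairment_profile"))
    is_stroke <- !identical(prof$label, "healthy")
    for (s in seq_len(gp$n_subjects)) {
      # subject-level draws (master stream); lognormal keeps the amplitude
      # ratio positive and its spread multiplicative
      ratio <- stats::rlnorm(1, log(prof$strength_ratio_mean),
                             prof$strength_ratio_sd)
      affected <- if (is_stroke) sample(emg_sides, 1L) else "left"
      meta <- if (is_stroke)
        subject_meta(sprintf("%s_S%02d", toupper(gname), s), "stroke",
                     sias_level = as.integer(prof$label),
                     paretic_side = affected)
      else
        subject_meta(sprintf("%s_S%02d", toupper(gname), s),
                     if (grepl("young", gname)) "healthy_young" else "healthy_elder",
                     dominant_side = "right")
      n_tr <- gp$n_trials * length(motions)
      trial_motions <- sample(rep(motions, gp$n_trials))
      trial_seeds <- sample.int(.Machine$integer.max - 1L, n_tr + 1L)
      sessions[[length(sessions) + 1L]] <- assemble_session(
        meta, trial_motions, trial_seeds, affected, ratio, prof,
        duration = duration, sample_rate = sample_rate, rest_s = rest_s,
        noise_floor = noise_floor, burst_duty = burst_duty,
        jitter_sd = jitter_sd, trial_gain_cv = trial_gain_cv)
    }
  }
  sessions
}

assemble_session <- function(meta, trial_motions, trial_seeds, affected,
                             ratio, prof, duration, sample_rate, rest_s,
                             noise_floor, burst_duty, jitter_sd,
                             trial_gain_cv) {
  n_tr <- length(trial_motions)
  n_trial <- as.integer(round(duration * sample_rate))
  n_rest <- as.integer(round(rest_s * sample_rate))
  montage <- full_montage()
  blocks <- vector("list", 2L * n_tr - 1L)
  ann <- data.frame(motion = character(), start_sample = integer(),
                    end_sample = integer(), stringsAsFactors = FALSE)
  truth <- vector("list", n_tr)
  pos <- 0L
  sdlog <- sqrt(log(1 + trial_gain_cv^2))
  for (k in seq_len(n_tr)) {
    set.seed(trial_seeds[k])
    base <- motion_coordination(trial_motions[k])
    # affected side takes the profile's perturbation; the other side a small
    # physiological baseline
    w <- list(right = perturb_coordination(base, if (affected == "right")
      prof$coordination_noise_sd else 0.01),
      left = perturb_coordination(base, if (affected == "left")
        prof$coordination_noise_sd else 0.01))
    g <- c(right = 1, left = 1)
    g[affected] <- ratio
    g <- g * stats::rlnorm(2L, -sdlog^2 / 2, sdlog)
    spec <- trial_spec(motion = trial_motions[k], duration = duration,
                       sample_rate = sample_rate,
                       coordination_right = w$right,
                       coordination_left = w$left,
                       gain_right = g[["right"]], gain_left = g[["left"]],
                       burst_duty = burst_duty, noise_floor = noise_floor,
                       jitter_sd = jitter_sd, seed = trial_seeds[k])
    seg <- generate_trial_samples(spec, meta, trial_index = k)
    blocks[[2L * k - 1L]] <- seg$samples
    ann <- rbind(ann, data.frame(motion = trial_motions[k],
                                 start_sample = pos + 1L,
                                 end_sample = pos + n_trial,
                                 stringsAsFactors = FALSE))
    truth[[k]] <- attr(seg, "ground_truth")
    pos <- pos + n_trial
    if (k < n_tr && n_rest > 0L) {
      floor_amp <- noise_floor * mean(c(w$right, w$left))
      rest <- t(vapply(seq_along(montage), function(j)
        floor_amp * bandlimited_noise(n_rest, sample_rate), numeric(n_rest)))
      blocks[[2L * k]] <- rest
      pos <- pos + n_rest
    }
  }
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  sess <- emg_session(do.call(cbind, blocks), montage, sample_rate, meta, ann)
  attr(sess, "ground_truth") <- truth
  sess
}

#' Write the ground-truth sidecar of a generated session
#'
#' Serializes the per-trial true coordination vectors and gains to
#' \code{<path>.truth.yaml}, so downstream metrics can be benchmarked
#' against the generating parameters.
#'
#' @param session A session produced by \code{\link{generate_cohort}}.
#' @param path The session CSV path (the truth file sits next to it).
#' @return The truth-file path, invisibly.
#' @export
write_ground_truth <- function(session, path) {
  truth <- attr(session, "ground_truth")
  if (is.null(truth)) stop("session carries no ground truth")
  out <- paste0(sub("\\.csv$", "", path), ".truth.yaml")
  yaml::write_yaml(lapply(truth, function(tr) list(
    coordination_right = as.numeric(tr$coordination_right),
    coordination_left = as.numeric(tr$coordination_left),
    gain_right = tr$gain_right, gain_left = tr$gain_left)), out)
  invisible(out)
}

#' Index records for a list of sessions
#'
#' @param sessions List of \code{emg_session} objects.
#' @param config An \code{\link{emg_config}}.
#' @return Row-bound data.frame of per-trial index records.
#' @export
cohort_indexes <- function(sessions, config = emg_config()) {
  do.call(rbind, lapply(sessions, session_indexes, config = config))
}
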