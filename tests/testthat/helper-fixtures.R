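# shared fixtures: tiny subjects and hand-built segments

healthy_meta <- function(id = "HY01")
  subject_meta(id, "healthy_young", dominant_side = "right")

stroke_meta <- function(id = "ST01", sias = 3L, side = "left")
  subject_meta(id, "stroke", sias_level = sias, paretic_side = side)

# a preprocessed segment whose channels hold constant envelope values;
# amplitudes given as named per-channel values, unnamed channels are zero
constant_segment <- function(amplitudes, duration = 5, sample_rate = 50,
                             motion = "elbow_flexion", meta = healthy_meta()) {
  montage <- full_montage()
  n <- duration * sample_rate
  samples <- matrix(0, length(montage), n, dimnames = list(montage, NULL))
  for (ch in names(amplitudes)) samples[ch, ] <- amplitudes[[ch]]
  seg <- emgbilat:::new_trial_segment(samples, montage, sample_rate, meta,
                                      motion = motion, preprocessed = TRUE)
  seg
}

# a small raw session with sinusoidal content on every montage channel
toy_session <- function(n = 600, sample_rate = 100, meta = healthy_meta(),
                        annotations = data.frame(motion = "elbow_flexion",
                                                 start_sample = 1L,
                                                 end_sample = as.integer(n))) {
  montage <- full_montage()
  t <- (seq_len(n) - 1) / sample_rate
  samples <- t(vapply(seq_along(montage), function(i)
    (0.5 + 0.1 * i) * sin(2 * pi * 35 * t + i), numeric(n)))
  rownames(samples) <- montage
  emg_session(samples, montage, sample_rate, meta, annotations)
}

# random valid coefficient vector (nonnegative, sums to 1)
random_coefficients <- function(n = 9) {
  w <- stats::runif(n)
  w / sum(w)
}
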