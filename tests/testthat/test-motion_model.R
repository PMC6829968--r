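test_that("per-second RMS quantization", {
  fs <- 1000
  expect_equal(rms_per_second(rep(2, 5 * fs), fs), rep(2, 5))
  expect_length(rms_per_second(rnorm(20 * fs), fs), 20L)
  # unit sinusoid with whole cycles per window: RMS = 1/sqrt(2)
  t <- (0:(3 * fs - 1)) / fs
  r <- rms_per_second(sin(2 * pi * 10 * t), fs)
  expect_equal(r, rep(1 / sqrt(2), 3), tolerance = 1e-3)
  # trailing partial second dropped
  expect_length(rms_per_second(rep(1, 2 * fs + 400), fs), 2L)
  expect_error(rms_per_second(rnorm(500), fs), "shorter than one second")
})

test_that("trial powers sum per side and respect the montage", {
  seg <- constant_segment(list(B_RIGHT = 3, BR_RIGHT = 1, B_LEFT = 0.5))
  pw <- trial_powers(seg)
  expect_s3_class(pw, "muscle_powers")
  expect_equal(pw$total_right, 4)
  expect_equal(pw$total_left, 0.5)
  expect_equal(sum(pw$powers$power[pw$powers$side == "right"]),
               pw$total_right)
  # all-zero left side
  pw0 <- trial_powers(constant_segment(list(B_RIGHT = 2)))
  expect_equal(pw0$total_left, 0)
  # missing channel is a montage error naming the channel
  seg_m <- seg
  seg_m$samples <- seg_m$samples[-5, ]
  seg_m$channels <- seg_m$channels[-5]
  expect_error(trial_powers(seg_m), "missing channel.*AD_RIGHT")
})

test_that("trial powers track programmed per-muscle amplitudes", {
  spec <- trial_spec(seed = 11)
  pw <- trial_powers(preprocess_trial(generate_trial(spec)))
  p_r <- pw$powers$power[pw$powers$side == "right"]
  truth <- spec$coordination_right
  expect_equal(p_r / sum(p_r), truth, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("coordination coefficients normalize each side to 1", {
  eq <- muscle_powers(rep(2, 9), rep(5, 9))
  cc <- coordination_coefficients(eq)
  expect_equal(unname(cc$a), rep(1 / 9, 9))
  expect_equal(unname(cc$b), rep(1 / 9, 9))
  one <- muscle_powers(c(4, rep(0, 8)), rep(1, 9))
  expect_equal(unname(coordination_coefficients(one)$a),
               c(1, rep(0, 8)))
  mix <- muscle_powers(c(2, 1, 1, rep(0, 6)), rep(1, 9))
  expect_equal(unname(coordination_coefficients(mix)$a)[1:3],
               c(0.5, 0.25, 0.25))
  degen <- muscle_powers(rep(0, 9), rep(1, 9))
  expect_error(coordination_coefficients(degen), "degenerate side.*right")
})

test_that("ESB anchor values, arithmetic and antisymmetry", {
  expect_equal(effective_strength_balance(5, 5), 0)
  expect_equal(effective_strength_balance(5, 0), 1)
  expect_equal(effective_strength_balance(0, 5), -1)
  expect_equal(effective_strength_balance(3, 1), 0.5)
  for (i in 1:20) {
    p <- runif(2, 0, 10)
    expect_equal(effective_strength_balance(p[1], p[2]),
                 -effective_strength_balance(p[2], p[1]))
  }
  expect_error(effective_strength_balance(0, 0), "undefined")
  expect_error(effective_strength_balance(-1, 2), "nonnegative")
})

test_that("MCS anchor values and affine invariance", {
  a <- c(0.5, 0.3, 0.2)
  expect_equal(muscle_coordination_similarity(a, a), 1)
  # hand-computed Pearson on the 3 reversed pairs: -13/14
  expect_equal(muscle_coordination_similarity(a, rev(a)), -13 / 14,
               tolerance = 1e-12)
  b <- 0.6 * a + 0.4 / 3
  expect_equal(muscle_coordination_similarity(a, b / sum(b)), 1,
               tolerance = 1e-12)
  expect_error(muscle_coordination_similarity(a, c(0.5, 0.5)), "length")
  expect_warning(m <- muscle_coordination_similarity(rep(1 / 3, 3), a),
                 "zero variance")
  expect_true(is.na(m))
})

test_that("MCS summation form matches an independent correlation oracle", {
  set.seed(41)
  for (i in 1:200) {
    a <- random_coefficients()
    b <- random_coefficients()
    expect_equal(muscle_coordination_similarity(a, b), cor(a, b),
                 tolerance = 1e-12)
  }
})

test_that("dissociation: gain scaling moves ESB only, permutation MCS only", {
  set.seed(42)
  right <- runif(9, 0.1, 1)
  left <- runif(9, 0.1, 1)
  base <- muscle_powers(right, left)
  esb0 <- effective_strength_balance(base$total_right, base$total_left)
  mcs0 <- muscle_coordination_similarity(coordination_coefficients(base))
  esb_k <- vapply(c(0.5, 2, 10), function(k) {
    sc <- muscle_powers(right * k, left)
    mcs_k <- muscle_coordination_similarity(coordination_coefficients(sc))
    if (k %in% c(0.5, 2)) {
      expect_identical(mcs_k, mcs0)  # power-of-two scaling is float-exact
    } else {
      expect_equal(mcs_k, mcs0, tolerance = 1e-12)
    }
    effective_strength_balance(sc$total_right, sc$total_left)
  }, 0)
  expect_true(all(diff(c(
    effective_strength_balance(0.5 * sum(right), sum(left)), esb_k[2:3])) > 0))
  expect_gt(esb_k[2], esb0)
  expect_lt(esb_k[1], esb0)
  perm <- muscle_powers(right[c(9, 1:8)], left)
  expect_identical(
    effective_strength_balance(perm$total_right, perm$total_left), esb0)
  expect_false(isTRUE(all.equal(
    muscle_coordination_similarity(coordination_coefficients(perm)), mcs0)))
})

test_that("trial_indexes composes the model and flags degenerate sides", {
  seg <- constant_segment(list(B_RIGHT = 2, BR_RIGHT = 1),
                          meta = stroke_meta())
  rec <- trial_indexes(seg)
  expect_equal(rec$esb, 1)
  expect_true(is.na(rec$mcs))
  expect_equal(rec$group, "stroke")
  expect_error(trial_indexes(constant_segment(list())), "zero power on both")
})

test_that("normalization and bounds hold on random power vectors", {
  set.seed(7)
  for (i in 1:100) {
    pw <- muscle_powers(runif(9), runif(9))
    cc <- coordination_coefficients(pw)
    expect_equal(sum(cc$a), 1, tolerance = 1e-12)
    expect_equal(sum(cc$b), 1, tolerance = 1e-12)
    esb <- effective_strength_balance(pw$total_right, pw$total_left)
    expect_lte(abs(esb), 1)
    mcs <- muscle_coordination_similarity(cc)
    if (!is.na(mcs)) expect_lte(abs(mcs), 1)
  }
})

test_that("boxplot statistics follow the 1.5 IQR convention", {
  s <- tukey_box_stats(rep(0.1, 4))
  expect_equal(s$median, 0.1)
  expect_equal(s$q1, s$q3)
  expect_length(s$outliers, 0L)
  s2 <- tukey_box_stats(c(1, 2, 3, 100))
  expect_equal(s2$q1, 1.75)
  expect_equal(s2$q3, 27.25)
  expect_equal(s2$outliers, 100)
  expect_equal(s2$whisker_high, 3)
  expect_error(tukey_box_stats(c(1, 2)), "at least 4")
})

test_that("activity print summarizes per muscle and side role", {
  set.seed(3)
  coeffs <- data.frame(
    muscle = rep(rep(emg_muscles, each = 8), 2),
    side_role = rep(c("dominant", "non_dominant"), each = 8 * 9),
    coefficient = runif(2 * 8 * 9))
  ap <- activity_print(coeffs)
  expect_s3_class(ap, "activity_print")
  expect_equal(nrow(ap), 18L)
  expect_true(all(ap$q1 <= ap$median & ap$median <= ap$q3))
  expect_true(all(ap$whisker_low >= ap$q1 - 1.5 * (ap$q3 - ap$q1) - 1e-12))
  # permuting rows changes nothing
  ap2 <- activity_print(coeffs[sample(nrow(coeffs)), ])
  expect_equal(as.data.frame(ap2), as.data.frame(ap))
  expect_error(activity_print(coeffs[1:3, ]), "fewer than 4")
})

test_that("side roles map paretic and dominant arms correctly", {
  expect_equal(side_role_map(stroke_meta(side = "left")),
               c(right = "non_paretic", left = "paretic"))
  expect_equal(side_role_map(healthy_meta()),
               c(right = "dominant", left = "non_dominant"))
})
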