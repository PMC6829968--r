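test_that("exact rank-sum enumeration matches closed-form small cases", {
  rt <- ranksum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rt$p_value, 0.1)
  expect_equal(rt$method, "exact")
  # a sample against itself is maximally central
  self <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(self$p_value, 1)
  expect_error(ranksum_test(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("exact and normal branches agree on moderate samples", {
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(10)
    b <- rnorm(10, mean = runif(1, -1, 1))
    p_exact <- ranksum_test(a, b)$p_value
    p_norm <- ranksum_test(a, b, exact_max = 0L)$p_value
    expect_equal(ranksum_test(a, b)$method, "exact")
    expect_equal(ranksum_test(a, b, exact_max = 0L)$method, "normal")
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
  # above the threshold the normal branch is selected automatically
  expect_equal(ranksum_test(rnorm(15), rnorm(15))$method, "normal")
})

test_that("Holm step-down rejects per the sorted-threshold rule", {
  h <- holm_adjust(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(h$significant, c(TRUE, FALSE, FALSE))
  expect_equal(h$adjusted, c(0.03, 0.06, 0.06))
  expect_true(all(holm_adjust(rep(0, 4))$significant))
  expect_false(any(holm_adjust(rep(1, 4))$significant))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Holm is between no correction and Bonferroni", {
  set.seed(23)
  for (i in 1:25) {
    p <- runif(6)
    h <- holm_adjust(p)$adjusted
    expect_true(all(h >= p - 1e-15))
    expect_true(all(h <= pmin(1, length(p) * p) + 1e-15))
  }
})

test_that("cohort summary reports per-group SD and Holm-corrected pairs", {
  set.seed(5)
  mk <- function(group, sias, esb, mcs)
    data.frame(subject_id = paste0(group, seq_along(esb)), group = group,
               sias_level = sias, motion = "elbow_flexion",
               trial_index = 1L, esb = esb, mcs = mcs,
               stringsAsFactors = FALSE)
  recs <- rbind(
    mk("healthy_young", NA, rnorm(8, 0.05, 0.02), rnorm(8, 0.97, 0.01)),
    mk("stroke", 1L, rnorm(8, 0.6, 0.1), rnorm(8, 0.3, 0.2)),
    mk("stroke", 5L, rep(0.1, 8), rnorm(8, 0.9, 0.05)))
  sm <- sias_summary(recs)
  panel <- sm$elbow_flexion$abs_esb
  expect_equal(nrow(panel$pairs), 3L)  # all-vs-all over three groups
  expect_true(all(panel$pairs$p_holm >= panel$pairs$p_raw - 1e-15))
  # constant group has SD 0
  expect_equal(panel$group_sd$sd[panel$group_sd$group == "sias_5"], 0)
  # healthy-vs-severe difference is large and survives Holm
  hv1 <- panel$pairs$significant[
    panel$pairs$group_a == "healthy_young" & panel$pairs$group_b == "sias_1"]
  expect_true(hv1)
})

test_that("summary on |ESB| is invariant to flipping every paretic side", {
  set.seed(9)
  mk <- function(group, sias, n) data.frame(
    subject_id = paste0(group, 1:n), group = group, sias_level = sias,
    motion = "steering", trial_index = 1L,
    esb = rnorm(n, 0.3, 0.2), mcs = rnorm(n, 0.7, 0.2),
    stringsAsFactors = FALSE)
  recs <- rbind(mk("stroke", 2L, 8), mk("healthy_elder", NA, 8))
  flipped <- transform(recs, esb = -esb)
  sm1 <- sias_summary(recs)$steering$abs_esb
  sm2 <- sias_summary(flipped)$steering$abs_esb
  expect_equal(sm1$pairs, sm2$pairs)
  expect_equal(sm1$group_sd, sm2$group_sd)
})

test_that("undefined MCS trials drop from MCS panels, stay in ESB panels", {
  recs <- data.frame(
    subject_id = rep(c("a", "b"), each = 6),
    group = rep(c("healthy_young", "stroke"), each = 6),
    sias_level = rep(c(NA, 1L), each = 6), motion = "elbow_flexion",
    trial_index = 1L, esb = runif(12),
    mcs = c(runif(6), runif(3), NA, NA, NA), stringsAsFactors = FALSE)
  sm <- sias_summary(recs)
  expect_equal(sm$elbow_flexion$mcs$n_excluded, 3L)
  expect_equal(sum(sm$elbow_flexion$mcs$group_sd$n), 9L)
  expect_equal(sum(sm$elbow_flexion$abs_esb$group_sd$n), 12L)
})

test_that("groups with too few defined values are excluded with a warning", {
  recs <- data.frame(
    subject_id = c("a", "a", "a", "a", "b", "b"),
    group = c(rep("healthy_young", 4), rep("stroke", 2)),
    sias_level = c(rep(NA_integer_, 4), 3L, 3L), motion = "steering",
    trial_index = 1L, esb = runif(6), mcs = runif(6),
    stringsAsFactors = FALSE)
  w <- capture_warnings(sm <- sias_summary(recs))
  expect_true(any(grepl("excluded.*sias_3", w)))
  expect_null(sm$steering$mcs$pairs)
})

test_that("summary tables write one TSV per panel", {
  set.seed(2)
  recs <- data.frame(
    subject_id = rep(c("a", "b"), each = 4),
    group = rep(c("healthy_young", "healthy_elder"), each = 4),
    sias_level = NA_integer_, motion = "elbow_flexion", trial_index = 1L,
    esb = runif(8), mcs = runif(8), stringsAsFactors = FALSE)
  sm <- sias_summary(recs)
  prefix <- file.path(withr::local_tempdir(), "panel")
  files <- write_summary_tables(sm, prefix)
  expect_true(all(file.exists(files)))
  expect_length(files, 4L)  # pairs + sd for each of two indexes
})
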