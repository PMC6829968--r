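#' Two-sided Wilcoxon rank-sum test
#'
#' For small samples (combined n <= 20) the null distribution of the
#' rank-sum statistic is enumerated exactly over all group assignments, with
#' ties handled by midranks; the two-sided p-value is the null probability
#' of a rank sum at least as far from its mean as the observed one. For
#' larger samples the normal approximation with tie correction (and
#' continuity correction) is used.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 3.
#' @param exact_max Combined-size threshold for exact enumeration, default 20.
#' @return List of class \code{ranksum_test}: \code{p_value},
#'   \code{statistic} (rank sum of \code{sample_a}), \code{method}
#'   (\code{"exact"} or \code{"normal"}), \code{n_a}, \code{n_b}.
#' @examples
#' ranksum_test(c(1, 2, 3), c(10, 11, 12))$p_value  # exact: 0.1
#' @export
ranksum_test <- function(sample_a, sample_b, exact_max = 20L) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  m <- length(sample_a)
  n <- length(sample_b)
  if (m < 3L || n < 3L)
    stop("both samples need at least 3 values (got ", m, " and ", n, ")")
  r <- rank(c(sample_a, sample_b))
  w_obs <- sum(r[seq_len(m)])
  if (m + n <= exact_max) {
    mu <- m * sum(r) / (m + n)
    combs <- utils::combn(m + n, m)
    w_all <- colSums(matrix(r[combs], nrow = m))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, exact = FALSE,
                         correct = TRUE)$p.value)
    method <- "normal"
  }
  structure(list(p_value = p, statistic = w_obs, method = method,
                 n_a = m, n_b = n),
            class = "ranksum_test")
}

#' Holm (step-down Bonferroni) multiple-comparison correction
#'
#' Sorts the p-values ascending and compares the k-th smallest to
#' alpha/(m - k + 1), rejecting until the first failure. Adjusted p-values
#' are the running maxima of min(1, (m - k + 1) p_(k)), as computed by
#' \code{p.adjust(method = "holm")}.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param alpha Family-wise error rate, default 0.05.
#' @return List: \code{adjusted} (Holm-adjusted p-values, input order),
#'   \code{significant} (logical, input order), \code{alpha}.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))$significant  # only the first survives
#' @export
holm_adjust <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adj, significant = adj <= alpha, alpha = alpha)
}

#' Group-level comparison of the symmetry indexes
#'
#' Reproduces the cohort-comparison layout: per motion and per index (MCS
#' and |ESB|), all-vs-all pairwise two-sided rank-sum tests across the
#' severity groups, Holm-corrected within each (index, motion) panel, with
#' per-group sample standard deviations alongside. |ESB| is used rather than
#' signed ESB so that side balance is assessed independently of which arm is
#' paretic.
#'
#' Trials with undefined MCS are excluded from MCS panels (counts reported)
#' but retained in ESB panels. Groups with fewer than 3 defined values in a
#' panel are excluded from that panel with a warning.
#'
#' @param records Index-record data.frame (see \code{\link{session_indexes}});
#'   stroke records are grouped by SIAS level (\code{sias_1}..\code{sias_5}),
#'   healthy records by their group name.
#' @param alpha Family-wise error rate per panel, default 0.05.
#' @param family \code{"all_vs_all"} (default) or \code{"vs_healthy"}
#'   (only pairs involving a healthy group).
#' @return List of class \code{sias_summary}: one element per motion, each
#'   with elements \code{mcs} and \code{abs_esb}; every panel is a list with
#'   \code{pairs} (data.frame: group_a, group_b, p_raw, p_holm, significant),
#'   \code{group_sd} (data.frame: group, sd, n), and \code{n_excluded}
#'   (undefined-MCS trials dropped, MCS panels only).
#' @export
sias_summary <- function(records, alpha = 0.05,
                         family = c("all_vs_all", "vs_healthy")) {
  family <- match.arg(family)
  req <- c("group", "sias_level", "motion", "esb", "mcs")
  if (!all(req %in% names(records)))
    stop("records need columns: ", paste(req, collapse = ", "))
  records$panel_group <- ifelse(records$group == "stroke",
                                paste0("sias_", records$sias_level),
                                records$group)
  level_order <- c("healthy_young", "healthy_elder",
                   paste0("sias_", 5:1))
  out <- list()
  for (mot in unique(records$motion)) {
    rm_ <- records[records$motion == mot, ]
    out[[mot]] <- list(
      mcs = comparison_panel(rm_, "mcs", alpha, family, level_order),
      abs_esb = comparison_panel(transform(rm_, value = abs(esb)),
                                 "value", alpha, family, level_order))
  }
  structure(out, class = "sias_summary")
}

comparison_panel <- function(df, col, alpha, family, level_order) {
  if (col == "mcs") {
    n_excluded <- sum(is.na(df$mcs))
    df <- df[!is.na(df$mcs), ]
  } else n_excluded <- 0L
  values <- split(df[[col]], df$panel_group)
  sizes <- vapply(values, length, 0L)
  small <- names(values)[sizes < 3L]
  if (length(small) > 0L) {
    warning("group(s) excluded (< 3 defined values): ",
            paste(small, collapse = ", "))
    values <- values[sizes >= 3L]
  }
  groups <- intersect(level_order, names(values))
  values <- values[groups]
  group_sd <- data.frame(group = groups,
                         sd = vapply(values, stats::sd, 0),
                         n = vapply(values, length, 0L),
                         stringsAsFactors = FALSE)
  rownames(group_sd) <- NULL
  pairs <- NULL
  if (length(groups) >= 2L) {
    cmb <- utils::combn(groups, 2L)
    if (family == "vs_healthy") {
      keep <- apply(cmb, 2L, function(p)
        any(grepl("^healthy", p)))
      cmb <- cmb[, keep, drop = FALSE]
    }
    if (ncol(cmb) > 0L) {
      p_raw <- apply(cmb, 2L, function(p)
        ranksum_test(values[[p[1]]], values[[p[2]]])$p_value)
      hl <- holm_adjust(p_raw, alpha)
      pairs <- data.frame(group_a = cmb[1L, ], group_b = cmb[2L, ],
                          p_raw = p_raw, p_holm = hl$adjusted,
                          significant = hl$significant,
                          stringsAsFactors = FALSE)
    }
  }
  list(pairs = pairs, group_sd = group_sd, n_excluded = n_excluded,
       alpha = alpha)
}

#' Write the panels of a cohort comparison to TSV files
#'
#' For each (motion, index) panel writes \code{<prefix>_<motion>_<index>_pairs.tsv}
#' (pairwise raw and Holm-adjusted p-values with significance) and
#' \code{<prefix>_<motion>_<index>_sd.tsv} (per-group standard deviations).
#'
#' @param summary A \code{\link{sias_summary}} result.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_summary_tables <- function(summary, prefix) {
  stopifnot(inherits(summary, "sias_summary"))
  written <- character()
  for (mot in names(summary)) {
    for (idx in names(summary[[mot]])) {
      panel <- summary[[mot]][[idx]]
      base <- paste0(prefix, "_", mot, "_", idx)
      if (!is.null(panel$pairs)) {
        f <- paste0(base, "_pairs.tsv")
        utils::write.table(panel$pairs, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <- c(written, f)
      }
      f <- paste0(base, "_sd.tsv")
      utils::write.table(panel$group_sd, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }
  }
  invisible(written)
}
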