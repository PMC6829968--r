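#' Tukey boxplot statistics of one sample
#'
#' Quartiles by linear interpolation between order statistics
#' (\code{quantile} type 7); whiskers extend to the most extreme points
#' within 1.5 IQR of the quartiles; points beyond the fences are outliers.
#'
#' @param x Numeric vector, length >= 4.
#' @return List: \code{median}, \code{q1}, \code{q3}, \code{whisker_low},
#'   \code{whisker_high}, \code{outliers}, \code{n}.
#' @export
tukey_box_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4L) stop("need at least 4 values for boxplot statistics")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = sort(x[!inside]), n = length(x))
}

#' Muscle activity print
#'
#' Summarizes the distribution of coordination coefficients per muscle and
#' side role across the trials of a group, as the boxplot statistics used to
#' display per-muscle activity (median, quartiles, 1.5 IQR whiskers,
#' outliers).
#'
#' @param coefficients Long-format coefficient data.frame with at least
#'   columns \code{muscle}, \code{side_role}, \code{coefficient} (e.g. from
#'   \code{\link{session_coefficients}}, optionally row-bound over sessions).
#' @param min_trials Minimum number of values per (muscle, side role) cell,
#'   default 4.
#' @return An object of class \code{activity_print}: data.frame with one row
#'   per (muscle, side_role) and columns \code{median}, \code{q1}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}, \code{n_outliers}, \code{n};
#'   the outlier values themselves in attribute \code{"outliers"} (a named
#'   list), and the quartile convention in attribute \code{"quartile_type"}.
#' @export
activity_print <- function(coefficients, min_trials = 4L) {
  req <- c("muscle", "side_role", "coefficient")
  if (!all(req %in% names(coefficients)))
    stop("coefficients need columns: ", paste(req, collapse = ", "))
  if (nrow(coefficients) == 0L) stop("no coefficient values")
  key <- interaction(factor(as.character(coefficients$muscle),
                            levels = emg_muscles),
                     coefficients$side_role, drop = TRUE, lex.order = TRUE)
  counts <- table(key)
  if (any(counts < min_trials))
    stop("fewer than ", min_trials, " trials for: ",
         paste(names(counts)[counts < min_trials], collapse = ", "))
  groups <- split(coefficients$coefficient, key)
  stats_list <- lapply(groups, tukey_box_stats)
  ks <- strsplit(names(groups), ".", fixed = TRUE)
  out <- data.frame(
    muscle = vapply(ks, `[`, "", 1L),
    side_role = vapply(ks, `[`, "", 2L),
    median = vapply(stats_list, `[[`, 0, "median"),
    q1 = vapply(stats_list, `[[`, 0, "q1"),
    q3 = vapply(stats_list, `[[`, 0, "q3"),
    whisker_low = vapply(stats_list, `[[`, 0, "whisker_low"),
    whisker_high = vapply(stats_list, `[[`, 0, "whisker_high"),
    n_outliers = vapply(stats_list, function(s) length(s$outliers), 0L),
    n = vapply(stats_list, `[[`, 0L, "n"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, outliers = lapply(stats_list, `[[`, "outliers"),
            quartile_type = "linear interpolation (type 7)",
            class = c("activity_print", "data.frame"))
}
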