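# Statistical analyses: Pearson correlation with exact two-sided t-based p,
# least-squares line, Welch's two-sample t, and the cohort group summaries.

#' Pearson correlation with regression line
#'
#' Product-moment correlation; the two-sided p-value comes from
#' `t = r sqrt(n-2) / sqrt(1-r^2)` against the t distribution with `n - 2`
#' degrees of freedom. Slope and intercept are the least-squares line of `y`
#' on `x`, and `r_squared = r^2`.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, both non-constant.
#' @return list with `r`, `p`, `n`, `slope`, `intercept`, `r_squared`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("pearson requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  slope <- sxy / sxx
  list(r = r, p = p, n = n, slope = slope,
       intercept = mean(y) - slope * mean(x), r_squared = r^2)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided p.
#'
#' @param a,b numeric vectors, each of length >= 2 and non-degenerate.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df = df))
}

#' Group means of the first-cycle columns
#'
#' Mean first-cycle duration (minutes) and first-cycle spindle count per
#' group, reported to 1 decimal.
#'
#' @param subjects data frame with `group` (`DS`/`NS`), `first_cycle_min`,
#'   `first_cycle_spindles`.
#' @return data frame with one row per group and columns `group`,
#'   `mean_first_cycle_min`, `mean_first_cycle_spindles`, `n`.
#' @export
cohort_summary <- function(subjects) {
  need <- c("group", "first_cycle_min", "first_cycle_spindles")
  if (!all(need %in% names(subjects))) {
    stop("subjects table lacks columns: ",
         paste(setdiff(need, names(subjects)), collapse = ", "))
  }
  if (nrow(subjects) == 0) stop("empty subjects table")
  round_half_up <- function(x) floor(x * 10 + 0.5) / 10   # commercial rounding
  rows <- lapply(split(subjects, subjects$group), function(d) {
    if (nrow(d) == 0) stop("empty group")
    data.frame(group = d$group[1],
               mean_first_cycle_min = round_half_up(mean(d$first_cycle_min)),
               mean_first_cycle_spindles = round_half_up(mean(d$first_cycle_spindles)),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spindle density vs PSQI correlation
#'
#' Pearson correlation between subjects' PSQI sleep-quality scores and their
#' spindle densities, plus the per-point scatter data for plotting/export.
#'
#' @param subjects data frame with `subject_id` and `psqi`.
#' @param densities data frame with `subject_id` and `density_per_min`.
#' @return list with `result` (see [pearson()]) and `scatter` (merged
#'   per-subject data frame).
#' @export
density_psqi_analysis <- function(subjects, densities) {
  merged <- merge(subjects[, c("subject_id", "psqi")],
                  densities[, c("subject_id", "density_per_min")],
                  by = "subject_id")
  if (nrow(merged) != nrow(subjects) || nrow(merged) != nrow(densities)) {
    stop("subject ids of the two tables do not match")
  }
  list(result = pearson(merged$psqi, merged$density_per_min),
       scatter = merged)
}
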