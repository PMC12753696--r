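#' Normalize channel intensities to per-experiment means
#'
#' Each channel value is divided by that channel's mean within its
#' experiment, so every experiment's per-channel mean becomes exactly 1.
#' This removes instrument gain and acquisition-setting differences between
#' experiments (including 8-bit vs 16-bit collection) before intensities are
#' pooled.
#'
#' @param cells a cohort table with columns `experiment`, `raw_green`,
#'   `raw_red`.
#' @return The same table with normalized columns `x` (green) and `y` (red)
#'   appended.
#' @export
normalize_per_experiment <- function(cells) {
  need <- c("experiment", "raw_green", "raw_red")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  mg <- stats::ave(cells$raw_green, cells$experiment, FUN = mean)
  mr <- stats::ave(cells$raw_red, cells$experiment, FUN = mean)
  if (any(mg <= 0) || any(mr <= 0)) {
    bad <- unique(cells$experiment[mg <= 0 | mr <= 0])
    stop("experiment(s) with nonpositive channel mean: ",
         paste(bad, collapse = ", "))
  }
  cells$x <- cells$raw_green / mg
  cells$y <- cells$raw_red / mr
  cells
}

#' Per-cell intrinsic noise
#'
#' The intrinsic noise of a cell with allele expression values `x` and `y`
#' is `(x - y)^2 / (2 * mean_x * mean_y)`, where `mean_x` and `mean_y` are
#' the average values of each allele over the reference group of cells.  It
#' measures how far a cell's pair of reporter alleles deviates from the
#' group's average allele ratio: 0 when the alleles agree exactly, large for
#' biased or monoallelic cells.  The extrinsic factor shared by both alleles
#' cancels in the difference.
#'
#' @param x,y numeric vectors of per-cell allele values (same length).
#' @param mean_x,mean_y positive group means of each allele (scalars or
#'   vectors matching `x`).
#' @return Numeric vector of intrinsic-noise values (>= 0).
#' @examples
#' intrinsic_noise(1.2, 0.8, 1, 1)  # 0.08
#' @export
intrinsic_noise <- function(x, y, mean_x, mean_y) {
  if (any(mean_x <= 0) || any(mean_y <= 0)) {
    stop("allele means must be positive")
  }
  (x - y)^2 / (2 * mean_x * mean_y)
}

#' Attach per-cell intrinsic noise to a normalized cohort table
#'
#' Allele means are computed per group-by-experiment stratum by default
#' (each experiment contributes its own reference ratio) or per pooled group;
#' the policy used is recorded on the result.  Records from all experiments
#' are then pooled for group summaries, matching the convention of reporting
#' N cells over three independent experiments.
#'
#' @param cells a normalized cohort table (see [normalize_per_experiment()])
#'   with columns `group`, `experiment`, `x`, `y`.
#' @param means `"group_experiment"` (default) or `"group"`: the stratum over
#'   which the allele means are taken.
#' @return The table with columns `mean_x`, `mean_y`, `eta` (intrinsic
#'   noise) appended; attribute `mean_policy` records the choice.
#' @export
group_noise <- function(cells, means = c("group_experiment", "group")) {
  means <- match.arg(means)
  need <- c("group", "experiment", "x", "y")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         if ("x" %in% miss) " (run normalize_per_experiment() first?)" else "")
  }
  if (nrow(cells) == 0L) stop("empty table")
  key <- if (means == "group_experiment") {
    interaction(cells$group, cells$experiment, drop = TRUE)
  } else {
    factor(cells$group)
  }
  cells$mean_x <- stats::ave(cells$x, key, FUN = mean)
  cells$mean_y <- stats::ave(cells$y, key, FUN = mean)
  cells$eta <- intrinsic_noise(cells$x, cells$y, cells$mean_x, cells$mean_y)
  attr(cells, "mean_policy") <- means
  cells
}

#' Allele-bias score: coefficient of determination
#'
#' The coefficient of determination between the two allele values across all
#' cells of a group.  Tightly coupled (biallelic) alleles give R-squared near
#' 1; decoupled, biased or monoallelic expression gives values near 0.
#' `method = "pearson"` squares the Pearson correlation; `method =
#' "regression"` computes 1 - SSres/SStot from the least-squares line of `y`
#' on `x`.  For a straight-line fit with intercept the two are analytically
#' identical, and they are kept as mutually checking routes.
#'
#' @param x,y numeric vectors (>= 3 cells, nonzero variance in both).
#' @param method `"pearson"` or `"regression"`.
#' @return R-squared in \\[0, 1\\].
#' @export
allele_r2 <- function(x, y, method = c("pearson", "regression")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  if (length(x) < 3L) stop("need at least 3 cells")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in one channel; R-squared undefined")
  }
  if (method == "pearson") {
    unname(stats::cor(x, y)^2)
  } else {
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    ss_res <- sum((y - (a + b * x))^2)
    ss_tot <- sum((y - mean(y))^2)
    1 - ss_res / ss_tot
  }
}

#' Boxplot-convention percentile summary
#'
#' Median plus the 5th, 10th, 25th, 75th, 90th and 95th percentiles: box
#' edges at the quartiles, whiskers at the 10th/90th, and dots at the
#' 5th/95th.  Percentiles use linear interpolation between closest ranks
#' (the common plotting default, `quantile` type 7).
#'
#' @param values numeric vector, n >= 1.
#' @return Named numeric vector: `n`, `median`, `p5`, `p10`, `p25`, `p75`,
#'   `p90`, `p95`.
#' @export
boxplot_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) stop("need >= 1 non-missing value")
  q <- stats::quantile(values, c(.05, .10, .25, .50, .75, .90, .95),
                       type = 7, names = FALSE)
  c(n = length(values), median = q[4],
    p5 = q[1], p10 = q[2], p25 = q[3], p75 = q[5], p90 = q[6], p95 = q[7])
}

#' Per-group summaries of intrinsic noise and allele bias
#'
#' @param cells output of [group_noise()].
#' @return Data frame with one row per group: `group`, `n`, `median_eta`,
#'   percentile columns, and `r2` (allele-bias score across all cells of the
#'   group, pooled over experiments).
#' @export
summarize_groups <- function(cells) {
  if (!all(c("group", "eta", "x", "y") %in% names(cells))) {
    stop("run group_noise() first")
  }
  groups <- unique(cells$group)
  rows <- lapply(groups, function(g) {
    sub <- cells[cells$group == g, ]
    bs <- boxplot_summary(sub$eta)
    data.frame(group = g, n = unname(bs["n"]),
               median_eta = unname(bs["median"]),
               p5 = unname(bs["p5"]), p10 = unname(bs["p10"]),
               p25 = unname(bs["p25"]), p75 = unname(bs["p75"]),
               p90 = unname(bs["p90"]), p95 = unname(bs["p95"]),
               r2 = allele_r2(sub$x, sub$y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
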