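#' Mann-Whitney rank-sum test (two-sided)
#'
#' U is computed from midranks of the pooled sample.  The null distribution
#' is exact when `length(a) * length(b) <= 400`: a full enumeration of rank
#' assignments when the number of combinations is small (this also handles
#' ties exactly), otherwise the classical count recurrence for tie-free
#' data.  Larger problems, and tied data too large to enumerate, use the
#' normal approximation with tie correction and (by default) a continuity
#' correction.
#'
#' @param a,b numeric samples (nonempty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact null; `NULL`
#'   (default) decides by the `n * m <= 400` rule.
#' @param correct apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return A `stat_result` list: `test`, `groups` (labels and sizes),
#'   `statistic` (U for the first sample), `p_value` (two-sided), `method`
#'   (`"exact enumeration"`, `"exact recurrence"` or
#'   `"normal approximation"`).
#' @export
mann_whitney_u <- function(a, b, exact = NULL, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- (n1 * n2 <= 400)

  method <- NULL; p <- NULL
  if (exact) {
    n_comb <- choose(N, n1)
    if (n_comb <= 2e5) {
      # full enumeration of group assignments of the observed midranks;
      # valid with or without ties
      combs <- utils::combn(N, n1)
      us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
      eps <- 1e-9
      p_le <- mean(us <= u1 + eps)
      p_ge <- mean(us >= u1 - eps)
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "exact enumeration"
    } else if (!has_ties) {
      cdf <- mw_u_counts(n1, n2)      # counts of U = 0..n1*n2
      tot <- sum(cdf)
      uu <- round(u1)
      p_le <- sum(cdf[seq_len(uu + 1)]) / tot
      p_ge <- sum(cdf[(uu + 1):length(cdf)]) / tot
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "exact recurrence"
    }
  }
  if (is.null(p)) {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u1 - mu
      cc <- if (correct) sign(z) * 0.5 else 0
      z <- (z - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  structure(
    list(test = "Mann-Whitney rank-sum, two-sided",
         groups = data.frame(label = c("a", "b"), n = c(n1, n2),
                             median = c(stats::median(a), stats::median(b))),
         statistic = c(U = unname(u1)),
         p_value = p, method = method),
    class = "stat_result"
  )
}

# counts of tie-free rank assignments giving each U value 0..n*m, via the
# classical recurrence c(i, j, u) = c(i-1, j, u-j) + c(i, j-1, u): the
# largest remaining observation comes from sample 1 (beating all j current
# sample-2 members) or from sample 2.
mw_u_counts <- function(n, m) {
  umax <- n * m
  grid <- vector("list", (n + 1L) * (m + 1L))
  idx <- function(i, j) i * (m + 1L) + j + 1L
  base <- rep(0, umax + 1); base[1] <- 1
  for (j in 0:m) grid[[idx(0L, j)]] <- base
  for (i in seq_len(n)) {
    grid[[idx(i, 0L)]] <- base
    for (j in seq_len(m)) {
      v <- grid[[idx(i, j - 1L)]]
      up <- grid[[idx(i - 1L, j)]]
      v[(j + 1):(umax + 1)] <- v[(j + 1):(umax + 1)] + up[seq_len(umax + 1 - j)]
      grid[[idx(i, j)]] <- v
    }
  }
  grid[[idx(n, m)]]
}

#' Kruskal-Wallis one-way analysis of variance on ranks
#'
#' H from midranks with tie correction; p-value from the chi-square
#' distribution with k - 1 degrees of freedom.  When every observation is
#' identical the statistic is defined as 0 with p = 1.
#'
#' @param groups list of >= 2 nonempty numeric vectors (optionally named).
#' @return A `stat_result` list with `statistic = c(H = ...)`, `df`,
#'   `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  ns <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / C
    p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  structure(
    list(test = "Kruskal-Wallis one-way ANOVA on ranks",
         groups = data.frame(label = labels, n = ns,
                             median = vapply(groups, stats::median, 1)),
         statistic = c(H = unname(H)), df = length(groups) - 1,
         p_value = p),
    class = "stat_result"
  )
}

#' Dunn's multiple-comparison procedure after Kruskal-Wallis
#'
#' For each requested pair (i, j), using the global midranks of the pooled
#' data, `z = (meanrank_i - meanrank_j) / sqrt(sigma2 * (1/n_i + 1/n_j))`
#' with `sigma2 = N(N+1)/12 - sum(t^3 - t) / (12(N-1))` (tie term over tie
#' group sizes t).  Two-sided p per pair; the family-wise adjustment is
#' Bonferroni over the requested comparison set (capped at 1).
#'
#' @param groups named list of numeric vectors.
#' @param comparisons two-column character matrix (or data frame) of group
#'   label pairs; `NULL` (default) compares all pairs.
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @param alpha family-wise significance level for the `significant` flag.
#' @return A `stat_result` list with a `comparisons` data frame: `group1`,
#'   `group2`, `z`, `p_value`, `p_adjusted`, `significant`.
#' @export
dunns_procedure <- function(groups, comparisons = NULL,
                            adjustment = c("bonferroni", "none"),
                            alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  labels <- names(groups)
  if (is.null(labels)) {
    labels <- paste0("g", seq_along(groups))
    names(groups) <- labels
  }
  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(labels, 2))
  }
  comparisons <- as.matrix(comparisons)
  if (!all(comparisons %in% labels)) {
    stop("comparison references unknown group: ",
         paste(setdiff(unique(as.vector(comparisons)), labels), collapse = ", "))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(labels, vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  m <- nrow(comparisons)
  z <- p <- numeric(m)
  for (k in seq_len(m)) {
    i <- comparisons[k, 1]; j <- comparisons[k, 2]
    se <- sqrt(sigma2 * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- if (se > 0) (mr[[i]] - mr[[j]]) / se else 0
    p[k] <- min(1, 2 * stats::pnorm(-abs(z[k])))
  }
  p_adj <- if (adjustment == "bonferroni") pmin(1, p * m) else p
  comp <- data.frame(group1 = comparisons[, 1], group2 = comparisons[, 2],
                     z = z, p_value = p, p_adjusted = p_adj,
                     significant = p_adj < alpha,
                     stringsAsFactors = FALSE)
  structure(
    list(test = "Dunn's procedure (global ranks)",
         groups = data.frame(label = labels,
                             n = as.integer(ns[labels]),
                             median = vapply(groups, stats::median, 1)),
         adjustment = adjustment, alpha = alpha,
         comparisons = comp,
         p_value = min(comp$p_adjusted)),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, "\n")
  if (!is.null(x$comparisons)) {
    for (k in seq_len(nrow(x$comparisons))) {
      cc <- x$comparisons[k, ]
      g1 <- x$groups[x$groups$label == cc$group1, ]
      g2 <- x$groups[x$groups$label == cc$group2, ]
      cat(sprintf(
        "  %s (median %.4g, n = %d) vs %s (median %.4g, n = %d): z = %.3f, adjusted P = %.4g (%s)\n",
        cc$group1, g1$median, g1$n, cc$group2, g2$median, g2$n,
        cc$z, cc$p_adjusted, x$adjustment))
    }
  } else {
    gl <- sprintf("%s (median %.4g, n = %d)", x$groups$label,
                  x$groups$median, x$groups$n)
    cat(" ", paste(gl, collapse = " vs "), "\n")
    cat(sprintf("  %s = %.4f, P = %.4g%s\n", names(x$statistic)[1],
                x$statistic[1], x$p_value,
                if (!is.null(x$method)) paste0(" [", x$method, "]") else ""))
  }
  invisible(x)
}
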