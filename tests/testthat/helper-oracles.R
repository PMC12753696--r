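`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles used across the suite.  These are written
# from the definitions, not by calling the package implementations.

# Two-sided Mann-Whitney p by full enumeration of group assignments of the
# observed midranks (handles ties).
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Kruskal-Wallis H with tie correction, straight from the rank formula.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  tt <- table(x)
  h / (1 - sum(tt^3 - tt) / (N^3 - N))
}

# Dunn z for one pair, by direct mean-rank arithmetic on global ranks.
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  mr <- tapply(r, g, mean)
  ns <- tabulate(g)
  tt <- table(x)
  s2 <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  (mr[[i]] - mr[[j]]) / sqrt(s2 * (1 / ns[i] + 1 / ns[j]))
}

# Percentile by explicit linear interpolation between closest ranks.
oracle_percentile <- function(values, p) {
  v <- sort(values)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(v[n])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}

# Exhaustive small-parsimony oracle: minimum number of active->silenced
# transitions over all assignments of internal nodes (and unlabeled leaves),
# counting a silenced root as one event (active ancestor); reversals
# forbidden in irreversible mode, otherwise counted too.
oracle_fitch <- function(tree, leaf_states, irreversible = TRUE) {
  free <- c(setdiff(tree$nodes, tree$leaves),
            setdiff(tree$leaves, names(leaf_states)[!is.na(leaf_states)]))
  fixed <- leaf_states[!is.na(leaf_states)]
  k <- length(free)
  best <- Inf
  for (code in 0:(2^k - 1)) {
    lab <- fixed
    bits <- as.integer(intToBits(code))[seq_len(max(k, 1))]
    lab[free] <- ifelse(bits[seq_len(k)] == 1, "silenced", "active")
    ev <- if (lab[[tree$root]] == "silenced") 1L else 0L
    ok <- TRUE
    for (n in tree$nodes) {
      p <- tree$parent[[n]]
      if (is.na(p)) next
      if (lab[[p]] == "active" && lab[[n]] == "silenced") ev <- ev + 1L
      if (lab[[p]] == "silenced" && lab[[n]] == "active") {
        if (irreversible) { ok <- FALSE; break }
        ev <- ev + 1L
      }
    }
    if (ok && ev < best) best <- ev
  }
  best
}

# Random rooted binary tree with n leaves (n >= 2), as a make_tree() input.
random_binary_tree <- function(n_leaves) {
  parent <- c(n1 = "r", n2 = "r")
  leaves <- c("n1", "n2")
  nxt <- 3L
  while (length(leaves) < n_leaves) {
    pick <- sample(leaves, 1)
    kids <- paste0("n", nxt + 0:1)
    nxt <- nxt + 2L
    parent[kids] <- pick
    leaves <- c(setdiff(leaves, pick), kids)
  }
  make_tree(parent)
}

# Naive two-pass reference for group_noise: explicit per-stratum means.
oracle_group_noise <- function(cells, means) {
  eta <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (means == "group_experiment") {
      sel <- cells$group == cells$group[i] &
        cells$experiment == cells$experiment[i]
    } else {
      sel <- cells$group == cells$group[i]
    }
    mx <- mean(cells$x[sel]); my <- mean(cells$y[sel])
    eta[i] <- (cells$x[i] - cells$y[i])^2 / (2 * mx * my)
  }
  eta
}
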