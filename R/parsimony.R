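#' Minimum silencing events on a lineage (small parsimony)
#'
#' Computes the minimum number of active-to-silenced transitions on a fixed
#' rooted tree consistent with observed leaf states, by bottom-up
#' propagation of per-state costs (Sankoff-style dynamic programming over
#' the two states).  The tree's root is assumed to descend from an active
#' ancestor, so a silenced root itself counts as one event.  In the default
#' irreversible mode silenced-to-active transitions are forbidden, matching
#' mitotically persistent silencing (maintenance = 1); the reversible mode
#' allows and counts them.
#'
#' Unsampled leaves (`NA` state) contribute no cost in either state
#' (universal-set semantics) rather than being imputed.
#'
#' @param tree a `lineage_tree` (see [build_intestine_lineage()] or
#'   [make_tree()]).
#' @param leaf_states named character vector over (a subset of) the leaves,
#'   values `"active"`, `"silenced"`, or `NA` for sampled-but-uninformative;
#'   leaves absent from the vector are treated as unsampled.
#' @param irreversible forbid silenced-to-active transitions (default TRUE).
#' @return List: `n_events` (minimum transition count), `labeling` (named
#'   character over all nodes, one optimal assignment), `events` (data frame
#'   `node`, `stage` of the active-to-silenced transitions in that
#'   labeling).
#' @export
fitch_min_events <- function(tree, leaf_states, irreversible = TRUE) {
  stopifnot(inherits(tree, "lineage_tree"))
  obs <- leaf_states[!is.na(leaf_states)]
  if (length(obs) == 0L) stop("no labeled leaves")
  if (!all(names(obs) %in% tree$leaves)) {
    stop("leaf_states names must be leaves of the tree")
  }
  if (!all(obs %in% c("active", "silenced"))) {
    stop("leaf states must be \"active\" or \"silenced\"")
  }
  states <- c("active", "silenced")
  # transition cost w[from, to]
  w <- matrix(c(0, 1, if (irreversible) Inf else 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(states, states))
  nodes <- tree$nodes
  cost <- matrix(0, nrow = length(nodes), ncol = 2L,
                 dimnames = list(nodes, states))
  for (lf in tree$leaves) {
    s <- if (lf %in% names(obs)) obs[[lf]] else NA_character_
    if (!is.na(s)) {
      cost[lf, ] <- ifelse(states == s, 0, Inf)
    }
  }
  post <- tree_postorder(tree)
  # child_choice[[node]][[state]] : named vector of chosen child states
  child_choice <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in post) {
    ch <- tree$children[[n]]
    if (is.null(ch)) next
    cc <- list(active = character(0), silenced = character(0))
    for (s in states) {
      tot <- 0
      for (c_ in ch) {
        v <- cost[c_, ] + w[s, ]
        # tie-break: keep the parent's state if tied, else active
        best <- if (v[[s]] <= min(v)) s else states[which.min(v)]
        cc[[s]] <- c(cc[[s]], stats::setNames(best, c_))
        tot <- tot + min(v)
      }
      cost[n, s] <- cost[n, s] + tot
    }
    child_choice[[n]] <- cc
  }
  root <- tree$root
  total_a <- cost[root, "active"]
  total_s <- cost[root, "silenced"] + 1  # event on the virtual edge above the root
  n_events <- min(total_a, total_s)
  if (!is.finite(n_events)) stop("no consistent labeling under the chosen mode")
  root_state <- if (total_a <= total_s) "active" else "silenced"

  labeling <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  labeling[root] <- root_state
  for (n in tree_preorder(tree)) {
    ch <- tree$children[[n]]
    if (is.null(ch)) next
    picks <- child_choice[[n]][[labeling[[n]]]]
    labeling[ch] <- picks[ch]
  }
  ev_nodes <- character(0)
  if (root_state == "silenced") ev_nodes <- root
  for (n in nodes) {
    p <- tree$parent[[n]]
    if (!is.na(p) && labeling[[p]] == "active" && labeling[[n]] == "silenced") {
      ev_nodes <- c(ev_nodes, n)
    }
  }
  list(
    n_events = unname(n_events),
    labeling = labeling,
    events = data.frame(node = ev_nodes,
                        stage = unname(tree$stage[ev_nodes]),
                        stringsAsFactors = FALSE)
  )
}

#' Infer the lineage stage at which silencing initiated
#'
#' Maps per-cell allele-expression states to per-allele leaf labels
#' (monoallelic against an allele means that allele is silenced; biased
#' states are treated as active by default, configurable), runs
#' [fitch_min_events()] for each allele, and reports the earliest division
#' stage among the inferred initiation events.  A whole intestine
#' monoallelic for green, for instance, is most parsimoniously explained by
#' a single red-allele event at stage 0 -- the E cell.
#'
#' @param tree lineage tree.
#' @param calls data frame with columns `cell` (leaf id) and `state` (one of
#'   the [call_mae_state()] states); one animal's cells.
#' @param biased_as how to label the allele disfavored by a biased state:
#'   `"active"` (default, conservative) or `"silenced"`.
#' @param irreversible passed to [fitch_min_events()] (default TRUE).
#' @return List with per-allele elements `green` and `red`, each the
#'   [fitch_min_events()] result plus `earliest_stage` (`NA` when no events),
#'   and `earliest_stage`, the minimum over alleles.
#' @export
infer_initiation_stage <- function(tree, calls,
                                   biased_as = c("active", "silenced"),
                                   irreversible = TRUE) {
  biased_as <- match.arg(biased_as)
  if (!all(c("cell", "state") %in% names(calls))) {
    stop("`calls` needs columns `cell` and `state`")
  }
  calls <- calls[!is.na(calls$state), , drop = FALSE]
  if (nrow(calls) == 0L) stop("no determinate calls")
  st <- as.character(calls$state)
  lab_for <- function(allele) {
    opp_mono <- if (allele == "green") "mono-red" else "mono-green"
    opp_bias <- if (allele == "green") "red-biased" else "green-biased"
    lab <- rep("active", length(st))
    lab[st == opp_mono] <- "silenced"
    if (biased_as == "silenced") lab[st == opp_bias] <- "silenced"
    stats::setNames(lab, calls$cell)
  }
  res <- lapply(c(green = "green", red = "red"), function(al) {
    fit <- fitch_min_events(tree, lab_for(al), irreversible = irreversible)
    fit$earliest_stage <- if (nrow(fit$events)) min(fit$events$stage) else NA_integer_
    fit
  })
  stages <- c(res$green$earliest_stage, res$red$earliest_stage)
  res$earliest_stage <- if (all(is.na(stages))) NA_integer_ else min(stages, na.rm = TRUE)
  res
}

#' Parent-progeny association of allele-bias patterns
#'
#' Tests whether an animal's overall allele-expression pattern is inherited
#' by its brood: Spearman correlation between a per-parent score and the
#' mean score of its progeny, with a seeded permutation p-value.  A natural
#' score is the signed allele fraction, `mean(x / (x + y)) - 0.5`, positive
#' when the intestine leans green (see [allele_bias_score()]).
#'
#' @param parent numeric vector of parent scores.
#' @param brood numeric vector of brood-mean scores, paired with `parent`.
#' @param n_perm number of permutations (>= 1000 recommended; default
#'   10000).
#' @param seed optional integer seed for the permutations.
#' @return List: `rho` (Spearman), `p_value` (two-sided permutation),
#'   `n_pairs`, `degenerate` (TRUE when either side has zero variance, in
#'   which case `rho` and `p_value` are `NA`).
#' @export
pattern_heritability <- function(parent, brood, n_perm = 10000L, seed = NULL) {
  if (length(parent) != length(brood)) stop("`parent` and `brood` must be paired")
  ok <- stats::complete.cases(parent, brood)
  parent <- parent[ok]; brood <- brood[ok]
  if (length(parent) < 3L) stop("need at least 3 parent-brood pairs")
  if (stats::sd(parent) == 0 || stats::sd(brood) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_,
                n_pairs = length(parent), degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  rho <- stats::cor(parent, brood, method = "spearman")
  hits <- 0L
  for (i in seq_len(n_perm)) {
    r <- stats::cor(parent, sample(brood), method = "spearman")
    if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
  }
  list(rho = rho, p_value = (hits + 1) / (n_perm + 1),
       n_pairs = length(parent), degenerate = FALSE)
}

#' Signed allele-fraction score per animal
#'
#' @param cells normalized table with columns `animal`, `x`, `y`.
#' @return Named numeric vector: per animal, `mean(x/(x+y)) - 0.5`.
#' @export
allele_bias_score <- function(cells) {
  if (!all(c("animal", "x", "y") %in% names(cells))) {
    stop("`cells` needs columns `animal`, `x`, `y`")
  }
  f <- cells$x / (cells$x + cells$y)
  tapply(f, cells$animal, mean) - 0.5
}
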