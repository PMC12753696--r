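#' Simulate clonal allele silencing on a lineage
#'
#' Each allele (green, red) is traversed independently from the root.  At a
#' node whose parent carries an active allele, silencing initiates with the
#' stage-specific probability `params$p_init[stage + 1]`; the node where this
#' happens is recorded as an initiation event.  A silenced label is passed to
#' each daughter with probability `params$maintenance` per division (1 =
#' fully clonal propagation, the mitotically persistent regime).
#'
#' @param tree a [build_intestine_lineage()] tree.
#' @param params a [genotype_params()] object.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so cohort-level simulations stay reproducible from one seed).
#' @return An object of class `silencing_state`: list with `silenced`
#'   (logical matrix, nodes x alleles), `events` (data frame `node`,
#'   `allele`, `stage`), and `tree`.
#' @export
simulate_silencing <- function(tree, params, seed = NULL) {
  stopifnot(inherits(tree, "lineage_tree"), inherits(params, "genotype_params"))
  if (!is.null(seed)) set.seed(seed)
  alleles <- c("green", "red")
  ord <- tree_preorder(tree)
  sil <- matrix(FALSE, nrow = length(tree$nodes), ncol = 2L,
                dimnames = list(tree$nodes, alleles))
  ev_node <- character(0); ev_allele <- character(0)
  for (al in alleles) {
    for (n in ord) {
      p <- tree$parent[[n]]
      parent_sil <- if (is.na(p)) FALSE else sil[p, al]
      if (parent_sil) {
        sil[n, al] <- stats::runif(1) < params$maintenance
      } else {
        st <- tree$stage[[n]]
        if (stats::runif(1) < params$p_init[st + 1L]) {
          sil[n, al] <- TRUE
          ev_node <- c(ev_node, n); ev_allele <- c(ev_allele, al)
        }
      }
    }
  }
  events <- data.frame(node = ev_node, allele = ev_allele,
                       stage = unname(tree$stage[ev_node]),
                       stringsAsFactors = FALSE)
  structure(list(silenced = sil, events = events, tree = tree),
            class = "silencing_state")
}

#' @export
print.silencing_state <- function(x, ...) {
  cat("<silencing_state>", sum(x$silenced[x$tree$leaves, "green"]),
      "green /", sum(x$silenced[x$tree$leaves, "red"]),
      "red silenced leaves;", nrow(x$events), "initiation event(s)\n")
  invisible(x)
}

#' Simulate per-cell two-channel measurements for one animal
#'
#' Expression of each allele in a sampled cell is
#' `mu * E_c * I_a * A_a + background`, where `E_c` is a lognormal extrinsic
#' factor shared by both alleles of the cell, `I_a` an independent lognormal
#' intrinsic factor per allele, and `A_a` is 1 for an active allele and
#' `params$residual` for a silenced one.  Nuclear signal of a freely
#' diffusing monomeric fluorophore tracks cytoplasmic content, so one value
#' per cell per channel is the appropriate resolution.
#'
#' @param tree lineage tree.
#' @param state a [simulate_silencing()] result on the same tree.
#' @param params [genotype_params()].
#' @param seed optional integer seed.
#' @param n_cells number of cells measured per animal (default 7, the usual
#'   yield of a one-sided confocal field covering rings I-IV).
#' @param leaf_pool leaves eligible for sampling (default all 20); the field
#'   of view determines this in real data, so it is configurable.
#' @return Data frame with one row per sampled cell: `cell`, `ring`, `slot`,
#'   `raw_green`, `raw_red`, `green_active`, `red_active`.
#' @export
simulate_animal <- function(tree, state, params, seed = NULL, n_cells = 7L,
                            leaf_pool = NULL) {
  stopifnot(inherits(state, "silencing_state"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(leaf_pool)) leaf_pool <- tree$leaves
  if (!all(leaf_pool %in% tree$leaves)) stop("`leaf_pool` must be leaves of the tree")
  if (n_cells > length(leaf_pool)) {
    stop("cannot sample ", n_cells, " cells from a pool of ", length(leaf_pool))
  }
  picked <- sort(sample(leaf_pool, n_cells))
  e_c <- stats::rlnorm(n_cells, 0, params$sigma_ext)
  i_g <- stats::rlnorm(n_cells, 0, params$sigma_int)
  i_r <- stats::rlnorm(n_cells, 0, params$sigma_int)
  a_g <- ifelse(state$silenced[picked, "green"], params$residual, 1)
  a_r <- ifelse(state$silenced[picked, "red"], params$residual, 1)
  rg <- params$mu[["green"]] * e_c * i_g * a_g + params$background
  rr <- params$mu[["red"]]   * e_c * i_r * a_r + params$background
  rm <- tree$ring_map
  idx <- match(picked, rm$leaf)
  data.frame(
    cell = picked,
    ring = if (is.null(rm)) NA_integer_ else rm$ring[idx],
    slot = if (is.null(rm)) NA_integer_ else rm$slot[idx],
    raw_green = unname(rg), raw_red = unname(rr),
    green_active = unname(!state$silenced[picked, "green"]),
    red_active = unname(!state$silenced[picked, "red"]),
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-experiment cohort of animals
#'
#' Generates `n_experiments` independent experiments of `n_animals` animals
#' each (the standard design is three independent experiments).  Each
#' experiment carries its own multiplicative per-channel scale factor
#' (instrument gain / staining batch effect), which downstream
#' per-experiment normalization removes.
#'
#' @param params a [genotype_params()] object, or a preset name accepted by
#'   [genotype_preset()].
#' @param n_animals animals per experiment.
#' @param n_experiments number of experiments.
#' @param seed integer seed; recorded on the output.
#' @param n_cells cells measured per animal.
#' @param group group label (defaults to the genotype name).
#' @param batch_sd log-scale SD of the per-experiment, per-channel scale
#'   factors (0 disables batch effects).
#' @param tree lineage tree (default [build_intestine_lineage()]).
#' @param leaf_pool optional leaf sampling pool, see [simulate_animal()].
#' @return A cohort table: data frame with columns `animal`, `experiment`,
#'   `group`, `cell`, `ring`, `slot`, `raw_green`, `raw_red`,
#'   `green_active`, `red_active`.  Attributes: `seed`, `scales` (data frame
#'   of per-experiment channel scale factors), `params_name`.
#' @examples
#' coh <- simulate_cohort(genotype_preset("wild-type"), n_animals = 10,
#'                        n_experiments = 3, seed = 1)
#' nrow(coh)  # 3 * 10 * 7 = 210 cells
#' @export
simulate_cohort <- function(params, n_animals = 10L, n_experiments = 3L,
                            seed = NULL, n_cells = 7L, group = NULL,
                            batch_sd = 0.15, tree = build_intestine_lineage(),
                            leaf_pool = NULL) {
  if (is.character(params)) params <- genotype_preset(params)
  stopifnot(inherits(params, "genotype_params"))
  if (n_animals < 1L || n_experiments < 1L) {
    stop("`n_animals` and `n_experiments` must be >= 1")
  }
  if (is.null(group)) group <- params$name
  if (!is.null(seed)) set.seed(seed)
  scales <- data.frame(
    experiment = seq_len(n_experiments),
    scale_green = stats::rlnorm(n_experiments, 0, batch_sd),
    scale_red = stats::rlnorm(n_experiments, 0, batch_sd)
  )
  out <- vector("list", n_experiments * n_animals)
  k <- 0L
  for (e in seq_len(n_experiments)) {
    for (a in seq_len(n_animals)) {
      st <- simulate_silencing(tree, params)
      cells <- simulate_animal(tree, st, params, n_cells = n_cells,
                               leaf_pool = leaf_pool)
      cells$raw_green <- cells$raw_green * scales$scale_green[e]
      cells$raw_red <- cells$raw_red * scales$scale_red[e]
      cells <- cbind(
        data.frame(animal = sprintf("%s_e%d_a%03d", group, e, a),
                   experiment = e, group = group,
                   stringsAsFactors = FALSE),
        cells
      )
      k <- k + 1L
      out[[k]] <- cells
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "seed") <- seed
  attr(tab, "scales") <- scales
  attr(tab, "params_name") <- params$name
  tab
}

#' Fraction of simulated animals with a fully monoallelic intestine
#'
#' Simulates silencing states only (no expression noise) and scores an
#' animal as fully monoallelic when every one of the 20 cells is silenced
#' for exactly one and the same allele.  Under E-stage-only initiation with
#' per-allele probability q and full maintenance, this fraction is
#' 2q(1 - q) exactly.
#'
#' @param params [genotype_params()].
#' @param n_animals number of animals to simulate.
#' @param seed integer seed.
#' @param tree lineage tree.
#' @return A list: `fraction`, `n`, and `se` (binomial Monte-Carlo standard
#'   error).
#' @export
fully_mono_fraction <- function(params, n_animals = 10000L, seed = NULL,
                                tree = build_intestine_lineage()) {
  if (!is.null(seed)) set.seed(seed)
  leaves <- tree$leaves
  hits <- 0L
  for (i in seq_len(n_animals)) {
    st <- simulate_silencing(tree, params)
    g <- st$silenced[leaves, "green"]
    r <- st$silenced[leaves, "red"]
    if ((all(g) && !any(r)) || (all(r) && !any(g))) hits <- hits + 1L
  }
  p <- hits / n_animals
  list(fraction = p, n = n_animals, se = sqrt(p * (1 - p) / n_animals))
}
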