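tr20 <- build_intestine_lineage()

test_that("parsimony handles the trivial clonal cases", {
  all_active <- setNames(rep("active", 20), tr20$leaves)
  fit <- fitch_min_events(tr20, all_active)
  expect_equal(fit$n_events, 0)
  expect_equal(nrow(fit$events), 0)

  # one complete subtree silenced -> a single event at the subtree root
  for (node in c("Ea", "Eap", "Eappp", "E")) {
    lab <- all_active
    lab[subtree_leaves(tr20, node)] <- "silenced"
    fit <- fitch_min_events(tr20, lab)
    expect_equal(fit$n_events, 1)
    expect_identical(fit$events$node, node)
    expect_equal(fit$events$stage, unname(tr20$stage[node]))
  }
  expect_error(fitch_min_events(tr20, setNames(NA_character_, tr20$leaves[1])),
               "no labeled leaves")
})

test_that("minimum event counts match the exhaustive oracle on small trees", {
  set.seed(77)
  for (rep in 1:30) {
    n_leaves <- sample(2:8, 1)
    tree <- random_binary_tree(n_leaves)
    states <- sample(c("active", "silenced", NA), n_leaves, replace = TRUE)
    if (all(is.na(states))) states[1] <- "active"
    lab <- setNames(states, tree$leaves)
    for (irr in c(TRUE, FALSE)) {
      fit <- fitch_min_events(tree, lab, irreversible = irr)
      expect_equal(fit$n_events, oracle_fitch(tree, lab, irreversible = irr),
                   info = paste("rep", rep, "irr", irr))
      # the reported labeling realizes the reported count
      ev <- if (fit$labeling[[tree$root]] == "silenced") 1L else 0L
      for (n in tree$nodes) {
        p <- tree$parent[[n]]
        if (is.na(p)) next
        chg <- fit$labeling[[p]] != fit$labeling[[n]]
        if (chg && fit$labeling[[n]] == "silenced") ev <- ev + 1L
        if (chg && fit$labeling[[n]] == "active") {
          expect_false(irr)
          ev <- ev + 1L
        }
      }
      expect_equal(ev, fit$n_events)
    }
  }
})

test_that("initiation-stage inference matches parsimony expectations", {
  # whole intestine mono-green: red allele silenced everywhere -> stage 0
  calls <- data.frame(cell = tr20$leaves, state = "mono-green")
  inf <- infer_initiation_stage(tr20, calls)
  expect_equal(inf$red$earliest_stage, 0)
  expect_true(is.na(inf$green$earliest_stage))
  expect_equal(inf$earliest_stage, 0)

  # one two-cell ring silenced, rest biallelic: event no earlier than stage 3
  ring3 <- tr20$ring_map$leaf[tr20$ring_map$ring == 3]
  calls <- data.frame(cell = tr20$leaves,
                      state = ifelse(tr20$leaves %in% ring3,
                                     "mono-red", "biallelic"))
  inf <- infer_initiation_stage(tr20, calls)
  expect_gte(inf$green$earliest_stage, 3)

  # salt-and-pepper alternation forces leaf-stage events
  alt <- rep(c("mono-green", "mono-red"), 10)
  calls <- data.frame(cell = tr20$leaves, state = alt)
  inf <- infer_initiation_stage(tr20, calls)
  expect_gte(inf$earliest_stage, 4)
  expect_true(all(inf$green$events$stage >= 4))
  expect_true(all(inf$red$events$stage >= 4))
})

test_that("clonal single-event simulations recover the true stage", {
  set.seed(123)
  n_ok <- 0L; n <- 200L
  nodes <- tr20$nodes
  for (i in seq_len(n)) {
    node <- sample(nodes, 1)
    allele <- sample(c("green", "red"), 1)
    silenced <- subtree_leaves(tr20, node)
    state <- ifelse(tr20$leaves %in% silenced,
                    if (allele == "green") "mono-red" else "mono-green",
                    "biallelic")
    calls <- data.frame(cell = tr20$leaves, state = state)
    inf <- infer_initiation_stage(tr20, calls)
    got <- if (allele == "green") inf$green$earliest_stage else inf$red$earliest_stage
    if (isTRUE(got == unname(tr20$stage[node]))) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("pattern heritability separates inherited from independent broods", {
  set.seed(31)
  parent <- runif(50, -0.5, 0.5)
  same <- pattern_heritability(parent, parent, n_perm = 2000, seed = 1)
  expect_equal(same$rho, 1)
  expect_lt(same$p_value, 0.01)

  ok <- 0L
  for (s in 1:5) {
    set.seed(500 + s)
    p <- runif(200, -0.5, 0.5)
    b <- runif(200, -0.5, 0.5)  # progeny re-randomized independently
    res <- pattern_heritability(p, b, n_perm = 2000, seed = s)
    if (abs(res$rho) < 0.15 && res$p_value > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 4)

  deg <- pattern_heritability(rep(0.1, 10), runif(10), n_perm = 100, seed = 2)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$rho))
  expect_error(pattern_heritability(1:2, 1:2), "at least 3")
})

test_that("allele bias scores are signed green-share means per animal", {
  cells <- data.frame(animal = c("a", "a", "b"),
                      x = c(2, 2, 1), y = c(2, 0, 3))
  sc <- allele_bias_score(cells)
  expect_equal(unname(sc["a"]), mean(c(0.5, 1)) - 0.5)
  expect_equal(unname(sc["b"]), 0.25 - 0.5)
})
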