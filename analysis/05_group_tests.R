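#!/usr/bin/env Rscript
# Inferential comparisons between genotypes on per-cell intrinsic noise
# (non-normal, hence rank-based throughout): Kruskal-Wallis ANOVA on ranks
# with Dunn's pairwise procedure across the three groups, a two-sided
# Mann-Whitney test for the key two-group contrast, and a parent-brood
# heritability check on the silencing-prone genotype (silencing patterns
# are persistent within an animal but not inherited).

library(armae)

noise <- utils::read.csv("results/noise_per_cell.csv", stringsAsFactors = FALSE)
groups <- split(noise$eta, noise$group)

kw <- kruskal_wallis(groups)
print(kw)
dunn <- dunns_procedure(groups)
print(dunn)

two <- grep("wild-type|met-2", names(groups), value = TRUE)
mw <- mann_whitney_u(groups[[two[2]]], groups[[two[1]]])
print(mw)

stats_out <- list(
  kruskal_wallis = list(H = unname(kw$statistic), df = kw$df,
                        p_value = kw$p_value),
  dunns = dunn$comparisons,
  mann_whitney = list(U = unname(mw$statistic), p_value = mw$p_value,
                      groups = two)
)
jsonlite::write_json(stats_out, "results/group_tests.json",
                     auto_unbox = TRUE, digits = NA)

# heritability null: parents and broods simulated independently, as when
# silencing is re-randomized in each generation at the E-cell
set.seed(7)
parents <- simulate_cohort(genotype_preset("met-2-null-like"), 60, 1,
                           seed = 71, group = "parents")
broods <- simulate_cohort(genotype_preset("met-2-null-like"), 60, 1,
                          seed = 72, group = "broods")
ps <- allele_bias_score(normalize_per_experiment(parents))
bs <- allele_bias_score(normalize_per_experiment(broods))
her <- pattern_heritability(unname(ps), unname(bs), n_perm = 10000, seed = 73)
message(sprintf(
  "parent-brood Spearman rho = %.3f, permutation P = %.3f over %d pairs (independent generations)",
  her$rho, her$p_value, her$n_pairs))
stats_out$heritability <- her
jsonlite::write_json(stats_out, "results/group_tests.json",
                     auto_unbox = TRUE, digits = NA)
message("Test results -> results/group_tests.json")
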