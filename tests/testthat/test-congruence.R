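test_that("clade compatibility follows the intersection rule", {
  expect_true(clade_compatible(c("A", "B"), tree_abc()))
  expect_false(clade_compatible(c("A", "B"), tree_quartet()))
  # absent but compatible on a star tree
  expect_true(clade_compatible(c("A", "B"), star4()))
  expect_error(clade_compatible(c("A", "Z"), star4()), "unknown")
})

test_that("discordance support returns own Pp when present, else max conflicting Pp", {
  present <- discordance_support(c("A", "B"), tree_abc())
  expect_true(present$present)
  expect_equal(present$support, 0.9)

  # {A,B} conflicts with both {A,C} (0.98) and {B,D} (0.60): max = 0.98
  absent <- discordance_support(c("A", "B"), tree_quartet())
  expect_false(absent$present)
  expect_equal(absent$support, 0.98)

  # star tree: nothing conflicts, support 0
  star <- discordance_support(c("A", "B"), star4())
  expect_false(star$present)
  expect_equal(star$support, 0)

  # never exceeds the maximum support present in the tree
  set.seed(5)
  for (i in 1:30) {
    tr <- generate_tree(8, "uniform")
    tr <- annotated_tree(structure(tr, class = "phylo"),
                         c(NA, runif(tr$Nnode - 1)))
    lv <- sample(tr$tip.label, sample(2:6, 1))
    ds <- discordance_support(sort(lv), tr)
    expect_lte(ds$support, max(tr$support, na.rm = TRUE) + 1e-12)
  }
})

test_that("classification assigns the four categories and strength classes", {
  # identical trees: everything concordant
  tr <- generate_tree(10, "yule", seed = 1)
  tr <- annotated_tree(structure(tr, class = "phylo"), c(NA, rep(0.99, tr$Nnode - 1)))
  res <- classify_nodes(tr, tr, tr)
  expect_equal(nrow(res), 8L)
  expect_true(all(res$category == "concordant"))
  expect_true(all(res$strength_class == "not_applicable"))

  # mtDNA wins with strong support on both sides
  combined <- parse_newick("(((A,B)0.99,C)0.99,D);")
  mt <- parse_newick("(((A,B)0.99,C)0.98,D);")
  nuc <- parse_newick("(((A,C)0.99,B)0.97,D);")
  res <- classify_nodes(combined, mt, nuc)
  ab <- res[vapply(res$leaves, function(l) identical(l, c("A", "B")), TRUE), ]
  expect_equal(as.character(ab$category), "mtDNA_wins")
  expect_equal(as.character(ab$strength_class), "strong_both")
  expect_equal(ab$mt_support, 0.99)
  expect_equal(ab$nuc_support, 0.99)

  expect_error(classify_nodes(combined, prune_taxa(mt, "D"), nuc),
               "leaf sets differ")
})

test_that("category counts are conserved over random tree triplets", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(6:14, 1)
    base <- generate_tree(n, "uniform")
    mt <- perturb_nni(base, sample(0:3, 1))
    nuc <- perturb_nni(base, sample(0:3, 1))
    res <- classify_nodes(base, mt, nuc)
    expect_equal(sum(table(res$category)), n - 2L)
    expect_equal(nrow(res), n - 2L)
  }
})

test_that("tree similarity: shared proportion and Rohlf CI(1)", {
  tr <- generate_tree(9, "yule", seed = 3)
  s_same <- tree_similarity(tr, tr)
  expect_equal(s_same$proportion_shared, 1)
  expect_equal(s_same$rohlf_ci1, 1)
  expect_equal(s_same$shared_count, 7L)

  # star strict consensus: totally unresolved -> CI(1) = 0
  a <- parse_newick("((((A,B),C),D),E);")
  b <- parse_newick("((((E,D),C),B),A);")
  s0 <- tree_similarity(a, b)
  expect_equal(s0$shared_count, 0L)
  expect_equal(s0$rohlf_ci1, 0)

  # n = 5, one trichotomy in the strict consensus:
  # CI(1) = 1 - ln 3 / ln 105
  a <- parse_newick("((A,B),(C,(D,E)));")
  b <- parse_newick("((A,B),((C,D),E));")
  s1 <- tree_similarity(a, b)
  expect_equal(s1$rohlf_ci1, 1 - log(3) / log(105), tolerance = 1e-12)

  # symmetry in every field
  set.seed(21)
  for (i in 1:20) {
    t1 <- generate_tree(8, "uniform")
    t2 <- perturb_nni(t1, sample(0:4, 1))
    expect_identical(tree_similarity(t1, t2), tree_similarity(t2, t1))
  }
})

test_that("an NNI never increases the shared-clade count", {
  set.seed(13)
  for (i in 1:100) {
    t1 <- generate_tree(10, "uniform")
    t2 <- perturb_nni(t1, 1)
    expect_lte(tree_similarity(t1, t2)$shared_count,
               tree_similarity(t1, t1)$shared_count)
    # single NNI on a binary tree changes exactly one clade
    expect_equal(tree_similarity(t1, t2)$shared_count, 10L - 2L - 1L)
  }
})

test_that("conflict summary tallies percentages and the exact binomial", {
  combined <- parse_newick("(((A,B)0.99,C)0.99,D);")
  mt <- parse_newick("(((A,B)0.99,C)0.98,D);")
  nuc <- parse_newick("(((A,C)0.99,B)0.97,D);")
  res <- classify_nodes(combined, mt, nuc)
  cs <- conflict_summary(res)
  expect_equal(cs$total_nodes, 2L)
  expect_equal(cs$pct_concordant + cs$pct_discordant, 100)
  expect_equal(cs$n_strong_discordant, 1L)
  expect_equal(cs$n_strong_resolved_mt, 1L)
  # k = n = 1 favoring mtDNA, one-sided toward the deviation: P = 0.5
  expect_equal(cs$binomial_P, 0.5)

  # all concordant: discordance fields empty, binomial absent
  tr <- annotated_tree(structure(generate_tree(8, "yule", seed = 2), class = "phylo"),
                       c(NA, rep(0.99, 6)))
  cs0 <- conflict_summary(classify_nodes(tr, tr, tr))
  expect_equal(cs0$pct_discordant, 0)
  expect_true(is.na(cs0$binomial_P))
  expect_true(is.na(cs0$pct_strong_resolved_mt))

  # four strength percentages sum to 100 over discordant nodes
  set.seed(31)
  for (i in 1:20) {
    base <- generate_tree(12, "uniform")
    sc <- build_scenario(scenario_config(n_taxa = 15, seed = i,
                                         n_mt_perturbations = 3,
                                         n_nuc_perturbations = 3))
    cs <- conflict_summary(classify_nodes(sc$combined, sc$mt, sc$nuc))
    if (cs$n_discordant > 0) {
      expect_equal(cs$pct_strong_discordance + cs$pct_strong_mt_weak_nuc +
                     cs$pct_weak_mt_strong_nuc + cs$pct_weak_both, 100)
    }
  }
})

test_that("binomial conventions in the summary reproduce published-style values", {
  fake_res <- function(n_strong_mt, n_strong_other, n_conc) {
    data.frame(
      category = factor(c(rep("mtDNA_wins", n_strong_mt),
                          rep("nucDNA_wins", n_strong_other),
                          rep("concordant", n_conc)),
                        levels = c("concordant", "mtDNA_wins", "nucDNA_wins", "unique")),
      strength_class = factor(c(rep("strong_both", n_strong_mt + n_strong_other),
                                rep("not_applicable", n_conc)),
                              levels = c("strong_both", "strong_mt_weak_nuc",
                                         "weak_mt_strong_nuc", "weak_both",
                                         "not_applicable")))
  }
  # 0 of 5 and 0 of 7 strong conflicts favoring mtDNA, one-sided: the
  # derivable published values 0.0313 and 0.0078
  expect_equal(conflict_summary(fake_res(0, 5, 10), threshold = 0.95)$binomial_P,
               0.03125)
  expect_equal(conflict_summary(fake_res(0, 7, 10), threshold = 0.95)$binomial_P,
               0.0078125)
  # the point-probability convention recovers the remaining printed style of
  # value, e.g. 15 of 19 -> 0.0074
  p_point <- conflict_summary(fake_res(15, 4, 17), threshold = 0.95,
                              binomial_convention = "point")$binomial_P
  expect_equal(round(p_point, 4), 0.0074)
})
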