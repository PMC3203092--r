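test_that("minimum-change length handles the hand cases", {
  tr <- parse_newick("((A1,A2),(B1,B2));")
  expect_equal(fitch_length(tr, c(A1 = "A", A2 = "A", B1 = "C", B2 = "C")), 1L)
  expect_equal(fitch_length(tr, c(A1 = "A", A2 = "A", B1 = "A", B2 = "A")), 0L)
  expect_equal(fitch_length(tr, c(A1 = "?", A2 = "?", B1 = "?", B2 = "?")), 0L)
  # fewer than two informative states
  expect_equal(fitch_length(tr, c(A1 = "A", A2 = "?", B1 = "?", B2 = "?")), 0L)
  # mismatched tree ((A1,B1),(A2,B2)): both splits mixed -> 2 changes
  tr_mis <- parse_newick("((A1,B1),(A2,B2));")
  expect_equal(fitch_length(tr_mis, c(A1 = "A", A2 = "A", B1 = "C", B2 = "C")), 2L)
  # ambiguity codes act as state subsets: R = {A,G} can absorb an A
  expect_equal(fitch_length(tr, c(A1 = "A", A2 = "R", B1 = "G", B2 = "G")), 1L)
  expect_error(fitch_length(tr, c(Z1 = "A")), "not in the tree")
})

test_that("minimum-change length equals exhaustive enumeration on random trees", {
  set.seed(71)
  for (i in 1:120) {
    n <- sample(4:8, 1)
    tr <- generate_tree(n, "uniform")
    states <- random_character(tr$tip.label)
    expect_equal(fitch_length(tr, states), brute_force_steps(tr, states))
  }
  # including trees with polytomies
  polytomies <- c("((A,B,C),(D,E));", "(A,B,C,D,E);", "((A,B),(C,D,E),F);")
  for (nw in polytomies) {
    tr <- parse_newick(nw)
    for (i in 1:30) {
      states <- random_character(tr$tip.label, p_missing = 0.2)
      expect_equal(fitch_length(tr, states), brute_force_steps(tr, states))
    }
  }
})

test_that("step count is monotone under leaf addition and order invariant", {
  set.seed(73)
  for (i in 1:25) {
    tr <- generate_tree(7, "uniform")
    states <- random_character(tr$tip.label, p_missing = 0)
    s_full <- fitch_length(tr, states)
    drop <- sample(tr$tip.label, 1)
    s_less <- fitch_length(prune_taxa(tr, drop), states[setdiff(names(states), drop)])
    expect_lte(s_less, s_full)
    # taxon order in the state vector is irrelevant
    expect_equal(fitch_length(tr, states[sample(names(states))]), s_full)
  }
})

test_that("variable and informative counts match a direct per-column tally", {
  m <- char_matrix(c(a = "AACC", b = "AACC", c = "AGTC", d = "A?TC"))
  cc <- character_counts(m)
  # site 1 constant; site 2 variable (A,A,G) but G observed once; site 3
  # has two states twice each (informative); site 4 constant
  expect_equal(cc$variable, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(cc$informative, c(FALSE, FALSE, TRUE, FALSE))

  set.seed(79)
  for (i in 1:200) {
    n_tax <- sample(3:8, 1); n_sites <- sample(1:12, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "?", "-"), n_tax * n_sites,
                       replace = TRUE, prob = c(rep(0.2, 4), 0.1, 0.1)),
                n_tax, n_sites, dimnames = list(paste0("t", 1:n_tax), NULL))
    cc <- character_counts(m)
    oracle_var <- oracle_inf <- 0L
    for (j in seq_len(n_sites)) {
      tab <- table(m[, j][m[, j] %in% c("A", "C", "G", "T")])
      oracle_var <- oracle_var + (length(tab) >= 2)
      oracle_inf <- oracle_inf + (sum(tab >= 2) >= 2)
    }
    expect_equal(cc$n_variable, oracle_var)
    expect_equal(cc$n_parsimony_informative, oracle_inf)
  }
})

test_that("ensemble CI and RI: perfect fit, hand case, and invariants", {
  # data simulated at negligible rate on the true tree: no homoplasy
  tr <- generate_tree(10, "yule", seed = 5)
  m <- simulate_matrix(tr, 300, rate = 1e-6, seed = 6)
  # force a little variation in: a clean two-state informative site
  cl <- extract_clades(tr)
  mid <- which(cl$n_leaves >= 2 & cl$n_leaves <= 8)  # informative split
  big <- cl$leaves[[mid[which.max(cl$n_leaves[mid])]]]
  m <- cbind(m, ifelse(rownames(m) %in% big, "A", "C"))
  h <- ensemble_indices(tr, m)
  expect_equal(h$CI, 1)
  expect_equal(h$RI, 1)

  # the mismatched quartet: s=2, m=1, g=2 -> CI = 0.5, RI = 0
  tr_q <- parse_newick("((A1,B1),(A2,B2));")
  m_q <- char_matrix(c(A1 = "A", A2 = "A", B1 = "C", B2 = "C"))
  h_q <- ensemble_indices(tr_q, m_q)
  expect_equal(h_q$S, 2L); expect_equal(h_q$M, 1L); expect_equal(h_q$G, 2L)
  expect_equal(h_q$CI, 0.5)
  expect_equal(h_q$RI, 0)

  # per character m <= s <= g
  set.seed(83)
  for (i in 1:20) {
    tr <- generate_tree(8, "uniform")
    m <- simulate_matrix(tr, 50, rate = sample(c(0.2, 1, 3), 1),
                         missing_fraction = 0.1)
    h <- ensemble_indices(tr, m)
    expect_true(all(h$per_site$m <= h$per_site$s))
    expect_true(all(h$per_site$s <= h$per_site$g))
  }

  # adding an uninformative character leaves CI unchanged (exclusion flag)
  tr8 <- generate_tree(8, "uniform", seed = 9)
  m8 <- simulate_matrix(tr8, 80, rate = 1, seed = 10)
  ci0 <- ensemble_indices(tr8, m8)$CI
  m8u <- cbind(m8, c("G", rep("A", 7)))
  expect_equal(ensemble_indices(tr8, m8u)$CI, ci0)

  # S invariant under taxon and site reordering
  h1 <- ensemble_indices(tr8, m8[sample(8), sample(80)])
  expect_equal(h1$S, ensemble_indices(tr8, m8)$S)

  # no informative variation -> indices absent
  m_const <- char_matrix(c(A1 = "AAAA", A2 = "AAAA", B1 = "AAAA", B2 = "AAAA"))
  h_c <- ensemble_indices(tr_q, m_const)
  expect_true(is.na(h_c$CI)); expect_true(is.na(h_c$RI))

  # matrix taxa must be leaves; missing rows treated as all-missing
  expect_error(ensemble_indices(tr_q, char_matrix(c(Z = "A"))), "absent")
  m_sub <- char_matrix(c(A1 = "A", A2 = "A", B1 = "C"))
  expect_equal(ensemble_indices(tr_q, m_sub)$S, 1L)
})

test_that("CI and RI decrease with the simulated substitution rate", {
  set.seed(89)
  rates <- c(0.05, 0.5, 2.0)
  mean_ci <- mean_ri <- numeric(3)
  tr <- generate_tree(12, "yule", seed = 12)
  for (r in seq_along(rates)) {
    cis <- ris <- numeric(20)
    for (k in 1:20) {
      m <- simulate_matrix(tr, 120, rate = rates[r])
      h <- ensemble_indices(tr, m)
      cis[k] <- h$CI; ris[k] <- h$RI
    }
    mean_ci[r] <- mean(cis, na.rm = TRUE)
    mean_ri[r] <- mean(ris, na.rm = TRUE)
  }
  expect_true(all(diff(mean_ci) < 0))
  expect_true(all(diff(mean_ri) < 0))
})

test_that("relative homoplasy sign conventions mirror each other", {
  expect_equal(relative_homoplasy(0.6, 0.3), 0.3)
  expect_equal(relative_homoplasy(0.6, 0.3, "homoplasy_difference"), -0.3)
})
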