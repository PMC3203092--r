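# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own computational paths.

# Brute-force minimum parsimony steps: enumerate every assignment of the four
# states to the internal nodes and count changes on each edge. Leaves may be
# constrained to a state subset; a leaf edge costs 0 iff the parent state can
# be matched by an allowed leaf state... here leaves are fixed to their
# subset, so a leaf edge contributes 1 unless the parent's state is in the
# subset OR the subset can absorb one change -- i.e. cost is 0 when parent
# state is allowed at the leaf, else 1.
brute_force_steps <- function(tree, states) {
  phy <- ape::reorder.phylo(mitonuc::annotated_tree(tree), "postorder")
  class(phy) <- "phylo"
  n_tip <- length(phy$tip.label)
  n_int <- phy$Nnode
  bases <- c("A", "C", "G", "T")
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = bases, `?` = bases, `-` = bases)
  leaf_allowed <- lapply(phy$tip.label, function(tp) {
    s <- states[tp]
    if (is.na(s)) bases else iupac[[s]]
  })
  grid <- as.matrix(expand.grid(rep(list(bases), n_int),
                                stringsAsFactors = FALSE))
  best <- Inf
  for (a in seq_len(nrow(grid))) {
    assign_state <- grid[a, ]
    total <- 0L
    for (k in seq_len(nrow(phy$edge))) {
      par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
      ps <- assign_state[par - n_tip]
      if (chi <= n_tip) {
        if (!(ps %in% leaf_allowed[[chi]])) total <- total + 1L
      } else {
        if (ps != assign_state[chi - n_tip]) total <- total + 1L
      }
      if (total >= best) break
    }
    best <- min(best, total)
  }
  as.integer(best)
}

# Exact Wilcoxon P by full enumeration of all group assignments.
enumerate_wilcoxon <- function(x, y, sidedness = "two") {
  n_x <- length(x); N <- n_x + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n_x)])
  combos <- utils::combn(N, n_x)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  eps <- 1e-9
  pl <- mean(w_all <= w_obs + eps)
  pu <- mean(w_all >= w_obs - eps)
  switch(sidedness,
         two = min(1, 2 * min(pl, pu)),
         greater = pu,
         less = pl)
}

# random character for a tree: resolved states plus optional missing cells
random_character <- function(tip_labels, p_missing = 0.15) {
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, length(tip_labels), replace = TRUE)
  mask <- runif(length(s)) < p_missing
  s[mask] <- "?"
  setNames(s, tip_labels)
}

# small fixed trees used in several files
tree_abc <- function() parse_newick("((A:1,B:1)0.9:0.5,C:2);")
tree_quartet <- function() parse_newick("((A:1,C:1)0.98:1,(B:1,D:1)0.60:1);")
star4 <- function() parse_newick("(A:1,B:1,C:1,D:1);")
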