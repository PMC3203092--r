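# Clade compatibility, discordance support, four-way clade classification,
# tree similarity indices, and the per-study conflict summary.

# internal: list of sorted leaf vectors for the non-root internal nodes,
# plus parallel support vector
tree_cladeset <- function(tree) {
  tree <- as_annotated(tree)
  cl <- extract_clades(tree)
  list(leaves = cl$leaves, support = cl$support,
       keys = vapply(cl$leaves, clade_key, character(1)),
       universe = sort(tree$tip.label, method = "radix"))
}

check_leafset <- function(leaves, universe) {
  unknown <- setdiff(leaves, universe)
  if (length(unknown))
    stop("leaf set contains taxa unknown to the tree: ",
         paste(unknown, collapse = ", "))
}

compatible_sets <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

#' Is a leaf set compatible with a tree?
#'
#' A leaf set `c` is compatible with a rooted tree when, for every clade `d`
#' of the tree, the intersection of `c` and `d` is empty, all of `c`, or all
#' of `d`. A clade that is absent from a tree can still be compatible with it
#' when the tree contains polytomies.
#'
#' @param leaves Character vector of leaf labels (the candidate clade).
#' @param tree An [annotated_tree] or `"phylo"` sharing those leaves.
#' @return `TRUE` or `FALSE`.
#' @export
clade_compatible <- function(leaves, tree) {
  cs <- tree_cladeset(tree)
  check_leafset(leaves, cs$universe)
  for (d in cs$leaves)
    if (!compatible_sets(leaves, d)) return(FALSE)
  TRUE
}

#' Support for or against a clade in a tree
#'
#' If the leaf set is a clade of the tree, returns its own support
#' (`present = TRUE`). Otherwise returns the highest support of any clade of
#' the tree that is incompatible with the monophyly of the leaf set
#' (`present = FALSE`); 0 if no incompatible clade exists or none carries a
#' support value.
#'
#' @inheritParams clade_compatible
#' @return A list with elements `present` (logical) and `support` (numeric;
#'   `NA` only when the clade is present but carries no support value).
#' @export
discordance_support <- function(leaves, tree) {
  cs <- tree_cladeset(tree)
  check_leafset(leaves, cs$universe)
  key <- clade_key(leaves)
  hit <- match(key, cs$keys)
  if (!is.na(hit))
    return(list(present = TRUE, support = cs$support[hit]))
  incomp <- !vapply(cs$leaves, compatible_sets, logical(1), b = leaves)
  supp <- cs$support[incomp]
  supp <- supp[!is.na(supp)]
  list(present = FALSE, support = if (length(supp)) max(supp) else 0)
}

CATEGORIES <- c("concordant", "mtDNA_wins", "nucDNA_wins", "unique")
STRENGTH <- c("strong_both", "strong_mt_weak_nuc", "weak_mt_strong_nuc",
              "weak_both", "not_applicable")

#' Classify every combined-tree clade against the mtDNA and nucDNA trees
#'
#' Assigns each non-trivial clade of the combined-data tree to one of four
#' resolution categories: `concordant` (present in both single-data trees),
#' `mtDNA_wins` (present only in the mtDNA tree), `nucDNA_wins` (present only
#' in the nucDNA tree), or `unique` (present in neither). For a tree in which
#' the clade is absent, its recorded support is the discordance support (see
#' [discordance_support()]). Discordant clades are further classed by whether
#' the supports on each side reach `threshold`.
#'
#' @param combined,mt,nuc Trees with identical leaf sets
#'   ([annotated_tree] or `"phylo"`).
#' @param threshold Posterior probability at or above which support counts as
#'   strong (default 0.95).
#' @param strict_presence When `TRUE` (default) a clade counts as present in
#'   a tree only if that exact leaf set is a clade of the tree; a clade that
#'   is merely compatible (via a polytomy) is still counted as discordant,
#'   with discordance support 0. When `FALSE`, compatible-but-absent clades
#'   count as present.
#' @param species_map,collapse_conspecific Passed to [extract_clades()] for
#'   the combined tree (single-species clades are then not classified).
#' @return A `clade_resolutions` data frame: one row per combined-tree clade
#'   with columns `clade_id`, `node_id`, `n_leaves`, `support`,
#'   `branch_length`, `depth_topological`, `depth_pathlength`, `category`,
#'   `mt_present`, `nuc_present`, `mt_support`, `nuc_support`,
#'   `strength_class`, and the list column `leaves`.
#' @export
classify_nodes <- function(combined, mt, nuc, threshold = 0.95,
                           strict_presence = TRUE,
                           species_map = NULL, collapse_conspecific = FALSE) {
  combined <- as_annotated(combined); mt <- as_annotated(mt); nuc <- as_annotated(nuc)
  check_same_leaves(combined, mt, "combined", "mt")
  check_same_leaves(combined, nuc, "combined", "nuc")
  cl <- extract_clades(combined, species_map = species_map,
                       collapse_conspecific = collapse_conspecific)
  mt_cs <- tree_cladeset(mt)
  nuc_cs <- tree_cladeset(nuc)
  n <- nrow(cl)
  res <- cl
  res$mt_present <- logical(n); res$nuc_present <- logical(n)
  res$mt_support <- numeric(n); res$nuc_support <- numeric(n)
  for (i in seq_len(n)) {
    lv <- cl$leaves[[i]]
    for (side in c("mt", "nuc")) {
      cs <- if (side == "mt") mt_cs else nuc_cs
      key <- clade_key(lv)
      hit <- match(key, cs$keys)
      if (!is.na(hit)) {
        present <- TRUE; supp <- cs$support[hit]
      } else {
        incomp <- !vapply(cs$leaves, compatible_sets, logical(1), b = lv)
        present <- if (strict_presence) FALSE else !any(incomp)
        ss <- cs$support[incomp]; ss <- ss[!is.na(ss)]
        supp <- if (length(ss)) max(ss) else 0
        if (present) supp <- NA_real_  # compatible counted as present: no Pp
      }
      if (side == "mt") { res$mt_present[i] <- present; res$mt_support[i] <- supp }
      else { res$nuc_present[i] <- present; res$nuc_support[i] <- supp }
    }
  }
  res$category <- factor(ifelse(res$mt_present & res$nuc_present, "concordant",
                         ifelse(res$mt_present, "mtDNA_wins",
                         ifelse(res$nuc_present, "nucDNA_wins", "unique"))),
                         levels = CATEGORIES)
  strong_mt <- !is.na(res$mt_support) & res$mt_support >= threshold
  strong_nuc <- !is.na(res$nuc_support) & res$nuc_support >= threshold
  res$strength_class <- factor(ifelse(res$category == "concordant", "not_applicable",
                              ifelse(strong_mt & strong_nuc, "strong_both",
                              ifelse(strong_mt, "strong_mt_weak_nuc",
                              ifelse(strong_nuc, "weak_mt_strong_nuc", "weak_both")))),
                              levels = STRENGTH)
  attr(res, "threshold") <- threshold
  class(res) <- c("clade_resolutions", class(res))
  res
}

check_same_leaves <- function(a, b, name_a, name_b) {
  la <- a$tip.label; lb <- b$tip.label
  d1 <- setdiff(la, lb); d2 <- setdiff(lb, la)
  if (length(d1) || length(d2))
    stop("leaf sets differ between ", name_a, " and ", name_b, " trees; only in ",
         name_a, ": {", paste(d1, collapse = ", "), "}; only in ", name_b,
         ": {", paste(d2, collapse = ", "), "}")
  invisible(TRUE)
}

# double factorial (2n-3)!! on the log scale: log number of rooted binary
# labelled topologies on n leaves
ldfact_rooted <- function(n) {
  if (n <= 2) return(0)
  sum(log(seq(1, 2 * n - 3, by = 2)))
}

#' Similarity between two rooted trees on the same leaves
#'
#' Two indices are computed. `proportion_shared` is the number of non-trivial
#' clades common to both trees divided by `n - 2`, the number of such clades
#' in a fully resolved rooted tree on `n` leaves. `rohlf_ci1` is the
#' consensus-information index CI(1) of the strict consensus `S` of the pair:
#' `1 - ln R(S) / ln((2n - 3)!!)`, where `R(S)` is the number of fully
#' resolved rooted trees compatible with `S` (the product over polytomies of
#' `d >= 3` children of `(2d - 3)!!`). Identical binary trees give 1 on both
#' indices; a pair whose strict consensus is the star tree gives
#' `rohlf_ci1 = 0`.
#'
#' @param tree_a,tree_b Trees with identical leaf sets.
#' @return A list: `shared_count`, `proportion_shared`, `rohlf_ci1`,
#'   `n_leaves`.
#' @export
tree_similarity <- function(tree_a, tree_b) {
  tree_a <- as_annotated(tree_a); tree_b <- as_annotated(tree_b)
  check_same_leaves(tree_a, tree_b, "first", "second")
  n <- length(tree_a$tip.label)
  ka <- tree_cladeset(tree_a)$keys
  kb <- tree_cladeset(tree_b)$keys
  shared <- length(intersect(ka, kb))
  # strict consensus of two rooted trees = clades present in both;
  # reconstruct its child counts from the laminar family of shared clades
  log_R <- consensus_log_resolutions(tree_a, shared_keys = intersect(ka, kb))
  denom <- ldfact_rooted(n)
  list(shared_count = shared,
       proportion_shared = shared / (n - 2),
       rohlf_ci1 = if (denom > 0) 1 - log_R / denom else NA_real_,
       n_leaves = n)
}

# log of the number of binary resolutions of the strict consensus whose
# internal clades are `shared_keys` (keys of clades present in both trees).
# The consensus node set = root + shared clades + leaves; each node's child
# count is the number of maximal elements of the family directly below it.
consensus_log_resolutions <- function(tree, shared_keys) {
  universe <- sort(tree$tip.label, method = "radix")
  cl <- extract_clades(tree)
  keep <- vapply(cl$leaves, function(lv) clade_key(lv) %in% shared_keys, logical(1))
  clades <- cl$leaves[keep]
  # nodes: root (universe) + kept clades; children resolved by containment
  nodes <- c(list(universe), clades)
  sizes <- lengths(nodes)
  log_R <- 0
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    # direct children among other clades: maximal proper subsets
    inside <- which(sizes < length(nd) &
                      vapply(nodes, function(x)
                        length(x) < length(nd) && all(x %in% nd), logical(1)))
    child_clades <- nodes[inside]
    if (length(inside) > 1L) {
      maximal <- vapply(seq_along(inside), function(j) {
        !any(vapply(seq_along(inside), function(k)
          k != j && all(child_clades[[j]] %in% child_clades[[k]]), logical(1)))
      }, logical(1))
      child_clades <- child_clades[maximal]
    }
    covered <- unlist(child_clades)
    n_children <- length(child_clades) + (length(nd) - length(covered))
    if (n_children >= 3L) log_R <- log_R + ldfact_rooted(n_children)
  }
  log_R
}

#' Summarize conflict classifications into a per-study report row
#'
#' Tallies the resolution categories from [classify_nodes()] into the
#' standard summary: percent concordant/discordant, the four
#' support-strength classes among discordant nodes, the percentage of
#' strongly supported conflicts resolved in favour of mtDNA, and an exact
#' binomial test of that percentage against 0.5.
#'
#' @param resolutions A `clade_resolutions` data frame.
#' @param threshold Support threshold used for the strength classes (defaults
#'   to the one recorded by [classify_nodes()]).
#' @param binomial_convention How the binomial P is computed from
#'   `k` strong conflicts favouring mtDNA out of `n`:
#'   `"deviation"` (default) is one-sided toward the observed deviation from
#'   0.5; `"two_sided"` is the minimum-likelihood two-sided test; `"point"`
#'   is the binomial point probability `dbinom(k, n, 0.5)` (the convention
#'   that reproduces some published tables).
#' @return A list of class `conflict_summary` with fields `total_nodes`,
#'   `n_concordant`, `n_discordant`, `pct_concordant`, `pct_discordant`,
#'   `pct_strong_discordance`, `pct_strong_mt_weak_nuc`,
#'   `pct_weak_mt_strong_nuc`, `pct_weak_both`, `n_strong_discordant`,
#'   `n_strong_resolved_mt`, `pct_strong_resolved_mt`, `binomial_P`.
#'   Percentages are on 0-100 at full precision; strong-conflict fields are
#'   `NA` when there are no strongly supported conflicts.
#' @export
conflict_summary <- function(resolutions,
                             threshold = attr(resolutions, "threshold"),
                             binomial_convention = c("deviation", "two_sided", "point")) {
  binomial_convention <- match.arg(binomial_convention)
  if (nrow(resolutions) == 0L) stop("empty resolution list")
  total <- nrow(resolutions)
  conc <- sum(resolutions$category == "concordant")
  disc <- total - conc
  sc <- resolutions$strength_class
  n_strong <- sum(sc == "strong_both")
  k_mt <- sum(sc == "strong_both" & resolutions$category == "mtDNA_wins")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  binom_P <- NA_real_
  if (n_strong > 0) {
    binom_P <- switch(binomial_convention,
      deviation = {
        side <- if (k_mt / n_strong >= 0.5) "greater" else "less"
        binom_exact(k_mt, n_strong, 0.5, sidedness = side)$p_value
      },
      two_sided = binom_exact(k_mt, n_strong, 0.5, sidedness = "two")$p_value,
      point = stats::dbinom(k_mt, n_strong, 0.5))
  }
  out <- list(
    total_nodes = total,
    n_concordant = conc, n_discordant = disc,
    pct_concordant = pct(conc, total), pct_discordant = pct(disc, total),
    pct_strong_discordance = pct(n_strong, disc),
    pct_strong_mt_weak_nuc = pct(sum(sc == "strong_mt_weak_nuc"), disc),
    pct_weak_mt_strong_nuc = pct(sum(sc == "weak_mt_strong_nuc"), disc),
    pct_weak_both = pct(sum(sc == "weak_both"), disc),
    n_strong_discordant = n_strong,
    n_strong_resolved_mt = if (n_strong > 0) k_mt else NA_integer_,
    pct_strong_resolved_mt = pct(k_mt, n_strong),
    binomial_P = binom_P,
    threshold = threshold
  )
  class(out) <- "conflict_summary"
  out
}

#' @export
print.conflict_summary <- function(x, ...) {
  cat(sprintf("Clade resolution summary (%d nodes, support threshold %.2f)\n",
              x$total_nodes, x$threshold))
  cat(sprintf("  concordant: %d (%.0f%%)   discordant: %d (%.0f%%)\n",
              x$n_concordant, x$pct_concordant, x$n_discordant, x$pct_discordant))
  if (x$n_discordant > 0) {
    cat(sprintf("  of discordant: strong both %.0f%%, strong mt/weak nuc %.0f%%, weak mt/strong nuc %.0f%%, weak both %.0f%%\n",
                x$pct_strong_discordance, x$pct_strong_mt_weak_nuc,
                x$pct_weak_mt_strong_nuc, x$pct_weak_both))
  }
  if (!is.na(x$pct_strong_resolved_mt))
    cat(sprintf("  strong conflicts resolved favouring mtDNA: %d/%d (%.0f%%), exact binomial P = %.4g\n",
                x$n_strong_resolved_mt, x$n_strong_discordant,
                x$pct_strong_resolved_mt, x$binomial_P))
  invisible(x)
}
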