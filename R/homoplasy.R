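# Parsimony step counts on a fixed rooted tree and the ensemble consistency
# and retention indices.

# Map state symbols to logical state-set rows over A,C,G,T.
BASES <- c("A", "C", "G", "T")

state_set <- function(symbol) {
  s <- IUPAC[[symbol]]
  if (is.null(s)) stop("unknown state symbol: ", symbol)
  BASES %in% s
}

#' Minimum number of state changes of one character on a rooted tree
#'
#' Computes the parsimony length of a single character on a fixed rooted
#' topology by unit-cost dynamic programming (Sankoff recursion over the
#' four nucleotide states). On strictly bifurcating trees this equals the
#' Fitch count; on polytomies the dynamic program still attains the true
#' minimum over all ancestral-state assignments (hard-polytomy semantics).
#' IUPAC ambiguity codes restrict a leaf to the corresponding state subset;
#' `?` and `-` leave it unconstrained, as do taxa absent from `states`.
#'
#' @param tree An [annotated_tree] or `"phylo"`.
#' @param states Named character vector of state symbols, names = leaf
#'   labels. Names outside the tree's leaf set raise an error.
#' @return Integer: the minimum number of changes (0 when fewer than two
#'   leaves carry an informative state).
#' @examples
#' tr <- parse_newick("((A1,A2),(B1,B2));")
#' fitch_length(tr, c(A1 = "A", A2 = "A", B1 = "C", B2 = "C"))  # 1
#' @export
fitch_length <- function(tree, states) {
  tree <- as_annotated(tree)
  phy <- ape::reorder.phylo(as_phylo(tree), "postorder")
  unknown <- setdiff(names(states), phy$tip.label)
  if (length(unknown))
    stop("states given for taxa not in the tree: ", paste(unknown, collapse = ", "))
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  # cost[node, state]: minimum changes in the subtree given the node's state
  cost <- matrix(0, nrow = n_all, ncol = 4L)
  for (i in seq_len(n_tip)) {
    sym <- states[phy$tip.label[i]]
    allowed <- if (is.na(sym)) rep(TRUE, 4L) else state_set(sym)
    cost[i, ] <- ifelse(allowed, 0, Inf)
  }
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    # staying in the child's state costs cost[chi, s]; one change costs min+1
    cost[par, ] <- cost[par, ] + pmin(cost[chi, ], min(cost[chi, ]) + 1)
  }
  as.integer(min(cost[n_tip + 1L, ]))
}

# Vectorized unit-cost Sankoff over all columns of a matrix at once: one
# pass over the edges with (sites x 4) cost blocks per node. Equals
# fitch_length() column by column.
fitch_lengths_matrix <- function(tree, mat) {
  tree <- as_annotated(tree)
  phy <- ape::reorder.phylo(as_phylo(tree), "postorder")
  n_tip <- length(phy$tip.label)
  n_sites <- ncol(mat)
  symbols <- names(IUPAC)
  allowed <- vapply(symbols, state_set, logical(4))  # 4 x n_symbols
  cost <- vector("list", n_tip + phy$Nnode)
  zero <- matrix(0, nrow = n_sites, ncol = 4L)
  for (i in seq_len(n_tip)) {
    tip <- phy$tip.label[i]
    if (tip %in% rownames(mat)) {
      idx <- match(mat[tip, ], symbols)
      if (anyNA(idx))
        stop("unknown state symbol(s): ",
             paste(unique(mat[tip, ][is.na(idx)]), collapse = ", "))
      ok <- t(allowed[, idx, drop = FALSE])  # n_sites x 4
      cost[[i]] <- ifelse(ok, 0, Inf)
    } else {
      cost[[i]] <- zero  # taxon absent: all-missing
    }
  }
  for (nd in seq.int(n_tip + 1L, n_tip + phy$Nnode)) cost[[nd]] <- zero
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    cc <- cost[[chi]]
    row_min <- pmin(cc[, 1L], cc[, 2L], cc[, 3L], cc[, 4L])
    cost[[par]] <- cost[[par]] + pmin(cc, row_min + 1)
  }
  rc <- cost[[n_tip + 1L]]
  as.integer(pmin(rc[, 1L], rc[, 2L], rc[, 3L], rc[, 4L]))
}

#' Count variable and parsimony-informative characters
#'
#' A character is variable when at least two distinct resolved states are
#' observed (IUPAC partial ambiguities and missing symbols are not counted
#' as states), and parsimony-informative when at least two states are each
#' observed in at least two taxa.
#'
#' @param mat A character matrix from [read_char_matrix()] or
#'   [char_matrix()].
#' @return A list with `n_variable`, `n_parsimony_informative`, and logical
#'   vectors `variable`, `informative` (one element per site).
#' @export
character_counts <- function(mat) {
  if (length(mat) == 0L) stop("empty matrix")
  site_stats <- apply(mat, 2L, function(col) {
    counts <- tabulate(match(col[col %in% BASES], BASES), 4L)
    counts <- counts[counts > 0]
    c(variable = length(counts) >= 2L,
      informative = sum(counts >= 2L) >= 2L)
  })
  variable <- as.logical(site_stats["variable", ])
  informative <- as.logical(site_stats["informative", ])
  list(n_variable = sum(variable),
       n_parsimony_informative = sum(informative),
       variable = variable, informative = informative)
}

#' Ensemble consistency and retention indices on a fixed tree
#'
#' For each character computes the observed minimum steps `s` on the tree
#' (via [fitch_length()]), the theoretical minimum `m` (number of observed
#' resolved states minus 1), and the maximum `g` (number of resolved cells
#' minus the largest state frequency; the star-tree step count). The
#' ensemble consistency index is `CI = sum(m) / sum(s)` over the included
#' characters (parsimony-informative characters only when
#' `exclude_uninformative_for_CI = TRUE`, the conventional "CI excluding
#' uninformative characters"); the retention index is
#' `RI = (sum(g) - sum(s)) / (sum(g) - sum(m))` over characters with
#' `g > m`. Lower values of either index indicate more homoplasy.
#'
#' @param tree The fixed evaluation tree (typically the combined-data tree).
#' @param mat Character matrix; taxa must be a subset of the tree's leaves
#'   (tree leaves absent from the matrix are treated as all-missing).
#' @param exclude_uninformative_for_CI Restrict CI to parsimony-informative
#'   characters (default `TRUE`)?
#' @return A list of class `homoplasy_result`: `n_sites`, `n_variable`,
#'   `n_parsimony_informative`, `S`, `M`, `G`, `CI`, `RI`. `CI`/`RI` are
#'   `NA` when no character contributes observed steps.
#' @export
ensemble_indices <- function(tree, mat, exclude_uninformative_for_CI = TRUE) {
  tree <- as_annotated(tree)
  extra <- setdiff(rownames(mat), tree$tip.label)
  if (length(extra))
    stop("matrix taxa absent from the tree: ", paste(extra, collapse = ", "))
  counts <- character_counts(mat)
  n_sites <- ncol(mat)
  s <- m <- g <- integer(n_sites)
  for (j in seq_len(n_sites)) {
    col <- mat[, j]
    tallies <- tabulate(match(col[col %in% BASES], BASES), 4L)
    tallies <- tallies[tallies > 0]
    k <- length(tallies)
    m[j] <- max(k - 1L, 0L)
    g[j] <- if (k > 0) sum(tallies) - max(tallies) else 0L
  }
  if (any(counts$variable))
    s[counts$variable] <- fitch_lengths_matrix(tree, mat[, counts$variable, drop = FALSE])
  ci_idx <- if (exclude_uninformative_for_CI) counts$informative else counts$variable
  ri_idx <- g > m
  S_ci <- sum(s[ci_idx])
  out <- list(
    n_sites = n_sites,
    n_variable = counts$n_variable,
    n_parsimony_informative = counts$n_parsimony_informative,
    S = sum(s), M = sum(m), G = sum(g),
    CI = if (S_ci > 0) sum(m[ci_idx]) / S_ci else NA_real_,
    RI = if (sum(g[ri_idx]) > sum(m[ri_idx]))
      (sum(g[ri_idx]) - sum(s[ri_idx])) / (sum(g[ri_idx]) - sum(m[ri_idx]))
    else NA_real_,
    per_site = data.frame(s = s, m = m, g = g,
                          variable = counts$variable,
                          informative = counts$informative)
  )
  class(out) <- "homoplasy_result"
  out
}

#' @export
print.homoplasy_result <- function(x, ...) {
  cat(sprintf("Homoplasy on fixed tree: %d sites (%d variable, %d informative)\n",
              x$n_sites, x$n_variable, x$n_parsimony_informative))
  cat(sprintf("  steps S = %d (min M = %d, max G = %d);  CI = %s, RI = %s\n",
              x$S, x$M, x$G, format(x$CI, digits = 4), format(x$RI, digits = 4)))
  invisible(x)
}

#' Relative homoplasy difference between two data partitions
#'
#' The cross-clade correlate of conflict resolution: the difference between
#' the nuclear and mitochondrial homoplasy index (consistency or retention).
#' Because these indices decrease with homoplasy, the default sign convention
#' `"index_difference"` returns `nuc - mt` (positive when mtDNA is the more
#' homoplastic partition); `"homoplasy_difference"` returns the negated
#' value, i.e. `(1 - nuc) - (1 - mt)`.
#'
#' @param nuc_index,mt_index Homoplasy index values (CI or RI) for the
#'   nuclear and mitochondrial partitions.
#' @param sign One of `"index_difference"`, `"homoplasy_difference"`.
#' @return Numeric vector of differences.
#' @export
relative_homoplasy <- function(nuc_index, mt_index,
                               sign = c("index_difference", "homoplasy_difference")) {
  sign <- match.arg(sign)
  d <- nuc_index - mt_index
  if (sign == "homoplasy_difference") -d else d
}
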