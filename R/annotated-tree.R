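#' @importFrom stats setNames
NULL

SEP <- "\x1f"

#' Annotated rooted trees
#'
#' An `annotated_tree` is an [ape::read.tree()] `"phylo"` object carrying one
#' extra component, `support`: a numeric vector of length `Nnode` holding the
#' clade support (posterior probability, in `[0, 1]`) of each internal node,
#' in node-number order (`Ntip + 1` is the root, whose support is always
#' `NA`). Missing supports are `NA`, never 0. All functions in the package
#' accept either an `annotated_tree` or a plain `"phylo"` object (which is
#' treated as having no support values).
#'
#' @param tree A `"phylo"` or `annotated_tree` object.
#' @param support Optional numeric vector of internal-node supports
#'   (length `Nnode`).
#' @return An object of class `c("annotated_tree", "phylo")`.
#' @export
annotated_tree <- function(tree, support = NULL) {
  if (inherits(tree, "annotated_tree") && is.null(support)) return(tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  n_node <- tree$Nnode
  if (is.null(support)) {
    support <- rep(NA_real_, n_node)
  } else {
    if (length(support) != n_node)
      stop("'support' must have length Nnode (", n_node, ")")
    support <- as.numeric(support)
  }
  validate_support(support)
  support[1L] <- NA_real_  # root carries no support
  tree$support <- support
  class(tree) <- unique(c("annotated_tree", class(tree)))
  validate_tree(tree)
  tree
}

as_annotated <- function(tree) {
  if (inherits(tree, "annotated_tree")) tree else annotated_tree(tree)
}

validate_support <- function(support) {
  bad <- which(!is.na(support) & (support < 0 | support > 1))
  if (length(bad))
    stop("support values outside [0, 1] after normalization at internal node(s) ",
         paste(bad, collapse = ", "))
  invisible(support)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicated leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("Annotated rooted tree:", length(x$tip.label), "leaves,",
      x$Nnode, "internal nodes\n")
  ns <- sum(!is.na(x$support))
  cat("Internal-node supports present:", ns, "of", x$Nnode - 1L,
      "(non-root)\n")
  invisible(x)
}

# Normalize a raw support value read from a label: percents (> 1) divided by
# 100; empty or non-numeric labels -> NA (absent, not zero).
normalize_support <- function(raw) {
  val <- suppressWarnings(as.numeric(raw))
  val[!is.na(val) & val > 1] <- val[!is.na(val) & val > 1] / 100
  val
}

#' Parse a Newick string into an annotated tree
#'
#' Reads a rooted Newick tree whose internal-node supports are encoded either
#' as internal node labels (the MrBayes / RAxML consensus convention, the
#' default) or inside square-bracket comments following the closing
#' parenthesis (e.g. `)[&prob=0.97]`). Support values greater than 1 are
#' interpreted as percentages and divided by 100, so both posterior
#' probabilities and bootstrap percentages are accepted. Missing supports are
#' recorded as `NA`, never as 0.
#'
#' @param text A Newick string (must end in `;`).
#' @param support_convention One of `"label"` (internal node labels),
#'   `"comment"` (first number inside a `[...]` comment after `)`), or
#'   `"none"` (ignore any support annotation).
#' @return An [annotated_tree].
#' @examples
#' tr <- parse_newick("((A:1,B:1)0.99:0.5,C:2);")
#' tr$support   # NA (root), 0.99
#' @export
parse_newick <- function(text, support_convention = c("label", "comment", "none")) {
  support_convention <- match.arg(support_convention)
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  if (support_convention == "comment") {
    # promote the first number in a post-')' comment to an internal label
    text <- gsub("(?<=\\))\\[[^][]*?([0-9]+\\.?[0-9]*([eE][-+]?[0-9]+)?)[^][]*\\]",
                 "\\1", text, perl = TRUE)
  }
  text <- gsub("\\[[^][]*\\]", "", text)  # strip any remaining comments
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick string")
  support <- rep(NA_real_, tree$Nnode)
  if (support_convention != "none" && !is.null(tree$node.label)) {
    support <- normalize_support(tree$node.label)
    support[1L] <- NA_real_
  }
  tree$node.label <- NULL
  annotated_tree(tree, support)
}

# Cheap syntax pre-check so parse errors can name a position.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  if (!grepl(";\\s*$", text))
    stop("malformed Newick: missing terminal ';' at position ", nchar(text))
  invisible(text)
}

#' Read an annotated tree from a Newick file
#'
#' @param path Path to a Newick file (first tree is used).
#' @inheritParams parse_newick
#' @return An [annotated_tree].
#' @export
read_annotated_tree <- function(path, support_convention = c("label", "comment", "none")) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               support_convention)
}

#' Serialize an annotated tree to Newick
#'
#' Supports are written back as internal node labels; `NA` supports produce
#' empty labels. Round-trips through [parse_newick()] preserve the leaf set,
#' clade set, branch lengths and supports.
#'
#' @param tree An [annotated_tree] or `"phylo"` object.
#' @param digits Number of significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  tree <- as_annotated(tree)
  lab <- ifelse(is.na(tree$support), "",
                formatC(tree$support, format = "g", digits = 12))
  phy <- tree
  class(phy) <- "phylo"
  phy$support <- NULL
  phy$node.label <- lab
  ape::write.tree(phy, digits = digits)
}

#' Prune taxa from an annotated tree
#'
#' Removes the given leaves; internal nodes left with a single child are
#' suppressed, their branch lengths summed onto the retained edge and their
#' supports discarded. Pruning the empty set returns the tree unchanged.
#'
#' @param tree An [annotated_tree] or `"phylo"`.
#' @param drop Character vector of leaf labels to remove; must be a strict
#'   subset of the leaf set leaving at least two leaves.
#' @return The pruned [annotated_tree].
#' @examples
#' tr <- parse_newick("((A:1,B:1)0.9:0.5,C:2);")
#' prune_taxa(tr, "C")
#' @export
prune_taxa <- function(tree, drop) {
  tree <- as_annotated(tree)
  drop <- as.character(drop)
  if (length(drop) == 0L) return(tree)
  unknown <- setdiff(drop, tree$tip.label)
  if (length(unknown))
    stop("cannot prune unknown taxa: ", paste(unknown, collapse = ", "))
  keep <- setdiff(tree$tip.label, drop)
  if (length(keep) < 2L)
    stop("pruning would leave fewer than two leaves")
  phy <- tree
  class(phy) <- "phylo"
  # carry supports through drop.tip via node labels
  phy$node.label <- ifelse(is.na(tree$support), "",
                           formatC(tree$support, format = "g", digits = 15))
  phy$support <- NULL
  pruned <- ape::drop.tip(phy, drop, trim.internal = TRUE, collapse.singles = TRUE)
  support <- rep(NA_real_, pruned$Nnode)
  if (!is.null(pruned$node.label)) {
    support <- normalize_support(pruned$node.label)
    support[1L] <- NA_real_
  }
  pruned$node.label <- NULL
  annotated_tree(pruned, support)
}

# ---- clade machinery -------------------------------------------------------

# List of leaf-label vectors (sorted) for every node, indexed by phylo node
# number (tips included as singletons).
node_leafsets <- function(tree) {
  phy <- ape::reorder.phylo(as_phylo(tree), "postorder")
  n_tip <- length(phy$tip.label)
  sets <- vector("list", n_tip + phy$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  lapply(sets, function(s) sort(s, method = "radix"))
}

as_phylo <- function(tree) {
  phy <- tree
  class(phy) <- "phylo"
  phy
}

clade_key <- function(leaves) paste(sort(leaves, method = "radix"), collapse = SEP)

# Number of edges from the root to each node (root = 0), by phylo node number.
node_depths_topo <- function(tree) {
  phy <- as_phylo(tree)
  n_tip <- length(phy$tip.label)
  depth <- numeric(n_tip + phy$Nnode)
  ord <- ape::reorder.phylo(phy, "cladewise")  # root-to-tip edge order
  for (k in seq_len(nrow(ord$edge)))
    depth[ord$edge[k, 2L]] <- depth[ord$edge[k, 1L]] + 1
  depth
}

# Sum of branch lengths from the root to each node (root = 0).
node_depths_path <- function(tree) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) return(NULL)
  n_tip <- length(phy$tip.label)
  depth <- numeric(n_tip + phy$Nnode)
  ord <- ape::reorder.phylo(phy, "cladewise")
  el <- ord$edge.length
  for (k in seq_len(nrow(ord$edge)))
    depth[ord$edge[k, 2L]] <- depth[ord$edge[k, 1L]] + el[k]
  depth
}

# Branch length of the edge subtending each node (NA for root), by node number.
subtending_lengths <- function(tree) {
  phy <- as_phylo(tree)
  n <- length(phy$tip.label) + phy$Nnode
  bl <- rep(NA_real_, n)
  if (!is.null(phy$edge.length)) bl[phy$edge[, 2L]] <- phy$edge.length
  bl
}

#' Extract the non-trivial clades of a rooted tree
#'
#' Returns one row per internal node excluding the root; leaves are never
#' counted. When `collapse_conspecific = TRUE`, clades whose entire leaf set
#' maps to a single species under `species_map` are omitted (such clades are
#' not numbered in the conventions this package follows). Rows are ordered
#' root-to-tips (by topological depth), ties broken by the smallest leaf
#' label, so the ordering is deterministic.
#'
#' @param tree An [annotated_tree] or `"phylo"`.
#' @param species_map Optional taxon-to-species mapping: either a named
#'   character vector (names = taxa) or a two-column data frame
#'   `(taxon, species)`.
#' @param collapse_conspecific Logical; drop single-species clades?
#' @return A data frame with columns `clade_id`, `node_id` (phylo node
#'   number), `n_leaves`, `support`, `branch_length`, `depth_topological`,
#'   `depth_pathlength`, and a list column `leaves`.
#' @export
extract_clades <- function(tree, species_map = NULL, collapse_conspecific = FALSE) {
  tree <- as_annotated(tree)
  phy <- as_phylo(tree)
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  internal <- setdiff(seq.int(n_tip + 1L, n_tip + phy$Nnode), root)
  sets <- node_leafsets(tree)
  if (collapse_conspecific) {
    map <- as_species_map(species_map)
    missing <- setdiff(phy$tip.label, names(map))
    if (length(missing))
      stop("species_map does not cover taxa: ", paste(missing, collapse = ", "))
    keep <- vapply(internal, function(nd)
      length(unique(map[sets[[nd]]])) > 1L, logical(1))
    internal <- internal[keep]
  }
  dt <- node_depths_topo(tree)
  dp <- node_depths_path(tree)
  bl <- subtending_lengths(tree)
  df <- data.frame(
    node_id = internal,
    n_leaves = vapply(internal, function(nd) length(sets[[nd]]), integer(1)),
    support = tree$support[internal - n_tip],
    branch_length = bl[internal],
    depth_topological = as.integer(dt[internal]),
    depth_pathlength = if (is.null(dp)) rep(NA_real_, length(internal)) else dp[internal],
    stringsAsFactors = FALSE
  )
  df$leaves <- sets[internal]
  first_leaf <- vapply(df$leaves, `[`, character(1), 1L)
  ord <- order(df$depth_topological, first_leaf, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$clade_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("clade_id", "node_id", "n_leaves", "support", "branch_length",
         "depth_topological", "depth_pathlength", "leaves")]
}

as_species_map <- function(species_map) {
  if (is.null(species_map))
    stop("species_map is required when collapse_conspecific = TRUE")
  if (is.data.frame(species_map)) {
    stopifnot(ncol(species_map) >= 2L)
    setNames(as.character(species_map[[2L]]), as.character(species_map[[1L]]))
  } else if (!is.null(names(species_map))) {
    setNames(as.character(species_map), names(species_map))
  } else {
    stop("species_map must be a named vector or two-column data frame")
  }
}

#' Read a taxon-to-species map from a two-column TSV
#'
#' @param path Path to a tab-separated file with columns taxon, species
#'   (no header).
#' @return A named character vector mapping taxon to species.
#' @export
read_species_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = c("taxon", "species"))
  setNames(df$species, df$taxon)
}
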