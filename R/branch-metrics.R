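# Node depths (topological and path-length), relative standardizations, and
# per-category means/SEs with exact rank-sum comparisons.

#' Depth and branch-length metrics for a set of clades
#'
#' For each supplied clade of a tree, computes the length of the branch
#' subtending the clade's ancestor node, the topological depth (number of
#' edges from the root to that node; children of the root have depth 1), the
#' path-length depth (sum of branch lengths along the root-to-ancestor path),
#' and the relative versions of depth and branch length. Relative depth is
#' the topological depth divided by the maximum topological depth over the
#' supplied clades (so larger values are shallower, and the shallowest clade
#' scores 1); relative branch length is the branch length divided by the
#' maximum branch length over the supplied clades (terminal branches never
#' enter the normalizer). Normalizers are computed over the supplied clades
#' only, so conspecific-collapsed or otherwise excluded clades do not affect
#' the standardization.
#'
#' @param tree An [annotated_tree] or `"phylo"`.
#' @param clades A clade table from [extract_clades()] or [classify_nodes()]
#'   (any data frame with a `node_id` column); defaults to all non-trivial
#'   clades of `tree`.
#' @return A data frame with columns `clade_id`, `node_id`, `branch_length`,
#'   `depth_topological`, `depth_pathlength`, `relative_depth`,
#'   `relative_branch_length`. Branch-length-derived columns are `NA` when
#'   the tree has no branch lengths.
#' @examples
#' tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
#' compute_metrics(tr)
#' @export
compute_metrics <- function(tree, clades = extract_clades(tree)) {
  tree <- as_annotated(tree)
  if (!"node_id" %in% names(clades)) stop("'clades' must have a node_id column")
  ids <- clades$node_id
  dt <- node_depths_topo(tree)[ids]
  dp <- node_depths_path(tree)
  bl <- subtending_lengths(tree)[ids]
  max_dt <- max(dt)
  max_bl <- if (all(is.na(bl))) NA_real_ else max(bl, na.rm = TRUE)
  data.frame(
    clade_id = if ("clade_id" %in% names(clades)) clades$clade_id else seq_along(ids),
    node_id = ids,
    branch_length = bl,
    depth_topological = as.integer(dt),
    depth_pathlength = if (is.null(dp)) NA_real_ else dp[ids],
    relative_depth = dt / max_dt,
    relative_branch_length = if (is.na(max_bl) || max_bl == 0) NA_real_ else bl / max_bl
  )
}

se_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

#' Per-category means and standard errors of branch lengths and depths
#'
#' Joins clade metrics to their resolution categories and reports, per
#' non-empty category (in the order concordant, mtDNA_wins, nucDNA_wins,
#' unique), the count, mean and standard error of branch length, raw
#' topological depth, and the relative versions of both. Standard errors use
#' the `n - 1` sample standard deviation and are `NA` for single-member
#' categories.
#'
#' @param metrics Output of [compute_metrics()].
#' @param resolutions Output of [classify_nodes()] with matching `node_id`s.
#' @return A data frame with one row per non-empty category.
#' @export
category_stats <- function(metrics, resolutions) {
  m <- merge(metrics, resolutions[, c("node_id", "category")], by = "node_id")
  out <- do.call(rbind, lapply(CATEGORIES, function(cat) {
    sub <- m[m$category == cat, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(
      category = cat, n = nrow(sub),
      mean_branch_length = mean_or_na(sub$branch_length),
      se_branch_length = se_or_na(sub$branch_length),
      mean_depth = mean_or_na(sub$depth_topological),
      se_depth = se_or_na(sub$depth_topological),
      mean_relative_branch_length = mean_or_na(sub$relative_branch_length),
      se_relative_branch_length = se_or_na(sub$relative_branch_length),
      mean_relative_depth = mean_or_na(sub$relative_depth),
      se_relative_depth = se_or_na(sub$relative_depth)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Compare a metric between two resolution categories
#'
#' Exact (tied-rank) Wilcoxon rank-sum test of the chosen variable between
#' two clade-resolution categories.
#'
#' @inheritParams category_stats
#' @param variable One of `"branch_length"`, `"depth"`, `"relative_depth"`,
#'   `"relative_branch_length"`.
#' @param cat_a,cat_b Category names (see [classify_nodes()]).
#' @param sidedness Passed to [wilcoxon_exact()] (default two-sided).
#' @return A `test_result` (see [wilcoxon_exact()]).
#' @export
compare_categories <- function(metrics, resolutions,
                               variable = c("branch_length", "depth",
                                            "relative_depth",
                                            "relative_branch_length"),
                               cat_a, cat_b, sidedness = "two") {
  variable <- match.arg(variable)
  col <- switch(variable, depth = "depth_topological", variable)
  m <- merge(metrics, resolutions[, c("node_id", "category")], by = "node_id")
  x <- m[[col]][m$category == cat_a]
  y <- m[[col]][m$category == cat_b]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L) stop("category '", cat_a, "' is empty for ", variable)
  if (length(y) == 0L) stop("category '", cat_b, "' is empty for ", variable)
  res <- wilcoxon_exact(x, y, sidedness = sidedness)
  res$name <- paste0("wilcoxon_exact: ", variable, " ", cat_a, " vs ", cat_b)
  res
}
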