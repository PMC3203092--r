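# Per-study orchestration and cross-study pooling.

#' Bundle a mito-nuclear clade study
#'
#' Packs the three trees (combined-data, mtDNA-only, nucDNA-only), optional
#' character matrices and configuration into one study object. Trees are
#' pruned to their common leaf set first; every pruned taxon is reported via
#' a message and recorded in the `pruned` element.
#'
#' @param name Study label.
#' @param combined,mt,nuc Rooted trees ([annotated_tree] or `"phylo"`).
#' @param mt_matrix,nuc_matrix Optional character matrices (see
#'   [read_char_matrix()]); taxa outside the common leaf set are dropped.
#' @param species_map Optional taxon-to-species map for conspecific-clade
#'   collapsing (see [extract_clades()]).
#' @param collapse_conspecific Collapse single-species clades?
#' @param threshold Strong-support threshold (posterior probability).
#' @return A list of class `clade_study`.
#' @export
clade_study <- function(name, combined, mt, nuc,
                        mt_matrix = NULL, nuc_matrix = NULL,
                        species_map = NULL, collapse_conspecific = FALSE,
                        threshold = 0.95) {
  combined <- as_annotated(combined); mt <- as_annotated(mt); nuc <- as_annotated(nuc)
  common <- Reduce(intersect, list(combined$tip.label, mt$tip.label, nuc$tip.label))
  if (length(common) < 3L)
    stop("fewer than three taxa shared by the three trees")
  pruned <- list(combined = setdiff(combined$tip.label, common),
                 mt = setdiff(mt$tip.label, common),
                 nuc = setdiff(nuc$tip.label, common))
  for (nm in names(pruned)) {
    if (length(pruned[[nm]])) {
      message("clade_study '", name, "': pruning from ", nm, " tree: ",
              paste(pruned[[nm]], collapse = ", "))
    }
  }
  if (length(pruned$combined)) combined <- prune_taxa(combined, pruned$combined)
  if (length(pruned$mt)) mt <- prune_taxa(mt, pruned$mt)
  if (length(pruned$nuc)) nuc <- prune_taxa(nuc, pruned$nuc)
  trim_matrix <- function(m) {
    if (is.null(m)) return(NULL)
    m[rownames(m) %in% common, , drop = FALSE]
  }
  out <- list(name = name, combined = combined, mt = mt, nuc = nuc,
              mt_matrix = trim_matrix(mt_matrix),
              nuc_matrix = trim_matrix(nuc_matrix),
              species_map = species_map,
              collapse_conspecific = collapse_conspecific,
              threshold = threshold, pruned = pruned)
  class(out) <- "clade_study"
  out
}

#' Run the full per-study analysis
#'
#' Classifies every combined-tree clade, computes depth/branch-length
#' metrics and per-category statistics, the three pairwise tree
#' similarities, and (when matrices are supplied) the homoplasy indices of
#' each partition on the combined tree. Deterministic given the study.
#'
#' @param study A [clade_study()].
#' @param binomial_convention Passed to [conflict_summary()].
#' @return A list of class `clade_report` with elements `name`,
#'   `resolutions`, `metrics`, `summary`, `category_stats`, `similarity`
#'   (list `mt_nuc`, `combined_mt`, `combined_nuc`), `homoplasy`
#'   (list `mt`, `nuc`, or `NULL`), `per_node` (merged per-clade table),
#'   `threshold`.
#' @export
analyze_clade <- function(study, binomial_convention = "deviation") {
  stopifnot(inherits(study, "clade_study"))
  res <- classify_nodes(study$combined, study$mt, study$nuc,
                        threshold = study$threshold,
                        species_map = study$species_map,
                        collapse_conspecific = study$collapse_conspecific)
  metrics <- compute_metrics(study$combined, res)
  per_node <- merge(
    res[, setdiff(names(res), c("leaves", "branch_length",
                                "depth_topological", "depth_pathlength"))],
    metrics[, setdiff(names(metrics), "clade_id")], by = "node_id")
  per_node <- per_node[order(per_node$clade_id), , drop = FALSE]
  rownames(per_node) <- NULL
  per_node$leaves <- res$leaves[match(per_node$node_id, res$node_id)]
  homo <- NULL
  if (!is.null(study$mt_matrix) && !is.null(study$nuc_matrix)) {
    homo <- list(mt = ensemble_indices(study$combined, study$mt_matrix),
                 nuc = ensemble_indices(study$combined, study$nuc_matrix))
  }
  out <- list(
    name = study$name,
    resolutions = res,
    metrics = metrics,
    summary = conflict_summary(res, binomial_convention = binomial_convention),
    category_stats = category_stats(metrics, res),
    similarity = list(
      mt_nuc = tree_similarity(study$mt, study$nuc),
      combined_mt = tree_similarity(study$combined, study$mt),
      combined_nuc = tree_similarity(study$combined, study$nuc)),
    homoplasy = homo,
    per_node = per_node,
    threshold = study$threshold
  )
  class(out) <- "clade_report"
  out
}

#' @export
print.clade_report <- function(x, ...) {
  cat("Clade study:", x$name, "\n")
  print(x$summary)
  cat(sprintf("  shared nodes: mt-nuc %.0f%%, combined-mt %.0f%%, combined-nuc %.0f%%\n",
              100 * x$similarity$mt_nuc$proportion_shared,
              100 * x$similarity$combined_mt$proportion_shared,
              100 * x$similarity$combined_nuc$proportion_shared))
  if (!is.null(x$homoplasy))
    cat(sprintf("  homoplasy CI (mt/nuc): %.4f / %.4f;  RI: %.4f / %.4f\n",
                x$homoplasy$mt$CI, x$homoplasy$nuc$CI,
                x$homoplasy$mt$RI, x$homoplasy$nuc$RI))
  invisible(x)
}

#' Binomial test of the depth pattern across studies
#'
#' Each study shows the predicted pattern when its conflicts resolved in
#' favour of nucDNA sit deeper in the combined tree (smaller mean relative
#' depth index) than those resolved in favour of mtDNA. Under the null the
#' three possible outcomes (nucDNA deeper / equal / mtDNA deeper) are
#' equiprobable and lumped into agree (probability 1/3) versus not, and the
#' count of agreeing studies is tested with a one-sided exact binomial
#' against 1/3.
#'
#' @param x Either a list of `clade_report`s, or a logical vector of per-study
#'   agreement indicators.
#' @param depth One of `"relative_depth"` (default: topological depth
#'   standardized by the shallowest node) or `"depth_pathlength"`.
#' @return A `test_result`; studies with an empty `mtDNA_wins` or
#'   `nucDNA_wins` category are excluded with a message.
#' @export
depth_pattern_test <- function(x, depth = c("relative_depth", "depth_pathlength")) {
  depth <- match.arg(depth)
  if (is.logical(x)) {
    agree <- x
  } else {
    agree <- logical(0)
    for (rep in x) {
      stopifnot(inherits(rep, "clade_report"))
      pn <- rep$per_node
      mt_d <- pn[[depth]][pn$category == "mtDNA_wins"]
      nuc_d <- pn[[depth]][pn$category == "nucDNA_wins"]
      if (length(mt_d) == 0L || length(nuc_d) == 0L) {
        message("depth_pattern_test: excluding study '", rep$name,
                "' (empty mtDNA_wins or nucDNA_wins category)")
        next
      }
      agree <- c(agree, mean(nuc_d) < mean(mt_d))
    }
  }
  if (length(agree) == 0L)
    stop("no study with both mtDNA_wins and nucDNA_wins non-empty")
  res <- binom_exact(sum(agree), length(agree), 1 / 3, sidedness = "greater")
  res$name <- "depth_pattern_binomial"
  res
}

#' Cross-study correlations of tree similarity with homoplasy and variability
#'
#' Pearson correlations of the proportion of nodes shared between the
#' combined-data and mtDNA trees with (a) the relative homoplasy difference
#' on the consistency index, (b) the same on the retention index, and (c)
#' the proportion of all variable sites that are mitochondrial,
#' `mt_variable / (mt_variable + nuc_variable)`. Also fits the two multiple
#' regressions of shared proportion on homoplasy difference, variability
#' proportion and their interaction (one per homoplasy index).
#'
#' @param tbl Data frame with columns `shared_combined_mt` (percent or
#'   proportion), `nuc_ci`, `mt_ci`, `nuc_ri`, `mt_ri`, `nuc_variable`,
#'   `mt_variable` — e.g. [vertebrate_summary()].
#' @param sign Sign convention for [relative_homoplasy()].
#' @return A list: `ci` , `ri`, `variable_sites` (Pearson `test_result`s),
#'   `regression_ci`, `regression_ri` (`ols_fit`s).
#' @export
cross_clade_correlations <- function(tbl, sign = "index_difference") {
  need <- c("shared_combined_mt", "nuc_ci", "mt_ci", "nuc_ri", "mt_ri",
            "nuc_variable", "mt_variable")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  shared <- tbl$shared_combined_mt
  d_ci <- relative_homoplasy(tbl$nuc_ci, tbl$mt_ci, sign)
  d_ri <- relative_homoplasy(tbl$nuc_ri, tbl$mt_ri, sign)
  p_mt <- tbl$mt_variable / (tbl$mt_variable + tbl$nuc_variable)
  out <- list(
    ci = pearson_test(shared, d_ci),
    ri = pearson_test(shared, d_ri),
    variable_sites = pearson_test(shared, p_mt),
    regression_ci = ols_regress(shared,
                                data.frame(homoplasy = d_ci, variability = p_mt),
                                interaction = TRUE),
    regression_ri = ols_regress(shared,
                                data.frame(homoplasy = d_ri, variability = p_mt),
                                interaction = TRUE))
  out$ci$name <- "pearson: shared(combined,mt) vs CI difference"
  out$ri$name <- "pearson: shared(combined,mt) vs RI difference"
  out$variable_sites$name <- "pearson: shared(combined,mt) vs mtDNA variable-site proportion"
  out
}

#' Missing data versus terminal branch length
#'
#' Spearman rank correlation between the percentage of missing cells per
#' taxon and the taxon's terminal branch length. When every taxon has the
#' same missing percentage the correlation is undefined and the result is
#' returned as not applicable (`P = NA`).
#'
#' @param mat Character matrix; taxa must be leaves of `tree`.
#' @param tree Tree providing terminal branch lengths.
#' @return A `test_result` (statistic `rs`), or a not-applicable result.
#' @export
missing_data_check <- function(mat, tree) {
  tree <- as_annotated(tree)
  extra <- setdiff(rownames(mat), tree$tip.label)
  if (length(extra))
    stop("matrix taxa absent from the tree: ", paste(extra, collapse = ", "))
  bl <- subtending_lengths(tree)
  n_tip <- length(tree$tip.label)
  term <- setNames(bl[seq_len(n_tip)], tree$tip.label)[rownames(mat)]
  ok <- !is.na(term)
  if (sum(ok) < 3L) stop("fewer than 3 taxa with terminal branch lengths")
  miss <- missing_percent(mat)[ok]
  term <- term[ok]
  res <- tryCatch(spearman_test(miss, term), error = function(e) {
    if (grepl("zero rank variance", conditionMessage(e)))
      test_result("spearman (not applicable: constant missing percentage)",
                  c(rs = NA_real_), NA_real_, "two", FALSE, c(n = sum(ok)))
    else stop(e)
  })
  res$name <- sub("^spearman", "spearman: missing% vs terminal branch length",
                  res$name)
  res
}

#' Pooled depth and branch-length tests across studies
#'
#' Pools per-clade relative depths and relative branch lengths across a list
#' of study reports and runs the standard comparisons: relative depth of
#' `mtDNA_wins` versus `nucDNA_wins` clades, relative depth of concordant
#' versus discordant clades, relative branch length of concordant versus
#' discordant clades (all exact tied-rank Wilcoxon), and the Spearman
#' correlation of relative depth with relative branch length over all
#' clades.
#'
#' @param reports List of `clade_report`s.
#' @return A list of `test_result`s: `depth_mt_vs_nuc`,
#'   `depth_concordant_vs_discordant`, `length_concordant_vs_discordant`,
#'   `depth_vs_length`; plus `pooled` (the pooled per-node data frame).
#' @export
pooled_depth_tests <- function(reports) {
  pooled <- do.call(rbind, lapply(reports, function(r) {
    cbind(study = r$name,
          r$per_node[, c("category", "relative_depth", "relative_branch_length")])
  }))
  pick <- function(cats) pooled[pooled$category %in% cats, , drop = FALSE]
  disc <- CATEGORIES[-1L]
  res <- list(
    depth_mt_vs_nuc = wilcoxon_exact(
      pick("mtDNA_wins")$relative_depth, pick("nucDNA_wins")$relative_depth),
    depth_concordant_vs_discordant = wilcoxon_exact(
      pick("concordant")$relative_depth, pick(disc)$relative_depth),
    length_concordant_vs_discordant = wilcoxon_exact(
      stats::na.omit(pick("concordant")$relative_branch_length),
      stats::na.omit(pick(disc)$relative_branch_length)),
    depth_vs_length = {
      ok <- !is.na(pooled$relative_branch_length)
      spearman_test(pooled$relative_depth[ok], pooled$relative_branch_length[ok])
    },
    pooled = pooled
  )
  res$depth_mt_vs_nuc$name <- "wilcoxon_exact: pooled relative depth, mtDNA_wins vs nucDNA_wins"
  res$depth_concordant_vs_discordant$name <- "wilcoxon_exact: pooled relative depth, concordant vs discordant"
  res$length_concordant_vs_discordant$name <- "wilcoxon_exact: pooled relative branch length, concordant vs discordant"
  res$depth_vs_length$name <- "spearman: pooled relative depth vs relative branch length"
  res
}

#' Packaged summary of 14 vertebrate mito-nuclear data sets
#'
#' A transcription of published per-study summary values for 14 vertebrate
#' clades (fish, frogs, salamanders, lizards, birds, turtles, mammals):
#' clade-resolution tallies, pairwise shared-node percentages, variable
#' character counts and ensemble consistency/retention indices per
#' partition. This fixture makes the cross-study layer (means,
#' [cross_clade_correlations()], [depth_pattern_test()]) runnable without
#' re-deriving the per-study trees from their original sequence data.
#'
#' @return A data frame with one row per study; see column names.
#' @export
vertebrate_summary <- function() {
  path <- system.file("extdata", "vertebrate_congruence.tsv",
                      package = "mitonuc", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = TRUE, quote = "")
}
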