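# Synthetic tree triplets and character matrices with known ground truth.
# Every generator is a pure function of its arguments and seed; the global
# RNG state is saved and restored around each call.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-component seed derived from a global seed and a label,
# kept below 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Generate a random rooted binary tree
#'
#' `"yule"` trees are pure-birth (clock-like, ultrametric) trees from
#' [ape::rphylo()]; `"uniform"` trees have uniformly random topology and
#' uniform branch lengths from [ape::rtree()].
#'
#' @param n_taxa Number of leaves (at least 4). Leaves are labelled
#'   `t1 ... tn`.
#' @param model `"yule"` or `"uniform"`.
#' @param seed Optional integer seed; the call is reproducible per seed and
#'   leaves the global RNG state untouched.
#' @return An [annotated_tree] with branch lengths and no supports.
#' @export
generate_tree <- function(n_taxa, model = c("yule", "uniform"), seed = NULL) {
  model <- match.arg(model)
  if (n_taxa < 4L) stop("n_taxa must be at least 4")
  with_seed(seed, {
    phy <- switch(model,
      yule = ape::rphylo(n_taxa, birth = 1, death = 0),
      uniform = ape::rtree(n_taxa))
    phy$tip.label <- paste0("t", seq_len(n_taxa))
    phy$node.label <- NULL
    annotated_tree(phy)
  })
}

# children of each node from an edge matrix
children_of <- function(phy, node) phy$edge[phy$edge[, 1L] == node, 2L]

#' Perturb a tree by random nearest-neighbour interchanges
#'
#' Applies `k` random NNI moves to internal edges of a rooted tree. Each
#' move swaps a random child of an internal non-root node `v` with a random
#' sibling subtree of `v`, changing exactly the clade at `v`; subtrees keep
#' their subtending branch lengths. The set of clades destroyed and created
#' is tracked move by move, so the returned tree carries an exact record of
#' which clades of the input survive.
#'
#' Supports of the input are discarded (clade identities change); assign new
#' supports downstream, e.g. via [build_scenario()].
#'
#' @param tree An [annotated_tree] or `"phylo"` with at least one internal
#'   edge.
#' @param k Number of NNI moves (`k = 0` returns the topology unchanged).
#' @param seed Optional integer seed.
#' @return An [annotated_tree] with attribute `"clade_keys"`: the keys (see
#'   internals) of the output tree's non-root internal clades.
#' @export
perturb_nni <- function(tree, k, seed = NULL) {
  tree <- as_annotated(tree)
  stopifnot(k >= 0)
  phy <- as_phylo(tree)
  phy$node.label <- NULL
  phy$support <- NULL
  with_seed(seed, {
    for (move in seq_len(k)) {
      n_tip <- length(phy$tip.label)
      root <- n_tip + 1L
      internal_children <- phy$edge[, 2L][phy$edge[, 2L] > n_tip]
      if (length(internal_children) == 0L) {
        warning("no internal edge available for NNI; returning current tree")
        break
      }
      v <- if (length(internal_children) == 1L) internal_children else
        sample(internal_children, 1L)
      u <- phy$edge[phy$edge[, 2L] == v, 1L]
      sibs <- setdiff(children_of(phy, u), v)
      w <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
      kids <- children_of(phy, v)
      c_node <- if (length(kids) == 1L) kids else sample(kids, 1L)
      # swap: w moves under v, c_node moves under u
      phy$edge[phy$edge[, 2L] == w, 1L] <- v
      phy$edge[phy$edge[, 2L] == c_node, 1L] <- u
      phy <- ape::reorder.phylo(phy, "cladewise")
    }
    # renumber nodes canonically through a newick round trip
    phy <- ape::read.tree(text = ape::write.tree(phy))
    out <- annotated_tree(phy)
    cl <- extract_clades(out)
    attr(out, "clade_keys") <- vapply(cl$leaves, clade_key, character(1))
    out
  })
}

#' Scenario configuration for synthetic tree triplets
#'
#' Bundles the tunable parameters of [build_scenario()]: the study
#' conditions under which the pipeline is exercised. Unperturbed clades
#' receive strong supports drawn from `support_strong`; clades touched by a
#' perturbation receive supports from `support_weak` (spanning the
#' weak/strong boundary used by the classifier). Substitution rates are in
#' expected substitutions per site per unit branch length.
#'
#' @param n_taxa Number of leaves (at least 4).
#' @param seed Global seed; per-component seeds are derived from it
#'   deterministically.
#' @param n_mt_perturbations,n_nuc_perturbations NNI counts applied
#'   independently to the base tree to produce the mtDNA and nucDNA trees.
#' @param support_strong,support_weak Ranges (length-2) from which supports
#'   are drawn uniformly for unperturbed / perturbed clades.
#' @param tree_model Base-tree model, see [generate_tree()].
#' @param concordant_length_multiplier Multiplier applied to the subtending
#'   branch length of concordant clades in the combined tree (1 = no
#'   category effect on branch lengths).
#' @param sites_mt,sites_nuc,rate_mt,rate_nuc,missing_fraction Character
#'   matrix model per partition; matrices are simulated on the combined tree
#'   when `generate_matrices = TRUE`.
#' @param generate_matrices Simulate the two character matrices?
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 20, seed = 1,
                            n_mt_perturbations = 2, n_nuc_perturbations = 2,
                            support_strong = c(0.95, 1),
                            support_weak = c(0.5, 0.94),
                            tree_model = "yule",
                            concordant_length_multiplier = 1,
                            sites_mt = 500, sites_nuc = 500,
                            rate_mt = 1, rate_nuc = 0.2,
                            missing_fraction = 0,
                            generate_matrices = FALSE) {
  stopifnot(n_taxa >= 4, n_mt_perturbations >= 0, n_nuc_perturbations >= 0,
            rate_mt > 0, rate_nuc > 0,
            missing_fraction >= 0, missing_fraction < 1)
  out <- as.list(environment())
  class(out) <- "scenario_config"
  out
}

assign_supports <- function(tree, base_keys, strong, weak, seed) {
  cl <- extract_clades(tree)
  keys <- vapply(cl$leaves, clade_key, character(1))
  with_seed(seed, {
    support <- rep(NA_real_, tree$Nnode)
    idx <- cl$node_id - length(tree$tip.label)
    is_base <- keys %in% base_keys
    support[idx[is_base]] <- stats::runif(sum(is_base), strong[1], strong[2])
    support[idx[!is_base]] <- stats::runif(sum(!is_base), weak[1], weak[2])
    annotated_tree(as_phylo(tree), support)
  })
}

#' Build a synthetic clade study with known ground truth
#'
#' Constructs a triplet of trees: the combined tree is the base tree; the
#' mtDNA and nucDNA trees are independent NNI perturbations of it. Supports
#' are assigned so clades shared with the base tree are strongly supported
#' and perturbed clades weakly supported. The ground-truth resolution
#' category of every combined-tree clade follows from the construction (the
#' clade-by-clade record kept by [perturb_nni()]), before any classification
#' code runs.
#'
#' @param config A [scenario_config()].
#' @return A `clade_study` (see [clade_study()]) with an extra element
#'   `ground_truth`: a data frame with `clade_id`, `node_id`,
#'   `mt_present`, `nuc_present` and `category` for every combined-tree
#'   clade.
#' @export
build_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  base <- generate_tree(config$n_taxa, config$tree_model,
                        seed = derive_seed(config$seed, "base_tree"))
  base_cl <- extract_clades(base)
  base_keys <- vapply(base_cl$leaves, clade_key, character(1))
  mt <- perturb_nni(base, config$n_mt_perturbations,
                    seed = derive_seed(config$seed, "mt_nni"))
  nuc <- perturb_nni(base, config$n_nuc_perturbations,
                     seed = derive_seed(config$seed, "nuc_nni"))
  mt_keys <- attr(mt, "clade_keys")
  nuc_keys <- attr(nuc, "clade_keys")
  truth <- data.frame(
    clade_id = base_cl$clade_id,
    node_id = base_cl$node_id,
    mt_present = base_keys %in% mt_keys,
    nuc_present = base_keys %in% nuc_keys
  )
  truth$category <- factor(ifelse(truth$mt_present & truth$nuc_present, "concordant",
                           ifelse(truth$mt_present, "mtDNA_wins",
                           ifelse(truth$nuc_present, "nucDNA_wins", "unique"))),
                           levels = CATEGORIES)
  combined <- base
  if (config$concordant_length_multiplier != 1) {
    conc_nodes <- truth$node_id[truth$category == "concordant"]
    sel <- combined$edge[, 2L] %in% conc_nodes
    combined$edge.length[sel] <- combined$edge.length[sel] *
      config$concordant_length_multiplier
  }
  combined <- assign_supports(combined, base_keys,
                              config$support_strong, config$support_strong,
                              derive_seed(config$seed, "combined_support"))
  mt <- assign_supports(mt, base_keys, config$support_strong,
                        config$support_weak,
                        derive_seed(config$seed, "mt_support"))
  nuc <- assign_supports(nuc, base_keys, config$support_strong,
                         config$support_weak,
                         derive_seed(config$seed, "nuc_support"))
  mt_matrix <- nuc_matrix <- NULL
  if (config$generate_matrices) {
    mt_matrix <- simulate_matrix(combined, config$sites_mt, config$rate_mt,
                                 seed = derive_seed(config$seed, "mt_matrix"),
                                 missing_fraction = config$missing_fraction)
    nuc_matrix <- simulate_matrix(combined, config$sites_nuc, config$rate_nuc,
                                  seed = derive_seed(config$seed, "nuc_matrix"),
                                  missing_fraction = config$missing_fraction)
  }
  study <- clade_study(name = paste0("synthetic_seed", config$seed),
                       combined = combined, mt = mt, nuc = nuc,
                       mt_matrix = mt_matrix, nuc_matrix = nuc_matrix,
                       threshold = 0.95)
  study$ground_truth <- truth
  study$config <- config
  study
}

#' Simulate an aligned nucleotide matrix on a tree
#'
#' Evolves `n_sites` independent sites along the tree under a symmetric
#' 4-state (Jukes-Cantor) substitution model with branch lengths multiplied
#' by `rate` (delegated to [phangorn::simSeq()]), then masks a fraction of
#' cells as missing (`?`) uniformly at random.
#'
#' @param tree An [annotated_tree] or `"phylo"` with branch lengths.
#' @param n_sites Number of sites (at least 1).
#' @param rate Rate multiplier (> 0); higher rates yield more multiple hits
#'   and hence more homoplasy.
#' @param seed Optional integer seed.
#' @param missing_fraction Fraction of cells masked as `?` (in `[0, 1)`).
#' @return A character matrix (rows = taxa) as from [read_char_matrix()].
#' @export
simulate_matrix <- function(tree, n_sites, rate, seed = NULL,
                            missing_fraction = 0) {
  stopifnot(n_sites >= 1, rate > 0,
            missing_fraction >= 0, missing_fraction < 1)
  tree <- as_annotated(tree)
  with_seed(seed, {
    sim <- phangorn::simSeq(as_phylo(tree), l = n_sites, rate = rate)
    mat <- toupper(as.character(sim))
    rownames(mat) <- names(sim)
    if (missing_fraction > 0) {
      n_mask <- round(missing_fraction * length(mat))
      if (n_mask > 0) mat[sample(length(mat), n_mask)] <- "?"
    }
    mat
  })
}
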