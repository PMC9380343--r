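# Key-mutant-gene screening: random walk with restart (RWR) proximity of
# mutated genes on the personalized network, tested against 50
# degree-preserving random-network nulls, intersected with hub genes.

#' Random walk with restart on a personalized network
#'
#' Iterates `p <- (1 - restart) * W p + restart * e` where `W` is the
#' column-normalized adjacency (unweighted unless `weighted = TRUE`) and
#' `e` is uniform over the seed genes present in the network. Mass landing
#' on a degree-zero node is re-injected at the seeds so the vector stays a
#' probability distribution.
#'
#' @param network A `personalized_network` or igraph object.
#' @param seeds Character vector of seed genes.
#' @param restart Restart probability in (0, 1\] (default 0.7).
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @param weighted Use edge weights in the transition matrix.
#' @return Named probability vector over the network nodes (sums to 1).
#' @export
rwr <- function(network, seeds, restart = 0.7, tol = 1e-10, max_iter = 10000,
                weighted = FALSE) {
  g <- if (inherits(network, "personalized_network"))
    pgin_igraph(network, weighted = weighted) else network
  nodes <- igraph::V(g)$name
  if (length(nodes) == 0) stop("network is empty")
  seeds <- intersect(seeds, nodes)
  if (length(seeds) == 0) stop("no seed gene present in the network")
  if (restart <= 0 || restart > 1) stop("restart must lie in (0, 1]")

  A <- igraph::as_adjacency_matrix(g, sparse = FALSE,
                                   attr = if (weighted) "weight" else NULL)
  colsum <- colSums(A)
  dangling <- colsum == 0
  scale <- ifelse(dangling, 0, 1 / pmax(colsum, .Machine$double.xmin))

  e <- stats::setNames(numeric(length(nodes)), nodes)
  e[seeds] <- 1 / length(seeds)

  p <- e
  for (it in seq_len(max_iter)) {
    flow <- as.numeric(A %*% (p * scale))
    lost <- sum(p[dangling])
    p_new <- (1 - restart) * (flow + lost * e) + restart * e
    if (sum(abs(p_new - p)) < tol) {
      names(p_new) <- nodes
      return(p_new)
    }
    p <- p_new
  }
  stop("RWR failed to converge within max_iter iterations")
}

#' Degree-preserving randomization of a network
#'
#' Attempts `n_swaps` double-edge swaps (rejecting any that would create a
#' self-loop or multi-edge), yielding a simple graph on the same nodes with
#' the identical degree sequence. Edge weights are set to 1: the nulls are
#' purely topological.
#'
#' @param network A `personalized_network`.
#' @param n_swaps Number of attempted swaps.
#' @param rng_seed Seed for reproducible rewiring.
#' @return A `personalized_network` with the same degree sequence.
#' @export
degree_preserving_randomization <- function(network, n_swaps,
                                            rng_seed = NULL) {
  g <- pgin_igraph(network, weighted = FALSE)
  if (igraph::ecount(g) >= 2) {
    g <- with_seed(rng_seed,
                   igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                            niter = n_swaps)))
  }
  el <- igraph::as_edgelist(g)
  cp <- canonical_pairs(el[, 1], el[, 2])
  edges <- data.frame(gene_a = cp$a, gene_b = cp$b,
                      weight = rep(1, nrow(el)),
                      delta_tumor = NA_real_, delta_normal = NA_real_,
                      p_tumor = NA_real_, p_normal = NA_real_,
                      stringsAsFactors = FALSE)
  out <- new_pgin(edges, weight_mode = "same", alpha_sig = network$alpha_sig)
  out$nodes <- network$nodes   # preserve isolated nodes, if any
  out
}

#' Significant co-mutated genes by randomization test
#'
#' RWR scores of the patient's mutated genes on the real network are
#' compared with their scores on `n_random` degree-preserving random
#' networks (same seeds, same restart). The empirical p-value uses the
#' add-one estimator `p = (1 + #{null >= observed}) / (1 + n_random)`, so
#' the smallest attainable p with 50 nulls is 1/51.
#'
#' @inheritParams rwr
#' @param mutated Character vector of the patient's mutated genes.
#' @param n_random Number of random networks (default 50).
#' @param n_swaps_factor Attempted swaps per null = factor x edge count.
#' @param rng_seed Seed controlling all rewiring.
#' @param alpha Significance level for membership in K.
#' @return List with `K` (significant co-mutant genes), `p_values` (named,
#'   over mutated genes in the network) and `rwr_scores` (all nodes).
#' @export
comutation_significance <- function(network, mutated, restart = 0.7,
                                    n_random = 50, n_swaps_factor = 10,
                                    rng_seed = NULL, alpha = 0.05,
                                    tol = 1e-10, max_iter = 10000) {
  cand <- intersect(mutated, network$nodes)
  if (length(cand) == 0) stop("no mutated gene present in the network")
  obs <- rwr(network, seeds = cand, restart = restart, tol = tol,
             max_iter = max_iter)
  n_swaps <- max(1L, n_swaps_factor * nrow(network$edges))
  null_ge <- stats::setNames(numeric(length(cand)), cand)
  with_seed(rng_seed, {
    for (r in seq_len(n_random)) {
      rnet <- degree_preserving_randomization(network, n_swaps)
      sc <- rwr(rnet, seeds = cand, restart = restart, tol = tol,
                max_iter = max_iter)
      null_ge <- null_ge + (sc[cand] >= obs[cand])
    }
  })
  p <- (1 + null_ge) / (1 + n_random)
  list(K = sort(names(p)[p < alpha]), p_values = p, rwr_scores = obs)
}

#' Hub genes of a personalized network
#'
#' @param network A `personalized_network`.
#' @return Genes whose degree strictly exceeds the network's mean degree.
#' @export
hub_genes <- function(network) {
  if (length(network$nodes) == 0) stop("network is empty")
  deg <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  tab <- table(c(network$edges$gene_a, network$edges$gene_b))
  deg[names(tab)] <- as.numeric(tab)
  sort(names(deg)[deg > mean(deg)])
}

#' Key mutant genes
#'
#' @param K Significant co-mutant gene set.
#' @param H Hub gene set.
#' @return Their intersection, sorted.
#' @export
key_mutant_genes <- function(K, H) sort(intersect(K, H))

#' Mutation profile of one patient
#'
#' @param snv Named vector in \{0, 1\}.
#' @param cnv Named vector in \{-1, 0, 1\}.
#' @param patient Patient identifier.
#' @return List with `patient`, `snv`, `cnv` and `mutated` (genes with any
#'   nonzero entry in either matrix column).
#' @export
mutation_profile <- function(snv, cnv = NULL, patient = NA_character_) {
  if (!all(snv %in% c(0, 1))) stop("SNV values must be 0/1")
  if (!is.null(cnv) && !all(cnv %in% c(-1, 0, 1)))
    stop("CNV values must be -1/0/1")
  mutated <- names(snv)[snv != 0]
  if (!is.null(cnv)) mutated <- union(mutated, names(cnv)[cnv != 0])
  list(patient = patient, snv = snv, cnv = cnv, mutated = sort(mutated))
}
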