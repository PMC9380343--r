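# Paired single-sample network (SSN) construction.
#
# The reference state is the expression matrix of the cohort's normal
# samples. Appending one extra sample (a patient's tumor or normal sample)
# perturbs the Pearson correlation of every gene pair; the perturbation
# dPCC = PCC^(n+1) - PCC^n is converted to a z-score
#   Z = dPCC / ((1 - (PCC^n)^2) / (n - 1))
# and a two-sided normal p-value. An interactome edge enters the patient's
# personalized network when its co-expression significance flips between
# the tumor and the normal state (significant in exactly one of the two).

#' Validate a genes-by-samples expression matrix
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns.
#' @param role Sample role, one of `"reference"`, `"tumor"`, `"normal"`.
#' @return The validated matrix (invisibly classed by its `role` attribute).
#' @export
expression_matrix <- function(values, role = c("reference", "tumor", "normal")) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("expression matrix needs unique gene rownames")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  attr(values, "role") <- role
  values
}

#' Pearson correlation of one gene pair across reference samples
#'
#' @param ref_expr Reference expression matrix (genes x samples).
#' @param gene_i,gene_j Gene symbols (rownames of `ref_expr`).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_edge <- function(ref_expr, gene_i, gene_j) {
  for (g in c(gene_i, gene_j))
    if (!g %in% rownames(ref_expr)) stop("gene not in expression matrix: ", g)
  if (ncol(ref_expr) < 3) stop("need at least 3 reference samples")
  xi <- ref_expr[gene_i, ]
  xj <- ref_expr[gene_j, ]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0)
    stop("degenerate correlation: zero-variance gene")
  stats::cor(xi, xj)
}

#' Differential-correlation statistics of one appended sample
#'
#' For each requested gene pair, computes the reference correlation, the
#' correlation after appending `extra_sample` as an (n+1)-th column, their
#' difference dPCC, the z-score and a two-sided normal p-value. Pairs whose
#' reference correlation is exactly +1/-1 (or undefined through zero
#' variance) make the z-score invalid and are excluded from the output;
#' their count is attached as attribute `n_degenerate`.
#'
#' @param ref_expr Reference expression matrix, n >= 3 samples.
#' @param extra_sample Named numeric vector over (at least) the genes used.
#' @param edges Two-column matrix or data frame of gene pairs.
#' @return Data frame with columns `gene_i`, `gene_j`, `pcc_ref`,
#'   `pcc_perturbed`, `delta_pcc`, `z`, `p_value`.
#' @export
ssn_edge_statistics <- function(ref_expr, extra_sample, edges) {
  n <- ncol(ref_expr)
  if (n < 3) stop("insufficient reference samples (need n >= 3)")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edges must have two gene columns")
  gi <- as.character(edges[[1]]); gj <- as.character(edges[[2]])
  genes <- unique(c(gi, gj))
  missing <- setdiff(genes, rownames(ref_expr))
  if (length(missing)) stop("genes absent from reference: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (!all(genes %in% names(extra_sample)))
    stop("extra_sample must be named over all edge genes")

  ref <- ref_expr[genes, , drop = FALSE]
  aug <- cbind(ref, extra_sample[genes])
  r_ref <- suppressWarnings(stats::cor(t(ref)))
  r_aug <- suppressWarnings(stats::cor(t(aug)))

  ii <- match(gi, genes); jj <- match(gj, genes)
  idx <- cbind(ii, jj)
  pcc_ref <- r_ref[idx]
  pcc_new <- r_aug[idx]
  degen <- !is.finite(pcc_ref) | abs(pcc_ref) >= 1 - 1e-12 | !is.finite(pcc_new)

  delta <- pcc_new - pcc_ref
  z <- delta / ((1 - pcc_ref^2) / (n - 1))
  p <- 2 * stats::pnorm(-abs(z))

  out <- data.frame(gene_i = gi, gene_j = gj,
                    pcc_ref = pcc_ref, pcc_perturbed = pcc_new,
                    delta_pcc = delta, z = z, p_value = p,
                    stringsAsFactors = FALSE)
  res <- out[!degen, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_degenerate") <- sum(degen)
  attr(res, "degenerate_pairs") <- out[degen, c("gene_i", "gene_j"), drop = FALSE]
  res
}

#' Paired-sample edge weight
#'
#' Weight of a retained edge from the tumor- and normal-state correlation
#' perturbations: `|log2 |dPCC_tumor / dPCC_normal||`. Both magnitudes are
#' floored at `clamp_eps` before the ratio so the weight stays finite.
#'
#' @param delta_tumor,delta_normal dPCC of the edge in each state.
#' @param clamp_eps Magnitude floor (default 1e-6).
#' @return Non-negative finite weight(s); symmetric in its two arguments.
#' @export
edge_weight_paired <- function(delta_tumor, delta_normal, clamp_eps = 1e-6) {
  dt <- pmax(abs(delta_tumor), clamp_eps)
  dn <- pmax(abs(delta_normal), clamp_eps)
  abs(log2(dt / dn))
}

#' Read / validate a reference interactome edge list
#'
#' @param edges Data frame with columns gene_a, gene_b and optionally score.
#' @return Canonicalized data frame (gene_a < gene_b, no self-loops, no
#'   duplicates) with a `score` column in \[0, 1\].
#' @export
interactome <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("interactome needs two gene columns")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  score <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, length(a))
  keep <- a != b
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  cp <- canonical_pairs(a, b)
  dup <- duplicated(cp$key)
  out <- data.frame(gene_a = cp$a[!dup], gene_b = cp$b[!dup],
                    score = score[!dup], stringsAsFactors = FALSE)
  if (any(out$score < 0 | out$score > 1))
    stop("interactome confidence scores must lie in [0, 1]")
  rownames(out) <- NULL
  out
}

#' Build the personalized weighted gene interaction network of one patient
#'
#' Scores every reference-interactome edge in the tumor state and in the
#' normal state with [ssn_edge_statistics()] and keeps an edge iff its
#' significance flips: exactly one of the two p-values is below
#' `alpha_sig`. Kept edges are weighted according to `weight_mode`:
#' \describe{
#'   \item{paired}{`|log2 |dPCC_tumor / dPCC_normal||` ([edge_weight_paired()]).}
#'   \item{tumor_only}{`|dPCC_tumor|`; edge retention uses the tumor p-value
#'     alone, and the patient's own normal sample (named by
#'     `exclude_ref_sample`) is dropped from the reference first.}
#'   \item{same}{all weights 1.}
#'   \item{original_network_score}{the interactome confidence score.}
#'   \item{random}{i.i.d. Uniform(0,1) weights drawn from `rng_seed`.}
#' }
#'
#' @param ref_expr Reference (normal-cohort) expression matrix.
#' @param tumor_sample,normal_sample Named expression vectors of the patient.
#' @param interactome Data frame as returned by [interactome()].
#' @param alpha_sig Per-edge significance level (default 0.05).
#' @param weight_mode One of the modes above.
#' @param neg_pcc_filter Optional threshold: edges with reference PCC below
#'   it are dropped before the flip test (default `NULL`, off).
#' @param clamp_eps Floor used by the paired weight.
#' @param rng_seed Seed for the random weight mode.
#' @param exclude_ref_sample Reference column to drop in tumor_only mode.
#' @return An object of class `personalized_network`: list with `nodes`,
#'   `edges` (gene_a, gene_b, weight, delta_tumor, delta_normal, p_tumor,
#'   p_normal), `weight_mode` and degenerate-edge counts.
#' @export
build_personalized_network <- function(ref_expr, tumor_sample, normal_sample,
                                       interactome,
                                       alpha_sig = 0.05,
                                       weight_mode = c("paired", "tumor_only",
                                                       "same",
                                                       "original_network_score",
                                                       "random"),
                                       neg_pcc_filter = NULL,
                                       clamp_eps = 1e-6,
                                       rng_seed = NULL,
                                       exclude_ref_sample = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (nrow(interactome) == 0) stop("interactome is empty")

  present <- interactome$gene_a %in% rownames(ref_expr) &
    interactome$gene_b %in% rownames(ref_expr)
  ia <- interactome[present, , drop = FALSE]
  if (nrow(ia) == 0) return(empty_pgin(weight_mode, alpha_sig))

  ref_t <- ref_expr
  if (weight_mode == "tumor_only" && !is.null(exclude_ref_sample) &&
      exclude_ref_sample %in% colnames(ref_t))
    ref_t <- ref_t[, setdiff(colnames(ref_t), exclude_ref_sample), drop = FALSE]

  st_t <- ssn_edge_statistics(ref_t, tumor_sample, ia[, 1:2])
  key_t <- paste(st_t$gene_i, st_t$gene_j, sep = "|")
  ia_key <- paste(ia$gene_a, ia$gene_b, sep = "|")

  if (weight_mode == "tumor_only") {
    keep <- st_t$p_value < alpha_sig
    if (!is.null(neg_pcc_filter)) keep <- keep & st_t$pcc_ref >= neg_pcc_filter
    kept <- st_t[keep, , drop = FALSE]
    edges <- data.frame(gene_a = kept$gene_i, gene_b = kept$gene_j,
                        weight = abs(kept$delta_pcc),
                        delta_tumor = kept$delta_pcc,
                        delta_normal = NA_real_,
                        p_tumor = kept$p_value,
                        p_normal = NA_real_,
                        stringsAsFactors = FALSE)
    return(new_pgin(edges, weight_mode, alpha_sig,
                    n_degenerate = attr(st_t, "n_degenerate")))
  }

  st_n <- ssn_edge_statistics(ref_expr, normal_sample, ia[, 1:2])
  key_n <- paste(st_n$gene_i, st_n$gene_j, sep = "|")
  common <- intersect(key_t, key_n)
  t_i <- match(common, key_t); n_i <- match(common, key_n)
  tt <- st_t[t_i, , drop = FALSE]; nn <- st_n[n_i, , drop = FALSE]

  keep <- xor(tt$p_value < alpha_sig, nn$p_value < alpha_sig)
  if (!is.null(neg_pcc_filter)) keep <- keep & tt$pcc_ref >= neg_pcc_filter
  tt <- tt[keep, , drop = FALSE]; nn <- nn[keep, , drop = FALSE]

  w <- switch(weight_mode,
    paired = edge_weight_paired(tt$delta_pcc, nn$delta_pcc, clamp_eps),
    same = rep(1, nrow(tt)),
    original_network_score = ia$score[match(paste(tt$gene_i, tt$gene_j, sep = "|"),
                                            ia_key)],
    random = with_seed(rng_seed, stats::runif(nrow(tt))))

  edges <- data.frame(gene_a = tt$gene_i, gene_b = tt$gene_j,
                      weight = w,
                      delta_tumor = tt$delta_pcc,
                      delta_normal = nn$delta_pcc,
                      p_tumor = tt$p_value,
                      p_normal = nn$p_value,
                      stringsAsFactors = FALSE)
  n_deg <- length(ia_key) - length(common)
  new_pgin(edges, weight_mode, alpha_sig, n_degenerate = n_deg)
}

new_pgin <- function(edges, weight_mode, alpha_sig, n_degenerate = 0) {
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges,
                 weight_mode = weight_mode,
                 alpha_sig = alpha_sig,
                 n_degenerate = n_degenerate),
            class = "personalized_network")
}

empty_pgin <- function(weight_mode, alpha_sig) {
  new_pgin(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), delta_tumor = numeric(),
                      delta_normal = numeric(), p_tumor = numeric(),
                      p_normal = numeric(), stringsAsFactors = FALSE),
           weight_mode, alpha_sig)
}

#' @export
print.personalized_network <- function(x, ...) {
  cat("Personalized gene interaction network\n")
  cat("  nodes:", length(x$nodes), " edges:", nrow(x$edges),
      " weight mode:", x$weight_mode, "\n")
  cat("  degenerate reference correlations excluded:", x$n_degenerate, "\n")
  invisible(x)
}

#' Convert a personalized network to an igraph object
#'
#' @param net A `personalized_network`.
#' @param weighted Attach edge weights as the `weight` attribute.
#' @return An undirected [igraph::graph] on the network's nodes.
#' @export
pgin_igraph <- function(net, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  if (weighted && nrow(net$edges)) igraph::E(g)$weight <- net$edges$weight
  g
}

#' Stability of personalized-network edge weights under reference subsampling
#'
#' Rebuilds the paired edge weights of the patient's personalized network on
#' `n_reps` random subsets of the reference samples (a fraction `fraction`
#' of them), forming a null weight distribution per edge. Each original
#' weight gets a two-sided empirical p-value against its null; the function
#' returns the proportion of edges that are NOT significantly different
#' (p > alpha) -- the robustness value. Larger reference fractions give
#' nulls closer to the original network and hence higher robustness.
#'
#' @inheritParams build_personalized_network
#' @param fraction Fraction of reference samples per subsample, in (0, 1].
#' @param n_reps Number of subsamples (default 100).
#' @param alpha Significance level for the empirical test.
#' @param rng_seed Seed for the subsampling.
#' @return Proportion in \[0, 1\]; 0 for an empty network.
#' @export
edge_robustness <- function(ref_expr, tumor_sample, normal_sample, interactome,
                            fraction, n_reps = 100, alpha = 0.05,
                            rng_seed = NULL, alpha_sig = 0.05,
                            clamp_eps = 1e-6) {
  n <- ncol(ref_expr)
  m <- ceiling(fraction * n)
  if (m < 3) stop("insufficient subsample: fraction * n must be >= 3")
  net <- build_personalized_network(ref_expr, tumor_sample, normal_sample,
                                    interactome, alpha_sig = alpha_sig,
                                    weight_mode = "paired",
                                    clamp_eps = clamp_eps)
  ne <- nrow(net$edges)
  if (ne == 0) return(0)
  pairs <- net$edges[, c("gene_a", "gene_b")]
  obs <- net$edges$weight

  null_w <- with_seed(rng_seed, {
    vapply(seq_len(n_reps), function(r) {
      cols <- sample.int(n, m)
      sub <- ref_expr[, cols, drop = FALSE]
      st_t <- ssn_edge_statistics(sub, tumor_sample, pairs)
      st_n <- ssn_edge_statistics(sub, normal_sample, pairs)
      kt <- paste(st_t$gene_i, st_t$gene_j, sep = "|")
      kn <- paste(st_n$gene_i, st_n$gene_j, sep = "|")
      key <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
      dt <- st_t$delta_pcc[match(key, kt)]
      dn <- st_n$delta_pcc[match(key, kn)]
      edge_weight_paired(dt, dn, clamp_eps)
    }, numeric(ne))
  })
  if (ne == 1) null_w <- matrix(null_w, nrow = 1)

  p <- vapply(seq_len(ne), function(i) {
    nulls <- null_w[i, ]
    nulls <- nulls[is.finite(nulls)]
    k <- length(nulls)
    if (k == 0) return(1)
    ge <- (1 + sum(nulls >= obs[i])) / (1 + k)
    le <- (1 + sum(nulls <= obs[i])) / (1 + k)
    min(1, 2 * min(ge, le))
  }, numeric(1))
  mean(p > alpha)
}
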