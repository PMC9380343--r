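# Patient-level differential expression and pathway dysregulation.

#' Identify a patient's differentially expressed genes
#'
#' Computes per-gene `log2((tumor + pseudocount) / (normal + pseudocount))`
#' and keeps genes whose absolute log2 fold change strictly exceeds `beta`.
#'
#' @param tumor_sample,normal_sample Named non-negative expression vectors
#'   over the same genes.
#' @param beta Fold-change threshold on the log2 scale (default 1).
#' @param pseudocount Added to both conditions before the ratio (default 1;
#'   0 is allowed when all inputs are strictly positive).
#' @return Object of class `deg_set`: named numeric vector of log2 fold
#'   changes for the DEGs, with attributes `beta` and `lfc_all` (all genes).
#' @export
identify_degs <- function(tumor_sample, normal_sample, beta = 1,
                          pseudocount = 1) {
  genes <- intersect(names(tumor_sample), names(normal_sample))
  if (length(genes) == 0) stop("samples share no genes")
  t <- tumor_sample[genes]; n <- normal_sample[genes]
  if (any(t < 0) || any(n < 0)) stop("expression must be non-negative")
  if (pseudocount == 0 && (any(t == 0) || any(n == 0)))
    stop("zero expression requires a positive pseudocount")
  lfc <- log2((t + pseudocount) / (n + pseudocount))
  degs <- lfc[abs(lfc) > beta]
  structure(degs, class = "deg_set", beta = beta, lfc_all = lfc)
}

#' @export
print.deg_set <- function(x, ...) {
  cat("DEG set:", length(x), "genes at |log2 fold change| >",
      attr(x, "beta"), "\n")
  invisible(x)
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `o_s` successes when drawing `o` genes
#' from a universe of `N` genes of which `s` are successes:
#' `sum_{i = o_s}^{min(o, s)} C(s, i) C(N - s, o - i) / C(N, o)`.
#'
#' @param N Universe size.
#' @param s Number of successes in the universe.
#' @param o Draw size.
#' @param o_s Observed successes in the draw.
#' @return p-value in \[0, 1\].
#' @export
hypergeometric_pvalue <- function(N, s, o, o_s) {
  if (s > N || o > N || o_s < 0 || o_s > min(o, s))
    stop("hypergeometric parameters out of range")
  stats::phyper(o_s - 1, s, N - s, o, lower.tail = FALSE)
}

#' Pathway collection constructor
#'
#' @param genesets Named list of character vectors (pathway id -> members).
#' @param topologies Optional named list of two-column edge data frames,
#'   keyed by pathway id; endpoints must be pathway members.
#' @return Object of class `pathway_collection`: list of pathways, each a
#'   list with `id`, `genes` and `edges` (possibly NULL).
#' @export
pathway_collection <- function(genesets, topologies = NULL) {
  if (is.null(names(genesets)) || anyDuplicated(names(genesets)))
    stop("genesets must be uniquely named by pathway id")
  pw <- lapply(names(genesets), function(id) {
    genes <- unique(as.character(genesets[[id]]))
    if (length(genes) == 0) stop("empty pathway: ", id)
    edges <- NULL
    if (!is.null(topologies) && id %in% names(topologies)) {
      e <- as.data.frame(topologies[[id]], stringsAsFactors = FALSE)
      if (nrow(e)) {
        bad <- !(e[[1]] %in% genes) | !(e[[2]] %in% genes)
        if (any(bad)) stop("topology of ", id, " has endpoints outside members")
        cp <- canonical_pairs(as.character(e[[1]]), as.character(e[[2]]))
        keep <- cp$a != cp$b & !duplicated(cp$key)
        edges <- data.frame(gene_a = cp$a[keep], gene_b = cp$b[keep],
                            stringsAsFactors = FALSE)
      }
    }
    list(id = id, genes = genes, edges = edges)
  })
  names(pw) <- names(genesets)
  structure(pw, class = "pathway_collection")
}

#' Dysregulated pathways of one patient
#'
#' Hypergeometric DEG enrichment per pathway with Benjamini-Hochberg
#' adjustment across all tested pathways; pathways with adjusted q below
#' `fdr_threshold` are called dysregulated.
#'
#' @param degs A [identify_degs()] result (or character vector of genes).
#' @param pathways A [pathway_collection()].
#' @param background Character vector: the gene universe. DEGs and pathway
#'   members are intersected with it before testing.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Data frame (pathway, n_members, n_deg_members, p, q) restricted
#'   to the dysregulated pathways, ordered by q; all tested pathways kept
#'   in attribute `all_tested`.
#' @export
dysregulated_pathways <- function(degs, pathways, background,
                                  fdr_threshold = 0.05) {
  if (length(background) == 0) stop("empty background universe")
  background <- unique(background)
  deg_genes <- intersect(if (is.character(degs)) degs else names(degs),
                         background)
  N <- length(background)
  s <- length(deg_genes)
  ids <- sort(names(pathways))
  rows <- lapply(ids, function(id) {
    members <- intersect(pathways[[id]]$genes, background)
    o <- length(members)
    o_s <- length(intersect(deg_genes, members))
    p <- if (o == 0) 1 else hypergeometric_pvalue(N, s, o, o_s)
    data.frame(pathway = id, n_members = o, n_deg_members = o_s, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  dp <- tab[tab$q < fdr_threshold, , drop = FALSE]
  dp <- dp[order(dp$q, dp$pathway), , drop = FALSE]
  rownames(dp) <- NULL
  attr(dp, "all_tested") <- tab
  dp
}
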