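# Readers and writers for the plain-text formats the pipeline consumes:
# genes-by-samples expression TSV, SNV/CNV matrices, interactome edge
# lists, GMT gene sets, SIF pathway topology, gene lists, and the
# personalized-network / ranking outputs.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a genes-by-samples expression matrix (TSV)
#'
#' Tab-separated, genes in rows, header row of sample ids, first column
#' gene symbols.
#'
#' @param path File path.
#' @param role Sample role attached to the matrix.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, role = "reference") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  expression_matrix(m, role = role)
}

#' Write an expression matrix as TSV
#' @param mat Numeric matrix with gene rownames.
#' @param path Destination file.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat),
                   apply(mat, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an interactome edge list (gene_a, gene_b, score TSV)
#' @param path File path; 2 or 3 tab-separated columns, no header.
#' @return Canonicalized interactome data frame ([interactome()]).
#' @export
read_interactome <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!ncol(tab) %in% c(2, 3))
    stop("interactome file must have 2 or 3 columns: ", path)
  interactome(tab)
}

#' Write an interactome edge list
#' @param ia Interactome data frame.
#' @param path Destination file.
#' @export
write_interactome <- function(ia, path) {
  out <- data.frame(ia$gene_a, ia$gene_b, fmt_num(ia$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an SNV or CNV genes-by-patients matrix (TSV)
#'
#' @param path File path (header of patient ids, first column genes).
#' @param kind `"snv"` (values 0/1) or `"cnv"` (values -1/0/1).
#' @return Integer matrix, genes x patients.
#' @export
read_mutation_matrix <- function(path, kind = c("snv", "cnv")) {
  kind <- match.arg(kind)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  legal <- if (kind == "snv") c(0, 1) else c(-1, 0, 1)
  if (!all(m %in% legal))
    stop("illegal ", toupper(kind), " values in ", path,
         " (allowed: ", paste(legal, collapse = "/"), ")")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write an SNV/CNV matrix as TSV
#' @param m Integer matrix, genes x patients.
#' @param path Destination file.
#' @export
write_mutation_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: id, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate pathway ids in ", path)
  sets
}

#' Write gene sets in GMT format
#' @param genesets Named list of character vectors.
#' @param path Destination file.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(names(genesets), function(id)
    paste(c(id, id, genesets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read pathway topology in SIF format
#'
#' Three whitespace-separated columns: node, relation, node. Two-column
#' edge lists are accepted as well.
#'
#' @param path File path.
#' @return Two-column data frame of undirected edges.
#' @export
read_sif <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 3) tab <- tab[, c(1, 3)]
  if (ncol(tab) != 2) stop("SIF file must have 2 or 3 columns: ", path)
  names(tab) <- c("gene_a", "gene_b")
  tab
}

#' Write pathway topology in SIF format
#' @param edges Two-column edge data frame.
#' @param path Destination file.
#' @param relation Relation label (middle column).
#' @export
write_sif <- function(edges, path, relation = "pp") {
  utils::write.table(data.frame(edges[[1]], relation, edges[[2]]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a plain gene list (one symbol per line)
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write a plain gene list
#' @param genes Character vector.
#' @param path Destination file.
#' @export
write_gene_list <- function(genes, path) writeLines(genes, path)

#' Write a personalized network as a TSV edge list
#'
#' Columns: gene_a, gene_b, weight, delta_tumor, delta_normal, p_tumor,
#' p_normal.
#'
#' @param net A `personalized_network`.
#' @param path Destination file.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  out <- data.frame(e$gene_a, e$gene_b, fmt_num(e$weight),
                    fmt_num(e$delta_tumor), fmt_num(e$delta_normal),
                    fmt_num(e$p_tumor), fmt_num(e$p_normal))
  colnames(out) <- c("gene_a", "gene_b", "weight", "delta_tumor",
                     "delta_normal", "p_tumor", "p_normal")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a personalized network written by [write_network()]
#' @param path File path.
#' @param weight_mode Weight mode recorded on the object.
#' @return A `personalized_network`.
#' @export
read_network <- function(path, weight_mode = "paired") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  new_pgin(tab, weight_mode = weight_mode, alpha_sig = NA_real_)
}

#' Write a per-patient driver ranking (rank, gene, infl_total TSV)
#' @param ranking The `ranking` data frame of an `influence_ranking`.
#' @param path Destination file.
#' @export
write_ranking <- function(ranking, path) {
  out <- ranking
  out$infl_total <- fmt_num(out$infl_total)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
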