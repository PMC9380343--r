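# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Reference expression matrix: n_genes x n_samples iid N(10, 1) values.
make_ref <- function(n_genes = 10, n_samples = 20, seed = 1,
                     genes = sprintf("g%02d", seq_len(n_genes))) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 10), nrow = n_genes,
              dimnames = list(genes, sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m)
}

# All-pairs interactome over the genes of a matrix.
make_full_interactome <- function(genes, seed = 1) {
  pairs <- t(combn(genes, 2))
  set.seed(seed)
  interactome(data.frame(pairs[, 1], pairs[, 2],
                         runif(nrow(pairs), 0.7, 1)))
}

# Random prize/cost graph for solver tests: connected-ish G(n, p) with
# Uniform(0,1) prizes (some zeroed) and Uniform(0,1) costs.
make_random_prize_graph <- function(n, seed, p_edge = 0.4) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                      cost = runif(sum(keep)), stringsAsFactors = FALSE)
  pz <- runif(n)
  pz[runif(n) < 0.3] <- 0   # some Steiner-only nodes
  pz[1] <- max(pz[1], 0.05) # prized root keeps every instance feasible
  prize_graph(edges, setNames(pz, nodes), root = nodes[1], nodes = nodes)
}

# Independent PCST oracle: enumerate every node subset containing the
# root, test connectivity by BFS, and take sum(prizes) minus the
# Kruskal MST cost. Deliberately shares no code with the package solver.
oracle_pcst <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  adj <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$gene_a[e], nodes)
    j <- match(graph$edges$gene_b[e], nodes)
    adj[i, j] <- min(adj[i, j], graph$edges$cost[e])
    adj[j, i] <- adj[i, j]
  }
  root <- match(graph$root, nodes)
  others <- setdiff(seq_len(n), root)
  best <- -Inf
  el_all <- which(is.finite(adj) & upper.tri(adj), arr.ind = TRUE)
  el_all <- el_all[order(adj[el_all]), , drop = FALSE]   # ascending cost once
  kruskal <- function(set) {
    keep <- el_all[, 1] %in% set & el_all[, 2] %in% set
    el <- el_all[keep, , drop = FALSE]
    comp <- seq_len(n)
    total <- 0; used <- 0
    for (r in seq_len(nrow(el))) {
      a <- comp[el[r, 1]]; b <- comp[el[r, 2]]
      if (a != b) {
        comp[comp == b] <- a
        total <- total + adj[el[r, 1], el[r, 2]]
        used <- used + 1
      }
    }
    if (used < length(set) - 1) Inf else total
  }
  connected <- function(set) {
    seen <- root; frontier <- root
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v)
        set[is.finite(adj[v, set])])))
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    length(seen) == length(set)
  }
  for (mask in 0:(2^length(others) - 1)) {
    set <- c(root, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    if (!connected(set)) next
    f <- sum(graph$prizes[set]) - kruskal(set)
    if (f > best) best <- f
  }
  best
}

# Small synthetic cohort used across pipeline tests.
small_cohort <- function(seed = 3, ...) {
  generate_cohort(synthetic_config(n_genes = 120, n_patients = 4,
                                   n_reference_samples = 20, n_pathways = 5,
                                   pathway_size = c(8, 12), rng_seed = seed,
                                   ...))
}

patient_vectors <- function(cohort, patient) {
  tumor <- cohort$tumor[, patient]
  normal <- cohort$normal[, patient]
  names(tumor) <- names(normal) <- rownames(cohort$tumor)
  list(tumor = tumor, normal = normal)
}
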