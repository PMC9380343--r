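# Synthetic cohort generator with planted drivers.
#
# Normal samples follow a latent-factor model with one factor per pathway
# module, giving block-correlated co-expression aligned to the pathways.
# Each patient's tumor sample (i) replaces the coherent factor signal of
# its planted driver's module by an incoherent high-amplitude component,
# so appending the tumor sample perturbs the reference correlations of
# module edges (the paired-SSN significance flip), and (ii) multiplies the
# module genes' expression by 2^deg_effect, creating DEGs downstream of
# the driver along the pathway topology. Drivers are always mutated;
# passengers are mutated at a configurable rate.

#' Configuration of a synthetic cohort
#'
#' @param n_genes Total genes (default 300).
#' @param n_patients Patients (default 10).
#' @param n_reference_samples Normal/reference samples; must be >= `n_patients`
#'   since each patient's normal sample is a reference column (default 50).
#' @param n_pathways Disjoint pathway modules (default 10).
#' @param pathway_size Length-2 range of module sizes (default c(10, 20)).
#' @param edge_density Background interactome edge density (default 0.01).
#' @param n_planted_drivers Planted drivers per patient (default 1).
#' @param rewiring_strength In \[0, 1\]: fraction of the tumor module signal
#'   replaced by the incoherent component (0 = no co-expression rewiring).
#' @param deg_effect Log2 fold-change magnitude applied to the driver's
#'   module genes in the tumor sample (0 = no DEGs planted).
#' @param passenger_rate Per-gene, per-patient passenger mutation
#'   probability (default 0.01).
#' @param n_comutated Additional mutated genes planted inside each
#'   driver's module (default 4), emulating the co-mutation clustering of
#'   pathway partners that the screening step scores; 0 disables it.
#' @param noise_sd Gene-level Gaussian noise standard deviation (default 1).
#' @param rng_seed Single seed all randomness flows from.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 300, n_patients = 10,
                             n_reference_samples = 50, n_pathways = 10,
                             pathway_size = c(10, 20), edge_density = 0.01,
                             n_planted_drivers = 1, rewiring_strength = 0.8,
                             deg_effect = 2, passenger_rate = 0.01,
                             n_comutated = 4, noise_sd = 1, rng_seed = 1) {
  cfg <- list(n_genes = n_genes, n_patients = n_patients,
              n_reference_samples = n_reference_samples,
              n_pathways = n_pathways, pathway_size = pathway_size,
              edge_density = edge_density,
              n_planted_drivers = n_planted_drivers,
              rewiring_strength = rewiring_strength,
              deg_effect = deg_effect, passenger_rate = passenger_rate,
              n_comutated = n_comutated, noise_sd = noise_sd,
              rng_seed = rng_seed)
  counts <- c(n_genes, n_patients, n_reference_samples, n_pathways,
              pathway_size)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (rewiring_strength < 0 || rewiring_strength > 1 ||
      passenger_rate < 0 || passenger_rate > 1)
    stop("rates must lie in [0, 1]")
  if (n_pathways * max(pathway_size) > n_genes)
    stop("infeasible config: pathways cannot fit in n_genes disjointly")
  if (n_reference_samples < max(3, n_patients))
    stop("need at least max(3, n_patients) reference samples")
  structure(cfg, class = "synthetic_config")
}

# Random tree over `genes` by sequential random attachment.
random_tree_edges <- function(genes) {
  k <- length(genes)
  if (k < 2) return(data.frame(gene_a = character(), gene_b = character(),
                               stringsAsFactors = FALSE))
  parent <- vapply(2:k, function(i) sample.int(i - 1, 1), integer(1))
  cp <- canonical_pairs(genes[parent], genes[2:k])
  data.frame(gene_a = cp$a, gene_b = cp$b, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with planted drivers
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_cohort`: list with `ref_expr`
#'   (reference matrix whose first `n_patients` columns are the patients'
#'   normal samples), `tumor` and `normal` (genes x patients matrices),
#'   `snv`, `cnv`, `interactome`, `pathways` and `truth` (list with
#'   `drivers` per patient, `rewired_edges`, `true_degs` per patient).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$rng_seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  base <- 10; loading <- 2; amp <- 3

  # disjoint pathway modules with a hub driver candidate each
  sizes <- sample(seq(cfg$pathway_size[1], cfg$pathway_size[2]),
                  cfg$n_pathways, replace = TRUE)
  ends <- cumsum(sizes)
  members <- lapply(seq_len(cfg$n_pathways), function(m)
    genes[(c(0, ends)[m] + 1):ends[m]])
  pw_ids <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  names(members) <- pw_ids
  module_of <- stats::setNames(rep(NA_integer_, cfg$n_genes), genes)
  for (m in seq_len(cfg$n_pathways)) module_of[members[[m]]] <- m
  hub <- vapply(members, `[`, character(1), 1)

  topo <- lapply(members, random_tree_edges)
  pathways <- pathway_collection(members, topo)

  # interactome: hub stars + random background edges; the pathway tree
  # topology deliberately stays out of the interactome so the
  # pathway-only cost branch of the prize/cost graph is exercised
  stars <- do.call(rbind, lapply(seq_len(cfg$n_pathways), function(m) {
    others <- setdiff(members[[m]], hub[m])
    cp <- canonical_pairs(rep(hub[m], length(others)), others)
    data.frame(gene_a = cp$a, gene_b = cp$b, stringsAsFactors = FALSE)
  }))
  n_bg <- round(cfg$edge_density * cfg$n_genes * (cfg$n_genes - 1) / 2)
  bg <- if (n_bg > 0) {
    a <- genes[sample.int(cfg$n_genes, n_bg, replace = TRUE)]
    b <- genes[sample.int(cfg$n_genes, n_bg, replace = TRUE)]
    keep <- a != b
    data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
  } else stars[0, ]
  all_e <- rbind(stars, bg)
  ia <- interactome(data.frame(all_e$gene_a, all_e$gene_b,
                               stats::runif(nrow(all_e), 0.7, 1)))

  in_mod <- !is.na(module_of)
  # one latent module-activity vector per individual; a patient's tumor
  # sample shares its individual's factors (paired samples), with
  # independent gene-level noise
  f_ref <- matrix(stats::rnorm(cfg$n_pathways * cfg$n_reference_samples),
                  nrow = cfg$n_pathways)
  draw_sample <- function(f) {
    x <- stats::setNames(base + cfg$noise_sd * stats::rnorm(cfg$n_genes),
                         genes)
    x[in_mod] <- x[in_mod] + loading * f[module_of[in_mod]]
    pmax(x, 0)
  }

  ref <- vapply(seq_len(cfg$n_reference_samples),
                function(s) draw_sample(f_ref[, s]),
                numeric(cfg$n_genes))
  rownames(ref) <- genes
  colnames(ref) <- c(patients,
                     sprintf("N%03d", seq_len(cfg$n_reference_samples -
                                                cfg$n_patients)))
  normal <- ref[, patients, drop = FALSE]

  drivers <- lapply(seq_len(cfg$n_patients), function(i) {
    mods <- ((i - 1 + seq_len(cfg$n_planted_drivers) - 1) %% cfg$n_pathways) + 1
    unname(hub[mods])
  })
  names(drivers) <- patients

  tumor <- matrix(0, cfg$n_genes, cfg$n_patients,
                  dimnames = list(genes, patients))
  true_degs <- vector("list", cfg$n_patients)
  names(true_degs) <- patients
  s <- cfg$rewiring_strength
  for (i in seq_len(cfg$n_patients)) {
    f <- f_ref[, i]   # shared with the patient's normal sample
    x <- stats::setNames(base + cfg$noise_sd * stats::rnorm(cfg$n_genes), genes)
    x[in_mod] <- x[in_mod] + loading * f[module_of[in_mod]]
    driver_mods <- unique(module_of[drivers[[i]]])
    mod_genes <- genes[in_mod & module_of %in% driver_mods]
    # rewire: replace coherent factor signal by an incoherent component
    x[mod_genes] <- base + cfg$noise_sd * stats::rnorm(length(mod_genes)) +
      loading * (1 - s) * f[module_of[mod_genes]] +
      s * amp * loading * stats::rnorm(length(mod_genes))
    # DEG shift propagated along the module topology
    x[mod_genes] <- x[mod_genes] * 2^cfg$deg_effect
    tumor[, i] <- pmax(x, 0)
    true_degs[[i]] <- if (cfg$deg_effect > 0) mod_genes else character()
  }

  snv <- matrix(0L, cfg$n_genes, cfg$n_patients,
                dimnames = list(genes, patients))
  cnv <- matrix(0L, cfg$n_genes, cfg$n_patients,
                dimnames = list(genes, patients))
  for (i in seq_len(cfg$n_patients)) {
    snv[drivers[[i]], i] <- 1L
    if (cfg$n_comutated > 0) {
      for (d in drivers[[i]]) {
        pool <- setdiff(members[[module_of[d]]], drivers[[i]])
        com <- sample(pool, min(cfg$n_comutated, length(pool)))
        snv[com, i] <- 1L
      }
    }
    pas <- stats::runif(cfg$n_genes) < cfg$passenger_rate
    kind <- stats::runif(cfg$n_genes) < 0.5
    snv[pas & kind, i] <- 1L
    cnv[pas & !kind, i] <- sample(c(-1L, 1L), sum(pas & !kind), replace = TRUE)
  }

  ia_key <- paste(ia$gene_a, ia$gene_b, sep = "|")
  rewired <- do.call(rbind, lapply(unique(unlist(drivers)), function(d) {
    m <- module_of[d]
    others <- setdiff(members[[m]], hub[m])
    cp <- canonical_pairs(rep(hub[m], length(others)), others)
    data.frame(gene_a = cp$a, gene_b = cp$b, stringsAsFactors = FALSE)
  }))
  if (!is.null(rewired)) {
    rk <- paste(rewired$gene_a, rewired$gene_b, sep = "|")
    rewired <- rewired[!duplicated(rk) & rk %in% ia_key, , drop = FALSE]
    rownames(rewired) <- NULL
  }

  structure(list(ref_expr = expression_matrix(ref, role = "reference"),
                 tumor = expression_matrix(tumor, role = "tumor"),
                 normal = expression_matrix(normal, role = "normal"),
                 snv = snv, cnv = cnv,
                 interactome = ia, pathways = pathways,
                 truth = list(drivers = drivers,
                              rewired_edges = rewired,
                              true_degs = true_degs),
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic cohort:", cfg$n_patients, "patients,", cfg$n_genes,
      "genes,", cfg$n_pathways, "pathways,", nrow(x$interactome),
      "interactome edges\n")
  invisible(x)
}

#' Write a synthetic cohort to a run directory
#'
#' Emits every artifact in the dialect the package readers consume:
#' `reference_expr.tsv`, `tumor_expr.tsv`, `normal_expr.tsv`, `snv.tsv`,
#' `cnv.tsv`, `interactome.tsv`, `pathways.gmt`, `topology/<id>.sif` and
#' `truth_drivers.tsv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "topology"), recursive = TRUE,
             showWarnings = FALSE)
  write_expression_matrix(cohort$ref_expr, file.path(dir, "reference_expr.tsv"))
  write_expression_matrix(cohort$tumor, file.path(dir, "tumor_expr.tsv"))
  write_expression_matrix(cohort$normal, file.path(dir, "normal_expr.tsv"))
  write_mutation_matrix(cohort$snv, file.path(dir, "snv.tsv"))
  write_mutation_matrix(cohort$cnv, file.path(dir, "cnv.tsv"))
  write_interactome(cohort$interactome, file.path(dir, "interactome.tsv"))
  write_gmt(lapply(cohort$pathways, `[[`, "genes"),
            file.path(dir, "pathways.gmt"))
  for (id in names(cohort$pathways)) {
    e <- cohort$pathways[[id]]$edges
    if (!is.null(e) && nrow(e))
      write_sif(e, file.path(dir, "topology", paste0(id, ".sif")))
  }
  td <- data.frame(patient = rep(names(cohort$truth$drivers),
                                 lengths(cohort$truth$drivers)),
                   gene = unlist(cohort$truth$drivers))
  utils::write.table(td, file.path(dir, "truth_drivers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a run directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return List with the same components as a `synthetic_cohort` (truth
#'   restricted to the planted drivers).
#' @export
read_cohort <- function(dir) {
  ref <- read_expression_matrix(file.path(dir, "reference_expr.tsv"))
  tumor <- read_expression_matrix(file.path(dir, "tumor_expr.tsv"),
                                  role = "tumor")
  normal <- read_expression_matrix(file.path(dir, "normal_expr.tsv"),
                                   role = "normal")
  snv <- read_mutation_matrix(file.path(dir, "snv.tsv"), "snv")
  cnv <- read_mutation_matrix(file.path(dir, "cnv.tsv"), "cnv")
  ia <- read_interactome(file.path(dir, "interactome.tsv"))
  sets <- read_gmt(file.path(dir, "pathways.gmt"))
  topo <- list()
  for (id in names(sets)) {
    f <- file.path(dir, "topology", paste0(id, ".sif"))
    if (file.exists(f)) topo[[id]] <- read_sif(f)
  }
  truth <- NULL
  tf <- file.path(dir, "truth_drivers.tsv")
  if (file.exists(tf)) {
    td <- utils::read.table(tf, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    truth <- list(drivers = split(td$gene, td$patient))
  }
  list(ref_expr = ref, tumor = tumor, normal = normal, snv = snv, cnv = cnv,
       interactome = ia, pathways = pathway_collection(sets, topo),
       truth = truth)
}

#' End-to-end planted-driver recovery on a synthetic cohort
#'
#' Generates a cohort, runs the full pipeline, and compares the top of the
#' cohort ranking against the planted drivers. A permutation null (random
#' orderings of the cohort's mutated genes) provides the band a random
#' ranking would fall in.
#'
#' @param config A [synthetic_config()].
#' @param params Pipeline parameters ([default_params()]).
#' @param k Cutoff for precision at k (default 5).
#' @param n_perm Permutation-null draws (default 1000).
#' @return List with `precision_at_k`, `null_mean`, `null_upper` (0.99
#'   quantile of the null), `above_null`, the cohort `ranking` and the
#'   planted `drivers`.
#' @export
end_to_end_recovery <- function(config, params = default_params(), k = 5,
                                n_perm = 1000) {
  cohort <- generate_cohort(config)
  params$rng_seed <- params$rng_seed %||% config$rng_seed
  res <- run_cohort(cohort, params)
  drivers <- unique(unlist(cohort$truth$drivers))
  mutated <- sort(unique(rownames(cohort$snv)[rowSums(cohort$snv != 0) +
                                                rowSums(cohort$cnv != 0) > 0]))
  ranked <- if (!is.null(res$cohort_ranking)) res$cohort_ranking$gene
            else character()
  prec <- if (length(ranked)) length(intersect(utils::head(ranked, k),
                                               drivers)) / k else 0
  null_prec <- with_seed(config$rng_seed + 10^6, {
    vapply(seq_len(n_perm), function(i)
      length(intersect(sample(mutated, min(k, length(mutated))), drivers)) / k,
      numeric(1))
  })
  list(precision_at_k = prec, k = k,
       null_mean = mean(null_prec),
       null_upper = unname(stats::quantile(null_prec, 0.99)),
       above_null = prec > unname(stats::quantile(null_prec, 0.99)),
       ranking = ranked, drivers = drivers, mutated = mutated)
}
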