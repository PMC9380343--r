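# Pipeline orchestration: per-patient run (network -> DEGs/pathways ->
# screening -> PCST ranking) and cohort-level aggregation/evaluation.

#' Default pipeline parameters
#'
#' @param ... Named overrides of any default.
#' @return Named list: `alpha_sig` (edge significance, 0.05), `beta` (DEG
#'   log2 fold-change threshold, 1), `pseudocount` (1), `fdr_threshold`
#'   (pathway FDR, 0.05), `restart` (RWR restart, 0.7), `n_random` (random
#'   networks, 50), `n_swaps_factor` (swaps per edge in each null, 10),
#'   `weight_mode` ("paired"), `screening_mode` ("rwr+hub"), `exact_limit`
#'   (PCST exact-solver cap, 15), `k_max` (evaluation cutoff, 50),
#'   `clamp_eps` (1e-6), `neg_pcc_filter` (NULL), `rng_seed` (NULL).
#' @export
default_params <- function(...) {
  p <- list(alpha_sig = 0.05, beta = 1, pseudocount = 1,
            fdr_threshold = 0.05, restart = 0.7, n_random = 50,
            n_swaps_factor = 10, weight_mode = "paired",
            screening_mode = "rwr+hub", exact_limit = 15, k_max = 50,
            clamp_eps = 1e-6, neg_pcc_filter = NULL, rng_seed = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Run the full prioritization pipeline for one patient
#'
#' Builds the personalized network, identifies DEGs and dysregulated
#' pathways, screens key mutant genes according to `screening_mode`
#' (`"rwr+hub"`, `"rwr"`, `"hub"` or `"all"`), and ranks them by total
#' PCST influence.
#'
#' @param cohort List with `ref_expr`, `tumor`, `normal` (genes x patients
#'   matrices), `snv`, `cnv`, `interactome`, `pathways` -- e.g. a
#'   [generate_cohort()] result or [read_cohort()] output.
#' @param patient Patient id (column of the tumor matrix).
#' @param params Pipeline parameters ([default_params()]).
#' @return List with `patient`, `network`, `degs`, `dp`, `K`, `H`, `M`,
#'   `result` (an `influence_ranking`) and `log` (named counts).
#' @export
run_patient <- function(cohort, patient, params = default_params()) {
  if (!patient %in% colnames(cohort$tumor))
    stop("patient not found in tumor expression matrix: ", patient)
  tumor <- cohort$tumor[, patient]
  normal <- cohort$normal[, patient]
  names(tumor) <- names(normal) <- rownames(cohort$tumor)

  net <- build_personalized_network(
    cohort$ref_expr, tumor, normal, cohort$interactome,
    alpha_sig = params$alpha_sig, weight_mode = params$weight_mode,
    neg_pcc_filter = params$neg_pcc_filter, clamp_eps = params$clamp_eps,
    rng_seed = params$rng_seed, exclude_ref_sample = patient)

  degs <- identify_degs(tumor, normal, beta = params$beta,
                        pseudocount = params$pseudocount)
  background <- intersect(rownames(cohort$ref_expr),
                          unique(c(cohort$interactome$gene_a,
                                   cohort$interactome$gene_b)))
  dp <- dysregulated_pathways(degs, cohort$pathways, background,
                              fdr_threshold = params$fdr_threshold)

  snv <- if (patient %in% colnames(cohort$snv)) cohort$snv[, patient] else
    stats::setNames(integer(0), character(0))
  cnv <- if (!is.null(cohort$cnv) && patient %in% colnames(cohort$cnv))
    cohort$cnv[, patient] else NULL
  prof <- mutation_profile(snv, cnv, patient)

  K <- H <- character()
  mutated_in_net <- intersect(prof$mutated, net$nodes)
  if (nrow(net$edges) > 0) {
    H <- hub_genes(net)
    if (length(mutated_in_net) &&
        params$screening_mode %in% c("rwr+hub", "rwr")) {
      K <- comutation_significance(net, prof$mutated,
                                   restart = params$restart,
                                   n_random = params$n_random,
                                   n_swaps_factor = params$n_swaps_factor,
                                   rng_seed = params$rng_seed,
                                   alpha = params$alpha_sig)$K
    }
  }
  M <- switch(params$screening_mode,
              "rwr+hub" = key_mutant_genes(K, H),
              "rwr" = sort(K),
              "hub" = sort(intersect(prof$mutated, H)),
              "all" = prof$mutated,
              stop("unknown screening_mode: ", params$screening_mode))
  if (length(M) == 0)
    warning("patient ", patient, ": no key mutant gene; empty ranking")

  result <- rank_patient_drivers(net, degs, dp, M, cohort$pathways,
                                 exact_limit = params$exact_limit)
  log <- c(n_network_edges = nrow(net$edges),
           n_degenerate_edges = net$n_degenerate,
           n_degs = length(degs), n_dysregulated_pathways = nrow(dp),
           n_mutated = length(prof$mutated), n_K = length(K),
           n_H = length(H), n_M = length(M))
  list(patient = patient, network = net, degs = degs, dp = dp,
       K = K, H = H, M = M, result = result, log = log)
}

#' Run the pipeline over a cohort and aggregate by Condorcet voting
#'
#' @inheritParams run_patient
#' @param gold Optional gold-standard driver gene set; when given, the
#'   cohort ranking is evaluated with [evaluate_ranking()].
#' @return List with `patients` (per-patient [run_patient()] results),
#'   `cohort_ranking` ([condorcet_rank()] table, NULL when every patient
#'   came up empty) and `evaluation` (an `evaluation_report` or NULL).
#' @export
run_cohort <- function(cohort, params = default_params(), gold = NULL) {
  ids <- colnames(cohort$tumor)
  base_seed <- params$rng_seed
  runs <- lapply(seq_along(ids), function(i) {
    p <- params
    if (!is.null(base_seed)) p$rng_seed <- (base_seed + i) %% .Machine$integer.max
    run_patient(cohort, ids[i], p)
  })
  names(runs) <- ids
  rankings <- lapply(runs, function(r) r$result$ranking$gene)
  rankings <- Filter(length, rankings)
  cohort_ranking <- if (length(rankings)) condorcet_rank(rankings) else NULL
  evaluation <- NULL
  if (!is.null(gold)) {
    if (is.null(cohort_ranking)) {
      warning("no patient produced a ranking; evaluation skipped")
    } else {
      mutated <- sort(unique(rownames(cohort$snv)[
        rowSums(cohort$snv != 0) +
          (if (is.null(cohort$cnv)) 0 else rowSums(cohort$cnv != 0)) > 0]))
      evaluation <- evaluate_ranking(cohort_ranking$gene, gold, mutated,
                                     k_max = params$k_max)
    }
  }
  list(patients = runs, cohort_ranking = cohort_ranking,
       evaluation = evaluation)
}
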