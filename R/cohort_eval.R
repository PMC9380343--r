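# Cohort-level aggregation of per-patient rankings (Condorcet/Copeland
# voting) and evaluation against a gold-standard driver list.

#' Condorcet aggregation of per-patient gene rankings
#'
#' Gene `a` beats gene `b` when `a` is ranked above `b` in strictly more
#' patient lists than the converse; genes absent from a list are tied
#' below all of its ranked genes (and tied with each other). Genes are
#' ordered by Copeland score (wins minus losses), ties broken by mean rank
#' (absent genes counting as one past the list length), then
#' lexicographically.
#'
#' @param rankings List of character vectors, best-first, one per patient.
#' @return Data frame with columns `rank`, `gene`, `copeland`, `mean_rank`.
#' @export
condorcet_rank <- function(rankings) {
  rankings <- Filter(length, rankings)
  if (length(rankings) == 0) stop("all rankings are empty")
  genes <- sort(unique(unlist(rankings)))
  n <- length(genes)

  # pos[v, g]: rank of g in voter v's list, or len+1 when absent
  pos <- matrix(0, nrow = length(rankings), ncol = n,
                dimnames = list(NULL, genes))
  for (v in seq_along(rankings)) {
    r <- rankings[[v]]
    pos[v, ] <- length(r) + 1
    pos[v, r] <- seq_along(r)
  }

  copeland <- stats::setNames(numeric(n), genes)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a_above <- sum(pos[, i] < pos[, j])
        b_above <- sum(pos[, j] < pos[, i])
        if (a_above > b_above) {
          copeland[i] <- copeland[i] + 1; copeland[j] <- copeland[j] - 1
        } else if (b_above > a_above) {
          copeland[j] <- copeland[j] + 1; copeland[i] <- copeland[i] - 1
        }
      }
    }
  }
  mean_rank <- colMeans(pos)
  ord <- order(-copeland, mean_rank, genes)
  data.frame(rank = seq_len(n), gene = genes[ord],
             copeland = unname(copeland[ord]),
             mean_rank = unname(mean_rank[ord]),
             stringsAsFactors = FALSE)
}

#' Precision, recall and F1 of a ranking against a gold standard
#'
#' For each cutoff k up to `k_max`: `precision(k) = |top-k n gold| / k`,
#' `recall(k) = |top-k n gold| / |mutated n gold|` and the harmonic-mean
#' F1 (0 whenever precision or recall is 0). Averages over k = 1..`k_max`
#' are reported alongside the per-k table.
#'
#' @param ranking Character vector, best-first (e.g. the `gene` column of
#'   [condorcet_rank()]).
#' @param gold Gold-standard driver gene set.
#' @param mutated Union of mutated genes across the cohort (the reachable
#'   set for recall).
#' @param k_max Largest cutoff (default 50).
#' @return Object of class `evaluation_report`: list with `per_k` (data
#'   frame k / precision / recall / f1), `avg_precision`, `avg_recall`,
#'   `avg_f1`, and the set sizes used.
#' @export
evaluate_ranking <- function(ranking, gold, mutated, k_max = 50) {
  if (length(ranking) == 0) stop("ranking is empty")
  reachable <- length(intersect(mutated, gold))
  if (reachable == 0)
    warning("no mutated gene is in the gold standard; recall reported as 0")
  ks <- seq_len(k_max)
  hit <- ranking %in% gold
  cum_hits <- cumsum(hit)
  hits_at <- function(k) if (k <= length(ranking)) cum_hits[k] else
    cum_hits[length(ranking)]
  h <- vapply(ks, hits_at, numeric(1))
  precision <- h / ks
  recall <- if (reachable > 0) h / reachable else rep(0, k_max)
  f1 <- ifelse(precision > 0 & recall > 0,
               2 / (1 / precision + 1 / recall), 0)
  per_k <- data.frame(k = ks, precision = precision, recall = recall, f1 = f1)
  structure(list(per_k = per_k,
                 avg_precision = mean(precision),
                 avg_recall = mean(recall),
                 avg_f1 = mean(f1),
                 n_gold = length(unique(gold)),
                 n_reachable = reachable,
                 k_max = k_max),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation over k = 1..", x$k_max, " (", x$n_reachable,
      " gold-standard genes reachable)\n", sep = "")
  cat(sprintf("  average precision: %.4f\n", x$avg_precision))
  cat(sprintf("  average recall:    %.4f\n", x$avg_recall))
  cat(sprintf("  average F1:        %.4f\n", x$avg_f1))
  invisible(x)
}
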