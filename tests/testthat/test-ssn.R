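# Single-sample network statistics and personalized network construction.

test_that("pearson_edge handles identity, anti-identity and matches a
           from-scratch covariance computation", {
  ref <- make_ref(4, 20, seed = 11)
  ref["g02", ] <- ref["g01", ]                      # exact copy
  ref["g03", ] <- -ref["g01", ] + 25                # affine flip
  expect_equal(pearson_edge(ref, "g01", "g02"), 1.0)
  expect_equal(pearson_edge(ref, "g01", "g03"), -1.0)

  x <- ref["g01", ]; y <- ref["g04", ]
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_edge(ref, "g01", "g04"), manual, tolerance = 1e-12)

  ref["g04", ] <- 5
  expect_error(pearson_edge(ref, "g01", "g04"), "zero-variance")
  expect_error(pearson_edge(ref, "g01", "nope"), "not in expression")
})

test_that("an extra sample at the reference means leaves correlations
           untouched (dPCC = 0, Z = 0, p = 1)", {
  ref <- make_ref(6, 15, seed = 2)
  extra <- rowMeans(ref)
  st <- ssn_edge_statistics(ref, extra,
                            data.frame(a = c("g01", "g02"),
                                       b = c("g03", "g05")))
  expect_equal(st$delta_pcc, c(0, 0), tolerance = 1e-12)
  expect_equal(st$z, c(0, 0), tolerance = 1e-10)
  expect_equal(st$p_value, c(1, 1), tolerance = 1e-10)
})

test_that("edges with a degenerate reference correlation are excluded and
           counted", {
  ref <- make_ref(4, 12, seed = 5)
  ref["g02", ] <- 2 * ref["g01", ]   # PCC^n = +1
  set.seed(6)
  extra <- setNames(rnorm(4, 10), rownames(ref))
  st <- ssn_edge_statistics(ref, extra,
                            data.frame(a = c("g01", "g03"),
                                       b = c("g02", "g04")))
  expect_equal(nrow(st), 1)
  expect_equal(st$gene_i, "g03")
  expect_equal(attr(st, "n_degenerate"), 1)
  expect_equal(attr(st, "degenerate_pairs")$gene_i, "g01")
})

test_that("dPCC and Z agree with recomputing both correlations from
           scratch on the stacked matrix", {
  ref <- make_ref(25, 20, seed = 7)
  set.seed(8)
  extra <- setNames(rnorm(25, 10), rownames(ref))
  pairs <- t(combn(rownames(ref), 2))
  st <- ssn_edge_statistics(ref, extra, pairs)
  n <- ncol(ref)
  for (r in sample(nrow(st), 40)) {
    gi <- st$gene_i[r]; gj <- st$gene_j[r]
    r_ref <- cor(ref[gi, ], ref[gj, ])
    r_new <- cor(c(ref[gi, ], extra[gi]), c(ref[gj, ], extra[gj]))
    d <- r_new - r_ref
    z <- d / ((1 - r_ref^2) / (n - 1))
    expect_equal(st$delta_pcc[r], d, tolerance = 1e-10)
    expect_equal(st$z[r], z, tolerance = 1e-10)
    expect_equal(st$p_value[r], 2 * pnorm(-abs(z)), tolerance = 1e-10)
  }
  expect_true(all(abs(st$delta_pcc) <= 2))
  expect_error(ssn_edge_statistics(ref[, 1:2], extra, pairs), "insufficient")
})

test_that("paired edge weight reproduces exact log2 identities and is
           symmetric under swapping the two perturbations", {
  expect_equal(edge_weight_paired(0.4, 0.1), 2.0)
  expect_equal(edge_weight_paired(0.3, 0.3), 0.0)
  expect_equal(edge_weight_paired(0.1, 0.4), 2.0)
  set.seed(9)
  a <- runif(50, -1, 1); b <- runif(50, -1, 1)
  expect_equal(edge_weight_paired(a, b), edge_weight_paired(b, a))
  w0 <- edge_weight_paired(0, 0.25, clamp_eps = 1e-6)
  expect_true(is.finite(w0) && w0 >= 0)
  expect_equal(w0, abs(log2(1e-6 / 0.25)))
})

test_that("network retention is the per-edge significance-flip (XOR) rule
           and edges stay inside the interactome", {
  co <- small_cohort(seed = 4)
  pv <- patient_vectors(co, "P02")
  net <- build_personalized_network(co$ref_expr, pv$tumor, pv$normal,
                                    co$interactome)
  # per-edge oracle: score both states independently and apply XOR
  st_t <- ssn_edge_statistics(co$ref_expr, pv$tumor, co$interactome[, 1:2])
  st_n <- ssn_edge_statistics(co$ref_expr, pv$normal, co$interactome[, 1:2])
  kt <- paste(st_t$gene_i, st_t$gene_j)
  kn <- paste(st_n$gene_i, st_n$gene_j)
  common <- intersect(kt, kn)
  flip <- xor(st_t$p_value[match(common, kt)] < 0.05,
              st_n$p_value[match(common, kn)] < 0.05)
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b), common[flip])
  expect_true(nrow(net$edges) > 0)
  for (e in seq_len(nrow(net$edges)))
    expect_true(xor(net$edges$p_tumor[e] < 0.05, net$edges$p_normal[e] < 0.05))
  ia_key <- paste(co$interactome$gene_a, co$interactome$gene_b)
  expect_true(all(paste(net$edges$gene_a, net$edges$gene_b) %in% ia_key))
})

test_that("weight modes behave as declared: unit weights, confidence
           scores, reproducible random weights, tumor-only selection", {
  co <- small_cohort(seed = 5)
  pv <- patient_vectors(co, "P01")
  args <- list(co$ref_expr, pv$tumor, pv$normal, co$interactome)
  same <- do.call(build_personalized_network, c(args, weight_mode = "same"))
  expect_true(all(same$edges$weight == 1))

  orig <- do.call(build_personalized_network,
                  c(args, weight_mode = "original_network_score"))
  ia_key <- paste(co$interactome$gene_a, co$interactome$gene_b)
  expect_equal(orig$edges$weight,
               co$interactome$score[match(paste(orig$edges$gene_a,
                                                orig$edges$gene_b), ia_key)])

  r1 <- do.call(build_personalized_network,
                c(args, weight_mode = "random", rng_seed = 42))
  r2 <- do.call(build_personalized_network,
                c(args, weight_mode = "random", rng_seed = 42))
  expect_identical(r1$edges$weight, r2$edges$weight)
  expect_true(all(r1$edges$weight >= 0 & r1$edges$weight <= 1))
  expect_identical(r1$edges$gene_a, same$edges$gene_a)  # same edge set

  to <- do.call(build_personalized_network,
                c(args, weight_mode = "tumor_only",
                  exclude_ref_sample = "P01"))
  expect_true(all(to$edges$p_tumor < 0.05))
  expect_equal(to$edges$weight, abs(to$edges$delta_tumor))
})

test_that("the negative reference-correlation filter drops edges below the
           threshold before the flip test", {
  co <- small_cohort(seed = 6)
  pv <- patient_vectors(co, "P03")
  plain <- build_personalized_network(co$ref_expr, pv$tumor, pv$normal,
                                      co$interactome)
  filt <- build_personalized_network(co$ref_expr, pv$tumor, pv$normal,
                                     co$interactome, neg_pcc_filter = -0.4)
  expect_true(nrow(filt$edges) <= nrow(plain$edges))
  st_t <- ssn_edge_statistics(co$ref_expr, pv$tumor, filt$edges[, 1:2])
  expect_true(all(st_t$pcc_ref >= -0.4))
})

test_that("robustness is a proportion in [0, 1], 0 on an empty network,
           and increases with the reference fraction", {
  co <- small_cohort(seed = 7)
  pv <- patient_vectors(co, "P01")
  # empty network: interactome restricted to genes absent from any edges
  tiny <- interactome(data.frame(a = "g_nope1", b = "g_nope2", s = 0.9))
  expect_equal(suppressWarnings(
    edge_robustness(co$ref_expr, pv$tumor, pv$normal, tiny, fraction = 0.5,
                    n_reps = 5)), 0)
  lo <- hi <- numeric(3)
  for (s in 1:3) {
    lo[s] <- edge_robustness(co$ref_expr, pv$tumor, pv$normal, co$interactome,
                             fraction = 0.3, n_reps = 40, rng_seed = s)
    hi[s] <- edge_robustness(co$ref_expr, pv$tumor, pv$normal, co$interactome,
                             fraction = 0.9, n_reps = 40, rng_seed = s)
  }
  expect_true(all(c(lo, hi) >= 0 & c(lo, hi) <= 1))
  expect_gte(mean(hi), mean(lo))
  expect_error(edge_robustness(co$ref_expr, pv$tumor, pv$normal,
                               co$interactome, fraction = 0.05),
               "insufficient")
})
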