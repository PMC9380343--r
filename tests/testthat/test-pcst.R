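# Prize/cost graph construction, rooted PCST solving, influence scores.

test_that("the worked example has the six known subtree objectives and an
           optimum of 3.3 at nodes {a, b, c}", {
  g <- example_prize_graph()
  # independent enumeration of every connected root-containing subset
  subsets <- list("a", c("a", "b"), c("a", "c"), c("a", "c", "d"),
                  c("a", "b", "c"), c("a", "b", "c", "d"))
  cost <- c("a|b" = 0.3, "a|c" = 0.2, "c|d" = 0.3)
  tree_cost <- function(s) {
    keys <- c(if (all(c("a", "b") %in% s)) "a|b",
              if (all(c("a", "c") %in% s)) "a|c",
              if (all(c("c", "d") %in% s)) "c|d")
    sum(cost[keys])
  }
  objs <- vapply(subsets, function(s) sum(g$prizes[s]) - tree_cost(s),
                 numeric(1))
  expect_equal(objs, c(0.7, 1.9, 2.1, 1.8, 3.3, 3.0), tolerance = 1e-12)
  sol <- solve_pcst(g)
  expect_true(sol$feasible)
  expect_equal(sol$objective, 3.3, tolerance = 1e-12)
  expect_setequal(sol$nodes, c("a", "b", "c"))
  expect_equal(sol$objective, max(objs), tolerance = 1e-12)
})

test_that("degenerate roots are handled: a lone prized root is its own
           tree, an isolated unprized root is infeasible and scores 0", {
  lone <- prize_graph(data.frame(gene_a = character(), gene_b = character(),
                                 cost = numeric()),
                      c(r = 2), root = "r")
  sol <- solve_pcst(lone)
  expect_true(sol$feasible)
  expect_equal(sol$objective, 2)

  iso <- prize_graph(data.frame(gene_a = "x", gene_b = "y", cost = 0.1),
                     c(x = 1), root = "r", nodes = c("r", "x", "y"))
  sol2 <- solve_pcst(iso)
  expect_false(sol2$feasible)
  expect_equal(influence_score(sol2, iso), 0)
  expect_error(solve_pcst(prize_graph(data.frame(gene_a = "a", gene_b = "b",
                                                 cost = -1),
                                      c(a = 1), root = "a")),
               "non-negative")
})

test_that("exact solver and heuristic both reach the brute-force optimum
           on 100 random graphs of up to 12 nodes", {
  agree_exact <- agree_heur <- 0
  for (i in 1:100) {
    n <- 5 + (i %% 8)   # 5..12 nodes
    g <- make_random_prize_graph(n, seed = 1000 + i)
    truth <- oracle_pcst(g)
    se <- solve_pcst(g, method = "exact")
    sh <- solve_pcst(g, method = "heuristic")
    agree_exact <- agree_exact + (abs(se$objective - truth) < 1e-9)
    agree_heur <- agree_heur + (abs(sh$objective - truth) < 1e-9)
  }
  expect_equal(agree_exact, 100)
  expect_equal(agree_heur, 100)
})

test_that("solutions are trees containing the root with objective at least
           the root prize", {
  for (i in 1:20) {
    g <- make_random_prize_graph(10, seed = 2000 + i)
    sol <- solve_pcst(g)
    expect_true(sol$feasible)
    expect_true(g$root %in% sol$nodes)
    expect_gte(sol$objective, unname(g$prizes[g$root]) - 1e-12)
    ne <- if (is.null(sol$edges)) 0 else nrow(sol$edges)
    expect_equal(ne, length(sol$nodes) - 1)
    if (ne > 0) {
      tg <- igraph::graph_from_data_frame(sol$edges, directed = FALSE)
      expect_true(igraph::is_connected(tg))
      expect_equal(igraph::vcount(tg), length(sol$nodes))
    }
  }
})

test_that("a zero-cost edge to an unreached prized node strictly improves
           the achievable objective", {
  g <- prize_graph(data.frame(gene_a = "r", gene_b = "a", cost = 0.4),
                   c(a = 0.2, far = 1), root = "r",
                   nodes = c("r", "a", "far"))
  base <- solve_pcst(g)$objective
  g2 <- prize_graph(rbind(g$edges[, c("gene_a", "gene_b", "cost")],
                          data.frame(gene_a = "a", gene_b = "far", cost = 0)),
                    c(a = 0.2, far = 1), root = "r")
  expect_gt(solve_pcst(g2)$objective, base)
})

test_that("the mutation-dysregulation graph matches a brute-force
           set-algebra oracle and implements the prize/cost rules", {
  co <- small_cohort(seed = 12)
  pv <- patient_vectors(co, "P01")
  net <- build_personalized_network(co$ref_expr, pv$tumor, pv$normal,
                                    co$interactome)
  degs <- identify_degs(pv$tumor, pv$normal)
  pw <- co$pathways[[1]]
  root <- co$truth$drivers[["P01"]][1]
  g <- build_mutation_dysregulation_network(net, pw, root, degs)

  # node oracle: V_p + root + first-order neighbors of both in the network
  core <- intersect(c(pw$genes, root), net$nodes)
  nbrs <- unique(unlist(lapply(core, function(v)
    c(net$edges$gene_b[net$edges$gene_a == v],
      net$edges$gene_a[net$edges$gene_b == v]))))
  expect_setequal(g$nodes, unique(c(pw$genes, root, nbrs)))
  expect_true(root %in% g$nodes)

  # edge oracle: network edges inside the node set, plus pathway topology
  in_net <- net$edges$gene_a %in% g$nodes & net$edges$gene_b %in% g$nodes
  net_keys <- paste(net$edges$gene_a[in_net], net$edges$gene_b[in_net])
  got_net <- paste(g$edges$gene_a[g$edges$in_network],
                   g$edges$gene_b[g$edges$in_network])
  expect_setequal(got_net, net_keys)
  pw_keys <- paste(pw$edges$gene_a, pw$edges$gene_b)
  all_keys <- paste(g$edges$gene_a, g$edges$gene_b)
  expect_true(all(pw_keys %in% all_keys))

  # prizes: |lfc| on DEG n V_p, zero elsewhere; pathway-only edges cost 0
  deg_pw <- intersect(names(degs), pw$genes)
  expect_equal(unname(g$prizes[deg_pw]),
               unname(abs(unclass(degs)[deg_pw])))
  expect_true(all(g$prizes[setdiff(g$nodes, deg_pw)] == 0))
  expect_true(all(g$edges$cost[!g$edges$in_network] == 0))
  expect_true(all(g$edges$cost >= 0 & g$edges$cost <= 1))

  # min-max normalization: the heaviest network edge has cost 0
  wmax <- which.max(net$edges$weight)
  if (in_net[wmax]) {
    key <- paste(net$edges$gene_a[wmax], net$edges$gene_b[wmax])
    expect_equal(g$edges$cost[match(key, all_keys)], 0)
  }
})

test_that("influence scores stay inside [0, 1] across a synthetic grid and
           hit the closed-form cases", {
  # direct arithmetic: f = 2.5 against prizes {2, 3}
  g <- prize_graph(data.frame(gene_a = "r", gene_b = "a", cost = 0.5),
                   c(a = 3, r = 0), root = "r")
  sol <- solve_pcst(g)
  expect_equal(influence_score(sol, g), sol$objective / 3)

  # full prize collection through zero-cost edges scores exactly 1
  g1 <- prize_graph(data.frame(gene_a = c("r", "a"), gene_b = c("a", "b"),
                               cost = c(0, 0)),
                    c(a = 1, b = 2), root = "r")
  expect_equal(influence_score(solve_pcst(g1), g1), 1)

  co <- small_cohort(seed = 13)
  pv <- patient_vectors(co, "P02")
  net <- build_personalized_network(co$ref_expr, pv$tumor, pv$normal,
                                    co$interactome)
  degs <- identify_degs(pv$tumor, pv$normal)
  prof <- mutation_profile(co$snv[, "P02"], co$cnv[, "P02"], "P02")
  for (pw in co$pathways) {
    for (root in head(prof$mutated, 3)) {
      pg <- build_mutation_dysregulation_network(net, pw, root, degs)
      s <- influence_score(solve_pcst(pg), pg)
      expect_true(s >= 0 && s <= 1)
    }
  }
})

test_that("patient rankings are descending row sums with lexicographic
           tie-breaks", {
  co <- small_cohort(seed = 14)
  pv <- patient_vectors(co, "P01")
  net <- build_personalized_network(co$ref_expr, pv$tumor, pv$normal,
                                    co$interactome)
  degs <- identify_degs(pv$tumor, pv$normal)
  background <- intersect(rownames(co$ref_expr),
                          unique(c(co$interactome$gene_a,
                                   co$interactome$gene_b)))
  dp <- dysregulated_pathways(degs, co$pathways, background)
  M <- head(sort(mutation_profile(co$snv[, "P01"], co$cnv[, "P01"])$mutated),
            3)
  r <- rank_patient_drivers(net, degs, dp, M, co$pathways)
  expect_equal(unname(r$totals), unname(colSums(r$influence)))
  expect_equal(r$ranking$gene, names(sort(-r$totals)))
  expect_true(all(diff(r$ranking$infl_total) <= 1e-12))

  # forced tie: two roots absent from everything -> both 0, lexicographic
  r0 <- rank_patient_drivers(net, degs, dp, c("zzz", "aaa"), co$pathways)
  expect_equal(r0$ranking$gene, c("aaa", "zzz"))
})
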