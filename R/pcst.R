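# Rooted prize-collecting Steiner tree (PCST) scoring of key mutant genes.
#
# For a key mutant gene g and a dysregulated pathway p, a
# mutation-dysregulation graph is assembled from the pathway, the root and
# their first-order network neighborhood. Node prizes are the |log2 fold
# changes| of DEGs inside the pathway; edge costs are 1 minus the min-max
# normalized personalized edge weight (pathway-only edges get the minimal
# cost). The rooted PCST maximizes collected prize minus paid cost; its
# objective, normalized by the total available prize, is the influence
# score infl(p, g) in [0, 1].

#' Build the prize/cost graph for one (root gene, pathway) pair
#'
#' Nodes are the pathway members, the root and the first-order neighbors
#' (in the personalized network) of all of them. Edges are the pathway
#' topology plus every personalized-network edge with both endpoints
#' inside the node set. Prizes are |log2 fold change| on DEGs that are
#' pathway members, 0 elsewhere. Costs are `1 - norm(w)` for network edges
#' and `1 - max(norm(W))` (= 0) for pathway-only edges, `norm` being the
#' min-max normalization over all personalized-network weights `W`; if all
#' weights are equal, `norm` is taken as 1 and every cost is 0.
#'
#' @param net A `personalized_network`.
#' @param pathway One element of a [pathway_collection()] (list with
#'   `genes` and optional `edges`).
#' @param root The key mutant gene used as the tree root.
#' @param degs A [identify_degs()] result.
#' @return Object of class `prize_graph`: list with `nodes`, `edges`
#'   (`gene_a`, `gene_b`, `cost`, `in_network`), `prizes` (named, >= 0)
#'   and `root`. The root is always a node, possibly isolated.
#' @export
build_mutation_dysregulation_network <- function(net, pathway, root, degs) {
  v_p <- pathway$genes
  g_net <- pgin_igraph(net, weighted = FALSE)
  core <- intersect(union(v_p, root), net$nodes)
  nh <- if (length(core)) {
    idx <- unique(unlist(igraph::adjacent_vertices(g_net, core),
                         use.names = FALSE))
    igraph::V(g_net)$name[idx]
  } else character()
  nodes <- sort(unique(c(v_p, root, nh)))

  W <- net$edges$weight
  if (length(W) && max(W) > min(W)) {
    norm_w <- (W - min(W)) / (max(W) - min(W))
  } else {
    norm_w <- rep(1, length(W))   # single-valued weights carry no signal
  }
  net_key <- paste(net$edges$gene_a, net$edges$gene_b, sep = "|")

  in_nodes <- net$edges$gene_a %in% nodes & net$edges$gene_b %in% nodes
  e_net <- data.frame(gene_a = net$edges$gene_a[in_nodes],
                      gene_b = net$edges$gene_b[in_nodes],
                      cost = 1 - norm_w[in_nodes],
                      in_network = rep(TRUE, sum(in_nodes)),
                      stringsAsFactors = FALSE)

  e_pw <- pathway$edges
  if (!is.null(e_pw) && nrow(e_pw)) {
    pw_key <- paste(e_pw$gene_a, e_pw$gene_b, sep = "|")
    extra <- !(pw_key %in% net_key)
    e_pw <- data.frame(gene_a = e_pw$gene_a[extra], gene_b = e_pw$gene_b[extra],
                       cost = rep(1 - max(c(norm_w, 1)), sum(extra)),
                       in_network = rep(FALSE, sum(extra)),
                       stringsAsFactors = FALSE)
  } else {
    e_pw <- e_net[0, , drop = FALSE]
  }
  edges <- rbind(e_net, e_pw)
  rownames(edges) <- NULL

  prizes <- stats::setNames(numeric(length(nodes)), nodes)
  deg_in_pw <- intersect(names(degs), v_p)
  prizes[intersect(deg_in_pw, nodes)] <-
    abs(unclass(degs)[intersect(deg_in_pw, nodes)])

  structure(list(nodes = nodes, edges = edges, prizes = prizes, root = root),
            class = "prize_graph")
}

#' Construct a prize/cost graph directly
#'
#' Low-level constructor used for worked examples and tests.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `cost`.
#' @param prizes Named non-negative numeric vector (nodes without an entry
#'   get prize 0).
#' @param root Root node.
#' @param nodes Optional full node set (defaults to everything mentioned).
#' @return A `prize_graph`.
#' @export
prize_graph <- function(edges, prizes, root, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  nodes <- sort(unique(c(nodes, root, edges$gene_a, edges$gene_b,
                         names(prizes))))
  pz <- stats::setNames(numeric(length(nodes)), nodes)
  pz[names(prizes)] <- prizes
  if (!"in_network" %in% names(edges))
    edges$in_network <- rep(TRUE, nrow(edges))
  structure(list(nodes = nodes, edges = edges, prizes = pz, root = root),
            class = "prize_graph")
}

# Minimum-spanning-tree cost of the induced subgraph on `idx` (indices into
# a dense symmetric cost matrix with Inf for non-edges). Returns Inf if the
# subset is not connected. Plain Prim's algorithm; subsets are small.
prim_mst <- function(costmat, idx, return_edges = FALSE) {
  k <- length(idx)
  if (k == 1) {
    if (return_edges) return(list(cost = 0, edges = NULL))
    return(0)
  }
  sub <- costmat[idx, idx, drop = FALSE]
  in_tree <- logical(k)
  in_tree[1] <- TRUE
  best <- sub[, 1]
  parent <- rep(1L, k)
  total <- 0
  edges <- if (return_edges) matrix(0L, nrow = k - 1, ncol = 2) else NULL
  for (step in seq_len(k - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    if (!is.finite(best[j])) {
      if (return_edges) return(list(cost = Inf, edges = NULL))
      return(Inf)
    }
    total <- total + best[j]
    in_tree[j] <- TRUE
    if (return_edges) edges[step, ] <- c(idx[parent[j]], idx[j])
    upd <- !in_tree & sub[, j] < best
    parent[upd] <- j
    best[upd] <- sub[upd, j]
  }
  if (return_edges) list(cost = total, edges = edges) else total
}

# Dense cost matrix over `nodes`; parallel edges collapse to the cheaper.
pcst_cost_matrix <- function(graph) {
  n <- length(graph$nodes)
  cm <- matrix(Inf, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$gene_a, graph$nodes)
    j <- match(graph$edges$gene_b, graph$nodes)
    for (e in seq_along(i)) {
      c_e <- graph$edges$cost[e]
      if (c_e < cm[i[e], j[e]]) {
        cm[i[e], j[e]] <- c_e
        cm[j[e], i[e]] <- c_e
      }
    }
  }
  diag(cm) <- Inf
  cm
}

# Exhaustively enumerate connected node subsets containing `root_i` and
# return the best subset under f(S) = sum(prize[S]) - MST(S). Standard
# connected-subgraph enumeration: children extend via an "extension" list,
# and each vertex popped from the list is forbidden for later branches.
pcst_exact <- function(costmat, prize, root_i) {
  n <- nrow(costmat)
  adj <- lapply(seq_len(n), function(i) which(is.finite(costmat[i, ])))
  best <- list(f = prize[root_i], set = root_i)
  recurse <- function(set, ext, forbidden) {
    f <- sum(prize[set]) - prim_mst(costmat, set)
    if (f > best$f + 1e-12) best <<- list(f = f, set = set)
    while (length(ext)) {
      v <- ext[1]
      ext <- ext[-1]
      new_forbidden <- c(forbidden, v)
      grow <- setdiff(adj[[v]], c(set, ext, new_forbidden))
      recurse(c(set, v), c(ext, grow), new_forbidden)
      forbidden <- new_forbidden
    }
  }
  recurse(root_i, setdiff(adj[[root_i]], root_i), integer())
  best
}

# Objective of a connected subset (used by the heuristic).
pcst_eval <- function(costmat, prize, set) sum(prize[set]) - prim_mst(costmat, set)

# Heuristic solver. Small components get a beam search over connected
# root-containing node subsets (beam ranked by f(S) = prizes - MST cost);
# larger components get greedy growth plus hill climbing with add-one,
# add-two (a connector plus its neighbor) and remove-one moves,
# multi-started from the root alone, the greedy solution and the full
# component. Neither route guarantees optimality.
pcst_heuristic <- function(costmat, prize, root_i, comp, beam_limit = 20,
                           beam_width = 1024) {
  adj <- lapply(seq_len(nrow(costmat)),
                function(i) intersect(which(is.finite(costmat[i, ])), comp))

  climb <- function(set) {
    f <- pcst_eval(costmat, prize, set)
    repeat {
      improved <- FALSE
      frontier <- setdiff(unique(unlist(adj[set])), set)
      for (v in frontier) {
        f2 <- pcst_eval(costmat, prize, c(set, v))
        if (f2 > f + 1e-12) { set <- c(set, v); f <- f2; improved <- TRUE }
      }
      if (!improved && length(comp) <= 80) {
        frontier <- setdiff(unique(unlist(adj[set])), set)
        for (w in frontier) {
          for (v in setdiff(adj[[w]], c(set, w))) {
            f2 <- pcst_eval(costmat, prize, c(set, w, v))
            if (f2 > f + 1e-12) {
              set <- c(set, w, v); f <- f2; improved <- TRUE
              break
            }
          }
          if (improved) break
        }
      }
      if (!improved) {
        for (v in setdiff(set, root_i)) {
          s2 <- setdiff(set, v)
          f2 <- pcst_eval(costmat, prize, s2)
          if (is.finite(f2) && f2 > f + 1e-12) {
            set <- s2; f <- f2; improved <- TRUE
            break
          }
        }
      }
      if (!improved) return(list(f = f, set = set))
    }
  }

  beam_search <- function() {
    best <- list(f = pcst_eval(costmat, prize, root_i), set = root_i)
    beam <- list(root_i)
    seen <- new.env(hash = TRUE)
    assign(paste(root_i), TRUE, envir = seen)
    repeat {
      nxt <- list()
      fs <- numeric()
      for (set in beam) {
        for (v in setdiff(unique(unlist(adj[set])), set)) {
          s2 <- sort(c(set, v))
          key <- paste(s2, collapse = ",")
          if (!is.null(seen[[key]])) next
          assign(key, TRUE, envir = seen)
          f2 <- pcst_eval(costmat, prize, s2)
          nxt[[length(nxt) + 1L]] <- s2
          fs <- c(fs, f2)
          if (f2 > best$f + 1e-12) best <- list(f = f2, set = s2)
        }
      }
      if (length(nxt) == 0) break
      keep <- order(-fs)[seq_len(min(beam_width, length(nxt)))]
      beam <- nxt[keep]
    }
    best
  }

  best <- NULL
  if (length(comp) <= beam_limit) best <- beam_search()
  starts <- list(root_i)
  greedy <- climb(root_i)
  starts <- c(starts, list(greedy$set))
  if (length(comp) <= 200) starts <- c(starts, list(comp))
  if (!is.null(best)) starts <- c(starts, list(best$set))
  for (s in starts) {
    res <- climb(s)
    if (is.null(best) || res$f > best$f) best <- res
  }
  best
}

#' Solve the rooted prize-collecting Steiner tree
#'
#' Maximizes `f(T) = sum of prizes in T - sum of edge costs in T` over
#' trees `T` containing the root. The search is restricted to the root's
#' connected component. Components with at most `exact_limit` nodes are
#' solved exactly by enumerating connected root-containing node subsets
#' (the cheapest tree on a node set is its minimum spanning tree); larger
#' components use a greedy/local-search heuristic whose objective is never
#' below the root-only tree.
#'
#' An isolated root with zero prize admits no informative subnetwork: the
#' solution is flagged infeasible and downstream influence is 0.
#'
#' @param graph A `prize_graph`.
#' @param exact_limit Component size up to which the solver is exact
#'   (default 15).
#' @param method `"auto"` (size-based), `"exact"` or `"heuristic"`.
#' @return Object of class `pcst_solution`: list with `nodes`, `edges`
#'   (tree edges), `objective`, `feasible` and `method`.
#' @export
solve_pcst <- function(graph, exact_limit = 15,
                       method = c("auto", "exact", "heuristic")) {
  method <- match.arg(method)
  if (any(graph$prizes < 0)) stop("prizes must be non-negative")
  if (nrow(graph$edges) && any(graph$edges$cost < 0))
    stop("edge costs must be non-negative")
  if (!graph$root %in% graph$nodes) stop("root is not a node of the graph")

  cm <- pcst_cost_matrix(graph)
  root_i <- match(graph$root, graph$nodes)
  g <- igraph::graph_from_adjacency_matrix(is.finite(cm), mode = "undirected",
                                           diag = FALSE)
  comp <- which(igraph::components(g)$membership ==
                  igraph::components(g)$membership[root_i])

  if (length(comp) == 1) {
    if (graph$prizes[root_i] > 0) {
      return(structure(list(nodes = graph$root, edges = NULL,
                            objective = unname(graph$prizes[root_i]),
                            feasible = TRUE, method = "trivial"),
                       class = "pcst_solution"))
    }
    return(structure(list(nodes = character(), edges = NULL,
                          objective = NA_real_, feasible = FALSE,
                          method = "trivial"),
                     class = "pcst_solution"))
  }

  use_exact <- method == "exact" ||
    (method == "auto" && length(comp) <= exact_limit)
  best <- if (use_exact) {
    pcst_exact(cm[comp, comp, drop = FALSE], graph$prizes[comp],
               match(root_i, comp))
  } else {
    pcst_heuristic(cm, graph$prizes, root_i, comp) |>
      (\(b) list(f = b$f, set = match(b$set, comp)))()
  }

  set_global <- comp[best$set]
  mst <- prim_mst(cm, set_global, return_edges = TRUE)
  tree_edges <- if (is.null(mst$edges)) NULL else
    data.frame(gene_a = graph$nodes[mst$edges[, 1]],
               gene_b = graph$nodes[mst$edges[, 2]],
               stringsAsFactors = FALSE)
  structure(list(nodes = graph$nodes[set_global], edges = tree_edges,
                 objective = unname(best$f), feasible = TRUE,
                 method = if (use_exact) "exact" else "heuristic"),
            class = "pcst_solution")
}

#' @export
print.pcst_solution <- function(x, ...) {
  if (x$feasible)
    cat("PCST solution (", x$method, "): ", length(x$nodes), " nodes, f(T) = ",
        format(x$objective), "\n", sep = "")
  else cat("PCST solution: infeasible (isolated unprized root)\n")
  invisible(x)
}

#' Influence score of a mutant gene on one dysregulated pathway
#'
#' The PCST objective normalized by the total prize available on the
#' pathway's DEGs: `infl(p, g) = f(T) / sum of prizes over DEG members`.
#' Infeasible solutions and pathways without any DEG prize score 0; the
#' ratio is clipped to \[0, 1\] against floating-point overshoot.
#'
#' @param solution A [solve_pcst()] result.
#' @param graph The `prize_graph` it was solved on.
#' @return Influence score in \[0, 1\].
#' @export
influence_score <- function(solution, graph) {
  denom <- sum(graph$prizes)
  if (!solution$feasible || denom <= 0) return(0)
  min(1, max(0, solution$objective / denom))
}

#' Rank a patient's key mutant genes by total influence
#'
#' For every (dysregulated pathway, key mutant gene) pair, builds the
#' prize/cost graph, solves the rooted PCST and records the influence
#' score. Total influence per gene is the sum over pathways; genes are
#' ranked by total influence, descending, with lexicographic tie-breaks.
#'
#' @param net A `personalized_network`.
#' @param degs A [identify_degs()] result.
#' @param dp A [dysregulated_pathways()] result (or character vector of
#'   pathway ids).
#' @param M Key mutant gene set.
#' @param pathways The full [pathway_collection()].
#' @param exact_limit Passed to [solve_pcst()].
#' @return Object of class `influence_ranking`: list with `influence`
#'   (pathways x genes matrix), `totals` (named vector) and `ranking`
#'   (data frame rank / gene / infl_total).
#' @export
rank_patient_drivers <- function(net, degs, dp, M, pathways,
                                 exact_limit = 15) {
  dp_ids <- if (is.data.frame(dp)) dp$pathway else as.character(dp)
  M <- sort(unique(M))
  infl <- matrix(0, nrow = length(dp_ids), ncol = length(M),
                 dimnames = list(dp_ids, M))
  for (pid in dp_ids) {
    for (g in M) {
      pg <- build_mutation_dysregulation_network(net, pathways[[pid]], g, degs)
      sol <- solve_pcst(pg, exact_limit = exact_limit)
      infl[pid, g] <- influence_score(sol, pg)
    }
  }
  totals <- if (length(M)) colSums(infl) else stats::setNames(numeric(0),
                                                              character(0))
  ord <- order(-totals, names(totals))
  ranking <- data.frame(rank = seq_along(ord),
                        gene = names(totals)[ord],
                        infl_total = unname(totals[ord]),
                        stringsAsFactors = FALSE)
  structure(list(influence = infl, totals = totals, ranking = ranking),
            class = "influence_ranking")
}

#' @export
print.influence_ranking <- function(x, ...) {
  cat("Influence ranking over", nrow(x$influence), "dysregulated pathways and",
      ncol(x$influence), "key mutant genes\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' A small worked prize-collecting Steiner tree instance
#'
#' Four genes: root `a` (prize 0.7), prized neighbors `b` (1.5, edge cost
#' 0.3) and `c` (1.6, edge cost 0.2), and a Steiner node `d` (prize 0)
#' hanging off `c` at cost 0.3. The six root-containing subtrees have
#' objectives 0.7, 1.9, 2.1, 1.8, 3.3 and 3.0; the optimum collects `a`,
#' `b` and `c` for f(T) = 3.3.
#'
#' @return A `prize_graph` with root `"a"`.
#' @export
example_prize_graph <- function() {
  prize_graph(edges = data.frame(gene_a = c("a", "a", "c"),
                                 gene_b = c("b", "c", "d"),
                                 cost = c(0.3, 0.2, 0.3),
                                 stringsAsFactors = FALSE),
              prizes = c(a = 0.7, b = 1.5, c = 1.6),
              root = "a")
}
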