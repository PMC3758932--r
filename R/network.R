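# Directed weighted symptom networks: group mean-PCR network construction,
# weighted degree and betweenness centrality, permutation nulls, layout and
# export. A symptom_network is a light container: a node table (id, mean
# frequency) and an edge table (from, to, weight in [0,10], n contributing
# participants).

#' Construct a symptom network
#'
#' @param nodes Data frame with columns `id` and optionally `frequency`
#'   (node attribute: mean symptom frequency) and `label`.
#' @param edges Data frame with columns `from`, `to`, `weight` and
#'   optionally `n`.
#' @return An object of class `symptom_network`.
#' @export
symptom_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"id" %in% names(nodes)) stop("nodes need an 'id' column")
  if (!all(c("from", "to", "weight") %in% names(edges))) {
    stop("edges need columns from, to, weight")
  }
  if (!"frequency" %in% names(nodes)) nodes$frequency <- NA_real_
  if (!"n" %in% names(edges)) edges$n <- NA_integer_
  nodes$id <- as.integer(nodes$id)
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  if (any(!edges$from %in% nodes$id) || any(!edges$to %in% nodes$id)) {
    stop("edge endpoints must be catalog node ids")
  }
  if (any(edges$weight < 0 | edges$weight > 10)) {
    stop("edge weights must lie in [0, 10]")
  }
  if (anyDuplicated(paste(edges$from, edges$to))) stop("duplicate edges")
  edges <- edges[order(edges$from, edges$to), ]
  structure(list(nodes = nodes, edges = edges), class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  cat("<symptom_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Group-level mean-PCR network
#'
#' Edge (i, j) is present iff at least `min_n` participants have a present
#' PCR(i, j) rating; its weight is the mean of those ratings (averaged over
#' the participants who endorsed both symptoms and answered). Node attribute
#' `frequency` is the mean frequency rating across all participants
#' (available-case).
#'
#' @param records Named list of `participant_record`.
#' @param min_n Minimum number of contributing participants per edge.
#' @param catalog A `symptom_catalog`.
#' @return A `symptom_network` over all 40 items.
#' @export
build_mean_network <- function(records, min_n = 1L,
                               catalog = default_catalog()) {
  if (length(records) < 1L) stop("need at least one record")
  S <- matrix(0, 40L, 40L)
  N <- matrix(0L, 40L, 40L)
  Fs <- matrix(0, 40L, 1L); Fn <- matrix(0L, 40L, 1L)
  for (rec in records) {
    pres <- !is.na(rec$pcr_status) & rec$pcr_status == STATUS_PRESENT
    S[pres] <- S[pres] + rec$pcr[pres]
    N[pres] <- N[pres] + 1L
    fobs <- !is.na(rec$frequencies)
    Fs[fobs] <- Fs[fobs] + rec$frequencies[fobs]
    Fn[fobs] <- Fn[fobs] + 1L
  }
  keep <- which(N >= min_n & N > 0L, arr.ind = TRUE)
  edges <- tibble(
    from = keep[, 1], to = keep[, 2],
    weight = S[keep] / N[keep], n = N[keep]
  )
  nodes <- tibble(
    id = catalog$items$id,
    frequency = ifelse(Fn[, 1] > 0, Fs[, 1] / Fn[, 1], NA_real_),
    label = catalog$items$abbreviation
  )
  symptom_network(nodes, edges)
}

#' Threshold a network's edges by weight
#'
#' @param net A `symptom_network`.
#' @param cutoff Weight cutoff in `[0, 10]`.
#' @param strict Keep edges with weight `> cutoff` (default) or `>= cutoff`.
#' @return The thresholded `symptom_network`.
#' @export
threshold_network <- function(net, cutoff, strict = TRUE) {
  stopifnot(inherits(net, "symptom_network"))
  if (cutoff < 0 || cutoff > 10) stop("cutoff must lie in [0, 10]")
  keep <- if (strict) net$edges$weight > cutoff else net$edges$weight >= cutoff
  symptom_network(net$nodes, net$edges[keep, ])
}

#' Weighted out- and indegree
#'
#' Outdegree is the sum of the weights of a node's outgoing edges; indegree
#' the sum over incoming edges. Isolated nodes score 0.
#'
#' @param net A `symptom_network`.
#' @return Tibble with columns `id`, `outdegree`, `indegree`.
#' @export
weighted_degrees <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  ids <- net$nodes$id
  out <- tapply(net$edges$weight, factor(net$edges$from, levels = ids), sum)
  inn <- tapply(net$edges$weight, factor(net$edges$to, levels = ids), sum)
  tibble(id = ids,
         outdegree = as.numeric(ifelse(is.na(out), 0, out)),
         indegree = as.numeric(ifelse(is.na(inn), 0, inn)))
}

# Brandes betweenness with Dijkstra over edge costs weight^(-alpha).
# adj: list per node of (neighbour index, cost) matrices. Fractional credit
# across co-minimal paths; relative tolerance for cost ties.
brandes_betweenness <- function(n, edges_idx, costs) {
  bc <- numeric(n)
  adj_to <- split(seq_along(costs), edges_idx[, 1])
  eps <- 1e-10
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    done <- rep(FALSE, n)
    order_popped <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0L) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      order_popped <- c(order_popped, u)
      out_e <- adj_to[[as.character(u)]]
      for (e in out_e) {
        v <- edges_idx[e, 2]
        nd <- dist[u] + costs[e]
        tol <- eps * max(1, abs(nd))
        if (nd < dist[v] - tol) {
          dist[v] <- nd
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (abs(nd - dist[v]) <= tol) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_popped)) {
      for (u in preds[[w]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

#' Weighted betweenness centrality over inverse-weight path costs
#'
#' For each node, the sum over ordered pairs of other nodes of the fraction
#' of minimal-cost directed paths passing through it, where an edge of
#' weight w costs `w^(-alpha)` (default alpha = 1: cost 1/weight, so
#' stronger causal links are shorter). Zero-weight edges are excluded
#' (infinite cost); unreachable pairs contribute 0; co-minimal paths share
#' credit fractionally. Raw (unnormalized) pair counts by default.
#'
#' @param net A `symptom_network`.
#' @param alpha Cost tuning exponent (> 0).
#' @param normalized Divide by `(n-1)(n-2)`.
#' @return Tibble with columns `id`, `betweenness`.
#' @export
betweenness_weighted <- function(net, alpha = 1, normalized = FALSE) {
  stopifnot(inherits(net, "symptom_network"))
  ids <- net$nodes$id
  n <- length(ids)
  e <- net$edges[net$edges$weight > 0, ]
  bc <- numeric(n)
  if (nrow(e) > 0) {
    idx <- cbind(match(e$from, ids), match(e$to, ids))
    bc <- brandes_betweenness(n, idx, e$weight^(-alpha))
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2))
  tibble(id = ids, betweenness = bc)
}

#' Permutation null distributions for the three centrality measures
#'
#' Builds `n_perm` permuted networks and recomputes outdegree, indegree and
#' betweenness in each. `shuffle_weights` (default) permutes the multiset of
#' observed edge weights over the existing edge positions (fixed topology);
#' `rewire_pairs` scatters the observed weights over all ordered node pairs
#' (absent edges count as zeros). Per node and measure the 2.5th, 50th and
#' 97.5th permutation percentiles are reported, with an extremity flag where
#' the observed value falls outside the central 95% interval.
#'
#' @param net A `symptom_network`.
#' @param n_perm Number of permuted networks (>= 100; the reference analysis
#'   used 1000).
#' @param seed RNG seed.
#' @param mode `"shuffle_weights"` or `"rewire_pairs"`.
#' @param alpha Betweenness cost exponent.
#' @return An object of class `pcr_centrality_report`: a tibble with one row
#'   per node and measure (`observed`, `p2.5`, `p50`, `p97.5`, `extreme`).
#' @export
permutation_null <- function(net, n_perm = 1000L, seed,
                             mode = c("shuffle_weights", "rewire_pairs"),
                             alpha = 1) {
  stopifnot(inherits(net, "symptom_network"))
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is mandatory")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  ids <- net$nodes$id
  n <- length(ids)
  deg <- weighted_degrees(net)
  btw <- betweenness_weighted(net, alpha = alpha)
  observed <- rbind(
    tibble(id = ids, measure = "outdegree", observed = deg$outdegree),
    tibble(id = ids, measure = "indegree", observed = deg$indegree),
    tibble(id = ids, measure = "betweenness", observed = btw$betweenness)
  )
  w_obs <- net$edges$weight
  all_pairs <- expand.grid(from = ids, to = ids)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  perm <- array(NA_real_, dim = c(n_perm, n, 3L))
  with_local_seed(seed, {
    for (k in seq_len(n_perm)) {
      if (mode == "shuffle_weights") {
        pe <- net$edges
        pe$weight <- sample(w_obs)
      } else {
        pos <- sample.int(nrow(all_pairs), length(w_obs))
        pe <- tibble(from = all_pairs$from[pos], to = all_pairs$to[pos],
                     weight = w_obs)
      }
      pnet <- symptom_network(net$nodes, pe)
      d <- weighted_degrees(pnet)
      b <- betweenness_weighted(pnet, alpha = alpha)
      perm[k, , 1] <- d$outdegree
      perm[k, , 2] <- d$indegree
      perm[k, , 3] <- b$betweenness
    }
  })
  qs <- apply(perm, c(2, 3), quantile, probs = c(0.025, 0.5, 0.975), type = 7)
  measure_order <- c("outdegree", "indegree", "betweenness")
  rows <- lapply(1:3, function(mi) {
    tibble(id = ids, measure = measure_order[mi],
           p2.5 = qs[1, , mi], p50 = qs[2, , mi], p97.5 = qs[3, , mi])
  })
  out <- merge(observed, do.call(rbind, rows), by = c("id", "measure"),
               sort = FALSE)
  out <- as_tibble(out)
  out$extreme <- out$observed < out$p2.5 | out$observed > out$p97.5
  out <- out[order(match(out$measure, measure_order), out$id), ]
  structure(out, class = c("pcr_centrality_report", class(out)),
            n_perm = n_perm, mode = mode, seed = seed)
}

#' Convert to an igraph object
#' @param net A `symptom_network`.
#' @return An igraph directed graph with `weight` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  v <- data.frame(name = as.character(net$nodes$id),
                  frequency = net$nodes$frequency)
  if ("label" %in% names(net$nodes)) v$label <- net$nodes$label
  e <- data.frame(from = as.character(net$edges$from),
                  to = as.character(net$edges$to),
                  weight = net$edges$weight)
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}

#' Force-directed node layout
#'
#' Fruchterman-Reingold layout (edge-crossing minimizing, symmetry aware;
#' strongly connected symptoms cluster together), deterministic given the
#' seed, centered on the origin. For plotting and export only.
#'
#' @param net A `symptom_network`.
#' @param seed RNG seed.
#' @return Matrix of (x, y) coordinates, one row per node, rownames = ids.
#' @export
layout_fruchterman_reingold <- function(net, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  g <- as_igraph(net)
  w <- igraph::E(g)$weight
  if (length(w) == 0 || all(w <= 0)) {
    w <- NULL  # unweighted layout for empty/degenerate edge sets
  } else {
    w[w <= 0] <- min(w[w > 0]) * 1e-3  # FR layout needs positive weights
  }
  xy <- with_local_seed(seed, igraph::layout_with_fr(g, weights = w))
  xy <- sweep(xy, 2, colMeans(xy))
  rownames(xy) <- net$nodes$id
  colnames(xy) <- c("x", "y")
  xy
}

#' Export a network
#'
#' `write_network_graphml` writes GraphML (via igraph);
#' `write_edge_list` writes the weighted edge list CSV
#' (`source,target,weight,n`).
#'
#' @param net A `symptom_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_list <- function(net, path) {
  out <- data.frame(source = net$edges$from, target = net$edges$to,
                    weight = net$edges$weight, n = net$edges$n)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
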