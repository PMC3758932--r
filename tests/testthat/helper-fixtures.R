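# Fixture builders and independent brute-force oracles used across the suite.

# build a participant record from a frequency vector (named by id) and a
# data frame of pcr rows
make_record <- function(id = "p1", freqs, pcr = NULL) {
  participant_record(id, freqs, pcr = pcr)
}

# all k-permutations of v (list of vectors)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(perms(v[-i]), function(p) c(v[i], p))
  }))
}

# oracle: enumerate simple directed cycles of length 2..max_len in adjacency
# matrix A by checking every subset permutation anchored at its smallest id
oracle_cycles <- function(A, max_len = 4L) {
  n <- nrow(A)
  res <- list()
  for (k in 2:min(max_len, n)) {
    subs <- combn(n, k, simplify = FALSE)
    for (s in subs) {
      tails <- if (k == 2L) list(s[2]) else perms(s[-1])
      for (p in tails) {
        cyc <- c(s[1], p)
        nxt <- c(cyc[-1], cyc[1])
        if (all(A[cbind(cyc, nxt)] != 0)) res[[length(res) + 1L]] <- cyc
      }
    }
  }
  res
}

cycle_keys <- function(cycles) {
  sort(vapply(cycles, paste, character(1), collapse = "-"))
}

# oracle: betweenness by exhaustive enumeration of all simple s->t paths and
# their costs (cost of an edge = weight^-alpha), fractional credit across
# co-minimal paths
oracle_betweenness <- function(W, alpha = 1) {
  n <- nrow(W)
  cost <- ifelse(W > 0, W^(-alpha), Inf)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- list()
      rec <- function(path, acc) {
        u <- path[length(path)]
        if (u == t) {
          paths[[length(paths) + 1L]] <<- list(path = path, cost = acc)
          return(invisible())
        }
        for (v in which(is.finite(cost[u, ]))) {
          if (!(v %in% path)) rec(c(path, v), acc + cost[u, v])
        }
      }
      rec(s, 0)
      if (length(paths) == 0L) next
      costs <- vapply(paths, `[[`, numeric(1), "cost")
      mn <- min(costs)
      minimal <- paths[costs <= mn + 1e-10 * max(1, abs(mn))]
      inner <- setdiff(seq_len(n), c(s, t))
      for (v in inner) {
        frac <- mean(vapply(minimal, function(p) v %in% p$path, logical(1)))
        bc[v] <- bc[v] + frac
      }
    }
  }
  bc
}

# oracle: Holm step-down by direct evaluation of its definition
oracle_holm <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- rep(FALSE, m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) reject[ord[k]] <- TRUE else break
  }
  reject
}

# random weighted digraph as a symptom_network on nodes 1..n
random_weighted_net <- function(n, p_edge = 0.4, w_min = 0.5, w_max = 9.5) {
  pairs <- expand.grid(from = 1:n, to = 1:n)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, ]
  edges$weight <- runif(nrow(edges), w_min, w_max)
  edges$n <- 1L
  symptom_network(tibble::tibble(id = 1:n), edges)
}

# weight matrix view of a symptom_network (n x n, 0 = absent)
net_weight_matrix <- function(net) {
  ids <- sort(net$nodes$id)
  n <- length(ids)
  W <- matrix(0, n, n)
  W[cbind(match(net$edges$from, ids), match(net$edges$to, ids))] <-
    net$edges$weight
  W
}

# two-participant toy population with endorsed anxiety/depression symptoms
toy_records <- function() {
  r1 <- make_record("a",
    c(`1` = 2L, `2` = 3L, `13` = 5L),
    pcr = data.frame(
      cause_id = c(1, 1, 2, 2, 13, 13),
      effect_id = c(2, 13, 1, 13, 1, 2),
      value = c(4, 6, 2, 8, 1, 3)))
  r2 <- make_record("b",
    c(`1` = 1L, `13` = 2L),
    pcr = data.frame(cause_id = c(1, 13), effect_id = c(13, 1),
                     value = c(5, 2)))
  list(a = r1, b = r2)
}
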