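# Independent brute-force oracle: all-pairs shortest directed path by
# exhaustive simple-path enumeration (exponential; use only for small graphs),
# and a random-digraph generator for property tests.

brute_shortest <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  w <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(net$edges))) {
    w[net$edges$source[k], net$edges$target[k]] <- net$edges$line_value[k]
  }
  best <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  rec <- function(origin, u, len, visited) {
    for (v in seq_len(n)) {
      if (!visited[v] && is.finite(w[u, v])) {
        nl <- len + w[u, v]
        if (nl < best[origin, v]) best[origin, v] <<- nl
        visited[v] <- TRUE
        rec(origin, v, nl, visited)
        visited[v] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    vis <- rep(FALSE, n)
    vis[s] <- TRUE
    rec(s, s, 0, vis)
  }
  best
}

brute_ne <- function(net) {
  d <- brute_shortest(net)
  sum(1 / d[is.finite(d)])
}

random_digraph <- function(n, n_edges, weights = c(10, 200)) {
  pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
  pairs <- pairs[pairs$s != pairs$t, ]
  pick <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ]
  nodes <- sprintf("v%02d", seq_len(n))
  pathway_network(
    data.frame(source = nodes[pick$s], target = nodes[pick$t],
               line_value = sample(weights, nrow(pick), replace = TRUE)),
    nodes = nodes)
}
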