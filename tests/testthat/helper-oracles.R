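# graph fixtures and brute-force oracles used across the topology tests

# build a ppi_network from a vector of "A-B" edge strings, confidence 1
make_net <- function(edges, nodes = NULL, confidence = 1) {
  if (length(edges) == 0) {
    return(ppi_network(nodes = nodes))
  }
  parts <- strsplit(edges, "-", fixed = TRUE)
  ppi_network(data.frame(node1 = vapply(parts, `[`, "", 1L),
                         node2 = vapply(parts, `[`, "", 2L),
                         confidence = confidence,
                         stringsAsFactors = FALSE),
              nodes = nodes)
}

random_connected_net <- function(n, p = 0.4) {
  # rejection-sample a connected Erdos-Renyi graph on n nodes
  nodes <- sprintf("N%02d", seq_len(n))
  repeat {
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) next
    net <- ppi_network(data.frame(node1 = pairs[keep, 1],
                                  node2 = pairs[keep, 2],
                                  confidence = 1,
                                  stringsAsFactors = FALSE),
                       nodes = nodes)
    if (oracle_connected(net)) return(net)
  }
}

oracle_adj <- function(net) {
  adj <- rep(list(character(0)), length(net$nodes))
  names(adj) <- net$nodes
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$node1[i]; b <- net$edges$node2[i]
    adj[[a]] <- sort(c(adj[[a]], b))
    adj[[b]] <- sort(c(adj[[b]], a))
  }
  adj
}

oracle_connected <- function(net) {
  adj <- oracle_adj(net)
  seen <- net$nodes[1]
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(net$nodes)
}

# exhaustive enumeration of all shortest paths between every unordered pair;
# fraction through each interior node accumulated directly
oracle_betweenness <- function(net) {
  adj <- oracle_adj(net)
  nodes <- net$nodes
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  all_paths <- function(s, t) {
    # BFS distances from s, then DFS over predecessor structure
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      }
      frontier <- unique(nxt)
    }
    if (is.infinite(dist[t])) return(list())
    walk <- function(v) {
      if (v == s) return(list(s))
      preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
      out <- list()
      for (p in preds) for (pth in walk(p)) {
        out[[length(out) + 1]] <- c(pth, v)
      }
      out
    }
    walk(t)
  }
  prs <- utils::combn(nodes, 2)
  for (i in seq_len(ncol(prs))) {
    paths <- all_paths(prs[1, i], prs[2, i])
    if (length(paths) == 0) next
    for (pth in paths) {
      interior <- pth[-c(1, length(pth))]
      bc[interior] <- bc[interior] + 1 / length(paths)
    }
  }
  bc
}

# naive recursive per-root shortest-path-tree walk (lexicographic parents)
oracle_bottleneck <- function(net) {
  adj <- oracle_adj(net)
  nodes <- net$nodes
  bn <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      }
      frontier <- sort(unique(nxt))
    }
    in_tree <- nodes[is.finite(dist)]
    parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
    for (v in setdiff(in_tree, s)) {
      cand <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
      parent[v] <- sort(cand)[1]
    }
    children <- function(v) names(parent)[!is.na(parent) & parent == v]
    subtree_size <- function(v) {
      kids <- children(v)
      if (length(kids) == 0) return(0)
      sum(vapply(kids, function(k) 1 + subtree_size(k), 0))
    }
    for (v in setdiff(in_tree, s)) {
      if (subtree_size(v) > length(in_tree) / 4) bn[v] <- bn[v] + 1
    }
  }
  bn
}

# brute-force induced-subgraph computations
oracle_mnc <- function(net) {
  adj <- oracle_adj(net)
  nodes <- net$nodes
  comp_sizes <- function(sub) {
    if (length(sub) == 0) return(0)
    remaining <- sub
    sizes <- integer(0)
    while (length(remaining) > 0) {
      seen <- remaining[1]
      frontier <- seen
      while (length(frontier) > 0) {
        nxt <- setdiff(intersect(unique(unlist(adj[frontier])), remaining),
                       seen)
        seen <- c(seen, nxt)
        frontier <- nxt
      }
      sizes <- c(sizes, length(seen))
      remaining <- setdiff(remaining, seen)
    }
    sizes
  }
  stats::setNames(vapply(nodes, function(v) max(comp_sizes(adj[[v]])),
                         numeric(1)), nodes)
}

oracle_clustcoef <- function(net) {
  adj <- oracle_adj(net)
  nodes <- net$nodes
  stats::setNames(vapply(nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) < 2) return(0)
    prs <- utils::combn(nb, 2)
    linked <- sum(vapply(seq_len(ncol(prs)),
                         function(i) prs[2, i] %in% adj[[prs[1, i]]],
                         logical(1)))
    linked / ncol(prs)
  }, numeric(1)), nodes)
}

# exhaustive hypergeometric upper tail by pmf summation with log-binomials
oracle_hyper_tail <- function(N, K, n, k) {
  kk <- k:min(K, n)
  kk <- kk[kk >= max(0, n - (N - K))]
  if (length(kk) == 0) return(0)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}
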