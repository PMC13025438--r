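#' Topological hub screens
#'
#' Five node-scoring methods used together to screen a confidence-filtered
#' PPI subnetwork for consensus hub genes: local clustering coefficient,
#' maximal neighborhood component (MNC), betweenness centrality, bottleneck
#' centrality, and MCODE molecular-complex detection. All five operate on the
#' unweighted topology; edge confidences are used upstream for filtering
#' only. Score vectors are plain named numeric vectors over every node of
#' the network.
#'
#' @name hub_screens
NULL

#' Local clustering coefficient
#'
#' `C(v) = 2 e(N(v)) / (deg(v) (deg(v) - 1))`, the fraction of a node's
#' neighbor pairs that are themselves connected; nodes of degree < 2 score 0.
#'
#' @param net a [ppi_network()].
#' @return Named numeric score vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  adj <- ppi_adjacency(net)
  scores <- vapply(net$nodes, function(v) {
    nb <- adj[[v]]
    d <- length(nb)
    if (d < 2) return(0)
    e <- sum(vapply(nb, function(u) sum(adj[[u]] %in% nb), 0L)) / 2
    2 * e / (d * (d - 1))
  }, numeric(1))
  scores
}

# connected components of the induced subgraph on `nodes`; returns a list of
# character vectors. `adj` is the full-graph adjacency list.
induced_components <- function(adj, nodes) {
  remaining <- nodes
  comps <- list()
  while (length(remaining) > 0) {
    comp <- character(0)
    queue <- remaining[1]
    remaining <- remaining[-1]
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      nxt <- intersect(adj[[v]], remaining)
      remaining <- setdiff(remaining, nxt)
      queue <- c(queue, nxt)
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

#' Maximal neighborhood component
#'
#' `MNC(v)` is the number of nodes in the largest connected component of the
#' subgraph induced by the open neighborhood `N(v)`. Isolated nodes score 0.
#'
#' @param net a [ppi_network()].
#' @return Named numeric score vector.
#' @export
mnc <- function(net) {
  adj <- ppi_adjacency(net)
  scores <- vapply(net$nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) == 0) return(0)
    max(lengths(induced_components(adj, nb)))
  }, numeric(1))
  scores
}

#' Betweenness centrality (Brandes)
#'
#' Unweighted shortest-path betweenness with unordered-pair counting:
#' `BC(v) = sum over s < t, s != v != t of sigma_st(v) / sigma_st`, computed
#' by Brandes' dependency accumulation. Pairs in different components
#' contribute 0.
#'
#' @param net a [ppi_network()].
#' @return Named numeric score vector.
#' @export
betweenness <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj_chr <- ppi_adjacency(net)
  adj <- lapply(adj_chr, function(x) match(x, nodes))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # single-source BFS with path counting
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency accumulation in reverse BFS order
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  scores <- bc / 2
  names(scores) <- nodes
  scores
}

# deterministic BFS shortest-path tree rooted at s: each non-root node's
# parent is its lexicographically smallest neighbor on the previous level.
# Returns an integer parent vector (NA for root and unreachable nodes),
# indices into `nodes`.
bfs_tree_parents <- function(nodes, adj, s) {
  n <- length(nodes)
  dist <- rep(-1L, n); dist[s] <- 0L
  parent <- rep(NA_integer_, n)
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    nxt <- sort(unique(nxt))
    for (w in nxt) {
      cand <- adj[[w]][dist[adj[[w]]] == dist[w] - 1L]
      # adjacency lists are sorted lexicographically, so the first candidate
      # is the lexicographically smallest eligible parent
      parent[w] <- cand[1]
    }
    frontier <- nxt
  }
  parent
}

#' Bottleneck centrality
#'
#' For each root `s`, a deterministic BFS shortest-path tree `T_s` is grown
#' (each node's parent is its lexicographically smallest neighbor on the
#' previous BFS level). A node `v != s` is a bottleneck of `T_s` when the
#' number of its strict descendants exceeds a quarter of the tree's node
#' count. `BN(v)` counts the roots for which `v` is a bottleneck.
#'
#' @param net a [ppi_network()].
#' @return Named numeric score vector.
#' @export
bottleneck <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj_chr <- ppi_adjacency(net)
  adj <- lapply(adj_chr, function(x) match(x, nodes))
  bn <- numeric(n)
  for (s in seq_len(n)) {
    parent <- bfs_tree_parents(nodes, adj, s)
    in_tree <- which(!is.na(parent))
    tree_n <- length(in_tree) + 1L  # plus root
    if (tree_n == 1L) next
    desc <- numeric(n)
    for (v in in_tree) {  # count strict descendants by walking up to root
      p <- parent[v]
      while (!is.na(p)) {
        desc[p] <- desc[p] + 1
        p <- parent[p]
      }
    }
    hit <- in_tree[desc[in_tree] > tree_n / 4]
    bn[hit] <- bn[hit] + 1
  }
  names(bn) <- nodes
  bn
}

# core number (degeneracy peel) of a small graph given as adjacency list over
# `nodes`; returns named integer vector of core numbers.
core_numbers <- function(nodes, adj) {
  deg <- vapply(nodes, function(v) length(intersect(adj[[v]], nodes)), 0L)
  names(deg) <- nodes
  core <- deg
  remaining <- nodes
  cur_deg <- deg
  while (length(remaining) > 0) {
    v <- remaining[order(cur_deg[remaining], remaining)][1]
    core[v] <- cur_deg[v]
    nb <- intersect(adj[[v]], remaining)
    # standard peel: neighbors lose a degree but never drop below v's level
    cur_deg[nb] <- pmax(cur_deg[nb] - 1L, cur_deg[v])
    remaining <- setdiff(remaining, v)
  }
  core
}

#' MCODE vertex weights
#'
#' Bader-Hogue core-clustering weighting: `w(v)` is `k_max` times the density
#' of the highest k-core of the closed neighborhood `N[v]`, where `k_max` is
#' the largest `k` for which that k-core is non-empty and density is
#' `2e / (n (n - 1))`. Isolated nodes score 0.
#'
#' @param net a [ppi_network()].
#' @return Named numeric score vector.
#' @export
mcode_vertex_weights <- function(net) {
  adj <- ppi_adjacency(net)
  scores <- vapply(net$nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) == 0) return(0)
    nodes <- sort(c(v, nb))
    core <- core_numbers(nodes, adj)
    kmax <- max(core)
    core_nodes <- names(core)[core == kmax]
    m <- length(core_nodes)
    if (m < 2) return(0)
    e <- sum(vapply(core_nodes,
                    function(u) sum(adj[[u]] %in% core_nodes), 0L)) / 2
    kmax * (2 * e / (m * (m - 1)))
  }, numeric(1))
  scores
}

#' MCODE molecular-complex detection
#'
#' Complexes are grown from unvisited seed vertices of highest MCODE weight
#' (ties broken lexicographically). Expansion is breadth-first: a neighbor is
#' admitted when its weight is at least `w_seed * (1 - vwp)`; admitted nodes
#' are marked visited and never reused. With `haircut = TRUE`, nodes of
#' degree < 2 within the complex are removed afterwards; complexes with
#' fewer than two remaining nodes are discarded. Each complex is scored as
#' its internal density times its size, and complexes are returned sorted by
#' score (descending), then size (descending), then seed symbol.
#'
#' @param net a [ppi_network()].
#' @param vwp vertex weight percentage in `[0, 1)` (default 0.2).
#' @param haircut remove degree-1 nodes from each complex (default TRUE)?
#' @param fluff unused compatibility flag; must be FALSE.
#' @return A list of complexes, each a list with elements `members` (sorted
#'   character vector), `seed`, `score`, `density`, `size`.
#' @export
mcode_complexes <- function(net, vwp = 0.2, haircut = TRUE, fluff = FALSE) {
  stopifnot(vwp >= 0, vwp < 1)
  if (isTRUE(fluff)) stop("fluff expansion is not implemented")
  w <- mcode_vertex_weights(net)
  adj <- ppi_adjacency(net)
  unvisited <- net$nodes[w[net$nodes] > 0]
  complexes <- list()
  while (length(unvisited) > 0) {
    ord <- unvisited[order(-w[unvisited], unvisited)]
    seed <- ord[1]
    thresh <- w[seed] * (1 - vwp)
    members <- seed
    unvisited <- setdiff(unvisited, seed)
    queue <- seed
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      cand <- intersect(adj[[v]], unvisited)
      admit <- cand[w[cand] >= thresh]
      if (length(admit) > 0) {
        members <- c(members, admit)
        unvisited <- setdiff(unvisited, admit)
        queue <- c(queue, sort(admit))
      }
    }
    if (haircut) {
      repeat {
        deg_in <- vapply(members,
                         function(u) sum(adj[[u]] %in% members), 0L)
        drop <- members[deg_in < 2]
        if (length(drop) == 0) break
        members <- setdiff(members, drop)
        if (length(members) == 0) break
      }
    }
    m <- length(members)
    if (m >= 2) {
      e <- sum(vapply(members,
                      function(u) sum(adj[[u]] %in% members), 0L)) / 2
      dens <- 2 * e / (m * (m - 1))
      complexes[[length(complexes) + 1]] <-
        list(members = sort(members), seed = seed,
             score = dens * m, density = dens, size = m)
    }
  }
  if (length(complexes) > 1) {
    ord <- order(-vapply(complexes, `[[`, 0, "score"),
                 -vapply(complexes, `[[`, 0L, "size"),
                 vapply(complexes, `[[`, "", "seed"))
    complexes <- complexes[ord]
  }
  complexes
}

#' Top-k nodes of a score vector
#'
#' Returns the `k` highest-scoring nodes, ties broken by lexicographic
#' symbol; when the network has fewer than `k` nodes all are returned.
#'
#' @param scores named numeric score vector (from one of the screens).
#' @param k number of nodes to select (default 8).
#' @return Ordered character vector of gene symbols.
#' @export
top_k_nodes <- function(scores, k = 8) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  nm <- names(scores)
  ord <- order(-as.numeric(scores), nm)
  nm[ord][seq_len(min(k, length(nm)))]
}

#' Five-way consensus of hub screens
#'
#' Intersects the per-method gene lists: by convention MCODE contributes the
#' full membership of its top complex while the four centrality screens
#' contribute their top-k lists. A gene is a consensus hub only when it
#' appears in every list.
#'
#' @param per_method_lists named list (>= 2 entries) of character vectors.
#' @return An object of class `consensus_result`: a list with
#'   `per_method` (the input lists) and `consensus` (sorted character
#'   vector, the intersection of all lists).
#' @export
consensus_hubs <- function(per_method_lists) {
  stopifnot(is.list(per_method_lists))
  if (length(per_method_lists) < 2) {
    stop("consensus needs at least two per-method gene lists")
  }
  inter <- sort(Reduce(intersect, per_method_lists))
  structure(list(per_method = per_method_lists, consensus = inter),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result\n")
  for (m in names(x$per_method)) {
    cat(sprintf("  %-12s (%d): %s\n", m, length(x$per_method[[m]]),
                paste(x$per_method[[m]], collapse = ", ")))
  }
  cat(sprintf("  consensus (%d): %s\n", length(x$consensus),
              paste(x$consensus, collapse = ", ")))
  invisible(x)
}

#' Run all five screens on a network
#'
#' Convenience wrapper producing the per-method lists and their consensus in
#' one call.
#'
#' @param net a [ppi_network()] (typically the induced core-pool subnetwork).
#' @param top_k list size for the four centrality screens (default 8).
#' @param mcode_full_module if TRUE (default) MCODE contributes the full
#'   membership of its highest-scoring complex; if FALSE, the top-k nodes by
#'   MCODE vertex weight.
#' @param vwp,haircut MCODE parameters, see [mcode_complexes()].
#' @return A `consensus_result`, see [consensus_hubs()].
#' @export
screen_hubs <- function(net, top_k = 8, mcode_full_module = TRUE,
                        vwp = 0.2, haircut = TRUE) {
  cx <- mcode_complexes(net, vwp = vwp, haircut = haircut)
  mcode_list <- if (mcode_full_module) {
    if (length(cx) > 0) cx[[1]]$members else character(0)
  } else {
    top_k_nodes(mcode_vertex_weights(net), k = top_k)
  }
  lists <- list(
    mcode = mcode_list,
    mnc = top_k_nodes(mnc(net), k = top_k),
    betweenness = top_k_nodes(betweenness(net), k = top_k),
    bottleneck = top_k_nodes(bottleneck(net), k = top_k),
    clustcoef = top_k_nodes(clustering_coefficient(net), k = top_k)
  )
  consensus_hubs(lists)
}
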