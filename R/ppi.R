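#' Protein-protein interaction network
#'
#' A `ppi_network` is a simple undirected graph over gene symbols whose edges
#' carry a confidence score in `[0, 1]` (a STRING-style combined score after
#' normalization). Self-loops are dropped and parallel edges collapsed to the
#' maximum confidence, so the object always satisfies the simple-graph
#' invariant.
#'
#' @param edges data frame with columns `node1`, `node2`, `confidence`
#'   (character, character, numeric in `[0, 1]`). May be empty.
#' @param nodes optional character vector of node symbols; defaults to the
#'   symbols appearing in `edges`. Symbols mentioned in `edges` are always
#'   included, so isolates can be represented by listing them here.
#' @return An object of class `ppi_network` with elements `nodes` (sorted
#'   character vector) and `edges` (data frame `node1`, `node2`, `confidence`
#'   with `node1 < node2`, sorted).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(node1 = character(), node2 = character(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    need <- c("node1", "node2", "confidence")
    if (!all(need %in% names(edges))) {
      stop("edge table must have columns node1, node2, confidence")
    }
    edges <- edges[, need]
    edges$node1 <- as.character(edges$node1)
    edges$node2 <- as.character(edges$node2)
    edges$confidence <- as.numeric(edges$confidence)
    if (anyNA(edges$confidence) || any(edges$confidence < 0) ||
        any(edges$confidence > 1)) {
      stop("edge confidence must lie in [0, 1]")
    }
    loops <- edges$node1 == edges$node2
    if (any(loops)) {
      warning(sprintf("dropping %d self-loop(s)", sum(loops)))
      edges <- edges[!loops, , drop = FALSE]
    }
    # canonical orientation, then collapse duplicates keeping max confidence
    flip <- edges$node1 > edges$node2
    tmp <- edges$node1[flip]
    edges$node1[flip] <- edges$node2[flip]
    edges$node2[flip] <- tmp
    if (nrow(edges) > 0) {
      key <- paste(edges$node1, edges$node2, sep = "\r")
      conf <- tapply(edges$confidence, key, max)
      parts <- strsplit(names(conf), "\r", fixed = TRUE)
      edges <- data.frame(node1 = vapply(parts, `[`, "", 1L),
                          node2 = vapply(parts, `[`, "", 2L),
                          confidence = as.numeric(conf),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  all_nodes <- sort(unique(c(as.character(nodes), edges$node1, edges$node2)))
  structure(list(nodes = all_nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a PPI network
#' @param net a [ppi_network()]
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# adjacency list: named list, one sorted character vector of neighbors
# per node (isolates get character(0))
ppi_adjacency <- function(net) {
  adj <- rep(list(character(0)), length(net$nodes))
  names(adj) <- net$nodes
  if (nrow(net$edges) > 0) {
    nb <- split(c(net$edges$node2, net$edges$node1),
                c(net$edges$node1, net$edges$node2))
    adj[names(nb)] <- lapply(nb, sort)
  }
  adj
}

#' Read a STRING-style edge list
#'
#' Reads a tab-separated file with columns `node1`, `node2`, `score`. A header
#' row is tolerated (detected by a non-numeric third field). Scores may be on
#' the native STRING integer scale 0-1000 or already in `[0, 1]`; with
#' `score_scale = "auto"` the file is treated as STRING-scaled when any score
#' exceeds 1 and divided by 1000. Duplicate pairs keep the maximum confidence
#' and self-loops are dropped with a warning.
#'
#' @param path file path.
#' @param score_scale one of `"auto"`, `"unit"`, `"string"`.
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path, score_scale = c("auto", "unit", "string")) {
  score_scale <- match.arg(score_scale)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(ppi_network())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed edge-list line %d: expected 3 tab-separated fields",
                 lineno[bad[1]]))
  }
  first_score <- suppressWarnings(as.numeric(fields[[1]][3]))
  start <- 1L
  if (is.na(first_score)) start <- 2L  # header row
  if (start > length(fields)) return(ppi_network())
  idx <- start:length(fields)
  n1 <- vapply(fields[idx], `[`, "", 1L)
  n2 <- vapply(fields[idx], `[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(fields[idx], `[`, "", 3L)))
  if (anyNA(sc)) {
    stop(sprintf("malformed edge-list line %d: score is not numeric",
                 lineno[idx[which(is.na(sc))[1]]]))
  }
  if (any(sc < 0)) stop("edge scores must be nonnegative")
  if (score_scale == "string" || (score_scale == "auto" && any(sc > 1))) {
    sc <- sc / 1000
  }
  if (any(sc > 1)) stop("edge scores exceed 1 after scale normalization")
  ppi_network(data.frame(node1 = n1, node2 = n2, confidence = sc,
                         stringsAsFactors = FALSE))
}

#' Write a PPI network as a normalized edge list
#'
#' @param net a [ppi_network()].
#' @param path output file path; columns `node1`, `node2`, `score` with scores
#'   in `[0, 1]`, tab-separated, with header.
#' @export
write_edge_list <- function(net, path) {
  out <- net$edges
  names(out) <- c("node1", "node2", "score")
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dynamic STRING confidence threshold
#'
#' Small query sets are filtered at high confidence (0.7) to keep only the
#' most reliable interactions during hub identification; larger sets use a
#' relaxed 0.4 threshold so enough candidates survive for cross-species
#' comparison.
#'
#' @param n_query_genes number of genes in the query set (>= 1).
#' @return 0.7 if `n_query_genes <= 20`, else 0.4.
#' @export
dynamic_threshold <- function(n_query_genes) {
  if (!is.numeric(n_query_genes) || length(n_query_genes) != 1 ||
      is.na(n_query_genes) || n_query_genes < 1) {
    stop("n_query_genes must be a single number >= 1")
  }
  if (n_query_genes <= 20) 0.7 else 0.4
}

#' Filter network edges by confidence
#'
#' Keeps edges with confidence greater than or equal to `threshold`
#' (inclusive comparison). Nodes are kept even when they become isolated,
#' unless `drop_isolates = TRUE`.
#'
#' @param net a [ppi_network()].
#' @param threshold confidence threshold in `[0, 1]`.
#' @param drop_isolates drop nodes with no surviving edge?
#' @return A filtered [ppi_network()].
#' @export
filter_by_confidence <- function(net, threshold, drop_isolates = FALSE) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  edges <- net$edges[net$edges$confidence >= threshold, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (drop_isolates) NULL else net$nodes
  ppi_network(edges, nodes = nodes)
}

#' Induced subnetwork on a query gene set
#'
#' Restricts the network to the queried symbols. Query genes absent from the
#' network (for example species-specific symbols with no counterpart in a
#' human reference network) are returned in `dropped` rather than raising an
#' error; an empty intersection yields an empty network with a warning.
#'
#' @param net a [ppi_network()].
#' @param query_genes character vector of gene symbols.
#' @return A list with elements `network` (the induced [ppi_network()]) and
#'   `dropped` (sorted character vector of query genes absent from `net`).
#' @export
induced_subnetwork <- function(net, query_genes) {
  query_genes <- unique(as.character(query_genes))
  present <- intersect(query_genes, net$nodes)
  dropped <- sort(setdiff(query_genes, present))
  if (length(present) == 0) {
    warning("no query gene is present in the network")
    return(list(network = ppi_network(), dropped = dropped))
  }
  keep <- net$edges$node1 %in% present & net$edges$node2 %in% present
  sub <- ppi_network(net$edges[keep, , drop = FALSE], nodes = present)
  list(network = sub, dropped = dropped)
}
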