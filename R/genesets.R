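#' Gene-set collection
#'
#' A species-tagged, GMT-backed collection of named gene sets used for
#' pathway (KEGG-like) and GO biological-process over-representation. Term
#' ids must be unique and gene sets non-empty; duplicate genes within a term
#' are removed.
#'
#' @param species species tag, e.g. `"human"` or `"mouse"`.
#' @param ids character vector of unique term ids.
#' @param names character vector of term names (display names used for
#'   cross-species matching); defaults to `ids`.
#' @param genes list of character vectors, one gene set per term.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(species, ids, genes, names = ids) {
  ids <- as.character(ids)
  names <- as.character(names)
  stopifnot(length(ids) == length(genes), length(names) == length(ids))
  if (anyDuplicated(ids)) stop("term ids must be unique")
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(lengths(genes) == 0)) stop("gene sets must be non-empty")
  names(genes) <- ids
  structure(list(species = species, ids = ids, names = names, genes = genes),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection (%s): %d terms, %d distinct genes\n",
              x$species, length(x$ids), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$ids)

#' All genes annotated in a collection
#' @param collection a [gene_set_collection()].
#' @return Sorted character vector of distinct gene symbols.
#' @export
collection_genes <- function(collection) {
  sort(unique(unlist(collection$genes, use.names = FALSE)))
}

#' Read / write GMT gene-set files
#'
#' Standard tab-separated GMT: one term per line as
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. Empty lines are skipped; a
#' line with fewer than three fields is a format error reported with its line
#' number. Duplicate genes within a term are removed with a warning. The
#' description field is used as the term name (falling back to the id when
#' empty).
#'
#' @param path file path.
#' @param species species tag attached to the collection.
#' @return `read_gmt()` returns a [gene_set_collection()]; `write_gmt()`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path, species = "human") {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("GMT file has no gene sets: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT format error at line %d: fewer than 3 fields",
                 lineno[short[1]]))
  }
  ids <- vapply(fields, `[`, "", 1L)
  nms <- vapply(fields, `[`, "", 2L)
  nms[!nzchar(nms)] <- ids[!nzchar(nms)]
  genes <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(genes, function(g) length(g) - length(unique(g)), 0L))
  if (ndup > 0) {
    warning(sprintf("removed %d duplicated gene(s) within terms", ndup))
    genes <- lapply(genes, unique)
  }
  gene_set_collection(species, ids, genes, names = nms)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$ids), function(i) {
    paste(c(collection$ids[i], collection$names[i],
            collection$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric probability
#'
#' Exact probability `P(X >= k)` of observing at least `k` annotated genes
#' when drawing `n` genes from a universe of `N` genes of which `K` carry the
#' annotation. This is the over-representation p-value of the hypergeometric
#' test.
#'
#' @param N universe size.
#' @param K number of annotated genes in the universe.
#' @param n query size.
#' @param k observed overlap.
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("N, K, n, k must be nonnegative integers")
  }
  if (N < max(K, n)) stop("universe size N must be >= max(K, n)")
  if (k > min(K, n)) stop("overlap k cannot exceed min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (Q-values), preserving input order. Inputs
#' outside `[0, 1]` are an error.
#'
#' @param p_values numeric vector of raw p-values.
#' @return Numeric vector of Q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests every term of a collection for over-representation of `query_genes`
#' within `universe`. Query genes outside the universe are dropped with a
#' warning; term gene sets are restricted to the universe. Only terms with at
#' least one overlapping gene are reported. Q-values are BH-adjusted across
#' the tested terms of this collection, and results are sorted by
#' `(q, p, term_id)`.
#'
#' @param query_genes character vector of query gene symbols.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of background gene symbols. A common
#'   choice is the genes present in both the expression matrix and the
#'   annotation collection.
#' @return Data frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `q`.
#' @export
enrich <- function(query_genes, collection, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("enrichment universe is empty")
  query <- unique(as.character(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_along(collection$ids), function(i) {
    term_genes <- intersect(collection$genes[[i]], universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, query))
    if (k < 1) return(NULL)
    data.frame(term_id = collection$ids[i], term_name = collection$names[i],
               k = k, K = K, n = n, N = N,
               p = hypergeom_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$q, res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Top enriched terms
#'
#' First `top_k` rows of an enrichment result (already sorted by
#' `(q, p, term_id)`), or all rows when fewer are available.
#'
#' @param results data frame from [enrich()].
#' @param top_k number of terms (default 5).
#' @return Data frame subset.
#' @export
top_terms <- function(results, top_k = 5) {
  stopifnot(top_k >= 1)
  utils::head(results, top_k)
}

normalize_term_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Cross-species shared term names
#'
#' Intersects two sets of term names case-insensitively after whitespace
#' normalization. Used to find the functional terms shared between the human
#' and mouse top term lists.
#'
#' @param terms_a,terms_b character vectors of term names.
#' @return Sorted character vector of shared normalized names.
#' @export
match_shared_terms <- function(terms_a, terms_b) {
  sort(intersect(normalize_term_name(terms_a), normalize_term_name(terms_b)))
}

#' Symbol-identity ortholog intersection
#'
#' Pairs mouse and human genes whose symbols are identical after
#' upper-casing (e.g. mouse `Psmb8` and human `PSMB8`). Returns the matched
#' genes in human casing, sorted.
#'
#' @param mouse_genes,human_genes character vectors of gene symbols.
#' @return Sorted character vector of conserved symbols (human casing).
#' @export
intersect_orthologs <- function(mouse_genes, human_genes) {
  human_genes <- unique(as.character(human_genes))
  hit <- toupper(human_genes) %in% toupper(as.character(mouse_genes))
  sort(human_genes[hit])
}

#' Select the top fraction of a ranked gene list
#'
#' Takes the first `ceiling(fraction * n)` genes of an already-ranked list
#' (ascending Q-value, most significant first). The ceiling rule means that
#' the top 25% of 61 genes is 16 genes.
#'
#' @param ranked_genes character vector, ranked most-significant first.
#' @param fraction fraction in `(0, 1]` (default 0.25).
#' @return Character vector, a prefix of `ranked_genes`.
#' @export
select_top_fraction <- function(ranked_genes, fraction = 0.25) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  utils::head(ranked_genes, ceiling(fraction * length(ranked_genes)))
}
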