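#' Differential-expression statistics for a two-group count matrix
#'
#' Lightweight negative-binomial differential expression for a gene-level
#' count matrix with two sample groups (`model` vs `dose`): median-of-ratios
#' size factors, method-of-moments dispersion with an optional 1/mean trend
#' fit, a Wald test on the log fold change with a delta-method variance, BH
#' adjustment, and threshold-based up/down classification.
#'
#' @name deg_stats
NULL

check_count_matrix <- function(counts, group) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts))) stop("counts must have gene symbols as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene symbols in counts")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  group <- as.character(group)
  if (length(group) != ncol(counts)) {
    stop("group must have one label per sample")
  }
  if (!all(group %in% c("model", "dose"))) {
    stop("group labels must be 'model' or 'dose'")
  }
  if (!all(c("model", "dose") %in% group)) stop("both groups must be non-empty")
  group
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio between the sample's count and the gene's geometric mean across
#' samples. Only genes with all-positive counts serve as reference genes.
#'
#' @param counts nonnegative integer matrix, genes x samples, with gene
#'   symbols as rownames and sample ids as colnames.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be nonnegative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("normalization error: no gene has all-positive counts")
  }
  ref <- counts[pos, , drop = FALSE]
  log_geo <- rowMeans(log(ref))
  factors <- apply(ref, 2, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  names(factors) <- colnames(counts)
  factors
}

#' Method-of-moments dispersion estimates
#'
#' Per-gene NB dispersion `alpha` with `Var = mu + alpha mu^2`, estimated
#' from the pooled within-group mean and variance of size-factor-normalized
#' counts, floored at 0 (the Poisson limit) and capped at `max_dispersion`.
#' Degenerate genes (zero mean or variance below the mean) get the floor.
#'
#' @param counts genes x samples count matrix.
#' @param size_factors per-sample size factors,
#'   see [size_factors_median_of_ratios()].
#' @param group character vector of `"model"` / `"dose"` labels per sample.
#' @param max_dispersion cap for the estimate (default 10).
#' @return Named nonnegative numeric vector, one `alpha` per gene.
#' @export
estimate_dispersion_mom <- function(counts, size_factors, group,
                                    max_dispersion = 10) {
  group <- check_count_matrix(counts, group)
  if (min(table(group)) < 2) stop("need at least 2 samples per group")
  norm <- sweep(counts, 2, size_factors, "/")
  groups <- c("model", "dose")
  ss <- 0
  df <- 0
  means <- 0
  for (g in groups) {
    sub <- norm[, group == g, drop = FALSE]
    m <- rowMeans(sub)
    ss <- ss + rowSums((sub - m)^2)
    df <- df + ncol(sub) - 1
    means <- means + m / length(groups)
  }
  v <- ss / df
  alpha <- ifelse(means > 0, (v - means) / means^2, 0)
  pmin(pmax(alpha, 0), max_dispersion)
}

# least-squares fit of alpha ~ a0 + a1/mean across genes, clamped at zero;
# returns fitted per-gene values. Genes with near-zero mean keep their raw
# estimate.
fit_dispersion_trend <- function(means, alphas) {
  ok <- means > 0
  if (sum(ok) < 10) return(alphas)
  x <- 1 / means[ok]
  fit <- stats::lm.fit(cbind(1, x), alphas[ok])
  a0 <- fit$coefficients[1]
  a1 <- fit$coefficients[2]
  fitted <- alphas
  fitted[ok] <- pmax(a0 + a1 / means[ok], 0)
  fitted
}

#' Negative-binomial Wald test for two groups
#'
#' Log2 fold change of dose versus model group means of normalized counts
#' (with pseudo-count `pseudo` guarding zero means), with a Wald statistic
#' based on the delta-method variance of the log ratio under the NB model
#' `Var = mu + alpha mu^2`, and a two-sided p-value from the standard normal
#' reference. By default the plugged-in dispersions are smoothed with a
#' `1/mean` trend fit across genes, which stabilizes the noisy per-gene
#' method-of-moments values at small sample sizes.
#'
#' @param counts genes x samples count matrix.
#' @param size_factors per-sample size factors.
#' @param dispersions per-gene dispersion estimates; when `NULL` they are
#'   computed with [estimate_dispersion_mom()].
#' @param group character vector of `"model"` / `"dose"` labels per sample.
#' @param pseudo pseudo-count added to group means (default 0.5).
#' @param trend smooth dispersions with the 1/mean trend fit (default TRUE)?
#' @return Data frame with columns `gene`, `base_mean`, `log2fc`, `p`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions = NULL, group,
                         pseudo = 0.5, trend = TRUE) {
  group <- check_count_matrix(counts, group)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion_mom(counts, size_factors, group)
  }
  norm <- sweep(counts, 2, size_factors, "/")
  m_model <- rowMeans(norm[, group == "model", drop = FALSE])
  m_dose <- rowMeans(norm[, group == "dose", drop = FALSE])
  base_mean <- (m_model + m_dose) / 2
  if (trend) dispersions <- fit_dispersion_trend(base_mean, dispersions)
  lfc <- log2((m_dose + pseudo) / (m_model + pseudo))
  # Var(log mean) by delta method; normalized count j has
  # Var = mu / sf_j + alpha mu^2
  var_log_mean <- function(m, sf, alpha) {
    mm <- m + pseudo
    (1 / length(sf)^2) * rowSums(outer(1 / mm, 1 / sf) + alpha)
  }
  sf_model <- size_factors[group == "model"]
  sf_dose <- size_factors[group == "dose"]
  v <- var_log_mean(m_model, sf_model, dispersions) +
    var_log_mean(m_dose, sf_dose, dispersions)
  z <- log(2) * lfc / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  p[v == 0 | (m_model == m_dose)] <- 1
  data.frame(gene = rownames(counts), base_mean = base_mean,
             log2fc = lfc, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full differential-expression table
#'
#' Runs normalization, dispersion estimation, the Wald test, BH adjustment
#' and direction classification in one call.
#'
#' @param counts genes x samples count matrix.
#' @param group character vector of `"model"` / `"dose"` labels per sample.
#' @param q_max,lfc_min classification thresholds, see [classify_degs()].
#' @param ... passed to [nb_wald_test()].
#' @return A DEG table: data frame `gene`, `base_mean`, `log2fc`, `p`, `q`,
#'   `direction`.
#' @export
deg_table <- function(counts, group, q_max = 0.05, lfc_min = 1, ...) {
  sf <- size_factors_median_of_ratios(counts)
  res <- nb_wald_test(counts, sf, group = group, ...)
  res$q <- bh_adjust(res$p)
  classify_degs(res, q_max = q_max, lfc_min = lfc_min)
}

#' Classify genes as up / down / not significant
#'
#' A gene is `down` when `q <= q_max` and `log2fc <= -lfc_min`, `up` when
#' `q <= q_max` and `log2fc >= lfc_min`, otherwise `ns`. Boundary equality is
#' inclusive.
#'
#' @param records data frame with columns `log2fc` and `q`.
#' @param q_max Q-value threshold in `(0, 1]` (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @return `records` with a `direction` factor column added/replaced.
#' @export
classify_degs <- function(records, q_max = 0.05, lfc_min = 1) {
  stopifnot(q_max > 0, q_max <= 1, lfc_min >= 0)
  dir <- rep("ns", nrow(records))
  sig <- records$q <= q_max
  dir[sig & records$log2fc <= -lfc_min] <- "down"
  dir[sig & records$log2fc >= lfc_min] <- "up"
  records$direction <- dir
  records
}

#' Rank a DEG table by significance
#'
#' Ascending Q-value (most significant first); ties broken by larger
#' absolute log2 fold change, then lexicographic gene symbol — a fully
#' deterministic order.
#'
#' @param records DEG table with columns `gene`, `log2fc`, `q`.
#' @return The reordered data frame.
#' @export
rank_degs <- function(records) {
  ord <- order(records$q, -abs(records$log2fc), records$gene)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write DEG tables as TSV
#'
#' Tab-separated with header `gene, base_mean, log2fc, p, q, direction`
#' (columns beyond `gene`, `log2fc`, `p`, `q`, `direction` are optional on
#' read). Round-trip stable.
#'
#' @param records DEG table data frame.
#' @param path file path.
#' @return `read_deg_table()` returns the data frame; `write_deg_table()`
#'   returns `path` invisibly.
#' @export
write_deg_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "p", "q")
  if (!all(need %in% names(tab))) {
    stop("DEG table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}
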