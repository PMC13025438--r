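#' Simulation parameters for a synthetic xenograft screening study
#'
#' Builds and validates the parameter set of the synthetic-study generator.
#' The generator emulates the statistical structure the screening funnel
#' assumes: negative-binomial counts for two groups (`model` vs `dose`) with
#' a planted set of down-regulated genes, paired human/mouse annotation
#' collections sharing term names, and a PPI network containing a planted
#' dense module whose designated hub dominates all five topological scores.
#'
#' Planted genes come in two tiers. The *network-module* tier (the clique
#' around the hub plus a decoy interaction module) carries the full effect
#' `lfc_down` and is drawn from the high end of the expression range, where
#' the dispersion trend makes tests most powerful — mirroring the situation
#' in which hub screening operates on the most significant quartile of the
#' conserved genes. The remaining planted genes carry the weaker `lfc_weak`.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_per_group samples per group (default 6).
#' @param frac_down fraction of genes planted as down-regulated
#'   (default 0.04, i.e. 80 genes at the default size, so that the
#'   conserved set lands around 70 genes and the core pool stays at or
#'   below 20 genes, the high-confidence 0.7 network regime).
#' @param lfc_down log2 fold change of the network-module tier (default -2).
#' @param lfc_weak log2 fold change of the remaining planted genes
#'   (default -1.5).
#' @param nb_dispersion asymptotic NB dispersion `alpha0` (default 0.02).
#' @param dispersion_trend trend coefficient `alpha1` of the mean-dependent
#'   dispersion `alpha(mu) = alpha0 + alpha1 / mu` (default 16.7; set to 0
#'   for a flat dispersion equal to `nb_dispersion`). At the defaults the
#'   average dispersion across the expression range is 0.2.
#' @param mean_log_range range (natural log) of the log-uniform distribution
#'   of background gene means (default `log(c(20, 2000))`).
#' @param planted_mean_range mean range of the weak-tier planted genes
#'   (default `c(100, 600)`, moderately expressed).
#' @param module_mean_range range of network-module gene means
#'   (default `c(1500, 2000)`, the top expression band); the hub is the
#'   module's standout expresser at twice the band ceiling.
#' @param clique_size size of the planted clique including the hub
#'   (default 8).
#' @param decoy_module_size size of the planted complete-bipartite decoy
#'   module (default 10, split evenly); must be even and >= 4.
#' @param n_bridges number of high-confidence bridge edges from the hub into
#'   the decoy module (default 6, split across the two sides; >= 2).
#' @param background_edge_prob Erdos-Renyi probability of a low-confidence
#'   background edge (default 0.002).
#' @param confidence_high Beta shape parameters for planted-edge confidence,
#'   mapped to `0.7 + 0.3 * Beta(a, b)` so planted edges always survive the
#'   0.7 filter (default `c(2, 2)`).
#' @param confidence_low Beta shape parameters for background-edge confidence
#'   (default `c(1.5, 5)`, mean about 0.23).
#' @param frac_mouse_specific fraction of genes that are mouse-specific, with
#'   no human counterpart in the PPI network (default 0.05).
#' @param n_mouse_specific_planted planted down-regulated genes among the
#'   mouse-specific set (default 4); these exercise the species-presence
#'   filter.
#' @param depth_log_range range (natural log) of per-sample sequencing-depth
#'   factors (default `log(c(0.75, 4/3))`).
#' @param seed integer RNG seed (default 1).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000,
                       n_per_group = 6,
                       frac_down = 0.04,
                       lfc_down = -2,
                       lfc_weak = -1.5,
                       nb_dispersion = 0.02,
                       dispersion_trend = 16.7,
                       mean_log_range = log(c(20, 2000)),
                       planted_mean_range = c(100, 600),
                       module_mean_range = c(1500, 2000),
                       clique_size = 8,
                       decoy_module_size = 10,
                       n_bridges = 6,
                       background_edge_prob = 0.002,
                       confidence_high = c(2, 2),
                       confidence_low = c(1.5, 5),
                       frac_mouse_specific = 0.05,
                       n_mouse_specific_planted = 4,
                       depth_log_range = log(c(0.75, 4 / 3)),
                       seed = 1) {
  p <- list(n_genes = n_genes, n_per_group = n_per_group,
            frac_down = frac_down, lfc_down = lfc_down, lfc_weak = lfc_weak,
            nb_dispersion = nb_dispersion,
            dispersion_trend = dispersion_trend,
            mean_log_range = mean_log_range,
            planted_mean_range = planted_mean_range,
            module_mean_range = module_mean_range,
            clique_size = clique_size,
            decoy_module_size = decoy_module_size,
            n_bridges = n_bridges,
            background_edge_prob = background_edge_prob,
            confidence_high = confidence_high,
            confidence_low = confidence_low,
            frac_mouse_specific = frac_mouse_specific,
            n_mouse_specific_planted = n_mouse_specific_planted,
            depth_log_range = depth_log_range,
            seed = seed)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  chk_count <- function(field, minimum = 2) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < minimum ||
        v != round(v)) {
      stop(sprintf("invalid parameter '%s': must be an integer >= %d",
                   field, minimum))
    }
  }
  chk_count("n_genes")
  chk_count("n_per_group")
  chk_count("clique_size")
  chk_count("decoy_module_size", 4)
  chk_count("n_bridges")
  chk_count("seed", minimum = -.Machine$integer.max)
  if (p$decoy_module_size %% 2 != 0) {
    stop("invalid parameter 'decoy_module_size': must be even")
  }
  if (!is.numeric(p$frac_down) || p$frac_down <= 0 || p$frac_down >= 1) {
    stop("invalid parameter 'frac_down': must lie in (0, 1)")
  }
  n_down <- round(p$frac_down * p$n_genes)
  if (n_down - p$n_mouse_specific_planted <
      p$clique_size + p$decoy_module_size) {
    stop("invalid parameter 'frac_down': planted set smaller than the ",
         "planted network module")
  }
  if (p$lfc_down > 0) stop("invalid parameter 'lfc_down': must be <= 0")
  if (p$nb_dispersion < 0) {
    stop("invalid parameter 'nb_dispersion': must be >= 0")
  }
  if (p$dispersion_trend < 0) {
    stop("invalid parameter 'dispersion_trend': must be >= 0")
  }
  if (p$background_edge_prob < 0 || p$background_edge_prob > 1) {
    stop("invalid parameter 'background_edge_prob': must lie in [0, 1]")
  }
  if (p$frac_mouse_specific < 0 || p$frac_mouse_specific >= 1) {
    stop("invalid parameter 'frac_mouse_specific': must lie in [0, 1)")
  }
  if (p$n_mouse_specific_planted < 0 ||
      p$n_mouse_specific_planted > floor(p$frac_mouse_specific * p$n_genes)) {
    stop("invalid parameter 'n_mouse_specific_planted': exceeds the ",
         "mouse-specific gene count")
  }
  invisible(p)
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_sim_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Mouse-style casing of a gene symbol
#'
#' Human symbols are conventionally all upper-case (`PSMB8`), mouse symbols
#' capitalize only the first letter (`Psmb8`). This helper converts a symbol
#' to mouse casing; `toupper()` inverts it.
#'
#' @param x character vector of gene symbols.
#' @return Character vector in mouse casing.
#' @export
to_mouse_case <- function(x) {
  paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
}

# deterministic gene universe and planted-role assignment derived from the
# parameter seed; shared genes carry human-cased base symbols, mouse-specific
# genes mouse-only predicted-gene style symbols
study_genes <- function(params) {
  with_sim_seed(params$seed, {
    n_ms <- floor(params$frac_mouse_specific * params$n_genes)
    n_shared <- params$n_genes - n_ms
    shared <- sprintf("GENE%04d", seq_len(n_shared))
    mouse_specific <- if (n_ms > 0) sprintf("Gm%05d", 10000 + seq_len(n_ms))
                      else character(0)
    n_down <- round(params$frac_down * params$n_genes)
    n_down_shared <- n_down - params$n_mouse_specific_planted
    planted_shared <- sort(sample(shared, n_down_shared))
    planted_ms <- if (params$n_mouse_specific_planted > 0) {
      sort(sample(mouse_specific, params$n_mouse_specific_planted))
    } else character(0)
    module_n <- params$clique_size + params$decoy_module_size
    module <- sample(planted_shared, module_n)
    clique <- sort(module[seq_len(params$clique_size)])
    decoy <- module[-seq_len(params$clique_size)]
    half <- params$decoy_module_size / 2
    decoy_a <- sort(decoy[seq_len(half)])
    decoy_b <- sort(decoy[-seq_len(half)])
    hub <- sample(clique, 1)
    n_a <- ceiling(params$n_bridges / 2)
    bridge_targets <- c(decoy_a[seq_len(min(n_a, length(decoy_a)))],
                        decoy_b[seq_len(min(params$n_bridges - n_a,
                                            length(decoy_b)))])
    weak <- setdiff(planted_shared, module)
    list(shared = shared, mouse_specific = mouse_specific,
         planted_shared = planted_shared, planted_ms = planted_ms,
         clique = clique, hub = hub,
         decoy_a = decoy_a, decoy_b = decoy_b,
         bridge_targets = bridge_targets, weak = weak)
  })
}

#' Simulate a two-group RNA-seq count matrix with planted down-regulation
#'
#' Gene means are drawn log-uniformly over `mean_log_range`; per-gene
#' dispersions follow `alpha(mu) = nb_dispersion + dispersion_trend / mu`
#' (flat when the trend is 0). Counts are sampled from a negative binomial
#' with `Var = mu + alpha mu^2` (Poisson when `alpha = 0`), scaled by
#' per-sample depth factors. Planted genes have their `dose`-group mean
#' multiplied by `2^lfc`, with the network-module tier at `lfc_down` and the
#' remaining planted genes at `lfc_weak`. Fully deterministic given
#' `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `synthetic_counts`: `counts` (integer matrix,
#'   genes x samples, mouse-cased rownames), `group` (named character vector
#'   of `"model"` / `"dose"`), `truth_down_genes` (mouse-cased symbols),
#'   `gene_means`, `dispersions`, `lfc` (per-gene simulation truth), and
#'   `roles` (the planted-structure assignment).
#' @export
simulate_counts <- function(params) {
  validate_sim_params(params)
  roles <- study_genes(params)
  with_sim_seed(params$seed + 1L, {
    genes_mouse <- c(to_mouse_case(roles$shared), roles$mouse_specific)
    n <- length(genes_mouse)
    lo <- params$mean_log_range[1]
    hi <- params$mean_log_range[2]
    mu <- exp(stats::runif(n, lo, hi))
    names(mu) <- genes_mouse
    # planted tiers: weak genes at moderate-to-high expression, module genes
    # at the top of the range, hub pinned at the maximum
    weak_all <- to_mouse_case(c(roles$weak, roles$planted_ms))
    mu[weak_all] <- exp(stats::runif(length(weak_all),
                                     log(params$planted_mean_range[1]),
                                     log(params$planted_mean_range[2])))
    module_all <- to_mouse_case(c(roles$clique, roles$decoy_a, roles$decoy_b))
    mu[module_all] <- exp(stats::runif(length(module_all),
                                       log(params$module_mean_range[1]),
                                       log(params$module_mean_range[2])))
    # the hub is the module's standout expresser, twice the band ceiling,
    # so its detection power tops the module the way a consensus hub's
    # significance rank must
    mu[to_mouse_case(roles$hub)] <- 2 * params$module_mean_range[2]
    alpha <- params$nb_dispersion + if (params$dispersion_trend > 0) {
      params$dispersion_trend / mu
    } else 0
    alpha <- rep_len(alpha, n)
    names(alpha) <- genes_mouse
    lfc <- stats::setNames(numeric(n), genes_mouse)
    lfc[weak_all] <- params$lfc_weak
    lfc[module_all] <- params$lfc_down
    n_s <- params$n_per_group
    samples <- c(sprintf("model_%d", seq_len(n_s)),
                 sprintf("dose_%d", seq_len(n_s)))
    group <- stats::setNames(rep(c("model", "dose"), each = n_s), samples)
    depth <- exp(stats::runif(2 * n_s, params$depth_log_range[1],
                              params$depth_log_range[2]))
    mu_mat <- cbind(matrix(mu, n, n_s), matrix(mu * 2^lfc, n, n_s))
    mu_mat <- sweep(mu_mat, 2, depth, "*")
    counts <- matrix(0L, n, 2 * n_s, dimnames = list(genes_mouse, samples))
    flat_mu <- as.vector(mu_mat)
    flat_alpha <- rep(alpha, times = 2 * n_s)
    pois <- flat_alpha == 0
    draws <- numeric(length(flat_mu))
    if (any(pois)) draws[pois] <- stats::rpois(sum(pois), flat_mu[pois])
    if (any(!pois)) {
      draws[!pois] <- stats::rnbinom(sum(!pois), mu = flat_mu[!pois],
                                     size = 1 / flat_alpha[!pois])
    }
    counts[] <- as.integer(draws)
    truth <- sort(c(to_mouse_case(roles$planted_shared), roles$planted_ms))
    structure(list(counts = counts, group = group, truth_down_genes = truth,
                   gene_means = mu, dispersions = alpha, lfc = lfc,
                   roles = roles),
              class = "synthetic_counts")
  })
}

# planted gene-set construction: module genes always included, weak planted
# genes sampled at `frac`, topped up with non-truth decoys while keeping the
# truth fraction of the set at or above `min_overlap`
planted_term_genes <- function(module, weak, decoy_pool, min_overlap,
                               frac = 0.9) {
  truth_part <- c(module, sample(weak, round(frac * length(weak))))
  n_decoy <- floor(length(truth_part) * (1 - min_overlap) / min_overlap)
  n_decoy <- min(n_decoy, length(decoy_pool))
  decoys <- if (n_decoy > 0) sample(decoy_pool, n_decoy) else character(0)
  sort(c(truth_part, decoys))
}

#' Simulate paired human/mouse annotation collections
#'
#' Builds two GO-BP-like collections whose shared terms carry identical
#' names in both species. The planted terms (immune/inflammation names by
#' default) are enriched for the planted down-regulated genes in both
#' species: every network-module gene and about 90% of the weak-tier planted
#' genes appear in each planted term, topped up with decoy genes while
#' keeping the truth fraction at or above `min_overlap`. Mouse gene symbols
#' are the title-cased counterparts of the human symbols, plus
#' species-specific decoy genes on each side.
#'
#' @param genes character vector of human-cased shared gene symbols (the
#'   cross-species universe).
#' @param n_terms_shared number of shared-name terms (default 15), including
#'   the planted ones.
#' @param n_terms_specific number of species-specific terms per species
#'   (default 5).
#' @param planted_terms names of the planted shared terms (default the four
#'   immune/inflammation processes).
#' @param truth_down_genes planted down-regulated genes, human casing.
#' @param seed integer RNG seed.
#' @param module_genes subset of `truth_down_genes` guaranteed to be present
#'   in every planted term (default none beyond sampling).
#' @param mouse_specific_genes extra mouse-only symbols mixed into the mouse
#'   collection (default none).
#' @param mouse_specific_truth mouse-only planted genes to include in the
#'   mouse planted terms (default none).
#' @param min_overlap minimum truth fraction of each planted term
#'   (default 0.8).
#' @return A list with elements `human` and `mouse`, each a
#'   [gene_set_collection()].
#' @export
simulate_annotations <- function(genes, n_terms_shared = 15,
                                 n_terms_specific = 5,
                                 planted_terms = c("immune response",
                                                   "adaptive immune response",
                                                   "immune system process",
                                                   "inflammatory response"),
                                 truth_down_genes, seed,
                                 module_genes = character(0),
                                 mouse_specific_genes = character(0),
                                 mouse_specific_truth = character(0),
                                 min_overlap = 0.8) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("gene universe is empty")
  if (length(planted_terms) > n_terms_shared) {
    stop("planted_terms cannot exceed n_terms_shared")
  }
  truth_down_genes <- intersect(toupper(truth_down_genes), genes)
  module_genes <- intersect(toupper(module_genes), genes)
  weak <- setdiff(truth_down_genes, module_genes)
  decoy_pool <- setdiff(genes, truth_down_genes)
  with_sim_seed(seed, {
    mouse_universe <- c(to_mouse_case(genes), mouse_specific_genes)
    ids_h <- character(0); sets_h <- list(); names_h <- character(0)
    ids_m <- character(0); sets_m <- list(); names_m <- character(0)
    add_term <- function(id, nm, set_h, set_m) {
      ids_h <<- c(ids_h, paste0("H:", id)); names_h <<- c(names_h, nm)
      sets_h[[length(sets_h) + 1]] <<- set_h
      ids_m <<- c(ids_m, paste0("M:", id)); names_m <<- c(names_m, nm)
      sets_m[[length(sets_m) + 1]] <<- set_m
    }
    for (i in seq_along(planted_terms)) {
      set_h <- planted_term_genes(module_genes, weak, decoy_pool, min_overlap)
      ms_decoys <- if (length(mouse_specific_genes) > 0) {
        sample(mouse_specific_genes,
               min(5, length(mouse_specific_genes)))
      } else character(0)
      set_m <- sort(c(to_mouse_case(set_h), mouse_specific_truth, ms_decoys))
      add_term(sprintf("PLANTED%02d", i), planted_terms[i], set_h, set_m)
    }
    n_bg <- n_terms_shared - length(planted_terms)
    for (i in seq_len(n_bg)) {
      nm <- sprintf("shared process %02d", i)
      size_h <- sample(30:120, 1)
      set_h <- sort(sample(genes, size_h))
      set_m <- sort(to_mouse_case(sample(genes, sample(30:120, 1))))
      add_term(sprintf("SHARED%02d", i), nm, set_h, set_m)
    }
    for (i in seq_len(n_terms_specific)) {
      ids_h <- c(ids_h, sprintf("H:ONLY%02d", i))
      names_h <- c(names_h, sprintf("human process %02d", i))
      sets_h[[length(sets_h) + 1]] <- sort(sample(genes, sample(20:80, 1)))
      ids_m <- c(ids_m, sprintf("M:ONLY%02d", i))
      names_m <- c(names_m, sprintf("mouse process %02d", i))
      sets_m[[length(sets_m) + 1]] <-
        sort(sample(mouse_universe, sample(20:80, 1)))
    }
    list(human = gene_set_collection("human", ids_h, sets_h, names_h),
         mouse = gene_set_collection("mouse", ids_m, sets_m, names_m))
  })
}

#' Simulate a KEGG-like pathway collection (mouse)
#'
#' One planted "Apoptosis" pathway contains every planted down-regulated
#' gene; three further planted tumour-suppressive signalling pathways each
#' contain a large random share of them. Background pathways are random gene
#' sets. All symbols are in mouse casing.
#'
#' @param genes_mouse mouse-cased gene universe (all measured genes).
#' @param truth_down_mouse planted down-regulated genes, mouse casing.
#' @param seed integer RNG seed.
#' @param n_background number of background pathways (default 16).
#' @return A [gene_set_collection()] with species `"mouse"`.
#' @export
simulate_pathways <- function(genes_mouse, truth_down_mouse, seed,
                              n_background = 16) {
  genes_mouse <- unique(as.character(genes_mouse))
  if (length(genes_mouse) == 0) stop("gene universe is empty")
  decoy_pool <- setdiff(genes_mouse, truth_down_mouse)
  with_sim_seed(seed, {
    planted_names <- c("Apoptosis", "TNF signaling pathway",
                       "NF-kappa B signaling pathway",
                       "Jak-STAT signaling pathway")
    ids <- character(0); nms <- character(0); sets <- list()
    for (i in seq_along(planted_names)) {
      truth_part <- if (i == 1) truth_down_mouse else {
        sample(truth_down_mouse,
               round(stats::runif(1, 0.6, 0.8) * length(truth_down_mouse)))
      }
      decoys <- sample(decoy_pool, round(0.25 * length(truth_part)))
      ids <- c(ids, sprintf("mmu%05d", 4200 + i))
      nms <- c(nms, planted_names[i])
      sets[[length(sets) + 1]] <- sort(c(truth_part, decoys))
    }
    for (i in seq_len(n_background)) {
      ids <- c(ids, sprintf("mmu%05d", 100 + i))
      nms <- c(nms, sprintf("background pathway %02d", i))
      sets[[length(sets) + 1]] <- sort(sample(genes_mouse,
                                              sample(40:150, 1)))
    }
    gene_set_collection("mouse", ids, sets, nms)
  })
}

# unrank pair indices: maps k in 1..N(N-1)/2 to the k-th pair (i < j) of
# 1..N in row-major order, vectorized and exact for N up to ~40k
unrank_pairs <- function(k, N) {
  k0 <- k - 1
  b <- 2 * N - 1
  r <- floor((b - sqrt(b^2 - 8 * k0)) / 2)
  off <- r * N - r * (r + 1) / 2
  # guard against floating-point off-by-one at segment boundaries
  fix_hi <- k0 < off
  r[fix_hi] <- r[fix_hi] - 1
  off <- r * N - r * (r + 1) / 2
  fix_lo <- k0 >= off + (N - 1 - r)
  r[fix_lo] <- r[fix_lo] + 1
  off <- r * N - r * (r + 1) / 2
  cbind(i = r + 1, j = k0 - off + r + 2)
}

#' Simulate a STRING-like PPI network with a planted hub module
#'
#' Plants (i) a complete clique over `clique_members` with high-confidence
#' edges (always at or above 0.7), (ii) a complete-bipartite decoy module
#' over `decoy_a` x `decoy_b`, likewise high-confidence, and (iii) bridge
#' edges from `planted_hub` to `bridge_targets` inside the decoy module, so
#' that the hub is the only cut vertex between the two dense structures and
#' dominates betweenness and bottleneck while the clique secures its MCODE,
#' MNC and clustering-coefficient membership. Background Erdos-Renyi edges
#' carry low confidence. The graph is simple: no self-loops, duplicate pairs
#' keep the planted (maximum) confidence.
#'
#' @param genes human-cased node universe.
#' @param clique_members clique gene symbols (must include `planted_hub`).
#' @param planted_hub hub gene symbol.
#' @param params a [sim_params()] (confidence and background parameters).
#' @param decoy_a,decoy_b the two sides of the decoy module.
#' @param bridge_targets decoy-module genes the hub bridges to (>= 2).
#' @param seed integer RNG seed (default `params$seed`).
#' @return A [ppi_network()] over `genes`.
#' @export
simulate_ppi <- function(genes, clique_members, planted_hub, params,
                         decoy_a = character(0), decoy_b = character(0),
                         bridge_targets = character(0),
                         seed = params$seed) {
  genes <- unique(as.character(genes))
  if (length(clique_members) > length(genes)) {
    stop("clique is larger than the gene universe")
  }
  if (!planted_hub %in% clique_members) {
    stop("planted_hub must be a clique member")
  }
  stopifnot(all(clique_members %in% genes), all(decoy_a %in% genes),
            all(decoy_b %in% genes),
            all(bridge_targets %in% c(decoy_a, decoy_b)))
  with_sim_seed(seed, {
    rhigh <- function(n) 0.7 + 0.3 * stats::rbeta(n, params$confidence_high[1],
                                                  params$confidence_high[2])
    pairs <- function(v) {
      if (length(v) < 2) return(NULL)
      t(utils::combn(v, 2))
    }
    e_clique <- pairs(clique_members)
    e_decoy <- if (length(decoy_a) > 0 && length(decoy_b) > 0) {
      as.matrix(expand.grid(decoy_a, decoy_b, stringsAsFactors = FALSE))
    } else NULL
    e_bridge <- if (length(bridge_targets) > 0) {
      cbind(planted_hub, bridge_targets)
    } else NULL
    planted <- rbind(e_clique, e_decoy, e_bridge)
    edges <- data.frame(node1 = planted[, 1], node2 = planted[, 2],
                        confidence = rhigh(nrow(planted)),
                        stringsAsFactors = FALSE)
    if (params$background_edge_prob > 0 && length(genes) >= 2) {
      N <- length(genes)
      M <- N * (N - 1) / 2
      n_bg <- stats::rbinom(1, M, params$background_edge_prob)
      if (n_bg > 0) {
        idx <- sample(M, n_bg)
        ij <- unrank_pairs(idx, N)
        bg <- data.frame(node1 = genes[ij[, 1]], node2 = genes[ij[, 2]],
                         confidence = stats::rbeta(n_bg,
                                                   params$confidence_low[1],
                                                   params$confidence_low[2]),
                         stringsAsFactors = FALSE)
        edges <- rbind(edges, bg)
      }
    }
    ppi_network(edges, nodes = genes)
  })
}

#' Generate a complete synthetic screening study
#'
#' Composes the count, annotation, pathway and network simulators into one
#' study object carrying its own ground truth. With default parameters the
#' full pipeline run on the study returns the planted hub as the sole
#' consensus gene.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `synthetic_study`: `counts`, `group`,
#'   `truth_down_genes` (mouse casing), `planted_hub` (human casing),
#'   `module` (planted network structure), `go_human`, `go_mouse`,
#'   `pathways_mouse`, `network`, `params`, `seed`.
#' @export
generate_study <- function(params = sim_params()) {
  validate_sim_params(params)
  sim <- simulate_counts(params)
  roles <- sim$roles
  ann <- simulate_annotations(
    genes = roles$shared,
    truth_down_genes = roles$planted_shared,
    seed = params$seed + 2L,
    module_genes = c(roles$clique, roles$decoy_a, roles$decoy_b),
    mouse_specific_genes = roles$mouse_specific,
    mouse_specific_truth = roles$planted_ms
  )
  pathways <- simulate_pathways(
    genes_mouse = rownames(sim$counts),
    truth_down_mouse = sim$truth_down_genes,
    seed = params$seed + 3L
  )
  network <- simulate_ppi(
    genes = roles$shared,
    clique_members = roles$clique,
    planted_hub = roles$hub,
    params = params,
    decoy_a = roles$decoy_a,
    decoy_b = roles$decoy_b,
    bridge_targets = roles$bridge_targets,
    seed = params$seed + 4L
  )
  study <- structure(
    list(counts = sim$counts, group = sim$group,
         truth_down_genes = sim$truth_down_genes,
         planted_hub = roles$hub,
         module = list(clique = roles$clique, hub = roles$hub,
                       decoy_a = roles$decoy_a, decoy_b = roles$decoy_b,
                       bridge_targets = roles$bridge_targets),
         go_human = ann$human, go_mouse = ann$mouse,
         pathways_mouse = pathways, network = network,
         params = params, seed = params$seed),
    class = "synthetic_study")
  stopifnot(to_mouse_case(study$planted_hub) %in% study$truth_down_genes,
            study$planted_hub %in% network$nodes)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study (seed %d): %d genes x %d samples, ",
                     "%d planted down genes, hub %s\n"),
              x$seed, nrow(x$counts), ncol(x$counts),
              length(x$truth_down_genes), x$planted_hub))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the pipeline's input files: `counts.tsv` (first column `gene`),
#' `samples.tsv` (`sample`, `group`), `go_human.gmt`, `go_mouse.gmt`,
#' `pathways_mouse.gmt`, `ppi_edges.tsv`, and `truth.json` (planted genes,
#' hub, module, seed, parameters).
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_df <- data.frame(gene = rownames(study$counts), study$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(study$group),
                                group = unname(study$group)),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(study$go_human, file.path(dir, "go_human.gmt"))
  write_gmt(study$go_mouse, file.path(dir, "go_mouse.gmt"))
  write_gmt(study$pathways_mouse, file.path(dir, "pathways_mouse.gmt"))
  write_edge_list(study$network, file.path(dir, "ppi_edges.tsv"))
  truth <- list(planted_hub = study$planted_hub,
                truth_down_genes = study$truth_down_genes,
                module = study$module,
                seed = study$seed,
                params = unclass(study$params))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
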