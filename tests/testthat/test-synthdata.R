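# synthetic-study generator: determinism, distributional structure, planting

test_that("parameter validation names the offending field", {
  expect_error(sim_params(n_genes = 1), "n_genes")
  expect_error(sim_params(frac_down = 0), "frac_down")
  expect_error(sim_params(frac_down = 0.004), "frac_down")  # < module size
  expect_error(sim_params(lfc_down = 1), "lfc_down")
  expect_error(sim_params(background_edge_prob = 2), "background_edge_prob")
  expect_error(sim_params(decoy_module_size = 7), "decoy_module_size")
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_counts(sim_params(seed = 11))
  b <- simulate_counts(sim_params(seed = 11))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth_down_genes, b$truth_down_genes)
  s1 <- generate_study(sim_params(seed = 12))
  s2 <- generate_study(sim_params(seed = 12))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$network$edges, s2$network$edges)
  expect_identical(s1$go_human$genes, s2$go_human$genes)
  expect_identical(s1$planted_hub, s2$planted_hub)
  c2 <- simulate_counts(sim_params(seed = 13))
  expect_false(identical(a$counts, c2$counts))
})

test_that("planted gene count follows frac_down arithmetic", {
  sim <- simulate_counts(sim_params(seed = 2, frac_down = 0.1))
  expect_length(sim$truth_down_genes, 200)
  expect_true(all(sim$truth_down_genes %in% rownames(sim$counts)))
})

test_that("null effect leaves group means balanced", {
  # equal depth so raw group means are directly comparable
  sim <- simulate_counts(sim_params(seed = 21, lfc_down = 0, lfc_weak = 0,
                                    depth_log_range = c(0, 0)))
  m1 <- rowMeans(sim$counts[, sim$group == "model"])
  m2 <- rowMeans(sim$counts[, sim$group == "dose"])
  # depth factors are drawn symmetrically around 1; ratios center at 1
  expect_lt(abs(stats::median(log2((m2 + 0.5) / (m1 + 0.5)))), 0.1)
  truth_ratio <- stats::median(log2((m2 + 0.5) / (m1 + 0.5))[sim$truth_down_genes])
  expect_lt(abs(truth_ratio), 0.2)
})

test_that("counts match negative-binomial moments", {
  # Poisson limit: dispersion 0 gives variance ~ mean
  pois <- simulate_counts(sim_params(seed = 23, n_genes = 1000,
                                     n_per_group = 25, frac_down = 0.02,
                                     lfc_down = 0, lfc_weak = 0,
                                     clique_size = 2, decoy_module_size = 4,
                                     n_bridges = 2,
                                     n_mouse_specific_planted = 0,
                                     nb_dispersion = 0, dispersion_trend = 0,
                                     depth_log_range = c(0, 0)))
  vm <- apply(pois$counts, 1, stats::var) / rowMeans(pois$counts)
  expect_lt(abs(stats::median(vm) - 1), 0.1)

  # NB: empirical moments within 3 standard errors at 10,000 draws per cell
  p <- sim_params(seed = 24, n_genes = 10, n_per_group = 5000,
                  frac_down = 0.9, lfc_down = 0, lfc_weak = 0,
                  clique_size = 2, decoy_module_size = 4, n_bridges = 2,
                  nb_dispersion = 0.2, dispersion_trend = 0,
                  n_mouse_specific_planted = 0,
                  depth_log_range = c(0, 0))
  sim <- simulate_counts(p)
  n_draw <- ncol(sim$counts)
  for (g in rownames(sim$counts)) {
    x <- sim$counts[g, ]
    mu <- sim$gene_means[g]
    sig2 <- mu + 0.2 * mu^2
    se_mean <- sqrt(sig2 / n_draw)
    expect_lt(abs(mean(x) - mu), 3 * se_mean)
    # SE of the sample variance of an NB via the fourth-moment formula is
    # awkward; a generous 4th-moment-free bound: relative error < 10%
    expect_lt(abs(stats::var(x) - sig2) / sig2, 0.1)
  }
})

test_that("annotation collections share planted terms with correct casing", {
  study <- generate_study(sim_params(seed = 14))
  ann_h <- study$go_human; ann_m <- study$go_mouse
  shared <- match_shared_terms(ann_h$names, ann_m$names)
  expect_true(all(c("immune response", "inflammatory response") %in% shared))
  # species-specific extras keep the name sets different
  expect_gt(length(ann_h$names), length(shared))

  # planted term truth overlap >= 80% by construction
  planted_h <- ann_h$genes[[which(ann_h$names == "immune response")]]
  truth_h <- toupper(study$truth_down_genes)
  expect_gte(mean(planted_h %in% truth_h), 0.8)

  # mouse planted sets are title-cased counterparts of human symbols
  planted_m <- ann_m$genes[[which(ann_m$names == "immune response")]]
  expect_true(all(to_mouse_case(planted_h) %in% planted_m))
  expect_true(any(grepl("^Gm", planted_m)))  # mouse-specific members exist
})

test_that("identical shared-term names when no species-specific terms", {
  ann <- simulate_annotations(sprintf("GENE%03d", 1:200),
                              n_terms_specific = 0,
                              truth_down_genes = sprintf("GENE%03d", 1:30),
                              seed = 7)
  expect_equal(sort(ann$human$names), sort(ann$mouse$names))
})

test_that("the planted network structure behaves as designed", {
  p <- sim_params(seed = 15)
  study <- generate_study(p)
  mod <- study$module
  # all clique edges survive the 0.7 filter by construction
  strict <- filter_by_confidence(study$network, 0.7)
  cl <- induced_subnetwork(strict, mod$clique)$network
  expect_equal(n_edges(cl), choose(length(mod$clique), 2))
  expect_true(all(clustering_coefficient(cl) == 1))
  # hub bridges into the decoy module
  hub_edges <- strict$edges[strict$edges$node1 == mod$hub |
                              strict$edges$node2 == mod$hub, ]
  partners <- setdiff(unique(c(hub_edges$node1, hub_edges$node2)), mod$hub)
  expect_true(all(mod$bridge_targets %in% partners))
  expect_gte(length(intersect(partners, c(mod$decoy_a, mod$decoy_b))), 2)

  # background_edge_prob = 0 leaves exactly the planted edges
  p0 <- sim_params(seed = 15, background_edge_prob = 0)
  net0 <- generate_study(p0)$network
  expected <- choose(p0$clique_size, 2) +
    (p0$decoy_module_size / 2)^2 + p0$n_bridges
  expect_equal(n_edges(net0), expected)
})

test_that("the study object satisfies its invariants", {
  study <- generate_study(sim_params(seed = 16))
  expect_true(all(study$truth_down_genes %in% rownames(study$counts)))
  expect_true(to_mouse_case(study$planted_hub) %in% study$truth_down_genes)
  expect_true(study$planted_hub %in% study$network$nodes)
  expect_equal(sort(unique(unname(study$group))), c("dose", "model"))
  # mouse-specific symbols are absent from the human network
  expect_false(any(grepl("^Gm", study$network$nodes)))
})

test_that("studies round-trip through the on-disk representation", {
  study <- generate_study(sim_params(seed = 18))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  inputs <- read_pipeline_inputs(file.path(dir, "counts.tsv"),
                                 file.path(dir, "samples.tsv"),
                                 file.path(dir, "go_human.gmt"),
                                 file.path(dir, "go_mouse.gmt"),
                                 file.path(dir, "pathways_mouse.gmt"),
                                 file.path(dir, "ppi_edges.tsv"))
  expect_equal(inputs$counts, study$counts)
  expect_equal(unname(inputs$group), unname(study$group))
  expect_equal(inputs$network$edges$node1, study$network$edges$node1)
  expect_equal(inputs$network$edges$confidence,
               study$network$edges$confidence, tolerance = 1e-12)
  expect_equal(inputs$go_human$genes, study$go_human$genes)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$planted_hub, study$planted_hub)
})
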