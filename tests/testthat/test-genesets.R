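# GMT handling, hypergeometric enrichment, cross-species matching, ranking

test_that("GMT files round-trip and report format errors with line numbers", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\timmune response\tA\tB\tC"), path)
  coll <- read_gmt(path)
  expect_length(coll, 1)
  expect_equal(coll$genes[["T1"]], c("A", "B", "C"))
  expect_equal(coll$names, "immune response")

  coll2 <- gene_set_collection("mouse", c("a", "b"),
                               list(c("X", "Y"), c("Z")),
                               names = c("term a", "term b"))
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll2, out)
  back <- read_gmt(out, species = "mouse")
  expect_equal(back$ids, coll2$ids)
  expect_equal(back$names, coll2$names)
  expect_equal(back$genes, coll2$genes)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tok\tA", "", "T2\tonly-two-fields"), bad)
  expect_error(read_gmt(bad), "line 3")

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines("T1\tdesc\tA\tB\tA", dup)
  expect_warning(colld <- read_gmt(dup), "duplicated")
  expect_equal(colld$genes[["T1"]], c("A", "B"))
})

test_that("hypergeometric tail matches enumeration on worked examples", {
  expect_equal(hypergeom_tail(10, 5, 4, 0), 1)
  # C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(hypergeom_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-14)
  # C(2,2) C(2,0) / C(4,2) = 1/6
  expect_equal(hypergeom_tail(4, 2, 2, 2), 1 / 6, tolerance = 1e-14)
  expect_error(hypergeom_tail(10, 12, 4, 1), "universe")
  expect_error(hypergeom_tail(10, 5, 4, 5), "overlap")
})

test_that("hypergeometric tail equals pmf summation for every N <= 25", {
  worst <- 0
  for (N in 2:25) for (K in 1:N) for (n in 1:N) {
    for (k in 0:min(K, n)) {
      worst <- max(worst, abs(hypergeom_tail(N, K, n, k) -
                                oracle_hyper_tail(N, K, n, k)))
    }
    # non-increasing in k
    tails <- vapply(0:min(K, n), function(k) hypergeom_tail(N, K, n, k),
                    numeric(1))
    expect_true(all(diff(tails) <= 1e-14))
  }
  expect_lt(worst, 1e-12)
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # permutation invariance
  withr::with_seed(5, {
    p <- stats::runif(50)
    perm <- sample(50)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
    expect_true(all(bh_adjust(p) >= p))
  })
})

test_that("enrichment handles edge cases and orders by (q, p, term_id)", {
  coll <- gene_set_collection("human", c("T1", "T2"),
                              list(c("A", "B", "C"), c("D", "E")))
  uni <- c("A", "B", "C", "D", "E")
  res <- enrich(c("A", "B", "C", "D", "E"), coll, uni)
  expect_equal(res$p, c(1, 1))  # query == universe
  expect_equal(res$term_id, c("T1", "T2"))  # tie broken by term_id

  expect_equal(nrow(enrich("Z", coll, c(uni, "Z"))), 0)
  expect_error(enrich("A", coll, character(0)), "universe")
  expect_warning(enrich(c("A", "OUTSIDE"), coll, uni), "outside")

  # permutation invariance in query order
  withr::with_seed(3, {
    uni2 <- sprintf("G%03d", 1:60)
    coll2 <- gene_set_collection("human", c("X", "Y"),
                                 list(uni2[1:20], uni2[15:40]))
    q <- sample(uni2, 25)
    expect_identical(enrich(q, coll2, uni2), enrich(rev(q), coll2, uni2))
  })
})

test_that("enriched planted terms rank top in both species of a synthetic study", {
  study <- generate_study(sim_params(seed = 5))
  down_truth <- study$truth_down_genes
  uni_m <- intersect(rownames(study$counts), collection_genes(study$go_mouse))
  res_m <- enrich(intersect(down_truth, uni_m), study$go_mouse, uni_m)
  uni_h <- intersect(toupper(rownames(study$counts)),
                     collection_genes(study$go_human))
  res_h <- enrich(intersect(toupper(down_truth), uni_h), study$go_human, uni_h)
  planted <- c("immune response", "adaptive immune response",
               "immune system process", "inflammatory response")
  expect_true(all(planted %in% top_terms(res_m, 5)$term_name))
  expect_true(all(planted %in% top_terms(res_h, 5)$term_name))
})

test_that("top_terms truncates deterministically", {
  df <- data.frame(term_id = c("A", "B", "C"), q = c(0.1, 0.2, 0.3))
  expect_equal(nrow(top_terms(df, 5)), 3)
  df10 <- data.frame(term_id = letters[1:10], q = seq(0.01, 0.1, 0.01))
  expect_equal(nrow(top_terms(df10, 5)), 5)
})

test_that("shared term matching is case- and whitespace-insensitive", {
  expect_equal(match_shared_terms("Immune  response ", "immune response"),
               "immune response")
  expect_equal(match_shared_terms(c("a"), c("b")), character(0))
})

test_that("ortholog intersection matches symbols after upper-casing", {
  expect_equal(intersect_orthologs("Psmb8", "PSMB8"), "PSMB8")
  expect_equal(intersect_orthologs(c("Aaa"), c("BBB")), character(0))
  expect_equal(intersect_orthologs(c("Aaa", "Gm123"), c("AAA", "CCC")), "AAA")
  # symmetric up to casing of output
  m <- c("Abc", "Def"); h <- c("DEF", "XYZ")
  expect_equal(toupper(intersect_orthologs(m, h)),
               toupper(intersect_orthologs(to_mouse_case(h), toupper(m))))
})

test_that("top-fraction selection uses the ceiling rule", {
  genes61 <- sprintf("G%02d", 1:61)
  expect_length(select_top_fraction(genes61, 0.25), 16)
  expect_equal(select_top_fraction(genes61, 0.25), genes61[1:16])
  expect_length(select_top_fraction(sprintf("G%d", 1:4), 0.25), 1)
  expect_length(select_top_fraction(sprintf("G%d", 1:16), 0.25), 4)
  expect_error(select_top_fraction(genes61, 0), "fraction")
  expect_error(select_top_fraction(genes61, 1.1), "fraction")
  # prefix property across random sizes
  withr::with_seed(2, {
    for (i in 1:10) {
      n <- sample(1:200, 1)
      f <- stats::runif(1, 0.05, 1)
      g <- sprintf("G%03d", seq_len(n))
      sel <- select_top_fraction(g, f)
      expect_length(sel, ceiling(f * n))
      expect_equal(sel, g[seq_along(sel)])
    }
  })
})
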