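test_that("best hit minimizes e-value then maximizes HSP length, stably", {
  h <- toy_hits(c(1, 1, 1), c(200, 300, 500),
                evalue = c(1e-50, 1e-50, 1e-10))
  bh <- best_hit(h)
  expect_equal(bh$evalue, 1e-50)
  expect_equal(bh$length, 300)
  expect_null(best_hit(h[0, ]))
  expect_equal(best_hit(h[3, ])$length, 500)
  # remaining ties resolve to input order
  tie <- toy_hits(c(1, 10), c(100, 109), evalue = 1e-5)
  expect_equal(best_hit(tie)$qstart, 1)
})

test_that("covered fraction merges query intervals and clips out-of-range hits", {
  expect_equal(covered_fraction(100, toy_hits(c(1, 41), c(50, 90))), 0.90)
  expect_equal(covered_fraction(100, NULL), 0)
  expect_equal(covered_fraction(100, toy_hits(1, 100)), 1.0)
  # overlapping + disjoint segments
  expect_equal(covered_fraction(100, toy_hits(c(1, 20, 60), c(30, 40, 70))),
               (40 + 11) / 100)
  expect_warning(cov <- covered_fraction(50, toy_hits(40, 80)), "clipped")
  expect_equal(cov, 11 / 50)
})

test_that("presence calls use the strict >90% deletion rule", {
  th <- missp_thresholds()
  expect_false(call_presence(100, toy_hits(1, 5), th)$present)    # 5% covered
  expect_true(call_presence(100, toy_hits(1, 10), th)$present)    # exactly 10%
  expect_true(call_presence(100, toy_hits(1, 95), th)$present)
  expect_false(call_presence(100, NULL, th)$present)
  ev <- call_presence(100, toy_hits(c(1, 1), c(40, 95),
                                    evalue = c(1e-80, 1e-60)), th)
  expect_equal(ev$best_evalue, 1e-80)
  expect_equal(ev$best_hsp_length, 40)
})

test_that("Jaccard distances follow the binary definition and the empty-union rule", {
  m <- cbind(x = c(1, 1, 0, 1), y = c(1, 0, 0, 1), z = c(1, 1, 0, 1))
  d <- jaccard_distances(m)
  expect_equal(d["x", "y"], 1 / 3)
  expect_equal(d["x", "z"], 0)
  expect_equal(diag(d), setNames(rep(0, 3), c("x", "y", "z")))
  disj <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(jaccard_distances(disj)["a", "b"], 1)
  empty <- cbind(a = c(0, 0), b = c(0, 0))
  expect_message(d0 <- jaccard_distances(empty), "empty union")
  expect_equal(d0["a", "b"], 0)
})

test_that("Jaccard distance agrees with the base binary metric and is a metric", {
  set.seed(404)
  for (i in 1:20) {
    m <- random_binary_matrix(30, 6)
    # guard against all-zero columns (oracle undefined there)
    m[1, colSums(m) == 0] <- 1L
    d <- jaccard_distances(m)
    oracle <- as.matrix(stats::dist(t(m), method = "binary"))
    expect_equal(unname(d), unname(oracle), tolerance = 1e-12)
    expect_equal(d, t(d))
    # triangle inequality over all triples
    for (a in 1:5) for (b in (a + 1):6) for (cc in 1:6)
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
  }
})

test_that("PCO reproduces analytic eigensystems and embeds Euclidean data exactly", {
  # equilateral triple at unit distance
  eq <- pco(matrix(1, 3, 3) - diag(3))
  expect_equal(eq$eigenvalues, c(0.5, 0.5, 0), tolerance = 1e-8)
  # two points at distance 2: one axis, eigenvalue 2, coordinates +-1
  two <- pco(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(two$eigenvalues[1], 2, tolerance = 1e-8)
  expect_equal(sort(two$points[, 1]), c(-1, 1), tolerance = 1e-8)
  # all-zero distances: all eigenvalues zero, no axes
  z <- pco(matrix(0, 4, 4))
  expect_equal(z$eigenvalues, rep(0, 4), tolerance = 1e-10)
  expect_equal(ncol(z$points), 0)
  # round trip on Euclidean-embeddable distances
  set.seed(505)
  pts <- matrix(rnorm(7 * 3), 7, 3)
  D <- as.matrix(dist(pts))
  emb <- pco(D)
  expect_equal(as.matrix(dist(emb$points)), D, tolerance = 1e-6,
               ignore_attr = TRUE)
  # eigenvalues match classical scaling
  cmd <- stats::cmdscale(D, k = 3, eig = TRUE)
  expect_equal(emb$eigenvalues[1:3], cmd$eig[1:3], tolerance = 1e-8)
  expect_error(pco(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
})

test_that("PERMANOVA reproduces the worked four-sample example exactly", {
  d <- matrix(2, 4, 4); d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1
  diag(d) <- 0
  res <- permanova(d, c("A", "A", "B", "B"))
  expect_equal(res$F, 7, tolerance = 1e-12)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_equal(unname(res$df), c(1, 2))
  # all-equal distances: F constant under permutation, p = 1
  flat <- matrix(1, 4, 4); diag(flat) <- 0
  expect_equal(permanova(flat, c("A", "A", "B", "B"))$p, 1)
  expect_error(permanova(d, c("A", "A", "A", "A")), "level|all samples")
})

test_that("PERMANOVA pseudo-F matches brute force and vegan on random instances", {
  set.seed(606)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    d <- as.matrix(dist(pts))
    g <- sample(rep(c("A", "B"), length.out = n))
    res <- permanova(d, g)
    expect_equal(res$F, permanova_f_oracle(d, g), tolerance = 1e-10)
  }
  if (requireNamespace("vegan", quietly = TRUE)) {
    set.seed(607)
    pts <- matrix(rnorm(12 * 3), 12, 3)
    d <- as.matrix(dist(pts))
    g <- rep(c("A", "B", "C"), each = 4)
    res <- permanova(d, g, n_perm = 99, seed = 1)
    vg <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
    expect_equal(res$F, vg$F[1], tolerance = 1e-8)
  }
})

test_that("exhaustive and sampled PERMANOVA p-values agree within Monte Carlo error", {
  set.seed(608)
  pts <- matrix(rnorm(7 * 2), 7, 2)
  d <- as.matrix(dist(pts))
  g <- c("A", "A", "A", "B", "B", "B", "B")
  exact <- permanova(d, g)$p
  mc <- permanova(d, g, n_perm = 1e4, seed = 42, exhaustive_limit = 1)
  se <- sqrt(exact * (1 - exact) / 1e4)
  expect_lt(abs(mc$p - exact), 3 * se + 2 / 1e4)
})

test_that("conservation classes split core / genus-conserved / dispersed exhaustively", {
  calls <- rbind(core = c(1, 1, 1, 1),
                 genus = c(1, 1, 0, 1),
                 disp = c(0, 1, 1, 1))
  colnames(calls) <- c("s1", "s2", "og1", "og2")
  pav <- list(calls = calls,
              is_outgroup = c(s1 = FALSE, s2 = FALSE, og1 = TRUE, og2 = TRUE))
  cc <- conservation_classes(pav)
  expect_equal(as.character(cc$classes[c("core", "genus", "disp")]),
               c("core", "genus_conserved", "dispersed"))
  expect_equal(sum(cc$counts), nrow(calls))
  # no outgroup: two-class fallback with a notice
  pav2 <- list(calls = calls[, 1:2], is_outgroup = c(s1 = FALSE, s2 = FALSE))
  expect_message(cc2 <- conservation_classes(pav2), "fallback")
  expect_equal(levels(cc2$classes), c("conserved", "dispersed"))
})

test_that("the statement fixture yields the recorded conservation counts", {
  fx <- load_fixtures()
  cc <- conservation_classes(fx$presence)
  expect_equal(as.integer(cc$counts["core"]), 2)
  expect_equal(as.integer(cc$counts["genus_conserved"]), 6)
  expect_equal(as.integer(cc$counts["dispersed"]), 14)
})

test_that("hit tables round-trip through the 12-column tabular format", {
  h <- toy_hits(c(5, 90), c(60, 10), evalue = c(1e-20, 1e-3),
                len = c(56, 81))
  f <- tempfile(fileext = ".tsv")
  write_hit_table(h, f)
  back <- read_hit_table(f)
  expect_equal(nrow(back), 2)
  expect_true(all(back$qstart <= back$qend))  # normalized on read
  expect_equal(back$evalue, c(1e-20, 1e-3))
  empty <- read_hit_table(tempfile_empty_file())
  expect_equal(nrow(empty), 0)
})
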