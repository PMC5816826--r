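test_that("FIRs measure the bases strictly between adjacent genes, strand-aware", {
  firs <- compute_firs(toy_genes())
  b <- firs[firs$gene_id == "b", ]
  expect_equal(b$fir5_bp, 300)    # 501 - 200 - 1
  expect_equal(b$fir3_bp, 1300)   # 2001 - 700 - 1
  # contig edges are undefined on the edge side
  a <- firs[firs$gene_id == "a", ]
  expect_true(is.na(a$fir5_bp)); expect_equal(a$fir3_bp, 300)
  # minus strand swaps 5'/3'
  g <- toy_genes(); g$strand[2] <- "-"
  bm <- compute_firs(g)[2, ]
  expect_equal(bm$fir5_bp, 1300)
  expect_equal(bm$fir3_bp, 300)
  # single gene on a contig: both undefined, region unassigned
  solo <- compute_firs(data.frame(gene_id = "s", contig = "tigX",
                                  start = 10, end = 20, strand = "+"))
  expect_true(is.na(solo$fir5_bp) && is.na(solo$fir3_bp))
  expect_equal(as.character(classify_region(solo)$region), "unassigned")
  # overlaps clamp to zero with a warning; duplicate ids error
  ovl <- data.frame(gene_id = c("x", "y"), contig = "t",
                    start = c(1, 50), end = c(100, 150), strand = "+")
  expect_warning(fo <- compute_firs(ovl), "clamped")
  expect_equal(fo$fir3_bp[1], 0)
  expect_error(compute_firs(data.frame(gene_id = c("x", "x"), contig = "t",
                                       start = c(1, 200), end = c(100, 300),
                                       strand = "+")), "duplicate")
})

test_that("FIRs are invariant to coordinate translation and contig reversal", {
  set.seed(303)
  n <- 40
  lens <- sample(100:900, n, replace = TRUE)
  gaps <- sample(0:5000, n, replace = TRUE)
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n])) + 1
  g <- data.frame(gene_id = paste0("g", 1:n), contig = "t",
                  start = starts, end = starts + lens - 1,
                  strand = sample(c("+", "-"), n, replace = TRUE))
  base <- compute_firs(g)
  shifted <- g; shifted$start <- g$start + 7777; shifted$end <- g$end + 7777
  expect_equal(compute_firs(shifted)[, c("fir5_bp", "fir3_bp")],
               base[, c("fir5_bp", "fir3_bp")])
  L <- max(g$end) + 500
  mirrored <- data.frame(gene_id = g$gene_id, contig = "t",
                         start = L - g$end + 1, end = L - g$start + 1,
                         strand = ifelse(g$strand == "+", "-", "+"))
  mir <- compute_firs(mirrored)
  mir <- mir[match(base$gene_id, mir$gene_id), ]
  expect_equal(mir$fir5_bp, base$fir5_bp)
  expect_equal(mir$fir3_bp, base$fir3_bp)
})

test_that("GDR/GSR classification is strict at the cutoff and one-sided-aware", {
  th <- missp_thresholds()
  mk <- function(f5, f3) data.frame(gene_id = "g", fir5_bp = f5,
                                    fir3_bp = f3)
  cls <- function(f5, f3) as.character(classify_region(mk(f5, f3), th)$region)
  expect_equal(cls(7000, 50), "GSR")       # 5' and/or 3' above cutoff
  expect_equal(cls(6495, 6495), "GDR")     # at the cutoff is not above it
  expect_equal(cls(6496, 0), "GSR")        # one bp over
  expect_equal(cls(NA, 100), "GDR")        # single defined flank, short
  expect_equal(cls(NA, 10000), "GSR")      # single defined flank, long
  expect_equal(cls(NA, NA), "unassigned")
})

test_that("heatmap binning conserves gene counts and averages overlays", {
  firs <- data.frame(gene_id = c("a", "b", "c", "edge"),
                     fir5_bp = c(100, 2000, 0, NA),
                     fir3_bp = c(50, 300, 10, 200))
  hm <- bin_heatmap(firs)
  expect_equal(sum(hm$counts), 3)          # only genes with both FIRs
  expect_equal(hm$n_excluded, 1)
  ov <- bin_heatmap(firs, overlay = list(v = setNames(rep(2.5, 3),
                                                      c("a", "b", "c"))))
  vals <- ov$overlays$v[ov$counts > 0]
  expect_true(all(vals == 2.5))
  empty <- bin_heatmap(firs[0, ])
  expect_equal(sum(empty$counts), 0)
})

test_that("compartment composition reports GSR fractions with exact enrichment p", {
  regions <- data.frame(
    gene_id = paste0("g", 1:8),
    region = factor(rep(c("GSR", "GDR"), each = 4),
                    levels = c("GDR", "GSR", "unassigned")))
  catalog <- data.frame(
    protein_id = paste0("g", c(1, 2, 3, 5)),
    sp_class = factor("SSP", levels = sp_class_levels()))
  comp <- region_composition(catalog, regions)
  ssp <- comp[comp$category == "SSP", ]
  expect_equal(ssp$gsr_fraction, 3 / 4)
  expect_equal(ssp$p_enrich, 17 / 70, tolerance = 1e-12)
  expect_equal(comp$gsr_fraction[comp$category == "genome"], 0.5)
  expect_equal(comp$p_enrich[comp$category == "genome"], 1)  # whole universe
  expect_true(is.na(comp$gsr_fraction[comp$category == "lipase"]))
  # all-GDR genome: every fraction zero
  regions$region[] <- "GDR"
  comp0 <- region_composition(catalog, regions)
  expect_true(all(comp0$gsr_fraction[!is.na(comp0$gsr_fraction)] == 0))
})

test_that("SSPs planted preferentially in sparse blocks come out GSR-enriched", {
  cfg <- sim_config(seed = 5, n_genes = 2000, n_contigs = 8, frac_gsr = 0.3)
  sim <- simulate_genome(cfg)
  firs <- classify_region(compute_firs(sim$genes))
  truth <- setNames(sim$truth_region$region, sim$truth_region$gene_id)
  # plant SSPs 2x more often among GSR genes
  set.seed(6)
  gsr_ids <- names(truth)[truth == "GSR"]
  gdr_ids <- names(truth)[truth == "GDR"]
  ssp_ids <- c(sample(gsr_ids, 120), sample(gdr_ids, 120))
  catalog <- data.frame(protein_id = ssp_ids,
                        sp_class = factor("SSP", levels = sp_class_levels()))
  comp <- region_composition(catalog, firs)
  ssp <- comp[comp$category == "SSP", ]
  genome <- comp[comp$category == "genome", ]
  expect_gt(ssp$gsr_fraction, genome$gsr_fraction)
  expect_lt(ssp$p_enrich, 0.05)
})

test_that("rank-sum comparison of compartment expression matches the exact extreme case", {
  regions <- data.frame(
    gene_id = paste0("g", 1:10),
    region = factor(rep(c("GSR", "GDR"), each = 5),
                    levels = c("GDR", "GSR", "unassigned")))
  vals <- setNames(c(1:5, 11:15), paste0("g", 1:10))  # GSR strictly below GDR
  res <- expression_by_region(vals, regions)
  expect_equal(res$median_gsr, 3)
  expect_equal(res$median_gdr, 13)
  # complete separation at 5 vs 5: exact two-sided p = 2/choose(10,5)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # empty compartment: comparison skipped with a notice
  sub <- regions[regions$region == "GSR", ]
  expect_message(res2 <- expression_by_region(vals[1:5], sub), "skipped")
  expect_true(is.na(res2$p_value))
})
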