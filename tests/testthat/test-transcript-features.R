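test_that("cpmk is library- and length-normalized density", {
  expect_equal(cpmk(100, 2000, 1e6), 50)
  expect_equal(cpmk(0, 5000, 3e6), 0)
  expect_equal(cpmk(100, 2000, 2e6), cpmk(100, 2000, 1e6) / 2)
  expect_error(cpmk(10, 0, 1e6), "length")
  expect_error(cpmk(10, 1000, 0), "positive")
})

test_that("median matching picks the largest best prefix of top-density genes", {
  # labeled median 5; prefix medians 10, 9.5, 9, 8, 7, 6, 5 -> k = 7
  m <- match_unlabeled_by_median(c(4, 5, 6), c(10, 9, 7, 5, 3, 2, 1),
                                 tol = 0)
  expect_equal(attr(m, "k"), 7)
  expect_equal(sort(unname(m)), c(1, 2, 3, 5, 7, 9, 10))
  # a full set whose median already matches is returned whole
  full <- match_unlabeled_by_median(c(5), c(9, 5, 1), tol = 0)
  expect_equal(attr(full, "k"), 3)
  expect_error(match_unlabeled_by_median(numeric(0), 1:5, 0), "non-empty")
  expect_error(match_unlabeled_by_median(c(100), c(1, 2), tol = 1),
               "best \\|difference\\|")
})

test_that("matched subsets always land within tolerance (random instances)", {
  set.seed(55)
  for (i in 1:300) {
    lab <- rlnorm(sample(3:30, 1), 1, 1)
    unl <- rlnorm(sample(5:80, 1), 1.3, 1)
    tol <- stats::median(lab) * 0.5
    m <- tryCatch(match_unlabeled_by_median(lab, unl, tol),
                  error = function(e) NULL)
    if (is.null(m)) next
    expect_lte(abs(stats::median(m) - stats::median(lab)), tol + 1e-12)
    expect_equal(abs(attr(m, "median_diff")),
                 abs(stats::median(m) - stats::median(lab)),
                 tolerance = 1e-12)
  }
})

test_that("read-through ratio is strand-aware and scale-invariant", {
  # + gene [1000, 2000), body mean 10; downstream [2000, 12000) mean 5
  track <- data.frame(chrom = "chr1", start = c(1000, 2000),
                      end = c(2000, 12000), value = c(10, 5))
  gene <- list(chrom = "chr1", start = 1000, end = 2000, strand = "+")
  expect_equal(as.numeric(readthrough_ratio(track, gene, 1e6)), 0.5)
  # scaling the track leaves the ratio unchanged
  track2 <- track; track2$value <- track2$value * 3.7
  expect_equal(as.numeric(readthrough_ratio(track2, gene, 1e6)), 0.5)
  # - gene: downstream lies upstream in genomic coordinates
  gene_m <- list(chrom = "chr1", start = 20000, end = 21000, strand = "-")
  track_m <- data.frame(chrom = "chr1", start = c(20000, 10000),
                        end = c(21000, 20000), value = c(4, 1))
  expect_equal(as.numeric(readthrough_ratio(track_m, gene_m, 1e6)), 0.25)
  # zero downstream coverage gives 0; zero body coverage is undefined
  gene2 <- list(chrom = "chr1", start = 1000, end = 2000, strand = "-")
  r0 <- readthrough_ratio(track, gene2, 1e6, downstream_bp = 500)
  expect_equal(as.numeric(r0), 0)
  nocov <- data.frame(chrom = "chr1", start = 5000, end = 6000, value = 2)
  rna <- readthrough_ratio(nocov, gene, 1e6)
  expect_true(is.na(rna))
  expect_false(attr(rna, "defined"))
})

test_that("inverted SINE pairs need opposite strands and a shared family", {
  reps <- data.frame(
    chrom = "chr1",
    start = c(100, 600, 1200, 2000), end = c(400, 900, 1500, 2300),
    strand = c("+", "-", "+", "-"),
    family = c("Alu", "Alu", "Alu", "MIR"), stringsAsFactors = FALSE
  )
  region <- list(chrom = "chr1", start = 0, end = 1000)
  pairs <- find_inverted_sine_pairs(reps, region)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$gap, 200)
  # same strand and cross-family pairs are rejected
  same <- reps; same$strand <- "+"
  expect_equal(nrow(find_inverted_sine_pairs(same, region)), 0)
  wide <- list(chrom = "chr1", start = 0, end = 2500)
  expect_equal(nrow(find_inverted_sine_pairs(reps, wide)), 2)  # Alu+/Alu-
  expect_equal(nrow(find_inverted_sine_pairs(reps, wide,
                                             same_family = FALSE)), 4)
  expect_equal(nrow(find_inverted_sine_pairs(reps, wide, max_gap = 250)),
               1)
  # input order does not change the count; growing the region never loses one
  shuf <- reps[c(3, 1, 4, 2), ]
  expect_equal(nrow(find_inverted_sine_pairs(shuf, wide)), 2)
  expect_gte(nrow(find_inverted_sine_pairs(reps, wide)),
             nrow(find_inverted_sine_pairs(reps, region)))
})

test_that("editing filter keeps strand-consistent A-to-G calls off SNPs", {
  events <- data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 40, 50),
    ref = c("A", "T", "A", "C", "A"),
    alt = c("G", "C", "G", "T", "G"),
    alt_count = 1, coverage = 10,
    gene_strand = c("+", "-", "+", "+", "-"), stringsAsFactors = FALSE
  )
  snps <- data.frame(chrom = "chr1", pos = 30)
  kept <- filter_edit_events(events, snps)
  # pos 10 (A>G, +), pos 20 (T>C, -) survive; pos 30 is a SNP; pos 40 is a
  # non-editing substitution; pos 50 is A>G on a minus-strand gene
  expect_equal(kept$pos, c(10, 20))
})

test_that("per-repeat edited fraction is summed alt over summed coverage", {
  reps <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200))
  ev <- data.frame(chrom = "chr1", pos = c(10, 50, 150),
                   alt_count = c(3, 1, 10), coverage = c(10, 10, 10))
  out <- summarize_repeat_editing(ev, reps)
  expect_equal(out$edited_fraction, c(0.2, 1.0))
  expect_equal(out$n_events, c(2L, 1L))
  none <- summarize_repeat_editing(ev[0, ], reps)
  expect_equal(none$edited_fraction, c(0, 0))
})

test_that("editing truth is recovered exactly on simulated data", {
  cfg <- sim_config(n_genes = 600, n_labeled = 40, seed = 91)
  gt <- simulate_gene_universe(cfg)
  st <- plant_labeled_clusters(gt, cfg)
  ctx <- simulate_context(gt, st, cfg, seed = 91)
  ed <- simulate_editing(gt, ctx$repeats,
                         edit_sim_config(n_true_edits = 100, n_snps = 50,
                                         seed = 91))
  kept <- filter_edit_events(ed$events, ed$snps)
  expect_equal(nrow(kept), 100)
  expect_true(all(kept$truth))  # precision = recall = 1
})

test_that("intron-retention flags use strict cutoffs and feed the incidence test", {
  ir <- data.frame(
    intron_id = paste0("i", 1:4), gene_id = c("g1", "g2", "g3", "g4"),
    delta_psi = c(0.25, 0.10, 0.30, 0.05),  # g2 exactly at 10%: excluded
    fdr = c(0.01, 0.01, 0.20, 0.01)          # g3 fails FDR
  )
  flags <- ir_gene_flags(ir, c("g1", "g2", "g3", "g4", "g5"))
  expect_identical(unname(flags), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  res <- ir_incidence_test(rep(c(TRUE, FALSE), c(30, 70)),
                           rep(c(TRUE, FALSE), c(10, 90)))
  expect_equal(res$chi2, 12.5)
  eq <- ir_incidence_test(rep(c(TRUE, FALSE), c(20, 80)),
                          rep(c(TRUE, FALSE), c(20, 80)))
  expect_equal(eq$chi2, 0)
})
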