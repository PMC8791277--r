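test_that("interval overlap test reproduces the small hypergeometric case", {
  # labeled 2/2 inside, unlabeled 2/4 inside -> P(X >= 2) = C(4,2)/C(6,2)
  gt <- toy_gene_table(list(chr1 = c(100, 200, 300, 400, 900, 950)),
                       chrom_len = 1e4)
  status <- as_status(c("LABELED", "LABELED", rep("UNLABELED", 4)))
  iv <- data.frame(chrom = "chr1", start = 0, end = 500)
  res <- interval_overlap_test(gt, status, iv)
  expect_equal(res$p, choose(4, 2) / choose(6, 2))
  expect_equal(sum(res$overlap$in_interval), 4)
  # empty and saturated annotations are degenerate with p = 1
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  expect_equal(interval_overlap_test(gt, status, empty)$p, 1)
  all_iv <- data.frame(chrom = "chr1", start = 0, end = 1e4)
  expect_equal(interval_overlap_test(gt, status, all_iv)$p, 1)
})

test_that("overlap flags are invariant under base-preserving interval splits", {
  gt <- toy_gene_table(list(chr1 = seq(50, 950, by = 100)), chrom_len = 1e3)
  status <- as_status(rep(c("LABELED", "UNLABELED"), 5))
  merged <- data.frame(chrom = "chr1", start = c(0, 600), end = c(400, 900))
  split_iv <- data.frame(chrom = "chr1",
                         start = c(0, 150, 300, 600, 700),
                         end = c(150, 300, 400, 700, 900))
  r1 <- interval_overlap_test(gt, status, merged)
  r2 <- interval_overlap_test(gt, status, split_iv)
  expect_identical(r1$overlap$in_interval, r2$overlap$in_interval)
  expect_equal(r1$p, r2$p)
})

test_that("contact normalization divides by the median with a strict peak cutoff", {
  nv <- normalize_contact_vector(c(1, 2, 3, 10))
  expect_equal(nv$normalized, c(0.4, 0.8, 1.2, 4.0))
  expect_equal(nv$peaks, 4L)
  flat <- normalize_contact_vector(c(5, 5, 5))
  expect_equal(flat$normalized, c(1, 1, 1))
  expect_length(flat$peaks, 0)
  # a value exactly 1.5x the median is not a peak
  at_cut <- normalize_contact_vector(c(2, 2, 3))
  expect_length(at_cut$peaks, 0)
  # scale invariance
  v <- c(0.5, 1.2, 8, 3, 0.1)
  expect_equal(normalize_contact_vector(v * 17), normalize_contact_vector(v))
  expect_error(normalize_contact_vector(c(0, 0, 0)), "degenerate")
  # zero bins excluded from the median unless requested
  withz <- normalize_contact_vector(c(0, 0, 2, 4, 6))
  expect_equal(withz$normalized[3], 0.5)
  incl <- normalize_contact_vector(c(0, 0, 2, 4, 6), include_zeros = TRUE)
  expect_equal(incl$normalized[3], 1)
})

test_that("contact group test ranks labeled genes against the expressed background", {
  gt <- toy_gene_table(list(chr1 = c(150, 250, 350, 450, 550, 650)),
                       chrom_len = 600 * 1 + 1e3)
  contacts <- data.frame(chrom = "chr1", bin_start = seq(100, 600, by = 100),
                         value = c(1, 2, 3, 4, 5, 6))
  # bins of 100 bp; gene i sits in bin i+1; labeled genes in the top bins
  status <- as_status(c(rep("UNLABELED", 3), rep("LABELED", 3)))
  res <- contact_group_test(contacts, 100, gt, status)
  expect_equal(res$p, 1 / 20)
  expect_gte(contact_group_test(contacts, 100, gt,
                                as_status(rep(c("LABELED", "UNLABELED"),
                                              3)))$p, 0.3)
})

test_that("hybrid ranking intersects replicates and orders by density", {
  gt <- toy_gene_table(list(chr1 = c(2000, 4000, 6000)), chrom_len = 1e4,
                       tpm = c(2, 4, 1))
  # widen genes so length is 2 kb
  gt$genes$start <- gt$genes$start - 999
  gt$genes$end <- gt$genes$end + 999
  hyb <- data.frame(gene_id = c("t001", "t002", "t003"),
                    reads_rep1 = c(6, 4, 9), reads_rep2 = c(4, 2, 0))
  res <- hybrid_density_rank(hyb, gt, top_n = 1)
  # t003 dropped (absent from rep2); t001: 10 reads / 2 kb = 5 /kb
  expect_equal(nrow(res$table), 2)
  expect_equal(res$table$density[res$table$gene_id == "t001"], 5)
  expect_equal(res$table$expr_norm[res$table$gene_id == "t001"], 5)
  expect_identical(res$top, "t001")
  expect_error(hybrid_density_rank(hyb, gt, top_n = 3), "top_n exceeds")
  # tpm = 0 flags expr_norm undefined but keeps the gene
  gt$genes$tpm[2] <- 0
  res0 <- hybrid_density_rank(hyb, gt, top_n = 2)
  row2 <- res0$table[res0$table$gene_id == "t002", ]
  expect_false(row2$expr_norm_defined)
  expect_true(is.na(row2$expr_norm))
})

test_that("planted contact and interval signals are recovered on synthetic data", {
  cfg <- sim_config(seed = 202)
  gt <- simulate_gene_universe(cfg)
  st <- plant_labeled_clusters(gt, cfg)
  status <- st$status[match(gt$genes$gene_id, st$gene_id)]
  ctx <- simulate_context(gt, st, cfg, peak_gain = 4, seed = 202)
  expect_lt(contact_group_test(ctx$contacts, 500000, gt, status)$p, 0.01)
  expect_lt(interval_overlap_test(gt, status, ctx$intervals)$p, 0.01)
})
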