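test_that("gene universe respects count, bounds, capacity and determinism", {
  cfg <- sim_config(n_chroms = 2, chrom_length_bp = 50e6, n_genes = 500,
                    n_labeled = 20, cluster_regions = data.frame(
                      chrom = "chr1", start = 10e6, end = 15e6), seed = 7)
  gt <- simulate_gene_universe(cfg)
  expect_equal(nrow(gt$genes), 500)
  expect_true(all(gt$genes$start >= 0 & gt$genes$start < gt$genes$end))
  expect_true(all(gt$genes$end <= 50e6))
  expect_true(all(gt$genes$tpm >= 0))
  # midpoints distinct within chromosomes
  mids <- gene_midpoints(gt)
  expect_false(any(duplicated(paste(gt$genes$chrom, mids))))
  # determinism
  gt2 <- simulate_gene_universe(cfg)
  expect_identical(gt, gt2)
  # capacity violation
  tiny <- cfg; tiny$n_chroms <- 1; tiny$chrom_length_bp <- 1000
  tiny$cluster_regions <- data.frame(chrom = "chr1", start = 0, end = 500)
  expect_error(simulate_gene_universe(tiny), "too many genes")
})

test_that("planted cluster membership is binomial-consistent", {
  cfg <- sim_config(n_chroms = 3, chrom_length_bp = 100e6, n_genes = 2000,
                    n_labeled = 60, cluster_fraction = 0.7, seed = 123)
  gt <- simulate_gene_universe(cfg)
  st <- plant_labeled_clusters(gt, cfg)
  expect_equal(sum(st$status == "LABELED"), 60)
  n_in <- sum(st$status == "LABELED" & st$in_cluster)
  # central 99.9% interval of Bin(60, 0.7): qbinom(c(5e-4, 1-5e-4), 60, .7)
  expect_true(n_in >= 31 && n_in <= 52)
})

test_that("cluster_fraction extremes force placement", {
  one_chrom_regions <- data.frame(chrom = "chr1", start = 10e6, end = 20e6)
  cfg1 <- sim_config(n_chroms = 3, chrom_length_bp = 50e6, n_genes = 1000,
                     n_labeled = 30, cluster_fraction = 1,
                     cluster_regions = one_chrom_regions, seed = 5)
  gt <- simulate_gene_universe(cfg1)
  st <- plant_labeled_clusters(gt, cfg1)
  lab_chrom <- gt$genes$chrom[st$status == "LABELED"]
  expect_true(all(lab_chrom == "chr1"))
  cfg0 <- cfg1; cfg0$cluster_fraction <- 0
  st0 <- plant_labeled_clusters(gt, cfg0)
  expect_equal(sum(st0$status == "LABELED" & st0$in_cluster), 0)
})

test_that("simulated proteome plants the requested truth structure", {
  sim <- simulate_proteome(300, 3, 50, effect_log2 = 2, noise_sd = 0.3,
                           seed = 1)
  expect_equal(sum(!is.na(sim$truth$specific_for)), 150)
  expect_equal(dim(sim$log2fe), c(300, 3))
  sim2 <- simulate_proteome(300, 3, 50, effect_log2 = 2, noise_sd = 0.3,
                            seed = 1)
  expect_identical(sim, sim2)
  expect_error(simulate_proteome(100, 3, 50), "exceed")
  # null case: planted and background distributions coincide
  null <- simulate_proteome(400, 2, 100, effect_log2 = 0, noise_sd = 0.3,
                            seed = 2)
  planted <- null$log2fe[!is.na(null$truth$specific_for), 1]
  bg <- null$log2fe[is.na(null$truth$specific_for), 1]
  expect_gt(ks.test(planted, bg)$p.value, 0.01)
})

test_that("contact vectors carry the planted multiplicative peak gain", {
  cfg <- sim_config(seed = 31)
  gt <- simulate_gene_universe(cfg)
  st <- plant_labeled_clusters(gt, cfg)
  ctx <- simulate_context(gt, st, cfg, bin_bp = 500000, peak_gain = 4,
                          seed = 31)
  cc <- ctx$contacts
  in_cluster <- rep(FALSE, nrow(cc))
  for (j in seq_len(nrow(cfg$cluster_regions))) {
    cr <- cfg$cluster_regions[j, ]
    in_cluster <- in_cluster | (cc$chrom == cr$chrom &
                                  cc$bin_start < cr$end &
                                  cc$bin_start + 500000 > cr$start)
  }
  expect_gte(sum(!in_cluster), 200)
  ratio <- mean(cc$value[in_cluster]) / mean(cc$value[!in_cluster])
  expect_true(ratio > 3 && ratio < 5)  # 4 within +-25%
})

test_that("a gain-free contact vector yields only the expected false-positive peaks", {
  cfg <- sim_config(seed = 13)
  gt <- simulate_gene_universe(cfg)
  st <- plant_labeled_clusters(gt, cfg)
  ctx <- simulate_context(gt, st, cfg, bin_bp = 500000, peak_gain = 1,
                          seed = 13)
  cc <- ctx$contacts[ctx$contacts$chrom == "chr1", ]
  nv <- normalize_contact_vector(cc$value)
  # Exponential(1): P(X > 1.5 * median) = exp(-1.5 log 2) ~ 0.354
  p_exceed <- 2^-1.5
  n <- length(cc$value)
  upper <- qbinom(0.999, n, p_exceed)
  expect_lte(length(nv$peaks), upper)
})

test_that("editing simulation plants strand-consistent edits disjoint from SNPs", {
  cfg <- sim_config(n_genes = 500, n_labeled = 40, seed = 3)
  gt <- simulate_gene_universe(cfg)
  st <- plant_labeled_clusters(gt, cfg)
  ctx <- simulate_context(gt, st, cfg, seed = 3)
  ecfg <- edit_sim_config(n_true_edits = 100, n_snps = 50, seed = 3)
  ed <- simulate_editing(gt, ctx$repeats, ecfg)
  expect_equal(nrow(ed$events), 150)
  expect_equal(sum(ed$events$truth), 100)
  true_ev <- ed$events[ed$events$truth, ]
  minus <- true_ev$gene_strand == "-"
  expect_true(all(true_ev$ref[minus] == "T" & true_ev$alt[minus] == "C"))
  expect_true(all(true_ev$ref[!minus] == "A" & true_ev$alt[!minus] == "G"))
  expect_equal(
    length(intersect(paste(true_ev$chrom, true_ev$pos),
                     paste(ed$snps$chrom, ed$snps$pos))), 0)
  # null case: nothing to retain
  ed0 <- simulate_editing(gt, ctx$repeats,
                          edit_sim_config(n_true_edits = 0, n_snps = 20,
                                          seed = 4))
  expect_equal(nrow(filter_edit_events(ed0$events, ed0$snps)), 0)
})

test_that("generators emit tables satisfying their type invariants", {
  cfg <- sim_config(n_genes = 300, n_labeled = 20, seed = 17)
  inp <- simulate_inputs(cfg)
  expect_s3_class(inp$genes, "gene_table")  # constructor validates
  expect_true(all(inp$status$status %in% c("LABELED", "UNLABELED")))
  expect_true(all(inp$enrichment$fold_enrichment > 0))
  expect_true(all(inp$enrichment$fdr >= 0 & inp$enrichment$fdr <= 1))
  expect_true(all(inp$context$repeats$start < inp$context$repeats$end))
  ev <- inp$editing$events
  expect_true(all(ev$alt_count <= ev$coverage & ev$alt_count >= 0))
})
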