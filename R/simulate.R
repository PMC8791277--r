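#' Simulation configuration
#'
#' Parameters of the synthetic genome used to exercise every analysis stage:
#' gene coordinates along chromosomes, a clustered subset of labeled genes,
#' log-normal expression, and sample counts. Defaults describe the benchmark
#' genome used throughout the package's recovery tests: 3 chromosomes of
#' 100 Mb, 3,000 expressed genes, 60 labeled genes of which 80\% fall inside
#' two planted 5 Mb cluster regions.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_genes number of genes.
#' @param n_labeled number of labeled genes.
#' @param cluster_regions data.frame (chrom, start, end) of planted cluster
#'   regions; NULL places two 5 Mb regions on the first two chromosomes.
#' @param cluster_fraction expected fraction of labeled genes drawn from
#'   inside the cluster regions.
#' @param tpm_log_mean,tpm_log_sd log-normal expression parameters
#'   (natural-log scale).
#' @param gene_span_bp fixed gene span; midpoint-centred, clipped to bounds.
#' @param n_samples number of count samples generated per gene.
#' @param seed integer seed; every generator taking this config is a pure
#'   function of (config, seed).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_chroms = 3, chrom_length_bp = 100e6,
                       n_genes = 3000, n_labeled = 60,
                       cluster_regions = NULL, cluster_fraction = 0.8,
                       tpm_log_mean = 1, tpm_log_sd = 1,
                       gene_span_bp = 2000, n_samples = 6, seed = 1) {
  if (is.null(cluster_regions)) {
    k <- min(2, n_chroms)
    cluster_regions <- data.frame(
      chrom = paste0("chr", seq_len(k)),
      start = rep(40e6, k),
      end = rep(45e6, k)
    )
    cluster_regions$end <- pmin(cluster_regions$end, chrom_length_bp)
    cluster_regions$start <- pmin(cluster_regions$start,
                                  cluster_regions$end - 1)
  }
  cfg <- list(n_chroms = n_chroms, chrom_length_bp = chrom_length_bp,
              n_genes = n_genes, n_labeled = n_labeled,
              cluster_regions = cluster_regions,
              cluster_fraction = cluster_fraction,
              tpm_log_mean = tpm_log_mean, tpm_log_sd = tpm_log_sd,
              gene_span_bp = gene_span_bp, n_samples = n_samples,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length_bp > 0, cfg$n_genes >= 1)
  if (cfg$n_labeled > cfg$n_genes) stop("n_labeled must not exceed n_genes")
  if (cfg$cluster_fraction < 0 || cfg$cluster_fraction > 1) {
    stop("cluster_fraction must lie in [0, 1]")
  }
  cr <- cfg$cluster_regions
  if (any(cr$start < 0 | cr$end > cfg$chrom_length_bp | cr$start >= cr$end)) {
    stop("cluster_regions must lie within chromosome bounds")
  }
  invisible(cfg)
}

#' Simulate a gene universe
#'
#' Places \code{n_genes} genes with distinct uniform-random midpoints across
#' the chromosomes (allocation proportional to chromosome length), a fixed
#' span centred on the midpoint and clipped to chromosome bounds, random
#' strand, log-normal TPM, and Poisson per-sample counts with mean
#' proportional to TPM. Deterministic for a given seed.
#'
#' @param config a [sim_config()].
#' @return A \code{gene_table} with a counts matrix attached.
#' @export
simulate_gene_universe <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(config$chrom_length_bp,
                                     config$n_chroms), chroms)
  capacity <- sum(floor(chrom_sizes / config$gene_span_bp))
  if (config$n_genes > capacity) {
    stop("too many genes for the genome: capacity ", capacity)
  }
  chrom <- sample(chroms, config$n_genes, replace = TRUE,
                  prob = chrom_sizes / sum(chrom_sizes))
  mid <- floor(stats::runif(config$n_genes, 0, chrom_sizes[chrom]))
  # enforce distinct midpoints per chromosome (collisions are rare)
  for (i in seq_len(100)) {
    dup <- duplicated(paste(chrom, mid))
    if (!any(dup)) break
    mid[dup] <- floor(stats::runif(sum(dup), 0, chrom_sizes[chrom[dup]]))
  }
  half <- floor(config$gene_span_bp / 2)
  start <- pmax(0, mid - half)
  end <- pmin(chrom_sizes[chrom], mid + half)
  o <- order(chrom, start)
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(config$n_genes)),
    chrom = chrom[o], start = start[o], end = end[o],
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    tpm = stats::rlnorm(config$n_genes, config$tpm_log_mean,
                        config$tpm_log_sd),
    stringsAsFactors = FALSE
  )
  counts <- matrix(
    stats::rpois(config$n_genes * config$n_samples,
                 lambda = rep(genes$tpm * 5, config$n_samples)),
    nrow = config$n_genes
  )
  colnames(counts) <- paste0("s", seq_len(config$n_samples))
  gene_table(genes, chrom_sizes, counts = counts)
}

#' Plant labeled gene clusters
#'
#' Assigns LABELED status to \code{n_labeled} genes: the number drawn from
#' inside the cluster regions is Binomial(n_labeled, cluster_fraction)
#' (capped by pool sizes), sampled without replacement from the genes whose
#' midpoints fall inside the regions; the remainder is drawn uniformly from
#' the genes outside. All other genes are UNLABELED. Ground-truth region
#' membership is recorded so recovery tests never re-derive it.
#'
#' @param genes a \code{gene_table} from [simulate_gene_universe()].
#' @param config the same [sim_config()].
#' @return data.frame with gene_id, status (factor over
#'   \code{label_levels()}), and in_cluster (logical: midpoint inside a
#'   planted region).
#' @export
plant_labeled_clusters <- function(genes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  mids <- gene_midpoints(genes)
  g <- genes$genes
  inside <- rep(FALSE, nrow(g))
  for (ch in unique(config$cluster_regions$chrom)) {
    cr <- config$cluster_regions[config$cluster_regions$chrom == ch, ,
                                 drop = FALSE]
    merged <- merge_intervals(cr$start, cr$end)
    sel <- g$chrom == ch
    inside[sel] <- points_in_intervals(mids[sel], merged)
    if (sum(sel & inside) == 0 && nrow(cr) > 0) {
      stop("cluster region on ", ch, " contains no genes")
    }
  }
  pool_in <- which(inside); pool_out <- which(!inside)
  n_in <- stats::rbinom(1, config$n_labeled, config$cluster_fraction)
  n_in <- min(n_in, length(pool_in))
  n_out <- min(config$n_labeled - n_in, length(pool_out))
  n_in <- config$n_labeled - n_out  # absorb shortfall from the outside pool
  labeled_idx <- c(sample(pool_in, n_in),
                   if (n_out > 0) sample(pool_out, n_out))
  status <- rep("UNLABELED", nrow(g))
  status[labeled_idx] <- "LABELED"
  data.frame(gene_id = g$gene_id,
             status = factor(status, levels = label_levels()),
             in_cluster = inside,
             stringsAsFactors = FALSE)
}

#' Simulate an enrichment table consistent with planted labels
#'
#' Produces per-gene fold-enrichment and FDR values that the sequencing
#' classifier maps back to the planted status: labeled genes draw fold
#' enrichment from 2-8 with FDR below 1e-12, unlabeled genes sit near or
#' below 1-fold with large FDR.
#'
#' @param status_df output of [plant_labeled_clusters()].
#' @param seed integer seed.
#' @return data.frame with feature_id, fold_enrichment, fdr.
#' @export
simulate_enrichment <- function(status_df, seed = 1) {
  set.seed(seed)
  n <- nrow(status_df)
  lab <- status_df$status == "LABELED"
  fe <- ifelse(lab, stats::runif(n, 2, 8), stats::runif(n, 0.4, 1.2))
  fdr <- ifelse(lab, stats::runif(n, 0, 1e-12), stats::runif(n, 0.3, 1))
  data.frame(feature_id = status_df$gene_id, fold_enrichment = fe,
             fdr = fdr, stringsAsFactors = FALSE)
}

#' Simulate a multi-compartment proteome
#'
#' Plants \code{n_specific_per_compartment} compartment-specific proteins per
#' compartment: in their own compartment their log2 fold-enrichment over the
#' infusion control is Normal(effect_log2, noise_sd), elsewhere
#' Normal(0, noise_sd); background proteins are Normal(0, noise_sd)
#' everywhere. FDR is small where an effect is planted and large otherwise.
#'
#' @param n_proteins total proteins.
#' @param n_compartments number of compartments.
#' @param n_specific_per_compartment planted specific proteins per
#'   compartment.
#' @param effect_log2 planted log2 enrichment.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param seed integer seed.
#' @return List with \code{log2fe} (matrix), \code{fdr} (matrix) and
#'   \code{truth} (data.frame protein_id, specific_for; NA for background).
#' @export
simulate_proteome <- function(n_proteins = 300, n_compartments = 3,
                              n_specific_per_compartment = 50,
                              effect_log2 = 2, noise_sd = 0.3, seed = 1) {
  if (n_specific_per_compartment * n_compartments > n_proteins) {
    stop("planted proteins exceed n_proteins")
  }
  set.seed(seed)
  comps <- paste0("comp", seq_len(n_compartments))
  ids <- sprintf("p%04d", seq_len(n_proteins))
  specific_for <- rep(NA_character_, n_proteins)
  specific_for[seq_len(n_specific_per_compartment * n_compartments)] <-
    rep(comps, each = n_specific_per_compartment)
  log2fe <- matrix(stats::rnorm(n_proteins * n_compartments, 0, noise_sd),
                   nrow = n_proteins, dimnames = list(ids, comps))
  fdr <- matrix(stats::runif(n_proteins * n_compartments, 0.2, 1),
                nrow = n_proteins, dimnames = list(ids, comps))
  for (k in seq_len(n_compartments)) {
    idx <- which(specific_for == comps[k])
    log2fe[idx, k] <- stats::rnorm(length(idx), effect_log2, noise_sd)
    if (effect_log2 != 0) {
      fdr[idx, k] <- stats::runif(length(idx), 0, 0.01)
    }
  }
  list(log2fe = log2fe, fdr = fdr,
       truth = data.frame(protein_id = ids, specific_for = specific_for,
                          stringsAsFactors = FALSE))
}

#' Simulate genomic context tracks
#'
#' Generates the spatial-context inputs around a simulated genome: per-bin
#' contact vectors with an exponential baseline multiplied by
#' \code{peak_gain} on bins overlapping the planted cluster regions; an
#' interval set covering the planted regions (a NAD-like annotation); a
#' RepeatMasker-style SINE table where a configurable fraction of labeled
#' (and of unlabeled) genes receives an inverted same-family pair in its 10 kb
#' downstream region; per-gene Pol II densities, log-normal with a
#' multiplicative shift for labeled genes; and two replicates of hybrid-read
#' counts elevated for labeled genes.
#'
#' @param genes a \code{gene_table}.
#' @param status_df output of [plant_labeled_clusters()].
#' @param config the [sim_config()] whose cluster regions were planted.
#' @param bin_bp contact-vector bin size.
#' @param peak_gain multiplicative contact gain on cluster bins.
#' @param inverted_frac_labeled,inverted_frac_unlabeled fractions of genes in
#'   each class receiving a planted inverted SINE pair downstream.
#' @param polii_shift_log natural-log shift of Pol II density for labeled
#'   genes.
#' @param hybrid_gain multiplicative hybrid-read gain for labeled genes.
#' @param seed integer seed.
#' @return List with \code{contacts} (chrom, bin_start, value),
#'   \code{intervals} (chrom, start, end), \code{repeats} (chrom, start, end,
#'   strand, family, gene_id), \code{polii} (named numeric, cpmk-scale
#'   density) and \code{hybrid} (gene_id, reads_rep1, reads_rep2).
#' @export
simulate_context <- function(genes, status_df, config, bin_bp = 500000,
                             peak_gain = 4,
                             inverted_frac_labeled = 0.8,
                             inverted_frac_unlabeled = 0.1,
                             polii_shift_log = log(2),
                             hybrid_gain = 5, seed = 1) {
  stopifnot(bin_bp > 0)
  set.seed(seed)
  g <- genes$genes
  lab <- status_df$status[match(g$gene_id, status_df$gene_id)] == "LABELED"

  contacts <- do.call(rbind, lapply(names(genes$chrom_sizes), function(ch) {
    len <- genes$chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = bin_bp)
    val <- stats::rexp(length(starts), rate = 1)
    cr <- config$cluster_regions[config$cluster_regions$chrom == ch, ,
                                 drop = FALSE]
    if (nrow(cr) > 0) {
      ends <- pmin(starts + bin_bp, len)
      hit <- rep(FALSE, length(starts))
      for (j in seq_len(nrow(cr))) {
        hit <- hit | (starts < cr$end[j] & ends > cr$start[j])
      }
      val[hit] <- val[hit] * peak_gain
    }
    data.frame(chrom = ch, bin_start = starts, value = val,
               stringsAsFactors = FALSE)
  }))

  intervals <- config$cluster_regions[, c("chrom", "start", "end")]

  # inverted SINE pairs in the strand-aware 10 kb downstream region
  frac <- ifelse(lab, inverted_frac_labeled, inverted_frac_unlabeled)
  gets_pair <- stats::runif(nrow(g)) < frac
  rep_rows <- lapply(which(gets_pair), function(i) {
    len <- genes$chrom_sizes[[g$chrom[i]]]
    if (g$strand[i] == "+") {
      s <- g$end[i]
    } else {
      s <- max(0, g$start[i] - 10000)
    }
    a1 <- min(s + 500, len - 1)
    a2 <- min(s + 5000, len - 300)
    data.frame(chrom = g$chrom[i],
               start = c(a1, a2), end = c(a1 + 300, a2 + 300),
               strand = c("+", "-"), family = "Alu",
               gene_id = g$gene_id[i], stringsAsFactors = FALSE)
  })
  repeats <- if (length(rep_rows) > 0) do.call(rbind, rep_rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), family = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)

  polii <- stats::rlnorm(nrow(g), meanlog = 1 + polii_shift_log * lab,
                         sdlog = 0.6)
  names(polii) <- g$gene_id

  base <- ifelse(lab, 2 * hybrid_gain, 2)
  hybrid <- data.frame(
    gene_id = g$gene_id,
    reads_rep1 = stats::rpois(nrow(g), lambda = base),
    reads_rep2 = stats::rpois(nrow(g), lambda = base),
    stringsAsFactors = FALSE
  )

  list(contacts = contacts, intervals = intervals, repeats = repeats,
       polii = polii, hybrid = hybrid)
}

#' Editing-simulation configuration
#'
#' @param n_true_edits number of planted true A-to-I edits.
#' @param n_snps number of SNP contaminant events.
#' @param alt_fraction_range range of the edited-read fraction.
#' @param coverage_range integer range of per-position coverage.
#' @param seed integer seed.
#' @return List of class \code{edit_sim_config}.
#' @export
edit_sim_config <- function(n_true_edits = 100, n_snps = 50,
                            alt_fraction_range = c(0.1, 0.6),
                            coverage_range = c(10, 100), seed = 1) {
  stopifnot(n_true_edits >= 0, n_snps >= 0,
            alt_fraction_range[1] <= alt_fraction_range[2],
            coverage_range[1] <= coverage_range[2])
  structure(list(n_true_edits = n_true_edits, n_snps = n_snps,
                 alt_fraction_range = alt_fraction_range,
                 coverage_range = coverage_range, seed = seed),
            class = "edit_sim_config")
}

#' Simulate editing events with SNP contamination
#'
#' True edits are A-to-I events on the transcribed strand at positions inside
#' repeats: genomic A>G for genes on "+", genomic T>C for genes on "-". SNP
#' contaminants are placed at disjoint positions with arbitrary
#' substitutions. Truth labels are attached to every event.
#'
#' @param genes a \code{gene_table} (supplies strands).
#' @param repeats repeat table from [simulate_context()] (needs chrom, start,
#'   end, gene_id columns).
#' @param config an [edit_sim_config()].
#' @return List with \code{events} (chrom, pos, ref, alt, alt_count,
#'   coverage, gene_strand, truth) and \code{snps} (chrom, pos).
#' @export
simulate_editing <- function(genes, repeats, config) {
  stopifnot(inherits(config, "edit_sim_config"))
  if (config$n_true_edits > 0 && nrow(repeats) == 0) {
    stop("repeats must be non-empty when planting true edits")
  }
  set.seed(config$seed)
  g <- genes$genes
  ev <- list()
  used <- character(0)
  if (config$n_true_edits > 0) {
    ridx <- sample(nrow(repeats), config$n_true_edits, replace = TRUE)
    pos <- floor(stats::runif(config$n_true_edits,
                              repeats$start[ridx], repeats$end[ridx]))
    key <- paste(repeats$chrom[ridx], pos)
    # de-duplicate planted positions
    for (i in seq_len(50)) {
      dup <- duplicated(key)
      if (!any(dup)) break
      pos[dup] <- floor(stats::runif(sum(dup), repeats$start[ridx[dup]],
                                     repeats$end[ridx[dup]]))
      key <- paste(repeats$chrom[ridx], pos)
    }
    strand <- g$strand[match(repeats$gene_id[ridx], g$gene_id)]
    cov <- sample(seq(config$coverage_range[1], config$coverage_range[2]),
                  config$n_true_edits, replace = TRUE)
    af <- stats::runif(config$n_true_edits, config$alt_fraction_range[1],
                       config$alt_fraction_range[2])
    alt_count <- pmax(1, stats::rbinom(config$n_true_edits, cov, af))
    ev$true <- data.frame(
      chrom = repeats$chrom[ridx], pos = pos,
      ref = ifelse(strand == "+", "A", "T"),
      alt = ifelse(strand == "+", "G", "C"),
      alt_count = alt_count, coverage = cov,
      gene_strand = strand, truth = TRUE, stringsAsFactors = FALSE
    )
    used <- paste(ev$true$chrom, ev$true$pos)
  }
  if (config$n_snps > 0) {
    chroms <- names(genes$chrom_sizes)
    ch <- sample(chroms, config$n_snps, replace = TRUE)
    pos <- floor(stats::runif(config$n_snps, 0, genes$chrom_sizes[ch]))
    key <- paste(ch, pos)
    for (i in seq_len(50)) {
      clash <- key %in% used | duplicated(key)
      if (!any(clash)) break
      pos[clash] <- floor(stats::runif(sum(clash), 0,
                                       genes$chrom_sizes[ch[clash]]))
      key <- paste(ch, pos)
    }
    if (any(key %in% used)) stop("could not place SNPs disjoint from edits")
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, config$n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    cov <- sample(seq(config$coverage_range[1], config$coverage_range[2]),
                  config$n_snps, replace = TRUE)
    ev$snp <- data.frame(
      chrom = ch, pos = pos, ref = ref, alt = alt,
      alt_count = pmax(1, stats::rbinom(config$n_snps, cov, 0.5)),
      coverage = cov,
      gene_strand = sample(c("+", "-"), config$n_snps, replace = TRUE),
      truth = FALSE, stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    events <- data.frame(chrom = character(0), pos = numeric(0),
                         ref = character(0), alt = character(0),
                         alt_count = integer(0), coverage = integer(0),
                         gene_strand = character(0), truth = logical(0),
                         stringsAsFactors = FALSE)
  }
  rownames(events) <- NULL
  snps <- if (is.null(ev$snp)) {
    data.frame(chrom = character(0), pos = numeric(0))
  } else {
    ev$snp[, c("chrom", "pos")]
  }
  list(events = events, snps = snps)
}

#' Simulate an intron-retention table
#'
#' Per-gene intron records with change-in-splicing (delta PSI) and FDR, where
#' labeled genes carry a significantly retained intron (delta PSI > 0.1,
#' FDR < 0.05) with probability \code{ir_frac_labeled} and control genes with
#' probability \code{ir_frac_control}; this emulates the per-intron output of
#' an external intron-retention caller.
#'
#' @param gene_ids character vector of genes to cover.
#' @param is_labeled logical vector aligned with \code{gene_ids}.
#' @param ir_frac_labeled,ir_frac_control probabilities of a significant
#'   retained intron per class.
#' @param seed integer seed.
#' @return data.frame intron_id, gene_id, delta_psi, fdr.
#' @export
simulate_ir_table <- function(gene_ids, is_labeled,
                              ir_frac_labeled = 0.3, ir_frac_control = 0.1,
                              seed = 1) {
  set.seed(seed)
  n <- length(gene_ids)
  hit <- stats::runif(n) < ifelse(is_labeled, ir_frac_labeled,
                                  ir_frac_control)
  delta_psi <- ifelse(hit, stats::runif(n, 0.15, 0.6),
                      stats::runif(n, 0, 0.08))
  fdr <- ifelse(hit, stats::runif(n, 0, 0.04), stats::runif(n, 0.1, 1))
  data.frame(intron_id = paste0(gene_ids, "_i1"), gene_id = gene_ids,
             delta_psi = delta_psi, fdr = fdr, stringsAsFactors = FALSE)
}
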