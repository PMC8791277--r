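#' Generate the full set of synthetic pipeline inputs
#'
#' Runs every generator on one configuration: gene universe, planted labeled
#' clusters, enrichment table, multi-compartment proteome, context tracks
#' (contacts, intervals, repeats, Pol II densities, hybrid counts), editing
#' events with SNP contamination and an intron-retention table.
#'
#' @param config a [sim_config()].
#' @param edit_config an [edit_sim_config()]; defaults to the standard
#'   100-edit / 50-SNP benchmark re-seeded from \code{config}.
#' @return List with elements genes, status, enrichment, proteome, context,
#'   editing, ir_table.
#' @export
simulate_inputs <- function(config = sim_config(),
                            edit_config = NULL) {
  genes <- simulate_gene_universe(config)
  status_df <- plant_labeled_clusters(genes, config)
  enrichment <- simulate_enrichment(status_df, seed = config$seed + 2L)
  proteome <- simulate_proteome(seed = config$seed + 3L)
  context <- simulate_context(genes, status_df, config,
                              seed = config$seed + 4L)
  if (is.null(edit_config)) {
    edit_config <- edit_sim_config(seed = config$seed + 5L)
  }
  editing <- if (nrow(context$repeats) > 0) {
    simulate_editing(genes, context$repeats, edit_config)
  } else {
    NULL
  }
  lab <- status_df$status == "LABELED"
  ir_table <- simulate_ir_table(status_df$gene_id, lab,
                                seed = config$seed + 6L)
  list(genes = genes, status = status_df, enrichment = enrichment,
       proteome = proteome, context = context, editing = editing,
       ir_table = ir_table, config = config)
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Classifies genes from counts and enrichment, runs the chromosome and
#' sliding-window clustering scans, the telomere test, the intergenic
#' resampling null, proteome specificity indices with high-confidence sets,
#' interval overlap and contact tests, hybrid-read ranking, Pol II density
#' matching, the editing filter/summary and the intron-retention incidence
#' contrast, and (optionally) writes every report table as TSV.
#'
#' @param inputs output of [simulate_inputs()] (or an equivalently shaped
#'   list built from real tables).
#' @param outdir optional directory for the report TSVs (created if absent).
#' @param n_iter resampling iterations (default 10,000).
#' @param seed seed for the resampling sampler.
#' @param contact_bin_bp bin width of the contact vectors.
#' @param match_tol tolerance of the Pol II median matching.
#' @return List of all result objects (invisibly when writing).
#' @export
run_pipeline <- function(inputs, outdir = NULL, n_iter = 10000, seed = 1,
                         contact_bin_bp = 500000, match_tol = 0.5) {
  genes <- inputs$genes
  g <- genes$genes

  detectable <- classify_expression(genes$counts)
  enr <- inputs$enrichment[match(g$gene_id, inputs$enrichment$feature_id), ]
  status <- classify_seq_status(enr$fold_enrichment, enr$fdr, detectable)
  status_tab <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                           start = g$start, end = g$end, strand = g$strand,
                           tpm = g$tpm, detectable = detectable,
                           fold_enrichment = enr$fold_enrichment,
                           fdr = enr$fdr, status = status,
                           stringsAsFactors = FALSE)

  chroms <- chromosome_enrichment(genes, status)
  windows <- window_scan(genes, status)
  telomere <- telomere_proximity_test(genes, status)
  resample <- cluster_resampling_test(genes, status, n_iter = n_iter,
                                      seed = seed)

  pm <- proteome_matrix(inputs$proteome$log2fe, inputs$proteome$fdr)
  si <- specificity_index(pm)
  enriched <- matrix(FALSE, nrow(pm$lfe), ncol(pm$lfe),
                     dimnames = dimnames(pm$lfe))
  for (k in seq_len(ncol(pm$lfe))) {
    enriched[, k] <- classify_ms_enriched(2^pm$raw_log2fe[, k], pm$fdr[, k])
  }
  hc <- high_confidence_sets(si, enriched)

  overlap <- interval_overlap_test(genes, status, inputs$context$intervals)
  contacts_norm <- do.call(rbind, lapply(
    split(inputs$context$contacts, inputs$context$contacts$chrom),
    function(cc) {
      nv <- normalize_contact_vector(cc$value)
      cc$normalized <- nv$normalized
      cc$peak <- seq_len(nrow(cc)) %in% nv$peaks
      cc
    }))
  rownames(contacts_norm) <- NULL
  contact <- contact_group_test(inputs$context$contacts, contact_bin_bp,
                                genes, status)
  hybrid <- hybrid_density_rank(inputs$context$hybrid, genes,
                                top_n = min(267, sum(
                                  inputs$context$hybrid$reads_rep1 > 0 &
                                    inputs$context$hybrid$reads_rep2 > 0)))

  polii <- inputs$context$polii[g$gene_id]
  lab <- status == "LABELED"
  unl <- status == "UNLABELED"
  matched <- match_unlabeled_by_median(polii[lab], polii[unl],
                                       tol = match_tol)
  matched_ids <- names(matched)

  editing_res <- NULL
  if (!is.null(inputs$editing)) {
    kept <- filter_edit_events(inputs$editing$events, inputs$editing$snps)
    per_repeat <- summarize_repeat_editing(kept, inputs$context$repeats)
    editing_res <- list(kept = kept, per_repeat = per_repeat)
  }

  sine_flags <- inverted_pair_flags(genes, inputs$context$repeats)
  sine_test <- incidence_test(sine_flags[g$gene_id[lab]],
                              sine_flags[matched_ids])

  ir_flags <- ir_gene_flags(inputs$ir_table, g$gene_id)
  ir_res <- ir_incidence_test(ir_flags[g$gene_id[lab]],
                              ir_flags[matched_ids])

  results <- list(status = status_tab, chromosomes = chroms,
                  windows = windows, telomere = telomere,
                  resample = resample, si = si, enriched = enriched,
                  high_confidence = hc, overlap = overlap,
                  contacts_norm = contacts_norm, contact_test = contact,
                  hybrid = hybrid, matched_controls = matched_ids,
                  editing = editing_res, sine_test = sine_test,
                  ir_test = ir_res)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(status_tab, "status.tsv")
    wt(chroms, "chromosomes.tsv")
    wt(as.data.frame(windows), "windows.tsv")
    wt(data.frame(real_median = resample$real_median, n = resample$n,
                  k = resample$k, p = resample$p,
                  delta_med = resample$delta_med), "resample.tsv")
    wt(telomere$distances, "telomere.tsv")
    si_df <- data.frame(protein_id = rownames(si$si), si$si,
                        defined = si$defined, stringsAsFactors = FALSE)
    wt(si_df, "si.tsv")
    hc_df <- do.call(rbind, lapply(names(hc), function(k) {
      if (length(hc[[k]]) == 0) return(NULL)
      data.frame(compartment = k, protein_id = hc[[k]],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(hc_df)) {
      hc_df <- data.frame(compartment = character(0),
                          protein_id = character(0))
    }
    wt(hc_df, "high_confidence.tsv")
    wt(overlap$overlap, "overlap.tsv")
    wt(contacts_norm, "contacts_norm.tsv")
    wt(hybrid$table, "hybrid_rank.tsv")
    if (!is.null(editing_res)) {
      wt(editing_res$kept, "editing.tsv")
      wt(editing_res$per_repeat, "editing_per_repeat.tsv")
    }
    ir_df <- data.frame(gene_id = names(ir_flags), has_ir = ir_flags,
                        row.names = NULL, stringsAsFactors = FALSE)
    wt(ir_df, "ir.tsv")
    return(invisible(results))
  }
  results
}
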