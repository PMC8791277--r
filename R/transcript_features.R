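#' Counts per million per kilobase
#'
#' Library-size and length normalized read density:
#' \code{(count * 1e6 / total_aligned) / (gene_length_bp / 1000)}.
#'
#' @param count read counts (vectorized).
#' @param gene_length_bp gene length in bp (> 0).
#' @param total_aligned total aligned reads in the library (> 0).
#' @return cpmk values.
#' @export
cpmk <- function(count, gene_length_bp, total_aligned) {
  if (any(gene_length_bp <= 0)) stop("gene length must be positive")
  if (length(total_aligned) != 1 || total_aligned <= 0) {
    stop("total_aligned must be a positive scalar")
  }
  (count * 1e6 / total_aligned) / (gene_length_bp / 1000)
}

#' Select unlabeled control genes matched on median density
#'
#' Sorts the unlabeled values in decreasing order and, over every prefix
#' size k, finds the top-k subset whose median is closest to the labeled
#' median; among subsets within \code{tol} of the target the absolute median
#' difference is minimized first, preferring the largest k on ties. This
#' reproduces the "highest-density unlabeled genes whose distribution median
#' matches the labeled genes" matching used for Pol II density controls.
#'
#' @param labeled_values numeric, densities of labeled genes.
#' @param unlabeled_values named numeric, densities of candidate control
#'   genes (names survive into the result).
#' @param tol maximum tolerated |median difference|.
#' @return The matched subset (named as the input), with attributes
#'   \code{k} and \code{median_diff}.
#' @export
match_unlabeled_by_median <- function(labeled_values, unlabeled_values, tol) {
  if (length(labeled_values) == 0) stop("labeled_values must be non-empty")
  if (length(unlabeled_values) == 0) stop("unlabeled_values must be non-empty")
  target <- stats::median(labeled_values)
  o <- order(unlabeled_values, decreasing = TRUE)
  sorted <- unlabeled_values[o]
  n <- length(sorted)
  # median of the first k elements of a sorted vector by direct lookup
  meds <- vapply(seq_len(n), function(k) {
    if (k %% 2 == 1) sorted[(k + 1) / 2]
    else (sorted[k / 2] + sorted[k / 2 + 1]) / 2
  }, 0)
  diffs <- abs(meds - target)
  ok <- which(diffs <= tol)
  if (length(ok) == 0) {
    stop(sprintf("no prefix matches the labeled median within tol; best |difference| = %g",
                 min(diffs)))
  }
  best <- ok[diffs[ok] == min(diffs[ok])]
  k <- max(best)
  out <- sorted[seq_len(k)]
  attr(out, "k") <- k
  attr(out, "median_diff") <- unname(meds[k] - target)
  out
}

#' Read-through ratio downstream of a gene
#'
#' Ratio of mean coverage in the strand-aware downstream window to mean
#' gene-body coverage, from a bedGraph-style track (regions absent from the
#' track count as zero coverage). For "+" genes the downstream window is
#' \code{[end, end + downstream_bp)}; for "-" genes it is
#' \code{[start - downstream_bp, start)}; both clipped to chromosome bounds.
#'
#' @param track data.frame with chrom, start, end, value (rpm-scale
#'   coverage intervals, 0-based half-open).
#' @param gene one-row data.frame (or list) with chrom, start, end, strand.
#' @param chrom_length chromosome length used for clipping.
#' @param downstream_bp window size (default 10 kb).
#' @return Ratio, or NA when the gene body has zero mean coverage (flagged
#'   via attribute \code{defined = FALSE}).
#' @export
readthrough_ratio <- function(track, gene, chrom_length,
                              downstream_bp = 10000) {
  window_mean <- function(ws, we) {
    if (we <= ws) return(NA_real_)
    tt <- track[track$chrom == gene$chrom & track$start < we &
                  track$end > ws, , drop = FALSE]
    if (nrow(tt) == 0) return(0)
    ov <- pmin(tt$end, we) - pmax(tt$start, ws)
    sum(tt$value * ov) / (we - ws)
  }
  body_mean <- window_mean(gene$start, gene$end)
  if (gene$strand == "+") {
    ds <- window_mean(gene$end, min(chrom_length, gene$end + downstream_bp))
  } else {
    ds <- window_mean(max(0, gene$start - downstream_bp), gene$start)
  }
  if (is.na(body_mean) || body_mean <= 0 || is.na(ds)) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  out <- ds / body_mean
  attr(out, "defined") <- TRUE
  out
}

#' Find inverted SINE pairs inside a region
#'
#' Returns every unordered pair of repeats fully inside the region that lie
#' on opposite strands and (by default) share a repeat family. A maximum gap
#' between the paired elements can be imposed.
#'
#' @param repeats data.frame with chrom, start, end, strand, family.
#' @param region list or one-row data.frame with chrom, start, end.
#' @param same_family require the two elements to share a family.
#' @param max_gap optional maximum gap in bp between the elements.
#' @return data.frame of pairs (indices into \code{repeats} plus
#'   coordinates); zero rows when none.
#' @export
find_inverted_sine_pairs <- function(repeats, region, same_family = TRUE,
                                     max_gap = NULL) {
  if (region$start >= region$end) stop("invalid region")
  inside <- which(repeats$chrom == region$chrom &
                    repeats$start >= region$start &
                    repeats$end <= region$end)
  empty <- data.frame(i = integer(0), j = integer(0),
                      family = character(0), gap = numeric(0))
  if (length(inside) < 2) return(empty)
  combos <- utils::combn(inside, 2)
  i <- combos[1, ]; j <- combos[2, ]
  keep <- repeats$strand[i] != repeats$strand[j]
  if (same_family) keep <- keep & repeats$family[i] == repeats$family[j]
  gap <- pmax(0, pmax(repeats$start[i], repeats$start[j]) -
                pmin(repeats$end[i], repeats$end[j]))
  if (!is.null(max_gap)) keep <- keep & gap <= max_gap
  data.frame(i = i[keep], j = j[keep],
             family = repeats$family[i[keep]], gap = gap[keep],
             stringsAsFactors = FALSE)
}

#' Flag genes with an inverted SINE pair in their read-through region
#'
#' For each gene, examines the strand-aware downstream window (as in
#' [readthrough_ratio()]) and flags the gene when at least one inverted
#' same-family repeat pair lies fully inside it.
#'
#' @param genes a \code{gene_table}.
#' @param repeats data.frame with chrom, start, end, strand, family.
#' @param downstream_bp window size (default 10 kb).
#' @param ... passed to [find_inverted_sine_pairs()].
#' @return Named logical vector per gene.
#' @export
inverted_pair_flags <- function(genes, repeats, downstream_bp = 10000, ...) {
  g <- genes$genes
  flags <- vapply(seq_len(nrow(g)), function(i) {
    len <- genes$chrom_sizes[[g$chrom[i]]]
    if (g$strand[i] == "+") {
      region <- list(chrom = g$chrom[i], start = g$end[i],
                     end = min(len, g$end[i] + downstream_bp))
    } else {
      region <- list(chrom = g$chrom[i],
                     start = max(0, g$start[i] - downstream_bp),
                     end = g$start[i])
    }
    if (region$start >= region$end) return(FALSE)
    nrow(find_inverted_sine_pairs(repeats, region, ...)) > 0
  }, TRUE, USE.NAMES = FALSE)
  stats::setNames(flags, g$gene_id)
}

#' Filter candidate editing events to strand-consistent A-to-I calls
#'
#' Drops events at known SNP positions (matched on position only, alleles
#' ignored) and keeps only events consistent with A-to-G editing on the
#' transcribed strand: genomic ref A / alt G for genes on "+", genomic
#' ref T / alt C for genes on "-".
#'
#' @param events data.frame with chrom, pos, ref, alt, gene_strand (plus any
#'   further columns, preserved).
#' @param snp_positions data.frame with chrom, pos.
#' @return The kept subset of \code{events}.
#' @export
filter_edit_events <- function(events, snp_positions) {
  at_snp <- paste(events$chrom, events$pos) %in%
    paste(snp_positions$chrom, snp_positions$pos)
  strand_ok <- (events$gene_strand == "+" & events$ref == "A" &
                  events$alt == "G") |
    (events$gene_strand == "-" & events$ref == "T" & events$alt == "C")
  out <- events[!at_snp & strand_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-repeat edited fraction
#'
#' For each repeat, the edited fraction is the summed alternative-allele
#' count over the summed coverage of the kept edit positions inside the
#' repeat; repeats without kept events score 0.
#'
#' @param events kept events from [filter_edit_events()] (chrom, pos,
#'   alt_count, coverage).
#' @param repeats data.frame with chrom, start, end.
#' @return data.frame with the repeat coordinates plus n_events,
#'   edited_fraction and defined (FALSE when events exist but total
#'   coverage is zero).
#' @export
summarize_repeat_editing <- function(events, repeats) {
  if (nrow(repeats) == 0) stop("repeats must be non-empty")
  res <- repeats[, c("chrom", "start", "end")]
  res$n_events <- 0L
  res$edited_fraction <- 0
  res$defined <- TRUE
  for (r in seq_len(nrow(repeats))) {
    hit <- events$chrom == repeats$chrom[r] &
      events$pos >= repeats$start[r] & events$pos < repeats$end[r]
    if (!any(hit)) next
    res$n_events[r] <- sum(hit)
    cov <- sum(events$coverage[hit])
    if (cov == 0) {
      res$edited_fraction[r] <- NA_real_
      res$defined[r] <- FALSE
    } else {
      res$edited_fraction[r] <- sum(events$alt_count[hit]) / cov
    }
  }
  res
}

#' Per-gene intron-retention flags from a caller table
#'
#' A gene is flagged when it has at least one intron with change in
#' splicing (delta PSI) strictly above \code{dpsi_thresh} and FDR strictly
#' below \code{fdr_thresh}.
#'
#' @param ir_table data.frame with gene_id, delta_psi, fdr (per intron).
#' @param gene_ids genes to flag (in order).
#' @param dpsi_thresh delta-PSI cutoff (default 0.10, strict).
#' @param fdr_thresh FDR cutoff (default 0.05, strict).
#' @return Named logical vector.
#' @export
ir_gene_flags <- function(ir_table, gene_ids, dpsi_thresh = 0.10,
                          fdr_thresh = 0.05) {
  sig <- ir_table$delta_psi > dpsi_thresh & ir_table$fdr < fdr_thresh
  hit_genes <- unique(ir_table$gene_id[sig])
  stats::setNames(gene_ids %in% hit_genes, gene_ids)
}

#' Intron-retention incidence contrast
#'
#' Builds the (with-IR, without-IR) x (labeled, matched-control) table and
#' tests it with the Pearson chi-squared test, falling back to the one-sided
#' exact test when any expected cell is below 5 (see [incidence_test()]).
#'
#' @param labeled_flags,matched_flags logical IR flags for the labeled genes
#'   and their density-matched unlabeled controls.
#' @return As [incidence_test()].
#' @export
ir_incidence_test <- function(labeled_flags, matched_flags) {
  incidence_test(labeled_flags, matched_flags)
}

#' Read a bedGraph coverage track
#'
#' @param file bedGraph path (chrom, start, end, value; no header).
#' @return data.frame with chrom, start, end, value.
#' @export
read_bedgraph <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  df
}
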