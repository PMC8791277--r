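#' Overlap of labeled genes with an interval annotation
#'
#' A gene overlaps the annotation when its midpoint lies inside a merged
#' interval (set \code{rule = "any"} for >= 1 bp overlap of the gene body
#' instead). Enrichment of labeled over unlabeled genes inside the intervals
#' is tested with the one-sided exact test; ambiguous and undetected genes
#' are excluded from the contrast.
#'
#' @param genes a \code{gene_table}.
#' @param status per-gene label-status factor aligned with the gene table.
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param rule "midpoint" (default) or "any".
#' @return List with \code{overlap} (data.frame gene_id, status, in_interval)
#'   and \code{p}.
#' @export
interval_overlap_test <- function(genes, status, intervals,
                                  rule = c("midpoint", "any")) {
  rule <- match.arg(rule)
  g <- genes$genes
  if (nrow(g) == 0) stop("empty gene set")
  stopifnot(length(status) == nrow(g))
  mids <- gene_midpoints(genes)
  inside <- rep(FALSE, nrow(g))
  for (ch in unique(g$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    merged <- merge_intervals(iv$start, iv$end)
    sel <- g$chrom == ch
    if (rule == "midpoint") {
      inside[sel] <- points_in_intervals(mids[sel], merged)
    } else {
      inside[sel] <- vapply(which(sel), function(i) {
        any(g$start[i] < merged[, "end"] & g$end[i] > merged[, "start"])
      }, TRUE)
    }
  }
  lab <- status == "LABELED"
  unl <- status == "UNLABELED"
  p <- fisher_one_sided(sum(lab & inside), sum(unl & inside),
                        sum(lab & !inside), sum(unl & !inside))
  list(overlap = data.frame(gene_id = g$gene_id, status = status,
                            in_interval = inside, stringsAsFactors = FALSE),
       p = p)
}

#' Median-normalize a contact vector and call peaks
#'
#' Divides per-bin contact values by the chromosome median and flags bins
#' strictly exceeding \code{cutoff} times the median as peaks. By default
#' the median is taken over non-zero bins, since zero bins typically reflect
#' unmappable regions; set \code{include_zeros = TRUE} to use all bins.
#'
#' @param values non-negative per-bin contact values.
#' @param cutoff peak threshold on the normalized scale (default 1.5).
#' @param include_zeros include zero bins in the median.
#' @return List with \code{normalized} (values / median) and \code{peaks}
#'   (integer bin indices).
#' @export
normalize_contact_vector <- function(values, cutoff = 1.5,
                                     include_zeros = FALSE) {
  if (any(values < 0)) stop("contact values must be non-negative")
  med_vals <- if (include_zeros) values else values[values > 0]
  med <- stats::median(med_vals)
  if (!length(med_vals) || !is.finite(med) || med <= 0) {
    stop("degenerate contact vector")
  }
  normalized <- values / med
  list(normalized = normalized, peaks = which(normalized > cutoff))
}

#' Rank-sum test of contact intensity at labeled genes
#'
#' Maps each gene to the normalized contact value of the bin containing its
#' midpoint and tests, one-sided, whether labeled genes sit in
#' higher-contact bins than the expressed background. By default the
#' background excludes the labeled genes so the two samples are disjoint;
#' \code{include_labeled_in_background = TRUE} compares against all
#' detectably expressed genes.
#'
#' @param contacts data.frame with chrom, bin_start, value (equal-width bins
#'   of \code{bin_bp}).
#' @param bin_bp bin width in bp.
#' @param genes a \code{gene_table}.
#' @param status per-gene label-status factor aligned with the gene table.
#' @param include_labeled_in_background keep labeled genes in the background
#'   sample.
#' @return List with \code{values} (per-gene normalized contact), \code{p}.
#' @export
contact_group_test <- function(contacts, bin_bp, genes, status,
                               include_labeled_in_background = FALSE) {
  g <- genes$genes
  stopifnot(length(status) == nrow(g))
  mids <- gene_midpoints(genes)
  vals <- rep(NA_real_, nrow(g))
  for (ch in unique(g$chrom)) {
    cc <- contacts[contacts$chrom == ch, , drop = FALSE]
    if (nrow(cc) == 0) next
    norm <- normalize_contact_vector(cc$value)$normalized
    sel <- which(g$chrom == ch)
    bstart <- floor(mids[sel] / bin_bp) * bin_bp
    idx <- match(bstart, cc$bin_start)
    ok <- !is.na(idx)
    vals[sel[ok]] <- norm[idx[ok]]
  }
  lab <- status == "LABELED" & !is.na(vals)
  bg <- status != "UNDETECTED" & !is.na(vals)
  if (!include_labeled_in_background) bg <- bg & !lab
  if (!any(lab) || !any(bg)) stop("empty group")
  p <- rank_sum_test(vals[lab], vals[bg], alternative = "greater")
  list(values = stats::setNames(vals, g$gene_id), p = p)
}

#' Rank genes by hybrid-read density
#'
#' Genes detected in both replicates are retained (replicate intersection);
#' hybrid reads are summed across replicates. Density is reads per kb of
#' gene length and the expression-normalized number is reads per TPM
#' (undefined, and flagged, at TPM = 0). The top-n set is taken by density,
#' ties broken by expression-normalized number, then gene id.
#'
#' @param hybrid data.frame with gene_id, reads_rep1, reads_rep2.
#' @param genes a \code{gene_table}.
#' @param top_n size of the shortlist.
#' @return List with \code{table} (gene_id, hybrid_reads, length_kb, tpm,
#'   density, expr_norm, expr_norm_defined, ranked) and \code{top}
#'   (character vector of the top-n gene ids).
#' @export
hybrid_density_rank <- function(hybrid, genes, top_n) {
  g <- genes$genes
  m <- match(hybrid$gene_id, g$gene_id)
  if (anyNA(m)) stop("hybrid table contains unknown gene ids")
  both <- hybrid$reads_rep1 > 0 & hybrid$reads_rep2 > 0
  h <- hybrid[both, , drop = FALSE]
  m <- m[both]
  if (top_n > nrow(h)) {
    stop("top_n exceeds the ", nrow(h), " genes detected in both replicates")
  }
  length_kb <- (g$end[m] - g$start[m]) / 1000
  reads <- h$reads_rep1 + h$reads_rep2
  tpm <- g$tpm[m]
  expr_norm <- ifelse(tpm > 0, reads / tpm, NA_real_)
  tab <- data.frame(gene_id = h$gene_id, hybrid_reads = reads,
                    length_kb = length_kb, tpm = tpm,
                    density = reads / length_kb,
                    expr_norm = expr_norm,
                    expr_norm_defined = tpm > 0,
                    stringsAsFactors = FALSE)
  o <- order(-tab$density, -ifelse(is.na(tab$expr_norm), -Inf, tab$expr_norm),
             tab$gene_id)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, top = tab$gene_id[seq_len(top_n)])
}

#' Read a contact vector TSV
#'
#' @param file TSV with columns chrom, bin_start, value.
#' @return data.frame.
#' @export
read_contacts <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  req <- c("chrom", "bin_start", "value")
  if (!all(req %in% names(df))) {
    stop("contacts table needs columns: ", paste(req, collapse = ", "))
  }
  df
}
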