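#' Per-chromosome enrichment of labeled genes
#'
#' For each chromosome, tests whether labeled genes are over-represented
#' among the detectably expressed genes it carries, using the one-sided
#' exact test against the rest of the genome, with Benjamini-Hochberg
#' correction across chromosomes. Undetected genes are excluded before
#' counting; chromosomes with no expressed genes are omitted. Non-canonical
#' contigs (names not matching \code{chr} followed by digits, X or Y) can be
#' pooled into a single "chrUn" stratum.
#'
#' @param genes a \code{gene_table}.
#' @param status factor of per-gene label status aligned with the gene table
#'   (levels from [label_levels()]).
#' @param pool_noncanonical pool non-canonical contigs into "chrUn"
#'   (default TRUE).
#' @return data.frame with chrom, n_labeled, n_expressed, p, q.
#' @export
chromosome_enrichment <- function(genes, status, pool_noncanonical = TRUE) {
  g <- genes$genes
  stopifnot(length(status) == nrow(g))
  expressed <- status != "UNDETECTED"
  labeled <- status == "LABELED"
  if (!any(labeled)) stop("no labeled genes")
  chrom <- g$chrom
  if (pool_noncanonical) {
    canonical <- grepl("^chr([0-9]+|X|Y)$", chrom)
    chrom[!canonical] <- "chrUn"
  }
  chrom_e <- chrom[expressed]
  lab_e <- labeled[expressed]
  tot_lab <- sum(lab_e)
  tot_exp <- length(lab_e)
  res <- do.call(rbind, lapply(sort(unique(chrom_e)), function(ch) {
    on_ch <- chrom_e == ch
    a <- sum(lab_e & on_ch)
    b <- sum(!lab_e & on_ch)
    data.frame(chrom = ch, n_labeled = a, n_expressed = a + b,
               p = fisher_one_sided(a, b, tot_lab - a,
                                    (tot_exp - a - b) - (tot_lab - a)),
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}

# Window tiling for one chromosome: full windows anchored at 0 advancing by
# step_bp, plus one final partial window when the chromosome end is not
# covered. Returns a matrix of (start, end).
tile_windows <- function(chrom_len, window_bp, step_bp) {
  starts <- seq(0, chrom_len, by = step_bp)
  full <- starts[starts + window_bp <= chrom_len]
  if (length(full) == 0) {
    return(cbind(start = 0, end = chrom_len))
  }
  covered <- max(full) + window_bp
  if (covered < chrom_len) {
    s <- max(full) + step_bp
    cbind(start = c(full, s), end = c(full + window_bp, chrom_len))
  } else {
    cbind(start = full, end = full + window_bp)
  }
}

#' Sliding-window scan for clustered labeled genes
#'
#' Slides a window (default 5 Mb, step 2.5 Mb) along every chromosome,
#' assigns genes to windows by midpoint, and tests each window for an excess
#' of labeled genes against the rest of the genome with the one-sided exact
#' test. q values are Benjamini-Hochberg across all windows genome-wide.
#' Selected windows form a greedy maximal non-overlapping set among windows
#' passing the threshold, chosen in ascending p (ties: leftmost start, then
#' smallest chromosome name).
#'
#' @param genes a \code{gene_table}.
#' @param status per-gene label-status factor aligned with the gene table.
#' @param window_bp,step_bp window size and step in bp.
#' @param q_thresh selection threshold on the BH q value.
#' @param use_raw_p select on raw p instead of q.
#' @return data.frame of class \code{window_scan} with chrom, start, end,
#'   n_labeled_in, n_expressed_in, p, q, selected.
#' @export
window_scan <- function(genes, status, window_bp = 5e6, step_bp = 2.5e6,
                        q_thresh = 0.05, use_raw_p = FALSE) {
  stopifnot(window_bp >= step_bp, step_bp > 0)
  g <- genes$genes
  stopifnot(length(status) == nrow(g))
  expressed <- status != "UNDETECTED"
  if (!any(expressed)) stop("no expressed genes")
  mids <- gene_midpoints(genes)
  chrom_e <- g$chrom[expressed]
  mids_e <- mids[expressed]
  lab_e <- (status == "LABELED")[expressed]
  tot_lab <- sum(lab_e)
  tot_exp <- length(lab_e)
  res <- do.call(rbind, lapply(names(genes$chrom_sizes), function(ch) {
    w <- tile_windows(genes$chrom_sizes[[ch]], window_bp, step_bp)
    on_ch <- chrom_e == ch
    m <- mids_e[on_ch]; l <- lab_e[on_ch]
    a <- vapply(seq_len(nrow(w)), function(i) {
      sum(l & m >= w[i, 1] & m < w[i, 2])
    }, 0)
    n_in <- vapply(seq_len(nrow(w)), function(i) {
      sum(m >= w[i, 1] & m < w[i, 2])
    }, 0)
    data.frame(chrom = ch, start = w[, 1], end = w[, 2],
               n_labeled_in = a, n_expressed_in = n_in,
               stringsAsFactors = FALSE)
  }))
  res$p <- fisher_one_sided(res$n_labeled_in,
                            res$n_expressed_in - res$n_labeled_in,
                            tot_lab - res$n_labeled_in,
                            (tot_exp - res$n_expressed_in) -
                              (tot_lab - res$n_labeled_in))
  res$q <- bh_adjust(res$p)
  crit <- if (use_raw_p) res$p else res$q
  cand <- which(crit < q_thresh)
  sel <- logical(nrow(res))
  o <- cand[order(res$p[cand], res$start[cand], res$chrom[cand])]
  for (i in o) {
    clash <- sel & res$chrom == res$chrom[i] &
      res$start < res$end[i] & res$end > res$start[i]
    if (!any(clash)) sel[i] <- TRUE
  }
  res$selected <- sel
  rownames(res) <- NULL
  class(res) <- c("window_scan", "data.frame")
  res
}

#' @export
print.window_scan <- function(x, ...) {
  cat("window_scan:", nrow(x), "windows,", sum(x$selected),
      "selected (non-overlapping)\n")
  sel <- x[x$selected, , drop = FALSE]
  if (nrow(sel) > 0) {
    print.data.frame(sel[order(sel$p), ], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Telomere-proximity test for labeled genes
#'
#' Per-gene telomere distance is \code{min(midpoint, chrom_length -
#' midpoint)}; a one-sided rank-sum test asks whether labeled genes lie
#' closer to telomeres than unlabeled genes (exact enumeration for combined
#' n <= 20, tie-corrected normal approximation otherwise).
#'
#' @param genes a \code{gene_table}.
#' @param status per-gene label-status factor aligned with the gene table.
#' @return List with \code{distances} (data.frame gene_id, status,
#'   telomere_dist) and \code{p}.
#' @export
telomere_proximity_test <- function(genes, status) {
  g <- genes$genes
  stopifnot(length(status) == nrow(g))
  mids <- gene_midpoints(genes)
  len <- genes$chrom_sizes[g$chrom]
  d <- pmin(mids, len - mids)
  keep <- status %in% c("LABELED", "UNLABELED")
  lab <- status == "LABELED"
  if (!any(lab) || !any(status == "UNLABELED")) {
    stop("both labeled and unlabeled groups must be non-empty")
  }
  p <- rank_sum_test(d[lab], d[status == "UNLABELED"], alternative = "less")
  list(distances = data.frame(gene_id = g$gene_id[keep],
                              status = status[keep],
                              telomere_dist = unname(d[keep]),
                              stringsAsFactors = FALSE),
       p = p)
}
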