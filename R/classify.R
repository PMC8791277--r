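#' Flag detectably expressed genes
#'
#' A gene counts as not detectably expressed when the fraction of samples with
#' fewer than \code{min_reads} reads is strictly greater than \code{frac}
#' (default: < 5 reads in > 50\% of samples). Equality at the fraction
#' threshold leaves the gene detectable.
#'
#' @param counts_matrix numeric matrix, genes x samples, non-negative counts.
#' @param min_reads read-count threshold below which a sample is "low".
#' @param frac fraction of low samples that must be exceeded to call a gene
#'   undetected.
#' @return Logical vector, TRUE for detectably expressed genes.
#' @export
classify_expression <- function(counts_matrix, min_reads = 5, frac = 0.5) {
  counts_matrix <- as.matrix(counts_matrix)
  if (ncol(counts_matrix) == 0) stop("no samples")
  if (any(counts_matrix < 0)) stop("counts must be non-negative")
  low_frac <- rowMeans(counts_matrix < min_reads)
  detectable <- !(low_frac > frac)
  names(detectable) <- rownames(counts_matrix)
  detectable
}

#' Label-status levels
#'
#' @return Character vector of the four per-gene label states.
#' @export
label_levels <- function() c("LABELED", "UNLABELED", "AMBIGUOUS", "UNDETECTED")

#' Classify genes from sequencing enrichment
#'
#' Applies the labeled / unlabeled cutoffs to fold-enrichment (linear scale,
#' labeled sample versus infusion control) and FDR. A gene is LABELED when
#' enriched more than \code{labeled_fc}-fold at FDR below \code{labeled_fdr};
#' UNLABELED when depleted below \code{unlabeled_fc_lo}-fold, or below
#' \code{unlabeled_fc_hi}-fold with FDR above \code{unlabeled_fdr};
#' detectable genes matching neither predicate are AMBIGUOUS. All
#' inequalities are strict, so equality at any threshold falls on the
#' non-significant side.
#'
#' @param fold_enrichment positive numeric vector (linear fold enrichment).
#' @param fdr numeric vector in [0, 1].
#' @param detectable logical vector from [classify_expression()]; genes with
#'   FALSE are UNDETECTED regardless of enrichment.
#' @param labeled_fc,labeled_fdr cutoffs for the labeled class.
#' @param unlabeled_fc_lo,unlabeled_fc_hi,unlabeled_fdr cutoffs for the
#'   unlabeled class.
#' @return Factor with levels \code{label_levels()}.
#' @export
classify_seq_status <- function(fold_enrichment, fdr, detectable = TRUE,
                                labeled_fc = 1.5, labeled_fdr = 1e-10,
                                unlabeled_fc_lo = 1.0, unlabeled_fc_hi = 1.5,
                                unlabeled_fdr = 0.1) {
  n <- length(fold_enrichment)
  stopifnot(length(fdr) == n)
  if (any(fold_enrichment <= 0)) stop("fold_enrichment must be positive")
  if (any(fdr < 0 | fdr > 1)) stop("fdr must lie in [0, 1]")
  detectable <- rep_len(detectable, n)
  status <- rep("AMBIGUOUS", n)
  labeled <- fold_enrichment > labeled_fc & fdr < labeled_fdr
  unlabeled <- fold_enrichment < unlabeled_fc_lo |
    (fold_enrichment < unlabeled_fc_hi & fdr > unlabeled_fdr)
  status[unlabeled] <- "UNLABELED"
  status[labeled] <- "LABELED"
  status[!detectable] <- "UNDETECTED"
  factor(status, levels = label_levels())
}

#' Flag mass-spectrometry enriched proteins
#'
#' A protein is enriched when its fold enrichment over the infusion control
#' exceeds \code{fc} (default 2) with FDR below \code{fdr} (default 0.05);
#' both inequalities strict.
#'
#' @param fold_enrichment positive numeric vector (linear fold enrichment).
#' @param fdr_values numeric vector in [0, 1].
#' @param fc,fdr cutoffs.
#' @return Logical vector.
#' @export
classify_ms_enriched <- function(fold_enrichment, fdr_values,
                                 fc = 2.0, fdr = 0.05) {
  stopifnot(length(fold_enrichment) == length(fdr_values))
  if (any(fold_enrichment <= 0)) stop("fold_enrichment must be positive")
  fold_enrichment > fc & fdr_values < fdr
}

#' Reads-per-million normalization
#'
#' Scales counts by 1e6 / total aligned reads, the factor used for
#' strand-specific coverage tracks.
#'
#' @param count non-negative numeric vector of read counts.
#' @param total_aligned total number of aligned reads in the library.
#' @return count * 1e6 / total_aligned.
#' @export
rpm_normalize <- function(count, total_aligned) {
  if (length(total_aligned) != 1 || total_aligned <= 0) stop("empty library")
  if (any(count < 0)) stop("counts must be non-negative")
  count * 1e6 / total_aligned
}

#' Read an enrichment table from TSV
#'
#' Expects columns \code{feature_id}, \code{fdr} and either
#' \code{fold_enrichment} (linear) or \code{log2fc} (converted with
#' \code{2^log2fc}).
#'
#' @param file TSV path.
#' @param log2 set TRUE to read a \code{log2fc} column instead of
#'   \code{fold_enrichment}.
#' @return data.frame with feature_id, fold_enrichment, fdr.
#' @export
read_enrichment_table <- function(file, log2 = FALSE) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (log2) {
    if (!"log2fc" %in% names(df)) stop("log2fc column not found")
    df$fold_enrichment <- 2^df$log2fc
  }
  req <- c("feature_id", "fold_enrichment", "fdr")
  if (!all(req %in% names(df))) {
    stop("enrichment table needs columns: ", paste(req, collapse = ", "))
  }
  df[, req]
}
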