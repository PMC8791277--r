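#' Proteins-per-million normalization
#'
#' Each protein's quantitative value divided by the sample total, times 1e6.
#'
#' @param values non-negative per-protein quantitative values.
#' @return Numeric vector summing to 1e6.
#' @export
to_ppm <- function(values) {
  if (any(values < 0)) stop("values must be non-negative")
  total <- sum(values)
  if (total <= 0) stop("all-zero input")
  values / total * 1e6
}

#' Construct a proteome matrix
#'
#' Stores raw protein-by-compartment log2 fold-enrichment (versus the
#' infusion control) together with its non-negative clipped version used by
#' the specificity index, and the per-cell FDR.
#'
#' @param log2fe numeric matrix, proteins x compartments, raw log2 fold
#'   enrichment (may be negative).
#' @param fdr numeric matrix of the same shape, FDR values in [0, 1].
#' @return Object of class \code{proteome_matrix} with elements
#'   \code{raw_log2fe}, \code{lfe} (clipped at 0), \code{fdr}.
#' @export
proteome_matrix <- function(log2fe, fdr) {
  log2fe <- as.matrix(log2fe)
  fdr <- as.matrix(fdr)
  if (!all(dim(log2fe) == dim(fdr))) stop("dimension mismatch")
  if (ncol(log2fe) < 2) stop("need at least 2 compartments")
  if (any(fdr < 0 | fdr > 1)) stop("fdr must lie in [0, 1]")
  structure(list(raw_log2fe = log2fe, lfe = pmax(log2fe, 0), fdr = fdr),
            class = "proteome_matrix")
}

#' Compartment specificity index
#'
#' For protein j and compartment k, SI is the protein's non-negative log2
#' fold-enrichment in k divided by the sum of its enrichment values over all
#' compartments (non-positive log2 enrichments are clipped to 0 first).
#' Proteins with all-zero clipped enrichment have no defined SI and are
#' flagged rather than imputed.
#'
#' @param pm a [proteome_matrix()] (or a plain matrix of raw log2 fold
#'   enrichment, clipped internally).
#' @return List with \code{si} (matrix, NA rows where undefined) and
#'   \code{defined} (logical per protein).
#' @export
specificity_index <- function(pm) {
  lfe <- if (inherits(pm, "proteome_matrix")) pm$lfe else pmax(as.matrix(pm), 0)
  if (ncol(lfe) < 2) stop("need at least 2 compartments")
  rs <- rowSums(lfe)
  defined <- rs > 0
  si <- lfe / rs
  si[!defined, ] <- NA_real_
  list(si = si, defined = defined)
}

#' High-confidence compartment-specific protein sets
#'
#' A protein is assigned to compartment k when it is enriched in k and its
#' specificity index for k strictly exceeds its SI for every other
#' compartment; ties are assigned nowhere.
#'
#' @param si_table output of [specificity_index()].
#' @param enriched logical matrix, proteins x compartments, e.g. from
#'   [classify_ms_enriched()] applied per compartment.
#' @return Named list (one element per compartment) of protein identifiers
#'   (row names, or row indices when unnamed).
#' @export
high_confidence_sets <- function(si_table, enriched) {
  si <- si_table$si
  enriched <- as.matrix(enriched)
  if (!all(dim(enriched) == dim(si))) stop("dimension mismatch")
  ids <- rownames(si)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(si)))
  comps <- colnames(si)
  if (is.null(comps)) comps <- paste0("comp", seq_len(ncol(si)))
  out <- lapply(seq_along(comps), function(k) {
    ok <- si_table$defined & enriched[, k]
    strict_max <- rep(FALSE, nrow(si))
    strict_max[ok] <- vapply(which(ok), function(j) {
      all(si[j, k] > si[j, -k])
    }, TRUE)
    ids[strict_max]
  })
  names(out) <- comps
  out
}

#' Rank-sum test on specificity indices between labeled and unlabeled
#' proteins
#'
#' One-sided rank-sum test of whether labeled proteins have higher SI for
#' the compartment than unlabeled proteins. Proteins with undefined SI are
#' excluded.
#'
#' @param si_table output of [specificity_index()].
#' @param labeled logical vector per protein (labeled in the compartment).
#' @param compartment column index or name of the compartment tested.
#' @return One-sided p value.
#' @export
si_group_test <- function(si_table, labeled, compartment) {
  si <- si_table$si[, compartment]
  keep <- si_table$defined
  x <- si[keep & labeled]
  y <- si[keep & !labeled]
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  rank_sum_test(x, y, alternative = "greater")
}

#' Shortlist filter for RNA-capture mass-spectrometry tables
#'
#' Keeps a protein when its abundance in both capture-oligo experiments
#' exceeds the input more than 2-fold, both input-normalized capture signals
#' strictly exceed the sense-oligo control, and at least one capture signal
#' exceeds its sense counterpart more than 2-fold.
#'
#' @param rows data.frame with columns protein_id, co1, co2, sense, input
#'   (positive abundances; input and sense must be > 0).
#' @param fc fold threshold (default 2).
#' @return The kept subset of \code{rows} with a logical \code{kept} column
#'   attached for all input rows as attribute "flags".
#' @export
chart_ms_filter <- function(rows, fc = 2) {
  req <- c("protein_id", "co1", "co2", "sense", "input")
  if (!all(req %in% names(rows))) {
    stop("rows needs columns: ", paste(req, collapse = ", "))
  }
  if (any(rows$input <= 0) || any(rows$sense <= 0)) {
    stop("input and sense abundances must be positive")
  }
  keep <- rows$co1 / rows$input > fc &
    rows$co2 / rows$input > fc &
    rows$co1 / rows$input > rows$sense / rows$input &
    rows$co2 / rows$input > rows$sense / rows$input &
    pmax(rows$co1, rows$co2) / rows$sense > fc
  out <- rows[keep, , drop = FALSE]
  attr(out, "flags") <- keep
  out
}

#' Read a proteome table from TSV
#'
#' Expects a \code{protein_id} column plus paired \code{log2fe_<comp>} and
#' \code{fdr_<comp>} columns, one pair per compartment.
#'
#' @param file TSV path.
#' @return A [proteome_matrix()].
#' @export
read_proteome_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  fe_cols <- grep("^log2fe_", names(df), value = TRUE)
  comps <- sub("^log2fe_", "", fe_cols)
  fdr_cols <- paste0("fdr_", comps)
  if (length(fe_cols) == 0 || !all(fdr_cols %in% names(df))) {
    stop("expected paired log2fe_<comp>/fdr_<comp> columns")
  }
  log2fe <- as.matrix(df[, fe_cols]); colnames(log2fe) <- comps
  fdr <- as.matrix(df[, fdr_cols]); colnames(fdr) <- comps
  rownames(log2fe) <- rownames(fdr) <- df$protein_id
  proteome_matrix(log2fe, fdr)
}
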