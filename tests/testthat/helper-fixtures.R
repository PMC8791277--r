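# In-code fixtures shared across the suite.

# Minimal gene table: genes placed by explicit midpoints on one or more
# chromosomes. A 2 bp span centred on the midpoint keeps
# floor((start + end) / 2) exactly equal to the requested midpoint.
toy_gene_table <- function(mids_by_chrom, chrom_len = 1e6, tpm = NULL,
                           strand = NULL) {
  rows <- do.call(rbind, lapply(names(mids_by_chrom), function(ch) {
    m <- mids_by_chrom[[ch]]
    data.frame(chrom = ch, mid = m, stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  if (is.null(tpm)) tpm <- rep(10, n)
  if (is.null(strand)) strand <- rep("+", n)
  start <- pmax(0, rows$mid - 1)
  end <- pmin(chrom_len, rows$mid + 1)
  cs <- stats::setNames(rep(chrom_len, length(mids_by_chrom)),
                        names(mids_by_chrom))
  gene_table(
    data.frame(gene_id = sprintf("t%03d", seq_len(n)), chrom = rows$chrom,
               start = start, end = end, strand = strand, tpm = tpm,
               stringsAsFactors = FALSE),
    cs
  )
}

# Status factor helper.
as_status <- function(x) factor(x, levels = label_levels())

# Exhaustive hypergeometric upper-tail oracle from binomial coefficients,
# independent of phyper: P(X >= a) for the (a b; c d) table.
hyper_tail_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + b   # row-1 total
  n <- a + c   # col-1 total
  if (N == 0) return(1)
  xs <- max(a, 0):min(K, n)
  if (length(xs) == 0 || a > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
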