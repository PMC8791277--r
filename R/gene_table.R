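#' Construct a gene table
#'
#' A gene table couples per-gene genomic coordinates with the chromosome sizes
#' they live on. Coordinates are 0-based, half-open (BED convention)
#' throughout the package; GTF input is converted on read.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} ("+" or "-") and \code{tpm}
#'   (non-negative transcript-per-million expression).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param counts optional integer matrix of per-sample read counts with one
#'   row per gene (rownames matching \code{gene_id}).
#'
#' @return An object of class \code{gene_table}: a list with elements
#'   \code{genes}, \code{chrom_sizes} and (optionally) \code{counts}.
#' @export
gene_table <- function(genes, chrom_sizes, counts = NULL) {
  stopifnot(is.data.frame(genes))
  req <- c("gene_id", "chrom", "start", "end", "strand", "tpm")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$tpm < 0)) stop("tpm must be non-negative")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector")
  }
  bad_chrom <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(bad_chrom) > 0) {
    stop("chromosomes absent from chrom_sizes: ", paste(bad_chrom, collapse = ", "))
  }
  len <- chrom_sizes[genes$chrom]
  if (any(genes$start < 0 | genes$start >= genes$end | genes$end > len)) {
    stop("coordinates must satisfy 0 <= start < end <= chromosome length")
  }
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (nrow(counts) != nrow(genes)) stop("counts rows must match genes")
    if (any(counts < 0)) stop("counts must be non-negative")
    rownames(counts) <- genes$gene_id
  }
  structure(
    list(genes = genes, chrom_sizes = chrom_sizes, counts = counts),
    class = "gene_table"
  )
}

#' @export
print.gene_table <- function(x, ...) {
  cat("gene_table:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosomes\n")
  if (!is.null(x$counts)) {
    cat("counts matrix:", ncol(x$counts), "samples\n")
  }
  invisible(x)
}

#' Gene midpoints
#'
#' Integer midpoint \code{floor((start + end) / 2)} of each gene, the single
#' coordinate used for window assignment, interval overlap and the
#' intergenic-distance resampling.
#'
#' @param gt a \code{gene_table}.
#' @return Named numeric vector of midpoints (names are gene ids).
#' @export
gene_midpoints <- function(gt) {
  stopifnot(inherits(gt, "gene_table"))
  mids <- floor((gt$genes$start + gt$genes$end) / 2)
  names(mids) <- gt$genes$gene_id
  mids
}

#' Read a gene table from TSV plus a chrom.sizes file
#'
#' @param genes_file TSV with columns gene_id, chrom, start, end, strand, tpm.
#' @param chrom_sizes_file two-column TSV (chrom, length), no header.
#' @return A \code{gene_table}.
#' @export
read_gene_table <- function(genes_file, chrom_sizes_file) {
  genes <- utils::read.delim(genes_file, stringsAsFactors = FALSE)
  gene_table(genes, read_chrom_sizes(chrom_sizes_file))
}

#' Read a chrom.sizes file
#'
#' @param file two-column TSV (chrom, length in bp), no header.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(file) {
  cs <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  stats::setNames(as.numeric(cs$length), cs$chrom)
}

#' Write a gene table and its chrom.sizes to TSV
#'
#' @param gt a \code{gene_table}.
#' @param genes_file,chrom_sizes_file output paths.
#' @export
write_gene_table <- function(gt, genes_file, chrom_sizes_file = NULL) {
  stopifnot(inherits(gt, "gene_table"))
  utils::write.table(gt$genes, genes_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(chrom_sizes_file)) {
    utils::write.table(
      data.frame(chrom = names(gt$chrom_sizes), length = gt$chrom_sizes),
      chrom_sizes_file, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  invisible(gt)
}

#' Read gene records from an Ensembl-dialect GTF
#'
#' Produces one record per gene spanning the outermost transcript bounds,
#' converting GTF 1-based closed coordinates to the package's 0-based
#' half-open convention. TPM values are not carried by GTF and are set to 0.
#'
#' @param gtf_file path to a GTF file.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return A \code{gene_table}.
#' @export
read_gtf_genes <- function(gtf_file, chrom_sizes) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gtf_genes requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(gtf_file, format = "gtf"))
  gr <- gr[gr$type %in% c("transcript", "exon"), , drop = FALSE]
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(gr$seqnames),
    start = gr$start - 1L,  # GTF 1-based closed to 0-based half-open
    end = gr$end,
    strand = as.character(gr$strand),
    stringsAsFactors = FALSE
  )
  agg <- do.call(rbind, lapply(split(df, df$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1], tpm = 0,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  gene_table(agg[order(agg$chrom, agg$start), , drop = FALSE], chrom_sizes)
}

#' Read an interval set from BED
#'
#' Accepts BED3+; extra columns beyond chrom/start/end are ignored except a
#' 6th (strand) and, when \code{family_col} is given, a repeat-family column.
#'
#' @param file BED file path (0-based half-open, as BED).
#' @param family_col optional index of a column holding a repeat family name.
#' @return data.frame with columns chrom, start, end and, when present,
#'   strand and family.
#' @export
read_bed <- function(file, family_col = NULL) {
  bed <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.numeric(bed[[2]]),
                    end = as.numeric(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 6) out$strand <- as.character(bed[[6]])
  if (!is.null(family_col)) out$family <- as.character(bed[[family_col]])
  if (any(out$start >= out$end)) stop("BED intervals must satisfy start < end")
  out
}

#' Write intervals as BED
#'
#' @param intervals data.frame with chrom, start, end and optional name,
#'   score, strand columns.
#' @param file output path.
#' @export
write_bed <- function(intervals, file) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(intervals)
}

# Merge possibly overlapping intervals on one chromosome; returns a matrix
# of (start, end) rows sorted by start. Used for midpoint-in-interval tests.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (length(start) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# Midpoint-in-merged-interval flags for positions on one chromosome.
points_in_intervals <- function(pos, merged) {
  if (nrow(merged) == 0) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, merged[, "start"])
  inside <- idx > 0
  inside[inside] <- pos[inside] < merged[idx[inside], "end"]
  inside
}
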