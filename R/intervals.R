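#' @import methods
#' @importFrom stats p.adjust pbinom pt rbinom runif rpois setNames var fisher.test fft
#' @importFrom utils read.delim write.table modifyList
NULL

#' Chromosome sizes
#'
#' Build a validated chromosome-size map (the coordinate system every interval
#' and coverage track is checked against) from a named vector, a
#' [Biostrings::DNAStringSet], or a FASTA file path.
#'
#' @param x Named numeric vector of lengths, a `DNAStringSet`, or a single
#'   FASTA path.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_sizes <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    x <- setNames(Biostrings::width(x), names(x))
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("chrom_sizes: all chromosomes must be named")
  }
  if (anyDuplicated(names(x))) stop("chrom_sizes: duplicated chromosome names")
  if (any(!is.finite(x)) || any(x <= 0)) stop("chrom_sizes: lengths must be positive")
  setNames(as.integer(x), names(x))
}

#' Construct genomic intervals
#'
#' Convenience constructor for a [GenomicRanges::GRanges] from parallel
#' vectors, validated against a chromosome-size map. Coordinates are 1-based
#' closed (the GRanges convention); BED input is converted on read by
#' [read_intervals()].
#'
#' @param chrom,start,end,strand Parallel vectors (strand defaults to `"*"`).
#' @param sizes Optional [chrom_sizes()] vector to validate against.
#' @return A `GRanges`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", sizes = NULL) {
  if (any(start < 1L) || any(end < start)) {
    stop("genomic_intervals: require 1 <= start <= end")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  if (!is.null(sizes)) validate_intervals(gr, sizes)
  gr
}

#' Validate intervals against a chromosome-size map
#'
#' @param gr A `GRanges`.
#' @param sizes A [chrom_sizes()] vector.
#' @return `gr`, invisibly, after checking every interval lies on a known
#'   chromosome and within its bounds.
#' @export
validate_intervals <- function(gr, sizes) {
  chr <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(chr), names(sizes))
  if (length(bad)) stop("intervals on unknown chromosomes: ", paste(bad, collapse = ", "))
  if (any(GenomicRanges::end(gr) > sizes[chr])) {
    stop("intervals extend beyond chromosome ends")
  }
  invisible(gr)
}

#' Do two intervals overlap?
#'
#' Strand-blind overlap under the usual peak/repeat intersection semantics:
#' true iff same chromosome and the intersection has positive width.
#'
#' @param a,b Single-interval `GRanges` (or equal-length vectors, compared
#'   elementwise).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  stopifnot(length(a) == length(b))
  as.character(GenomicRanges::seqnames(a)) == as.character(GenomicRanges::seqnames(b)) &
    GenomicRanges::start(a) <= GenomicRanges::end(b) &
    GenomicRanges::start(b) <= GenomicRanges::end(a)
}

#' Count query intervals overlapping a subject set
#'
#' Each query interval is counted at most once, however many subject
#' intervals it touches. Strand is ignored.
#'
#' @param query,subject `GRanges`.
#' @return Single integer count.
#' @export
count_overlapping <- function(query, subject) {
  if (length(query) == 0L || length(subject) == 0L) return(0L)
  sum(GenomicRanges::countOverlaps(query, subject, ignore.strand = TRUE) > 0L)
}

# ---- gene models -------------------------------------------------------------

#' Construct a gene-model table
#'
#' A gene model records, per gene: chromosome, strand, TSS, the annotated
#' first exon, and the gene body. The TSS must sit on the strand-appropriate
#' edge of the gene body and the first exon must lie inside the body. In
#' trans-splicing nematodes the annotated gene start is typically the
#' trans-splice acceptor, so the promoter (and the outron) lies upstream of
#' and outside the gene body.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `exon1_start`, `exon1_end`, `body_start`, `body_end` (1-based closed).
#' @return The validated data.frame with class `gene_models`.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tss",
            "exon1_start", "exon1_end", "body_start", "body_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene_models: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("gene_models: duplicated gene ids")
  if (!all(df$strand %in% c("+", "-"))) stop("gene_models: strand must be + or -")
  ok_exon <- df$exon1_start >= df$body_start & df$exon1_end <= df$body_end
  if (!all(ok_exon)) stop("gene_models: first exon not contained in gene body")
  edge <- ifelse(df$strand == "+", df$body_start, df$body_end)
  if (!all(df$tss == edge)) stop("gene_models: TSS must equal the 5' edge of the gene body")
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Gene bodies as GRanges
#' @param genes A [gene_models()] table.
#' @return `GRanges` of gene bodies (named by gene id).
#' @export
gene_body_ranges <- function(genes) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$body_start, genes$body_end),
                               strand = genes$strand)
  names(gr) <- genes$gene_id
  gr
}
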