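# Coverage tracks: per-base, per-chromosome signal held as run-length encoded
# vectors (IRanges Rle), one RleList per strand when stranded. ATAC signal is
# unstranded; nuclear RNA-seq signal is stranded.

#' Create an empty coverage track
#'
#' @param sizes A [chrom_sizes()] vector.
#' @param stranded Logical; stranded tracks hold one signal vector per strand.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(sizes, stranded = FALSE) {
  zero <- methods::as(setNames(as.list(sizes * 0L), names(sizes)), "RleList")
  zero <- IRanges::RleList(lapply(sizes, function(n) S4Vectors::Rle(0, n)))
  names(zero) <- names(sizes)
  tr <- list(sizes = sizes, stranded = isTRUE(stranded),
             plus = zero, minus = if (isTRUE(stranded)) zero else NULL)
  class(tr) <- "coverage_track"
  tr
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), %s\n", length(x$sizes),
              if (x$stranded) "stranded" else "unstranded"))
  invisible(x)
}

#' Build a coverage track from weighted segments
#'
#' Segment scores add where segments overlap, as with piled-up read coverage.
#'
#' @param segments `GRanges` with a numeric `score` column; for stranded
#'   tracks, strand must be `+` or `-`.
#' @param sizes A [chrom_sizes()] vector.
#' @param stranded Logical.
#' @return A `coverage_track`.
#' @export
track_from_segments <- function(segments, sizes, stranded = FALSE) {
  validate_intervals(segments, sizes)
  sc <- segments$score
  if (is.null(sc)) stop("track_from_segments: segments need a score column")
  if (any(sc < 0)) stop("track_from_segments: coverage must be non-negative")
  tr <- coverage_track(sizes, stranded)
  cov1 <- function(gr) {
    gr <- GenomicRanges::GRanges(
      factor(as.character(GenomicRanges::seqnames(gr)), levels = names(sizes)),
      IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
      score = gr$score,
      seqlengths = sizes)
    GenomicRanges::coverage(gr, weight = gr$score)
  }
  if (stranded) {
    st <- as.character(GenomicRanges::strand(segments))
    if (any(st == "*")) stop("track_from_segments: stranded track needs +/- segments")
    tr$plus <- cov1(segments[st == "+"])
    tr$minus <- cov1(segments[st == "-"])
  } else {
    tr$plus <- cov1(segments)
  }
  tr
}

strand_slot <- function(track, strand) {
  if (!track$stranded) return(track$plus)
  switch(strand, "+" = track$plus, "-" = track$minus,
         stop("coverage_track: strand must be '+' or '-' for a stranded track"))
}

#' Extract a per-base signal window
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed coordinates.
#' @param strand Which strand's signal to read (ignored for unstranded).
#' @return Numeric vector of length `end - start + 1`.
#' @export
track_view <- function(track, chrom, start, end, strand = "+") {
  rl <- strand_slot(track, strand)
  if (!chrom %in% names(rl)) stop("track_view: unknown chromosome ", chrom)
  n <- track$sizes[[chrom]]
  if (start < 1L || end > n || start > end) stop("track_view: window out of bounds")
  as.numeric(S4Vectors::window(rl[[chrom]], start, end))
}

#' Write a coverage track as bedGraph
#'
#' Unstranded tracks write one file; stranded tracks write one per strand.
#' Zero runs are omitted (the bedGraph convention); reading restores them.
#'
#' @param track A `coverage_track`.
#' @param path Output path (unstranded), or base path: `<path>.plus.bedGraph`
#'   and `<path>.minus.bedGraph` when stranded.
#' @return Invisibly, the path(s) written.
#' @export
write_coverage <- function(track, path) {
  dump1 <- function(rl, p) {
    gr <- methods::as(rl, "GRanges")
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, p, format = "bedGraph")
    p
  }
  if (track$stranded) {
    paths <- c(dump1(track$plus, paste0(path, ".plus.bedGraph")),
               dump1(track$minus, paste0(path, ".minus.bedGraph")))
  } else {
    paths <- dump1(track$plus, path)
  }
  invisible(paths)
}

#' Read a coverage track from bedGraph
#'
#' @param sizes A [chrom_sizes()] vector.
#' @param path Path to a bedGraph (unstranded) or plus-strand file.
#' @param minus_path Optional path to the minus-strand bedGraph; providing it
#'   yields a stranded track.
#' @return A `coverage_track`.
#' @export
read_coverage <- function(sizes, path, minus_path = NULL) {
  load1 <- function(p, strand) {
    gr <- rtracklayer::import(p, format = "bedGraph")
    GenomicRanges::strand(gr) <- strand
    gr
  }
  if (is.null(minus_path)) {
    track_from_segments(load1(path, "*"), sizes, stranded = FALSE)
  } else {
    track_from_segments(c(load1(path, "+"), load1(minus_path, "-")),
                        sizes, stranded = TRUE)
  }
}
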