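# Readers/writers for the plain-text formats the pipeline touches. All format
# parsing is delegated to rtracklayer/Biostrings; these wrappers pin down the
# package's conventions (validation against chrom sizes, gene-model columns).

#' Read a BED file as intervals
#'
#' BED 0-based half-open coordinates are converted to 1-based closed GRanges
#' on read (rtracklayer semantics).
#'
#' @param path BED file path.
#' @param sizes Optional [chrom_sizes()] to validate against.
#' @return `GRanges` with any name/score columns carried in `mcols`.
#' @export
read_intervals <- function(path, sizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(sizes)) validate_intervals(gr, sizes)
  gr
}

#' Write intervals as BED
#'
#' @param gr `GRanges`; `name`/`score` metadata columns are written if present.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature per gene (ID = gene id) and one `exon` feature for
#' the annotated first exon (Parent = gene id).
#'
#' @param genes A [gene_models()] table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$body_start, genes$body_end),
                              strand = genes$strand,
                              type = "gene", ID = genes$gene_id,
                              Parent = NA_character_)
  e <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$exon1_start, genes$exon1_end),
                              strand = genes$strand,
                              type = "exon",
                              ID = paste0(genes$gene_id, ".e1"),
                              Parent = genes$gene_id)
  gr <- c(g, e)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Takes `gene` features for gene bodies and, per gene, the 5'-most `exon`
#' feature as the annotated first exon. GFF3 1-based inclusive coordinates are
#' kept (GRanges convention). The TSS is the strand-appropriate edge of the
#' gene body.
#'
#' @param path GFF3 path.
#' @param chromosomes Optional character vector: restrict to these chromosomes
#'   (e.g. fully assembled ones), dropping genes elsewhere.
#' @return A [gene_models()] table.
#' @export
read_gene_models <- function(path, chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "GFF3")
  if (!is.null(chromosomes)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% chromosomes]
  }
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  if (!length(genes)) stop("read_gene_models: no gene features in ", path)
  gid <- as.character(genes$ID)
  parent <- vapply(as.list(exons$Parent),
                   function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  strand_g <- as.character(GenomicRanges::strand(genes))
  exon1 <- t(vapply(seq_along(genes), function(i) {
    ex <- exons[parent == gid[i]]
    if (!length(ex)) stop("read_gene_models: gene without exons: ", gid[i])
    first <- if (strand_g[i] == "+") ex[which.min(GenomicRanges::start(ex))]
             else ex[which.max(GenomicRanges::end(ex))]
    c(GenomicRanges::start(first), GenomicRanges::end(first))
  }, integer(2)))
  gene_models(data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    strand = strand_g,
    tss = ifelse(strand_g == "+", GenomicRanges::start(genes), GenomicRanges::end(genes)),
    exon1_start = exon1[, 1], exon1_end = exon1[, 2],
    body_start = GenomicRanges::start(genes),
    body_end = GenomicRanges::end(genes),
    stringsAsFactors = FALSE
  ))
}

#' Read/write a TSV table with header
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @param df data.frame to write.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
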