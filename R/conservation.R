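# Cross-species conservation of co-opted promoters over 1:1 orthologs.
# Eligibility: at least one ortholog carries a CERP2-like co-opted promoter
# (divergent m1m2 pair, 12-16 bp spacing). Classes, first matching rule wins:
#   conserved              both orthologs have a co-opted promoter
#   potentially_conserved  the other ortholog has a promoter containing a lone
#                          m1 or m2, OR a divergent m1m2 pair sits in the
#                          putative promoter window [TSS-1000, TSS+200]
#                          (strand-oriented) without an annotated promoter
#   species_specific       none of the above

#' Read a 1:1 ortholog table
#'
#' @param path TSV with two id columns (species A, species B).
#' @return data.frame with columns `gene_a`, `gene_b`, validated 1:1.
#' @export
read_ortholog_pairs <- function(path) {
  df <- read_tsv_table(path)
  if (ncol(df) < 2L) stop("read_ortholog_pairs: need two id columns")
  ortholog_pairs(df[[1]], df[[2]])
}

#' Construct a validated 1:1 ortholog table
#' @param gene_a,gene_b Parallel id vectors.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
ortholog_pairs <- function(gene_a, gene_b) {
  if (anyDuplicated(gene_a) || anyDuplicated(gene_b)) {
    stop("ortholog_pairs: mapping must be 1:1 (duplicated ids)")
  }
  data.frame(gene_a = as.character(gene_a), gene_b = as.character(gene_b),
             stringsAsFactors = FALSE)
}

# per-species evidence for one gene
gene_evidence <- function(gene_id, promoters, pairs, singles, genes,
                          upstream, downstream) {
  g <- genes[genes$gene_id == gene_id, ]
  pr <- promoters[promoters$gene_id == gene_id, , drop = FALSE]
  if (nrow(pr) && any(pr$is_coopted)) {
    fam <- pr$coopted_family[pr$is_coopted]
    return(list(code = if (any(fam == "CERP2_like")) "coopted_CERP2" else "coopted",
                coopted = TRUE, cerp2 = any(fam == "CERP2_like")))
  }
  # (i) a promoter of this gene containing a lone m1 or m2
  if (nrow(pr) && length(singles)) {
    sr <- GenomicRanges::GRanges(pr$chrom, IRanges::IRanges(pr$start, pr$end))
    hit <- GenomicRanges::findOverlaps(sr, singles, ignore.strand = TRUE)
    if (length(hit)) {
      mot <- unique(singles$motif[S4Vectors::subjectHits(hit)])
      return(list(code = paste0("promoter_single_", paste(sort(mot), collapse = "")),
                  coopted = FALSE, cerp2 = FALSE))
    }
  }
  # (ii) a divergent pair in the putative promoter window, not in a promoter
  div <- pairs[pairs$arrangement == "divergent"]
  if (length(div)) {
    win <- if (g$strand == "+") c(g$tss - upstream, g$tss + downstream)
           else c(g$tss - downstream, g$tss + upstream)
    win_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(max(1L, win[1]), win[2]))
    inwin <- div[GenomicRanges::countOverlaps(div, win_gr, ignore.strand = TRUE) > 0L]
    if (length(inwin)) {
      if (nrow(promoters)) {
        all_pr <- GenomicRanges::GRanges(
          promoters$chrom, IRanges::IRanges(promoters$start, promoters$end))
        inwin <- inwin[GenomicRanges::countOverlaps(inwin, all_pr,
                                                    ignore.strand = TRUE) == 0L]
      }
      if (length(inwin)) {
        return(list(code = "window_pair", coopted = FALSE, cerp2 = FALSE))
      }
    }
  }
  list(code = "none", coopted = FALSE, cerp2 = FALSE)
}

#' Classify conservation of co-opted promoters over ortholog pairs
#'
#' @param pairs An [ortholog_pairs()] table.
#' @param promoters_a,promoters_b Promoter calls (after [flag_coopted()]) per
#'   species.
#' @param motif_pairs_a,motif_pairs_b Pair `GRanges` from
#'   [pair_and_classify()] per species.
#' @param singles_a,singles_b `GRanges` of individual m1/m2 occurrences per
#'   species (a `motif` metadata column names the motif).
#' @param genes_a,genes_b [gene_models()] tables per species.
#' @param upstream,downstream Putative-promoter window around the TSS in bp
#'   (defaults 1000 upstream, 200 downstream, oriented by gene strand).
#' @return data.frame: `gene_a`, `gene_b`, `eligible`, `class` (NA for
#'   ineligible pairs), `evidence_a`, `evidence_b`.
#' @export
classify_conservation <- function(pairs, promoters_a, promoters_b,
                                  motif_pairs_a, motif_pairs_b,
                                  singles_a, singles_b, genes_a, genes_b,
                                  upstream = 1000L, downstream = 200L) {
  bad_a <- setdiff(pairs$gene_a, genes_a$gene_id)
  bad_b <- setdiff(pairs$gene_b, genes_b$gene_id)
  if (length(bad_a) || length(bad_b)) {
    stop("classify_conservation: gene ids absent from gene models: ",
         paste(c(bad_a, bad_b), collapse = ", "))
  }
  out <- pairs
  out$eligible <- FALSE
  out$class <- NA_character_
  out$evidence_a <- out$evidence_b <- NA_character_
  for (i in seq_len(nrow(pairs))) {
    ea <- gene_evidence(pairs$gene_a[i], promoters_a, motif_pairs_a, singles_a,
                        genes_a, upstream, downstream)
    eb <- gene_evidence(pairs$gene_b[i], promoters_b, motif_pairs_b, singles_b,
                        genes_b, upstream, downstream)
    out$evidence_a[i] <- ea$code
    out$evidence_b[i] <- eb$code
    if (!ea$cerp2 && !eb$cerp2) next  # ineligible: no CERP2-like co-option
    out$eligible[i] <- TRUE
    out$class[i] <- if (ea$coopted && eb$coopted) "conserved"
      else if (ea$code %in% c("promoter_single_m1", "promoter_single_m2",
                              "promoter_single_m1m2", "window_pair") ||
               eb$code %in% c("promoter_single_m1", "promoter_single_m2",
                              "promoter_single_m1m2", "window_pair"))
        "potentially_conserved"
      else "species_specific"
  }
  out
}

#' Tabulate conservation classes
#' @param calls Output of [classify_conservation()].
#' @return data.frame of class counts and percentages over eligible pairs.
#' @export
conservation_summary <- function(calls) {
  el <- calls[calls$eligible, ]
  cls <- c("conserved", "potentially_conserved", "species_specific")
  n <- vapply(cls, function(k) sum(el$class == k), integer(1))
  data.frame(class = cls, count = n,
             percent = fraction_percent(n, nrow(el)),
             stringsAsFactors = FALSE)
}
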