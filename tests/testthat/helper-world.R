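# Shared fixtures, generated in code and cached for the whole test run.
# The "small" world (0.8 Mb) exercises every feature including bidirectional
# promoters; the "default" world (5 Mb) is the stated world of the
# acceptance criteria.

.world_cache <- new.env(parent = emptyenv())

small_world_config <- function(seed = 7L) {
  synthetic_config(seed = seed,
                   chrom_lengths = c(chrI = 400000L, chrII = 400000L),
                   n_genes = 80L, n_cerp2 = 50L, n_cele2 = 34L,
                   n_bidirectional = 3L)
}

small_world <- function() {
  if (is.null(.world_cache$small)) {
    .world_cache$small <- suppressWarnings(generate_world(small_world_config()))
  }
  .world_cache$small
}

default_world <- function() {
  if (is.null(.world_cache$default)) {
    .world_cache$default <- suppressWarnings(generate_world(synthetic_config(seed = 1L)))
  }
  .world_cache$default
}

world_pipeline <- function(world_fn, species = c("a", "b")) {
  species <- match.arg(species)
  key <- paste0(substitute(world_fn), "_", species)
  key <- paste0(if (identical(world_fn, small_world)) "small" else "default",
                "_", species)
  if (is.null(.world_cache[[key]])) {
    w <- world_fn()
    sp <- w$species[[species]]
    .world_cache[[key]] <- suppressWarnings(run_species_pipeline(
      sp$genome, sp$genes, sp$sites_gr, sp$counts,
      wt_cols = c("wt_1", "wt_2"), gl_cols = c("gl_1", "gl_2"),
      rna = sp$rna, pwms = w$pwms))
  }
  .world_cache[[key]]
}

# brute-force quadratic overlap-count oracle
oracle_count_overlapping <- function(query, subject) {
  n <- 0L
  for (i in seq_along(query)) {
    hit <- FALSE
    for (j in seq_along(subject)) {
      if (as.character(GenomicRanges::seqnames(query)[i]) ==
            as.character(GenomicRanges::seqnames(subject)[j]) &&
          GenomicRanges::start(query)[i] <= GenomicRanges::end(subject)[j] &&
          GenomicRanges::start(subject)[j] <= GenomicRanges::end(query)[i]) {
        hit <- TRUE
        break
      }
    }
    n <- n + hit
  }
  n
}

random_intervals <- function(n, sizes, max_width = 500L) {
  chr <- sample(names(sizes), n, replace = TRUE)
  w <- sample(seq_len(max_width), n, replace = TRUE)
  s <- vapply(seq_len(n), function(i) sample(sizes[[chr[i]]] - w[i], 1L), integer(1))
  GenomicRanges::GRanges(chr, IRanges::IRanges(s, width = w))
}

# expand bidirectional site rows into one row per (site, gene)
truth_site_gene <- function(sp) {
  do.call(rbind, lapply(seq_len(nrow(sp$sites)), function(i) {
    data.frame(site_id = sp$sites$site_id[i],
               gene_id = strsplit(sp$sites$gene_id[i], ",")[[1]],
               germline = sp$sites$germline[i], stringsAsFactors = FALSE)
  }))
}
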