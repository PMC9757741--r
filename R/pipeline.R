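# End-to-end convenience wrapper: from a species' raw inputs (genome, genes,
# peaks, ATAC counts, RNA track, PWMs) to accessibility calls, promoter
# calls with co-option flags, motif occurrences and pairs.

#' Run the per-species analysis chain
#'
#' Accessibility classification, motif scanning (m1 and m2), pair
#' annotation, promoter annotation, and co-option flagging, in order.
#'
#' @param genome `DNAStringSet`.
#' @param genes [gene_models()] table.
#' @param peaks `GRanges` of accessible sites (named).
#' @param counts Count matrix with wild-type / germline-less columns.
#' @param wt_cols,gl_cols Condition column names in `counts`.
#' @param rna Stranded [coverage_track()].
#' @param pwms List with elements `m1` and `m2` ([pwm()] objects).
#' @param p_threshold Motif scan threshold (default 5e-4).
#' @param ... Passed to [annotate_promoters()].
#' @return List: `accessibility`, `m1_hits`, `m2_hits`, `pairs`,
#'   `promoters` (with germline and co-option flags), `background`.
#' @export
run_species_pipeline <- function(genome, genes, peaks, counts, wt_cols, gl_cols,
                                 rna, pwms, p_threshold = 0.0005, ...) {
  pcm <- peak_count_matrix(peaks, counts, wt_cols, gl_cols)
  acc <- classify_germline_specific(pcm)
  bg <- estimate_background(genome)
  m1_hits <- scan_pwm(genome, pwms$m1, p_threshold, background = bg)
  m2_hits <- scan_pwm(genome, pwms$m2, p_threshold, background = bg)
  pairs <- pair_and_classify(m1_hits, m2_hits)
  prom <- annotate_promoters(peaks, rna, genes, accessibility_calls = acc, ...)
  prom <- flag_coopted(prom, pairs)
  list(accessibility = acc, m1_hits = m1_hits, m2_hits = m2_hits,
       pairs = pairs, promoters = prom, background = bg)
}

#' Minimal command-line interface
#'
#' Subcommands: `simulate` (generate the synthetic world),
#' `enrich` (permutation enrichment from BED inputs). Configuration is JSON
#' (`--config config.json`); common flags: `--seed`, `--out`.
#'
#' @param args Character vector of arguments (default: command line).
#' @return Exit status, invisibly.
#' @export
mite_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mitecoopt <simulate|enrich> [--config <json>] [--seed <int>]",
    "[--out <dir>]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  cfg_file <- opt("--config")
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "mitecoopt_out")
  if (cmd == "simulate") {
    over <- if (!is.null(cfg_file)) jsonlite::read_json(cfg_file, simplifyVector = TRUE) else list()
    cfg <- do.call(synthetic_config, modifyList(list(seed = seed), as.list(over)))
    generate_world(cfg, out_dir = out)
    message("world written to ", out)
  } else if (cmd == "enrich") {
    conf <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
    sizes <- chrom_sizes(read_genome(conf$genome))
    res <- permutation_enrichment(
      read_intervals(conf$repeats, sizes), read_intervals(conf$promoters, sizes),
      read_intervals(conf$gene_bodies, sizes), sizes,
      n = if (!is.null(conf$n)) conf$n else 1000L, seed = seed)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_permutation_result(res, file.path(out, "enrichment.tsv"))
    message("p = ", res$pvalue)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
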