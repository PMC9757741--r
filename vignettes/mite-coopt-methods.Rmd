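---
title: "Methods: detecting MITE-derived germline promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting MITE-derived germline promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`mitecoopt`, the assumptions behind them, the tunable parameters with their
defaults and units, what the synthetic-data generator emulates (and what it
does not), and the numerical and design choices made where the methods left
room. It states no empirical result that the package's tests and acceptance
script do not themselves compute.

## 1. The inference chain

The package reconstructs how miniature inverted repeat transposable elements
(MITEs) become germline promoters. Two element families matter: a
CERP2-like family whose inverted repeats carry the m1 and m2 motifs in
*divergent* orientation spaced 12–16 bp apart, and a CELE2-like family
carrying them as a *tandem m2+m1+* arrangement spaced 23–28 bp apart. The
chain is: classify accessible sites as germline-specific (ATAC), annotate
promoters from nuclear RNA signal, map motif pairs and flag co-opted
promoters, test repeat enrichment by permutation, call direct targets of the
regulating transcription factor, and classify cross-species conservation of
each co-option event.

Coordinates are handled as `GRanges` (1-based closed) throughout;
BED/bedGraph 0-based half-open conversion happens in `rtracklayer` at the
I/O boundary. All overlap tests ignore strand unless a procedure states
otherwise. Inter-motif *spacing* is the count of bases strictly between two
occurrence intervals (gap semantics, `start2 − end1 − 1` in 1-based closed
terms), not a center-to-center distance; this choice changes arrangement
classifications and is therefore stated prominently. The distinct
CERP2/CELE2 spacing supports (12–16 vs 23–28 bp) are consistent with gap
semantics.

## 2. Germline-specific accessibility

`classify_germline_specific()` takes a peak count matrix (≥ 2 replicates per
condition) and labels a peak `germline_specific` iff the log2 fold change of
mean germline-less CPM over mean wild-type CPM (pseudocount 1 on CPM) is
below −2 **and** the Benjamini–Hochberg adjusted p-value is below 0.01.

The differential test is a declared stand-in for a DiffBind/DESeq2 fit: a
**pooled-variance two-sample t-test** (df = n₁+n₂−2) on log2(CPM+1) across
replicates. Welch's variant was considered and rejected: with the default
two replicates per condition its Satterthwaite df collapses toward 1 and the
measured null rejection rate at α = 0.05 is ≈ 0.034, i.e. badly
conservative, whereas the pooled test measures ≈ 0.051 — calibration was
preferred over the specific test name. Degenerate zero-variance inputs
(exactly reproducible counts, as in the noise-free synthetic world) are
resolved deterministically: p = 0 when the condition means differ, p = 1
when they are equal.

Two properties are worth spelling out. The label set is invariant under
replicate relabeling (both the LFC and the pooled test are symmetric in
replicates). Monotonicity under decreasing germline-less counts holds for
the LFC but **not** universally for the p-value: any test built on replicate
variance can see its p-value worsen when counts drop unevenly. The tests
therefore assert the guaranteed form — LFC monotone, and the extreme
decrease (all germline-less counts zero) always preserves the label.

## 3. Promoter annotation from nuclear RNA signal

Trans-splicing replaces the 5′ outron of the pre-mRNA with a leader
sequence, so annotated gene starts mark trans-splice acceptors; promoters
lie upstream, connected to the first exon by outron transcription visible in
nuclear RNA-seq. `annotate_promoters()` calls a site a promoter of gene *g*
iff both of:

1. **Linking** (`link_site_to_first_exon()`): walking from the site
   *midpoint* toward *g*'s annotated first exon over strand-matched
   coverage, no maximal run of zero-coverage positions exceeds `max_gap`
   (default **200 bp**; a 201-bp gap breaks the link — this boundary is
   tested exactly). A midpoint already inside the first exon links
   trivially (flagged); a midpoint strand-downstream of the first exon
   cannot link.
2. **Directional asymmetry** (`directional_signal_test()`): summed
   strand-matched coverage in the window +75..+350 bp from the midpoint (in
   the downstream gene's orientation) must significantly exceed the
   −350..−75 bp window. "Significantly higher" is not defined by the source
   procedure; the package's choice is a one-sided binomial test on the
   integerized window sums (success = downstream), requiring total ≥ 10 and
   p < 0.05. It is simple, calibrated under signal symmetry, and matches
   the windowed-count framing. Windows truncated by a chromosome end fail
   with a `truncated` flag. Zero signal in both windows fails (no
   evidence), it is not an error.

Candidate genes are those whose first exon lies within `search_radius`
(default **5 kb**) strand-downstream of the site midpoint; the search is not
bounded in the source procedure and 5 kb covers outron lengths seen in
practice while keeping the candidate set small. A site may be the promoter
of two genes — divergent gene pairs sharing one accessible site yield two
promoter calls. The walk anchor is the site midpoint (the same anchor the
directional test uses). Walks that cross another gene's body are linked but
flagged (`crosses_gene`), since the source procedure does not state whether
linking may pass intervening genes. Where a gene has several annotated
first exons the 5′-most is used (the synthetic world plants exactly one).
Per-track depth normalization replaces the source's pseudoreplicate
balancing of sequencing depth; at desk scale the tracks are generated, not
sequenced, so there is no depth imbalance to correct.

## 4. Motif scanning and pair classification

`scan_pwm()` reports occurrences with exact p-value ≤ `p_threshold`
(default **5×10⁻⁴**) on both strands. Scores are log2 odds against a
0-order background, by default the scanned sequence's own composition,
complement-symmetrized (A/T pooled, C/G pooled) so both strands share one
null distribution and a reverse-complemented genome yields the mirror-image
hit set exactly. Windows containing N are skipped.

P-values are exact by dynamic programming: the score matrix is discretized
onto a common grid of `bins = 1000` steps across the attainable score range,
the distribution of the integer score under the background is built by
convolving per-column distributions, and **both** the scan and the p-value
lookup use the same integer scores — so reported p-values are exact for the
discretized matrix, and discretization perturbs any window's continuous
score by at most `width × eps / 2` (eps = range/1000; both bounds are
tested, the DP against exhaustive enumeration up to width 8). Candidate
windows are located at C speed with `Biostrings::matchPWM` at the integer
threshold score. A PWM column summing to zero is an error; the pseudocount
(default 0.001, mixed with the background) keeps scores finite.

`pair_and_classify()` emits every (m1, m2) occurrence pair with spacing in
[10, 30] bp — all pairs, not an exclusive matching, since the analysis
counts pairs. Overlapping occurrences (negative spacing) are excluded.
Arrangements follow inverted-repeat geometry: *divergent* = opposite strands
pointing away (left motif on minus), *convergent* = opposite strands
pointing toward each other, *tandem* = same strand, named by 5′→3′ order
along that strand. Family hints: `CERP2_like` iff divergent and spaced
12–16 bp; `CELE2_like` iff tandem m2+m1+ and spaced 23–28 bp. The
classification maps onto itself under genome-wide reverse complement
(property-tested). A promoter is **co-opted** iff its interval overlaps at
least one pair footprint (leftmost to rightmost motif base).

`pair_window_sequences()` extracts each pair footprint ±50 bp oriented by
the m1 strand — the input for cross-element comparisons (guide trees,
anchored profiles). `tt_periodicity()` computes the per-offset TT
dinucleotide frequency over equal-length anchored windows and scores the
share of spectral power at period 10 bp (the nucleosome-positioning signal
these elements carry): the mean-centered profile is projected onto the
period-10 Fourier component and normalized by total power. A flat profile
scores 0. Note that for a sparse periodic spike train part of the power
sits in harmonics (period 5, 10/3, …), so even a perfectly periodic TT
arrangement scores well below 1.

## 5. Permutation enrichment

`permutation_enrichment()` counts repeats overlapping at least one promoter,
then builds a null by `n = 1000` shuffles that re-place each repeat
uniformly at random on its own chromosome among positions not intersecting
the exclusion set (gene bodies), preserving lengths — shuffleBed semantics:
shuffled intervals may overlap each other, only the exclusion set is
forbidden. Placement is by rejection sampling capped at 10,000 attempts per
round (error naming the chromosome if exhausted), which gives exactly
uniform placement over the allowed space without building gap indexes. The
empirical p-value is add-one, `(1 + #{null ≥ observed})/(n + 1)`: it can
never be 0, and n = 1000 reports maximal significance as p = 1/1001 ≤ 0.001.
Null calibration is tested by drawing the "observed" repeats from the
shuffle null itself: with 199 permutations the add-one p ≤ 0.05 event has
probability exactly 10/200, and the rejection rate over 200 runs must stay
within the 99% binomial interval.

## 6. Direct targets and summary fractions

`de_directions()` labels genes up (LFC > 0, p.adj < 0.001), down (LFC < 0,
p.adj < 0.001) or ns; duplicated gene ids are an error. A **direct target**
is a down-regulated gene with a ChIP peak on a promoter linked to it. The
published prose uses two definitions (down-regulated only vs misregulated);
both are surfaced: `mode = "down_only"` (default) and
`mode = "misregulated"`, never silently merged. `summarize_fractions()`
reports the headline counts and percentages; percentages are **truncated**
to one decimal, because that is the only convention consistent with all the
printed worked ratios (193/304 prints as 63.4, which rounding would make
63.5). `direction_bound_fisher()` provides the standard hypergeometric test
for down-vs-up skew among bound genes as a summary statistic.

## 7. Conservation classification

Over a validated 1:1 ortholog table, a pair is **eligible** iff at least one
ortholog has a CERP2-like co-opted promoter (divergent pair spaced
12–16 bp) — CELE2-like co-option is single-species and is not classified.
Classes are assigned by the first matching rule: **conserved** iff both
orthologs have a co-opted promoter; **potentially conserved** iff the other
ortholog has a promoter containing a lone m1 or m2, or a divergent pair
within the putative promoter window of its TSS without an annotated promoter
overlapping the pair; otherwise **species-specific**. The window is
TSS−1000..TSS+200 bp *oriented by gene strand* (the source notation is
strand-ambiguous; upstream-1000/downstream-200 is the biologically sensible
reading). "Associated with a promoter" means the promoter call links to
that gene, not mere proximity. Classification is symmetric in species
labels (property-tested); evidence codes record which criterion fired on
each side.

## 8. The synthetic world

`generate_world()` builds two "species" (a scaffold of 1:1 ortholog genes,
independently re-planted) with full ground truth. Defaults define the
stated world of the acceptance suite:

| parameter | default | meaning |
|---|---|---|
| chromosomes | 2 × 2.5 Mb | desk-scale genome, dense coverage affordable |
| genes | 500 | ortholog-paired, laid out in non-overlapping blocks |
| CERP2-like / CELE2-like elements | 360 / 240 | ≥ 500 repeat intervals total |
| promoter fraction | 0.45 | ~270 elements planted as active promoters (≥ 200) |
| germline fraction | 0.7 | active promoters that are germline-specific |
| base composition | A=T=0.32, C=G=0.18 | worm-like AT-rich background |
| ATAC counts | 2000 high / 4 low per replicate | deterministic by default |
| RNA height / gap rate / max gap | 20 / 0.02 / 150 bp | outron signal with bounded gaps |
| motif consensus m1 / m2 | TATCCAGCCCTC / TATTGTACTC | see below |
| mutation rate | 0 | noise-free stated world |

Signal magnitudes (ATAC heights, RNA height) are free parameters of the
generator — the procedures being emulated report no quantitative heights —
chosen so that the germline-specific LFC margin is large and the directional
test has overwhelming evidence. They are documented here precisely because
they are *not* derived from any measured dataset.

Layout: each gene occupies a block with, in gene orientation, an accessible
site (300 bp, midpoint ~450 bp upstream of the TSS), then the TSS = first
exon start (the trans-splice acceptor convention: the gene body begins at
the annotated gene start, the promoter and outron lie outside it, so
gene-body-excluding shuffles can still hit promoters and the enrichment null
is non-degenerate). Planted elements are centered in their site. Inactive
elements occupy their own intergenic blocks. Divergent gene pairs sharing
one site (`n_bidirectional`, default 0 — enabled in the test suite) exercise
bidirectional promoter calls. RNA signal runs from the site midpoint
through the first exon with injected zero-coverage gaps never exceeding
150 bp, so linking succeeds for every true promoter *by construction*;
between two gaps at least one covered base remains, so the directional
window always contains evidence.

Species B realizes the conservation truth: each eligible A-gene draws a
scenario (defaults 53% conserved, 15% lone-motif, 9% near-TSS pair, 13%
A-specific, plus B-specific co-options at 10% of the eligible pool) and B's
gene is planted accordingly — a CERP2-like promoter, a lone m1/m2 inside an
active promoter, an inactive divergent pair within TSS−1000..+200, or
nothing. ChIP peaks are planted on all co-opted promoters, a fraction
(default 0.8) of plain promoters, and 20 intergenic false positives; the DE
table is simulated directly (model fitting is out of scope), with direction
probabilities chosen per gene class. Every file (FASTA, GFF3, BEDs,
bedGraphs, count and DE tables, ortholog map, truth tables, flat
`manifest.yaml` with sub-seeds and checksums) is emitted deterministically:
one master seed drives everything and identical seeds give byte-identical
files.

**Background scrubbing.** A scan threshold of P ≤ 5×10⁻⁴ *by definition*
admits approximately `p × 2L` chance windows on an i.i.d. background — on
5 Mb, thousands of chance motif hits. No motif design can avoid this: the
chance-hit rate *is* the attained p-value. Because the spec of the world
requires noise-free recovery of planted features to be exact by
construction, the generator scrubs its own background after assembly: it
scans the genome with the configured PWMs, and every hit that is not a
planted occurrence has its non-planted bases redrawn, iterating until a
fresh scan finds exactly the planted set. Chance hits *overlapping* planted
motifs (partial self-matches) are handled by redrawing only their free
bases; the default consensus pair was selected computationally so that no
window fully contained in planted bases can reach the threshold (containment
margin ≈ −90 bins) and the worst-case per-alignment persistence probability
is ≈ 0.007, so the loop converges in a handful of rounds. The scrub count
is recorded in the manifest.

**What the synthetic world does not emulate.** Read-level noise and mapping
artifacts; irreproducible-peak structure (peaks are inputs); repeat-family
sequence evolution and truncated element copies; motif degeneracy (planted
copies are exact consensus unless `mutation_rate > 0`); HOT-region biology
(stand-in ChIP false positives are random intergenic intervals); realistic
DE effect-size distributions. A green recovery test therefore establishes
that the *inference chain* is implemented correctly — not that it would
reach the same numbers on real sequencing data, whose headline counts depend
on data-scale properties the desk-scale world does not model.

## 9. Numerical choices and degenerate inputs

* PWM score discretization: 1000 bins; error bound `width × eps / 2`,
  tested.
* Integerized window sums in the binomial directional test: `round()` of
  the summed coverage; ties at the threshold follow `pbinom` exactly.
* `fraction_percent()` truncates to one decimal; 0/N = 0.0, N/0 = NA.
* Empty inputs: empty query/subject overlap counts are 0; an empty promoter
  set is an error where a fraction of promoters is requested; zero-signal
  directional windows fail rather than error.
* The "fully assembled chromosomes" input filter survives as the
  `chromosomes` argument of `read_gene_models()`; the synthetic world has
  no scaffolds, so it is a no-op there.
* CLI configuration is JSON (`jsonlite`), not YAML: no YAML parser is
  available in the supported dependency set, and the generator only *writes*
  the flat `manifest.yaml`.

## 10. Known limitations

* The accessibility stand-in is not DiffBind: it will not reproduce
  DiffBind/DESeq2 dispersion shrinkage on real count matrices, and with two
  replicates its p-values carry the irreducible approximation error of a
  t-test on discrete counts (measured ≈ +0.1 percentage point at α = 0.05).
* Promoter annotation assumes one annotated first exon per gene and does
  not refine TSS positions or detect trans-splice sites.
* The permutation model is global-uniform per chromosome (shuffleBed-like);
  GC-matched or locality-preserving nulls are out of scope.
* Conservation classification consumes upstream calls; it does not align
  genomes or infer orthology.
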