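---
title: "Methods: comparative genomics of glycogen-accumulating organisms with gaoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of glycogen-accumulating organisms with gaoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaoscope)
```

gaoscope re-implements, as tested reusable functions, the desk computations
behind a typical comparative-genomics characterisation of a
glycogen-accumulating organism (GAO) and its relatives: 16S rRNA
percent-identity statistics and taxonomic rank placement, whole-genome
average nucleotide identity (ANI), KEGG-module completeness with annotation
rescue, cumulative GC-skew replication-origin analysis, coverage binning,
and gene presence/absence matrices. Every input the pipeline consumes can
be simulated with recorded ground truth, so all stages are testable without
database downloads.

This vignette explains the models and procedures, the parameters that
matter, the numerical choices, and what the synthetic data do and do not
establish about real data.

## Pairwise identity on aligned 16S genes

For two equal-length rows of a multiple sequence alignment, the percent
(proportion of) nucleotide identity (PID, also PNI) is

$$\mathrm{PID}(a, b) \;=\; \frac{\#\{i : a_i = b_i,\ a_i, b_i \in \{A,C,G,T\}\}}
{\#\{i : a_i \neq \text{gap} \ \text{or}\ b_i \neq \text{gap}\}},$$

i.e. identical unambiguous nucleotides over aligned columns, with columns
gapped in *both* sequences (shared indels) excluded from the denominator.
Shared indels usually reflect a deletion in a common ancestor or an
insertion elsewhere in the alignment; counting them would reward shared
absence of data. Two conventions are genuinely defensible for columns
gapped in exactly *one* sequence; `pairwise_pid()` counts them in the
denominator as non-identical (an indel is a difference), and
`count_single_gaps = FALSE` switches to excluding every gap-containing
column. Ambiguity codes (N, R, Y, ...) never count as identical, even to
themselves — treating `N == N` as a match would inflate identity in
low-quality stretches; `ambiguity_identical = TRUE` restores plain
character equality.

`pid_matrix()` applies this to all pairs; `group_pni()` collects the
between-group (or within-group) distribution for labelled clades, genera
or families, the substrate of the violin-style comparisons used to reason
about taxonomic placement.

### Rank thresholds and placement

`place_group()` reduces a between-group distribution to its median and
reads it against minimal inclusion thresholds for genus, family and order
(defaults 0.945 / 0.865 / 0.82, conventional 16S values from the
rank-threshold literature; always overridable, because such thresholds are
calibration conventions, not constants of nature). The median drives the
call because it is robust to a minority of divergent or misannotated
sequences; the fraction of pairs above each threshold is reported alongside
for transparency but does not change the call.

The median inter-family statistic (`median_inter_family()`) summarises how
different two families within a reference order typically are: for every
pair of distinct families the mean between-family PNI is computed, and the
MIF is the median of those means, with the min–max band reported. Published
figure legends mix "mean" and "median" wording for this yardstick; gaoscope
fixes mean-within-pair / median-across-pairs and also reports the
mean-of-means so either reading is recoverable.

### Trees

`build_nj_tree()` provides a light distance-based tree (neighbor joining on
$d = 1 - \mathrm{PID}$, negative branches clamped to zero) for clade
visualisation. It is deliberately not a substitute for likelihood-based
phylogenetics; it exists so clade structure in the identity matrix can be
seen and tested in-repo.

## Fragment-based ANI

`compute_ani()` follows the classic fragment design: each genome is cut
into consecutive non-overlapping fragments (default 1020 bp, remainder
discarded, mostly-N fragments dropped); each fragment is mapped onto the
other genome by exact k-mer seeding (k = 16, seeds sampled every 24 bp,
both strands) with the modal seed diagonal defining a candidate window;
the fragment is then scored against that window. Hits must cover at least
70% of the fragment at 50% identity or better; fragments are paired
reciprocally (the best hit of fragment *i* of genome A must land in the
fragment of genome B whose best hit lands back in *i*), and the ANI is the
mean identity over reciprocal pairs, in percent. With fewer than 20% of all
fragments in reciprocal pairs the ANI is reported as undefined rather than
as a number computed from almost nothing — the expected outcome for
unrelated genomes. `classify_species_boundary()` applies the conventional
~95% species cutoff; genuinely distinct species typically sit far below it.

Numerical choices worth knowing:

* **Two-tier extension.** The ungapped placement along the winning diagonal
  is scored first; the affine gapped aligner (global in the fragment, local
  in a window extended by 5% of the fragment length; match +1, mismatch −2,
  gap open 6, extend 2) only runs when ungapped identity falls below 0.75
  or the diagonal leaves the subject. At species-level divergences the
  ungapped score is exact, and the gapped aligner engages precisely where
  indels are plausible.
* **Identity denominator** is alignment columns including internal gaps,
  the common ANI convention, so values are exactly reproducible.
* **Multi-contig genomes** are concatenated with a 50-N spacer for mapping;
  fragments never span contigs, and no seed can match across the spacer.

On genome pairs simulated with substitutions only at per-site rate $p$,
the estimator recovers $100(1-p)$ within one percentage point for
$p \le 0.10$ (the parameter-recovery checks in the test suite and
acceptance script run exactly this, at 200-kb genome size).

## KEGG-module completeness

`parse_module_definition()` implements the DEFINITION grammar: space
separates sequential blocks (all required), comma separates alternatives,
`+` joins subunits of a complex, a leading `-` marks a non-essential
component, parentheses nest, and the gap marker `--` denotes a reaction
step with no KO assigned. Two grammar semantics are choices rather than
facts, and are therefore explicit here: optional `-K` components are
ignored entirely in completeness evaluation (they are non-essential by
KEGG's own convention), and `--` counts as satisfied, so that steps no
annotation could ever prove do not dominate the completeness call.

`classify_status()` reproduces the four-level reporting scheme used in
published module tables:

| status | meaning | rule |
|---|---|---|
| `C` | complete | 0 missing blocks |
| `+` | largely intact | ≤ 2 missing blocks |
| `?` | incomplete | > 2 missing blocks |
| `-` | absent | no module genes detected, or diagnostic override |

`genes_detected` counts genes with multiplicity (two paralogs of one KO
count twice), because published per-module gene counts exceed distinct-KO
counts. Cells render as `"status | n"`.

**Diagnostic-gene override.** Some modules share almost all their enzymes
with another pathway; the glyoxylate cycle, whose non-diagnostic enzymes
are all TCA-cycle members, is the canonical case. When a module carries a
non-empty diagnostic KO set (e.g. isocitrate lyase K01637 and malate
synthase K01638 for M00012) and none of those KOs is present, the module is
called absent regardless of how many shared genes were found, and the call
is flagged `override_applied`. The diagnostic list is explicit per-module
configuration: deciding which genes are diagnostic is a biological
judgment, and the package does not guess it.

**Rescue.** Primary KO annotation pipelines produce false negatives that a
second annotation source catches at the gene-product level.
`apply_rescue()` encodes this cross-referencing as explicit rules
(match on gene symbol, product regex, or gene id → add a target KO, with
provenance `rescued`). Rescue never removes KOs, is idempotent, and can
only raise a module's status in the order `- < ? < + < C`. Typical real
uses are restoring a malyl-CoA thioesterase or a glycogen debranching
enzyme that the KO assignment missed but the product annotation named.
Because whether published gene counts were taken before or after such
manual rescue is ambiguous, `completeness_matrix()` can be run on either
profile and both are recorded by the generators' truth.

## GC skew, replication origin, coverage

`windowed_gc_skew()` computes $(G-C)/(G+C)$ in non-overlapping windows
(default 5 kb, matching the conventional coverage binning; the final
partial window is retained) and its running sum. Windows with no G or C
have skew 0. Under the G-rich-leading-strand convention the cumulative
curve attains its minimum at the replication origin and its maximum at the
terminus; `predict_ori_ter()` reports the corresponding window midpoints,
ties broken at the lowest position, and `ori_at = "max"` inverts the
convention for organisms where the sign runs the other way.

Two properties needed care:

* **Detrending.** When the two replichores have unequal lengths the
  cumulative curve acquires a net drift per revolution, and the location of
  its raw global extrema then depends on where the circle was linearised.
  For circular replicons the curve is therefore detrended (the linear trend
  `window_index × mean(skew)` is subtracted) before the extrema are taken;
  predictions are then equivariant under rotation of the genome to within
  one window.
* **Strand symmetry.** Reverse-complementing the genome negates each
  window's skew (G↔C) but also reverses the direction of integration,
  which negates the cumulative differences again: the two cancel, so the
  predicted origin and terminus are strand-symmetric — they land on the
  mirrored coordinates of themselves, not on each other. The test suite
  asserts this (correct) invariant.

`dnaa_proximity()` reports the minimal circular distance between the
predicted origin and the annotated replication-initiator gene (dnaA by
default), the standard sanity check; it insists on exactly one matching
annotation row. `bin_coverage()` averages per-base depth in the same
fixed windows, keeps the partial final window, and returns the exact
per-window sums (`total_depth`) alongside the means so that depth
conservation can be checked exactly rather than to round-off.

## Presence/absence matrices

`build_presence_matrix()` screens annotation tables against a configured
gene panel. Symbol matching is case-insensitive and by default strips a
trailing copy-number digit (`glgB1`, `glgB2` → `glgB`), because paralog
families are tabulated as one locus in published gene panels; `"ko"` and
`"any"` modes add KO-id matching for panels that mix symbols and KO/COG
identifiers (symbol matches take precedence in `"any"`). Cells are binary
`+`/`-` in the rendered table, with copy numbers in a companion table —
presence is defined as copies ≥ 1, so a cell can only flip from absent to
present as annotation rows are added.

## Synthetic data: what it emulates, and what it does not

All generators are deterministic given `seed` and record their ground
truth alongside the data.

* `simulate_clade_alignment()` evolves a uniform random root under
  Jukes–Cantor along a star-of-stars tree: clade ancestors at
  $(d_b - d_w)/2$ from the root, members at $d_w/2$ from their ancestor,
  so total path divergence is $d_w$ within and $d_b$ between clades, and
  the expected identity is the JC closed form
  $\tfrac14 + \tfrac34 e^{-4d/3}$ of the path divergence. Gap columns are
  planted by masking alignment columns: shared gaps mask the same columns
  in every member of clade 1, unshared gaps mask one sequence each. JC
  with no rate heterogeneity and no indel-evolution model is deliberate:
  the placement statistics depend on identity structure, not on realism of
  the substitution process. Defaults (2 clades × 4 members, 1500 nt,
  $d_w = 0.02$, $d_b = 0.30$) are sized like a small full-length 16S
  clade comparison.
* `simulate_genome_pair()` applies i.i.d. substitutions (always to a
  different base) at rate $p$ — the exact regime in which ANI should
  equal $100(1-p)$.
* `simulate_skew_genome()` draws bases with $P(G)-P(C) = \pm s$ on the two
  replichore arcs (expected window skew $s/\mathrm{GC}$, recorded in
  truth) and plants a dnaA row at the origin.
* `simulate_annotation_tables()` emits KO-bearing rows realising a planted
  missing-block count per (genome, module) — a small solver enumerates
  which blocks to leave unsatisfied and verifies the plan is achievable,
  erroring with the offending (genome, module) otherwise — and can hide a
  fraction of KOs behind empty KO cells with rescuable product strings,
  generating the matching rescue rules.

What passing on synthetic data shows: the statistics, parsers, evaluators
and predictors compute what they claim, at known truth, over the parameter
ranges exercised. What it does not show: robustness to alignment error,
rate heterogeneity among 16S sites, real indel processes, assembly
fragmentation and contamination, horizontally transferred regions
(which depress ANI non-uniformly), or annotation pipelines' correlated
errors. Conclusions about real genomes still require the judgment steps —
curated alignments, cautious diagnostic-gene lists, manual review of
rescued annotations — that these tools make explicit rather than replace.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their simulations as a
deliberate compromise between statistical resolution and desk-scale
runtime: identity oracles on alignments up to 10 × 200; JC recovery on 200
pairs of 1500 nt per divergence; placement recovery on 100 seeded runs per
rank class (6 sequences × 1500 nt each); NJ recovery over the complete
enumerations of 4- and 5-taxon topologies; ANI recovery on 200-kb genomes
(5 seeds per rate in the acceptance script, a 3-rate subset in the routine
test suite); origin prediction on a 1-Mb genome at skew strength 0.05 and
window 5 kb. Each check's tolerance is derived from the construction
(binomial/standard-error bounds, one-window localisation), not tuned to
the observed results.

## Running the full pipeline

`run_pipeline()` wires the stages behind a single declarative
configuration (list or YAML) with one output directory per run: every
requested stage writes its TSV/JSON outputs and a `report.json` aggregates
the per-stage summaries with the seed, package version and a configuration
hash, so a run is reproducible and auditable. Input paths are validated
before any stage executes.

```{r, eval = FALSE}
cfg <- list(
  output_dir = "run1", seed = 7,
  simulate_clades = list(n_clades = 2, members_per_clade = 4,
                         d_w = 0.01, d_b = 0.30),
  pid = list(),
  place = list(query = "clade01", reference = "clade02")
)
report <- run_pipeline(cfg)
report$stages$place$rank_call
```

## Known limitations

* The ANI engine targets desk-scale genomes (hundreds of kb to a few Mb);
  it is a transparent reference implementation, not a replacement for
  optimised tools on large genome sets.
* Fragment mapping assumes mostly collinear homology at the fragment
  scale; heavy rearrangement within a fragment length degrades coverage
  before it degrades identity.
* The module evaluator freezes one reading of the DEFINITION grammar;
  block segmentation in edge cases (deeply nested alternatives spanning
  spaces) follows the stated precedence — space binds loosest, then comma,
  then `+`/`-` — which is also what the exhaustive truth-table tests pin
  down.
* Rank placement inherits every caveat of fixed identity thresholds;
  the thresholds are configuration, and the placement call should be read
  together with the reported distribution, not instead of it.
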