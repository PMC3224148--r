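---
title: "Taxonomy-aware probe set design for rRNA gene fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomy-aware probe set design for rRNA gene fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfps)
```

## The problem

Oligonucleotide fingerprinting of rRNA genes (OFRG) estimates the makeup of
a microbial community by hybridizing a small set of short DNA probes
(10-mers) against arrayed 16S rRNA gene clones.  Each clone yields a binary
*fingerprint*: one bit per probe, 1 where the probe is predicted to
hybridize.  With `k` probes, at most `2^k` fingerprints exist, so the probes
must be chosen so that fingerprints coincide exactly when the underlying
organisms belong together.  The hybridization model is deliberately simple:
a probe is assumed to bind a gene if and only if the probe string occurs
exactly as a substring of the gene sequence (forward strand).

The original selection objective, the Maximum Distinguishing Probe Set
(MDPS), asks every training sequence to receive a unique fingerprint and
treats all collisions as equally bad, ignoring both sequence similarity and
taxonomy.  The Maximum Fidelity Probe Set (MFPS) implemented here replaces
that objective: training sequences are first clustered into operational
taxonomic units (OTUs, >= 99% mutual similarity, per genus), and probe sets
are scored by how well their fingerprints stay *confined* to taxonomic
groups at up to three levels (OTU, genus, phylum).

## The cost function

Let `N` be the number of distinct fingerprints a candidate probe set
produces on the training sequences, and let `gamma[i, f]` be the number of
groups at taxonomic level `i` containing at least one sequence with
fingerprint `f`.  With per-level penalties `P[i]`,

    C = 1/2 * sum_f sum_i  P[i] * gamma[i, f] * (gamma[i, f] - 1)

A fingerprint confined to one group at a level (`gamma = 1`) accrues no
penalty there; the quadratic form charges one unit per *pair* of groups a
fingerprint fails to separate.  `mfps_cost()` implements this directly on
the accounting produced by `gamma_counts()`.  The MDPS objective is the
special case in which each sequence is its own singleton group with
penalties `(1, 0, 0)`; `mdps_cost()` computes it as the number of
undistinguished sequence pairs, and a property test verifies the reduction
exactly.

Because groups nest (an OTU lies in one genus, a genus in one phylum),
confinement propagates upward: optimizing OTU fidelity tends to deliver
genus and phylum fidelity for free.  The default penalties are therefore
`P = (1, 30, 0)` -- OTU penalty 1, genus penalty 30, phylum penalty 0 --
the setting found optimal on large training sets; the phylum penalty stays
at zero because phylum fidelity saturates on its own.

The quality metric reported everywhere is the **High Fidelity Ratio
(HFR)**: the fraction of distinct fingerprints confined to a single group
at a level.  Unlike raw costs, HFR is comparable across penalty settings
and probe set sizes.  HFR is monotone in the level by the nesting argument
(`HFR_otu <= HFR_genus <= HFR_phylum`), which the suite checks on hundreds
of randomized instances.

## Training-data preparation

`prep_pipeline()` chains the sequence-level stages on a pre-aligned,
gapped FASTA set:

1. **Hypervariable removal** (`remove_hypervariable()`): a column mask
   distinguishes conserved from hypervariable alignment columns; the
   hypervariable columns are dropped.  Probes from those regions would bind
   only narrow taxa while being common enough in skewed training data to be
   selected.  Mask dialect: characters `0`, `-`, `.` in the mask record
   mean *drop*; anything else means *keep*.  Mask encodings vary between
   sources, so the record id prefix is configurable (`mask_id`).
2. **Primer localisation** (`find_primer_region()`): the degapped majority
   consensus is scanned for the IUPAC-degenerate primers (defaults 27F
   `AGAGTTTGATCMTGGCTCAG` and 1392R `ACGGGCGGTGTGTRC`, the reverse primer
   via its reverse complement).  A window qualifies when at least 50% of
   sequences match it exactly under IUPAC degeneracy with no internal gaps;
   the threshold is a package choice -- the regions are described only as
   "highly conserved" -- and ties resolve leftmost (forward) / rightmost
   (reverse).
3. **Truncation** (`truncate_to_primers()`): columns outside the primers
   are removed, then a further 10 positions inward per side.  "Positions"
   are counted on the *ungapped consensus* and mapped back to alignment
   columns, since nucleotide positions are sequence, not column,
   coordinates.  All intervals in the package are 0-based half-open.
4. **Quality filtering** (`qc_filter()`), in order: sequences that never
   reached a primer (end gap after truncation with an all-gap truncated
   section on the same end), sequences with ambiguity codes, and exact
   duplicates of an earlier sequence's degapped truncated string (first
   occurrence wins).  Keying the duplicate check on the post-mask,
   post-truncation string follows from the observation that duplicate
   counts differ between pipelines precisely because of hypervariable
   handling.  Whether deduplication preceded truncation in the historical
   workflow is not recorded; the order here is a documented choice.
   `qc_filter()` removes sequences but keeps all columns, so it is
   idempotent and commutes with the truncation step.

The legacy pipeline -- hypervariable regions retained -- is available as
`prep_pipeline(original = TRUE)` for pipeline-comparison experiments.

## OTU clustering

`pairwise_distances()` computes mismatches over comparable columns.  The
gap policy is declared rather than inherited: both-gap columns are ignored,
gap-versus-base counts one mismatch, adjacent gaps count per column.  The
exact terminal-gap conventions of historical clustering tools are not
recorded, so the policy is stated here and enforced by a brute-force oracle
test.

`cluster_otus()` is complete-linkage agglomeration cut at 1% distance,
*written in the package* rather than delegated: complete linkage is the
only linkage under which "minimum similarity 99%" is literally guaranteed
(the cluster diameter is bounded by the cut height), and a hand-rolled
agglomerator lets ties be broken deterministically (earliest eligible
cluster pair; OTU numbers by first-member input order).  `stats::hclust`
with complete linkage serves as an independent cross-check in the tests,
never as the implementation.  Clustering runs independently per genus
(`assign_otus()`); OTU identifiers are scoped within their genus.

## Probe matrix

`probe_matrix()` enumerates every distinct ungapped 10-mer in the processed
sequences, ranks candidates by *conservation* -- the number of distinct
OTUs containing the probe -- keeps the top 1000 (ties at the boundary break
lexicographically; the historical tie rule is unrecorded), and builds the
binary incidence matrix with taxonomy encoded as dense integer codes.
Homopolymer-containing candidates are deliberately not filtered.
Reverse-complement matching exists behind a flag (`revcomp = TRUE`) but
defaults to off, matching the forward-strand substring model.  The matrix
serializes to a plain-text TSV that round-trips bit-exactly.

## Annealing

`anneal()` minimizes either cost over size-`k` subsets by simulated
annealing.  No schedule is prescribed by the method's description, so the
defaults are standard practice, all exposed in `annealing_config()`:

* initial temperature calibrated during a 200-move warm-up so ~80% of
  uphill moves would be accepted (override with `t_initial`);
* geometric cooling, factor 0.995 per step;
* `steps = 200 * k` moves per run;
* `restarts = 10` independent runs, reporting the single best probe set
  (ties to the lowest restart index); a run stops early at cost 0, which is
  a global optimum;
* one root seed; restart `r` derives seed `seed + r - 1`, making restarts
  independently reproducible.

Moves replace one non-retained member with a uniformly random eligible
probe; `retained` and `avoided` sets implement the practical need to pin or
ban specific probes after wet-lab experience.  Costs are recomputed in full
at every step (no incremental bookkeeping); at desk scale a full
evaluation is microseconds, and full recomputation removes a class of
drift bugs.  On tiny instances (about a dozen candidates) annealing is
verified against exhaustive enumeration over all subsets for both cost
functions.

Convergence effort matters when comparing cost functions: with very small
budgets the MFPS landscape -- whose genus term dominates early -- lags the
simpler MDPS landscape.  The comparison experiments in the acceptance suite
use 250 moves per probe (steps = 250 k), at which point the expected
ordering MFPS >= MDPS >= random holds on the synthetic world.

## Evaluation harnesses

* `hfr()` -- the ratio above, per level.
* `low_fidelity_distance_histogram()` -- for every low-fidelity distinct
  fingerprint (judged at the OTU level by default; the genus variant is a
  flag), the average pairwise distance of its sequences, binned at 1%,
  averaged over replicate probe sets.  High-fidelity fingerprints are
  excluded because their sequences share one OTU and cannot exceed the 1%
  cut-off -- asserted, not assumed, in the tests.
* `crossval()` -- the 20%-train / 100%-validate flavour of 5-fold
  cross-validation: disjoint 20% training samples, evaluation on all
  sequences, so CV scores stay comparable with full-data runs.  Training
  samples are simple random draws without stratification (only the
  fractions are specified by the method); small folds may miss rare OTUs,
  which yields a warning, not an error.
* `phylum_holdout()` -- trains with a whole phylum removed, evaluates on
  everything; the proxy for detecting novel taxa.
* `random_probe_sets()` -- the uniform control.
* `positional_bias()` -- first-match start positions of selected probes on
  the degapped consensus of the processed alignment.  The coordinate system
  of the historical position plots is unrecorded; the degapped consensus is
  this package's documented choice.
* `penalty_sweep()` -- genus-penalty sweep at fixed OTU penalty, reporting
  mean and SD of OTU/genus HFR over replicate sets (100 replicates in the
  original experiments; configurable down for desk-scale runs).

## The synthetic world

Everything is testable offline through `synthetic_spec()` /
`generate_alignment()`: a star phylogeny (root -> phylum -> genus -> OTU ->
sequence) with independent per-column substitutions, two planted concrete
primer sites, hypervariable blocks that evolve fast and carry all gaps, and
a mask record marking them.  Defaults state the world once: 3 phyla x 3
genera x 4 OTUs x 5 sequences over 600 columns with one 60-column
hypervariable block; branch rates 0.06 / 0.03 / 0.015 per column at the
phylum / genus / OTU levels (pairwise divergence is roughly twice the
rate, so between-genus divergence is well above the 1% OTU cut-off and
between-OTU divergence ~3%); hypervariable substitution 0.25 with gap rate
0.10.  The within-OTU bound is enforced by construction -- each sequence
differs from its OTU ancestor in at most `floor(w * n_free / 2)` conserved
columns -- so planted OTUs always respect the 99% threshold and the
pipeline's recovered partition can be compared to the planted one exactly.

`plant_discriminative_probes()` embeds known probes into disjoint conserved
windows of all members of exactly one group per probe and fails loudly on
collisions with background k-mers (draw probes with
`random_probes(avoid = enumerate_candidates(aln))` to avoid them).  This
provides instances whose optimum is known by construction: one planted
probe per OTU is an exhaustively verified zero-cost MFPS solution.

One subtlety is exercised deliberately in the acceptance suite: planted
OTU-specific probes have conservation 1 (they occur in exactly one OTU), so
the top-1000 conservation filter would discard them in a candidate pool of
several thousand.  The planted-recovery experiment therefore builds its
matrix with `top_n = Inf`.  On realistic data the filter is not a problem
-- discrimination comes from conserved probes whose *absence* in a group is
informative -- and indeed the same synthetic world reaches cost 0 from the
top-1000 matrix as well.

What a green synthetic run does **not** establish: the star phylogeny has
no rate heterogeneity beyond two classes, no indels outside hypervariable
blocks, no chimeras or sequencing errors, and its taxonomy is balanced,
none of which hold for real rRNA collections.  Absolute HFR values from
the original large-scale training data (81% OTU / 98% genus HFR at 40
probes; 203,218 sequences in 34,701 OTUs) depend on a dated external
database download and are out of scope here; the package validates the
machinery and the qualitative orderings instead.

## The MDPS reading

The predecessor objective is described, not printed, in the sources
available to this package: all undistinguished clones are "equally
undesirable".  The implementation takes that as the pair count
`1/2 * sum_f n_f (n_f - 1)` over sequences sharing a fingerprint.  This
reading makes the singleton-group reduction exact, which is the property
the tests pin down.

## Numerical and degenerate-input choices

* Probe sets are index vectors into the matrix's probe list; `k = 0` is
  legal and produces a single empty fingerprint shared by all sequences.
* Distance threshold comparisons use `<=` (a pair at exactly 1% distance
  may share an OTU).
* A sequence pair with no comparable columns is an error, not a distance.
* `qc_filter()` may legitimately empty a training set; that is a warning.
* All RNG goes through one seed argument per entry point; identical seeds
  give byte-identical outputs, including through the command-line layer.

## Command-line layer

The core design workflow is scriptable via `inst/cli/mfps.R`
(`synth`, `prep`, `matrix`, `select`, `evaluate`); the experiment harnesses
(`crossval()`, `phylum_holdout()`, `penalty_sweep()`,
`positional_bias()`, `low_fidelity_distance_histogram()`) are R functions
-- they produce tables meant for interactive analysis and plotting, which
is how they are expected to be consumed.
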