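# mfps

Taxonomy-aware design of small DNA probe sets for microbial community
fingerprinting.

## What this is for

Oligonucleotide fingerprinting of rRNA genes (OFRG) profiles a microbial
community by hybridizing a small set of 10-mer DNA probes against arrayed
16S rRNA gene clones.  Each clone gets a binary fingerprint — one bit per
probe — and clones with identical fingerprints are counted together.  The
probes must therefore be chosen so that fingerprints coincide exactly when
sequences belong to the same taxon.

This package implements the **Maximum Fidelity Probe Set (MFPS)** approach:
training sequences are prepared (hypervariable-region masking,
primer-anchored truncation, quality filtering), clustered per genus into
OTUs at 99% similarity, and probe sets are selected by simulated annealing
under a cost that penalises fingerprints shared across taxonomic groups at
up to three levels.  With `N` distinct fingerprints, `γ_{i,f}` the number
of groups at level `i` (OTU, genus, phylum) containing fingerprint `f`,
and per-level penalties `P_i` (default `(1, 30, 0)`):

```
C = 1/2 · Σ_f Σ_i  P_i · γ_{i,f} · (γ_{i,f} − 1)
```

A fingerprint confined to one group at a level accrues no penalty.  The
predecessor objective (MDPS — a distinct fingerprint for every sequence,
all collisions equally bad) is included for comparison, as are the
evaluation metrics: the High Fidelity Ratio (fraction of distinct
fingerprints confined to a single group) and the low-fidelity
average-pairwise-distance histogram, plus cross-validation, phylum-holdout,
random-control, penalty-sweep and positional-bias harnesses.  A
deterministic generator of taxonomically structured synthetic alignments
makes everything testable without any external download.

## Worked example

```r
library(mfps)

# a synthetic training world: 3 phyla x 3 genera x 4 OTUs x 5 sequences
spec  <- synthetic_spec(seed = 1)
aln   <- generate_alignment(spec)

# preparation pipeline: mask, primers, QC, truncation
proc  <- prep_pipeline(aln)
tax   <- aln$taxonomy[aln$taxonomy$id %in% names(proc$seqs),
                      c("id", "phylum", "genus")]
world <- label_set(proc, tax, assign_otus(proc, tax))

# candidate 10-mers -> top 1000 by OTU conservation -> incidence matrix
pm <- probe_matrix(world, top_n = 1000)
pm
#> ProbeMatrix: 1000 probes x 180 sequences
#>   groups: 36 OTUs, 9 genera, 3 phyla

# select 20 probes under the MFPS cost
sel <- anneal(pm, k = 20, cost = "mfps", pen = penalty_config(1, 30, 0),
              cfg = annealing_config(steps = 5000, restarts = 10, seed = 1))
sel
#> ProbeSelection: 20 probes, mfps cost 0 (best of 1 restart(s))

hfr(sel$probe_indices, pm, "otu")
#> HFR (otu): 69 / 69 distinct fingerprints high-fidelity = 1.000
```

Cost 0 means every one of the 69 distinct fingerprints is confined to a
single OTU (and hence a single genus and phylum): the 20 probes fingerprint
all 36 planted OTUs faithfully.  On real training collections fidelity is
not perfect; `hfr()`, `crossval()` and `low_fidelity_distance_histogram()`
quantify how close a probe set comes.

The same workflow is scriptable:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mfps.R", package = "mfps"))')
Rscript $CLI synth  --out-fasta raw.fasta --out-tax tax.tsv --seed 1
Rscript $CLI prep   --in raw.fasta --tax tax.tsv \
                    --out-fasta proc.fasta --out-tax proc.tsv
Rscript $CLI matrix --in proc.fasta --tax proc.tsv --out matrix.tsv
Rscript $CLI select --matrix matrix.tsv --k 20 --seed 1 \
                    --out-probes probes.txt --out-report report.json
Rscript $CLI evaluate --matrix matrix.tsv --probes probes.txt --out hfr.tsv
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full computation from scratch against the installed package —
synthetic world, preparation pipeline, OTU clustering, probe matrix, MFPS
annealing — prints the per-stage summary and HFR values it computes, and
writes the JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/probe-set-design.Rmd`) describes the cost
function, the pipeline stages and their conventions (mask dialect, inset
coordinates, gap policy, linkage choice), the annealing schedule, the
synthetic world and its limits, and all design decisions taken where the
method description leaves choices open.
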