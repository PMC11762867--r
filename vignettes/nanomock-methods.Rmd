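---
title: "nanomock: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nanomock: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What nanomock is for

Validating metagenomic classifiers and HTS-based diagnostic assays
needs samples whose composition is known *exactly*: how many reads
belong to each organism, where each read came from, and which errors it
carries. nanomock generates such mock Nanopore-style samples *de novo*
from reference FASTA files. Its central guarantee is the **exact-total
abundance contract**: the resolved integer read counts always sum to
the designed total, and the simulator emits exactly the resolved count
for every organism. Trained-model simulators that pad samples with
random "unaligned" reads can lose on the order of 10% of the designed
abundance; a limit-of-detection study at 5 or 10 pathogen reads per
sample cannot tolerate that, which is the niche this tool fills.

# The sample design model

A design declares organisms (or taxa with subtaxa), an abundance
specification per entry, a total read count, a read-length model, an
error profile and a seed. Abundance modes:

* **absolute** — an exact integer read count;
* **relative** — a percentage of the sample total;
* **random** — the entry shares whatever is left after absolute and
  relative entries, by a symmetric Dirichlet draw over the random
  entries.

Resolution order is: absolutes reserved first, relatives rounded next,
random entries share the leftover, and finally a `fill_remainder` host
(if declared) absorbs the rest. Over-allocation is a hard error; the
tool never silently rescales a design.

## Integer rounding

Fractional read quotas must become integers without breaking the exact
total. We use largest-remainder (Hamilton) apportionment: every
category gets the floor of its quota and the leftover units go to the
largest fractional remainders, ties broken by declaration order. The
source material for this tool never states a rounding rule; Hamilton
was chosen because it is the standard apportionment scheme that
guarantees the exact-total invariant and keeps every count within one
read of its quota. A subtlety: when relatives must fill the remaining
total *exactly*, largest-remainder correction can push an individual
relative entry up to one full read away from its requested percentage
(conservation forces it). When a random-mode entry or fill-remainder
host absorbs the leftover, relative entries are instead rounded
independently (`round(quota)`) and each lands within half a read of its
requested percentage. Both branches conserve the total exactly.

## "Pseudo-random" abundances

Random-mode shares are drawn from a symmetric Dirichlet with
concentration `alpha = 1` (flat over the simplex), scaled to the
leftover reads and integerised by largest remainder. The concentration
is exposed (`random_alpha`) because flatness is a choice, not a fact:
real communities are often far more uneven (small `alpha`) than a flat
simplex.

## Taxa with subtaxa

When only a higher taxon's abundance is known (e.g. a species complex),
the taxon carries the abundance spec and its members receive either an
`equal` split (floor of the mean, remainder to the first members in
declaration order) or a `random` Dirichlet split. The split is seeded
per taxon, so adding an unrelated organism never changes it.

## Dilution series

`make_dilution_series()` fixes the sample total (the fill-remainder
host absorbs the difference) and sets the target organism's absolute
abundance to each level, with `replicates` independent samples per
level. Child seeds are a stable hash of (base seed, level index,
replicate index): replicates are independent but individually
reproducible, and adding a level never changes existing samples.

# The read model

## Lengths

Read lengths are truncated-Gaussian: `round(N(mean, sd))`,
rejected/redrawn while outside `[min_len, min(max_len, longest
contig)]` (up to 1000 rounds, then clamped). The "mean ± sd"
parameterisation is taken at face value — the conventional reading of a
spec like "2000 ± 200 nucleotides" — and a Gaussian is the matching
minimal family. Defaults: mean 2000, sd 200, `min_len` 50 (about the
shortest fragment a Nanopore library realistically yields). The length
model governs the **pre-error template fragment**; insertions and
deletions then perturb the emitted read length. This keeps locus
arithmetic exact: the truth table's `[start, end)` always spans exactly
`fragment_length` template bases.

## Loci and strands

A contig is chosen with probability proportional to its number of valid
placements (`length − fragment_length + 1`) among contigs long enough
to hold the fragment, and the start is uniform over valid placements —
i.e. uniform over all possible placements genome-wide, the natural
null model for shotgun sequencing of naked DNA. Strand is Bernoulli(½)
per read (`forward_only = TRUE` disables the flip, for read-derived or
amplicon-like references). Fragments may span N runs; N passes through
to the read.

## Errors

One event per template base is drawn from {substitution `rate_sub`,
insertion `rate_ins`, deletion `rate_del`, match} in a single
left-to-right pass (competing risks). At Nanopore-scale error rates
(≤ 5%) this is indistinguishable in practice from independent
per-event Bernoullis, and it gives exact per-base bookkeeping: reported
accuracy is identically `1 − (n_sub + n_ins + n_del)/template_bases`.

Substitutions use a transition/transversion-weighted model: the
transition partner (A↔G, C↔T) has weight `kappa`, each of the two
transversion partners weight 1, so the transition probability is
`kappa/(kappa + 2)`. The purine/pyrimidine chemistry fixes the
*structure* of this model; the weight itself defaults to the classical
ti/tv ≈ 2 convention and is fully exposed. N is never substituted (an
event landing on N is re-counted as a match).

Insertions emit the template base plus `k ≥ 1` extra uniform bases,
`k` geometric with continuation probability `ins_extend` (default 0.2,
mean insertion length 1.25). Deletions drop single bases; multi-base
deletion events are approximated by adjacent single-base ones.

Presets: `guppy` (overall error 0.05: sub 0.025, ins 0.0125, del
0.0125) and `dorado` (overall error 0.01), both with `kappa = 2`,
`ins_extend = 0.2`, plus `perfect` (no errors). These are
*representative* of the two base-caller generations' accuracies, not
vendor-canonical values — no published rate table was reproduced — and
any measured profile can be supplied as a YAML/JSON file. Known
Nanopore effects deliberately **not** modelled: homopolymer-length
errors, position- or quality-dependent rates, k-mer-conditioned error
spectra, chimeric reads and adapters. A green error-model test
establishes that configured rates are recovered, not that the reads
fool a base-caller-aware tool.

# Determinism

One base seed governs a run. Every organism, taxon split, random
abundance draw, replicate and dilution level derives its own substream
seed via a stable string hash, so streams are independent and
insensitive to declaration order, and any single sample can be
regenerated from its run-parameters report alone (`parse_design()`
accepts that report as a design). Reports, truth table and FASTA are
byte-reproducible given the seed.

# What the synthetic fixtures do and do not establish

Tests and the acceptance script run on i.i.d. uniform-composition
random references (`generate_random_reference()`), which have realistic
GC but no repeats, no shared homology between organisms and no
low-complexity structure. Read counting, abundance arithmetic, length
statistics and error bookkeeping are insensitive to sequence content,
so green tests on synthetic references carry over to real genomes. What
they do *not* establish is downstream behaviour that depends on
sequence similarity — mappability, assembly contiguity, classifier
confusion between related taxa. Those require real references and
external tools and are explicitly out of scope.

# Numerical and edge-case choices

* Ambiguity codes other than N in input FASTA are converted to N (with
  a logged count) rather than rejected: real assemblies contain them,
  and rejection would make most public references unusable.
* Contigs shorter than the drawn fragment are excluded per draw;
  an organism whose every contig is shorter than `min_len` is a hard
  error naming the organism.
* Remainder ties in apportionment break by declaration order —
  deterministic and documented, rather than random.
* Relative percentages are reported to 3 decimals, the minimum that
  distinguishes 5 reads in 100,000 (0.005%) from zero.
* Seeds are kept below 2³¹ so they are valid R integer seeds.

# Known limitations

* Abundance is expressed purely as read counts; genome-copy or
  cell-count abundance (which would weight by genome length) is not
  modelled.
* FASTA output only — no quality strings, no signal-level data.
* The error model is sequence-context-free (see above).
* Relative-mode entries cannot be guaranteed closer than one read to
  their requested percentage when they must exactly fill the total.
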