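---
title: "Tracing spliceosomal introns through ancient gene duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing spliceosomal introns through ancient gene duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Spliceosomal introns interrupt nearly all nuclear genes of eukaryotes, and
many of them are old: a sizeable fraction of present-day intron positions
was already present in the last eukaryotic common ancestor (LECA). The
eukaryotic gene repertoire also grew by massive gene duplication during
eukaryogenesis, so an intron inserted *before* a duplication should be
found today at the same protein position in both descendant paralogs.
`paralintron` implements the computational chain needed to test this:

1. **Mapping** — extract intron positions from genome annotations
   (GFF3 + genome FASTA), convert them to protein coordinates with codon
   phase, and project them onto per-orthogroup protein alignments.
2. **Tabulation** — build a species-by-position table of presence (`1`),
   absence (`0`) and missing data (`?`) per orthogroup (OG).
3. **Ancestral reconstruction** — fit a two-state branch-specific
   gain/loss model on a rooted species tree by maximum likelihood,
   compute posterior presence probabilities per node, and call LECA
   introns at a posterior threshold of 0.5.
4. **Paralog comparison** — transfer LECA introns to a merged family
   alignment and classify them as *shared* (an equivalent LECA intron in
   a paralogous OG) or *unique*, with a parallel-gain control based on
   separately acquired homologs.
5. **Dollo parsimony** — on duplication-annotated gene trees, infer which
   introns existed before each duplication, and count gains and losses
   before duplications versus on the branches leading to the LECA
   families.
6. **Statistics** — chi-squared and Fisher exact contingency tests,
   two-sample Kolmogorov–Smirnov comparisons of relative intron
   positions, Benjamini–Hochberg FDR control, Wilson score intervals and
   intron phase distributions. All tests are two-sided.

A forward simulator of the whole process (module `simulate_*`) produces
genomes, annotations, alignments, trees and a complete event-level truth
log, so that every stage is verifiable without any external dataset.

## Coordinate conventions

GFF3 coordinates are 1-based inclusive; they are converted once, at parse
time, to 0-based half-open, and everything downstream uses the latter.
An intron's `coding_offset` is the number of coding nucleotides 5' of it;
its phase is `coding_offset mod 3`. The **anchor convention**: an intron
is attached to the residue whose codon contains the first coding
nucleotide 3' of the intron, i.e. `anchor = coding_offset %/% 3 + 1` for
all phases (a phase-0 intron is anchored to the residue that follows it,
phase-1/2 introns to the residue they interrupt). Any consistent
convention preserves which introns coincide across sequences — which is
the only thing the analyses consume — but mixing conventions would not,
so the package applies this one everywhere, including the simulator.

Two intron positions match only if they agree *exactly* in alignment
column and phase. No near-miss (±1 column) merging is attempted, because
no principled sliding-window rule exists; local misalignment therefore
translates into false "unique" calls, never false "shared" ones.
The annotated GFF3 phase column is ignored (annotation phases are
frequently wrong) and recomputed from coordinates. A transcript whose
CDS length is not a multiple of 3 is kept but flagged, and contributes
`"?"` (missing) rather than fabricated positions.

## The gain/loss model

Each intron position evolves on the rooted species tree as a two-state
(absent/present) Markov chain with per-branch transition probabilities:
gain `g_b = P(0 -> 1)` and loss `l_b = P(1 -> 0)` on branch `b`, plus a
root prior `pi`. Parameterising branches directly by probabilities rather
than rate times length keeps the model usable on topology-only trees; a
`global_rate` mode (`1 - exp(-rate * length)`) exists when branch lengths
are available. Likelihoods come from Felsenstein pruning with `?` leaves
contributing 1 to both states; posteriors (per node, and per branch for
gains/losses) from the standard up–down recursion. Multifurcations —
including the unresolved-root species topology used as a robustness
check — are handled as products over children.

**Observability correction.** Positions absent in every species never
appear in an intron table, so the likelihood is conditioned on "present
in at least one leaf": `L(pattern) / (1 - P0)` with `P0` the all-absent
pattern probability. Unconditioned ML would bias gain probabilities
downwards. For ancestral counts the package uses the unbiased
"including missing sites" estimator
`sum(posterior at node) + n * P0/(1 - P0) * P(node present | all absent)`;
the superficially simpler `sum(posterior)/(1 - P0)` is biased upwards
(by roughly 30% at loss 0.3 / gain 0.02 on a 12-leaf tree, measured with
the true parameters in the test suite's simulations).

**Optimisation.** `estimate_rates()` maximises the conditional
log-likelihood by multi-start L-BFGS-B on logit-transformed parameters
(start seeds 1..5, first start a fixed moderate guess, ties broken by the
first seed). The gradient is analytic, assembled from posterior branch
transition probabilities, so per-branch fits over dozens of branches take
seconds, not hours. Patterns are collapsed to unique rows with weights
before fitting.

**Root identifiability.** With free per-branch probabilities the root
prior is *not* identifiable: the joint distribution of the root's
children has fewer degrees of freedom than the local parameters, so
`pi` lies on a likelihood ridge and joint-ML per-branch fits can place
it far from the truth even when every branch loss probability is
recovered well. The package therefore uses the per-branch mode for
branch-wise rate maps and the identifiable `global` (or `global_rate`)
mode wherever ancestral counts or root posteriors are the target. At the
validation design point (5000 positions, 20 leaves, gain 0.02, loss 0.3)
the global-mode root count is within a few percent of truth while the
per-branch root count can err by ~20% despite a higher likelihood.

**LECA calls** use an inclusive threshold of 0.5 on the posterior at the
LECA node (the root under the Opimoda–Diphoda rooting, or the root of
the multifurcation under the unresolved-root variant). One category of
rates is fitted — no rates-across-sites variation. This is a deliberate
simplification; in simulation the 0.5-threshold calls are robust to it
(about 91% call accuracy at the default study conditions, recomputed by
`scripts/acceptance.R` on every run).

## Shared introns and the parallel-gain control

LECA introns are transferred to merged family coordinates by ungapped
residue rank and matched exactly. OGs within one *acquisition* (one gene
that entered the proto-eukaryote) are paralogs: a position matched
between them is a **shared** LECA intron. OGs that are alone in their
acquisition are separately acquired homologs: a match between two of
them can only be a parallel gain, so those OGs form the **control set**.
Three rules keep the comparison clean and symmetric:

- an intron whose only matches cross the paralog/control divide is
  excluded from both numerator and denominator on both sides;
- a control OG needs at least one other separately acquired OG in the
  family, mirroring how every paralog-set OG has at least one
  within-acquisition partner, so the two sets face comparable numbers of
  comparison partners;
- OGs flagged ambiguous (an acquisition with another acquisition as
  sister) are excluded from both sets.

Shared *fractions* are reported per intron. The Fisher exact test of
paralogs versus control, however, counts distinct *positions*: one
sharing event creates matching introns in at least two OGs at once, and
counting both would enter every event twice and overdisperse the
hypergeometric null. With position counting the null p-value
distribution is uniform in simulation (200 seeds of pure parallel gain);
with intron counting it is visibly anticonservative.

## Dollo parsimony on gene trees

Within a gene tree (leaves = LECA OGs, internal nodes = duplications),
each intron is allowed exactly one gain and unlimited losses: presence
is assigned to the minimal spanning subtree of its carrier leaves, the
gain to the branch entering that subtree, and one loss to every branch
leaving it. Gains and losses on branches entering internal nodes happened
before a duplication; those entering leaves happened on the branches that
produced the LECA families. A duplication node with a non-empty presence
set had introns before it duplicated; a secondary flag records
duplications whose more ancestral duplication had introns. Multifurcating
gene trees are used as-is. The reconstruction is exactly minimal: the
test suite checks it against exhaustive enumeration over all single-gain
assignments on 200 random trees.

## Relative positions and masking

For positional analyses, alignment columns with 90% or more gaps are
masked (only `-` counts as a gap; `X` is a residue). An intron's relative
position is the rank of its column among kept columns divided by the
number of kept columns; an intron in a masked column takes the rank of
the nearest kept column 5' of it (an intron 5' of every kept column gets
0). This keeps every intron while preventing sparsely occupied columns
from stretching the coordinate.

## What the simulator emulates — and what it does not

Defaults (all overridable in `simulation_config()`) describe a desk-scale
study: 50 families on a random 20-species tree; 1–3 acquisitions per
family and 0–3 duplications per acquisition at uniform times on a stem of
length 1; stem gain rate 12 and loss rate 4 per unit time; phase weights
(0.5, 0.3, 0.2), matching the universal phase-0 excess; 3'-biased loss
with weight `exp(2 * relative position)`, the simplest monotone form of
loss by reverse-transcriptase-mediated recombination; parallel gains as
independent hits on a family-level pool of 20 proto-splice hotspots at
probability 0.15 per gain, chosen so the separate-acquisition background
lands at a few percent of introns; post-LECA per-branch loss 0.15, re-gain
0.005, 0.3 new positions per branch per OG; 5% missing orthologs per
species; protein length 400.

The hotspot mechanism deserves a note: parallel gains must be *symmetric*
across lineage pairs for the control comparison to be calibrated, which
a "re-use any already occupied position" rule is not (lineages simulated
later see more occupied positions). A fixed hotspot pool hit
independently by all lineages is both symmetric and the protosplice-site
model in miniature.

The simulator covers intron bookkeeping, not sequence realism: proteins
are random sequences with uniform synonymous back-translation and a small
substitution rate, alignments are emitted as truth (no aligner runs),
indels are optional OG-level deletions, and there is no codon model, no
rate heterogeneity across sites and no annotation error. Consequently,
passing tests demonstrate the correctness of the pipeline's logic and
estimators under the stated model — they say nothing about alignment
quality, gene-model errors or orthology assignment in real data, which
the exact-match rule and the `"?"` conventions only partially absorb.

## Numerical choices

Pruning partials are rescaled per internal node (log-scale accumulator),
so likelihoods of thousands of positions on large trees do not
underflow; an impossible pattern yields log-likelihood `-Inf` and a
clear error from the posterior routines. Logit-transformed parameters
are box-bounded at ±9 (probabilities between ~1e-4 and ~1 - 1e-4) to
keep boundary fits finite; a fit touching the boundary reports loss ~0
as "no loss observed", which is the correct reading. Fisher p-values are
capped at 1 to absorb floating-point overshoot. Chi-squared tests use no
continuity correction, matching the classical statistic and degrees of
freedom. KS tests use the exact p-value for small, tie-free samples and
the asymptotic one otherwise. BH adjustment is the standard step-up; it
is order-equivariant and monotone but *not* idempotent (re-adjusting
already-adjusted values can only push them up — a property the tests
assert instead of the false idempotence claim).

## Problem sizes used in validation

The test suite validates likelihoods/posteriors against exhaustive
enumeration on 200 random trees of up to 6 leaves (tolerance 1e-10),
Dollo reconstructions against enumeration on 200 trees of up to 8
leaves, the coordinate round-trip on >1000 simulator-planted introns
across both strands and all phases, parameter recovery on 5000 positions
over 20 species, shared-intron fidelity and the control calibration on
50–200 seeded replicates, and the 3'-loss positional signal at a
documented effect size (loss weighting `exp(8 r)`, ~240 surviving introns
per cohort) over 50 seeds. These sizes were chosen as the smallest at
which the corresponding statistical checks have comfortable power.

## Known limitations

- Exact (column, phase) matching plus trust in the merged alignment:
  locally misaligned merges lose shared introns silently.
- One rate category; no rates-across-sites variation in the
  reconstruction model.
- The root prior is unidentifiable in the per-branch model (see above);
  users who need ancestral counts must use an identifiable mode.
- Gene conversion between paralogs, an alternative source of shared
  positions, is not modelled.
- The unresolved-root robustness variant changes only the root
  multifurcation; it does not explore other rootings.
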