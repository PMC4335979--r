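---
title: "Delimiting a transporter gene family and reconstructing its history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting a transporter gene family and reconstructing its history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jenscape)
```

`jenscape` chains the standard steps of a gene-family study — reciprocal
homology screening, multiple alignment, distance phylogeny, duplication–loss
reconciliation, motif scanning, and consumption-rate estimation — into one
package with explicit, testable contracts.  This vignette documents the
models behind each stage, the parameters that matter, the numerical
conventions, and the limits of what the synthetic validation shows.

## Pairwise alignment and search statistics

Global (Needleman–Wunsch) and local (Smith–Waterman) alignment use an
affine gap model in which a gap of length $L$ costs
$o + (L-1)\,e$ with opening penalty $o$ and extension penalty $e$.  The
default scheme is BLOSUM62 with $o = 11$, $e = 1$ — the standard protein
search defaults — and the matching gapped Karlin–Altschul parameters
$\lambda = 0.267$, $K = 0.041$ so that
$E = K\,m\,n\,e^{-\lambda S}$ gives E-values on the familiar scale and an
$E \le 10^{-10}$ cutoff means what practitioners expect.  No heuristic
seeding is performed: every query–subject pair is aligned exactly, which is
what makes score-level oracle tests possible.  The unknown residue `X`
scores 0 against everything, so unknowns neither penalise nor certify
similarity; for the same reason an `X`–`X` column is not counted as an
identity (otherwise identity could exceed similarity).

Co-optimal alignments are resolved deterministically: substitution columns
are preferred over gaps in the first sequence, which are preferred over
gaps in the second.  Determinism matters because the reciprocal screen's
"top hit" rule, and therefore family membership, must not depend on
evaluation order.  Percent identity and similarity are reported over the
full alignment length including gap columns (the EMBOSS pairwise
convention), with similarity defined as a positive substitution score.

## The reciprocal screen

Family membership is decided by a two-step reciprocal rule.  For each seed
protein and each other species, the single top forward hit passing the
E-value cutoff (database length $n$ = total residues of that proteome) is
aligned back against the entire seed proteome; it joins the family if and
only if its top reciprocal hit is one of the seeds.  Ties at the top are
broken canonically (E-value ascending, raw score descending, subject id
ascending).  Screening only the single top forward hit per (seed, species)
is a deliberate, conservative reading of "top hit": paralogs missed this
way can still be admitted through other seeds, and the provenance table
records every admitting pair.  The screen's output is invariant to the
order of records in the input proteomes, which the tests enforce.

## Progressive alignment and block filtering

The aligner is the textbook progressive scheme: all-pairs global alignment
distances ($1 - \text{identity}/100$) feed a Neighbor-Joining guide tree,
and profiles are merged bottom-up by profile–profile Needleman–Wunsch.  A
column pair is scored by the arithmetic mean of substitution scores over
residue–residue pairs (gap entries excluded from the mean); new gaps pay
the affine penalties.  This is the simplest standard choice — matching the
output of any particular production aligner is a non-goal, and the
simulator produces no indels, so alignment-quality questions reduce to
"gapless inputs must stay gapless", which is tested.

Block filtering keeps a column when its gap fraction is at most
`max_gap_fraction` (default 0.5) and its most frequent residue, gaps
excluded, reaches `min_conserved_fraction` (default 0.5); maximal runs of
eligible columns shorter than `min_block_length` (default 3) are dropped.
The defaults are mild on purpose: the filter is a noise guard ahead of
distance computation, not a reimplementation of any specific published
filter's flank and anchor rules.  The filter is idempotent.

## Distances, tree building, and support

Pairwise p-distances use pairwise deletion (only columns where both rows
carry residues are compared); a pair with no comparable columns is an
error, not a silent zero.  Two corrections are offered: Poisson,
$d = -\ln(1-p)$, and a Γ rate-heterogeneity law,
$d = \alpha\big((1-p)^{-1/\alpha} - 1\big)$, which approaches the Poisson
form as $\alpha \to \infty$.  The shape parameter is user-supplied with
default $\alpha = 1$: maximum-likelihood optimisation of $\alpha$ (and ML
tree inference generally) is outside this package's scope, so no default
could be "estimated from the data" and an explicit, documented constant is
the honest choice.  Distances with $p > 0.99$ are treated as saturated and
raise an error by default; a cap (default 10 substitutions/site) can be
requested instead, so saturation is always a visible decision.

Neighbor-Joining follows the Saitou–Nei agglomeration with the standard
three-point branch lengths.  Two conventions make it reproducible:
co-minimal $Q$ pairs are broken by the lexicographically smallest pair of
representative labels (the smallest leaf label under each node), and
negative branch lengths are clamped to zero with the deficit moved to the
sibling edge, preserving path lengths.  BioNJ shares the loop but reduces
distances with the variance-weighted $\lambda$ (clamped to $[0,1]$),
variances initialised to the distances themselves.  On additive matrices
both reduce to exact tree recovery, which is the core consistency test.

Bootstrap support resamples alignment columns with replacement, rebuilds a
tree per replicate, and reports for each internal bipartition of the main
tree the percentage of replicates containing it (default 100 replicates).
Replicates whose distance computation fails — a saturated or incomparable
pair after resampling — are skipped, counted, and reported, rather than
silently imputed.  Trivial bipartitions are shown as 100 by convention.
Outgroup rooting requires the outgroup to be monophyletic in the unrooted
sense and places the root at the midpoint of the separating edge.

## Duplication–loss reconciliation

Given rooted binary gene and species trees and a leaf map, each gene node
is mapped to the species-tree LCA of its children's images; a node is a
duplication exactly when its image equals a child's image.  Losses are
charged per skipped species branch — path length minus one for
speciations, path length for duplications — and placed on the sibling
branches passed over, which yields a unique, checkable placement.  The LCA
mapping provably minimises both the duplication count and the total event
count, and the tests verify this against an independent dynamic program
that minimises over *all* valid mappings on hundreds of random instances.
Polytomies are rejected rather than auto-resolved: silent resolution
changes event counts, so resolving is the user's explicit decision.  In
the pipeline, gene trees are rooted with a designated outgroup before
reconciliation.

`scenario_report()` renders the reconciliation as per-branch bookkeeping:
copies entering each species branch, duplications and losses placed on it,
and copies leaving.  The leaving counts are derived independently from the
edge paths of the reconciliation, so the row identity
$\text{leaving} = \text{entering} + \text{dup} - \text{loss}$, and the
requirement that copies leaving a terminal branch equal the genes observed
in that species, are genuine consistency checks rather than restatements
of the computation.  The family is taken to enter the species tree on the
stem of the gene root's image — branches above it carry no copies.

## What the simulators emulate — and what they do not

The generators provide inputs with recorded ground truth under the
conditions the analyses assume:

* **Species trees**: Yule topologies (uniform random leaf splitting) with
  i.i.d. exponential branch lengths of mean 0.1 substitutions/site.  Real
  species trees are data-derived; the mean is a configuration knob
  (`branch_length_mean`) precisely because no empirical value is available
  to copy.
* **Gene families**: a forward birth–death process along the species tree.
  Each lineage accrues duplications and losses as competing Poisson
  processes (`dup_rate`, `loss_rate` events per unit branch length,
  defaults 0.3 and 0.1 — a moderately dynamic family of the kind that
  motivates reconciliation analyses); event times come from exponential
  waiting times, so the simulator returns an exact event list, not just
  counts.
* **Sequences**: the 20-state equal-rates substitution model, applied as
  the exact per-branch transition probability
  $P(\text{change}) = \tfrac{19}{20}\big(1 - e^{-\frac{20}{19} r t}\big)$.
  Using the exact transition (rather than "at most one substitution per
  branch") means multiple hits and back-substitutions are modelled and the
  expected p-distance between any two sequences follows the closed form
  $0.95\,(1 - e^{-\frac{20}{19} r\,\text{path}})$, which the tests check at
  10,000 sites.  Empirical exchange matrices and site-rate heterogeneity
  are deliberately out of scope: the uniform model has closed-form
  expectations, which is what makes the simulator usable as an oracle.
* **Decoys**: uniform random sequences, 200–800 residues, guaranteeing
  that decoys are unrelated to the family so screen specificity is
  well-posed.
* **Consumption curves**: linear decay $\max(0, c_0 - r t)$, optionally
  with one breakpoint and a second rate, plus Gaussian noise re-clipped at
  zero.  Default panels use rates in the 0.05–0.3 g/L/h range with
  noise SD 0.05 g/L and about a dozen samples over 40 h — the scale of a
  flask HPLC experiment.

Because decoys are uniform random and family sequences carry no indels or
compositional bias, a perfect screen recovery on simulated data does **not**
show that the E-value cutoff separates true homologs from, say,
low-complexity or promiscuous-domain matches in real proteomes; it shows
the machinery is correct under the stated model.  The same caveat applies
to the gapless alignments (no indel model) and to rate fits (no growth
coupling, no measurement drift — only i.i.d. Gaussian noise).

### When is the simulated history recoverable?

Parsimony can only under-count a true history, so the simulator flags
replicates whose history is provably recoverable (`clean_history`): every
loss must be *immediate* (its lineage created by a speciation and dead
before any further branching, so the surviving sister forces the charge),
every speciation must keep survivors on at least one side — on both sides
for the root, otherwise the pruned root's image slides below the species
root and stem events vanish — and every duplication must keep survivors on
both sides *whose surviving descendants still span the species node the
duplication sits on*, otherwise the LCA mapping pulls the duplication down
the tree.  These conditions are sufficient, not necessary: some flagged
histories would still reconcile exactly.  On flagged replicates the tests
require exact equality of event counts; on all replicates they require the
parsimony counts never to exceed the truth.

## Consumption-rate estimation

Rates are ordinary least squares of concentration on time; the reported
rate is the negated slope (a positive slope yields rate 0 with a warning),
and R² is the squared Pearson correlation, matching how such tables report
a "coefficient of linear correlation".  The default window truncates the
series before the first observation at or below 0 g/L, because
post-depletion zeros would bias the slope toward zero.  Segmented fits
around a breakpoint (default 22 h, the point where co-substrates run out
in the motivating experiments) fit the two sides independently, with a
boundary sample belonging to both windows; the breakpoint is a parameter,
not an estimate — changepoint detection is a non-goal.  Ratio tables store
the unrounded mutant/reference ratio and display it rounded half away from
zero at a configurable number of significant figures, since published
tables of this kind are rounded that way (and are occasionally internally
inconsistent, which is why the unrounded value is always kept).

## Motif scanning

Patterns combine fixed residues, `X` wildcards, and residue classes
(`(S/T)` or `[ST]`).  All overlapping windows are reported with 1-based
anchor coordinates for every non-wildcard element, so statements like "the
signature's histidine sits at residue 383" are direct outputs.  An `X` *in
a sequence* satisfies only wildcards — an unknown residue never certifies
a motif.  `diagnose_motif()` reports near-miss windows with at most a
given number of violated elements, which is the tool for localising which
position of a signature a divergent paralog has replaced.  The scanner is
property-tested against a lookahead-regex oracle.

## Pipeline orchestration

`pipeline_config()` validates a declarative run description — stage
toggles, inputs, thresholds, one master seed — before anything executes,
and `run_pipeline()` writes every artifact as FASTA/Newick/TSV plus a JSON
manifest with per-stage seeds and md5 checksums.  Per-stage seeds are
derived deterministically from the master seed by a label hash, so enabling
or disabling one stage does not shift another stage's random stream, and a
rerun with the same configuration is byte-identical.  The package's
functions are the interface; the pipeline is a convenience wrapper around
them, not a separate code path.

## Numerical conventions and degenerate inputs

* All user-facing sequence coordinates are 1-based inclusive; internally,
  alignments are index vectors with 0 marking gaps.
* Branch lengths are serialised with 17 significant digits, so
  Newick round-trips preserve sums to floating-point accuracy.
* A single sequence "aligns" to itself as a one-row alignment; two
  sequences reduce to the exact pairwise global alignment.
* Two-taxon trees are returned as a single path whose total length equals
  the input distance (split at its midpoint, since a rooted binary
  container cannot carry a bare edge).
* Constant concentration series fit as rate 0 with a warning rather than
  an error; zero time-variance is an error.
* Simulators save and restore the caller's RNG state: they are pure
  functions of their arguments and seed.

## Problem sizes used in validation

The test suite validates the alignment kernel against exhaustive
enumeration on short peptides and against an independent library
implementation on longer ones; reconciliation against the exhaustive
dynamic program on 300 random instances (gene trees up to 8 leaves,
species trees up to 5); NJ consistency on 200 random additive matrices of
4–12 taxa; end-to-end screen recovery on 50 simulated 6-species clades
with 20 decoys per proteome and 250-residue proteins; rate recovery on 500
simulated curves; and the motif scanner against the regex oracle on 1,000
random sequences.  These sizes keep the full suite around a minute on one
CPU while leaving each statistical check enough replicates for its stated
tolerance.

## Known limitations

* No maximum-likelihood or Bayesian tree inference, and no model
  selection; distance methods with optional Γ correction are the scope.
* No indel model in the sequence simulator, hence no stress test of the
  aligner's gap placement on truth-labelled data.
* Reconciliation assumes binary rooted trees and a duplication–loss model:
  no transfers, no incomplete lineage sorting, no uncertainty propagation
  from bootstrap trees into event counts.
* The screen's specificity guarantees are relative to unrelated random
  decoys; real proteomes contain related non-orthologs (domain shuffling,
  ancient paralogs) that only the reciprocal rule — not the E-value — can
  reject, and no synteny evidence is used (user-supplied ortholog
  constraints can be validated, but synteny detection is out of scope).
* Consumption-rate fits assume a known breakpoint and i.i.d. Gaussian
  noise; kinetic parameters (K~m~, V~max~) require transport assays and
  are not estimable from these curves.
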