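---
title: "Screening strain divergence: variant filtering, T1SS cargo prediction, and biofilm founder back-calculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening strain divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straindrift)
library(dplyr)
```

`straindrift` implements the computational skeleton of a strain-divergence
study: deciding which deviations in a bacterial resequencing experiment are
real, attributing them to lineages, interpreting them at the codon level,
predicting which proteins a type I secretion system (T1SS) exports, and
back-projecting an observed biofilm to the minimal population that founded
it. This vignette documents the models, the defaults and why they hold, and
what the synthetic generators do and do not emulate.

## The variant acceptance rule

A candidate site in a pileup summary is described by its total depth $d$,
alternate-read count $a$, and the strand split $(a_f, a_r)$ of those
alternate reads. The rule is a deterministic threshold filter, not a
genotype-likelihood model:

$$\text{pass} \iff \frac{a}{d} \ge 0.10 \;\wedge\;
  \left(\frac{a}{d} \ge 0.80 \;\vee\; \frac{\max(a_f, a_r)}{a} < 0.70\right)$$

Three choices here were genuinely open and are worth recording:

* **The strand-bias statistic.** "Strand bias" has no unique definition; we
  use the majority-strand share $\max(a_f,a_r)/a \in [0.5, 1]$, the
  simplest statistic for which "limited to less than 70%" is meaningful,
  with a strict `<` comparison. A perfectly balanced variant scores 0.5; a
  single-strand artifact scores 1.
* **Boundary conventions.** The frequency clause uses $\ge$ ("at least
  10%") and the waiver clause $\ge$ 0.80, mirroring the rule's wording;
  `filter_thresholds()` exposes all three numbers.
* **Failure attribution.** `fail_reason` reports the first violated clause
  (`below_min_frequency` before `strand_biased`), so downstream tallies of
  why candidates die are unambiguous.

At 63× coverage this rule is insensitive to variants below ~6 reads and
waives the strand test exactly where true variants are common enough that
strand asymmetry carries no artifact signal. The test suite checks the
implementation against an exhaustive clause-by-clause truth table over all
pileup configurations with depth ≤ 30 (5,455 alt-depth/strand
combinations), and a monotonicity property: at fixed depth and strand
ratio, passing is monotone in alt depth.

Indels and other length-changing alleles are rejected with an explicit
error rather than silently dropped: the screen's substance is
substitutions, and silently ignoring a row would bias cross-sample
classification.

## Cross-sample classification

With samples assigned to strains (and optionally a designated "later"
sample, e.g. a biofilm resequenced after selection), each variant key
receives exactly one label, evaluated in this order: `shared_all` (passes
everywhere — the signature of an error in the original reference genome,
not a new mutation), `emergent` (passing calls confined to later samples),
`strain_unique` (passing calls confined to one strain), `other`. The order
matters: a variant passing in a strain's batch *and* biofilm samples is
`strain_unique`, not `emergent`; `emergent` is reserved for alleles absent
from the batch culture that rose to detectability under selection. The
partition property (every key, exactly one label) is tested on randomized
designs.

For reporting, variants with a maximum passing frequency ≥ 0.9 are flagged
`near_fixed` ("at or near 100%"); the cutoff is a reporting convention, not
part of the acceptance rule, and is configurable.

## Codon annotation

`annotate_codon_change()` maps an equal-length substitution at CDS position
$p$ to residue $\lceil p/3 \rceil$ and translates reference and alternate
codons with the standard genetic code (codon 635 of a GC-initial codon:
G→C gives A635P, GC→CT gives A635L, G→T gives A635S). A multi-nucleotide
variant spanning a codon boundary yields one row per affected codon.
Genome-space annotation (`annotate_variants()` over `read_gff3_cds()`
intervals) handles minus-strand genes by reverse-complementing both the
spliced CDS and the alleles; for a minus-strand MNV the mapped CDS position
is that of the 5′-most coding base, i.e. the highest genome coordinate. All
user-facing coordinates are 1-based inclusive.

## The T1SS/RTX cargo screen

T1SS export substrates share structural characteristics rather than
sequence homology. `screen_proteome()` requires, by default: length ≥ 1000
aa; pI ≤ 4.5; ≤ 3 cysteines; at least one hit of a calcium-binding repeat
signature; and ≥ 1 GGXGXDXXX nonamer starting in the C-terminal 25% of the
sequence. Gly/Ala-rich windows are reported (30-aa windows with ≥ 40% G+A,
merged into maximal segments) but do not gate the verdict, since they are
descriptive rather than discriminative. Each criterion is individually
configurable or removable, and `failed_criteria` names every violated rule
so that relaxing exactly one failing criterion flips the verdict — a
property the tests exercise.

Defaults were set where the qualitative criteria ("large", "acidic", "few
cysteines", "near the C terminus") needed numbers: the known cargo exceed
2400 aa while typical bacterial proteins are ~300 aa, so 1000 aa separates
the classes with a wide margin; the known cargo sit at pI 4.03–4.20, so
4.5 bounds "acidic" loosely; one known cargo has 3 cysteines, so 3 is the
ceiling; the known repeats sit in the final ~6% of their proteins, so a
25% window is deliberately generous.

**Motif matching.** The nonamer constrains only its conserved positions —
glycines at 1, 2, 4 and aspartate at 6 — with the remaining five positions
free, and matching is case-insensitive. Patterns are expressed in PROSITE
syntax, for which the package implements a full parser (`x`, sets,
exclusions, `(n)`/`(n,m)` repeats, terminal anchors) and a scanner that
reports every match at every offset, including overlaps and, for
variable-length patterns, multiple ends per start. Zero-length matches of
all-optional patterns are not reported. The scanner is verified against a
brute-force enumerator (expand all repeat-count combinations, test every
window position by position) on 1,000 random pattern/sequence cases up to
100 aa.

**The calcium-repeat signature** is a config datum, not code: the screen
parses whatever PROSITE-syntax pattern stands in
`extdata/ps00330_synthetic.prosite` (or any file you point
`ca_repeat_pattern()` at). The bundled pattern is a synthetic stand-in —
two consecutive nonamer turns, `G-G-x-G-x-D-x-x-x-G-G-x-G-x-D` — built
from the tandem architecture of hemolysin-type Ca²⁺-binding repeats;
substitute the genuine PROSITE release pattern (accession PS00330) for
production use against real proteomes.

**Isoelectric point.** The net charge at a given pH sums
Henderson–Hasselbalch terms over ionizable side chains (D, E, C, Y acidic;
H, K, R basic) and the two termini:
$Q(\mathrm{pH}) = \sum_{\text{basic}} (1+10^{\mathrm{pH}-pK_a})^{-1} -
\sum_{\text{acidic}} (1+10^{pK_a-\mathrm{pH}})^{-1}$. $Q$ is strictly
decreasing in pH, so the pI is found by bisection on $[0, 14]$ to
$|Q| < 10^{-4}$ (≤ 200 iterations); the tests confirm agreement within
0.01 pH of a 0.001-step grid argmin on random 30-mers, and monotonicity
under appending acidic/basic residues. Two pKa sets are bundled
(Bjellqvist/Expasy-style, the default, and EMBOSS); published pI values
computed with unknown tools can differ by ~0.1 pH between sets, which is
why the screen's pI threshold is deliberately loose. A sequence with no
ionizable groups and the terminus model disabled has no defined pI and
errors.

## The founder back-calculation

The chain converts an areal protein observation to a lower bound on the
founding population:

$$N_0 = \frac{P \cdot A}{c} \cdot (1 - \phi) \cdot 2^{-t/g}$$

with $P$ the areal protein (µg/cm²), $A$ the colonizable area (vessel +
slides; 231 + 7 × 15 = 336 cm² by default), $c$ the protein content per
cell (278 fg, with the µg→fg factor of 10⁹ handled internally), $\phi$ the
known non-producer fraction, and $t/g$ the elapsed doublings. Three
conventions matter:

* **Doubling rounding** defaults to nearest integer (120 h at 6.8 h is
  17.65 → 18 doublings); `floor` and `continuous` modes are provided, and
  the forward/backward round trip is exact only in `continuous` mode.
* **Elapsed time is total residence**, including any batch lead before
  continuous flow; the reactor simulator uses the same clock, so the two
  are mutually consistent.
* **Censoring**: observations below the 1.3 µg/cm² detection limit are
  refused for inference with an explicit error, never imputed. The result
  is a lower bound regardless, since effluent losses are ignored.

With the defaults this chain gives, at two significant figures, 5.4 × 10⁹
total cells, 4.1 × 10⁹ producers, 18 doublings and 1.6 × 10⁴ founders from
a 4.5 µg/cm² observation at 120 h — the numbers the acceptance tests pin.
A second published estimate of the same style (9.9 × 10³ founders from
398 µg/cm² at 168 h) is *not* reproducible from these constants — the
documented chain yields ~1.2 × 10⁴ — so it is not asserted anywhere; the
discrepancy presumably reflects unstated intermediate assumptions.

Utilities cover the reactor hydraulics: $D = 60 \cdot \text{flow}/V$
links flow (ml/min) and working volume (ml), so 0.70 ml/min at
$D = 0.112\,h^{-1}$ implies 375 ml, which predicts $D = 0.152\,h^{-1}$ at
0.95 ml/min; `washout_flag()` marks $D > \ln 2 / g$, where planktonic
cells cannot persist (advisory — biofilm is retained regardless).

`fit_generation_time()` estimates $g$ as $\ln 2 / \text{slope}$ of
ln OD vs time. The exponential window is either user-supplied or chosen by
maximizing $R^2$ over contiguous windows of at least half the usable
points (longer windows break ties) — the half-length floor keeps the
search from fixating on short, noise-inflated stretches. Points at or
below an OD floor (default 0.01, a practical blank level) are excluded;
slopes at numerical-noise level (≤ 10⁻⁸ h⁻¹) raise a no-growth error
rather than returning an absurd doubling time.

## What the synthetic generators emulate — and what they do not

`simulate_pileup()` draws, per planted variant and carrying sample, depth
from Poisson(63) (the shotgun approximation to "average 63× coverage";
`fixed` is available), alternate reads Binomial(depth, true frequency),
and forward-strand alternates Binomial(alt, strand skew). Non-carrying
samples get explicit zero-alternate rows so classification sees the full
grid. Spurious noise is drawn per site over a `region_length` universe
(the plan's addition — a per-site rate needs a site count; the demo plan
uses the ~3.57-Mb chromosome plus plasmid) at 2 × 10⁻⁶ per site, each
artifact confined to one random sample at a true frequency uniform on
0.01–0.08 — below the 10% rule, exercising the filter's rejection path.
The default rate plants a handful of artifact sites genome-wide, matching
a post-mapping-QC candidate list whose noise sits well under the
acceptance threshold; it is a free knob, not an estimate of any specific
caller's error model. Binomial sampling occasionally lifts an 8% site
above 10%, so a seeded strain-unique count can exceed the planted 12 by
one — visible across seeds of `scripts/acceptance.R`. What is *not*
simulated: read-level data, base qualities, mapping error, or
multi-allelic sites (overlapping planted variants in one sample are
rejected), so passing tests say nothing about alignment artifacts in real
data.

`simulate_proteome()` builds cargo from an acid-heavy, Gly/Ala-enriched,
cysteine-free background, embeds the requested tandem nonamers inside the
C-terminal window (free positions drawn from a G/D/C-free alphabet so no
shifted window matches), places the exact cysteine count, scrubs any
spurious backbone matches, and nudges composition into the target pI band
(default 4.0–4.3, bracketing the known cargo) by bounded D/E↔N/Q swaps —
an infeasible band errors after bounded attempts. Decoys alternate between
dipeptide-preserving shuffles of the cargo (same composition, length and
pI, destroyed motifs) and random-composition proteins of 200–1200 aa, each
re-drawn until it fails the screen, so planted-truth recovery is exact by
construction. Real proteomes differ: motif-adjacent degenerate repeats,
modular domain structure, and annotation artifacts are all absent.

`simulate_reactor()` is deliberately minimal — deterministic doubling from
the founders at the generation time, capped at a carrying capacity
(default 400 µg/cm², the order of observed steady-state biofilm), censored
below the detection limit (censored rows report `NA`, never a number). It
omits attachment/detachment kinetics, effluent losses and measurement
noise; its purpose is to be the exact inverse of the back-calculation,
which the round-trip tests verify to floating-point accuracy.

## Problem sizes and runtime

The test suite runs the property checks at sizes chosen to finish in about
a minute on one core while keeping estimator standard errors far from the
asserted bounds: 1,000 random PROSITE cases (≤ 100 aa), 50 random 30-mers
for the pI grid cross-check, the full depth ≤ 30 filter truth table, 100
seeds × 12 planted variants for the ≥ 95% sensitivity bound (the measured
sensitivity under frequencies uniform on [0.2, 1] at 63× has a standard
error of ~0.5 percentage points at this size), and a 100-decoy proteome
for planted-cargo recovery.

## Known limitations

* The filter is a threshold rule; it has no notion of base quality,
  mapping quality, or genotype likelihood, and inherits whatever depth the
  upstream pileup reports.
* Multi-allelic sites must be represented as separate single-sample plans
  or hand-built pileup rows; the generator rejects same-sample overlaps.
* The bundled calcium-repeat signature is a synthetic stand-in (see
  above); screens of real proteomes should drop in the PROSITE release
  pattern.
* pI values are model-dependent at the ±0.1 pH level across pKa sets.
* The founder estimate is a lower bound with strong assumptions (no
  effluent loss, constant generation time, biofilm protein ≈ cell
  protein); treat order-of-magnitude conclusions only.
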