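---
title: "Methods: quantifying Cre recognition of mutant loxP sites from competitive excision screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Cre recognition of mutant loxP sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxscreen)
```

## The measurement

A *lox* site is 34 bp: two 13-bp recombinase-binding elements (RBEs) in
inverted orientation around an asymmetric 8-bp spacer. The spacer sets
compatibility — *loxP* recombines with *loxP*, *lox2272* with *lox2272*,
never across — while the RBEs set Cre affinity. `loxscreen` quantifies how
substitutions in the *right* RBE of *loxP* change its recognition by Cre,
using a competitive construct:

```
5'flank - loxP#1 - markerB - lox2272#1 - stuffer - loxP#2 - markerA - lox2272#2 - 3'flank
```

All four sites share orientation. Excision through the *loxP* pair removes
everything between them — including markerB and one *lox2272* — so no second
excision is possible; excision through the *lox2272* pair likewise removes
markerA and one *loxP*. The two events are mutually exclusive, and among
molecules that recombined, the fraction that took the *loxP* route is the
per-variant **cleavage rate**:

$$\text{cleavage rate} = 100\cdot\frac{n_{loxP}}{n_{loxP}+n_{lox2272}}.$$

For the wild-type right RBE both competing pairs are fully recognized and
the rate sits near 50%; affinity-reducing substitutions push it down. The
**non-cleavage rate**, $100\,n_{NC}/(n_{NC}+n_{loxP}+n_{lox2272})$, tracks
induction efficiency rather than site affinity and should be small and
uniform across variants.

### Assumptions

* Both *loxP* copies in a molecule carry the *same* variant RBE. This is a
  modelling decision, not an observation: if only one copy were mutated, a
  *lox2272*-excised molecule would lose its variant copy and the three-way
  per-variant tally would be impossible. Under this assumption the variant
  identity survives every outcome (the hybrid site left by *loxP* excision
  inherits the shared variant).
* Per-molecule outcomes are independent draws from
  $\text{Multinomial}(n;\, p_{NC},\,(1-p_{NC})p_{loxP},\,(1-p_{NC})(1-p_{loxP}))$.
  Kinetics of induction, PCR amplification bias and chimeric molecules are
  out of scope.
* One read pair per molecule; classification treats the pair as one unit.

## Library design model

Doped synthesis keeps the original base at each position with probability
$x/100$ and substitutes uniformly among the three alternatives otherwise.
The substitution count over $L = 13$ positions is
$\text{Binomial}(L, 1 - x/100)$; `substitution_count_distribution()` is the
closed form, `sample_library()` the sampler. At the design point
$x = 84.7$ the mode is $y = 2$ and $P(2) = 78\cdot0.847^{11}\cdot0.153^2 =
0.2939$ — the doping rate maximizing double substitutions, chosen because
singles barely move the rate and the $\binom{13}{y}3^y$ class sizes explode
past $y = 2$ (39, 702, 7722, ...), making coverage of deeper classes
infeasible. Explicit class enumeration is capped at $k \le 2$ by default
(larger classes are counted analytically) to bound memory; the cap is a
function argument.

## The synthetic-data generator

The generator stands in for everything between primer synthesis and the
sequencer. What it emulates:

* **Construct** — concrete coordinates are artifact-defined (the real
  plasmid layout is not part of the data model; only the marker decision
  logic is contractual). Defaults: 12-bp flanks, 24-bp marker tags, 20-bp
  stuffer, giving a 228-bp uncleaved amplicon fully covered by a 2×150
  pair. Marker tags and flanks are drawn uniformly at random once per run
  (rejecting draws containing either 21-bp lox anchor on either strand, or
  one another) and recorded in `markers.yaml`.
* **Outcomes** — one multinomial draw per variant at its true
  $(p_{NC}, p_{loxP})$.
* **Reads** — mate 1 is the amplicon's first 150 bases, mate 2 the reverse
  complement of its last 150; substitution errors i.i.d. per base at a
  configurable rate (default 0 in tests, 0.001 in the staged workflow);
  constant Phred 37 qualities. Indels, quality gradients, adapter
  read-through and UMI structure are *not* modelled — so passing tests show
  the estimator is correct under clean multinomial sampling, not that it is
  robust to every artifact of real libraries. The exact-match design makes
  real-data degradation conservative: damaged anchors become counted
  extraction failures, never misassignments.
* **qPCR** — $C_q = b + m\log_{10}(\text{copies}) + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.15$ cycles by default
  (a typical SYBR replicate spread), quantified back through a curve fitted
  to a simulated 7-point 10-fold dilution series ($10^6..1$ relative
  copies), one independent curve per assay.

### The default truth model

The spec of a truth table is per-variant $(p_{NC}, p_{loxP})$.
Where a study-derived table is wanted, `table1_truth()` uses the packaged
reference table of 50 published variants with their printed rates. Where a
generic model suffices, `default_truth()` sets $p_{loxP}(k) = 0.5\cdot
0.85^k$: 0.5 at wild type (symmetric competition between two fully
recognized pairs) with a 15% multiplicative affinity loss per substitution —
a single-parameter monotone decay consistent with the observed range
(roughly 17–35% for $k = 2..6$ among strongly affected variants, with the
bulk higher). $p_{NC}$ defaults to 0.035, the screen-wide average. These are
defaults of the generator, not estimates; any truth table can be supplied.

## Classification and estimation choices

* **Exact matching.** Anchors (21 bp) and markers (24 bp) are matched with
  zero mismatches on both mates and both strands. Mismatch tolerance would
  trade conservative failure counting for silent misassignment; the simple
  exact scan also matches how such screens are typically scripted.
* **Discordant extractions fail.** If a pair contains several anchor hits
  whose following 13-mers disagree (a sequencing error inside the RBE), the
  pair is an extraction failure — never a majority vote.
* **Denominators.** Unclassified pairs (neither marker) enter neither rate.
  The non-cleavage denominator is the three recombination classes only;
  this is configurable in principle but fixed here for determinism.
* **Cutoff.** `passes_cutoff` is strict: a variant needs *more than* 500
  classified pairs. Ties at exactly 500 fail.
* **Precision and conventions.** Rates are kept at full precision
  internally and rounded to 1 decimal in TSV output. Coordinates are
  0-based half-open internally; user-facing positions are 1-based. The
  *loxP* spacer is written top-strand as `ATGTATGC`; variant tables in the
  wet-lab convention print its reverse complement `GCATACAT`.
* **qPCR replicates** are averaged on the copy scale, not the $C_q$ scale,
  because the downstream statistic is a ratio of copies. Calibration
  requires $\ge 3$ distinct positive levels and a negative slope; the
  fit-then-quantify round trip is exact to $10^{-6}$ relative on noiseless
  series. Extrapolation beyond the dilution range is allowed but flagged
  (with $10^{-8}$ relative slack at the boundaries so noiseless round trips
  are not spuriously flagged).
* **Group comparisons** use Welch's unequal-variance two-tailed *t*-test
  between adjacent substitution classes; equal variances across classes is
  not defensible a priori.

## Reproducibility

Every sampler takes an integer seed and restores the caller's RNG state.
`run_end_to_end()` stamps each stage file with a hash of the configuration
(excluding output paths, never timestamps), so reruns with one config are
byte-identical.

## Problem sizes in the shipped checks

The test suite exercises parameter recovery at 100 variants × 2000
molecules (truth rates evenly spaced over 0.5–60%, zero read error:
recovery within per-variant multinomial 3σ and $R^2 \ge 0.99$), oracle
equivalence on $10^5$ pairs against a brute-force substring scan of each
molecule's source amplicon, goodness-of-fit of $10^5$ library draws against
the binomial closed form, and qPCR concordance on 10 matched variants
($R^2 \ge 0.95$). The staged workflow under `analysis/` runs 200 variants ×
2000 molecules at error rate 0.001. These sizes were chosen as the smallest
that leave the statistical bounds comfortably away from their noise floors.

## Known limitations

* The affinity decay model is a one-parameter stand-in; real per-variant
  rates depend on *which* positions are substituted, not just how many.
  Position-specific effects enter only through user-supplied truth tables.
* Exact-match extraction discards any read pair whose anchor carries even
  one error, biasing depth (though not rates, which condition on extracted
  pairs) downward at high error rates.
* The qPCR simulator draws noise on the cycle scale only; pipetting error,
  inhibition and efficiency drift between plates are not modelled.
* Sequencing errors inside the RBE create spurious low-depth "variants";
  the read-depth cutoff is the sole guard against them, as in the original
  analysis design.
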