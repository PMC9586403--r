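# loxscreen

Quantifying Cre recombination efficiency across libraries of mutant *loxP*
sites.

## The problem

Sparse genetic labeling needs a dial: a way to mark a chosen, reproducible
fraction of a cell population. One such dial is the *loxP* site itself —
mutating the 13-bp right recombinase-binding element (RBE) of *loxP* lowers
its affinity for Cre, and each mutant site recombines at a characteristic,
heritable rate. Measuring that rate for many mutants at once is done with a
competitive construct carrying a mutant *loxP* pair and a heterospecific
*lox2272* pair: Cre excision through one pair destroys the other, so among
recombined molecules the fraction that chose the *loxP* route reads out the
mutant site's recognition efficiency.

`loxscreen` implements the full quantification pipeline for such a screen,
plus a synthetic-data generator that stands in for the wet-lab steps, so the
statistical machinery can be exercised and validated end to end. It is aimed
at researchers designing doped-oligo *lox* libraries or re-analyzing
competitive excision screens.

## The model

**Library design.** Doped synthesis keeps the original base at each of the
13 RBE positions with probability *x*/100 (here *x* = 84.7) and substitutes
otherwise. The number of substitutions *y* per library member is binomial:

$$P(y) = \binom{13}{y}\left(\frac{x}{100}\right)^{13-y}\left(\frac{100-x}{100}\right)^{y}$$

At *x* = 84.7 the mode is *y* = 2 and about 30% of the library carries
exactly two substitutions. The *y*-substitution class contains
$\binom{13}{y} 3^y$ distinct sequences (39 singles, 702 doubles, ...).

**Read classification.** Each paired-end amplicon read pair is assigned its
variant by exact matching of the 21-base *loxP* anchor (left RBE + spacer)
and taking the following 13 bases, then classified by the presence of two
diagnostic marker sequences A and B: both present = not cleaved; A only =
cleaved between *loxP*; B only = cleaved between *lox2272*; neither =
unclassified. Per variant, with read-pair counts $n_P$ (loxP-cleaved),
$n_{2272}$ (lox2272-cleaved) and $n_{NC}$ (uncleaved):

$$\text{cleavage rate} = 100 \cdot \frac{n_P}{n_P + n_{2272}}, \qquad
  \text{non-cleavage rate} = 100 \cdot \frac{n_{NC}}{n_{NC} + n_P + n_{2272}}$$

Variants with more than 500 classified pairs pass the reliability cutoff.

**qPCR validation.** Three standard-curve assays (non-cleaved, *loxP*
junction, *lox2272* junction; each calibrated on a 7-point 10-fold dilution
series, copies $=10^{(C_q-b)/m}$) re-measure the same rates from copy
numbers; concordance with sequencing is summarized as the squared Pearson
correlation.

## Worked example

Evaluate the design model, then simulate and re-measure four published
low-efficiency variants at depth 2000:

```r
library(loxscreen)

round(substitution_count_distribution(84.7)[1:5], 4)
#>      0      1      2      3      4
#> 0.1155 0.2712 0.2939 0.1947 0.0879

tr  <- table1_truth(n_molecules = 2000)[1:4, ]   # printed rates as truth
sim <- generate_fastq(tr, tempfile(), config = construct_config(1), seed = 1)
est <- estimate_library(sim$r1, sim$r2, sim$markers, cutoff = 500)
est[, c("variant", "n_loxP", "n_lox2272", "cleavage_rate_pct", "passes_cutoff")]
#>         variant n_loxP n_lox2272 cleavage_rate_pct passes_cutoff
#> 1 GATGTCAAGATAG    331      1597          17.16805          TRUE
#> 2 TGGAGCATGTCAT    404      1533          20.85700          TRUE
#> 3 CGTACAAAGTTAT    459      1475          23.73320          TRUE
#> 4 TCAACCAAGTTAT    539      1391          27.92746          TRUE
```

The recovered cleavage rates sit within sampling noise of the reference
values the simulation was fed (17.3, 23.0, 23.5, 26.0), and the
non-cleavage rates cluster at the simulated 3.5% background.

The `analysis/` directory holds the staged workflow (design → simulate →
classify → qPCR validation → summary); run the numbered scripts in order
from the repository root. Stage outputs land under `results/`.

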