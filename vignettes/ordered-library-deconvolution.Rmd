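---
title: "Designing and decoding ordered transposon libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and decoding ordered transposon libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnsudoku)
```

## The problem

An ordered transposon library is an arrayed collection of clonal insertion
mutants in which the identity (genomic insertion site) of the mutant in
every well is known. Building one the naive way means sequencing tens of
thousands of colonies individually. Combinatorial pooling — the
Knockout-Sudoku family of designs — instead arrays mutants in 96-well
plates arranged in a higher-order grid and sequences a small number of
*pools*: all wells of each well column, each well row, each plate column
and each plate row. A mutant's reads then appear in exactly four pools,
one per axis, and those four coordinates identify its well.

`tnsudoku` implements the full desk-side machinery around such a build:

1. the pooling geometry (`pooling_design()`),
2. Monte Carlo saturation planning (`simulate_coverage()`,
   `mutants_for_target()`),
3. a forward simulator of the whole experiment (`generate_reference()`,
   `simulate_picking()`, `simulate_pool_counts()`),
4. deconvolution of pooled read counts into well addresses
   (`deconvolve()`),
5. assembly of the redundant and consolidated collections with coverage
   and accuracy statistics (`build_collection()`, `coverage_report()`,
   `expected_accuracy()`), and
6. crystal-violet biofilm screen analysis (`call_fold_hits()`,
   `ttest_vs_control()`).

## Pooling geometry

A design with a `g_r x g_c` plate grid and `p_r x p_c` wells per plate has
`p_c + p_r + g_c + g_r` pools and `g_r * g_c * p_r * p_c` wells. The
geometry this package was built around — a 19 x 19 grid of 96-well plates —
yields 58 pools and 34,656 wells:

```{r}
d <- pooling_design(19, 19, 8, 12)
d
pools_for_well(d, well_address(d, 3, 7, "B", 11))
```

The four-coordinate code is injective: two distinct wells differ in at
least one axis, so the intersection of a mutant's four pools is a single
well. (Descriptions of this pooling scheme sometimes quote a smaller
total pool count; the axis sizes above are what the arithmetic of the
four-axis code requires, and the constructor accepts arbitrary dimensions,
including partial grids via an occupied-plate list, so other geometries
can be expressed directly.)

## How many colonies to pick: Monte Carlo saturation

Transposon insertion is approximately uniform along the genome, so the
chance that a gene of length $L$ escapes all of $n$ independent insertions
in a genome of length $G$ is $(1 - L/G)^n$, and the expected fraction of
ORFs covered is

$$ C(n) \;=\; \frac{1}{|\mathcal G|} \sum_{g \in \mathcal G}
   \left[ 1 - \left(1 - \frac{L_g}{G}\right)^{n} \right]. $$

A Poisson estimate with a single average gene length would overestimate
coverage of short genes and underestimate long ones; working per gene
keeps both right. `expected_coverage_analytic()` evaluates the closed
form; `simulate_coverage()` draws actual insertion positions (uniform per
bp by default, or uniform over TA dinucleotides for a mariner-family
transposon such as miniHimar1, which targets TA sites — both models are
offered because published pick-count calculations do not always state
which was used) and must agree with the closed form within Monte Carlo
error; `mutants_for_target()` inverts the curve by doubling plus
bisection:

```{r}
ref <- generate_reference(50, seed = 1)
mutants_for_target(ref$genes, ref$genome_length, target = 0.99)
```

The library this package models picked 34,656 colonies — exactly the
capacity of its 361-plate array — after such a calculation indicated that
count would cover 99% of ORFs.

## The synthetic experiment

Because no public dataset is needed to exercise the pipeline, the package
ships a forward simulator whose defaults are the study conditions it
models:

* **Reference** (`generate_reference()`): non-overlapping
  gamma-distributed genes (mean 900 bp, sd 500 bp — typical bacterial
  values), 12% intergenic sequence, essentiality classes apportioned
  exactly (largest-remainder) to 83% / 4% / 13%
  non-essential / high-fitness / essential, the approximate class shares
  of an alpha-proteobacterial genome.
* **Picking** (`simulate_picking()`): wells fill in plate order; default
  `duplicate_rate = 0.36` reproduces the observed ratio of unique
  insertions to picked colonies (22,219 / 34,656) in the library this
  package models. Essential genes take insertions only in their terminal
  10% under the default `"ends-only"` policy, where a truncated product
  can retain function — the pattern real libraries show; `"exclude"` and
  `"allow"` are available.
* **Counts** (`simulate_pool_counts()`): member pools draw
  negative-binomial reads (`depth = 500`, `dispersion = 5`; pooled
  sequencing is overdispersed), per-pool depth varies lognormally
  (`depth_sdlog = 0.25`), memberships drop out with probability
  `dropout = 0.01`, and non-member cells are contaminated with
  probability `epsilon = 0.005` at Poisson mean `lambda = 3`. No
  quantitative noise characterisation of the real pools is published
  beyond the observation that their signal-to-noise ratio defeated an
  off-the-shelf Bayesian decoder, so these defaults are our own choices,
  exposed as parameters.

Two numerical choices deserve a note:

* *Noise-free semantics.* `noise_free()` means Poisson member counts with
  no contamination, dropout or depth variation. Under the default
  negative-binomial dispersion of 5 a member pool would fall below the
  50-read primary threshold about 0.02% of the time — that is count
  noise, so it is not part of the noise-free configuration.
* *Common random numbers.* Contamination draws come from a dedicated RNG
  stream and are made for every cell regardless of `epsilon`; a cell is
  contaminated when its uniform draw falls below `epsilon`. Hence for a
  fixed seed the contaminated cells at a smaller `epsilon` are a subset
  of those at a larger one, with identical counts on the shared cells —
  noise ladders are monotone by construction and degradation studies are
  not confounded by resampling.

What the simulator does **not** emulate: PCR chimeras, barcode hopping
between pools, Illumina error profiles, positional biases of transposase
or of colony picking. Passing the round-trip tests therefore shows the
decoder is correct *given this noise family*, not that the thresholds are
optimal for any particular sequencing run — which is why they are
parameters.

## Deconvolution: thresholds, SNR, triangulation

For each insertion site, the counts of each axis are reduced to the top
coordinate, its count, and the next-highest count. An axis is **resolved**
when

* top count >= `primary_threshold` (default 50 reads), and
* SNR = top / second >= `snr_threshold` (default 9; SNR is `Inf` when the
  second count is 0 and the top is positive, 0 when the top is 0, and an
  exact tie gives SNR 1, never resolved).

The defaults are the operating point of the library this package models.
A site with all four axes resolved is assigned automatically (`auto`).
Sites where at least two axes carry two or more coordinates above the
primary threshold are flagged `multilocated` — the signature of a clone
picked into several wells — and excluded from well assignment, since only
unique placements enter an ordered library. Two `auto` sites claiming one
well are both demoted to `ambiguous` rather than erroring: real pools
contain artifacts.

Remaining sites keep per-axis **candidate sets**: every coordinate with
count at least `max(candidate_floor, top / snr_threshold)`. The floor
(default 10) discards trace counts; the `top / snr_threshold` term keeps
any coordinate that could plausibly be the winner's equal. This rule is
our own formalisation of what was manual judgment in the original
GUI-driven analysis, and both knobs are exposed.

**Triangulation** then exploits the fact that confidently placed mutants
occupy wells: a pending site's candidate wells are the Cartesian product
of its axis candidate sets minus occupied wells (and minus absent plates
in partial grids); when exactly one well survives, the site is placed and
its well eliminated for everyone else, iterating to a fixpoint
(`max_rounds` caps the iteration; hitting the cap warns). Sites are
processed in descending total-read order with ties broken by site id, so
the procedure is fully deterministic. Sites still holding two or more
candidate wells end `ambiguous`; the rest stay `unresolved`.

`brute_force_oracle()` re-derives the same result for small designs by
enumerating every well and re-scanning the full well list at each
elimination step — an independent implementation used by the property
tests, which require exact agreement across randomly generated noisy
instances.

```{r}
d2 <- pooling_design(2, 2, 4, 6)
ref2 <- generate_reference(30, seed = 4)
pl <- simulate_picking(ref2, d2, 60, duplicate_rate = 0.2, seed = 5)
pcm <- simulate_pool_counts(pl, d2, noise_model(), seed = 6)
res <- deconvolve(pcm, d2)
res
assignment_accuracy(res, pl)$pct_correct
```

## Library assembly and its statistics

`locate_in_gene()` maps a placed insertion to its gene and computes the
**gene fraction**: distance from the translational start over gene length,
`(pos - start) / len` on `+` genes and `(end - pos) / len` on `-` genes,
so 0 is the start codon on either strand and values lie in `[0, 1)`. The
denominator is the full gene length in bp with 1-based inclusive
coordinates; published figures rarely state this convention, so it is
fixed and documented here, and the reflection identity
`f(+, pos) = f(-, start + end - pos)` is property-tested.

`build_collection()` keeps up to three distinct insertions per gene
(ascending gene fraction — most upstream first, the entries most likely
to disrupt the product), ranks them, and flags the rank-1 entry as the
**consolidated** representative; intergenic placements are kept as
controls. `coverage_report()` stratifies ORF coverage by essentiality
class with percentages rounded half-up to one decimal — the convention
that reproduces every self-consistent cell of the published coverage
tables. `fraction_histogram()` bins genic hits in 20 bins of 0.05.

The redundancy-accuracy model: if a single mutant's annotation is correct
with probability $p$ (estimated at $40/53 \approx 75\%$ from independent
re-sequencing of 53 random clones), a gene represented $k$ times is
correct at least once with probability $a_k = 1 - (1-p)^k$, i.e. 94% for
duplicates and 99% for triplicates. `expected_accuracy()` weights the
$a_k$ by the collection's redundancy shares; with shares 21% / 25% / 54%
and $a_k$ rounded to two decimals (the reporting convention that
reproduces the published headline) the expectation is 93%.

## Crystal-violet screen statistics

Biofilm signal is crystal violet absorbance normalised by growth,
OD540/OD660; wells without measurable growth are masked. A mutant is
called when its replicate-averaged value differs from the plate mean by
at least 1.5-fold in either direction. Two conventions were genuinely
open and are flags: the plate mean excludes designated control wells by
default (`exclude_controls`), and calls are made on replicate-averaged
values rather than per-replicate (we average; per-replicate calling would
multiply the false-positive rate at this fold threshold). Significance
uses the classic pooled-variance unpaired t-test (`welch = TRUE` for the
unequal-variance form); no multiple-testing correction is applied by
default, matching screening practice at this scale, with
Benjamini–Hochberg available via `screen_hits(adjust = "BH")`.

## Problem sizes used in the checks

The package's own verification uses sizes a desk machine handles in
seconds while preserving the regime of interest: saturation checks use a
50-gene annotation embedded in a sparse genome so that coverage at
n = 1000 sits well away from 0 and 1, where the Monte Carlo/closed-form
comparison is informative; deconvolution completeness uses a full
5 x 5-grid library (2,400 wells); oracle-equivalence property tests run
100 seeded noisy instances on 3 x 3-grid designs (432 wells); the noise
ladder uses a 4 x 4 grid at contamination rates 0–5%. The 19 x 19
geometry itself is exercised for its arithmetic (capacity, pool count,
injectivity), which does not depend on simulation scale.

## Known limitations

* Exact-match read location only: the toy mapper is for synthetic
  round-trips; real junction reads should be aligned externally and
  supplied as a counts TSV (`read_pool_counts()` validates them against a
  design).
* The triangulation candidate rule is a deterministic stand-in for what
  was interactive curation in the original analysis; on very noisy axes
  it can leave sites `ambiguous` that a human (or a Bayesian decoder)
  might place.
* The accuracy model treats per-mutant correctness as exchangeable with a
  single $p$; adjacency effects ("right neighbourhood, wrong gene") enter
  only through how $p$ was estimated.
* Essentiality classes are taken from the annotation as given; the
  package does not infer essentiality from insertion density.
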