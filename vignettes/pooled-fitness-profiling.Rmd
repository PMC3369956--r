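---
title: "Methods: differential strain sensitivity analysis of pooled fitness screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential strain sensitivity analysis of pooled fitness screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dssa)
```

This vignette is the package's account of its statistical machinery: the
models behind each stage, the parameters that matter and their defaults,
what the synthetic data does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## The experimental design being modeled

A pooled deletion collection (~4,600 viable haploid-convertible diploid
deletion strains, each carrying a unique barcode) is inoculated into a
stress medium (here: zinc-limiting, the *treatment*) and a replete medium
(the *control*), four independent replicate cultures per condition. Pools
grow competitively for 5 or 15 *pool generations* — one generation is one
doubling of total culture biomass, tracked by OD. The 15-generation design
is two serial batches: inoculate at OD 0.005, grow to 1.2 (eight
generations), dilute to OD 0.01, grow to 1.2 again (seven generations); the
dilution is a population bottleneck. Genomic DNA from the endpoint pools is
PCR-amplified at the barcodes and hybridized to tag arrays, one array per
culture, so each strain's log2 signal tracks its endpoint abundance.

## Growth and signal model

`simulate_pool_growth()` treats each strain as doubling at its own relative
rate $w_i$ (wild type $w = 1$, dimensionless doublings per pool
generation): $a_i(g) = a_i(0)\,2^{g w_i}$. A zero-rate strain therefore
keeps constant expected abundance, and the total doubles per generation to
a very good approximation because a genome-scale pool is dominated by
neutral strains. Two modes are provided: `"expected"` propagates expected
counts (deterministic, so closed-form oracles apply exactly), and
`"sampled"` draws a multinomial of the stated size at the bottleneck — the
only sampling step whose depth is actually limited in the design (the
default bottleneck, $1.5\times 10^7$ cells at generation 8, is the OD-0.01
reinoculum of a 100 ml culture). Endpoint DNA sampling and PCR are deep
enough to be folded into chip noise rather than modeled separately.

`abundance_to_signals()` maps endpoint abundance to array signal as

$$\mathrm{signal} = \log_2(a + 1) + \alpha_i + \varepsilon,$$

with a per-strain probe affinity $\alpha_i \sim N(0, \sigma_a^2)$ drawn
once and shared by all arrays (tag probes are fixed), and i.i.d. chip noise
$\varepsilon \sim N(0, \sigma_e^2)$. The affinity cancels exactly in any
within-strain treatment−control ratio, which is what makes pair-based
inference workable without between-chip normalization. The pseudocount of 1
cell-equivalent keeps extinct strains finite. Defaults:
$\sigma_a = 1$ log2 unit (it cancels, so its value is inert downstream) and
$\sigma_e = 0.25$ log2 units — no published chip-noise magnitude was
available, so this is a simulation choice, picked once as a typical
replicate spread for two-channel-era array data and exposed as a parameter.
At $\sigma_e = 0.25$ a per-pair ratio has SD $0.25\sqrt2 \approx 0.35$,
against which a 15-generation, 0.3-deficit depletion signal of
$15 \times 0.3 = 4.5$ log2 units is a ~13-sigma outlier; the tests confirm
the resulting operating characteristics rather than assuming them.

`make_truth()` plants `round(n · frac)` sensitive and resistant strains
with per-strain effect magnitudes $\sim N(e, (e/5)^2)$ truncated below at
$e/10$: the screen's biology has a distribution of effect sizes, not one
value, but every affected strain must keep its class label for recovery
scoring to be meaningful.

## DSSA

Stage by stage, for a matrix with $n_t$ treatment and $n_c$ control arrays:

1. **Pairs.** Default `"all_cross"`: every treatment array against every
   control array, $n_t n_c$ *effective pairs* (16 for 4+4). The
   alternative `"matched"` (by replicate index) is provided, but with only
   4 pairs the minimum binomial p-value is $1/2^4 = 0.0625$, which can
   never pass a 0.05 q cutoff — the thresholds are only jointly satisfiable
   with the cross product, which is why it is the default.
2. **Outliers.** Within each pair, $z = (r - \mathrm{median}\,r) /
   (1.4826\,\mathrm{MAD}\,r)$, two-sided normal p, BH within the pair. The
   robust location/scale makes the test invariant to chip-wide shifts, and
   a degenerate MAD of 0 returns p = 1 everywhere rather than dividing by
   zero. The original screens delegated this stage to a prior outlier
   method whose algorithm is not restated in the source; the robust-z
   stand-in is a declared design choice with the same interface
   (a q ≤ 0.05 outlier call per pair), not an inference of that method.
3. **Consistency.** A pair is a success iff outlier q ≤ 0.05 *and* the
   ratio sign equals the sign of the strain's fitness score; zero ratios
   and zero fitness never match. Successes are treated as Bernoulli(0.5)
   trials and $k$ of $n$ gets the exact upper-tail binomial probability.
   One-sided, because successes are defined as evidence for the
   consensus direction.
4. **Genome-wide correction.** BH step-up over all strains (`"storey"`
   rescaling by $\hat\pi_0$ is available behind a flag, off by default for
   determinism). Calls at q ≤ 0.05 by fitness-score sign.

The suite checks the exact distributional identities (binomial vs full
$2^n$ enumeration), the structural invariants (antisymmetry under condition
relabeling, chip-shift invariance, q ≥ p, rank monotonicity), and the
operating characteristics under the study conditions: on fully neutral
4607-strain pools the mean called fraction at q ≤ 0.05 is ~0 (the
consistency test needs 13 of 16 same-sign successes before correction even
begins, which chance essentially never produces), and with 5% planted
sensitive strains at deficit 0.3 over 15 generations, recall is ≥ 0.999
and empirical FDR 0 over 25 seeds. Those numbers say the pipeline is
well-calibrated *under this noise model*; real screens add probe
cross-hybridization, PCR bias, strain mislabeling and culture-condition
drift that the simulation deliberately leaves out, so real-data FDR
should be expected to be higher.

## Enrichment

FunSpec-style over-representation: flat category lists (GMT), an explicit
universe, hypergeometric upper tail $P(X \ge k)$, Bonferroni. The universe
is a required input because published FunSpec-era analyses used an internal
universe of unstated size, making their exact p-values unrecoverable; the
honest reproducible choice is to force the caller to say what the universe
is (the analysis drivers use all strains in the screen). The Bonferroni
factor defaults to the number of categories with at least one hit, the
common FunSpec reading; `m_all_categories = TRUE` switches to all
categories. No GO-DAG propagation: propagation would change every category
size $f$ and silently decouple the output from the annotation file.

## Active modules

Per-gene $z = \Phi^{-1}(1-p)$ from the DSSA binomial p-values. Two choices
here were genuinely open:

- **Clipping.** p is clipped to $[10^{-15}, 1-10^{-15}]$ before inversion
  so z stays finite; an unclipped p = 1 would give $z = -\infty$ and any
  module containing that gene would score $-\infty$.
- **Direction.** The search targets the sensitive direction, so strains
  with non-negative fitness get z = 0 — the same neutral-linker convention
  as genes absent from the screen — rather than a large negative z from a
  p-value near 1, which would make resistant genes actively repel modules
  and distort linker traversal.

Subsets score $z_A = \sum z_i/\sqrt k$ ($z_A$ of i.i.d. standard normals
is standard normal for every $k$, so sizes are comparable under an ideal
null). Because a screen's z pool is not standard normal, scores are
calibrated against Monte-Carlo random $k$-subsets of the actual pool:
$(z_A - \mu_k)/\sigma_k$, with $z_A - \mu_k$ used when $\sigma_k = 0$
(e.g. an all-zero pool). The search itself is a greedy hill-climb from the
top-z seed nodes, bounded to `max_depth` hops (default 2) around the seed,
capped at 50 nodes: simulated annealing buys little at these scales and
costs reproducibility. One structural subtlety: candidates are any nodes
within the depth bound, added *together with a shortest connecting path*,
because single-node growth can never cross a zero-z linker (for a path
A(z=3)–B(0)–C(3), {A,B} scores $3/\sqrt2 < 3$ but {A,B,C} scores
$6/\sqrt3 > 3$). Exhaustive enumeration on 12-node networks shows the
greedy top module reaching the 100th percentile of connected-subset scores
in the tested cases, and planted 10-node modules in 500-node random
networks are recovered at ~95% node overlap; the property guaranteed by
construction — and checked — is that every module induces a connected
subgraph. Greedy search is not optimal in general; the percentile-based
test states exactly what is claimed.

## Confirmation assays

- **Gating** splits events on the GFP channel. `"auto"` puts the boundary
  at the valley of a kernel-density estimate between the two dominant
  modes (modes below 5% of the peak height are ignored as ripple) and
  refuses unimodal data; an explicit threshold always wins, which is the
  right tool for very unbalanced mixtures — at 1% mutant prevalence the
  minor mode is undetectable, which is precisely why bench analyses mark
  the boundary manually.
- **Competition ratios** are reported at the precision competition tables
  use: two decimals below a raw ratio of 0.095, one decimal above
  (0.095 is the natural two-decimal/one-decimal rounding boundary
  consistent with published rows such as 0.08 and 0.1); the unrounded
  value is kept as an attribute.
- **Prevalence tests** are pooled-variance Student's t (df $= n_1+n_2-2$),
  per the stated methods of such assays; Welch is behind a flag. Published
  per-row p-values are not always recomputable from printed means and SDs
  at n = 3, so p-values are validated against the t distribution, not
  against table rows.
- **Growth AUC** is the trapezoidal integral of background-corrected OD
  over time; the default blank is the first-timepoint minimum. AUC is
  exactly additive over contiguous segments, which the tests exploit.
- **Culture arithmetic**: doublings $=\log_2(\mathrm{OD_f/OD_i})$ with
  half-away-from-zero integer rounding (0.005 → 1.2 gives 7.91 → 8), and
  per-genotype inoculum $= V \cdot \rho / n$ at two significant figures
  (100 ml at $6\times10^5$ /ml over 4607 strains → 13,000).

## Problem sizes and determinism

The test and acceptance workloads run the genome-scale scenario (4607
strains, 4+4 arrays) with 25 simulation seeds for the DSSA calibration and
recovery experiments, 20 seeds of 500-node networks for module recovery,
and full enumeration oracles at $n \le 16$ (binomial) and $N \le 12$
(hypergeometric) — sizes chosen so every claim is either exact or averaged
over enough replicates to be stable, while a complete run stays in the
low minutes on a single core. All generators are bit-reproducible for a
fixed seed; pipeline stages derive their seeds deterministically from one
top-level seed, and the run manifest omits timestamps so identical runs
are byte-identical.

## Known limitations

- The simulation has no sequence-level barcode/PCR model, no probe-level
  or spatial chip artifacts, and no cross-hybridization; chip noise is
  i.i.d. normal. Calibration results transfer to real arrays only insofar
  as that approximation holds.
- The robust-z outlier stage is a documented stand-in for the original
  screens' outlier method, and whether those screens used matched or
  cross-product pairs is not stated; both schemes are implemented.
- Headline counts from the original zinc screen (hundreds of sensitive
  strains, the 283-gene sub-network) depend on the real arrays and
  era-specific annotation/interaction databases and are out of scope;
  the package validates against worked arithmetic and simulations with
  ground truth instead.
- The greedy module search is deterministic given a calibration table but
  is a heuristic; on large networks it can miss distant high-z pockets
  reachable only outside the depth bound.
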