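---
title: "Windowed multi-trait GWAS colocation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed multi-trait GWAS colocation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salicoloc)
```

# The problem

Reproductive-stage salinity tolerance in rice is polygenic: many loci of
small effect act on yield and its components, and single-trait GWAS on a
diversity panel rarely clears a genome-wide threshold for such traits.
The approach implemented here gains power by *colocation*: a locus that
shows a (sub-threshold) association peak for relative grain yield **and**
for several physiological or agronomic traits in the same genomic window
is far less likely to be a chance artefact than any single peak.  The
package provides the whole chain needed to study and apply that idea:

1. a synthetic diversity-panel generator (block-LD genotypes, planted
   treatment-specific QTLs, replicated two-treatment phenotypes),
2. relative-trait derivation and small reusable statistics,
3. a marginal association scan with PC covariates,
4. the windowed colocation enrichment test, and
5. haplotype-group favourability ranking within colocating loci.

# Relative traits

For a trait measured under control and saline treatments with
replicates, each line's relative value is

$$\mathrm{rel}_i \;=\; 100 \times
  \frac{\overline{y}_{i,\mathrm{saline}}}{\overline{y}_{i,\mathrm{control}}}$$

with means over non-missing replicates.  Lines with a missing treatment
mean or a control mean $\le 0$ are excluded and counted.  We take the
ratio of replicate means rather than the mean of per-replicate ratios:
it is robust to unbalanced missing replicates, and per-replicate pairing
is not meaningful in a split-plot layout where replicates of different
treatments sit in different main plots.  Values above 100 are not
capped; a line may genuinely out-yield its control under stress.

# The association scan

Each SNP is tested by ordinary least squares of the (relative) trait on
the alt-allele dosage plus an intercept and $K$ principal-component
covariates; the reported p-value is the two-sided t-test on the dosage
coefficient.  A mixed model with a kinship matrix is the field's
standard for real panels; we use OLS + PCs deliberately.  The package's
purpose is the downstream colocation statistic, which consumes p-values
from *any* scan, and the simulator draws line effects i.i.d., so there
is no kinship structure to absorb beyond what the PCs capture (the
two-subpopulation simulator mode is exactly the structure PCs handle).
Users scanning real data can substitute their favourite mixed-model
scan and feed its summary statistics straight into `coloc_scan()`.

Practical details:

* **MAF filter** — SNPs with minor allele frequency strictly greater
  than 0.05 are kept (`maf_filter()`).
* **LD pruning** — a greedy forward pass per chromosome drops a SNP iff
  its dosage $r^2$ with any kept SNP within 2 kb upstream exceeds 0.85
  (`ld_prune()`).  We always drop the *later* SNP of an offending pair
  rather than the lower-MAF one: the result is deterministic and
  order-independent given sorted input, which matters for reproducible
  window occupancy.
* **Missing data** — trait-missing lines are dropped per scan; missing
  dosages are handled per SNP on complete cases (pairwise-complete with
  a mean-imputation fallback for pruning and Meff when a pair shares
  fewer than 3 lines).  SNPs monomorphic after dropping missing lines
  get $p = 1$ instead of being removed, so window occupancy — the
  denominator of the colocation test — does not depend on the trait.
* **Genome-wide threshold** — Bonferroni correction uses an effective
  number of independent tests rather than the raw SNP count:
  per chromosome, the eigenvalues $\lambda$ of the SNP correlation
  matrix are mapped through
  $f(\lambda) = \mathbf{1}\{\lambda \ge 1\} + (\lambda - \lfloor
  \lambda \rfloor)$ and summed (`meff_threshold()`), the eigenvalue
  method of Li & Ji (2005).  The literature contains several Meff
  recipes; this one is a standard choice and is labelled as such.  For
  large chromosomes the spectrum is computed in adjacent position
  blocks and summed, which bounds memory and slightly over-counts
  across block edges (conservative: Meff, and hence the threshold,
  can only grow).
* **K selection** — `n_pcs = "bic"` picks $K \in 0..K_{max}$ minimizing
  $n\ln(RSS/n) + (K+1)\ln n$ for the trait-on-PCs regression.

# The colocation statistic

Each chromosome is tiled into fixed windows of width $W$ from position
1 (window $k$ covers $[(k-1)W + 1,\, kW]$); a fixed grid, not
SNP-anchored sliding windows, so loci have stable round boundaries.
For one experiment, `Nwind` is the number of windows containing at
least one tested SNP — *occupied* windows, not genome length over $W$.
A window is *significant* for a trait when its best SNP reaches
$-\log_{10} p \ge T$, and the trait's empirical peak probability is

$$p_\mathrm{trait} = \frac{\#\ \text{significant windows}}{N_\mathrm{wind}}.$$

For a trait pair, under independence the number of jointly significant
windows is modelled as Binomial($N_\mathrm{wind}$, $p_\mathrm{coloc}$)
with $p_\mathrm{coloc} = p_\mathrm{anchor} \cdot p_\mathrm{other}$:

$$\mathrm{expNcoloc} = N_\mathrm{wind}\, p_\mathrm{coloc}, \qquad
  \sigma = \sqrt{N_\mathrm{wind}\, p_\mathrm{coloc}
  (1 - p_\mathrm{coloc})}, \qquad
  z = \frac{\mathrm{obsNcoloc} - \mathrm{expNcoloc}}{\sigma},$$

and the P-value is the one-sided upper-tail standard-normal probability
of $z$ — one-sided because only an *excess* of colocations is evidence
of shared genetics.  A pair is significant at $P < 0.05$.  When the
expected count is given directly (as when reproducing published
tables), the rare-peak limit $\sigma = \sqrt{\mathrm{expNcoloc}}$ — the
binomial's Poisson limit for vanishing $p_\mathrm{coloc}$ — is used.
Degenerate rule: $p_\mathrm{coloc} = 0$ gives $P = 1$ for zero observed
colocations and $P = 0$ otherwise, with a flag.

Pair tests are computed **within** an experiment (panels differ in SNP
sets and power); the multi-trait locus summary then **pools**
experiments by window: for every window where the anchor trait is
significant in at least one experiment, it counts the distinct
non-anchor trait names significant there, and windows reaching
`min_traits` (default 7) qualify as multi-trait loci.  The same trait
appearing in two experiments counts once; `min_traits` is the switch to
change the stringency.

`sweep_configs()` scans thresholds $T \in \{3, 3.5, 4\}$ and window
sizes $W \in \{1, 2, 5, 20, 100\}$ kb and selects the cell identifying
the most significantly colocated pairs, ties toward larger $W$ then
lower $T$ (larger windows tolerate LD displacement of peaks; lower
thresholds keep power).

## Numerical behaviour of the z approximation

The normal tail is a good approximation when
$\mathrm{expNcoloc}$ is a few counts or more; for expected counts well
below 1 the statistic is driven by the discreteness of small counts
(any observed colocation is then highly significant).  The package
reports the statistic as defined rather than switching to an exact
binomial tail, because the published worked examples are all in the
regime where the two agree to within a few percent.

# The synthetic panel

`simulate_genotypes()` uses a founder-mosaic model: SNP positions are a
homogeneous Poisson process; each SNP gets a design alt frequency drawn
uniformly from `maf_range`; `n_founders` founder haplotypes carry
Bernoulli alleles at those frequencies; each inbred line follows one
founder at a time, switching with probability $1 - e^{-d/L}$ between
SNPs $d$ bp apart ($L$ = `ld_block_scale`); the haplotype is doubled to
a dosage in $\{0, 2\}$, with optional heterozygosity.  A founder mosaic
was chosen over a coalescent simulation because the analysis needs
controllable block LD (to exercise 2-kb pruning and 100-kb windows),
not demographic realism.

Phenotypes follow
$$y_{itjk} = \mu_{tj} + \textstyle\sum_q a_{qtj} x_{iq} + g_{it}
  + \varepsilon_{itjk},$$
with treatment means $\mu_{tj}$, additive QTL effects $a_{qtj}$ (per
trait $t$ and treatment $j$ — a saline-only QTL has $a_{q,t,\mathrm{
control}} = 0$), line effects $g_{it} \sim N(0, \sigma^2_g)$ shared
across treatments and replicates, and residuals
$\varepsilon \sim N(0, \sigma^2_e)$.  Relative traits are *not*
simulated directly; they are derived downstream exactly as for real
data.  Listing a QTL for two traits plants a true colocation.

Defaults describe the study conditions the pipeline is designed around:
300 lines, five 2-Mb chromosomes at 2 SNPs/kb (about 20k SNPs — a
diversity panel scaled down ~40-fold in genome length at the real SNP
density), three replicates per treatment, $\sigma^2_g = \sigma^2_e = 1$
on a control mean of 10 (line-mean heritability of a null trait ~0.75,
typical for yield components in replicated trials).  `n_founders = 8`
and `ld_block_scale = 50` kb were calibrated once so that the all-null
per-trait empirical peak probability at $(T = 3, W = 100\ \mathrm{kb})$
falls at ~0.1, the scale real panels show for these settings (published
expected colocation counts divided by their window counts give
$p_\mathrm{trait} \approx 0.015$–$0.09$).  Two caveats the simulator
does not model: the finite founder pool broadens the realized MAF
spectrum beyond `maf_range` (some sites drift to fixation among eight
founders), and i.i.d. line effects mean no kinship beyond the optional
two-subpopulation mode.  Passing tests therefore demonstrate the
statistical machinery on panels with realistic LD scale and peak
probabilities, not performance under strong cryptic relatedness,
genotyping error, or real rice demography.

# Haplotype favourability

Within a qualifying locus (one grid window, typically 100 kb), the
sub-window with the best phenotypic distinction is sought among 20-,
40- and 60-kb sub-windows at 20-kb steps (`choose_subwindow()`).  In
each sub-window:

* `extract_window_haplotypes()` collapses each line's dosages over the
  region's SNPs into a string (missing imputed to the SNP's major
  dosage, heterozygous kept as 1; boundaries inclusive);
* `group_haplotypes()` groups identical strings, and when distinct
  strings exceed `max_groups` (default 15, the variety-group setting),
  merges them by average-linkage (UPGMA) clustering on the normalized
  Hamming distance (a dosage mismatch contributes $|d_1 - d_2|/2$ per
  SNP).  The reference tool's grouping algorithm is undocumented, so
  this transparent, deterministic surrogate is used: clustering is over
  distinct strings (unweighted by line counts), and at equal merge
  distance the pair with the lexicographically smallest representative
  strings merges first, making the partition independent of input
  order.  Group labels are 1..G by descending size.
* `summarize_groups()` computes group means of the anchor trait,
  scores distinction by one-way ANOVA over groups with $n \ge$ `min_n`
  (default 3 — singleton haplotypes cannot be called favourable), and
  calls the group with the highest mean favourable (ties to the larger
  group).  "Best phenotypic distinction" is operationalized as the
  largest ANOVA F; the original criterion is qualitative.

Sub-window ties break toward the smaller window, then leftmost.  When
the same locus is analysed in several panels, favourability is reported
per panel; agreement between panels is the user's consistency check.

# Small statistics

`correlation_matrix()` returns pairwise-complete Pearson $r$ with
two-sided p-values from the t transform on $n - 2$ degrees of freedom
and the usual 0.05/0.01/0.001 star codes.  Pearson (not Spearman) and
pairwise-complete deletion match the conventions of the correlation
displays this feeds; the choice is configurable only by pre-ranking
the inputs.  `anova_lsd()` is one-way ANOVA plus Fisher's LSD at
$\alpha = 0.05$ from the pooled error mean square, with a compact
letter display; degenerate zero-variance layouts return $F = 0$ rather
than 0/0 noise.

# Determinism, seeds and problem sizes

Every stochastic stage is a pure function of its configuration's seed:
`simulate_genotypes()` seeds the genotype stream and
`simulate_phenotypes()` a stream offset by one, so genotype draws are
unchanged when QTLs are added to the phenotype model.  The bundled demo
configuration runs the full pipeline (120 lines, two 2-Mb chromosomes,
~4k SNPs) in well under a minute and is byte-identical across reruns.
The package's own test studies use the default study-scale panel (300
lines, ~20k SNPs) for calibration and power, 50 seeds for power, 20 for
haplotype recovery, and 100 random instances for the pruning oracle —
sizes chosen so the whole suite completes in a few minutes on one CPU
while keeping Monte-Carlo error well inside the asserted bands.

# Known limitations

* OLS + PCs is not a substitute for a kinship mixed model on real,
  strongly structured panels; use external summary statistics there.
* The binomial null treats windows as exchangeable; heterogeneous SNP
  density or LD across windows makes the test anti-conservative (shared
  peak-prone windows inflate colocation counts for all traits).  The
  simulator's homogeneous density keeps this mild; on real data the
  threshold/window sweep is the practical guard.
* The Meff block approximation ignores inter-block LD (conservative).
* UPGMA haplotype grouping is a surrogate for the reference tool's
  undocumented algorithm; group *identities* will differ even where
  the favourable-group call agrees.
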