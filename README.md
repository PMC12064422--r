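# salicoloc

Multi-trait GWAS colocation analysis for reproductive-stage salinity
tolerance in inbred diversity panels (rice-style), as one reproducible
R pipeline: synthetic panel simulation → relative traits → association
scan → windowed colocation enrichment → haplotype favourability.

## Who this is for

Quantitative geneticists and breeders working with diversity-panel
GWAS on stress-tolerance traits, where single-trait signals are weak
and the question is whether association peaks for a tolerance index
(relative grain yield) *co-occur* with peaks for physiological and
agronomic traits more often than chance allows — and, at loci where
they do, which haplotype group carries the favourable alleles.

## The statistic at the core

Tile each chromosome into fixed windows of width *W* (window *k*
covers [(k−1)W+1, kW]).  For one experiment, let N<sub>wind</sub> be
the number of windows containing a tested SNP.  A window is
significant for a trait when its best SNP reaches −log₁₀ p ≥ T, giving
an empirical peak probability p<sub>trait</sub> = #significant /
N<sub>wind</sub>.  For a trait pair, the observed number of jointly
significant windows obsNcoloc is referred to a binomial null with
p<sub>coloc</sub> = p<sub>anchor</sub> · p<sub>other</sub>:

    expNcoloc = Nwind * p_coloc
    sigma     = sqrt(Nwind * p_coloc * (1 - p_coloc))
    z         = (obsNcoloc - expNcoloc) / sigma

with a one-sided upper-tail normal P-value; pairs with P < 0.05 are
significantly colocated.  Windows where the anchor trait colocates
with many distinct traits (default ≥ 7) are the multi-trait loci fed
into haplotype-group favourability ranking.  Details, assumptions and
numerical behaviour are in `vignettes/colocation-methods.Rmd`.

## Worked example

The bundled demo configuration simulates 120 lines on two 2-Mb
chromosomes (~4k SNPs) with two planted saline-only QTLs — one shared
by grain yield, filled grains and panicle length (a true colocation),
one by grain yield and shoot biomass — then runs the whole pipeline:

```r
library(salicoloc)
cfg <- system.file("extdata", "demo_config.yaml", package = "salicoloc")
man <- run_pipeline(cfg, "demo_out")
read.table("demo_out/coloc_pairs.tsv", header = TRUE, sep = "\t")
```

```
  experiment          trait obs expected     sigma         z          p significant
1       sim1  filled_grains   3     1.05 1.0111565 1.9284848 0.02689742        TRUE
2       sim1 panicle_length   3     0.90 0.9379499 2.2389256 0.01258038        TRUE
3       sim1  shoot_biomass   1     0.60 0.7687652 0.5203149 0.30142206       FALSE
```

The two traits sharing the planted chr1 QTL colocate with relative
grain yield about three times more often than the ~1 window expected
by chance (one-sided P ≈ 0.027 and 0.013); the weaker chr2 QTL does
not clear the cut in this small panel.  `coloc_loci.tsv` shows the
windows driving the signal — the 100-kb windows flanking the planted
QTL at chr1:1,000,000:

```
   window chrom   start     end n_traits                       traits qualifies
1 chr1:10  chr1  900001 1000000        2 filled_grains,panicle_length      TRUE
2 chr1:11  chr1 1000001 1100000        2 filled_grains,panicle_length      TRUE
...
```

and the `hap_*.tsv` outputs rank haplotype groups in the best 20/40/60-kb
sub-window of the top locus by mean relative grain yield.  Reruns with
the same config are byte-identical; `force = TRUE` recomputes.

A thin CLI over the same functions lives at `inst/cli/salicoloc.R`
(subcommands `run`, `simulate`, `gwas`, `coloc`, `haplo`).

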