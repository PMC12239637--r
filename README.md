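# pollenTau

Comparative tissue-specificity analysis of pollen, style, and leaf gene
expression in two *Solanum* species, paired with statistics for pollen-tube
growth phenotypes.

## The science

Selfing and outcrossing tomato relatives differ sharply in their
reproductive biology: pollen from a selfing species (`SL`,
*Solanum lycopersicum*) and an outcrossing one (`SP`, *S. pennellii*)
grows at different rates in culture versus inside the style, and the genes
underlying pollen-tube growth show strong tissue bias. pollenTau implements
the analysis layer for this comparison:

* **TPM normalization** from counts and gene lengths (union-exon lengths
  from GFF3 supported), with leaf subtissue sections and pollen germination
  states averaged into per-replicate tissue values.
* **The tau specificity index** — for tissue means
  `x_1..x_N`, `tau = sum(1 - x_i/max(x)) / (N - 1)` — classifying each
  expressed gene (tissue mean ≥ 2 TPM anywhere) per species as
  tissue-**biased** (`tau ≥ 0.7`), tissue-**specific** (biased, focal mean
  ≥ 2 TPM, all other tissues < 0.1 TPM), or unbiased, plus a
  **reproductive-specific** flag (no leaf expression in either species).
* **Expression-domain comparison**: which pollen-biased genes have
  secondary expression in the style, in which species it is higher, and
  which are absent from `SL` styles entirely.
* **Stand-in differential contrasts**: median-of-ratios size factors, a
  Welch t on `log2(normalized + 1)` per gene, Benjamini–Hochberg
  correction within each tissue contrast.
* **PME/PMEI family curation** from annotation keywords, intersected with
  reproductive specificity.
* **Pollen-tube assay statistics**: donor-level growth rates in vitro
  (tube length / 3 h) and in vivo (mean of the 5 longest tubes / elapsed
  time), style lengths, proportion of style traversed, germination and
  diameter — compared between species with Welch tests and a
  variance-ratio F test.
* **A synthetic-data generator** with exact ground truth (planted classes,
  directions, families, and phenotype effects) that makes the whole
  pipeline verifiable end to end.

## Worked example

Simulate a dataset with known truth, classify genes, and compare the
species (all output below is real):

```r
library(pollenTau)

sim <- generateExpression(syntheticConfig(seed = 1))
sim$counts
#> TissueCounts: 2000 genes x 60 samples
#>   species: SL, SP | tissues: leaf, pollen, style
#>   gene length range: 501-4999 bp

prof <- tissueProfiles(collapseSubtissues(computeTpm(sim$counts)))
uni <- filterExpressed(prof)   # genes with >= 2 TPM in some tissue/species
length(uni)
#> [1] 1800

cl <- classifyGenes(prof, uni)
head(cl, 3)
#>     gene_id species tau focal_tissue    class reproductive_specific
#> 1 gene00001      SL   1         leaf specific                 FALSE
#> 2 gene00002      SL   1         leaf specific                 FALSE
#> 3 gene00003      SL   1         leaf specific                 FALSE

tbl <- table1Report(summarizeTable1(cl, prof))
tbl[tbl$tissue == "total", ]
#>   species tissue n_expressed n_biased n_specific prop_biased prop_specific
#> 4      SL  total        1800     1200        480       0.667           0.4
#> 8      SP  total        1800     1200        480       0.667           0.4

dc <- compareSecondaryStyleExpression(cl, prof)
unlist(dc[c("n_union", "n_secondary", "n_higher_SP", "n_higher_SL",
            "n_absent_SL_style")])
#>           n_union       n_secondary       n_higher_SP       n_higher_SL
#>               400                45                40                 5
#> n_absent_SL_style
#>                40
```

The generator planted 40 secondary-style genes higher in `SP` and 5 higher
in `SL`; the classification recovers exactly those. The phenotype panel
reproduces the planted sign reversal — faster growth in culture for `SL`,
faster growth inside the style for `SP`:

```r
pheno <- generatePhenotypes(phenotypeConfig(seed = 1))
rep <- speciesComparisonReport(summarizeAssays(pheno))
rep[rep$metric == "growth_rate_um_per_h",
    c("metric", "assay_type", "mean_SL", "mean_SP", "diff_SP_minus_SL", "p")]
#>                 metric assay_type  mean_SL   mean_SP diff_SP_minus_SL            p
#> 1 growth_rate_um_per_h   in_vitro 100.1427  69.92798        -30.21468 3.734800e-03
#> 4 growth_rate_um_per_h    in_vivo 284.5678 424.00439        139.43662 8.347835e-05
```

The same analysis runs end to end from the command line:

```sh
Rscript inst/scripts/run_pipeline.R all --out out/ --seed 1
```

writing TSV/JSON artifacts for every stage plus a checksummed manifest;
two runs with the same seed are byte-identical.

## Documentation

The methods vignette
(`vignettes/tissue-specificity-methods.Rmd`) documents the model, every
threshold and unit, the design of the synthetic generator (and what it
deliberately does not emulate), the Welch-versus-pooled choice, why the
species contrast is a stand-in rather than a count-model test, and a power
analysis for the variance-ratio test.
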