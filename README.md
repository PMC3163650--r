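# divergene

Candidate-gene discovery for mouse lines selectively bred for divergent
behaviour (high- vs low-anxiety lines, HAB/LAB). The package implements,
as tested tidyverse-style functions, the analysis chain that leads from
raw brain-region transcriptome measurements to annotated candidate loci:

* **Two-colour microarray normalization** — MA transform
  (`M = log2 R − log2 G`, `A = log2 √(RG)`), global median centring,
  intensity-dependent loess correction (40% span), sub-array (print-block)
  balancing, and dye-swap orientation into a probe × array log2(HAB/LAB)
  matrix.
* **Permutation differential expression** — a one-sample t on oriented M
  per probe with Westfall–Young **step-down maxT** adjusted p-values under
  the sign-flip null that the dye-swap design provides exactly
  (`p = (1 + b)/(1 + B)`, complete enumeration when `2^n ≤ B`, compiled
  counting kernel). A single-channel path offers quantile normalization
  and an empirical-Bayes **moderated t** with closed-form moment-matched
  hyperparameters.
* **Cross-region candidate selection** — both printed rule variants:
  *strictA* (≥40% regulation in one region, ≥30% in all others, adjusted
  p < 0.05) and *strictB* (≥30% with p < 0.10 in all or ≥3 regions), with
  percent regulation `100·(max(r, 1/r) − 1)` of the oriented fold
  `r = 2^mean_M`, direction-consistency checks, and a report of
  region-specific oppositely regulated probes.
* **qPCR relative quantification** — the 2^−ΔΔCt model with
  duplicate averaging on the Cp scale, single or paired housekeeping
  references, and fold regulation relative to the lowest-expressing group
  (reference fold exactly 1); plus the in-situ-hybridization
  signal-minus-background arithmetic.
* **Variant analysis** — global alignment of line alleles into
  SNP/insertion/deletion events, annotation against a single-locus gene
  model (promoter / exons with UTRs / introns / downstream enhancer
  region), type-by-region tallies, sliding-window density cluster
  detection, and codon-level coding consequences.
* **Nonparametric group statistics** — Kruskal–Wallis (exact permutation
  variant for small n), Mann–Whitney (exact enumeration for small
  tie-free samples), Holm step-down ("sequential Bonferroni"), and the
  gated omnibus → pairwise → correction reporting chain.
* **Synthetic data** — every input the pipeline consumes can be generated
  with known ground truth (`synth_config()` and the `synth_*()`
  generators), including dye-swapped arrays with intensity-dependent dye
  bias, null self-hybridizations, Cp plates, behaviour tables, and a
  deterministic synthetic reconstruction of the cathepsin B (Ctsb)
  variant table that reproduces the published summary accounting.

See the methods vignette
(`vignettes/candidate-gene-pipeline.Rmd`) for the models, the parameter
choices and their rationale, and known limitations.

## Worked example

Generate one region's dye-swapped replicate slides (2,400 probes, 30
planted regulated probes), normalize, and test:

```r
library(divergene)
library(dplyr)

cfg <- synth_config(seed = 1, n_probes = 2400, n_de_probes = 30,
                    n_subarrays = 8)
tc <- synth_twocolor(cfg, "PVN")
stack <- normalize_twocolor(tc$arrays)
de <- de_permutation(stack, n_perm = 1024, seed = 1, region = "PVN")
de
#> <de_result> region PVN
#>   2400 probes, 10 arrays, 1024 permutations (complete enumeration)
#>   probes with p_adj < 0.05: 30
tidy(de) |> arrange(p_adj, desc(regulation_pct)) |> head(3)
#> # A tibble: 3 × 7
#>   probe_id n_arrays mean_M t_raw fold_pct regulation_pct   p_adj
#>   <chr>       <int>  <dbl> <dbl>    <dbl>          <dbl>   <dbl>
#> 1 P00108         10  -1.54 -35.0     34.3           191. 0.00293
#> 2 P00707         10   1.53  32.5    288.            188. 0.00293
#> 3 P02106         10  -1.48 -23.4     35.8           179. 0.00293
```

Exactly the 30 planted probes reach family-wise significance: `mean_M` is
the oriented log2(HAB/LAB) ratio, `fold_pct = 100·2^mean_M` (values below
100 mean higher expression in LAB), `regulation_pct` the magnitude ratio
as percent, and `p_adj` the step-down maxT adjusted p-value (minimum
`2/1025 ≈ 0.002` under complete enumeration of ten arrays).

qPCR validation of a planted 2.6-fold regulation, normalized to a
housekeeping pair:

```r
plate <- synth_qpcr_plate(synth_config(seed = 1), "Ctsb",
                          c(HAB = 1, LAB = 2.6))
fold_regulation(ddct_quantify(plate, "Ctsb", c("Gapdh", "Hprt1")))
#> # A tibble: 2 × 5
#>   group     n  fold    sem reference
#>   <chr> <int> <dbl>  <dbl> <lgl>
#> 1 HAB       8  1    0.0122 TRUE
#> 2 LAB       8  2.53 0.0647 FALSE
```

Variant accounting and cluster detection on the synthetic Ctsb
reconstruction:

```r
v <- ctsb_variant_table()
tally_variants(v) |> filter(type == "total" | region == "total")
#> # A tibble: 8 × 3
#>   region   type          n
#>   <chr>    <chr>     <int>
#> 1 DER      total        16
#> 2 exon     total         8
#> 3 intron   total        57
#> 4 promoter total        12
#> 5 total    SNP          76
#> 6 total    deletion      9
#> 7 total    insertion     8
#> 8 total    total        93
cluster_scan(v, 550, region = "intron")
#> # A tibble: 1 × 3
#>      start      end     n
#>      <int>    <int> <int>
#> 1 63256100 63256649    18
```

76 SNPs, 8 insertions and 9 deletions in total; the densest 550-bp
intronic window holds 18 variants (intron 3 of the synthetic model).

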