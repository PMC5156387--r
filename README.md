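# megadesign

Custom-content design and evaluation for multi-ethnic genotyping
arrays.

Genotyping arrays carry a fixed backbone of probes tuned to tag common
variation genome-wide. When diverse cohorts are genotyped, that
backbone under-serves populations with different LD structure and the
less-frequent (1–5%) and rare (<1%) variation inside trait-associated
regions. `megadesign` is a toolkit for spending a custom-content budget
well and for measuring what it buys:

- **Prioritize** GWAS-catalog associations (smaller discovery samples
  first — they imply larger effects), keep the top-K, and build
  ±100 kb locus windows and ±50 kb gene windows (`rank_associations`,
  `locus_window`, `gene_region`, `merge_regions`).
- **Augment tagging**: greedy maximum-coverage tag-SNP selection over a
  *fixed* scaffold, across all populations simultaneously. A target is
  a biallelic region site with MAF ≥ 1% in a population; it is covered
  when a fixed-or-selected site reaches r² ≥ 0.2 with it
  (`select_tags`, `coverage_report`).
- **Fine-mapping proxies**: per index variant, all SNPs with r² ≥ 0.6
  within the 200 kb locus window, excluding triallelic sites and sites
  with MAF < 1% in the ancestry-matched LD reference population
  (`select_proxies`, `finemap_batch`, `pick_ld_population`).
- **Assemble**: consolidate multi-annotator consequence calls to the
  most deleterious per variant, keep singletons/synonymous variants
  inside priority genes, apply the strict design-score filter (> 0.5),
  and resolve category overlap into a final manifest
  (`consolidate_consequences`, `exome_inclusion_filter`,
  `apply_design_filter`, `dedup_categories`).
- **Evaluate**: leave-one-out imputation accuracy under a haploid
  Li–Stephens HMM, stratified by population and MAF bin
  (0.5–1%, 1–5%, >5%), comparing scaffolds with and without the custom
  content (`loo_accuracy`, `compare_scaffolds`,
  `augmentation_experiment`).
- **Simulate**: a Balding–Nichols + founder-mosaic generator produces
  phased multi-population panels with controllable frequency
  divergence (F_ST) and distance-decaying LD, so everything above is
  testable without external data (`sim_params`, `synth_panel`).

The LD statistic is the phased-haplotype r²:
D = p_ab − p_a·p_b, r² = D² / (p_a(1−p_a) p_b(1−p_b)), with LD at
population-monomorphic sites reported as a distinguished undefined
value, never 0.

## Worked example

```r
library(megadesign)

# a two-population phased panel: 200 SNVs on 100 kb
sim <- sim_params(n_sites = 200, chrom_length = 100000,
                  n_samples_per_pop = c(AFR = 60, EUR = 60),
                  fst = c(AFR = 0.08, EUR = 0.10), n_founders = 40,
                  seed = 42)
panel <- synth_panel(sim)$panel
panel
#> hap_panel: 200 sites x 120 samples ( 240 haplotypes )
#>   chrom(s): 1
#>   populations: AFR=60, EUR=60

# augment a 25-site backbone inside the whole region
backbone <- panel$sites$vid[seq(1, 200, by = 8)]
regions  <- region_set("1", 0, 100000, "demo_region")
tags <- select_tags(panel, regions, fixed = backbone)
tags
#> tag_selection: 81 tags selected over 25 fixed sites
#>  population n_targets n_covered mean_best_r2 frac_min_r2 frac_enhanced
#>         AFR       103       103    0.8839019           1     0.8252427
#>         EUR       100       100    0.8798805           1     0.8200000
#>  n_uncoverable
#>              0
#>              0
```

Every MAF ≥ 1% target in both populations ends covered at r² ≥ 0.2
(`frac_min_r2 = 1`), and ~82% reach the enhanced-region goal of
r² ≥ 0.8; 81 custom tags were needed on top of the 25 fixed sites.

```r
# fine-mapping proxies around a common index variant (EUR LD panel)
fs <- select_proxies(panel, "1:15865:A:G", design_params(), "EUR")
fs
#> finemap_set: index 1:15865:A:G (LD pop EUR ): 5 members;
#>   0 triallelic and 132 rare candidates excluded
head(fs$members)
#>           vid        r2
#> 1  1:3957:A:G 0.6172249
#> 2 1:15865:A:G 1.0000000
#> 3 1:44633:A:G 0.6172249
#> 4 1:66200:A:G 0.9642218
#> 5 1:87923:A:G 0.7943649
```

(The proxy example uses a stronger-LD panel, `n_founders = 6,
switch_rate = 2e-6`; r² ≥ 0.6 proxies are scarce under weak LD.)

`run_pipeline(run_config(...))` chains all stages from files (VCF +
panel/loci/genes/scores TSVs) to deterministic TSV/BED artifacts, and
`inst/scripts/megadesign.R` exposes the same stages as shell
subcommands (`simulate`, `ld`, `tags`, `finemap`, `loo-eval`, `run`).

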