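---
title: "Designing and evaluating custom array content with megadesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating custom array content with megadesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megadesign)
```

## The design problem

Genome-wide genotyping arrays carry a fixed backbone of a few hundred
thousand to a couple of million probes, chosen to tag common variation
genome-wide. When a consortium genotypes multi-ethnic cohorts, that
backbone under-serves two things: populations whose linkage
disequilibrium (LD) structure differs from the panels the backbone was
tuned on, and the less frequent (1&ndash;5%) and rare (&lt;1%) variation
in regions already implicated in disease. The remedy is *custom
content*: a budget of extra probes spent inside priority regions
— windows around top-ranked GWAS loci and around trait-relevant genes —
so that coverage and downstream imputation improve where it matters.

`megadesign` implements that design loop as composable stages:

1. **Prioritize** (`rank_associations`): catalog associations are
   deduplicated by variant and ranked by *ascending* discovery sample
   size — a smaller discovery cohort at genome-wide significance implies
   a larger effect, so those loci are refined first. Ties break by
   p-value, then variant id, making the ranking a total order. The top
   500 (configurable) define the loci.
2. **Regions** (`locus_window`, `gene_region`, `merge_regions`): each
   locus is the index SNP &plusmn;100 kb (200 kb total); each gene is
   the min&ndash;max span of its reported transcripts &plusmn;50 kb.
   Overlapping windows are merged (half-open interval arithmetic;
   merging is delegated to `GenomicRanges::reduce`).
3. **Tag augmentation** (`select_tags`): with the rest of the array
   held as *fixed content*, greedy maximum coverage selects tags for
   the (population, target) pairs not yet covered. A target is any
   biallelic region site with MAF &ge; 1% in that population; it counts
   as covered when some fixed-or-selected site within the LD window
   reaches r&sup2; &ge; 0.2 with it. Selection stops when no candidate
   adds coverage; the report also states the fraction of targets at the
   enhanced-region goal of r&sup2; &ge; 0.8 (the backbone itself is
   designed to a *mean* r&sup2; of 0.6, so the minimum-0.8 goal is the
   stricter, enhanced criterion — reported, not used as a stopping
   rule).
4. **Fine-mapping proxies** (`select_proxies`): per index variant, all
   SNPs with r&sup2; &ge; 0.6 to the index within the 200 kb locus
   window, excluding triallelic-or-more sites and sites with MAF &lt; 1%
   in the LD reference population. The reference population follows the
   discovery ancestry: EUR whenever European-descent samples were in
   the discovery, ASN for East/South-Asian-only discoveries; mappings
   for African-descent (AFR) and Hispanic/Latino (AMR) discoveries are
   a documented extension and are flagged.
5. **Annotation and assembly** (`consolidate_consequences`,
   `exome_inclusion_filter`, `apply_design_filter`,
   `dedup_categories`): multiple annotators' consequence calls collapse
   to the most deleterious per variant under an explicit severity table;
   inside priority genes the MAF floor is dropped (singletons and
   doubletons enter) and synonymous/UTR classes are kept; probes must
   have an Illumina-style design score strictly above 0.5 (missing
   scores fail unless explicitly kept); variants proposed under several
   content categories are assigned once, to the highest-precedence
   category, producing a before/after manifest.
6. **Evaluation** (`loo_accuracy`, `compare_scaffolds`): leave-one-out
   imputation accuracy, stratified by population and MAF bin, under the
   scaffold with and without the custom content.

`run_pipeline()` chains the stages from a single validated config and
writes deterministic TSV/BED artifacts plus a provenance record; a thin
Rscript CLI (`inst/scripts/megadesign.R`) wraps the same functions.

## LD and its undefined value

LD is computed from *phased haplotype* counts, not genotype-composite
correlation: for biallelic sites with alt-allele frequencies $p_a, p_b$
and (1,1)-haplotype frequency $p_{ab}$,

$$ D = p_{ab} - p_a p_b, \qquad
   r^2 = \frac{D^2}{p_a(1-p_a)\,p_b(1-p_b)}, \qquad
   D' = \frac{|D|}{D_{\max}}. $$

A site monomorphic in the chosen population has *undefined* LD. That is
a distinguished `NA`, never 0: tag selection must treat such targets as
uncoverable, and silently scoring them 0 would let a content set claim
coverage it cannot deliver. Frequencies are computed in double
precision and r&sup2; is clipped to [0, 1] after a 1e-12 tolerance
check. Multiallelic sites are loaded intact — the triallelic exclusion
in fine-mapping needs to see them — but LD operations accept only
biallelic sites.

## Coordinates

VCF and site tables are 1-based; all internal interval arithmetic and
BED output are 0-based half-open. Conversion happens only at I/O
boundaries, so `locus_window(chrom, 150000)` covers 1-based positions
49,999+1 .. 250,000 and prints in BED as `49999 250000`. Missing
genotypes are rejected at load — every downstream formula assumes
complete haplotypes — with an explicit, loudly-logged
`impute_missing_as_ref` escape hatch for user data.

## The synthetic panel generator

Every stage is testable without external data because `synth_panel()`
builds a phased multi-population panel with two controllable layers:

* **Frequency divergence** (Balding&ndash;Nichols): ancestral
  $p_i \sim \mathrm{Beta}(a,b)$ i.i.d. per site; each population draws
  $p_{ik} \sim \mathrm{Beta}\!\big(p_i\tfrac{1-F_k}{F_k},\,
  (1-p_i)\tfrac{1-F_k}{F_k}\big)$, with mean $p_i$ and variance
  $p_i(1-p_i)F_k$.
* **LD** (founder mosaic): per population, `n_founders` founder
  haplotypes are drawn site-wise Bernoulli($p_{ik}$); each sample
  haplotype copies a founder and switches to a uniformly chosen founder
  between adjacent sites with probability $1-e^{-\rho d}$; finally each
  allele flips independently with the private-mutation rate.

Defaults — the package's study conditions — are six populations (AAC,
AFR, AMR, ASN, EUR, SAS) of 100 samples each, 500 SNVs on a 200 kb
chromosome, $F_{ST}$ between 0.05 and 0.12 (the human continental
range), and a strongly U-shaped ancestral spectrum
($\mathrm{Beta}(0.25, 0.25)$), since sequence panels are dominated by
rare variation. The founder pool size (100) balances two
representational constraints that pull in opposite directions: the
pool's frequency granularity ($1/n_\text{founders}$) must reach the
rarest analysed MAF stratum (0.5&ndash;1%), while each founder must be
copied by more than one sample haplotype (expected copies =
haplotypes/founders = 2) or no haplotype shares segments with any other
and imputation accuracy collapses for *all* frequencies. The flip rate
(1e-5) keeps linkage-equilibrium noise an order of magnitude below the
rarest stratum, so flip singletons do not masquerade as rare variants.

What the generator does **not** emulate: cross-population haplotype
sharing (founder pools are population-private; only allele frequencies
are correlated across populations), admixture LD, hierarchical
coalescent sharing (all founders are exchangeable), and selection.
Passing tests therefore demonstrate correctness of the algorithms and
qualitative behaviour of the evaluation, not quantitative transfer to
1000 Genomes-scale data.

## The imputation evaluator

The accuracy study needs an imputation engine that is deterministic,
dependency-free and exactly testable, so the package implements a
haploid Li&ndash;Stephens hidden Markov model: the hidden state is the
reference haplotype being copied; between adjacent scaffold sites the
state switches with probability $1-e^{-\rho d}$ (uniform landing);
emissions match the observed allele with probability $1-\varepsilon$
($\varepsilon = 0.01$, $\rho = 10^{-6}$/bp by default). Posterior state
probabilities come from a scaled forward&ndash;backward pass at the
scaffold sites and are interpolated linearly in physical distance at
each evaluation site (a genetic map is not required at the scales the
package targets); the haplotype dosage is the posterior-weighted
reference allele, and the diploid dosage the sum over the two focal
haplotypes, clipped to [0, 2]. The implementation is verified against
exhaustive hidden-path enumeration on small cases and against
perfect-proxy and linkage-equilibrium limits.

Accuracy is aggregated as squared Pearson correlation &times; 100
between imputed dosage and true genotype across a population's samples,
per site, averaged within population-specific MAF bins (default edges
0.005, 0.01, 0.05, i.e. 0.5&ndash;1%, 1&ndash;5%, &gt;5%); plain $r$ is
available via `accuracy = "r"`. Bins are population-specific because a
site's frequency class genuinely differs between populations. Sites
with zero dosage variance or below the lowest edge are excluded and
counted; populations with fewer than three samples report `NA`.

## The scaffold-augmentation experiment

`augmentation_experiment()` packages the evaluation study: simulate the
study-condition panel, mark 80% of sites manufacturable (a design-score
pass), lay a backbone over every second manufacturable site (density
comparable, relative to panel density, to a GWAS backbone), select
custom tags over that fixed backbone, and compare leave-one-out
accuracy at off-array sites under backbone-only versus
backbone-plus-custom. Evaluation sites are drawn stratified by MAF bin
(up to 40 per bin) so every stratum is populated; per-population and
per-bin deltas are site-pooled means in percentage points.

Adding the selected content raises accuracy in every population. One
qualitative pattern from real arrays does **not** reproduce at this
scale, and deliberately stays a failing expectation rather than a
weakened one: on real panels the largest accuracy gains concentrate
below 1% MAF. Here a population-MAF 0.5&ndash;1% site has only one or
two carriers among 200 haplotypes; leave-one-out removes the focal
carrier, leaving at most one reference carrier, and founder pools are
population-private, so no cross-population haplotype can stand in. The
bin's accuracy is therefore pinned low under *any* scaffold, its
~10&ndash;15 (population, site) cells give bin means with several
points of Monte-Carlo noise, and the backbone sparse enough to leave
commons room to improve necessarily leaves them far from their ceiling.
Reproducing the rare-bin concentration requires per-population
reference sizes several times larger (where that bin holds 7&ndash;30
carriers) and cross-population sharing — both outside these study
conditions.

## Numerical and policy choices

* **Severity order**: annotators do not agree on a consolidation
  order; the shipped table (stop_gained &gt; frameshift &gt; stop_lost
  &gt; splice donor/acceptor &gt; inframe &gt; missense &gt; splice
  region &gt; 5'UTR &gt; 3'UTR &gt; synonymous &gt; intronic &gt;
  intergenic) is a Sequence-Ontology-style default; whether UTR should
  outrank missense is genuinely open, so the table is an argument, and
  all behaviour re-derives from the table passed.
* **Design filter**: strictly greater than 0.5; a score of exactly 0.5
  fails. Missing scores fail by default because manufacturability is
  unknown, not granted.
* **Category precedence** for overlap removal defaults to the
  manifest's reporting order and is configurable — the overlap rule is
  a reporting convention, not a scientific claim.
* **Ranking ties** (p-value, then vid) and the greedy tie-break
  (larger mean MAF, then smaller position, then vid) exist purely for
  determinism; permuting inputs never changes outputs.
* **"Within 200 kb"** is read as &plusmn;100 kb around the index,
  consistent with the locus definition; the fine-map MAF exclusion is
  applied in the LD reference population.
* **Problem sizes**: tests and the acceptance script run the study at
  500 sites &times; 600 samples (tag selection, five-seed evaluation)
  and verify engines against exhaustive oracles at enumerable sizes
  (&le;4 reference haplotypes &times; &le;5 sites for path enumeration,
  &le;12 candidates for set cover).

## Known limitations

Unphased input is out of scope (pre-phase upstream); LD is never
computed across chromosomes or for multiallelic sites; the greedy
objective (uncovered pairs summed over populations, optionally
weighted) is one defensible aggregation among several; the evaluator's
linear posterior interpolation ignores recombination within the
flanking interval; and the generator's weak pairwise LD at realistic
founder-pool sizes means pairwise-r&sup2; proxy sets on synthetic
panels are much smaller than on real sequence data.
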