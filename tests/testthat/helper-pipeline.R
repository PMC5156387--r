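# build a complete set of pipeline inputs from the synthetic generator
make_pipeline_inputs <- function(dir, seed = 101) {
  params <- sim_params(n_sites = 120, chrom_length = 400000,
                       n_samples_per_pop = c(EUR = 25, AFR = 25),
                       fst = c(EUR = 0.1, AFR = 0.08), seed = seed)
  sim <- synth_panel(params)
  panel <- sim$panel
  paths <- list(vcf = file.path(dir, "panel.vcf"),
                samples = file.path(dir, "samples.tsv"),
                loci = file.path(dir, "loci.tsv"),
                genes = file.path(dir, "genes.tsv"),
                fixed = file.path(dir, "fixed.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                scores = file.path(dir, "scores.tsv"))
  set.seed(seed)
  write.table(data.frame(vid = panel$sites$vid,
                         design_score = round(runif(nrow(panel$sites),
                                                    0.3, 1), 3)),
              paths$scores, sep = "\t", quote = FALSE, row.names = FALSE)
  write_phased_vcf(panel, paths$vcf)
  write.table(panel$samples, paths$samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  mafs <- sapply(panel$sites$vid, function(v) maf(panel, v, "EUR"))
  idxs <- names(which(mafs > 0.1))[1:4]
  loci <- data.frame(vid = idxs, trait = "T2D",
                     discovery_n = c(5000L, 20000L, 8000L, 100000L),
                     p_value = c(1e-8, 1e-10, 1e-7, 1e-12),
                     ancestry = "European",
                     chrom = "1",
                     pos = panel$sites$pos[match(idxs, panel$sites$vid)])
  write.table(loci, paths$loci, sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- data.frame(gene = "GENE1", chrom = "1",
                      start = 150000L, end = 170000L)
  write.table(genes, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fixed <- data.frame(vid = panel$sites$vid[seq(1, 120, 10)])
  write.table(fixed, paths$fixed, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ann_vids <- panel$sites$vid[seq(2, 120, 7)]
  set.seed(seed + 1)
  ann <- data.frame(vid = rep(ann_vids, 2),
                    source = rep(c("annovar", "vep"), each = length(ann_vids)),
                    term = sample(c("missense", "synonymous", "utr3",
                                    "intronic"),
                                  2 * length(ann_vids), TRUE))
  write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
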