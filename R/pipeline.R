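# deterministic TSV writer with a provenance header line
.write_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA"))
  invisible(path)
}

#' Write a synthetic panel to disk
#'
#' Emits the three files a simulation run produces: a phased VCF, a
#' sample-to-population panel TSV and a true-frequency TSV, all
#' reproducible from (params, seed).
#'
#' @param params a \code{\link{sim_params}}.
#' @param dir output directory (created if needed).
#' @return invisible list of written paths.
#' @export
write_synth <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- synth_panel(params)
  vcf <- file.path(dir, "panel.vcf")
  write_phased_vcf(sim$panel, vcf)
  pan <- file.path(dir, "samples.tsv")
  write.table(sim$panel$samples, pan, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fr <- data.frame(vid = sim$panel$sites$vid,
                   ancestral = sim$freqs$ancestral)
  fr <- cbind(fr, as.data.frame(sim$freqs$pop))
  frq <- file.path(dir, "true_frequencies.tsv")
  write.table(fr, frq, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(vcf = vcf, samples = pan, frequencies = frq))
}

#' Pipeline configuration
#'
#' Collects input paths and parameters for \code{\link{run_pipeline}}.
#'
#' @param vcf phased VCF path.
#' @param panel sample-to-population TSV path.
#' @param loci GWAS association TSV (vid, trait, discovery_n, p_value,
#'   ancestry, and chrom/pos for windows).
#' @param genes optional gene transcript TSV (gene, chrom, start, end;
#'   0-based half-open; one row per transcript).
#' @param fixed optional TSV of fixed scaffold content (column vid).
#' @param annotations optional consequence-call TSV (vid, source, term).
#' @param scores optional site-metadata TSV (vid, design_score) carrying
#'   the manufacturability scores; sites absent from it stay unscored.
#' @param out_dir output directory.
#' @param params a \code{\link{design_params}}.
#' @param ls a \code{\link{ls_params}}.
#' @param precedence category precedence for the manifest.
#' @param run_impute whether to run the leave-one-out scaffold
#'   comparison (the slowest stage).
#' @param n_eval_sites cap on evaluation sites for the comparison.
#' @param seed integer seed recorded in every output header and used
#'   for any subsampling.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(vcf, panel, loci, genes = NULL, fixed = NULL,
                       annotations = NULL, scores = NULL,
                       out_dir = "megadesign_out",
                       params = design_params(), ls = ls_params(),
                       precedence = c("gwas_catalog", "enhanced_gwas",
                                      "enhanced_exome", "finemap",
                                      "regulatory", "clinical", "pathway"),
                       run_impute = FALSE, n_eval_sites = 100L,
                       seed = 1L) {
  cfg <- structure(list(vcf = vcf, panel = panel, loci = loci,
                        genes = genes, fixed = fixed,
                        annotations = annotations, scores = scores,
                        out_dir = out_dir,
                        params = params, ls = ls, precedence = precedence,
                        run_impute = isTRUE(run_impute),
                        n_eval_sites = as.integer(n_eval_sites),
                        seed = as.integer(seed)),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @export
validate_config <- function(config) {
  for (f in c("vcf", "panel", "loci")) {
    if (is.null(config[[f]])) stop("config is missing required path: ", f)
    if (!file.exists(config[[f]]))
      stop("config path does not exist: ", f, " = ", config[[f]])
  }
  for (f in c("genes", "fixed", "annotations", "scores")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config path does not exist: ", f, " = ", config[[f]])
  }
  invisible(config)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(lapply(config, function(x)
    if (is.list(x)) unclass(x) else x), auto_unbox = TRUE, digits = NA,
    null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full content-design pipeline
#'
#' Executes prioritization, region construction, tag selection,
#' fine-mapping proxy selection, annotation consolidation and manifest
#' assembly (plus, optionally, the leave-one-out scaffold comparison),
#' writing deterministic TSV/BED artifacts and a provenance file to the
#' output directory.  Re-running with an identical config reproduces
#' byte-identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  params <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- paste0("megadesign ", packageVersion("megadesign"),
                 " seed=", config$seed, " config=", .config_hash(config))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[megadesign] %-12s %6.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  pop_panel <- stage("load", {
    read_population_panel(config$panel)
  })
  panel <- stage("vcf", read_phased_vcf(config$vcf, pop_panel))
  if (!is.null(config$scores)) {
    sc <- read.table(config$scores, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    panel$sites$design_score <-
      sc$design_score[match(panel$sites$vid, sc$vid)]
  }

  assoc <- read.table(config$loci, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
  ranked <- stage("prioritize",
                  rank_associations(assoc, params$top_k,
                                    params$locus_flank_bp))
  .write_tsv(ranked, file.path(config$out_dir, "ranked_loci.tsv"), meta)

  regions <- stage("regions", {
    locus_regs <- if (all(c("chrom", "pos") %in% names(ranked)) &&
                      nrow(ranked) > 0) {
      do.call(rbind, lapply(seq_len(nrow(ranked)), function(i)
        locus_window(ranked$chrom[i], ranked$pos[i],
                     params$locus_flank_bp, ranked$vid[i])))
    } else region_set()
    gene_regs <- region_set()
    if (!is.null(config$genes)) {
      gt <- read.table(config$genes, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, comment.char = "#")
      gene_regs <- do.call(rbind, lapply(split(gt, gt$gene), function(g)
        gene_region(g$chrom[1], g$start, g$end, params$gene_flank_bp,
                    g$gene[1])))
    }
    merge_regions(rbind(locus_regs, gene_regs))
  })
  write_bed(regions, file.path(config$out_dir, "regions.bed"))

  fixed <- character()
  if (!is.null(config$fixed)) {
    ft <- read.table(config$fixed, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    fixed <- intersect(ft$vid, panel$sites$vid)
  }

  tags <- stage("tags", select_tags(panel, regions, fixed, params))
  .write_tsv(tags$summary,
             file.path(config$out_dir, "coverage_summary.tsv"), meta)

  fm <- stage("finemap", finemap_batch(panel, ranked, params))
  .write_tsv(fm$manifest,
             file.path(config$out_dir, "finemap_manifest.tsv"), meta)
  members <- do.call(rbind, lapply(fm$sets, function(s)
    cbind(index_vid = s$index_vid, s$members)))
  if (!is.null(members))
    .write_tsv(members,
               file.path(config$out_dir, "finemap_members.tsv"), meta)

  manifest <- stage("assemble", {
    terms <- NULL
    if (!is.null(config$annotations)) {
      calls <- read.table(config$annotations, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
      terms <- consolidate_consequences(calls)
    }
    cat_map <- list(
      gwas_catalog = intersect(ranked$vid, panel$sites$vid),
      enhanced_gwas = tags$selected,
      finemap = setdiff(fm$all_members,
                        vapply(fm$sets, `[[`, character(1), "index_vid")))
    if (!is.null(terms)) {
      incl <- exome_inclusion_filter(
        panel$sites$chrom[match(names(terms), panel$sites$vid)],
        panel$sites$pos[match(names(terms), panel$sites$vid)],
        unname(terms), regions)
      cat_map$enhanced_exome <- names(terms)[!is.na(incl) & incl]
    }
    vids <- unique(unlist(cat_map))
    cats <- vapply(vids, function(v)
      paste(names(cat_map)[vapply(cat_map, function(s) v %in% s,
                                  logical(1))], collapse = ","),
      character(1))
    st <- site_table(panel)
    content <- st[match(vids, st$vid), , drop = FALSE]
    content$categories <- unname(cats)
    filt <- apply_design_filter(content, params$design_score_min,
                                keep_unscored = all(is.na(content$design_score)))
    man <- dedup_categories(filt$passing, config$precedence)
    before <- dedup_categories(content, config$precedence)
    man$counts$n_submitted <- before$counts$n_before
    write_site_table(filt$passing,
                     file.path(config$out_dir, "content_sites.tsv"))
    .write_tsv(man$counts,
               file.path(config$out_dir, "manifest_counts.tsv"), meta)
    man
  })

  impute <- NULL
  if (config$run_impute) {
    impute <- stage("loo-eval", {
      custom <- intersect(manifest$assignment$vid, panel$sites$vid)
      custom <- custom[is_biallelic(panel)[match(custom, panel$sites$vid)]]
      with_scaf <- union(fixed, custom)
      eligible <- setdiff(panel$sites$vid[is_biallelic(panel)], with_scaf)
      set.seed(config$seed)
      eval_sites <- if (length(eligible) > config$n_eval_sites)
        sort(sample(eligible, config$n_eval_sites)) else eligible
      compare_scaffolds(panel, with_scaf, fixed, eval_sites, config$ls,
                        params$maf_bin_edges)
    })
    acc <- as.data.frame(impute$accuracy)
    acc <- cbind(population = rownames(acc), acc,
                 setNames(as.data.frame(impute$delta),
                          paste0("delta_", colnames(impute$delta))))
    .write_tsv(acc, file.path(config$out_dir, "imputation_accuracy.tsv"),
               meta)
  }

  prov <- list(tool = "megadesign",
               version = as.character(packageVersion("megadesign")),
               seed = config$seed, config_hash = .config_hash(config),
               n_sites = nrow(panel$sites),
               n_samples = nrow(panel$samples),
               n_ranked_loci = nrow(ranked),
               n_tags_selected = length(tags$selected),
               n_finemap_members = length(fm$all_members),
               n_content = nrow(manifest$assignment))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE),
             file.path(config$out_dir, "provenance.json"))
  invisible(list(panel = panel, ranked = ranked, regions = regions,
                 tags = tags, finemap = fm, manifest = manifest,
                 impute = impute, out_dir = config$out_dir))
}
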