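#' Scaffold-augmentation evaluation experiment
#'
#' Runs the package's end-to-end imputation-accuracy study on one
#' synthetic panel: simulate a multi-population panel under the default
#' study conditions, mark a fraction of sites as manufacturable
#' (design-score pass), lay a backbone scaffold over every other
#' manufacturable site, let \code{\link{select_tags}} choose custom
#' content over that fixed backbone, and score leave-one-out imputation
#' accuracy at off-array evaluation sites (stratified so every MAF bin
#' is populated) under the backbone alone versus backbone plus custom
#' content.
#'
#' @param seed integer seed controlling the panel and all subsampling.
#' @param sim a \code{\link{sim_params}} (default: the study conditions).
#' @param designable_frac fraction of sites that pass probe design.
#' @param backbone_every backbone takes every k-th manufacturable site.
#' @param eval_per_bin evaluation sites drawn per MAF bin.
#' @param params a \code{\link{design_params}}.
#' @param ls a \code{\link{ls_params}}.
#' @return list with the \code{\link{compare_scaffolds}} report
#'   (\code{cmp}), \code{n_tags}, \code{n_backbone}, \code{n_eval},
#'   \code{pop_delta} (per population, mean per-site accuracy delta in
#'   percentage points, pooled over bins) and \code{bin_delta} (per MAF
#'   bin, pooled over populations).
#' @export
augmentation_experiment <- function(seed,
                                    sim = sim_params(seed = seed),
                                    designable_frac = 0.8,
                                    backbone_every = 2L,
                                    eval_per_bin = 40L,
                                    params = design_params(),
                                    ls = ls_params()) {
  panel <- synth_panel(sim)$panel
  vids <- panel$sites$vid
  n <- length(vids)
  set.seed(seed)
  designable <- sort(sample(n, round(n * designable_frac)))
  panel$sites$design_score <- ifelse(seq_len(n) %in% designable, 0.9, 0.1)
  backbone <- vids[designable[seq(1, length(designable),
                                  by = backbone_every)]]
  regions <- region_set(panel$sites$chrom[1], 0,
                        max(panel$sites$pos) + 1, "study_region")
  tags <- select_tags(panel, regions, fixed = backbone, params)
  with_scaf <- union(backbone, tags$selected)

  pops <- sort(unique(panel$samples$population))
  mafmat <- vapply(pops, function(p) .maf_vector(panel, p),
                   numeric(n))
  elig <- setdiff(vids, with_scaf)
  bins <- params$maf_bin_edges
  pick <- character()
  for (b in seq_along(bins)) {
    lo <- bins[b]
    hi <- if (b < length(bins)) bins[b + 1] else 0.5
    inb <- elig[apply(mafmat[match(elig, vids), , drop = FALSE], 1,
                      function(m) any(m > lo & m <= hi))]
    inb <- setdiff(inb, pick)
    pick <- c(pick,
              if (length(inb) > eval_per_bin) sort(sample(inb, eval_per_bin))
              else inb)
  }
  eval_sites <- sort(unique(pick))
  cmp <- compare_scaffolds(panel, with_scaf, backbone, eval_sites, ls,
                           bins)
  m <- merge(cmp$per_site, cmp$without$per_site,
             by = c("population", "vid"),
             suffixes = c("_with", "_without"))
  m <- m[!is.na(m$bin_with) & !is.na(m$accuracy_with) &
           !is.na(m$accuracy_without), , drop = FALSE]
  d <- m$accuracy_with - m$accuracy_without
  pop_delta <- tapply(d, m$population, mean)[pops]
  bin_delta <- setNames(rep(NA_real_, length(bins)),
                        colnames(cmp$accuracy))
  bd <- tapply(d, m$bin_with, mean)
  bin_delta[as.integer(names(bd))] <- bd
  list(cmp = cmp, n_tags = length(tags$selected),
       n_backbone = length(backbone), n_eval = length(eval_sites),
       pop_delta = pop_delta, bin_delta = bin_delta)
}
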