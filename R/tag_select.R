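# -- internal machinery shared by select_tags / coverage_report ----------

# Build the LD coverage context for a panel restricted to a region set:
# the relevant sites (biallelic region sites plus any extra vids, e.g.
# fixed scaffold content), per-population MAF, and per-population r2
# matrices masked to the LD window.
.ld_context <- function(panel, regions, extra_vids, params) {
  in_reg <- in_regions(regions, panel$sites$chrom, panel$sites$pos)
  bi <- is_biallelic(panel)
  rel <- which((in_reg & bi) | panel$sites$vid %in% extra_vids)
  vids <- panel$sites$vid[rel]
  pops <- sort(unique(panel$samples$population))
  pos <- panel$sites$pos[rel]
  chrom <- panel$sites$chrom[rel]
  within <- outer(chrom, chrom, "==") &
    abs(outer(pos, pos, "-")) <= params$ld_window_bp
  maf_pop <- vapply(pops, function(p) .maf_vector(panel, p)[rel],
                    numeric(length(rel)))
  maf_pop <- matrix(maf_pop, nrow = length(rel),
                    dimnames = list(vids, pops))
  bi_rel <- bi[rel]
  r2 <- lapply(pops, function(p) {
    rows <- .pop_hap_rows(panel, p)
    X <- panel$alleles[rows, rel, drop = FALSE]
    # multiallelic sites get no LD: zero them so .r2_matrix marks them NA
    if (any(!bi_rel)) X[, !bi_rel] <- 0L
    m <- .r2_matrix(X)
    m[!within] <- NA_real_
    m
  })
  names(r2) <- pops
  list(idx = rel, vids = vids, pos = pos, chrom = chrom,
       in_region = in_reg[rel], biallelic = bi[rel],
       pops = pops, maf = maf_pop, r2 = r2, within = within)
}

# best covering r2 per (site, population) given a covering set of vids;
# a site covers itself with r2 = 1 (when polymorphic in the population)
.best_r2 <- function(ctx, cover_vids, target_mask) {
  ci <- match(intersect(cover_vids, ctx$vids), ctx$vids)
  out <- matrix(0, nrow = length(ctx$vids), ncol = length(ctx$pops),
                dimnames = list(ctx$vids, ctx$pops))
  for (p in ctx$pops) {
    m <- ctx$r2[[p]]
    if (is.null(m)) next
    if (length(ci)) {
      sub <- m[ci, , drop = FALSE]
      best <- apply(sub, 2, function(col) {
        if (all(is.na(col))) 0 else max(col, na.rm = TRUE)
      })
      out[, p] <- best
    }
  }
  out
}

#' Greedy cross-population tag-SNP selection over a fixed scaffold
#'
#' Selects custom tag SNPs inside priority regions so that, together
#' with the fixed array scaffold, they cover the regional variation in
#' every population.  For each population \code{p}, the targets are the
#' biallelic region sites with population MAF at or above
#' \code{tag_min_maf}; a (population, target) pair is covered when some
#' site in the fixed-plus-selected set within \code{ld_window_bp}
#' reaches r-squared of at least \code{tag_min_r2} with it (a site
#' covers itself).  The greedy loop repeatedly picks the candidate
#' covering the most currently uncovered pairs, summed over populations
#' (optionally weighted), until no candidate adds coverage.  Ties break
#' by larger mean MAF across populations, then smaller position, then
#' vid.
#'
#' Candidates are biallelic region sites passing the MAF floor in at
#' least one population, not already in the fixed set, and passing the
#' design-score filter whenever design scores are present.
#'
#' @param panel a \code{hap_panel}.
#' @param regions a \code{\link{region_set}} of priority regions.
#' @param fixed character vector of fixed-content vids (must exist in
#'   the panel).
#' @param params a \code{\link{design_params}}.
#' @param pop_weights optional named weights per population for the
#'   greedy objective (default: equal).
#' @return object of class \code{tag_selection}: \code{selected} (vids
#'   in selection order), \code{coverage} (best-r2 matrix, targets x
#'   populations, \code{NA} for non-targets), \code{summary} (per
#'   population: n_targets, n_covered, mean best r2, fraction at or
#'   above \code{tag_min_r2} and \code{enhanced_min_r2},
#'   n_uncoverable), and bookkeeping fields.
#' @export
select_tags <- function(panel, regions, fixed = character(),
                        params = design_params(), pop_weights = NULL) {
  stopifnot(inherits(params, "design_params"))
  miss <- setdiff(fixed, panel$sites$vid)
  if (length(miss)) stop("fixed vids not in panel: ",
                         paste(head(miss, 5), collapse = ", "))
  if (nrow(regions) == 0) stop("regions must be non-empty")
  if (!any(regions$chrom %in% panel$sites$chrom))
    stop("regions and panel have no chromosome in common")
  ctx <- .ld_context(panel, regions, fixed, params)
  pops <- ctx$pops
  if (is.null(pop_weights)) pop_weights <- setNames(rep(1, length(pops)), pops)

  # targets: biallelic region sites with MAF >= floor, per population
  target <- ctx$maf >= params$tag_min_maf & ctx$in_region & ctx$biallelic
  if (!any(target)) {
    warning("no polymorphic targets in regions")
    empty_sum <- data.frame(population = pops, n_targets = 0L,
                            n_covered = 0L, mean_best_r2 = NA_real_,
                            frac_min_r2 = NA_real_, frac_enhanced = NA_real_,
                            n_uncoverable = 0L)
    return(structure(list(selected = character(), coverage = NULL,
                          summary = empty_sum, fixed = fixed,
                          params = params), class = "tag_selection"))
  }

  scored <- !all(is.na(panel$sites$design_score))
  ds <- panel$sites$design_score[ctx$idx]
  cand <- ctx$in_region & ctx$biallelic &
    apply(ctx$maf >= params$tag_min_maf, 1, any) &
    !(ctx$vids %in% fixed)
  if (scored) cand <- cand & !is.na(ds) & ds > params$design_score_min

  # coverage indicator per population: C[s, t] TRUE when s covers t
  C <- lapply(pops, function(p) {
    m <- ctx$r2[[p]]
    cc <- !is.na(m) & m >= params$tag_min_r2
    diag(cc) <- ctx$maf[, p] > 0        # self-coverage when polymorphic
    cc
  })
  names(C) <- pops

  # start from fixed coverage
  uncovered <- target
  fi <- which(ctx$vids %in% fixed)
  for (p in pops) {
    if (length(fi))
      uncovered[, p] <- uncovered[, p] &
        !apply(C[[p]][fi, , drop = FALSE], 2, any)
  }
  # pairs no candidate can ever cover
  coverable <- matrix(FALSE, nrow = length(ctx$vids), ncol = length(pops),
                      dimnames = dimnames(target))
  ci_all <- which(cand)
  for (p in pops) if (length(ci_all))
    coverable[, p] <- apply(C[[p]][ci_all, , drop = FALSE], 2, any)
  uncoverable <- uncovered & !coverable
  uncovered <- uncovered & coverable

  mean_maf <- rowMeans(ctx$maf)
  selected <- character()
  cand_now <- cand
  while (any(uncovered)) {
    gain <- numeric(length(ctx$vids))
    for (p in pops) {
      u <- which(uncovered[, p])
      if (length(u))
        gain <- gain + pop_weights[[p]] *
          rowSums(C[[p]][, u, drop = FALSE])
    }
    gain[!cand_now] <- 0
    best <- max(gain)
    if (best <= 0) break
    tied <- which(gain == best)
    tied <- tied[order(-mean_maf[tied], ctx$pos[tied], ctx$vids[tied])]
    s <- tied[1]
    selected <- c(selected, ctx$vids[s])
    cand_now[s] <- FALSE
    for (p in pops) uncovered[, p] <- uncovered[, p] & !C[[p]][s, ]
  }

  cover_set <- union(fixed, selected)
  best <- .best_r2(ctx, cover_set, target)
  best[!target] <- NA_real_
  summary <- do.call(rbind, lapply(pops, function(p) {
    t_idx <- which(target[, p])
    b <- best[t_idx, p]
    data.frame(population = p, n_targets = length(t_idx),
               n_covered = sum(b >= params$tag_min_r2),
               mean_best_r2 = if (length(b)) mean(b) else NA_real_,
               frac_min_r2 = if (length(b)) mean(b >= params$tag_min_r2) else NA_real_,
               frac_enhanced = if (length(b)) mean(b >= params$enhanced_min_r2) else NA_real_,
               n_uncoverable = sum(uncoverable[, p]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(selected = selected, coverage = best, summary = summary,
                 targets = target, uncoverable = uncoverable,
                 fixed = fixed, params = params),
            class = "tag_selection")
}

#' @export
print.tag_selection <- function(x, ...) {
  cat("tag_selection:", length(x$selected), "tags selected over",
      length(x$fixed), "fixed sites\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Coverage report for an arbitrary site set
#'
#' Per population: mean best r-squared over targets, fraction of targets
#' covered at the enhanced goal (r2 >= \code{enhanced_min_r2}) and at
#' the tagging floor (r2 >= \code{tag_min_r2}), with uncovered targets
#' contributing best r2 = 0.
#'
#' @param panel a \code{hap_panel}.
#' @param regions priority \code{\link{region_set}}.
#' @param sites character vector of vids forming the scaffold/content
#'   evaluated.
#' @param params a \code{\link{design_params}}.
#' @return data.frame, one row per population.
#' @export
coverage_report <- function(panel, regions, sites,
                            params = design_params()) {
  miss <- setdiff(sites, panel$sites$vid)
  if (length(miss)) stop("sites not in panel: ",
                         paste(head(miss, 5), collapse = ", "))
  ctx <- .ld_context(panel, regions, sites, params)
  target <- ctx$maf >= params$tag_min_maf & ctx$in_region & ctx$biallelic
  best <- .best_r2(ctx, sites, target)
  out <- do.call(rbind, lapply(ctx$pops, function(p) {
    t_idx <- which(target[, p])
    b <- best[t_idx, p]
    data.frame(population = p, n_targets = length(t_idx),
               n_covered = sum(b >= params$tag_min_r2),
               n_uncovered = sum(b < params$tag_min_r2),
               mean_best_r2 = if (length(b)) mean(b) else 0,
               frac_min_r2 = if (length(b)) mean(b >= params$tag_min_r2) else 0,
               frac_enhanced = if (length(b)) mean(b >= params$enhanced_min_r2) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
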