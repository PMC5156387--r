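#' Fine-mapping proxy selection around an index variant
#'
#' A fine-mapped locus consists of the index variant plus all correlated
#' SNPs with r-squared at or above \code{params$finemap_r2} within the
#' locus window (total width \code{params$finemap_window_bp}, i.e.
#' half that distance on each side of the index).  Candidates are
#' excluded when triallelic-or-more (two or more alternate alleles) or
#' when their MAF in the LD reference population is below 1\%; both
#' exclusion counts are reported.  The index itself is always a member
#' (with r-squared 1).
#'
#' @param panel a \code{hap_panel}.
#' @param index_vid vid of the index variant (must be biallelic and
#'   polymorphic in \code{population}).
#' @param params a \code{\link{design_params}}.
#' @param population LD reference population code (see
#'   \code{\link{pick_ld_population}}).
#' @return object of class \code{finemap_set}: \code{index_vid},
#'   \code{ld_population}, \code{members} (data.frame vid, r2, ordered
#'   by position), \code{n_excluded_triallelic}, \code{n_excluded_rare}.
#' @export
select_proxies <- function(panel, index_vid, params = design_params(),
                           population) {
  ji <- match(index_vid, panel$sites$vid)
  if (is.na(ji)) stop("index variant not in panel: ", index_vid)
  n_alt <- n_alt_alleles(panel)
  if (n_alt[ji] >= 2L)
    stop("index variant ", index_vid, " is triallelic; fine-mapping ",
         "requires a biallelic index")
  rows <- .pop_hap_rows(panel, population)
  hi <- panel$alleles[rows, ji]
  if (all(hi == hi[1]))
    stop("index variant ", index_vid, " is monomorphic in population ",
         population)
  half <- params$finemap_window_bp / 2
  same <- panel$sites$chrom == panel$sites$chrom[ji]
  dist <- abs(panel$sites$pos - panel$sites$pos[ji])
  in_win <- same & dist <= half & seq_len(nrow(panel$sites)) != ji

  tri <- in_win & n_alt >= 2L
  mafs <- .maf_vector(panel, population)
  rare <- in_win & !tri & mafs < 0.01
  cand <- which(in_win & !tri & !rare)

  keep_vid <- character(); keep_r2 <- numeric()
  for (j in cand) {
    r2 <- ld_pair(hi, panel$alleles[rows, j])$r2
    if (!is.na(r2) && r2 >= params$finemap_r2) {
      keep_vid <- c(keep_vid, panel$sites$vid[j])
      keep_r2 <- c(keep_r2, r2)
    }
  }
  members <- data.frame(vid = c(index_vid, keep_vid),
                        r2 = c(1, keep_r2), stringsAsFactors = FALSE)
  members <- members[order(match(members$vid, panel$sites$vid)), ,
                     drop = FALSE]
  rownames(members) <- NULL
  structure(list(index_vid = index_vid, ld_population = population,
                 members = members,
                 n_excluded_triallelic = sum(tri),
                 n_excluded_rare = sum(rare)),
            class = "finemap_set")
}

#' @export
print.finemap_set <- function(x, ...) {
  cat("finemap_set: index", x$index_vid, "(LD pop", x$ld_population, "):",
      nrow(x$members), "members;",
      x$n_excluded_triallelic, "triallelic and",
      x$n_excluded_rare, "rare candidates excluded\n")
  invisible(x)
}

#' Batch fine-mapping over ranked loci
#'
#' Runs \code{\link{select_proxies}} for each ranked locus, choosing the
#' LD reference population from the locus's discovery ancestry, and
#' summarizes per-locus member counts.
#'
#' @param panel a \code{hap_panel}.
#' @param ranked_loci data.frame from \code{\link{rank_associations}};
#'   must contain \code{vid} and \code{ancestry} (semicolon-joined
#'   labels).
#' @param params a \code{\link{design_params}}.
#' @param sd_type "sample" (n-1 denominator, default) or "population"
#'   for the manifest SD of per-locus counts.
#' @return list with \code{sets} (one \code{finemap_set} per locus),
#'   \code{manifest} (per-locus counts), \code{mean_members},
#'   \code{sd_members}, \code{max_members}, \code{skipped} (loci whose
#'   index is absent from the panel), and \code{all_members} (deduped
#'   vid union across loci).
#' @export
finemap_batch <- function(panel, ranked_loci, params = design_params(),
                          sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("vid", "ancestry") %in% names(ranked_loci)))
  present <- ranked_loci$vid %in% panel$sites$vid
  skipped <- ranked_loci$vid[!present]
  loci <- ranked_loci[present, , drop = FALSE]
  sets <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    anc <- strsplit(loci$ancestry[i], ";", fixed = TRUE)[[1]]
    pop <- as.character(pick_ld_population(anc))
    sets[[i]] <- select_proxies(panel, loci$vid[i], params, pop)
  }
  counts <- vapply(sets, function(s) nrow(s$members), integer(1))
  n <- length(counts)
  sdv <- if (n >= 2) {
    if (sd_type == "sample") sd(counts)
    else sqrt(mean((counts - mean(counts))^2))
  } else NA_real_
  manifest <- data.frame(
    index_vid = loci$vid,
    ld_population = vapply(sets, `[[`, character(1), "ld_population"),
    n_members = counts,
    n_excluded_triallelic = vapply(sets, `[[`, integer(1),
                                   "n_excluded_triallelic"),
    n_excluded_rare = vapply(sets, `[[`, integer(1), "n_excluded_rare"),
    stringsAsFactors = FALSE)
  all_members <- unique(unlist(lapply(sets, function(s) s$members$vid)))
  list(sets = sets, manifest = manifest,
       mean_members = if (n) mean(counts) else NA_real_,
       sd_members = sdv,
       max_members = if (n) max(counts) else NA_integer_,
       skipped = skipped, all_members = all_members)
}
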