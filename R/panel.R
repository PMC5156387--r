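#' Phased haplotype panel
#'
#' Container for a phased multi-population haplotype panel: a site table,
#' a sample table with population labels, and an integer allele matrix of
#' shape (2 x n_samples) x n_sites.  Sites are kept strictly sorted by
#' (chrom, pos); multiallelic sites are stored intact (alt alleles
#' comma-joined) so triallelic exclusion rules can act on them.  Allele
#' matrix entries are allele indices: 0 = REF, k = k-th ALT.  No missing
#' data: every downstream LD and imputation formula assumes complete
#' haplotypes.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{vid}, \code{ref}, \code{alt} (comma-joined for multiallelics);
#'   optional \code{design_score} (in \code{[0,1]} or \code{NA}) and
#'   \code{categories} (comma-joined content-category tags, "" for none).
#' @param samples data.frame with columns \code{sample_id},
#'   \code{population}.
#' @param alleles integer matrix, rows = haplotypes (two consecutive rows
#'   per sample, in \code{samples} order), columns = sites in \code{sites}
#'   order.
#' @return object of class \code{hap_panel} with per-population alternate
#'   allele frequencies precomputed in \code{$pop_af} (for multiallelic
#'   sites, the frequency of any non-reference allele).
#' @export
hap_panel <- function(sites, samples, alleles) {
  stopifnot(is.data.frame(sites), is.data.frame(samples), is.matrix(alleles))
  req <- c("chrom", "pos", "vid", "ref", "alt")
  if (!all(req %in% names(sites)))
    stop("sites must have columns: ", paste(req, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("samples must have columns sample_id, population")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples")
  if (is.null(sites$design_score)) sites$design_score <- NA_real_
  if (is.null(sites$categories)) sites$categories <- ""
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  if (any(!nzchar(sites$ref)) || any(!nzchar(sites$alt)))
    stop("ref and alt alleles must be non-empty")
  ord <- order(sites$chrom, sites$pos, sites$vid)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    alleles <- alleles[, ord, drop = FALSE]
  }
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom,pos,ref,alt) site")
  if (anyDuplicated(sites$vid)) stop("duplicate vid in sites")
  rownames(sites) <- NULL
  if (nrow(alleles) != 2L * nrow(samples))
    stop("allele matrix must have 2 rows per sample")
  if (ncol(alleles) != nrow(sites))
    stop("allele matrix must have one column per site")
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles)) stop("missing allele calls are not allowed")
  n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  bad <- which(apply(alleles, 2, max) > n_alt | apply(alleles, 2, min) < 0L)
  if (length(bad))
    stop("allele index out of range at site ", sites$vid[bad[1]])
  colnames(alleles) <- sites$vid
  rownames(alleles) <- paste(rep(samples$sample_id, each = 2L),
                             rep(1:2, nrow(samples)), sep = "|")
  obj <- structure(list(sites = sites, samples = samples, alleles = alleles,
                        pop_af = NULL),
                   class = "hap_panel")
  obj$pop_af <- .panel_pop_af(obj)
  obj
}

# per-population alternate (non-reference) allele frequency matrix,
# n_sites x n_populations
.panel_pop_af <- function(panel) {
  pops <- sort(unique(panel$samples$population))
  hap_pop <- rep(panel$samples$population, each = 2L)
  af <- vapply(pops, function(p) {
    rows <- hap_pop == p
    colMeans(panel$alleles[rows, , drop = FALSE] > 0L)
  }, numeric(nrow(panel$sites)))
  af <- matrix(af, nrow = nrow(panel$sites),
               dimnames = list(panel$sites$vid, pops))
  af
}

#' @export
print.hap_panel <- function(x, ...) {
  pops <- table(x$samples$population)
  cat("hap_panel:", nrow(x$sites), "sites x", nrow(x$samples), "samples (",
      nrow(x$alleles), "haplotypes )\n")
  cat("  chrom(s):", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  populations:",
      paste(sprintf("%s=%d", names(pops), pops), collapse = ", "), "\n")
  n_multi <- sum(n_alt_alleles(x) >= 2L)
  if (n_multi) cat("  multiallelic sites:", n_multi, "\n")
  invisible(x)
}

#' Number of alternate alleles per site
#' @param panel a \code{hap_panel}.
#' @return integer vector named by vid; sites with 2 or more are
#'   "triallelic-or-more".
#' @export
n_alt_alleles <- function(panel) {
  setNames(lengths(strsplit(panel$sites$alt, ",", fixed = TRUE)),
           panel$sites$vid)
}

#' @rdname n_alt_alleles
#' @export
is_biallelic <- function(panel) n_alt_alleles(panel) == 1L

# haplotype row indices belonging to one population (or all, p = NULL)
.pop_hap_rows <- function(panel, population = NULL) {
  if (is.null(population)) return(seq_len(nrow(panel$alleles)))
  keep <- panel$samples$population == population
  if (!any(keep)) stop("unknown population: ", population,
                       " (panel has: ",
                       paste(sort(unique(panel$samples$population)),
                             collapse = ", "), ")")
  which(rep(keep, each = 2L))
}

#' Subset a panel by site or sample
#'
#' @param panel a \code{hap_panel}.
#' @param vids site ids to keep (in panel order).
#' @param drop_samples sample ids to remove.
#' @return a new \code{hap_panel} (frequencies recomputed).
#' @export
subset_panel <- function(panel, vids = NULL, drop_samples = NULL) {
  sites <- panel$sites
  alleles <- panel$alleles
  samples <- panel$samples
  if (!is.null(vids)) {
    idx <- match(vids, sites$vid)
    if (anyNA(idx)) stop("unknown vid: ", vids[which(is.na(idx))[1]])
    idx <- sort(idx)
    sites <- sites[idx, , drop = FALSE]
    alleles <- alleles[, idx, drop = FALSE]
  }
  if (!is.null(drop_samples)) {
    keep <- !(samples$sample_id %in% drop_samples)
    samples <- samples[keep, , drop = FALSE]
    alleles <- alleles[rep(keep, each = 2L), , drop = FALSE]
  }
  rownames(samples) <- NULL
  hap_panel(sites, samples, alleles)
}
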