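#' Read a sample-to-population panel table
#'
#' @param path TSV with columns \code{sample_id} and \code{population}
#'   (header required).
#' @param populations optional declared population set; labels outside it
#'   are an error.  Default: the six continental super-populations
#'   AAC, AFR, AMR, ASN, EUR, SAS plus whatever the file contains if
#'   \code{populations = NULL}.
#' @return data.frame (sample_id, population).
#' @export
read_population_panel <- function(path, populations = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "population") %in% names(df)))
    stop("population panel needs columns sample_id, population")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in population panel")
  if (!is.null(populations)) {
    bad <- setdiff(unique(df$population), populations)
    if (length(bad))
      stop("population codes not in declared set: ",
           paste(bad, collapse = ", "))
  }
  df[c("sample_id", "population")]
}

#' Read phased genotypes from VCF into a haplotype panel
#'
#' Loads biallelic and multiallelic SNVs from a VCF (plain or gzipped)
#' into a \code{\link{hap_panel}}.  All genotypes must be phased
#' (\code{|} separator) and complete; per-population alternate-allele
#' frequencies are computed at load.  Multiallelic records are loaded
#' intact (not split) so that triallelic exclusion rules can act on them.
#'
#' @param path VCF file.
#' @param panel sample-to-population table as returned by
#'   \code{\link{read_population_panel}}.
#' @param region optional \code{\link{region_set}}; only sites inside are
#'   retained.
#' @param drop_unlisted if \code{TRUE}, VCF samples absent from
#'   \code{panel} are dropped; otherwise they are an error.
#' @param impute_missing_as_ref escape hatch for user data with missing
#'   genotypes: replace \code{.} alleles by REF, with a loud warning.
#'   Default is to reject missing data.
#' @return a \code{hap_panel}.
#' @export
read_phased_vcf <- function(path, panel, region = NULL,
                            drop_unlisted = FALSE,
                            impute_missing_as_ref = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  id <- as.character(fix[, "ID"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  vid <- ifelse(is.na(id) | id == ".", paste(chrom, pos, ref, alt, sep = ":"), id)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(vid))
  vcf_samples <- colnames(v@gt)[-1]
  colnames(gt) <- vcf_samples

  extra <- setdiff(vcf_samples, panel$sample_id)
  if (length(extra)) {
    if (!drop_unlisted)
      stop("VCF sample(s) absent from population panel: ",
           paste(head(extra, 5), collapse = ", "),
           " (use drop_unlisted = TRUE to drop them)")
    gt <- gt[, setdiff(vcf_samples, extra), drop = FALSE]
    vcf_samples <- colnames(gt)
  }

  keep <- rep(TRUE, length(vid))
  if (!is.null(region)) keep <- in_regions(region, chrom, pos)
  if (!any(keep)) stop("no VCF sites in requested region")
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
  alt <- alt[keep]; vid <- vid[keep]

  if (anyNA(gt)) {
    if (!impute_missing_as_ref) {
      w <- which(is.na(gt), arr.ind = TRUE)[1, ]
      stop("missing genotype for sample ", vcf_samples[w[2]],
           " at site ", vid[w[1]],
           " (use impute_missing_as_ref = TRUE to treat as REF)")
    }
    warning("imputing ", sum(is.na(gt)), " missing genotypes as REF (0|0)")
    gt[is.na(gt)] <- "0|0"
  }
  unph <- grepl("/", gt, fixed = TRUE)
  if (any(unph)) {
    w <- which(matrix(unph, nrow = nrow(gt)), arr.ind = TRUE)[1, ]
    stop("unphased genotype for sample ", vcf_samples[w[2]],
         " at site ", vid[w[1]], ": all genotypes must be phased (a|b)")
  }
  part <- grepl(".", gt, fixed = TRUE)
  if (any(part)) {
    if (!impute_missing_as_ref)
      stop("missing allele call ('.') found; use impute_missing_as_ref = TRUE")
    warning("imputing partially missing allele calls as REF")
    gt <- gsub(".", "0", gt, fixed = TRUE)
  }

  # split "a|b" into two haplotype rows per sample; gt is sites x samples
  a1 <- sub("\\|.*", "", gt)
  a2 <- sub(".*\\|", "", gt)
  n_s <- ncol(gt); n_v <- nrow(gt)
  alleles <- matrix(0L, nrow = 2L * n_s, ncol = n_v)
  alleles[seq(1L, 2L * n_s, by = 2L), ] <- t(matrix(as.integer(a1), n_v, n_s))
  alleles[seq(2L, 2L * n_s, by = 2L), ] <- t(matrix(as.integer(a2), n_v, n_s))

  samples <- panel[match(vcf_samples, panel$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  sites <- data.frame(chrom = chrom, pos = pos, vid = vid, ref = ref,
                      alt = alt, stringsAsFactors = FALSE)
  hap_panel(sites, samples, alleles)
}

#' Write a haplotype panel as phased VCF
#'
#' Deterministic plain-text VCF 4.2 writer; CHROM/POS/ID/REF/ALT/GT
#' round-trip exactly through \code{\link{read_phased_vcf}}.
#'
#' @param panel a \code{hap_panel}.
#' @param path output file.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=megadesign",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples$sample_id),
                     collapse = "\t")), con)
  al <- panel$alleles
  h1 <- al[seq(1L, nrow(al), by = 2L), , drop = FALSE]
  h2 <- al[seq(2L, nrow(al), by = 2L), , drop = FALSE]
  for (j in seq_len(nrow(panel$sites))) {
    s <- panel$sites[j, ]
    gts <- paste(h1[, j], h2[, j], sep = "|")
    writeLines(paste(c(s$chrom, s$pos, s$vid, s$ref, s$alt, ".", ".", ".",
                       "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write and read site tables
#'
#' Site tables are TSVs with one row per variant site: \code{vid, chrom,
#' pos, ref, alt}, one alternate-allele-frequency column per population
#' (\code{af_<POP>}), \code{design_score} and \code{categories}
#' (comma-joined).  Rows are ordered by (chrom, pos, vid); writers are
#' deterministic.
#'
#' @param sites data.frame of sites (as in \code{hap_panel$sites});
#'   frequency columns \code{af_*} are written if present.
#' @param path file path.
#' @return \code{read_site_table} returns the data.frame.
#' @export
write_site_table <- function(sites, path) {
  if (nrow(sites) == 0) stop("refusing to write an empty site table")
  if (is.null(sites$design_score)) sites$design_score <- NA_real_
  if (is.null(sites$categories)) sites$categories <- ""
  ord <- order(sites$chrom, sites$pos, sites$vid)
  sites <- sites[ord, , drop = FALSE]
  af_cols <- grep("^af_", names(sites), value = TRUE)
  cols <- c("vid", "chrom", "pos", "ref", "alt", af_cols,
            "design_score", "categories")
  write.table(sites[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = NA, na.strings = "NA")
  df$chrom <- as.character(df$chrom)
  df$categories <- ifelse(is.na(df$categories), "", as.character(df$categories))
  df
}

#' Attach per-population frequency columns to a panel's site table
#'
#' @param panel a \code{hap_panel}.
#' @return the panel's site data.frame with one \code{af_<POP>} column per
#'   population, ready for \code{\link{write_site_table}}.
#' @export
site_table <- function(panel) {
  sites <- panel$sites
  af <- panel$pop_af
  for (p in colnames(af)) sites[[paste0("af_", p)]] <- unname(af[, p])
  sites
}

#' Write and read BED intervals
#'
#' Standard BED (0-based, half-open), sorted; the fourth column carries
#' the region label.
#'
#' @param regions a \code{\link{region_set}}.
#' @param path file path.
#' @return \code{read_bed} returns a \code{region_set}.
#' @export
write_bed <- function(regions, path) {
  df <- as.data.frame(regions)[, c("chrom", "start", "end", "label")]
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(region_set())
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  lab <- if (ncol(df) >= 4) df[[4]] else NULL
  region_set(df$chrom, df$start, df$end, lab)
}
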