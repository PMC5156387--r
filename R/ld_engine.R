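#' Pairwise LD from phased haplotypes
#'
#' Computes r-squared and D' from the 2x2 haplotype table of two binary
#' allele vectors (biallelic sites):
#' \deqn{r^2 = (p_{ab} - p_a p_b)^2 / (p_a(1-p_a) p_b(1-p_b))}
#' where \eqn{p_{ab}} is the frequency of the (1,1) haplotype
#' configuration.  LD is undefined when either site is monomorphic in the
#' vectors supplied; the distinguished value \code{NA} (not 0) is
#' returned so callers can treat such targets as uncoverable rather than
#' silently covered.
#'
#' @param h_a,h_b equal-length binary haplotype allele vectors (length
#'   at least 2).
#' @return list with \code{r2}, \code{d_prime} (both \code{NA} when LD is
#'   undefined) and \code{defined}.
#' @export
ld_pair <- function(h_a, h_b) {
  stopifnot(length(h_a) == length(h_b), length(h_a) >= 2)
  if (any(h_a > 1L) || any(h_b > 1L))
    stop("ld_pair accepts only biallelic (0/1) haplotype vectors")
  pa <- mean(h_a); pb <- mean(h_b)
  if (pa == 0 || pa == 1 || pb == 0 || pb == 1)
    return(list(r2 = NA_real_, d_prime = NA_real_, defined = FALSE))
  pab <- mean(h_a == 1L & h_b == 1L)
  D <- pab - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  if (r2 > 1 + 1e-12) stop("r2 exceeded 1 beyond numerical tolerance")
  r2 <- min(max(r2, 0), 1)
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  dp <- if (dmax == 0) 0 else abs(D) / dmax
  dp <- min(max(dp, 0), 1)
  list(r2 = r2, d_prime = dp, defined = TRUE)
}

#' @rdname ld_pair
#' @return \code{r2_phased} returns just the r-squared value (\code{NA}
#'   when undefined).
#' @export
r2_phased <- function(h_a, h_b) ld_pair(h_a, h_b)$r2

# r2 matrix among a set of biallelic columns of a haplotype matrix X
# (rows = haplotypes).  Monomorphic columns give NA rows/cols.
.r2_matrix <- function(X) {
  n <- nrow(X)
  p <- colMeans(X)
  P11 <- crossprod(X) / n
  D <- P11 - tcrossprod(p)
  denom <- tcrossprod(p * (1 - p))
  r2 <- D^2 / denom
  r2[!is.finite(r2)] <- NA_real_
  r2[denom == 0] <- NA_real_
  r2 <- pmin(pmax(r2, 0), 1)
  mono <- p == 0 | p == 1
  r2[mono, ] <- NA_real_
  r2[, mono] <- NA_real_
  diag(r2)[!mono] <- 1
  r2
}

#' Minor allele frequency of a site in one population
#'
#' Folded frequency \code{min(f, 1-f)} of the alternate allele among the
#' population's haplotypes; for multiallelic sites, one minus the
#' frequency of the most common allele.
#'
#' @param panel a \code{hap_panel}.
#' @param vid site id.
#' @param population population code (or \code{NULL} for all samples).
#' @return MAF value; at most 0.5 for biallelic sites, bounded by
#'   \code{1 - 1/n_alleles} for multiallelic ones.
#' @export
maf <- function(panel, vid, population = NULL) {
  j <- match(vid, panel$sites$vid)
  if (is.na(j)) stop("unknown vid: ", vid)
  rows <- .pop_hap_rows(panel, population)
  x <- panel$alleles[rows, j]
  tab <- tabulate(x + 1L, nbins = max(x) + 1L)
  1 - max(tab) / length(x)
}

# MAF for every site in a population, vectorized (biallelic: fold alt AF;
# multiallelic: 1 - max allele frequency)
.maf_vector <- function(panel, population = NULL) {
  rows <- .pop_hap_rows(panel, population)
  X <- panel$alleles[rows, , drop = FALSE]
  n_alt <- n_alt_alleles(panel)
  f_alt <- colMeans(X > 0L)
  m <- pmin(f_alt, 1 - f_alt)
  multi <- which(n_alt >= 2L)
  for (j in multi) {
    tab <- tabulate(X[, j] + 1L, nbins = n_alt[j] + 1L)
    m[j] <- 1 - max(tab) / nrow(X)
  }
  setNames(m, panel$sites$vid)
}

#' Windowed LD around a focal site
#'
#' One LD result per biallelic site within \code{window_bp} of the focal
#' site on the same chromosome (focal excluded).  Sites with undefined LD
#' (monomorphic in the population) are omitted; their count is returned
#' in the \code{n_undefined} attribute.
#'
#' @param panel a \code{hap_panel}.
#' @param focal focal site vid (must be biallelic and polymorphic in the
#'   population).
#' @param window_bp maximum distance in bp.
#' @param population population code in which LD is computed.
#' @return data.frame (vid_a, vid_b, population, r2, d_prime,
#'   distance_bp), with attribute \code{n_undefined}.
#' @export
windowed_ld <- function(panel, focal, window_bp, population) {
  jf <- match(focal, panel$sites$vid)
  if (is.na(jf)) stop("focal site not in panel: ", focal)
  if (n_alt_alleles(panel)[jf] != 1L)
    stop("focal site is not biallelic: ", focal)
  rows <- .pop_hap_rows(panel, population)
  hf <- panel$alleles[rows, jf]
  if (all(hf == hf[1]))
    stop("focal site ", focal, " is monomorphic in population ", population)
  same <- panel$sites$chrom == panel$sites$chrom[jf]
  dist <- abs(panel$sites$pos - panel$sites$pos[jf])
  cand <- which(same & dist <= window_bp & is_biallelic(panel) &
                  seq_len(nrow(panel$sites)) != jf)
  out <- data.frame(vid_a = character(), vid_b = character(),
                    population = character(), r2 = numeric(),
                    d_prime = numeric(), distance_bp = integer(),
                    stringsAsFactors = FALSE)
  n_undef <- 0L
  if (length(cand)) {
    res <- lapply(cand, function(j) ld_pair(hf, panel$alleles[rows, j]))
    def <- vapply(res, `[[`, logical(1), "defined")
    n_undef <- sum(!def)
    if (any(def)) {
      keep <- cand[def]
      out <- data.frame(
        vid_a = focal,
        vid_b = panel$sites$vid[keep],
        population = population,
        r2 = vapply(res[def], `[[`, numeric(1), "r2"),
        d_prime = vapply(res[def], `[[`, numeric(1), "d_prime"),
        distance_bp = as.integer(dist[keep]),
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "n_undefined") <- n_undef
  out
}
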