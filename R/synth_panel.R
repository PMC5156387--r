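#' Simulation parameters for synthetic multi-population panels
#'
#' The simulator has two layers.  Allele frequencies diverge across
#' populations under the Balding-Nichols model: an ancestral frequency
#' \eqn{p \sim Beta(a, b)} per site, then each population draws its own
#' frequency from \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)}, which has mean
#' \eqn{p} and variance \eqn{p(1-p)F}.  Haplotypes then come from a
#' founder-mosaic model: per population a small pool of founder
#' haplotypes is drawn site-wise Bernoulli(population frequency), and
#' each sample haplotype copies a founder, switching founders between
#' adjacent sites with probability \eqn{1 - \exp(-\rho d)} (distance
#' \eqn{d} in bp), plus a per-site allele flip.  Fewer founders and lower
#' switch rates give stronger, longer-range LD.
#'
#' Defaults emulate a 1000 Genomes-style continental panel at desk scale:
#' six populations of 100 samples, 500 SNVs on a 200 kb chromosome, FST
#' between 0.05 and 0.12 (the human continental range), and a strongly
#' U-shaped ancestral frequency spectrum (real sequence panels are
#' dominated by rare variation).  The founder pool size balances two
#' representational constraints: pool allele-frequency granularity
#' (1/n_founders) must reach the rarest analysed MAF stratum, while each
#' founder must be copied by more than one sample haplotype so that
#' haplotypes share segments the way panel members do (copies per founder
#' = haplotypes/founders).  At 100 founders per 200-haplotype population
#' the granularity is 1\% and expected sharing is 2.  The flip (private
#' mutation) rate sits well below the rarest stratum so
#' linkage-equilibrium noise does not masquerade as rare variation, and
#' the 1e-5/bp switch rate makes LD decay appreciably across the region.
#'
#' @param n_sites number of variant sites.
#' @param chrom_length chromosome length in bp.
#' @param n_samples_per_pop named integer vector, samples per population.
#' @param fst named vector of Balding-Nichols F values in (0,1).
#' @param beta_shape length-2 shape of the ancestral frequency Beta.
#' @param n_founders founder haplotypes per population (>= 1).
#' @param switch_rate founder-switch intensity per bp (>= 0).
#' @param flip_rate per-site allele flip (private mutation) probability.
#' @param seed integer RNG seed; same seed, same panel.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(n_sites = 500L,
                       chrom_length = 200000L,
                       n_samples_per_pop = c(AAC = 100L, AFR = 100L,
                                             AMR = 100L, ASN = 100L,
                                             EUR = 100L, SAS = 100L),
                       fst = c(AAC = 0.05, AFR = 0.08, AMR = 0.07,
                               ASN = 0.12, EUR = 0.10, SAS = 0.10),
                       beta_shape = c(0.25, 0.25),
                       n_founders = 100L,
                       switch_rate = 1e-5,
                       flip_rate = 1e-5,
                       seed = 1L) {
  stopifnot(n_sites >= 1, chrom_length >= n_sites,
            length(n_samples_per_pop) >= 1,
            !is.null(names(n_samples_per_pop)),
            all(n_samples_per_pop >= 1),
            all(names(n_samples_per_pop) %in% names(fst)),
            all(fst > 0), all(fst < 1),
            length(beta_shape) == 2, all(beta_shape > 0),
            n_founders >= 1, switch_rate >= 0,
            flip_rate >= 0, flip_rate <= 1)
  structure(list(n_sites = as.integer(n_sites),
                 chrom_length = as.integer(chrom_length),
                 n_samples_per_pop = n_samples_per_pop,
                 fst = fst[names(n_samples_per_pop)],
                 beta_shape = beta_shape,
                 n_founders = as.integer(n_founders),
                 switch_rate = switch_rate,
                 flip_rate = flip_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate population allele frequencies (Balding-Nichols)
#'
#' @param params a \code{\link{sim_params}}.
#' @return list with \code{ancestral} (vector of ancestral frequencies)
#'   and \code{pop} (matrix n_sites x populations).  Deterministic given
#'   \code{params$seed}.
#' @export
simulate_frequencies <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- rbeta(params$n_sites, params$beta_shape[1], params$beta_shape[2])
  pops <- names(params$n_samples_per_pop)
  popf <- vapply(pops, function(k) {
    f <- params$fst[[k]]
    rbeta(params$n_sites, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }, numeric(params$n_sites))
  popf <- matrix(popf, nrow = params$n_sites, dimnames = list(NULL, pops))
  list(ancestral = p, pop = popf)
}

#' Simulate phased haplotypes (founder mosaic)
#'
#' @param freqs output of \code{\link{simulate_frequencies}}.
#' @param params the same \code{\link{sim_params}}.
#' @return a \code{\link{hap_panel}} on chromosome \code{"1"} with site
#'   positions drawn uniformly without replacement on
#'   \code{[1, chrom_length]}.
#' @export
simulate_haplotypes <- function(freqs, params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_sites > params$chrom_length)
    stop("n_sites exceeds chrom_length")
  set.seed(params$seed + 1L)
  pos <- sort(sample.int(params$chrom_length, params$n_sites))
  pops <- names(params$n_samples_per_pop)
  d <- diff(pos)
  p_switch <- 1 - exp(-params$switch_rate * d)

  hap_blocks <- vector("list", length(pops))
  names(hap_blocks) <- pops
  for (k in pops) {
    nf <- params$n_founders
    founders <- matrix(rbinom(nf * params$n_sites, 1L, rep(freqs$pop[, k], each = nf)),
                       nrow = nf)
    n_hap <- 2L * params$n_samples_per_pop[[k]]
    H <- matrix(0L, nrow = n_hap, ncol = params$n_sites)
    # founder index path per haplotype: switch between adjacent sites
    idx <- sample.int(nf, n_hap, replace = TRUE)
    H[, 1] <- founders[cbind(idx, 1L)]
    for (j in seq_len(params$n_sites - 1L)) {
      sw <- runif(n_hap) < p_switch[j]
      if (any(sw)) idx[sw] <- sample.int(nf, sum(sw), replace = TRUE)
      H[, j + 1L] <- founders[cbind(idx, j + 1L)]
    }
    if (params$flip_rate > 0) {
      flips <- matrix(runif(length(H)) < params$flip_rate, nrow = n_hap)
      H[flips] <- 1L - H[flips]
    }
    hap_blocks[[k]] <- H
  }
  alleles <- do.call(rbind, hap_blocks)
  samples <- data.frame(
    sample_id = unlist(lapply(pops, function(k)
      sprintf("%s%04d", k, seq_len(params$n_samples_per_pop[[k]])))),
    population = rep(pops, times = unlist(params$n_samples_per_pop)),
    stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "1", pos = pos,
                      vid = sprintf("1:%d:A:G", pos),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  hap_panel(sites, samples, alleles)
}

#' One-call synthetic panel
#'
#' @param params a \code{\link{sim_params}}.
#' @return list with \code{panel} (a \code{hap_panel}) and \code{freqs}
#'   (the simulated true frequencies).
#' @export
synth_panel <- function(params = sim_params()) {
  freqs <- simulate_frequencies(params)
  panel <- simulate_haplotypes(freqs, params)
  list(panel = panel, freqs = freqs)
}
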