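# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementation paths.

# r2 / D' from explicit 2x2 haplotype contingency-table counts
oracle_ld <- function(ha, hb) {
  n <- length(ha)
  n11 <- sum(ha == 1 & hb == 1)
  n10 <- sum(ha == 1 & hb == 0)
  n01 <- sum(ha == 0 & hb == 1)
  n00 <- sum(ha == 0 & hb == 0)
  pa <- (n11 + n10) / n
  pb <- (n11 + n01) / n
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    return(list(r2 = NA_real_, d_prime = NA_real_))
  D <- n11 / n - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  list(r2 = r2, d_prime = if (dmax == 0) 0 else abs(D) / dmax)
}

# brute-force three-rule fine-mapping filter: enumerate all sites, apply
# window / triallelic / rare-MAF rules independently, then the r2 rule
oracle_finemap <- function(panel, index_vid, params, population) {
  ji <- match(index_vid, panel$sites$vid)
  rows <- which(rep(panel$samples$population == population, each = 2))
  hi <- panel$alleles[rows, ji]
  half <- params$finemap_window_bp / 2
  keep <- index_vid
  n_tri <- 0L; n_rare <- 0L
  for (j in seq_len(nrow(panel$sites))) {
    if (j == ji) next
    if (panel$sites$chrom[j] != panel$sites$chrom[ji]) next
    if (abs(panel$sites$pos[j] - panel$sites$pos[ji]) > half) next
    n_alt <- length(strsplit(panel$sites$alt[j], ",")[[1]])
    if (n_alt >= 2) { n_tri <- n_tri + 1L; next }
    x <- panel$alleles[rows, j]
    tab <- table(factor(x, levels = 0:n_alt))
    m <- 1 - max(tab) / length(x)
    if (m < 0.01) { n_rare <- n_rare + 1L; next }
    r2 <- oracle_ld(hi, x)$r2
    if (!is.na(r2) && r2 >= params$finemap_r2) keep <- c(keep, panel$sites$vid[j])
  }
  list(members = sort(keep), n_tri = n_tri, n_rare = n_rare)
}

# exhaustive minimum set cover: smallest number of candidate sets whose
# union covers the universe (universe/candidates as index vectors)
oracle_min_set_cover <- function(universe, cover_sets) {
  if (length(universe) == 0) return(0L)
  n <- length(cover_sets)
  stopifnot(n <= 14)
  best <- Inf
  for (mask in seq_len(2^n) - 1L) {
    chosen <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(chosen) >= best) next
    cov <- unique(unlist(cover_sets[chosen]))
    if (all(universe %in% cov)) best <- length(chosen)
  }
  best
}

# exhaustive hidden-path enumeration for the haploid copying model:
# posterior state probabilities at every site
oracle_ls_posterior <- function(ref, obs, pos, eps, rho) {
  H <- nrow(ref); S <- ncol(ref)
  q <- if (S > 1) 1 - exp(-rho * diff(pos)) else numeric(0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), S)))
  pr <- apply(paths, 1, function(k) {
    p <- 1 / H
    for (s in seq_len(S)) {
      p <- p * if (ref[k[s], s] == obs[s]) 1 - eps else eps
      if (s < S) {
        same <- k[s + 1] == k[s]
        p <- p * ((1 - q[s]) * same + q[s] / H)
      }
    }
    p
  })
  post <- matrix(0, H, S)
  for (s in seq_len(S)) for (k in seq_len(H))
    post[k, s] <- sum(pr[paths[, s] == k])
  sweep(post, 2, colSums(post), "/")
}

# covered basepairs of an interval union by boolean mask on a toy chromosome
oracle_covered_bp <- function(starts, ends, L) {
  mask <- logical(L)
  for (i in seq_along(starts)) mask[(starts[i] + 1):ends[i]] <- TRUE
  sum(mask)
}

# build a hap_panel directly from an allele matrix (rows = haplotypes,
# two consecutive rows per sample), positions, and population labels
toy_panel <- function(alleles, pos, populations, chrom = "1",
                      alt = NULL, design_score = NULL) {
  n_s <- nrow(alleles) / 2
  stopifnot(n_s == length(populations))
  if (is.null(alt)) alt <- rep("G", length(pos))
  sites <- data.frame(chrom = chrom, pos = pos,
                      vid = paste0("v", seq_along(pos)),
                      ref = "A", alt = alt, stringsAsFactors = FALSE)
  if (!is.null(design_score)) sites$design_score <- design_score
  samples <- data.frame(sample_id = sprintf("S%03d", seq_len(n_s)),
                        population = populations,
                        stringsAsFactors = FALSE)
  hap_panel(sites, samples, alleles)
}

# random biallelic panel for property tests
random_panel <- function(n_sites, n_samples, pops = "POP", seed = 1,
                         chrom_length = 100000L) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_sites))
  f <- runif(n_sites, 0.05, 0.95)
  al <- matrix(rbinom(2 * n_samples * n_sites, 1, rep(f, each = 2 * n_samples)),
               nrow = 2 * n_samples)
  toy_panel(al, pos, rep_len(pops, n_samples))
}
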