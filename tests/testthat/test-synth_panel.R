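test_that("population frequencies collapse to the ancestral values as F -> 0", {
  p <- sim_params(n_sites = 1000, chrom_length = 1e6,
                  n_samples_per_pop = c(EUR = 5),
                  fst = c(EUR = 1e-6), seed = 2)
  fr <- simulate_frequencies(p)
  expect_true(mean(abs(fr$pop[, "EUR"] - fr$ancestral) < 0.01) > 0.999)
})

test_that("Balding-Nichols conditional variance matches p(1-p)F", {
  # pin the ancestral frequency near 0.5 with a huge symmetric Beta
  p <- sim_params(n_sites = 10000, chrom_length = 1e6,
                  n_samples_per_pop = c(EUR = 5), fst = c(EUR = 0.1),
                  beta_shape = c(1e7, 1e7), seed = 4)
  fr <- simulate_frequencies(p)
  expect_lt(abs(var(fr$pop[, "EUR"]) - 0.025) / 0.025, 0.10)
})

test_that("simulation is deterministic in the seed", {
  p1 <- sim_params(n_sites = 50, chrom_length = 10000,
                   n_samples_per_pop = c(EUR = 10), fst = c(EUR = 0.1),
                   seed = 9)
  p2 <- sim_params(n_sites = 50, chrom_length = 10000,
                   n_samples_per_pop = c(EUR = 10), fst = c(EUR = 0.1),
                   seed = 10)
  a <- synth_panel(p1); b <- synth_panel(p1); c <- synth_panel(p2)
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$freqs, b$freqs)
  expect_false(identical(a$panel$alleles, c$panel$alleles))
})

test_that("degenerate founder pools behave as expected", {
  # one founder, no flips: every haplotype in a population is identical
  p <- sim_params(n_sites = 40, chrom_length = 5000,
                  n_samples_per_pop = c(EUR = 10), fst = c(EUR = 0.2),
                  n_founders = 1, flip_rate = 0, seed = 3)
  pan <- synth_panel(p)$panel
  expect_true(all(apply(pan$alleles, 2, function(x) length(unique(x)) == 1)))

  # two founders, no switching, no flips: every polymorphic pair has r2 = 1
  p2 <- sim_params(n_sites = 30, chrom_length = 5000,
                   n_samples_per_pop = c(EUR = 20), fst = c(EUR = 0.2),
                   n_founders = 2, switch_rate = 0, flip_rate = 0, seed = 5)
  pan2 <- synth_panel(p2)$panel
  poly <- which(apply(pan2$alleles, 2, function(x) var(x) > 0))
  if (length(poly) >= 2) {
    combos <- combn(poly[seq_len(min(6, length(poly)))], 2)
    for (i in seq_len(ncol(combos))) {
      r2 <- r2_phased(pan2$alleles[, combos[1, i]],
                      pan2$alleles[, combos[2, i]])
      expect_equal(r2, 1)
    }
  }
})

test_that("LD decays with distance (Spearman trend < 0 over seeds)", {
  trends <- vapply(1:5, function(sd_) {
    p <- sim_params(n_sites = 200, chrom_length = 200000,
                    n_samples_per_pop = c(EUR = 50), fst = c(EUR = 0.1),
                    n_founders = 20, switch_rate = 1e-5, flip_rate = 0,
                    seed = sd_)
    pan <- synth_panel(p)$panel
    X <- pan$alleles
    f <- colMeans(X)
    poly <- which(f > 0.05 & f < 0.95)
    set.seed(sd_)
    pairs <- t(combn(sample(poly, min(40, length(poly))), 2))
    r2 <- apply(pairs, 1, function(ij) r2_phased(X[, ij[1]], X[, ij[2]]))
    d <- abs(pan$sites$pos[pairs[, 1]] - pan$sites$pos[pairs[, 2]])
    ok <- !is.na(r2)
    # mean r2 in distance bins must be non-increasing overall
    bins <- cut(d[ok], breaks = quantile(d[ok], 0:4 / 4),
                include.lowest = TRUE)
    m <- tapply(r2[ok], bins, mean)
    cor(seq_along(m), m, method = "spearman")
  }, numeric(1))
  expect_true(all(trends < 0))
})

test_that("empirical MAF tracks the folded simulated frequency at n = 500", {
  p <- sim_params(n_sites = 300, chrom_length = 1e5,
                  n_samples_per_pop = c(EUR = 500), fst = c(EUR = 0.05),
                  n_founders = 2000, flip_rate = 0, seed = 6)
  sim <- synth_panel(p)
  emp <- pmin(colMeans(sim$panel$alleles), 1 - colMeans(sim$panel$alleles))
  truth <- pmin(sim$freqs$pop[, "EUR"], 1 - sim$freqs$pop[, "EUR"])
  expect_lt(mean(abs(emp - truth)), 0.02)
})

test_that("inter-population differentiation tracks the target FST", {
  for (f in c(0.05, 0.2)) {
    p <- sim_params(n_sites = 2000, chrom_length = 1e6,
                    n_samples_per_pop = c(A = 5, B = 5, C = 5, D = 5),
                    fst = c(A = f, B = f, C = f, D = f),
                    beta_shape = c(5, 5), seed = 8)
    fr <- simulate_frequencies(p)
    # per-site ratio of across-population variance to p(1-p), averaged
    anc <- fr$ancestral
    v <- apply(fr$pop, 1, var)
    est <- mean(v) / mean(anc * (1 - anc))
    expect_lt(abs(est - f) / f, 0.2)
  }
})

test_that("generator rejects impossible configurations", {
  expect_error(sim_params(n_sites = 100, chrom_length = 50),
               "chrom_length")
  p <- sim_params(n_sites = 10, chrom_length = 100,
                  n_samples_per_pop = c(EUR = 2), fst = c(EUR = 0.1))
  expect_s3_class(synth_panel(p)$panel, "hap_panel")
})
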