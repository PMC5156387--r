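ls_post <- megadesign:::.ls_posterior

test_that("forward-backward posteriors are normalized and match path enumeration", {
  set.seed(14)
  for (rep_ in 1:5) {
    H <- sample(2:4, 1); S <- sample(3:5, 1)
    ref <- matrix(rbinom(H * S, 1, 0.5), H, S)
    obs <- rbinom(S, 1, 0.5)
    pos <- sort(sample.int(100000, S))
    ls <- ls_params(emission_error = 0.05, switch_rate = 1e-5)
    post <- ls_post(ref, obs, pos, ls)
    expect_true(all(abs(colSums(post) - 1) < 1e-9))
    oracle <- oracle_ls_posterior(ref, obs, pos, 0.05, 1e-5)
    expect_equal(post, oracle, tolerance = 1e-8)
  }
})

test_that("a single reference haplotype forces its own alleles", {
  ref <- matrix(c(1, 0, 1), 1, 3)
  post <- ls_post(ref, c(0, 0, 0), c(10, 20, 30), ls_params())
  expect_equal(as.numeric(post), c(1, 1, 1))
  # panel: focal sample + one other sample with two identical haplotypes
  al <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L),   # focal
              c(1L, 1L, 0L), c(1L, 1L, 0L))   # reference (identical pair)
  p <- toy_panel(al, pos = c(100, 200, 300), populations = c("EUR", "EUR"))
  d <- impute_dosage(p, "S001", scaffold = c("v1", "v3"), eval_sites = "v2")
  expect_equal(unname(d["v2"]), 2)   # both copies forced to allele 1
})

test_that("a perfect proxy on the scaffold recovers the true genotype", {
  set.seed(15)
  x <- rbinom(60, 1, 0.5)
  noise <- rbinom(60, 1, 0.5)
  al <- cbind(x, x, noise)        # v2 is an exact copy of scaffold site v1
  p <- toy_panel(al, pos = c(1000, 1100, 5000), populations = rep("EUR", 30))
  ls <- ls_params(emission_error = 1e-6, switch_rate = 1e-8)
  truth <- al[seq(1, 59, 2), 2] + al[seq(2, 60, 2), 2]
  for (i in c(1, 7, 20)) {
    d <- impute_dosage(p, p$samples$sample_id[i],
                       scaffold = c("v1", "v3"), eval_sites = "v2", ls)
    expect_equal(unname(d["v2"]), truth[i], tolerance = 1e-3)
  }
})

test_that("dosages are bounded and eval sites on the scaffold return truth", {
  p <- random_panel(12, 15, pops = "EUR", seed = 19)
  scaf <- p$sites$vid[c(1, 4, 8, 12)]
  d <- impute_dosage(p, "S001", scaf, p$sites$vid)
  expect_true(all(d >= 0 & d <= 2))
  obs <- attr(d, "observed")
  expect_equal(p$sites$vid[obs], scaf[order(match(scaf, p$sites$vid))])
  truth <- p$alleles[1, ] + p$alleles[2, ]
  expect_equal(unname(d[obs]), unname(truth[match(names(d)[obs],
                                                  p$sites$vid)]))
  expect_error(impute_dosage(p, "S001", character(0), "v1"), "zero scaffold")
  expect_error(impute_dosage(p, "nope", scaf, "v2"), "unknown sample")
})

test_that("observed eval sites give accuracy 100 in every populated bin", {
  p <- random_panel(10, 20, pops = c("EUR", "AFR"), seed = 25)
  scaf <- p$sites$vid
  rep_ <- loo_accuracy(p, scaf, p$sites$vid[c(2, 5, 9)])
  acc <- rep_$accuracy
  expect_true(all(abs(acc[rep_$n_sites > 0] - 100) < 1e-9))
})

test_that("populations with fewer than 3 samples are reported NA", {
  p <- random_panel(8, 10, pops = c(rep("EUR", 8), "TINY", "TINY"), seed = 33)
  rep_ <- loo_accuracy(p, p$sites$vid[c(1, 5)], p$sites$vid[c(3, 7)])
  expect_true(all(is.na(rep_$accuracy["TINY", ])))
})

test_that("identical scaffolds give zero delta; perfect proxies drive accuracy to 100", {
  set.seed(41)
  n <- 40
  base <- matrix(rbinom(2 * n * 4, 1, 0.5), 2 * n)
  # eval sites v5..v8 are exact copies of custom sites v1..v4
  al <- cbind(base, base)
  pos <- c(1000, 2000, 3000, 4000, 1100, 2100, 3100, 4100)
  p <- toy_panel(al[, order(pos)], sort(pos), rep("EUR", n))
  custom <- c("v2", "v4", "v6", "v8")   # copies interleave after sorting
  sparse <- c("v2", "v6")
  evals <- c("v1", "v3", "v5", "v7")
  stopifnot(!any(evals %in% custom))
  same <- compare_scaffolds(p, custom, custom, evals)
  expect_true(all(same$delta[same$n_sites > 0] == 0))
  rich <- compare_scaffolds(p, custom, sparse, evals)
  # every eval site has an exact-copy neighbour on the with-scaffold
  expect_true(all(rich$accuracy[rich$n_sites > 0] > 99))
})

test_that("the evaluator is deterministic", {
  p <- random_panel(15, 12, pops = "EUR", seed = 55)
  scaf <- p$sites$vid[c(1, 6, 11)]
  ev <- p$sites$vid[c(3, 8)]
  r1 <- loo_accuracy(p, scaf, ev)
  r2 <- loo_accuracy(p, scaf, ev)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("the reference cap limits the haplotypes used, deterministically", {
  p <- random_panel(10, 12, pops = "EUR", seed = 61)
  scaf <- p$sites$vid[c(2, 6, 9)]
  capped <- impute_dosage(p, "S005", scaf, "v4", ls_params(ref_cap = 4))
  expect_true(all(capped >= 0 & capped <= 2))
  # cap 4 keeps the first two samples' haplotypes: identical to running
  # uncapped on a panel holding only S001, S002 and the focal sample
  small <- subset_panel(p, drop_samples = p$samples$sample_id[c(3:4, 6:12)])
  expect_equal(unname(capped),
               unname(impute_dosage(small, "S005", scaf, "v4")))
})
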