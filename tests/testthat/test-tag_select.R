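# panel of k perfect-LD blocks: all sites inside a block share one
# binary pattern, patterns across blocks are (nearly) independent
block_panel <- function(k, sites_per_block, n_samples, seed = 1,
                        spacing = 100L) {
  set.seed(seed)
  n_hap <- 2 * n_samples
  patterns <- replicate(k, {
    x <- rbinom(n_hap, 1, 0.5)
    while (var(x) == 0) x <- rbinom(n_hap, 1, 0.5)
    x
  })
  al <- patterns[, rep(seq_len(k), each = sites_per_block), drop = FALSE]
  pos <- seq_len(k * sites_per_block) * spacing
  toy_panel(al, pos, rep("EUR", n_samples))
}

whole_chrom <- function(panel)
  region_set("1", 0, max(panel$sites$pos) + 1, "all")

test_that("nothing is selected when the fixed set already covers all targets", {
  p <- block_panel(3, 3, 30, seed = 2)
  fixed <- p$sites$vid[c(1, 4, 7)]   # one per block
  res <- select_tags(p, whole_chrom(p), fixed = fixed)
  expect_equal(res$selected, character(0))
  expect_equal(res$summary$frac_min_r2, 1)
  expect_equal(res$summary$n_uncoverable, 0L)
})

test_that("two perfect-LD triples need exactly two tags (set-cover oracle)", {
  p <- block_panel(2, 3, 40, seed = 3)
  res <- select_tags(p, whole_chrom(p), fixed = character())
  expect_equal(length(res$selected), 2L)
  sel_block <- ceiling(match(res$selected, p$sites$vid) / 3)
  expect_setequal(sel_block, 1:2)
  # exhaustive minimum set cover agrees
  targets <- p$sites$vid
  cover <- lapply(seq_len(6), function(j) {
    r2s <- sapply(seq_len(6), function(t)
      r2_phased(p$alleles[, j], p$alleles[, t]))
    targets[!is.na(r2s) & r2s >= 0.2]
  })
  expect_equal(oracle_min_set_cover(targets, cover), 2L)
})

test_that("greedy matches exhaustive minimum set cover on small block panels", {
  for (seed in 1:5) {
    k <- sample(2:4, 1)
    p <- block_panel(k, 3, 30, seed = seed)
    res <- select_tags(p, whole_chrom(p))
    targets <- p$sites$vid
    nc <- nrow(p$sites)
    cover <- lapply(seq_len(nc), function(j) {
      r2s <- sapply(seq_len(nc), function(t)
        r2_phased(p$alleles[, j], p$alleles[, t]))
      targets[!is.na(r2s) & r2s >= 0.2]
    })
    expect_equal(length(res$selected),
                 oracle_min_set_cover(targets, cover))
  }
})

test_that("every reported covered pair is confirmed by the LD oracle", {
  p <- random_panel(30, 40, pops = c("EUR", "AFR"), seed = 17)
  res <- select_tags(p, whole_chrom(p), fixed = p$sites$vid[1:3])
  cover_set <- union(res$fixed, res$selected)
  params <- res$params
  for (pop in c("EUR", "AFR")) {
    rows <- which(rep(p$samples$population == pop, each = 2))
    t_idx <- which(res$targets[, pop])
    for (t in t_idx) {
      best <- res$coverage[t, pop]
      if (is.na(best) || best < params$tag_min_r2) next
      tv <- rownames(res$coverage)[t]
      r2s <- sapply(cover_set, function(s) {
        if (s == tv) return(1)
        o <- oracle_ld(p$alleles[rows, match(s, p$sites$vid)],
                       p$alleles[rows, match(tv, p$sites$vid)])
        if (is.na(o$r2)) -1 else o$r2
      })
      expect_gte(max(r2s) + 1e-12, params$tag_min_r2)
      expect_equal(max(r2s), best, tolerance = 1e-10)
    }
  }
})

test_that("greedy never adds zero-gain tags and respects fixed monotonicity", {
  for (seed in 1:10) {
    p <- random_panel(20, 30, pops = "EUR", seed = 100 + seed)
    r_none <- select_tags(p, whole_chrom(p))
    expect_lte(length(r_none$selected), nrow(p$sites))
    fixed <- p$sites$vid[seq(1, 20, 4)]
    r_fixed <- select_tags(p, whole_chrom(p), fixed = fixed)
    expect_lte(length(r_fixed$selected), length(r_none$selected))
    expect_length(intersect(r_fixed$selected, fixed), 0)
  }
})

test_that("with tag_min_r2 = 1 on pairwise-imperfect sites each target tags itself", {
  set.seed(55)
  # random panel: with high probability no two columns are in perfect LD
  p <- random_panel(12, 40, pops = "EUR", seed = 77)
  r2m <- outer(seq_len(12), seq_len(12), Vectorize(function(i, j)
    if (i == j) NA_real_ else r2_phased(p$alleles[, i], p$alleles[, j])))
  expect_false(any(r2m == 1, na.rm = TRUE))   # no perfect pairs by construction
  params <- design_params(tag_min_r2 = 1)
  res <- select_tags(p, whole_chrom(p), params = params)
  n_targets <- sum(sapply(p$sites$vid, function(v) maf(p, v, "EUR")) >= 0.01)
  expect_equal(length(res$selected), n_targets)
})

test_that("coverage_report handles self-coverage and the empty site set", {
  p <- random_panel(15, 30, pops = "EUR", seed = 31)
  all_t <- p$sites$vid
  full <- coverage_report(p, whole_chrom(p), all_t)
  expect_equal(full$mean_best_r2, 1)
  expect_equal(full$frac_enhanced, 1)
  none <- coverage_report(p, whole_chrom(p), character(0))
  expect_equal(none$frac_min_r2, 0)
  expect_equal(none$mean_best_r2, 0)
  expect_equal(none$n_uncovered, none$n_targets)
})

test_that("coverage_report agrees with the pairwise max-r2 oracle", {
  p <- random_panel(40, 30, pops = "EUR", seed = 23)
  sites <- p$sites$vid[seq(1, 40, 5)]
  rep_ <- coverage_report(p, whole_chrom(p), sites)
  mafs <- sapply(p$sites$vid, function(v) maf(p, v, "EUR"))
  t_idx <- which(mafs >= 0.01)
  best <- sapply(t_idx, function(t) {
    vals <- sapply(sites, function(s) {
      if (s == p$sites$vid[t]) return(1)
      o <- oracle_ld(p$alleles[, match(s, p$sites$vid)], p$alleles[, t])
      if (is.na(o$r2)) 0 else o$r2
    })
    max(vals)
  })
  expect_equal(rep_$mean_best_r2, mean(best), tolerance = 1e-10)
  expect_equal(rep_$frac_min_r2, mean(best >= 0.2), tolerance = 1e-10)
})

test_that("degenerate inputs give warnings or errors, not silent results", {
  p <- random_panel(10, 20, pops = "EUR", seed = 3)
  expect_error(select_tags(p, region_set("99", 0, 100), fixed = character()),
               "chromosome")
  monom <- toy_panel(matrix(0L, 8, 4), c(10, 20, 30, 40), rep("EUR", 4))
  expect_warning(res <- select_tags(monom, whole_chrom(monom)),
                 "no polymorphic targets")
  expect_equal(res$selected, character(0))
})
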