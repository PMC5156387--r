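test_that("the most deleterious annotation wins consolidation", {
  calls <- data.frame(vid = c("a", "a", "b"),
                      source = c("annovar", "vep", "vep"),
                      term = c("synonymous", "missense", "utr3"),
                      stringsAsFactors = FALSE)
  out <- consolidate_consequences(calls)
  expect_equal(unname(out["a"]), "missense")
  expect_equal(unname(out["b"]), "utr3")
  expect_error(consolidate_consequences(
    data.frame(vid = "x", source = "s", term = "weird")), "weird")
})

test_that("consolidation equals the min-rank oracle and ignores call order", {
  tab <- severity_table()
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    calls <- data.frame(vid = sample(letters[1:6], n, TRUE),
                        source = sample(c("s1", "s2", "s3"), n, TRUE),
                        term = sample(unclass(tab), n, TRUE),
                        stringsAsFactors = FALSE)
    out <- consolidate_consequences(calls, tab)
    for (v in unique(calls$vid)) {
      ranks <- match(calls$term[calls$vid == v], tab)
      expect_equal(unname(out[v]), unclass(tab)[min(ranks)])
    }
    # order invariance and duplicate invariance
    shuf <- calls[sample(nrow(calls)), ]
    expect_equal(consolidate_consequences(shuf, tab)[names(out)], out)
    dup <- rbind(calls, calls[1, ])
    expect_equal(consolidate_consequences(dup, tab)[names(out)], out)
  }
})

test_that("a custom severity table changes the outcome (no hidden ordering)", {
  tab <- severity_table(c("synonymous", "missense"))
  calls <- data.frame(vid = "a", source = c("x", "y"),
                      term = c("synonymous", "missense"))
  expect_equal(unname(consolidate_consequences(calls, tab)["a"]),
               "synonymous")
  expect_error(severity_table(c("missense", "missense")), "duplicate")
})

test_that("exome rule keeps singletons and synonymous variants in priority genes", {
  genes <- region_set("1", 1000, 2000, "GENE1")
  # singleton synonymous variant inside the gene: included
  expect_true(exome_inclusion_filter("1", 1500, "synonymous", genes))
  # intergenic consequence inside the gene region: excluded
  expect_false(exome_inclusion_filter("1", 1500, "intergenic", genes))
  # outside the gene regions: the filter abstains
  expect_true(is.na(exome_inclusion_filter("1", 5000, "missense", genes)))
})

test_that("exome decisions equal the three-clause boolean oracle on random sites", {
  genes <- merge_regions(region_set(c("1", "1"), c(100, 5000),
                                    c(1000, 8000), c("g1", "g2")))
  tab <- severity_table()
  exonic <- c("stop_gained", "frameshift", "stop_lost", "splice_donor",
              "splice_acceptor", "inframe_indel", "missense",
              "splice_region", "utr5", "utr3", "synonymous")
  set.seed(3)
  pos <- sample(1:10000, 200, TRUE)
  term <- sample(unclass(tab), 200, TRUE)
  got <- exome_inclusion_filter(rep("1", 200), pos, term, genes)
  inside <- (pos >= 101 & pos <= 1000) | (pos >= 5001 & pos <= 8000)
  want <- ifelse(!inside, NA, term %in% exonic)
  expect_equal(got, want)
})

test_that("design filter is strict at the boundary and partitions exhaustively", {
  sites <- data.frame(vid = c("a", "b", "c", "d"),
                      design_score = c(0.5, 0.51, NA, 0.9),
                      stringsAsFactors = FALSE)
  res <- apply_design_filter(sites)
  expect_equal(res$passing$vid, c("b", "d"))   # 0.5 exactly fails
  expect_equal(res$failing$vid, c("a", "c"))   # missing score fails
  keep <- apply_design_filter(sites, keep_unscored = TRUE)
  expect_true("c" %in% keep$passing$vid)
  set.seed(6)
  rnd <- data.frame(vid = paste0("v", 1:50),
                    design_score = ifelse(runif(50) < 0.2, NA, runif(50)))
  r <- apply_design_filter(rnd)
  expect_equal(sort(c(r$passing$vid, r$failing$vid)), sort(rnd$vid))
  expect_length(intersect(r$passing$vid, r$failing$vid), 0)
})

test_that("category dedup assigns by precedence and conserves variants", {
  prec <- c("gwas_catalog", "enhanced_gwas", "enhanced_exome", "finemap")
  sites <- data.frame(vid = c("a", "b", "c"),
                      categories = c("finemap,gwas_catalog",
                                     "enhanced_gwas", "finemap"),
                      stringsAsFactors = FALSE)
  m <- dedup_categories(sites, prec)
  expect_equal(m$assignment$category[m$assignment$vid == "a"],
               "gwas_catalog")
  expect_equal(sum(m$counts$n_after), 3L)
  expect_true(all(m$counts$n_after <= m$counts$n_before))
  # no overlap: before equals after
  m2 <- dedup_categories(sites[2:3, ], prec)
  expect_equal(m2$counts$n_before, m2$counts$n_after)
  expect_error(dedup_categories(
    data.frame(vid = "x", categories = "mystery"), prec), "mystery")
  # conservation on random multi-membership fixtures
  set.seed(11)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    cats <- vapply(seq_len(n), function(j)
      paste(sample(prec, sample(1:3, 1)), collapse = ","), character(1))
    s <- data.frame(vid = paste0("v", seq_len(n)), categories = cats)
    mm <- dedup_categories(s, prec)
    expect_equal(sum(mm$counts$n_after), n)
    expect_true(all(mm$counts$n_after <= mm$counts$n_before))
  }
})
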