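test_that("tier_of partitions [0,1] with the published boundaries", {
  expect_identical(tier_of(0.96), "variant")
  expect_identical(tier_of(0.85), "family")
  expect_identical(tier_of(0.95), "family")       # upper bound inclusive
  expect_identical(tier_of(0.60), "superfamily")
  expect_identical(tier_of(0.80), "superfamily")
  expect_identical(tier_of(0.50), "unrelated")
  grid <- seq(0, 1, by = 0.001)
  tiers <- tier_of(grid)
  expect_true(all(tiers %in% c("variant", "family", "superfamily",
                               "unrelated")))
  expect_error(tier_of(1.2), "identity")
})

test_that("assign_names ranks by abundance with zero-padded names", {
  set.seed(18)
  fams <- list(sat_family(canonical_monomer(rand_seq(245)), abundance = 0.01),
               sat_family(canonical_monomer(rand_seq(168)), abundance = 0.03))
  catal <- assign_names(sat_catalog(fams), prefix = "Pko")
  df <- as.data.frame(catal)
  expect_identical(df$name, c("PkoSat01-168", "PkoSat02-245"))
  expect_identical(df$rank, 1:2)
  # idempotent
  expect_identical(as.data.frame(assign_names(catal)), df)
  # ties broken by consensus, deterministically
  tie <- list(sat_family("CCGTACGTACGT", abundance = 0.02),
              sat_family("AAGTACGTACGT", abundance = 0.02))
  d1 <- as.data.frame(assign_names(sat_catalog(tie), prefix = "Xxx"))
  d2 <- as.data.frame(assign_names(sat_catalog(rev(tie)), prefix = "Xxx"))
  expect_identical(d1, d2)
  expect_identical(d1$consensus[1], "AAGTACGTACGT")
  # missing abundance is an error
  expect_error(assign_names(sat_catalog(list(sat_family("ACGTACGT")))),
               "abundance")
})

test_that("summary_stats reproduces the published catalog statistics", {
  nms <- c("PkoSat01-168", "PkoSat02-245", "PkoSat03-324", "PkoSat04-149",
           "PkoSat05-166", "PkoSat06-150")
  st <- summary_stats(sat_catalog(family_from_name(nms), prefix = "Pko"))
  expect_equal(st$median_rul, 167)
  expect_equal(st$min_rul, 149)
  expect_equal(st$max_rul, 324)
  expect_true(is.na(st$at_fraction))  # consensus sequences unknown
  one <- sat_catalog(list(sat_family(rand_seq(100))))
  s1 <- summary_stats(one)
  expect_equal(s1$median_rul, 100)
  expect_equal(s1$min_rul, s1$max_rul)
  at <- summary_stats(sat_catalog(list(sat_family("AATT"),
                                       sat_family("GGCC"))))
  expect_equal(at$at_fraction, 0.5)
  expect_error(summary_stats(sat_catalog()), "empty")
})

test_that("merge_catalogs folds per-sex catalogs by the family tier", {
  set.seed(27)
  m1 <- canonical_monomer(rand_seq(100))
  m2 <- canonical_monomer(rand_seq(100))
  # a close relative of m1 (family tier) and an exact copy (variant tier)
  x <- strsplit(m1, "")[[1L]]
  pos <- sample(100, 10)
  x[pos] <- vapply(x[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  m1_rel <- canonical_monomer(paste(x, collapse = ""))
  a <- sat_catalog(list(sat_family(m1)), prefix = "Tst")
  b <- sat_catalog(list(sat_family(m1), sat_family(m1_rel),
                        sat_family(m2)))
  merged <- merge_catalogs(a, b)
  expect_equal(length(merged), 2L)   # m1 (+variant) and m2
  expect_equal(nrow(merged$families[[1]]$variants), 1L)
  expect_identical(merged$families[[1]]$variants$consensus, m1_rel)
  expect_identical(merged$families[[2]]$consensus, m2)
})

test_that("group_superfamilies links by single linkage in the 50-80% tier", {
  set.seed(19)
  a <- canonical_monomer(rand_seq(120))
  mut_frac <- function(s, k) {
    x <- strsplit(s, "")[[1L]]
    pos <- sample(length(x), k)
    x[pos] <- vapply(x[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
    paste(x, collapse = "")
  }
  b <- canonical_monomer(mut_frac(a, 42))    # ~65% identity to a
  cc <- canonical_monomer(mut_frac(b, 42))   # ~65% to b, ~45% to a
  d <- canonical_monomer(rand_seq(120, alphabet = c("A", "T")))  # unrelated
  catal <- assign_names(sat_catalog(list(
    sat_family(a, abundance = 0.04), sat_family(b, abundance = 0.03),
    sat_family(cc, abundance = 0.02), sat_family(d, abundance = 0.01)),
    prefix = "Tst"))
  out <- as.data.frame(group_superfamilies(catal))
  ids <- setNames(out$superfamily_id, out$consensus)
  expect_equal(ids[[a]], ids[[b]])   # direct link
  expect_equal(ids[[b]], ids[[cc]])  # chained by single linkage
  expect_false(ids[[d]] == ids[[a]]) # unrelated family keeps its own id
})
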