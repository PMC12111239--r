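test_that("quality_trim cuts at the first bad window and drops short pairs", {
  cfg <- mining_config()
  q30 <- strrep("?", 100)                       # Phred 30
  good <- lib_from_seqs(rand_seq(100), rand_seq(100))
  expect_identical(quality_trim(good, cfg)$seq1, good$seq1)
  # quality drops to Q10 (char '+') from position 51. Window means: at 49
  # (30,30,10,10) = 20, still passing; at 50 (30,10,10,10) = 15, the first
  # failure -- so 49 bases survive (within window granularity of the drop)
  qtail <- paste0(strrep("?", 50), strrep("+", 50))
  lib <- read_library(rand_seq(100), qtail, rand_seq(100), q30)
  tr <- quality_trim(lib, cfg)
  expect_equal(nchar(tr$seq1), 49L)
  expect_equal(nchar(tr$seq2), 100L)
  # a mate trimmed below 36 bp takes the whole pair with it
  qbad <- paste0(strrep("?", 20), strrep("+", 80))
  lib2 <- read_library(c(rand_seq(100), rand_seq(100)), c(q30, qbad),
                       c(rand_seq(100), rand_seq(100)), c(q30, q30))
  tr2 <- quality_trim(lib2, cfg)
  expect_equal(n_pairs(tr2), 1L)
})

test_that("filter_catalog_reads removes matching pairs inclusively", {
  set.seed(15)
  m <- canonical_monomer(rand_seq(50))
  catal <- sat_catalog(list(sat_family(m)))
  tandem <- strrep(m, 10)
  # pure satellite reads vanish
  sat_lib <- lib_from_seqs(substring(tandem, 1, 100),
                           reverse_complement(substring(tandem, 101, 200)))
  expect_equal(n_pairs(filter_catalog_reads(sat_lib, catal)), 0L)
  # background-only reads survive
  bg <- lib_from_seqs(replicate(20, rand_seq(100)),
                      replicate(20, rand_seq(100)))
  expect_equal(n_pairs(filter_catalog_reads(bg, catal)), 20L)
  # boundary: exactly 80 of 100 read bases are satellite at identity 1
  half <- paste0(substring(tandem, 1, 80), rand_seq(20))
  mix <- lib_from_seqs(c(half, rand_seq(100)), replicate(2, rand_seq(100)))
  expect_equal(n_pairs(filter_catalog_reads(mix, catal)), 1L)
  # mates travel together: matching mate 2 removes the pair
  mix2 <- lib_from_seqs(rand_seq(100), substring(tandem, 7, 106))
  expect_equal(n_pairs(filter_catalog_reads(mix2, catal)), 0L)
})

test_that("run_mining terminates, is exhaustive and deterministic", {
  spec <- small_sim_spec(seed = 16)
  g <- build_genomes(spec)
  lib <- simulate_reads(g$female, spec, sex = "female")
  cfg <- mining_config(seed = 4)
  mined <- run_mining(lib, cfg)
  expect_equal(length(mined), 2L)
  log <- attr(mined, "mining_log")
  expect_lte(nrow(log), 3L)
  expect_true(all(diff(log$pool_pairs_after) <= 0))  # pool non-increasing
  expect_equal(log$new_families[nrow(log)], 0L)      # stopped on exhaustion
  # re-mining the filtered pool discovers nothing new
  re <- run_mining(attr(mined, "pool"), mining_config(seed = 5))
  expect_equal(length(re), 0L)
  # no two final families fall in the same family tier
  cons <- vapply(mined$families, function(f) f$consensus, character(1L))
  expect_lte(rotation_identity(cons[1], cons[2]), 0.80)
  # determinism: identical catalog on rerun
  mined2 <- run_mining(lib, cfg)
  expect_identical(
    vapply(mined$families, function(f) f$consensus, character(1L)),
    vapply(mined2$families, function(f) f$consensus, character(1L)))
})

test_that("mining pure background yields an empty catalog", {
  spec <- sim_spec(genome_length = 1.5e5, families = list(), coverage = 0.3,
                   seed = 17)
  g <- build_genomes(spec)
  lib <- simulate_reads(g$female, spec, sex = "female")
  mined <- run_mining(lib, mining_config(seed = 6))
  expect_equal(length(mined), 0L)
  expect_equal(nrow(attr(mined, "mining_log")), 1L)
})

test_that("rank_catalog orders families by quantified abundance", {
  spec <- small_sim_spec(seed = 16)
  g <- build_genomes(spec)
  lib <- simulate_reads(g$female, spec, sex = "female")
  mined <- run_mining(lib, mining_config(seed = 4))
  catal <- rank_catalog(mined, lib, prefix = "Tst")
  df <- as.data.frame(catal)
  expect_true(all(diff(df$abundance) <= 0))
  expect_match(df$name[1], "^TstSat01-")
  # the 8% family outranks the 6% family
  expect_equal(df$rul[1], 150L)
})
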