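test_that("detect_period finds the smallest qualifying lag", {
  expect_equal(detect_period("ACGACGACGACG", min_period = 2,
                             max_mismatch_rate = 0), 3L)
  # one substitution breaks two lag-3 comparisons: agreement 7/9, so the
  # period is visible at tau = 0.25 but not at tau = 0.15
  expect_equal(detect_period("ACGACGACTACG", min_period = 2,
                             max_mismatch_rate = 0.25), 3L)
  expect_true(is.na(detect_period("ACGACGACTACG", min_period = 2,
                                  max_mismatch_rate = 0.15)))
  # random reads have no period at strict tolerance
  set.seed(12)
  for (i in 1:20) {
    expect_true(is.na(detect_period(rand_seq(100), min_period = 5,
                                    max_mismatch_rate = 0.05)))
  }
  # internally periodic monomers report the divisor period
  expect_equal(detect_period("ACACACACACAC", min_period = 2,
                             max_mismatch_rate = 0), 2L)
})

test_that("extract_copies tiles and canonicalises windows", {
  expect_identical(extract_copies("ACGACGACG", 3), rep("ACG", 3))
  # a phase-shifted read yields the same canonical copies
  expect_identical(extract_copies("CGACGACGA", 3),
                   extract_copies("ACGACGACG", 3))
  expect_length(extract_copies("ACGACGACGA", 3), 3L)  # trailing base dropped
})

test_that("cluster_candidates groups copies and votes a consensus", {
  set.seed(13)
  m <- canonical_monomer(rand_seq(60))
  # 100 identical copies from 100 reads -> one candidate
  cp <- data.frame(copy = rep(m, 100), read_id = paste0(1:100, "/1"))
  out <- cluster_candidates(cp, min_support = 10)
  expect_length(out, 1L)
  expect_identical(out[[1]]$consensus, m)
  expect_equal(out[[1]]$support_reads, 100L)
  # two unrelated monomers stay apart
  m2 <- canonical_monomer(rand_seq(150))
  m3 <- canonical_monomer(rand_seq(150))
  cp2 <- data.frame(copy = c(rep(m2, 50), rep(m3, 50)),
                    read_id = paste0(1:100, "/1"))
  expect_length(cluster_candidates(cp2, min_support = 10), 2L)
  # copies at 2% divergence: majority vote recovers the master
  master <- canonical_monomer(rand_seq(80))
  copies <- canonical_monomer(vapply(1:100, function(i)
    mutate_copy(master, 0.02, 2), character(1L)))
  cp3 <- data.frame(copy = copies, read_id = paste0(1:100, "/1"))
  out3 <- cluster_candidates(cp3, min_support = 10)
  expect_length(out3, 1L)
  expect_gte(rotation_identity(out3[[1]]$consensus, master), 0.99)
  # support below min_support drops the cluster
  expect_length(cluster_candidates(cp[1:5, ], min_support = 10), 0L)
  # deterministic under the ordering rule
  out_b <- cluster_candidates(cp3[sample(100), ], min_support = 10)
  expect_identical(out_b[[1]]$consensus, out3[[1]]$consensus)
})

test_that("tandem_filter keeps tandem candidates and rejects by bounds", {
  mk <- function(tf, rul = 50L) {
    monomer_candidate(canonical_monomer(strrep("ACGGT", rul / 5)),
                      support_reads = 50L, tandem_fraction = tf)
  }
  expect_true(tandem_filter(mk(1.0)))
  expect_true(tandem_filter(mk(0.8)))   # inclusive boundary
  expect_false(tandem_filter(mk(0.79)))
  cand <- monomer_candidate("ACGT", support_reads = 50L,
                            tandem_fraction = 1.0)
  expect_false(tandem_filter(cand, min_rul = 5))  # rul below bound
})

test_that("dispersed decoy repeats fail the tandem test", {
  spec <- sim_spec(genome_length = 3e5, families = list(
    planted_family("sat", rul = 40L, target_abundance = 0.05,
                   divergence = 0.01),
    planted_family("decoy", rul = 90L, target_abundance = 0.04,
                   divergence = 0.01, arrangement = "dispersed")),
    coverage = 0.3, seed = 14)
  g <- build_genomes(spec)
  lib <- simulate_reads(g$female, spec, sex = "female")
  decoy <- g$truth$monomer[g$truth$family == "decoy"]
  st <- tandem_stats(decoy, lib)
  expect_gt(st$support_reads, 10L)     # the decoy is genuinely repetitive
  expect_lt(st$tandem_fraction, 0.3)   # but almost never tandem
  cand <- monomer_candidate(decoy, support_reads = st$support_reads,
                            tandem_fraction = st$tandem_fraction)
  expect_false(tandem_filter(cand))
  # and the discovery front end reports only the tandem family
  cands <- discover_candidates(lib)
  expect_length(cands, 1L)
  sat <- g$truth$monomer[g$truth$family == "sat"]
  expect_gte(rotation_identity(cands[[1]]$consensus, sat), 0.98)
})

test_that("both discovery paths recover planted monomers", {
  spec <- small_sim_spec(seed = 11)
  g <- build_genomes(spec)
  lib <- simulate_reads(g$female, spec, sex = "female")
  cands <- discover_candidates(lib)
  expect_length(cands, 2L)
  ids <- vapply(cands, function(cc)
    max(vapply(g$truth$monomer, function(m)
      rotation_identity(cc$consensus, m), numeric(1L))), numeric(1L))
  expect_true(all(ids >= 0.98))
  ruls <- sort(vapply(cands, function(cc) cc$rul, integer(1L)))
  expect_equal(ruls, sort(g$truth$rul))
  expect_setequal(vapply(cands, function(cc) cc$source, character(1L)),
                  c("period", "assembly"))
})
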