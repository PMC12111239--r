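test_that("reverse_complement follows Watson-Crick pairing with N fixed", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAGG"), "CCTT")
  expect_identical(reverse_complement("ATN"), "NAT")
  # involution over random sequences
  set.seed(1)
  for (i in 1:20) {
    s <- rand_seq(sample(1:60, 1), c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
  expect_error(reverse_complement("ACGU"), "alphabet")
  expect_error(reverse_complement(""), "empty")
})

test_that("canonical_monomer matches brute-force enumeration and is
           rotation/strand invariant", {
  expect_identical(canonical_monomer("ACGT"), "ACGT")
  expect_identical(canonical_monomer("GGC"), "CCG")
  expect_identical(canonical_monomer("ATAT"), "ATAT")
  expect_error(canonical_monomer("ACN"), "alphabet")
  set.seed(42)
  for (i in 1:200) {
    s <- rand_seq(sample(2:30, 1))
    canon <- canonical_monomer(s)
    expect_identical(canon, oracle_canonical(s))
    # identical for every rotation and every rotation of the complement
    rots <- c(oracle_rotations(s), oracle_rotations(oracle_revcomp(s)))
    expect_true(all(canonical_monomer(rots) == canon))
  }
})

test_that("align_pair books matches, transitions, transversions and gaps", {
  a <- align_pair("ACGT", "ACGT", mode = "global")
  expect_equal(a$identity, 1)
  expect_equal(a$gap_columns, 0)
  b <- align_pair("ACGT", "ACAT", mode = "global")
  expect_equal(b$matches, 3)
  expect_equal(b$transitions, 1)  # G vs A
  expect_equal(b$transversions, 0)
  expect_equal(b$identity, 0.75)
  g <- align_pair("AC", "TTACTT", mode = "glocal")
  expect_equal(g$matches, 2)
  expect_equal(g$gap_columns, 0)
  expect_equal(g$identity, 1)
  # column accounting closes over random pairs, any mode
  set.seed(7)
  for (mode in c("global", "local", "glocal")) {
    for (i in 1:10) {
      x <- align_pair(rand_seq(sample(10:40, 1)), rand_seq(sample(10:60, 1)),
                      mode = mode)
      expect_equal(x$matches + x$transitions + x$transversions +
                     x$gap_columns, x$aligned_columns)
      expect_equal(x$identity, x$matches / x$aligned_columns)
    }
  }
  # self-alignment is always perfect
  set.seed(8)
  for (i in 1:10) {
    s <- rand_seq(sample(5:80, 1))
    x <- align_pair(s, s, mode = "global")
    expect_equal(x$identity, 1)
    expect_equal(x$gap_columns, 0)
  }
})

test_that("N never matches and is excluded from K2P sites", {
  x <- align_pair("ANT", "ANT", mode = "global")
  expect_equal(x$matches, 2)
  expect_equal(x$transversions, 1)
  expect_equal(x$sites, 2)
})

test_that("rotation_identity is invariant to rotation and strand", {
  expect_equal(rotation_identity("CGTA", "ACGT"), 1)
  expect_equal(rotation_identity("ACGT", "ACGT"), 1)
  expect_equal(rotation_identity("ACGTT", "AACGT"), 1)  # strands
  set.seed(33)
  for (i in 1:15) {
    m <- rand_seq(sample(10:50, 1))
    k <- sample(nchar(m), 1)
    rot <- paste0(substring(m, k), substring(m, 1, k - 1))
    if (sample(c(TRUE, FALSE), 1)) rot <- oracle_revcomp(rot)
    expect_equal(rotation_identity(rot, m), 1)
  }
  # unrelated long monomers fall far below the variant tier
  set.seed(34)
  expect_lt(rotation_identity(rand_seq(150), rand_seq(150)), 0.8)
})

test_that("k2p_distance implements the closed form with saturation marker", {
  expect_identical(k2p_distance(0, 0, 100), 0)
  expect_equal(k2p_distance(10, 5, 100), oracle_k2p(0.10, 0.05),
               tolerance = 1e-12)
  expect_true(k2p_saturated(k2p_distance(50, 0, 100)))
  expect_true(k2p_saturated(k2p_distance(0, 50, 100)))
  expect_error(k2p_distance(1, 1, 0), "sites")
  expect_error(k2p_distance(60, 50, 100), "exceed")
  # monotone nondecreasing in each argument over the unsaturated domain
  d <- outer(0:30, 0:20, function(ts, tv) k2p_distance(ts, tv, 100))
  fin <- is.finite(d)
  expect_true(all(diff(d)[fin[-1, ] & fin[-nrow(d), ]] >= 0))
  expect_true(all(t(diff(t(d)))[fin[, -1] & fin[, -ncol(d)]] >= 0))
})
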