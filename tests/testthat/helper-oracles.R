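# Independent oracles and small fixture builders. These deliberately avoid
# the package's own primitives (brute-force enumeration, direct formula
# evaluation) so they can validate them.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

oracle_rotations <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n) - 1L, function(k)
    paste0(substring(s, k + 1L, n), substring(s, 1L, k)), character(1L))
}

# lexicographically smallest string over all rotations of s and of its
# reverse complement
oracle_canonical <- function(s) {
  min(c(oracle_rotations(s), oracle_rotations(oracle_revcomp(s))))
}

# K2P in its textbook two-term form (algebraically equal to the packaged
# single-log form, but evaluated differently)
oracle_k2p <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute exactly the requested transitions/transversions at given
# positions (positions must be distinct)
mutate_exact <- function(s, ts_pos = integer(0), tv_pos = integer(0)) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversion <- c(A = "C", G = "T", C = "A", T = "G")
  x <- strsplit(s, "")[[1L]]
  x[ts_pos] <- transition[x[ts_pos]]
  x[tv_pos] <- transversion[x[tv_pos]]
  paste(x, collapse = "")
}

# a library built directly from sequences (constant Q30 qualities)
lib_from_seqs <- function(seq1, seq2, sex = "unknown") {
  q1 <- strrep("?", nchar(seq1))
  q2 <- strrep("?", nchar(seq2))
  read_library(seq1, q1, seq2, q2, sex = sex)
}

# small two-family simulation shared by several tests (one short-period and
# one assembly-path family)
small_sim_spec <- function(seed = 11) {
  sim_spec(genome_length = 3e5, families = list(
    planted_family("tinyA", rul = 30L, target_abundance = 0.06,
                   divergence = 0.02),
    planted_family("tinyB", rul = 150L, target_abundance = 0.08,
                   divergence = 0.03)),
    coverage = 0.3, seed = seed)
}
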