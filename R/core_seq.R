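#' @useDynLib satmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
NULL

.NUC_ALPHABET <- c("A", "C", "G", "T", "N")

.check_seq <- function(x, allow_n = TRUE, arg = "seq") {
  if (!is.character(x) || anyNA(x)) {
    stop(sprintf("'%s' must be a character vector without NA", arg), call. = FALSE)
  }
  if (any(nchar(x) < 1L)) {
    stop(sprintf("'%s' contains an empty sequence", arg), call. = FALSE)
  }
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf(
      "'%s' contains characters outside the %s alphabet: %s", arg,
      if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}",
      substr(x[bad][1L], 1L, 40L)
    ), call. = FALSE)
  }
  invisible(x)
}

.rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1L),
         USE.NAMES = FALSE)
}

#' Reverse complement of nucleotide sequences
#'
#' Watson-Crick complement, reversed. `N` is its own complement.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}` (uppercase).
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AAGG")  # "CCTT"
#' @export
reverse_complement <- function(seq) {
  .check_seq(seq, allow_n = TRUE)
  .rev_string(chartr("ACGTN", "TGCAN", seq))
}

#' Canonical form of a circular repeat monomer
#'
#' Satellite monomers are circular units: two monomers describe the same
#' repeat if one is a rotation of the other on either strand. The canonical
#' form is the lexicographically smallest string among all rotations of the
#' sequence and all rotations of its reverse complement, making string
#' equality a rotation- and strand-invariant comparison.
#'
#' @param seq Character vector of N-free sequences.
#' @return Character vector of canonical monomers.
#' @examples
#' canonical_monomer("GGC")  # "CCG"
#' @export
canonical_monomer <- function(seq) {
  .check_seq(seq, allow_n = FALSE)
  fwd <- .least_rotation_batch(seq)
  rev <- .least_rotation_batch(reverse_complement(seq))
  ifelse(fwd <= rev, fwd, rev)
}

# Substitution matrix implementing the package-wide scoring: match +1,
# mismatch -1; N never matches (N/N scores -1).
.subst_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      mm <- matrix(-1, 5L, 5L, dimnames = list(.NUC_ALPHABET, .NUC_ALPHABET))
      diag(mm) <- 1
      mm["N", "N"] <- -1
      m <<- mm
    }
    m
  }
})

.aln_type <- function(mode) {
  switch(mode,
    global = "global",
    local  = "local",
    glocal = "global-local",
    stop("unknown alignment mode: ", mode, call. = FALSE)
  )
}

# Vectorised pairwise alignment of many patterns against one subject.
# Returns a data.frame of column tallies plus identity.
.align_batch <- function(patterns, subject, mode = "glocal") {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = .aln_type(mode), substitutionMatrix = .subst_matrix(),
    gapOpening = 1, gapExtension = 1
  )
  tal <- .aln_tally(as.character(Biostrings::alignedPattern(aln)),
                    as.character(Biostrings::alignedSubject(aln)))
  out <- as.data.frame(tal)
  out$identity <- out$matches / out$aligned_columns
  out
}

#' Pairwise alignment with substitution-class accounting
#'
#' Aligns two sequences with affine gap penalties (match +1, mismatch -1,
#' gap open -2, gap extend -1; the first gapped column costs 2) and tallies
#' the alignment columns into matches, transitions (A<->G, C<->T),
#' transversions (all other mismatches), and gap columns. `N` never matches:
#' it is booked as a transversion for identity purposes but excluded from the
#' ungapped `sites` count used by [k2p_distance()].
#'
#' @param a,b Single sequences (character). In `glocal` mode all of `a` is
#'   aligned within `b` (free end gaps in `b`).
#' @param mode One of `"global"`, `"local"`, `"glocal"`.
#' @return An object of class `alignment_result`: a list with `matches`,
#'   `transitions`, `transversions`, `gap_columns`, `aligned_columns`,
#'   `sites`, `pattern_bp` and `identity` (= matches / aligned_columns).
#' @examples
#' align_pair("ACGT", "ACAT", mode = "global")
#' @export
align_pair <- function(a, b, mode = c("global", "local", "glocal")) {
  mode <- match.arg(mode)
  .check_seq(a, arg = "a"); .check_seq(b, arg = "b")
  stopifnot(length(a) == 1L, length(b) == 1L)
  row <- .align_batch(a, b, mode = mode)
  res <- as.list(row)
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> identity %.4f over %d columns (%d match, %d ts, %d tv, %d gap)\n",
    x$identity, x$aligned_columns, x$matches, x$transitions, x$transversions,
    x$gap_columns))
  invisible(x)
}

# Identity of many query monomers against one reference monomer, maximised
# over strand, with rotation handled by aligning against the reference
# concatenated to itself (so any phase of a full-length query fits).
.rotation_identity_many <- function(queries, ref) {
  dimer <- strrep(ref, 2L)
  id_f <- .align_batch(queries, dimer, mode = "glocal")$identity
  id_r <- .align_batch(queries, reverse_complement(dimer), mode = "glocal")$identity
  pmax(id_f, id_r)
}

# Rotation/strand-invariant ungapped identity normalised by the longer
# monomer: best cyclic-shift match count over max(nchar(a), nchar(b)).
# Penalises length mismatch instead of rewarding a short monomer for
# matching any window of a long one, and keeps the chance identity of
# unrelated monomers far below the superfamily boundary.
.monomer_identity_norm <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  .cyclic_identity_batch(a, b)
}

#' Rotation- and strand-invariant identity between two monomers
#'
#' Glocal alignment of the shorter sequence against the dimer (self-
#' concatenation) of the longer one, on both strands; the larger identity is
#' returned. Dimerisation makes the comparison invariant to the arbitrary
#' phase at which a circular repeat unit was linearised.
#'
#' @param a,b Single N-free sequences.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' rotation_identity("CGTA", "ACGT")  # 1
#' @export
rotation_identity <- function(a, b) {
  .check_seq(a, allow_n = FALSE, arg = "a")
  .check_seq(b, allow_n = FALSE, arg = "b")
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  .rotation_identity_many(a, b)
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with transition proportion
#' `P = transitions/sites` and transversion proportion `Q =
#' transversions/sites`. Saturated inputs (`1 - 2P - Q <= 0` or
#' `1 - 2Q <= 0`) return `Inf`, the saturation marker. Plain (not
#' CpG-adjusted) K2P; sites are ungapped, N-free aligned columns.
#'
#' @param transitions,transversions,sites Non-negative counts (vectorised).
#' @return Numeric vector of distances; `Inf` marks saturation.
#' @examples
#' k2p_distance(10, 5, 100)
#' @export
k2p_distance <- function(transitions, transversions, sites) {
  if (any(sites < 1L)) stop("'sites' must be >= 1", call. = FALSE)
  if (any(transitions < 0) || any(transversions < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(transitions + transversions > sites)) {
    stop("transitions + transversions must not exceed sites", call. = FALSE)
  }
  P <- transitions / sites
  Q <- transversions / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(w1 <= 0 | w2 <= 0, Inf, -0.5 * log(w1 * sqrt(pmax(w2, 0))))
  # exact zero for identical inputs, avoiding -0.0
  d[P == 0 & Q == 0] <- 0
  d
}

#' Is a K2P distance saturated?
#'
#' @param d Numeric vector returned by [k2p_distance()].
#' @return Logical vector; `TRUE` where the distance hit the saturation
#'   marker (`Inf`).
#' @export
k2p_saturated <- function(d) is.infinite(d)
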