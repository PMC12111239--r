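#' Discovery configuration
#'
#' Tuning knobs for de-novo monomer discovery in one read sample.
#'
#' @param min_period,max_mismatch_rate Smallest period searched per read and
#'   the tolerated per-offset mismatch fraction (tau) of [detect_period()].
#' @param min_support Minimum supporting reads for a kept candidate.
#' @param min_rul,max_rul Admissible repeat-unit-length range in bp.
#' @param min_tandem_fraction Tandem-evidence floor of [tandem_filter()].
#' @param variant_threshold Identity above which two monomers are the same
#'   variant (>0.95, the variant tier).
#' @param family_threshold Identity above which two monomers belong to the
#'   same family (>0.80, the family tier).
#' @param kmer_k K-mer size for repetitiveness screening and assembly
#'   anchoring.
#' @param min_kmer_count A k-mer occurring at least this often in the sample
#'   counts as repetitive. Scales with sample depth: satellite monomers are
#'   covered tens to hundreds of times even at sub-1x genome coverage.
#' @param repetitive_fraction A read enters the assembly pool when at least
#'   this fraction of its k-mers is repetitive -- for both the read and its
#'   mate, so the whole fragment lies inside an array and contigs stay free
#'   of flanking background. Divergent families retain only a minority of
#'   intact monomer k-mers per copy (at 5% divergence about 40% of 17-mers),
#'   which sets the scale of the default.
#' @param overlap_min,overlap_identity Minimum overlap (bp) and identity for
#'   greedy read extension during long-monomer assembly.
#' @param max_contig_length,max_contigs Assembly stopping bounds.
#' @param contig_tau Mismatch tolerance when calling the period of an
#'   assembled contig (looser than the per-read tau because contig copies
#'   come from distinct, independently diverged genomic copies).
#' @return A list of class `discover_config`.
#' @export
discover_config <- function(min_period = 5L, max_mismatch_rate = 0.1,
                            min_support = 10L, min_rul = 5L, max_rul = 1000L,
                            min_tandem_fraction = 0.8,
                            variant_threshold = 0.95, family_threshold = 0.80,
                            kmer_k = 17L, min_kmer_count = 8L,
                            repetitive_fraction = 0.3, overlap_min = 40L,
                            overlap_identity = 0.85,
                            max_contig_length = 2000L, max_contigs = 40L,
                            contig_tau = 0.25) {
  structure(as.list(environment()), class = "discover_config")
}

#' Detect the tandem period of a single read
#'
#' Returns the smallest period `p` with `min_period <= p <= floor(L/2)` such
#' that the fraction of offsets `i` with `read[i] == read[i+p]` is at least
#' `1 - max_mismatch_rate`; `NA` when no period qualifies. `N` never agrees.
#' When the true monomer is itself internally periodic the divisor period is
#' reported (smallest qualifying `p` wins).
#'
#' @param read A read sequence (character scalar), length >= `2 * min_period`.
#' @param min_period Smallest period considered.
#' @param max_mismatch_rate Tolerated disagreement fraction (tau).
#' @return Integer period or `NA`.
#' @examples
#' detect_period("ACGACGACGACG", max_mismatch_rate = 0, min_period = 2)
#' @export
detect_period <- function(read, min_period = 5L, max_mismatch_rate = 0.1) {
  .check_seq(read, arg = "read")
  stopifnot(length(read) == 1L)
  .detect_period_batch(read, as.integer(min_period), max_mismatch_rate)[1L]
}

#' @rdname detect_period
#' @param reads Character vector of reads (vectorised form).
#' @export
detect_periods <- function(reads, min_period = 5L, max_mismatch_rate = 0.1) {
  .check_seq(reads, arg = "reads")
  .detect_period_batch(reads, as.integer(min_period), max_mismatch_rate)
}

# consecutive full windows of length p (trailing partial window discarded)
.tile_windows <- function(s, p) {
  k <- nchar(s) %/% p
  substring(s, (seq_len(k) - 1L) * p + 1L, seq_len(k) * p)
}

#' Extract monomer copies from a periodic read
#'
#' Tiles consecutive windows of the detected period across the read and
#' rotates each window to its canonical form, so copies from any phase or
#' strand become column-comparable. Windows containing `N` are dropped.
#'
#' @param read Read sequence.
#' @param period Period returned by [detect_period()] for this read.
#' @return Character vector of canonical copies.
#' @export
extract_copies <- function(read, period) {
  .check_seq(read, arg = "read")
  stopifnot(length(read) == 1L, period >= 1L)
  w <- .tile_windows(read, period)
  w <- w[!grepl("N", w, fixed = TRUE)]
  if (length(w) == 0L) return(character(0))
  canonical_monomer(w)
}

#' Construct a monomer candidate
#'
#' @param consensus Canonical consensus monomer.
#' @param support_reads Number of distinct supporting reads.
#' @param tandem_fraction Fraction of supporting reads with tandem evidence
#'   (two in-read copies, or a supporting mate for monomers longer than half
#'   a read); `NA` until [tandem_stats()] is applied.
#' @param n_copies Aligned copies that built the consensus.
#' @param source `"period"` (in-read periodicity) or `"assembly"`
#'   (long-monomer contig path).
#' @return An object of class `monomer_candidate`.
#' @export
monomer_candidate <- function(consensus, support_reads = NA_integer_,
                              tandem_fraction = NA_real_,
                              n_copies = NA_integer_, source = "period") {
  .check_seq(consensus, allow_n = FALSE, arg = "consensus")
  structure(list(consensus = consensus, rul = nchar(consensus),
                 support_reads = as.integer(support_reads),
                 tandem_fraction = tandem_fraction,
                 n_copies = as.integer(n_copies), source = source),
            class = "monomer_candidate")
}

#' @export
print.monomer_candidate <- function(x, ...) {
  cat(sprintf("<monomer_candidate> rul %d, support %s, tandem %s (%s)\n",
              x$rul, x$support_reads,
              ifelse(is.na(x$tandem_fraction), "NA",
                     sprintf("%.2f", x$tandem_fraction)), x$source))
  invisible(x)
}

# ---- cluster machinery ------------------------------------------------------

.BASES <- c("A", "C", "G", "T")

.new_cluster <- function(copy, count, reads) {
  counts <- matrix(0L, 4L, nchar(copy), dimnames = list(.BASES, NULL))
  idx <- match(strsplit(copy, "")[[1L]], .BASES)
  counts[cbind(idx, seq_along(idx))] <- count
  list(seed_len = nchar(copy), counts = counts, consensus = copy,
       reads = reads, n_members = count)
}

.cluster_add <- function(cl, copy, count, reads) {
  cl$reads <- unique(c(cl$reads, reads))
  cl$n_members <- cl$n_members + count
  if (nchar(copy) == cl$seed_len) {
    idx <- match(strsplit(copy, "")[[1L]], .BASES)
    cl$counts[cbind(idx, seq_along(idx))] <-
      cl$counts[cbind(idx, seq_along(idx))] + count
    # per-column majority; ties resolved alphabetically (A < C < G < T,
    # which.max takes the first maximum in row order)
    cl$consensus <- paste(.BASES[apply(cl$counts, 2L, which.max)],
                          collapse = "")
  }
  cl
}

.hamming_identity <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  sum(x == y) / length(x)
}

#' Greedy clustering of extracted copies into monomer candidates
#'
#' Unique copies are processed in order of decreasing multiplicity (ties
#' broken lexicographically). Each copy joins the first existing cluster
#' whose current consensus it matches at the variant tier
#' (rotation identity >= `variant_threshold`), else founds a new cluster;
#' after every assignment the cluster consensus is recomputed by per-column
#' majority vote over the phase-aligned members (ties alphabetic). Clusters
#' whose consensus falls in the family tier of an earlier, larger cluster
#' (rotation identity > `family_threshold`) are then folded into it --
#' divergent families fragment at the variant threshold and the family tier
#' is what defines membership of one family. Finally, clusters supported by
#' fewer than `min_support` reads are dropped and consensus sequences are
#' canonicalised.
#'
#' @param copies `data.frame` with columns `copy` (canonical copy sequences,
#'   see [extract_copies()]) and `read_id`.
#' @param min_support Minimum distinct supporting reads.
#' @param variant_threshold,family_threshold Tier thresholds.
#' @return List of [monomer_candidate()] objects, ordered by support
#'   (decreasing) then consensus.
#' @export
cluster_candidates <- function(copies, min_support = 10L,
                               variant_threshold = 0.95,
                               family_threshold = 0.80) {
  stopifnot(is.data.frame(copies), all(c("copy", "read_id") %in%
                                         names(copies)))
  if (nrow(copies) == 0L) return(list())
  reads_by_copy <- split(as.character(copies$read_id),
                         as.character(copies$copy))
  cnt <- lengths(reads_by_copy)
  ord <- order(-cnt, names(cnt))
  uniq <- names(cnt)[ord]
  clusters <- list()
  for (u in uniq) {
    rr <- unique(reads_by_copy[[u]])
    k <- length(reads_by_copy[[u]])
    joined <- FALSE
    for (i in seq_along(clusters)) {
      cons <- clusters[[i]]$consensus
      # equal-length copies carry no indels, so the rotation/strand-invariant
      # identity is the best cyclic-shift match; alignment handles the rest
      id <- if (u == cons) 1 else if (nchar(u) == nchar(cons)) {
        .cyclic_identity_batch(u, cons)
      } else {
        .rotation_identity_many(u, cons)
      }
      if (id >= variant_threshold) {
        clusters[[i]] <- .cluster_add(clusters[[i]], u, k, rr)
        joined <- TRUE
        break
      }
    }
    if (!joined) clusters[[length(clusters) + 1L]] <- .new_cluster(u, k, rr)
  }
  # fold family-tier fragments into their larger sibling
  ord2 <- order(-vapply(clusters, function(cl) length(cl$reads), integer(1L)),
                vapply(clusters, function(cl) cl$consensus, character(1L)))
  clusters <- clusters[ord2]
  keep <- rep(TRUE, length(clusters))
  if (length(clusters) > 1L) {
    for (j in 2L:length(clusters)) {
      for (i in seq_len(j - 1L)) {
        if (!keep[i]) next
        if (rotation_identity(clusters[[j]]$consensus,
                              clusters[[i]]$consensus) > family_threshold) {
          if (clusters[[j]]$seed_len == clusters[[i]]$seed_len) {
            # phase fragment columns onto the sibling's frame when aligned
            same_frame <- clusters[[j]]$consensus == clusters[[i]]$consensus ||
              .hamming_identity(clusters[[j]]$consensus,
                                clusters[[i]]$consensus) > family_threshold
            if (same_frame) {
              clusters[[i]]$counts <- clusters[[i]]$counts +
                clusters[[j]]$counts
              clusters[[i]]$consensus <- paste(
                .BASES[apply(clusters[[i]]$counts, 2L, which.max)],
                collapse = "")
            }
          }
          clusters[[i]]$reads <- unique(c(clusters[[i]]$reads,
                                          clusters[[j]]$reads))
          clusters[[i]]$n_members <- clusters[[i]]$n_members +
            clusters[[j]]$n_members
          keep[j] <- FALSE
          break
        }
      }
    }
  }
  clusters <- clusters[keep]
  clusters <- Filter(function(cl) length(cl$reads) >= min_support, clusters)
  out <- lapply(clusters, function(cl) {
    monomer_candidate(canonical_monomer(cl$consensus),
                      support_reads = length(cl$reads),
                      n_copies = cl$n_members, source = "period")
  })
  ord3 <- order(-vapply(out, function(x) x$support_reads, integer(1L)),
                vapply(out, function(x) x$consensus, character(1L)))
  out[ord3]
}

# ---- k-mer utilities --------------------------------------------------------

.kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq.int(k, n))
}

# Canonical (strand-min) k-mers per read, computed in one vectorised pass;
# k-mers containing N are dropped.
.read_canon_kmers <- function(reads, k) {
  kml <- lapply(unname(reads), .kmers_of, k = k)
  lens <- lengths(kml)
  all <- unlist(kml, use.names = FALSE)
  if (length(all) == 0L) return(rep(list(character(0)), length(reads)))
  keep <- !grepl("N", all, fixed = TRUE)
  u <- unique(all[keep])
  canon_of <- if (length(u)) {
    rcu <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(u)))
    stats::setNames(pmin(u, rcu), u)
  } else character(0)
  canon <- rep(NA_character_, length(all))
  canon[keep] <- canon_of[all[keep]]
  out <- split(canon, rep(seq_along(kml), lens))
  out <- lapply(out, function(v) v[!is.na(v)])
  # reads too short to yield a k-mer produce no split group
  full <- rep(list(character(0)), length(reads))
  full[as.integer(names(out))] <- out
  full
}

# canonical (strand-min) k-mer multiplicities across a read set
.kmer_counts <- function(reads, k, read_kmers = NULL) {
  if (is.null(read_kmers)) read_kmers <- .read_canon_kmers(reads, k)
  all <- unlist(read_kmers, use.names = FALSE)
  if (length(all) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(all)
  stats::setNames(as.integer(tab), names(tab))
}

# fraction of a read's k-mers found in a canonical k-mer set
.kmer_match_fraction <- function(reads, canon_set, k, read_kmers = NULL) {
  if (is.null(read_kmers)) read_kmers <- .read_canon_kmers(reads, k)
  vapply(read_kmers, function(km) {
    if (length(km) == 0L) return(0)
    mean(km %in% canon_set)
  }, numeric(1L), USE.NAMES = FALSE)
}

.canon_kmer_set <- function(s, k) {
  km <- unique(unlist(lapply(s, .kmers_of, k = k), use.names = FALSE))
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0L) return(character(0))
  rkm <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  unique(pmin(km, rkm))
}

# ---- long-monomer assembly --------------------------------------------------

# Offset-anchored overlap of an oriented read against a contig: shared exact
# k-mers imply candidate offsets; the best extension passing the identity
# check wins. Assumes substitution-only differences (no indels), which holds
# for the generator's arrays and read errors.
.best_extension <- function(contig, read, k, overlap_min, overlap_identity) {
  cl <- nchar(contig); rl <- nchar(read)
  ckm <- .kmers_of(substring(contig, max(1L, cl - 2L * rl), cl), k)
  coff <- max(1L, cl - 2L * rl) - 1L
  best <- NULL
  for (orient in c("+", "-")) {
    r <- if (orient == "+") read else reverse_complement(read)
    rkm <- .kmers_of(r, k)
    hit <- which(ckm %in% rkm)
    if (length(hit) == 0L) next
    # every contig occurrence of a shared k-mer implies a candidate offset;
    # the earliest read occurrence maximises the extension for that anchor
    offs <- unique(coff + hit - match(ckm[hit], rkm))
    for (off in offs) {
      # read starts at contig position off + 1
      ext <- off + rl - cl
      if (ext <= 0L) next
      ov <- rl - ext
      if (ov < overlap_min || off < 0L) next
      idt <- .hamming_identity(substring(contig, off + 1L, cl),
                               substring(r, 1L, ov))
      if (idt >= overlap_identity &&
          (is.null(best) || ext > best$ext)) {
        best <- list(ext = ext, tail = substring(r, ov + 1L, rl))
      }
    }
  }
  best
}

# Greedy assembly of long monomers (rul > read_length/2) from repetitive,
# non-periodic reads. Returns a list of monomer_candidate objects.
.assemble_long_monomers <- function(reads, kmer_count, cfg,
                                    read_kmers = NULL) {
  k <- cfg$kmer_k
  if (is.null(read_kmers)) read_kmers <- .read_canon_kmers(reads, k)
  names(read_kmers) <- names(reads)
  rl_max <- max(nchar(reads))
  pool <- names(reads)
  score <- vapply(read_kmers, function(km) {
    if (!length(km)) return(0)
    cnt <- kmer_count[km]
    cnt[is.na(cnt)] <- 0L
    mean(cnt)
  }, numeric(1L))
  out <- list()
  while (length(pool) >= cfg$min_support && length(out) < cfg$max_contigs) {
    seed <- pool[order(-score[pool], pool)][1L]
    contig <- reads[[seed]]
    pool <- setdiff(pool, seed)
    used <- seed
    repeat {
      if (nchar(contig) >= cfg$max_contig_length || length(pool) == 0L) break
      # candidate extenders share a k-mer with the contig tail
      tail_set <- .canon_kmer_set(substring(
        contig, max(1L, nchar(contig) - 3L * rl_max), nchar(contig)), k)
      frac <- .kmer_match_fraction(reads[pool], tail_set, k,
                                   read_kmers = read_kmers[pool])
      cand <- pool[frac > 0]
      if (length(cand) == 0L) break
      step <- NULL; step_read <- NULL
      for (rid in cand) {
        b <- .best_extension(contig, reads[[rid]], k, cfg$overlap_min,
                             cfg$overlap_identity)
        if (!is.null(b) && (is.null(step) || b$ext > step$ext)) {
          step <- b; step_read <- rid
        }
      }
      if (is.null(step)) break
      contig <- paste0(contig, step$tail)
      pool <- setdiff(pool, step_read)
      used <- c(used, step_read)
    }
    p <- detect_period(contig, min_period = cfg$min_period,
                       max_mismatch_rate = cfg$contig_tau)
    if (!is.na(p)) {
      wins <- .tile_windows(contig, p)
      wins <- wins[!grepl("N", wins, fixed = TRUE)]
      if (length(wins) >= 2L) {
        cl <- Reduce(function(acc, w) .cluster_add(acc, w, 1L, character(0)),
                     wins[-1L], .new_cluster(wins[1L], 1L, character(0)))
        cand <- monomer_candidate(canonical_monomer(cl$consensus),
                                  support_reads = length(used),
                                  n_copies = length(wins),
                                  source = "assembly")
        out[[length(out) + 1L]] <- cand
        # retire remaining reads of this family from the pool
        ref_set <- .canon_kmer_set(strrep(cand$consensus, 2L), k)
        if (length(pool)) {
          fr <- .kmer_match_fraction(reads[pool], ref_set, k,
                                     read_kmers = read_kmers[pool])
          pool <- pool[fr < 0.5]
        }
      }
    }
  }
  out
}

# ---- tandem evidence --------------------------------------------------------

#' Support and tandem evidence for a candidate monomer
#'
#' Aligns every read of the library locally against a tandem reference
#' (enough head-to-tail consensus copies to span any read, both strands,
#' k-mer prescreened). A read supports the candidate when its best hit
#' reaches `min_identity` over at least `min(0.8 * rul, 0.5 * read length)`
#' read bases. A supporting read shows tandem evidence when it contains two
#' full copies (aligned span >= 1.8 * rul, possible only when the monomer
#' fits twice in a read) or, for longer monomers, when its mate also
#' supports the candidate -- a lone dispersed copy can hold one read but not
#' a whole fragment, so dispersed repeats fail this test.
#'
#' @param consensus Candidate monomer.
#' @param lib A [read_library()].
#' @param min_identity Identity floor for a supporting hit.
#' @param prefilter_k K-mer size of the alignment prescreen.
#' @param read_kmers Optional cached canonical k-mer list for the library's
#'   reads (internal optimisation when screening many candidates).
#' @return List with `support_reads` (count) and `tandem_fraction`.
#' @export
tandem_stats <- function(consensus, lib, min_identity = 0.8,
                         prefilter_k = 12L, read_kmers = NULL) {
  stopifnot(inherits(lib, "read_library"))
  reads <- .all_reads(lib)
  rl_max <- max(nchar(reads))
  rul <- nchar(consensus)
  nrep <- max(3L, ceiling(2 * rl_max / rul) + 1L)
  ref <- strrep(consensus, nrep)
  ref_set <- .canon_kmer_set(ref, prefilter_k)
  frac <- .kmer_match_fraction(reads, ref_set, prefilter_k,
                               read_kmers = read_kmers)
  idx <- which(frac > 0)
  if (length(idx) == 0L) {
    return(list(support_reads = 0L, tandem_fraction = NA_real_))
  }
  af <- .align_batch(reads[idx], ref, mode = "local")
  ar <- .align_batch(reads[idx], reverse_complement(ref), mode = "local")
  better <- af$identity * af$pattern_bp >= ar$identity * ar$pattern_bp
  identity <- ifelse(better, af$identity, ar$identity)
  bp <- ifelse(better, af$pattern_bp, ar$pattern_bp)
  rlen <- nchar(reads[idx])
  support <- identity >= min_identity & bp >= pmin(0.8 * rul, 0.5 * rlen)
  sup_ids <- names(reads)[idx][support]
  if (length(sup_ids) == 0L) {
    return(list(support_reads = 0L, tandem_fraction = NA_real_))
  }
  pair_of <- sub("/[12]$", "", sup_ids)
  mate_of <- paste0(pair_of, ifelse(grepl("/1$", sup_ids), "/2", "/1"))
  in_read_tandem <- bp[support] >= 1.8 * rul
  mate_tandem <- mate_of %in% sup_ids
  tandem <- in_read_tandem | mate_tandem
  list(support_reads = length(sup_ids), tandem_fraction = mean(tandem))
}

#' Keep or reject a candidate on tandem evidence and length bounds
#'
#' Screens out candidates that are repetitive but not tandemly organised
#' (e.g. dispersed multigene families): kept iff `tandem_fraction >=
#' min_tandem_fraction` (inclusive) and the repeat unit length lies within
#' `[min_rul, max_rul]`.
#'
#' @param candidate A [monomer_candidate()] with populated `tandem_fraction`.
#' @param min_tandem_fraction Inclusive threshold.
#' @param min_rul,max_rul Repeat-unit-length bounds in bp.
#' @return `TRUE` (keep) or `FALSE` (reject).
#' @export
tandem_filter <- function(candidate, min_tandem_fraction = 0.8,
                          min_rul = 5L, max_rul = 1000L) {
  stopifnot(inherits(candidate, "monomer_candidate"))
  if (is.na(candidate$tandem_fraction)) return(FALSE)
  candidate$tandem_fraction >= min_tandem_fraction &&
    candidate$rul >= min_rul && candidate$rul <= max_rul
}

# ---- orchestration ----------------------------------------------------------

#' Discover candidate satellite monomers in one read sample
#'
#' Two complementary detection paths feed one candidate set. Short monomers
#' (up to half a read) reveal themselves as in-read periodicity:
#' [detect_period()] flags such reads, [extract_copies()] harvests their
#' copies and [cluster_candidates()] groups them. Monomers longer than half
#' a read cannot show two copies within one read, so repetitive reads
#' (identified by elevated k-mer multiplicity) lacking an in-read period are
#' greedily assembled into contigs by exact-k-mer-anchored overlaps, and the
#' contig period yields the monomer. Candidates from both paths are merged
#' at the family tier, scored with [tandem_stats()] and screened by
#' [tandem_filter()]; rejected candidates are reported in the
#' `"rejected"` attribute.
#'
#' @param lib A [read_library()] sample.
#' @param cfg A [discover_config()].
#' @return List of kept [monomer_candidate()]s, with rejected candidates as
#'   an attribute.
#' @export
discover_candidates <- function(lib, cfg = discover_config()) {
  stopifnot(inherits(lib, "read_library"))
  reads <- .all_reads(lib)
  periods <- detect_periods(reads, cfg$min_period, cfg$max_mismatch_rate)
  periodic <- which(!is.na(periods))
  copies <- if (length(periodic)) {
    do.call(rbind, lapply(periodic, function(i) {
      cp <- extract_copies(reads[[i]], periods[i])
      if (length(cp) == 0L) return(NULL)
      data.frame(copy = cp, read_id = names(reads)[i])
    }))
  } else NULL
  cands <- if (!is.null(copies) && nrow(copies)) {
    cluster_candidates(copies, min_support = cfg$min_support,
                       variant_threshold = cfg$variant_threshold,
                       family_threshold = cfg$family_threshold)
  } else list()
  # assembly pool: non-periodic reads from fragments wholly inside an array
  # (read and mate both repetitive)
  rk <- .read_canon_kmers(reads, cfg$kmer_k)
  counts <- .kmer_counts(reads, cfg$kmer_k, read_kmers = rk)
  high <- names(counts)[counts >= cfg$min_kmer_count]
  rep_frac <- .kmer_match_fraction(reads, high, cfg$kmer_k, read_kmers = rk)
  np <- length(reads) %/% 2L
  mate_idx <- c(np + seq_len(np), seq_len(np))
  rep_ok <- rep_frac >= cfg$repetitive_fraction
  pool_idx <- which(rep_ok & rep_ok[mate_idx] & is.na(periods))
  if (length(pool_idx) >= cfg$min_support) {
    cands <- c(cands, .assemble_long_monomers(reads[pool_idx], counts, cfg,
                                              read_kmers = rk[pool_idx]))
  }
  if (length(cands) == 0L) return(structure(list(), rejected = list()))
  # merge duplicates across paths at the family tier
  ord <- order(-vapply(cands, function(x) x$support_reads, integer(1L)),
               vapply(cands, function(x) x$consensus, character(1L)))
  cands <- cands[ord]
  keep <- rep(TRUE, length(cands))
  if (length(cands) > 1L) {
    for (j in 2L:length(cands)) {
      for (i in seq_len(j - 1L)) {
        if (!keep[i]) next
        if (rotation_identity(cands[[j]]$consensus, cands[[i]]$consensus) >
            cfg$family_threshold) {
          cands[[i]]$support_reads <- cands[[i]]$support_reads +
            cands[[j]]$support_reads
          keep[j] <- FALSE
          break
        }
      }
    }
  }
  cands <- cands[keep]
  # uniform support/tandem accounting across both paths
  rk12 <- .read_canon_kmers(reads, 12L)
  kept <- list(); rejected <- list()
  for (cand in cands) {
    st <- tandem_stats(cand$consensus, lib, read_kmers = rk12)
    cand$support_reads <- st$support_reads
    cand$tandem_fraction <- st$tandem_fraction
    ok <- cand$support_reads >= cfg$min_support &&
      tandem_filter(cand, cfg$min_tandem_fraction, cfg$min_rul, cfg$max_rul)
    if (ok) kept[[length(kept) + 1L]] <- cand
    else rejected[[length(rejected) + 1L]] <- cand
  }
  structure(kept, rejected = rejected)
}
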