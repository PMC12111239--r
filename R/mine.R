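#' Mining loop configuration
#'
#' @param sample_pairs_per_iteration Read pairs sampled from the remaining
#'   pool at each iteration (default 500,000, the full-scale value; desk
#'   runs use far less).
#' @param filter_identity,filter_coverage A read is removed from the pool
#'   when it matches a catalog consensus at `>= filter_identity` over
#'   `>= filter_coverage` of its length (both inclusive).
#' @param max_iterations Upper bound on mining iterations.
#' @param trim_window,trim_quality,trim_min_length Sliding-window quality
#'   trimming: reads are cut at the first window of `trim_window` bases with
#'   mean Phred quality below `trim_quality`; pairs with a mate shorter than
#'   `trim_min_length` are dropped.
#' @param seed Integer seed driving the per-iteration sampling.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(sample_pairs_per_iteration = 500000L,
                          filter_identity = 0.90, filter_coverage = 0.80,
                          max_iterations = 10L, trim_window = 4L,
                          trim_quality = 20, trim_min_length = 36L,
                          seed = 1L) {
  stopifnot(sample_pairs_per_iteration >= 1L, max_iterations >= 1L,
            filter_identity > 0, filter_identity <= 1,
            filter_coverage > 0, filter_coverage <= 1)
  structure(as.list(environment()), class = "mining_config")
}

#' Sliding-window quality trimming
#'
#' Scans each read 5' to 3' and truncates it immediately before the first
#' window of `trim_window` bases whose mean quality falls below
#' `trim_quality`. Pairs in which either trimmed mate is shorter than
#' `trim_min_length` are dropped entirely (mates travel together).
#'
#' @param lib A [read_library()].
#' @param cfg A [mining_config()].
#' @return The trimmed [read_library()].
#' @export
quality_trim <- function(lib, cfg = mining_config()) {
  stopifnot(inherits(lib, "read_library"))
  w <- cfg$trim_window
  keep_len <- function(qual) {
    vapply(qual, function(q) {
      qs <- utf8ToInt(q) - 33L
      n <- length(qs)
      if (n < w) return(n)
      cs <- cumsum(qs)
      roll <- (cs[w:n] - c(0L, cs)[1:(n - w + 1L)]) / w
      bad <- which(roll < cfg$trim_quality)
      if (length(bad) == 0L) n else bad[1L] - 1L
    }, integer(1L), USE.NAMES = FALSE)
  }
  l1 <- keep_len(lib$qual1); l2 <- keep_len(lib$qual2)
  ok <- l1 >= cfg$trim_min_length & l2 >= cfg$trim_min_length
  read_library(substr(lib$seq1[ok], 1L, l1[ok]),
               substr(lib$qual1[ok], 1L, l1[ok]),
               substr(lib$seq2[ok], 1L, l2[ok]),
               substr(lib$qual2[ok], 1L, l2[ok]),
               species = lib$species, sex = lib$sex, source = lib$source)
}

# Head-to-tail consensus copies long enough that any read (any phase) can
# align end-to-end; at least a dimer.
.tandem_reference <- function(consensus, span) {
  rul <- nchar(consensus)
  strrep(consensus, max(2L, ceiling(span / rul) + 1L))
}

# Per-read best local hit against one family reference (both strands,
# k-mer prescreened). Returns NULL or a data.frame indexed by read.
.family_hits <- function(reads, consensus, prefilter_k = 12L,
                         read_kmers = NULL) {
  ref <- .tandem_reference(consensus, 2L * max(nchar(reads)))
  ref_set <- .canon_kmer_set(ref, prefilter_k)
  frac <- .kmer_match_fraction(reads, ref_set, prefilter_k,
                               read_kmers = read_kmers)
  idx <- which(frac > 0)
  if (length(idx) == 0L) return(NULL)
  af <- .align_batch(reads[idx], ref, mode = "local")
  ar <- .align_batch(reads[idx], reverse_complement(ref), mode = "local")
  fwd <- af$identity * af$pattern_bp >= ar$identity * ar$pattern_bp
  best <- af
  best[!fwd, ] <- ar[!fwd, ]
  best$read_idx <- idx
  best
}

#' Remove catalog-matching reads from the pool
#'
#' A read is removed when its best local alignment against any family
#' consensus (as a head-to-tail tandem reference, both strands) reaches
#' `filter_identity` over at least `filter_coverage` of the read length
#' (both boundaries inclusive). Mates are removed together when either
#' matches.
#'
#' @param lib The read pool, a [read_library()].
#' @param catalog A non-empty [sat_catalog()].
#' @param cfg A [mining_config()].
#' @return The filtered [read_library()].
#' @export
filter_catalog_reads <- function(lib, catalog, cfg = mining_config()) {
  stopifnot(inherits(lib, "read_library"), inherits(catalog, "sat_catalog"))
  if (length(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  reads <- .all_reads(lib)
  rlen <- nchar(reads)
  rk <- .read_canon_kmers(reads, 12L)
  hit <- rep(FALSE, length(reads))
  for (f in catalog$families) {
    h <- .family_hits(reads, f$consensus, read_kmers = rk)
    if (is.null(h)) next
    i <- h$read_idx
    hit[i] <- hit[i] | (h$identity >= cfg$filter_identity &
                          h$pattern_bp >= cfg$filter_coverage * rlen[i])
  }
  n <- n_pairs(lib)
  pair_hit <- hit[seq_len(n)] | hit[n + seq_len(n)]
  subset_pairs(lib, which(!pair_hit))
}

#' Iterative satellitome mining
#'
#' Runs the detect-and-remove loop on a quality-trimmed read pool: sample
#' up to `sample_pairs_per_iteration` pairs, discover candidate monomers
#' ([discover_candidates()]), merge them into the working catalog by
#' similarity tier (>0.95 to an existing family: an occurrence of that
#' family's variant, logged; (0.80, 0.95]: a new named variant of the
#' family; <=0.80 to everything: a new family), then remove catalog-matching
#' reads from the pool. Terminates when an iteration founds no new family or
#' after `max_iterations`. The returned catalog is unranked; rank and name
#' it with abundances (see [rank_catalog()]).
#'
#' @param lib Input [read_library()] (the female library by default contains
#'   the W-linked superset in a ZW species).
#' @param cfg A [mining_config()].
#' @param dcfg A [discover_config()].
#' @return A [sat_catalog()] with attributes `mining_log` (per-iteration
#'   `data.frame`) and `pool` (the final filtered [read_library()]).
#' @export
run_mining <- function(lib, cfg = mining_config(), dcfg = discover_config()) {
  stopifnot(inherits(lib, "read_library"))
  pool <- quality_trim(lib, cfg)
  if (n_pairs(pool) == 0L) {
    stop("read pool is empty after quality trimming", call. = FALSE)
  }
  families <- list()
  log <- list()
  for (iter in seq_len(cfg$max_iterations)) {
    n <- n_pairs(pool)
    take <- min(cfg$sample_pairs_per_iteration, n)
    idx <- if (take < n) {
      withr::with_seed(.sub_seed(cfg$seed, 1000L + iter),
                       sort(sample.int(n, take)))
    } else seq_len(n)
    sample_lib <- subset_pairs(pool, idx)
    cands <- discover_candidates(sample_lib, dcfg)
    n_new <- 0L; n_var <- 0L
    for (cand in cands) {
      if (length(families) == 0L) {
        ids <- numeric(0)
      } else {
        ids <- vapply(families, function(f)
          rotation_identity(cand$consensus, f$consensus), numeric(1L))
      }
      if (length(ids) && max(ids) > dcfg$variant_threshold) {
        # same variant of an existing family; nothing new to record
        n_var <- n_var + 1L
      } else if (length(ids) && max(ids) > dcfg$family_threshold) {
        k <- which.max(ids)
        families[[k]]$variants <- rbind(
          families[[k]]$variants,
          data.frame(consensus = cand$consensus, identity = max(ids)))
        n_var <- n_var + 1L
      } else {
        fam <- sat_family(cand$consensus,
                          support_reads = cand$support_reads)
        families[[length(families) + 1L]] <- fam
        n_new <- n_new + 1L
      }
    }
    before <- n_pairs(pool)
    if (length(families) > 0L) {
      pool <- filter_catalog_reads(pool, sat_catalog(families), cfg)
    }
    log[[iter]] <- data.frame(
      iteration = iter, sampled_pairs = take,
      candidates = length(cands),
      rejected_candidates = length(attr(cands, "rejected")),
      new_families = n_new, variant_matches = n_var,
      pool_pairs_before = before, pool_pairs_after = n_pairs(pool))
    message(sprintf(
      "mining iteration %d: %d candidates, %d new families, pool %d -> %d pairs",
      iter, length(cands), n_new, before, n_pairs(pool)))
    if (n_new == 0L) break
  }
  structure(sat_catalog(families),
            mining_log = do.call(rbind, log), pool = pool)
}

#' Rank and name a mined catalog by quantified abundance
#'
#' Masks the library against the catalog, estimates per-family genome
#' fractions and applies [assign_names()].
#'
#' @param catalog An unranked [sat_catalog()] from [run_mining()].
#' @param lib The [read_library()] to quantify against.
#' @param prefix Species code for the names.
#' @param qcfg A [quant_config()].
#' @return The named, ranked catalog.
#' @export
rank_catalog <- function(catalog, lib, prefix = "Xxx",
                         qcfg = quant_config()) {
  stopifnot(inherits(catalog, "sat_catalog"))
  if (length(catalog) == 0L) return(sat_catalog(list(), prefix = prefix))
  # temporary names so hits can refer to families
  for (i in seq_along(catalog$families)) {
    if (is.na(catalog$families[[i]]$name)) {
      catalog$families[[i]]$name <- sprintf("tmp%03d", i)
    }
  }
  hits <- mask_reads(lib, catalog, qcfg)
  ab <- abundance(hits, attr(hits, "total_sampled_bp"),
                  families = vapply(catalog$families, function(f) f$name,
                                    character(1L)))
  for (i in seq_along(catalog$families)) {
    catalog$families[[i]]$abundance <-
      ab$fraction[ab$family == catalog$families[[i]]$name]
    catalog$families[[i]]$name <- NA_character_
  }
  assign_names(catalog, prefix)
}
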