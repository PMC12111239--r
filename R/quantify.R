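#' Quantification configuration
#'
#' @param sample_pairs Read pairs sampled for quantification (default
#'   5,000,000, the full-scale value; smaller libraries are used whole).
#' @param min_hit_identity,min_hit_length Hits below this identity or with
#'   fewer aligned read bases are discarded.
#' @param bin_width Landscape bin width on the K2P distance axis.
#' @param overflow Distances above this (or saturated) fall into the
#'   overflow bin.
#' @param prefilter_k K-mer size of the alignment prescreen.
#' @param seed Integer seed for the subsample.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(sample_pairs = 5000000L, min_hit_identity = 0.70,
                         min_hit_length = 30L, bin_width = 0.01,
                         overflow = 0.5, prefilter_k = 12L, seed = 1L) {
  stopifnot(min_hit_identity > 0, min_hit_identity <= 1, bin_width > 0)
  structure(as.list(environment()), class = "quant_config")
}

#' Mask reads against a satellite catalog
#'
#' Aligns each read locally against every family consensus (as a
#' head-to-tail tandem reference, both strands) and keeps, per read, the
#' single best hit by aligned-bp x identity score (ties go to the
#' lexicographically first family name), provided it reaches
#' `min_hit_identity` and `min_hit_length`. Transitions and transversions
#' are counted over ungapped aligned sites and converted to a K2P distance
#' (`Inf` = saturated). Mates are treated as independent sequences.
#'
#' @param lib A [read_library()].
#' @param catalog A non-empty, named [sat_catalog()].
#' @param cfg A [quant_config()].
#' @return `data.frame` of hits with columns `read`, `family`,
#'   `aligned_bp`, `identity`, `transitions`, `transversions`, `sites`,
#'   `k2p`; attributes `total_sampled_bp` (bp of all sampled reads, the
#'   abundance denominator) and `n_sampled_reads`.
#' @export
mask_reads <- function(lib, catalog, cfg = quant_config()) {
  stopifnot(inherits(lib, "read_library"), inherits(catalog, "sat_catalog"))
  if (length(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  n <- n_pairs(lib)
  if (cfg$sample_pairs < n) {
    idx <- withr::with_seed(.sub_seed(cfg$seed, 7L),
                            sort(sample.int(n, cfg$sample_pairs)))
    lib <- subset_pairs(lib, idx)
  }
  reads <- .all_reads(lib)
  fam_names <- vapply(catalog$families, function(f) f$name, character(1L))
  if (anyNA(fam_names)) {
    stop("catalog families must be named before masking", call. = FALSE)
  }
  ord <- order(fam_names)
  nr <- length(reads)
  best_score <- rep(-Inf, nr)
  best <- data.frame(family = rep(NA_character_, nr), aligned_bp = 0L,
                     identity = 0, transitions = 0L, transversions = 0L,
                     sites = 0L)
  rk <- .read_canon_kmers(reads, cfg$prefilter_k)
  for (j in ord) {
    f <- catalog$families[[j]]
    h <- .family_hits(reads, f$consensus, prefilter_k = cfg$prefilter_k,
                      read_kmers = rk)
    if (is.null(h)) next
    score <- h$identity * h$pattern_bp
    i <- h$read_idx
    upd <- score > best_score[i]  # strict: ties keep the earlier family name
    i <- i[upd]
    best_score[i] <- score[upd]
    best$family[i] <- fam_names[j]
    best$aligned_bp[i] <- h$pattern_bp[upd]
    best$identity[i] <- h$identity[upd]
    best$transitions[i] <- h$transitions[upd]
    best$transversions[i] <- h$transversions[upd]
    best$sites[i] <- h$sites[upd]
  }
  keep <- !is.na(best$family) & best$identity >= cfg$min_hit_identity &
    best$aligned_bp >= cfg$min_hit_length & best$sites >= 1L
  hits <- cbind(read = names(reads)[keep], best[keep, , drop = FALSE])
  rownames(hits) <- NULL
  hits$k2p <- if (nrow(hits)) {
    k2p_distance(hits$transitions, hits$transversions, hits$sites)
  } else numeric(0)
  structure(hits, total_sampled_bp = sum(nchar(reads)),
            n_sampled_reads = nr)
}

#' Per-family genomic abundance from masked reads
#'
#' The abundance of a family is the proportion of read bases assigned to it
#' relative to the total number of analysed nucleotides.
#'
#' @param hits Hit table from [mask_reads()].
#' @param total_sampled_bp Total bp analysed (defaults to the attribute
#'   carried by `hits`).
#' @param families Optional character vector of family names to report
#'   (families without hits get fraction 0).
#' @return `data.frame` with `family`, `aligned_bp`, `n_reads`, `fraction`;
#'   attribute `total_satellite_fraction` is the sum over families.
#' @export
abundance <- function(hits, total_sampled_bp = attr(hits, "total_sampled_bp"),
                      families = NULL) {
  if (is.null(total_sampled_bp) || total_sampled_bp <= 0) {
    stop("'total_sampled_bp' must be positive", call. = FALSE)
  }
  fams <- sort(unique(c(families, hits$family)))
  bp <- vapply(fams, function(f) sum(hits$aligned_bp[hits$family == f]),
               numeric(1L))
  nr <- vapply(fams, function(f) sum(hits$family == f), integer(1L))
  out <- data.frame(family = fams, aligned_bp = bp, n_reads = nr,
                    fraction = bp / total_sampled_bp, row.names = NULL)
  structure(out, total_satellite_fraction = sum(out$fraction))
}

#' K2P repeat landscapes
#'
#' Bins the aligned bp of every hit by its K2P distance from the family
#' consensus (bin width `bin_width`), with an overflow bin for saturated
#' hits or distances above `overflow`. Empty bins are retained up to the
#' highest occupied bin, so the histogram has no holes. Per family, the bp
#' column sums exactly to the family's total aligned bp.
#'
#' @param hits Hit table from [mask_reads()].
#' @param bin_width,overflow See [quant_config()].
#' @return `data.frame` with `family`, `bin_low`, `bin_high`, `bp`,
#'   `fraction_family` (of the family's aligned bp) and `fraction_total`
#'   (of all aligned bp).
#' @export
landscape <- function(hits, bin_width = 0.01, overflow = 0.5) {
  total_bp <- sum(hits$aligned_bp)
  out <- lapply(sort(unique(hits$family)), function(f) {
    h <- hits[hits$family == f, , drop = FALSE]
    over <- is.infinite(h$k2p) | h$k2p >= overflow
    bin <- floor(h$k2p[!over] / bin_width)
    nbin <- if (length(bin)) max(bin) + 1L else 0L
    bp <- vapply(seq_len(nbin) - 1L, function(b)
      sum(h$aligned_bp[!over][bin == b]), numeric(1L))
    df <- data.frame(family = f,
                     bin_low = (seq_len(nbin) - 1L) * bin_width,
                     bin_high = seq_len(nbin) * bin_width, bp = bp)
    if (any(over)) {
      df <- rbind(df, data.frame(family = f, bin_low = overflow,
                                 bin_high = Inf,
                                 bp = sum(h$aligned_bp[over])))
    }
    df$fraction_family <- df$bp / sum(h$aligned_bp)
    df
  })
  out <- if (length(out)) do.call(rbind, out) else {
    data.frame(family = character(), bin_low = numeric(),
               bin_high = numeric(), bp = numeric(),
               fraction_family = numeric())
  }
  out$fraction_total <- if (total_bp > 0) out$bp / total_bp else numeric(0)
  rownames(out) <- NULL
  out
}
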