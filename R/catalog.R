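#' Construct a satellite DNA family record
#'
#' @param consensus Canonical monomer sequence, or `NULL` when only the
#'   repeat unit length is known (e.g. a family quoted by name).
#' @param rul Repeat unit length in bp; defaults to `nchar(consensus)`.
#' @param abundance Genome fraction occupied by the family (may be `NA`
#'   before quantification).
#' @param name Catalog name (`<Prefix>Sat<NN>-<RUL>`), assigned by
#'   [assign_names()].
#' @param rank 1-based rank by decreasing abundance.
#' @param variants `data.frame` with columns `consensus` and `identity`
#'   (rotation identity to the family consensus, in (0.80, 1]).
#' @param support_reads Reads supporting the family at discovery time.
#' @param superfamily_id Optional group label from [group_superfamilies()].
#' @return An object of class `sat_family`.
#' @export
sat_family <- function(consensus = NULL, rul = NULL, abundance = NA_real_,
                       name = NA_character_, rank = NA_integer_,
                       variants = data.frame(consensus = character(),
                                             identity = numeric()),
                       support_reads = NA_integer_,
                       superfamily_id = NA_integer_) {
  if (is.null(consensus) && is.null(rul)) {
    stop("either 'consensus' or 'rul' must be given", call. = FALSE)
  }
  if (!is.null(consensus)) {
    .check_seq(consensus, allow_n = FALSE, arg = "consensus")
    if (is.null(rul)) rul <- nchar(consensus)
    if (rul != nchar(consensus)) {
      stop("'rul' must equal the consensus length", call. = FALSE)
    }
  }
  structure(list(
    name = name, rank = as.integer(rank), consensus = consensus,
    rul = as.integer(rul), abundance = abundance, variants = variants,
    support_reads = as.integer(support_reads),
    superfamily_id = as.integer(superfamily_id)
  ), class = "sat_family")
}

#' Construct a satellite DNA catalog
#'
#' @param families List of [sat_family()] objects.
#' @param prefix Species code used in family names (e.g. `"Pko"`); `"Sat"`
#'   and the rank number are appended by [assign_names()].
#' @return An object of class `sat_catalog`.
#' @export
sat_catalog <- function(families = list(), prefix = "Xxx") {
  stopifnot(is.list(families))
  structure(list(prefix = prefix, families = families), class = "sat_catalog")
}

#' Parse a family record from its catalog name
#'
#' Names follow `<Prefix>Sat<NN>-<RUL>` (e.g. `"PkoSat01-168"`), where `NN`
#' is the abundance rank and `RUL` the repeat unit length in bp. Useful for
#' computing catalog statistics from published family names alone.
#'
#' @param name Character vector of catalog names.
#' @return List of [sat_family()] objects (consensus unknown).
#' @examples
#' summary_stats(sat_catalog(family_from_name(c(
#'   "PkoSat01-168", "PkoSat02-245", "PkoSat03-324",
#'   "PkoSat04-149", "PkoSat05-166", "PkoSat06-150")), prefix = "Pko"))
#' @export
family_from_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+)Sat([0-9]+)-([0-9]+)$", name))
  lapply(seq_along(name), function(i) {
    g <- m[[i]]
    if (length(g) != 4L) {
      stop("cannot parse catalog name: ", name[i], call. = FALSE)
    }
    sat_family(rul = as.integer(g[4L]), rank = as.integer(g[3L]),
               name = name[i])
  })
}

#' @export
length.sat_catalog <- function(x) length(x$families)

#' @export
print.sat_catalog <- function(x, ...) {
  cat(sprintf("<sat_catalog> prefix %s, %d families\n", x$prefix, length(x)))
  if (length(x) > 0L) print(as.data.frame(x))
  invisible(x)
}

#' @method as.data.frame sat_catalog
#' @export
as.data.frame.sat_catalog <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(
    name = vapply(x$families, function(f) f$name, character(1L)),
    rank = vapply(x$families, function(f) f$rank, integer(1L)),
    rul = vapply(x$families, function(f) f$rul, integer(1L)),
    abundance = vapply(x$families, function(f) f$abundance, numeric(1L)),
    n_variants = vapply(x$families, function(f) nrow(f$variants), integer(1L)),
    superfamily_id = vapply(x$families, function(f) f$superfamily_id,
                            integer(1L)),
    consensus = vapply(x$families, function(f)
      if (is.null(f$consensus)) NA_character_ else f$consensus, character(1L)),
    stringsAsFactors = FALSE
  )
}

#' Similarity tier of a pairwise identity
#'
#' Monomer pairs are tiered by identity: variants (>95%), families
#' (80-95%], superfamilies (50-80%], unrelated (<=50%). Upper bounds are
#' inclusive and lower bounds exclusive, so the three published intervals
#' partition (0.5, 1].
#'
#' @param identity Numeric vector in `[0, 1]`.
#' @return Character vector with values `"variant"`, `"family"`,
#'   `"superfamily"`, `"unrelated"`.
#' @examples
#' tier_of(c(0.96, 0.85, 0.60, 0.50))
#' @export
tier_of <- function(identity) {
  if (any(identity < 0 | identity > 1)) {
    stop("'identity' must lie in [0, 1]", call. = FALSE)
  }
  out <- character(length(identity))
  out[identity > 0.95] <- "variant"
  out[identity > 0.80 & identity <= 0.95] <- "family"
  out[identity > 0.50 & identity <= 0.80] <- "superfamily"
  out[identity <= 0.50] <- "unrelated"
  out
}

#' Rank and name catalog families by abundance
#'
#' Families are sorted by decreasing abundance (ties broken by consensus,
#' then existing name, lexicographically) and named
#' `<prefix>Sat<NN>-<RUL>` with the rank zero-padded to two digits, so the
#' most abundant family is number 01. Idempotent.
#'
#' @param catalog A [sat_catalog()] with abundances populated.
#' @param prefix Species code; defaults to the catalog's own prefix.
#' @return The renamed, re-ordered catalog.
#' @examples
#' fams <- list(sat_family("ACGTACGTACGT", abundance = 0.01),
#'              sat_family("AATTCCGGAATTCCG", abundance = 0.03))
#' as.data.frame(assign_names(sat_catalog(fams, prefix = "Tst")))
#' @export
assign_names <- function(catalog, prefix = catalog$prefix) {
  stopifnot(inherits(catalog, "sat_catalog"))
  ab <- vapply(catalog$families, function(f) f$abundance, numeric(1L))
  if (anyNA(ab)) stop("all families need an abundance before naming",
                      call. = FALSE)
  tie <- vapply(catalog$families, function(f)
    if (!is.null(f$consensus)) f$consensus else f$name, character(1L))
  ord <- order(-ab, tie)
  fams <- catalog$families[ord]
  for (i in seq_along(fams)) {
    fams[[i]]$rank <- i
    fams[[i]]$name <- sprintf("%sSat%02d-%d", prefix, i, fams[[i]]$rul)
  }
  sat_catalog(fams, prefix = prefix)
}

#' Catalog summary statistics
#'
#' Median (mean of the central two when the count is even), minimum and
#' maximum repeat unit length, and the A+T fraction computed over the
#' unweighted concatenation of the family consensus monomers (`NA` when any
#' consensus is unknown).
#'
#' @param catalog A non-empty [sat_catalog()].
#' @return List with `median_rul`, `min_rul`, `max_rul`, `at_fraction`.
#' @export
summary_stats <- function(catalog) {
  stopifnot(inherits(catalog, "sat_catalog"))
  if (length(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  ruls <- vapply(catalog$families, function(f) f$rul, integer(1L))
  cons <- vapply(catalog$families, function(f)
    if (is.null(f$consensus)) NA_character_ else f$consensus, character(1L))
  at <- if (anyNA(cons)) NA_real_ else {
    all_bases <- paste(cons, collapse = "")
    counts <- table(strsplit(all_bases, "")[[1L]])
    sum(counts[names(counts) %in% c("A", "T")]) / nchar(all_bases)
  }
  list(median_rul = stats::median(ruls), min_rul = min(ruls),
       max_rul = max(ruls), at_fraction = at)
}

#' Merge two catalogs by the family tier
#'
#' Supports mining the sexes independently: families of `b` whose rotation
#' identity to some family of `a` exceeds the family threshold (0.80) are
#' recorded as variants of that family (unless they exceed the variant
#' threshold, in which case they are the same variant and only counted);
#' the rest are appended as new families. The result is unranked -- rank it
#' with [rank_catalog()] or [assign_names()].
#'
#' @param a,b [sat_catalog()] objects carrying consensus sequences.
#' @param variant_threshold,family_threshold Tier boundaries.
#' @return A merged, unranked [sat_catalog()] with `a`'s prefix.
#' @export
merge_catalogs <- function(a, b, variant_threshold = 0.95,
                           family_threshold = 0.80) {
  stopifnot(inherits(a, "sat_catalog"), inherits(b, "sat_catalog"))
  fams <- lapply(a$families, function(f) { f$name <- NA_character_;
    f$rank <- NA_integer_; f$abundance <- NA_real_; f })
  for (g in b$families) {
    ids <- if (length(fams)) vapply(fams, function(f)
      rotation_identity(g$consensus, f$consensus), numeric(1L)) else numeric(0)
    if (length(ids) && max(ids) > variant_threshold) {
      next  # same variant of an existing family
    } else if (length(ids) && max(ids) > family_threshold) {
      k <- which.max(ids)
      fams[[k]]$variants <- rbind(
        fams[[k]]$variants,
        data.frame(consensus = g$consensus, identity = max(ids)))
    } else {
      g$name <- NA_character_; g$rank <- NA_integer_
      g$abundance <- NA_real_
      fams[[length(fams) + 1L]] <- g
    }
  }
  sat_catalog(fams, prefix = a$prefix)
}

#' Group catalog families into superfamilies
#'
#' Single-linkage grouping: families whose pairwise identity falls in the
#' superfamily tier (50-80%] are connected, and connected components share a
#' `superfamily_id`. Variant- or family-tier identities between final
#' catalog entries should not occur (the mining loop merges those), but are
#' treated as links too. Singletons keep their own id.
#'
#' The identity used here is rotation- and strand-invariant but ungapped and
#' normalised by the longer monomer length (best cyclic match count / longer
#' RUL): gapped glocal identity between unrelated monomers of similar length
#' sits near 55-60% under the package's permissive gap costs, which would
#' place every random pair in the superfamily tier, and a short monomer
#' matching some window of a long one would link families of very different
#' repeat unit lengths.
#'
#' @param catalog A [sat_catalog()] whose families carry consensus sequences.
#' @return The catalog with `superfamily_id` populated.
#' @export
group_superfamilies <- function(catalog) {
  stopifnot(inherits(catalog, "sat_catalog"))
  n <- length(catalog)
  if (n == 0L) return(catalog)
  cons <- vapply(catalog$families, function(f) f$consensus, character(1L))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        id <- .monomer_identity_norm(cons[i], cons[j])
        if (id > 0.50) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  ids <- match(roots, unique(roots))
  for (i in seq_len(n)) catalog$families[[i]]$superfamily_id <- ids[i]
  catalog
}
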