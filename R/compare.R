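#' Screen a read library for catalog families
#'
#' The in-silico analogue of probing another sample for a known satellite:
#' the library is masked against the catalog and a family is called present
#' when it attracts at least `min_reads` supporting reads and at least
#' `min_fraction` of the analysed nucleotides.
#'
#' @param catalog A named [sat_catalog()].
#' @param lib A [read_library()].
#' @param min_reads,min_fraction Detection floor (both must be met).
#' @param cfg A [quant_config()].
#' @param hits Optional precomputed [mask_reads()] result for `lib` against
#'   `catalog`, to avoid re-aligning.
#' @return `data.frame` with `family`, `fraction`, `n_reads`, `present`;
#'   attribute `label` carries the library description.
#' @export
screen_library <- function(catalog, lib, min_reads = 5L,
                           min_fraction = 1e-5, cfg = quant_config(),
                           hits = NULL) {
  stopifnot(inherits(catalog, "sat_catalog"))
  if (length(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  if (is.null(hits)) hits <- mask_reads(lib, catalog, cfg)
  fam_names <- vapply(catalog$families, function(f) f$name, character(1L))
  ab <- abundance(hits, attr(hits, "total_sampled_bp"), families = fam_names)
  out <- data.frame(family = ab$family, fraction = ab$fraction,
                    n_reads = ab$n_reads,
                    present = ab$n_reads >= min_reads &
                      ab$fraction >= min_fraction)
  structure(out, label = paste(lib$species, lib$sex))
}

#' Female-versus-male abundance ratios (W-linkage candidates)
#'
#' Sequence-level analogue of comparative genomic hybridization between the
#' sexes: both libraries are quantified against the catalog and each family
#' gets `log2((female_fraction + eps) / (male_fraction + eps))`. In a ZW
#' species a W-linked satellite is present only in females, so a strongly
#' positive ratio (at least `bias_threshold`) flags a W candidate. The
#' pseudo-fraction `eps` keeps zero abundances finite; ratios are capped at
#' +/- 20 for sortable reports.
#'
#' @param catalog A named [sat_catalog()].
#' @param female_lib,male_lib [read_library()] objects.
#' @param eps Pseudo-fraction added to both abundances.
#' @param bias_threshold log2-ratio at or above which a family is flagged.
#' @param cfg A [quant_config()].
#' @param female_hits,male_hits Optional precomputed [mask_reads()] results.
#' @return `data.frame` with `family`, `female_fraction`, `male_fraction`,
#'   `log2_ratio`, `w_candidate`.
#' @export
sex_bias <- function(catalog, female_lib, male_lib, eps = 1e-7,
                     bias_threshold = 1.0, cfg = quant_config(),
                     female_hits = NULL, male_hits = NULL) {
  stopifnot(inherits(catalog, "sat_catalog"))
  if (length(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  if (n_pairs(female_lib) == 0L || n_pairs(male_lib) == 0L) {
    stop("both libraries must be non-empty", call. = FALSE)
  }
  fam_names <- vapply(catalog$families, function(f) f$name, character(1L))
  hf <- if (is.null(female_hits)) mask_reads(female_lib, catalog, cfg) else
    female_hits
  hm <- if (is.null(male_hits)) mask_reads(male_lib, catalog, cfg) else
    male_hits
  af <- abundance(hf, attr(hf, "total_sampled_bp"), families = fam_names)
  am <- abundance(hm, attr(hm, "total_sampled_bp"), families = fam_names)
  stopifnot(identical(af$family, am$family))
  ratio <- log2((af$fraction + eps) / (am$fraction + eps))
  ratio <- pmin(pmax(ratio, -20), 20)
  data.frame(family = af$family, female_fraction = af$fraction,
             male_fraction = am$fraction, log2_ratio = ratio,
             w_candidate = ratio >= bias_threshold)
}
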