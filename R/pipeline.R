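#' Run the whole pipeline on a synthetic experiment
#'
#' Simulates female and male low-pass libraries from a [sim_spec()], mines
#' the female library (the superset that contains any W-linked repeat),
#' ranks and names the catalog by quantified abundance, groups
#' superfamilies, builds K2P landscapes, screens the male library and
#' computes female/male abundance ratios. When `out_dir` is given, all
#' tables, the catalog FASTA and a JSON manifest are written there.
#'
#' @param spec A [sim_spec()].
#' @param prefix Species code for family names.
#' @param cfg A [mining_config()].
#' @param dcfg A [discover_config()].
#' @param qcfg A [quant_config()].
#' @param min_reads,min_fraction Detection floor of [screen_library()].
#' @param eps,bias_threshold Parameters of [sex_bias()].
#' @param out_dir Optional output directory.
#' @return List with `truth`, `catalog`, `summary`, `abundance`,
#'   `landscape`, `screen_male`, `sex_bias`, `mining_log`, and the two
#'   simulated libraries (`female_lib`, `male_lib`) plus the final filtered
#'   `pool`.
#' @export
run_all <- function(spec = sim_spec(), prefix = "Sim",
                    cfg = mining_config(seed = spec$seed),
                    dcfg = discover_config(), qcfg = quant_config(),
                    min_reads = 5L, min_fraction = 1e-5, eps = 1e-7,
                    bias_threshold = 1.0, out_dir = NULL) {
  g <- build_genomes(spec)
  lib_f <- simulate_reads(g$female, spec, sex = "female")
  lib_m <- simulate_reads(g$male, spec, sex = "male")
  mined <- run_mining(lib_f, cfg, dcfg)
  catalog <- rank_catalog(mined, lib_f, prefix = prefix, qcfg = qcfg)
  if (length(catalog) > 0L) catalog <- group_superfamilies(catalog)
  hits <- if (length(catalog)) mask_reads(lib_f, catalog, qcfg) else NULL
  hits_m <- if (length(catalog)) mask_reads(lib_m, catalog, qcfg) else NULL
  fam_names <- vapply(catalog$families, function(f) f$name, character(1L))
  ab <- if (length(catalog)) {
    abundance(hits, attr(hits, "total_sampled_bp"), families = fam_names)
  } else NULL
  land <- if (length(catalog)) landscape(hits, qcfg$bin_width,
                                         qcfg$overflow) else NULL
  scr <- if (length(catalog)) {
    screen_library(catalog, lib_m, min_reads, min_fraction, qcfg,
                   hits = hits_m)
  } else NULL
  sb <- if (length(catalog)) {
    sex_bias(catalog, lib_f, lib_m, eps, bias_threshold, qcfg,
             female_hits = hits, male_hits = hits_m)
  } else NULL
  smry <- if (length(catalog)) summary_stats(catalog) else NULL
  res <- list(truth = g$truth, catalog = catalog, summary = smry,
              abundance = ab, landscape = land, screen_male = scr,
              sex_bias = sb, mining_log = attr(mined, "mining_log"),
              female_lib = lib_f, male_lib = lib_m, hits_female = hits,
              pool = attr(mined, "pool"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (length(catalog)) {
      write_catalog(catalog, file.path(out_dir, "catalog.fasta"))
    }
    tables <- Filter(Negate(is.null), list(
      truth = g$truth, mining_log = res$mining_log, abundance = ab,
      landscape = land, screen_male = scr, sex_bias = sb,
      catalog = if (length(catalog)) as.data.frame(catalog) else NULL))
    cfg_all <- list(sim = unclass(spec), mining = unclass(cfg),
                    discover = unclass(dcfg), quant = unclass(qcfg),
                    prefix = prefix)
    cfg_all$sim$families <- lapply(spec$families, unclass)
    write_report(tables, out_dir,
                 manifest = list(stage = "run_all", seed = spec$seed,
                                 config = cfg_all,
                                 summary = smry))
  }
  res
}
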