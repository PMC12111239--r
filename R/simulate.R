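#' Specify a planted satellite family
#'
#' Describes one tandem-repeat family to plant into a synthetic genome:
#' either an explicit monomer or a generation recipe (length + GC), the
#' genome fraction it should occupy, how many array loci it is split
#' across, the expected per-copy K2P divergence from the master monomer,
#' the transition:transversion ratio of those substitutions, and its
#' linkage. A `W_linked` family is present only in the female genome,
#' emulating a W-chromosome satellite in a ZW species. `dispersed`
#' arrangement plants every copy as a lone insertion (a decoy mimicking
#' interspersed repeats such as multigene families, which the tandem filter
#' must reject).
#'
#' @param name Family label used in the truth table.
#' @param monomer Explicit monomer sequence, or `NULL` to generate one.
#' @param rul Monomer length in bp (>= 5) when generating.
#' @param gc GC fraction of a generated monomer.
#' @param target_abundance Fraction of the genome occupied, in (0, 0.5].
#' @param n_loci Number of array loci.
#' @param divergence Expected per-copy K2P distance from the master monomer.
#' @param ts_tv_ratio Transition:transversion probability ratio (kappa).
#' @param linkage `"autosomal"` or `"W_linked"`.
#' @param arrangement `"tandem"` (head-to-tail arrays) or `"dispersed"`.
#' @return An object of class `planted_family`.
#' @export
planted_family <- function(name, monomer = NULL, rul = NULL, gc = 0.5,
                           target_abundance, n_loci = 4L, divergence = 0.02,
                           ts_tv_ratio = 2,
                           linkage = c("autosomal", "W_linked"),
                           arrangement = c("tandem", "dispersed")) {
  linkage <- match.arg(linkage)
  arrangement <- match.arg(arrangement)
  if (!is.null(monomer)) {
    .check_seq(monomer, allow_n = FALSE, arg = "monomer")
    rul <- nchar(monomer)
  }
  if (is.null(rul) || rul < 5L) stop("monomer length must be >= 5",
                                     call. = FALSE)
  if (target_abundance <= 0 || target_abundance > 0.5) {
    stop("target_abundance must lie in (0, 0.5]", call. = FALSE)
  }
  if (divergence < 0) stop("divergence must be >= 0", call. = FALSE)
  structure(list(name = name, monomer = monomer, rul = as.integer(rul),
                 gc = gc, target_abundance = target_abundance,
                 n_loci = as.integer(n_loci), divergence = divergence,
                 ts_tv_ratio = ts_tv_ratio, linkage = linkage,
                 arrangement = arrangement),
            class = "planted_family")
}

#' Default planted families
#'
#' Five families spanning the monomer-length and abundance structure of a
#' typical snake satellitome: repeat unit lengths from 25 to 200 bp,
#' genome fractions 2-8%, per-copy divergences 1-5%, and one W-linked
#' family present only in the female genome.
#'
#' @return List of [planted_family()] objects.
#' @export
default_planted_families <- function() {
  list(
    planted_family("simFamA", rul = 170L, target_abundance = 0.08,
                   divergence = 0.02),
    planted_family("simFamB", rul = 160L, target_abundance = 0.05,
                   divergence = 0.02, linkage = "W_linked"),
    planted_family("simFamC", rul = 200L, target_abundance = 0.04,
                   divergence = 0.05),
    planted_family("simFamD", rul = 48L, target_abundance = 0.025,
                   divergence = 0.03),
    planted_family("simFamE", rul = 25L, target_abundance = 0.02,
                   divergence = 0.01)
  )
}

#' Specify a synthetic low-pass sequencing experiment
#'
#' @param genome_length Haploid genome length in bp.
#' @param families List of [planted_family()] objects.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp.
#' @param coverage Fold coverage per haploid genome (may be < 1, low-pass).
#' @param error_rate Per-base sequencing error probability.
#' @param background_gc GC fraction of the random background sequence.
#' @param seed Integer seed controlling every random choice downstream.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(genome_length = 2e6,
                     families = default_planted_families(),
                     read_length = 100L, insert_mean = 300, insert_sd = 30,
                     coverage = 0.2, error_rate = 0.001,
                     background_gc = 0.5, seed = 1L) {
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  if (read_length > insert_mean) {
    stop("read_length must not exceed insert_mean", call. = FALSE)
  }
  tot <- sum(vapply(families, function(f) f$target_abundance, numeric(1L)))
  if (tot > 0.8) stop("planted families exceed 0.8 of the genome",
                      call. = FALSE)
  structure(list(genome_length = genome_length, families = families,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, error_rate = error_rate,
                 background_gc = background_gc, seed = as.integer(seed)),
            class = "sim_spec")
}

.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

.random_bases <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a random monomer without internal periodicity
#'
#' Draws i.i.d. bases at the requested GC until the monomer has no internal
#' period (checked on its self-dimer), so that the detected period of a
#' planted array equals the intended repeat unit length.
#'
#' @param rul Monomer length in bp.
#' @param gc GC fraction.
#' @return A monomer string (not canonicalised).
#' @export
random_monomer <- function(rul, gc = 0.5) {
  for (i in 1:100) {
    m <- paste(.random_bases(rul, gc), collapse = "")
    p <- detect_period(strrep(m, 2L), min_period = 2L,
                       max_mismatch_rate = 0.15)
    if (!is.na(p) && p == rul) return(m)
  }
  stop("could not generate an aperiodic monomer", call. = FALSE)
}

# Per-site substitution probability s such that the expected K2P estimate
# equals d, given transition:transversion ratio kappa
# (P = s*kappa/(kappa+1), Q = s/(kappa+1)).
.k2p_rate_for_divergence <- function(d, kappa) {
  if (d == 0) return(0)
  f <- function(s) {
    P <- s * kappa / (kappa + 1)
    Q <- s / (kappa + 1)
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) return(Inf)
    -0.5 * log(w1 * sqrt(w2)) - d
  }
  # saturation bound for this kappa
  hi <- 1
  while (!is.finite(f(hi))) hi <- hi * 0.9
  if (f(hi) < 0) stop("divergence lies in the saturated regime", call. = FALSE)
  stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Mutate one copy of a monomer to a target K2P divergence
#'
#' Substitutions are placed i.i.d. per site with total probability chosen so
#' that the expected estimated K2P distance from the master equals
#' `divergence` (the K2P closed form solved for the substitution rate given
#' kappa); given a substitution, a transition is chosen with probability
#' `kappa/(kappa+1)` and each of the two transversions with probability
#' `1/(2*(kappa+1))`. No indels are introduced.
#'
#' @param monomer Master monomer string.
#' @param divergence Target expected K2P distance (>= 0, below saturation).
#' @param ts_tv_ratio kappa >= 0.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can embed this in a larger seeded simulation).
#' @return The mutated copy (same length as `monomer`).
#' @export
mutate_copy <- function(monomer, divergence, ts_tv_ratio = 2, seed = NULL) {
  .check_seq(monomer, allow_n = FALSE, arg = "monomer")
  body <- function() {
    if (divergence == 0) return(monomer)
    s <- .k2p_rate_for_divergence(divergence, ts_tv_ratio)
    x <- strsplit(monomer, "")[[1L]]
    hit <- which(stats::runif(length(x)) < s)
    if (length(hit) == 0L) return(monomer)
    is_ts <- stats::runif(length(hit)) < ts_tv_ratio / (ts_tv_ratio + 1)
    for (j in seq_along(hit)) {
      b <- x[hit[j]]
      x[hit[j]] <- if (is_ts[j]) .TRANSITION[[b]] else {
        .TRANSVERSIONS[[b]][1L + (stats::runif(1) < 0.5)]
      }
    }
    paste(x, collapse = "")
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

# mismatch tally of equal-length ungapped copies vs master
.copy_divergence <- function(copies, master) {
  mm <- strsplit(master, "")[[1L]]
  d <- vapply(strsplit(copies, ""), function(cc) {
    diff <- which(cc != mm)
    if (length(diff) == 0L) return(0)
    ts <- sum(.TRANSITION[mm[diff]] == cc[diff])
    k2p_distance(ts, length(diff) - ts, length(mm))
  }, numeric(1L))
  mean(d)
}

#' Build female and male genomes with planted satellite families
#'
#' The background is i.i.d. random sequence at the configured GC. Each
#' family is realised once as a set of mutated copies summing (after
#' rounding to whole copies) to `target_abundance * genome_length` bp,
#' split across `n_loci` head-to-tail arrays (or as single dispersed
#' copies), and inserted at random positions. Autosomal arrays are shared
#' between the sexes; `W_linked` arrays appear only in the female genome.
#' Both genomes have exactly `genome_length` bp.
#'
#' @param spec A [sim_spec()].
#' @return List with `female`, `male` (genome strings), `truth` (per-family
#'   `data.frame`: name, linkage, arrangement, canonical monomer, rul,
#'   bp and genome fraction per sex, realised mean copy divergence) and
#'   `loci` (per-locus coordinates per sex).
#' @export
build_genomes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(.sub_seed(spec$seed, 1L), {
    fams <- spec$families
    realised <- lapply(fams, function(f) {
      monomer <- if (is.null(f$monomer)) random_monomer(f$rul, f$gc) else
        f$monomer
      bp_target <- round(f$target_abundance * spec$genome_length)
      n_copies <- max(1L, round(bp_target / f$rul))
      copies <- vapply(seq_len(n_copies), function(i)
        mutate_copy(monomer, f$divergence, f$ts_tv_ratio), character(1L))
      n_loci <- if (f$arrangement == "dispersed") n_copies else
        min(f$n_loci, n_copies)
      grp <- sort(rep_len(seq_len(n_loci), n_copies))
      arrays <- vapply(split(copies, grp), paste, character(1L),
                       collapse = "")
      list(fam = f, monomer = monomer, arrays = unname(arrays),
           bp = sum(nchar(copies)),
           mean_div = .copy_divergence(copies, monomer))
    })
    build_one <- function(keep) {
      arrs <- unlist(lapply(realised[keep], `[[`, "arrays"))
      labs <- unlist(lapply(realised[keep], function(r)
        rep(r$fam$name, length(r$arrays))))
      sat_bp <- sum(nchar(arrs))
      bg_len <- spec$genome_length - sat_bp
      if (bg_len < 0) stop("planted abundances infeasible for genome length",
                           call. = FALSE)
      k <- length(arrs)
      if (k == 0L) {
        bg <- paste(.random_bases(bg_len, spec$background_gc), collapse = "")
        return(list(genome = bg,
                    loci = data.frame(family = character(),
                                      start = integer(), end = integer())))
      }
      ord <- sample.int(k)
      arrs <- arrs[ord]; labs <- labs[ord]
      cuts <- sort(sample.int(bg_len + 1L, k, replace = TRUE) - 1L)
      seg_len <- diff(c(0L, cuts, bg_len))
      bg <- paste(.random_bases(bg_len, spec$background_gc), collapse = "")
      segs <- substring(bg, cumsum(c(1L, seg_len[-length(seg_len)])),
                        cumsum(seg_len))
      pieces <- character(2L * k + 1L)
      pieces[seq(1L, 2L * k + 1L, by = 2L)] <- segs
      pieces[seq(2L, 2L * k, by = 2L)] <- arrs
      genome <- paste(pieces, collapse = "")
      starts <- cumsum(c(1L, nchar(pieces)[-length(pieces)]))
      arr_at <- seq(2L, 2L * k, by = 2L)
      loci <- data.frame(family = labs, start = starts[arr_at],
                         end = starts[arr_at] + nchar(arrs) - 1L)
      list(genome = genome, loci = loci)
    }
    keep_f <- seq_along(fams)
    keep_m <- which(vapply(fams, function(f) f$linkage == "autosomal",
                           logical(1L)))
    female <- build_one(keep_f)
    male <- build_one(keep_m)
    truth <- do.call(rbind, lapply(realised, function(r) {
      w <- r$fam$linkage == "W_linked"
      data.frame(
        family = r$fam$name, linkage = r$fam$linkage,
        arrangement = r$fam$arrangement,
        monomer = canonical_monomer(r$monomer), rul = r$fam$rul,
        n_loci = length(r$arrays),
        female_bp = r$bp, male_bp = if (w) 0L else r$bp,
        female_fraction = r$bp / spec$genome_length,
        male_fraction = if (w) 0 else r$bp / spec$genome_length,
        mean_divergence = r$mean_div)
    }))
    if (is.null(truth)) {
      truth <- data.frame(family = character(), linkage = character(),
                          arrangement = character(), monomer = character(),
                          rul = integer(), n_loci = integer(),
                          female_bp = integer(), male_bp = integer(),
                          female_fraction = numeric(),
                          male_fraction = numeric(),
                          mean_divergence = numeric())
    }
    loci <- rbind(
      if (nrow(female$loci)) cbind(sex = "female", female$loci),
      if (nrow(male$loci)) cbind(sex = "male", male$loci))
    list(female = female$genome, male = male$genome, truth = truth,
         loci = loci)
  })
}

#' Simulate paired-end low-pass reads from a genome
#'
#' Draws `round(coverage * genome_length / (2 * read_length))` fragment
#' pairs: fragment starts are uniform, insert sizes are
#' `Normal(insert_mean, insert_sd)` truncated below at the read length,
#' fragment strand is chosen at random (so mates swap roles half the time),
#' mate 2 is reverse-complemented, and per-base errors are i.i.d. at
#' `error_rate` with a uniform wrong-base choice. Qualities are constant
#' Q30. Deterministic given `seed`.
#'
#' @param genome Genome string (see [build_genomes()]).
#' @param spec A [sim_spec()].
#' @param sex Sex label recorded in the library metadata.
#' @param seed Integer seed; defaults to a stream derived from `spec$seed`
#'   and `sex` so the two sexes get independent reads.
#' @return A [read_library()].
#' @export
simulate_reads <- function(genome, spec, sex = "unknown", seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  .check_seq(genome, arg = "genome")
  L <- nchar(genome)
  if (L <= spec$insert_mean + 6 * spec$insert_sd) {
    stop("genome too short for the configured insert distribution",
         call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- .sub_seed(spec$seed, 100L + match(sex, c("female", "male",
                                                     "unknown")))
  }
  rl <- spec$read_length
  withr::with_seed(seed, {
    n <- round(spec$coverage * L / (2 * rl))
    ins <- pmax(rl, pmin(L, round(stats::rnorm(n, spec$insert_mean,
                                               spec$insert_sd))))
    start <- floor(stats::runif(n, 1, L - ins + 2))
    m1 <- substring(genome, start, start + rl - 1L)
    m2 <- reverse_complement(substring(genome, start + ins - rl,
                                       start + ins - 1L))
    flip <- stats::runif(n) < 0.5
    tmp <- m1[flip]; m1[flip] <- m2[flip]; m2[flip] <- tmp
    if (spec$error_rate > 0) {
      add_errors <- function(reads) {
        nerr <- stats::rbinom(length(reads), rl, spec$error_rate)
        for (i in which(nerr > 0L)) {
          x <- strsplit(reads[i], "")[[1L]]
          pos <- sample.int(rl, nerr[i])
          x[pos] <- vapply(x[pos], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
          reads[i] <- paste(x, collapse = "")
        }
        reads
      }
      m1 <- add_errors(m1); m2 <- add_errors(m2)
    }
    q <- strrep("?", rl)  # Phred+33 Q30
    read_library(m1, rep(q, n), m2, rep(q, n), sex = sex,
                 species = "synthetic", source = "simulate_reads")
  })
}

#' Run the full simulation and write its files
#'
#' Builds the two genomes, simulates one library per sex, and writes paired
#' FASTQ files, a truth table TSV and a JSON manifest to `dir`.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory.
#' @return Invisibly, a list with the two [read_library()] objects and the
#'   truth `data.frame`.
#' @export
simulate_run <- function(spec, dir) {
  g <- build_genomes(spec)
  lib_f <- simulate_reads(g$female, spec, sex = "female")
  lib_m <- simulate_reads(g$male, spec, sex = "male")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq_pair(lib_f, file.path(dir, "female_R1.fastq.gz"),
                   file.path(dir, "female_R2.fastq.gz"))
  write_fastq_pair(lib_m, file.path(dir, "male_R1.fastq.gz"),
                   file.path(dir, "male_R2.fastq.gz"))
  cfg <- unclass(spec)
  cfg$families <- lapply(spec$families, unclass)
  write_report(list(truth = g$truth, loci = g$loci), dir,
               manifest = list(stage = "simulate", config = cfg,
                               seed = spec$seed))
  invisible(list(female = lib_f, male = lib_m, truth = g$truth))
}
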