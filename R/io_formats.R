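#' Construct a paired-end read library
#'
#' A `read_library` holds mate-1 and mate-2 sequences with per-base Phred+33
#' qualities and library metadata. Mate streams must have equal counts and
#' every quality string must match its sequence length.
#'
#' @param seq1,seq2 Character vectors of mate sequences.
#' @param qual1,qual2 Character vectors of Phred+33 quality strings.
#' @param species Species label.
#' @param sex One of `"female"`, `"male"`, `"unknown"`.
#' @param source Source path(s) or description.
#' @return An object of class `read_library`.
#' @export
read_library <- function(seq1, qual1, seq2, qual2,
                         species = "unknown",
                         sex = c("unknown", "female", "male"),
                         source = NA_character_) {
  sex <- match.arg(sex)
  if (length(seq1) != length(seq2)) {
    stop("mate 1 and mate 2 streams have unequal read counts", call. = FALSE)
  }
  .check_seq(c(seq1, seq2), allow_n = TRUE, arg = "reads")
  if (any(nchar(qual1) != nchar(seq1)) || any(nchar(qual2) != nchar(seq2))) {
    stop("quality string length must equal sequence length", call. = FALSE)
  }
  structure(list(seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
                 species = species, sex = sex, source = source),
            class = "read_library")
}

#' Number of read pairs in a library
#' @param lib A [read_library()].
#' @return Integer pair count.
#' @export
n_pairs <- function(lib) {
  stopifnot(inherits(lib, "read_library"))
  length(lib$seq1)
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("<read_library> %d pairs (%s, %s)\n", n_pairs(x), x$species,
              x$sex))
  invisible(x)
}

#' Subset a read library by pair index
#' @param lib A [read_library()].
#' @param idx Integer vector of pair indices to keep.
#' @return A [read_library()] with the selected pairs, in `idx` order.
#' @export
subset_pairs <- function(lib, idx) {
  stopifnot(inherits(lib, "read_library"))
  read_library(lib$seq1[idx], lib$qual1[idx], lib$seq2[idx], lib$qual2[idx],
               species = lib$species, sex = lib$sex, source = lib$source)
}

# All reads of a library as one character vector (mate 1 then mate 2),
# with ids "<pair>/1", "<pair>/2".
.all_reads <- function(lib) {
  n <- n_pairs(lib)
  stats::setNames(c(lib$seq1, lib$seq2),
                  c(paste0(seq_len(n), "/1"), paste0(seq_len(n), "/2")))
}

.read_fastq_one <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(seq = toupper(as.character(x, use.names = FALSE)),
       qual = as.character(S4Vectors::mcols(x)$qualities, use.names = FALSE),
       names = names(x))
}

#' Read (and optionally subsample) a paired FASTQ library
#'
#' Reads 4-line FASTQ (optionally gzip-compressed, Phred+33). When
#' `max_pairs` is smaller than the number of pairs on disk, a uniform random
#' sample of pairs without replacement is taken, reproducibly for a given
#' `seed`; mates are kept together.
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @param max_pairs Maximum pairs to keep; `Inf` keeps all.
#' @param seed Integer seed for the subsample (required when subsampling).
#' @param species,sex Library metadata (see [read_library()]).
#' @return A [read_library()].
#' @export
read_fastq_pair <- function(path1, path2, max_pairs = Inf, seed = 1L,
                            species = "unknown", sex = "unknown") {
  for (p in c(path1, path2)) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  r1 <- .read_fastq_one(path1)
  r2 <- .read_fastq_one(path2)
  if (length(r1$seq) != length(r2$seq)) {
    stop(sprintf("pairing error: %d mate-1 reads vs %d mate-2 reads",
                 length(r1$seq), length(r2$seq)), call. = FALSE)
  }
  lib <- read_library(r1$seq, r1$qual, r2$seq, r2$qual, species = species,
                      sex = sex, source = paste(path1, path2, sep = ";"))
  n <- n_pairs(lib)
  if (is.finite(max_pairs) && max_pairs < n) {
    idx <- withr::with_seed(seed, sort(sample.int(n, max_pairs)))
    lib <- subset_pairs(lib, idx)
  }
  lib
}

#' Write a paired read library as FASTQ
#'
#' @param lib A [read_library()].
#' @param path1,path2 Output FASTQ paths (`.gz` suffix enables compression).
#' @param id_prefix Read name prefix.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(lib, path1, path2, id_prefix = "read") {
  stopifnot(inherits(lib, "read_library"))
  n <- n_pairs(lib)
  ids <- sprintf("%s%06d", id_prefix, seq_len(n))
  .write_one <- function(seq, qual, mate, path) {
    x <- Biostrings::DNAStringSet(seq)
    names(x) <- paste0(ids, "/", mate)
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual),
                                compress = grepl("\\.gz$", path))
  }
  .write_one(lib$seq1, lib$qual1, 1L, path1)
  .write_one(lib$seq2, lib$qual2, 2L, path2)
  invisible(c(path1, path2))
}

.fmt_num <- function(x) {
  # fixed 6-significant-digit formatting so reports diff cleanly
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

# full precision for catalog headers, so numbers survive a read/write cycle
# and a rewritten catalog is byte-identical
.fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

#' Write a satellite catalog as FASTA
#'
#' Headers follow the grammar `><Name> rank=<NN> rul=<int>
#' abundance=<fraction>`; named variants are written as additional records
#' tagged `variant_of=<Name>`. [read_catalog()] inverts the writer.
#'
#' @param catalog A named, ranked [sat_catalog()] (see [assign_names()]).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "sat_catalog"))
  nms <- vapply(catalog$families, function(f) f$name, character(1L))
  if (anyNA(nms)) stop("catalog must be named before writing", call. = FALSE)
  if (anyDuplicated(nms)) stop("duplicate family names", call. = FALSE)
  lines <- character(0)
  for (f in catalog$families) {
    lines <- c(lines, sprintf(">%s rank=%02d rul=%d abundance=%s",
                              f$name, f$rank, f$rul, .fmt_full(f$abundance)),
               f$consensus)
    if (nrow(f$variants) > 0L) {
      for (k in seq_len(nrow(f$variants))) {
        lines <- c(lines,
                   sprintf(">%s.v%d variant_of=%s identity=%s", f$name, k,
                           f$name, .fmt_full(f$variants$identity[k])),
                   f$variants$consensus[k])
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a satellite catalog written by [write_catalog()]
#'
#' @param path FASTA path with the catalog header grammar.
#' @return A [sat_catalog()]. The prefix is recovered from the first family
#'   name.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  fams <- list(); variants <- list()
  for (i in seq_along(hdr_idx)) {
    hdr <- sub("^>", "", lines[hdr_idx[i]])
    seq <- toupper(paste(lines[seq.int(hdr_idx[i] + 1L, ends[i])],
                         collapse = ""))
    fields <- strsplit(hdr, "[[:space:]]+")[[1L]]
    nm <- fields[1L]
    kv <- fields[-1L]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    rec <- stats::setNames(as.list(vals), keys)
    if (!is.null(rec$variant_of)) {
      variants[[length(variants) + 1L]] <- list(
        parent = rec$variant_of, consensus = seq,
        identity = as.numeric(rec$identity))
    } else {
      for (need in c("rank", "rul", "abundance")) {
        if (is.null(rec[[need]])) {
          stop(sprintf("catalog header missing '%s=': %s", need, hdr),
               call. = FALSE)
        }
      }
      if (as.integer(rec$rul) != nchar(seq)) {
        stop("rul= does not match sequence length for ", nm, call. = FALSE)
      }
      fams[[nm]] <- sat_family(seq, abundance = as.numeric(rec$abundance),
                               name = nm, rank = as.integer(rec$rank))
    }
  }
  if (anyDuplicated(names(fams))) stop("duplicate family names", call. = FALSE)
  for (v in variants) {
    if (is.null(fams[[v$parent]])) {
      stop("variant of unknown family: ", v$parent, call. = FALSE)
    }
    fams[[v$parent]]$variants <- rbind(
      fams[[v$parent]]$variants,
      data.frame(consensus = v$consensus, identity = v$identity))
  }
  prefix <- sub("Sat[0-9]+-[0-9]+$", "", names(fams)[1L])
  sat_catalog(unname(fams), prefix = prefix)
}

#' Write pipeline report tables and a run manifest
#'
#' Each table is written as `<name>.tsv` (tab-separated, numeric columns at
#' six significant digits, stable row order as supplied); the manifest,
#' recording configuration and seeds, is written as `manifest.json`.
#'
#' @param tables Named list of `data.frame`s.
#' @param dir Output directory (created if missing).
#' @param manifest Named list recorded as JSON alongside the tables.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, dir, manifest = list()) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) {
    stop("'tables' must be a named list", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    num <- vapply(tb, is.numeric, logical(1L))
    tb[num] <- lapply(tb[num], .fmt_num)
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tb, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest$satmine_version <-
    as.character(utils::packageVersion("satmine"))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}

#' Read back a run manifest
#' @param dir Directory written by [write_report()].
#' @return Named list.
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}
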