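# Count-file dialect shared by every module: one row per targeted position,
# strand-resolved depth plus strand-resolved per-base read counts.
COUNTS_COLS <- c(
  "chrom", "pos", "ref", "depth_fwd", "depth_rev",
  "A_fwd", "A_rev", "C_fwd", "C_rev", "G_fwd", "G_rev", "T_fwd", "T_rev"
)

#' Coerce a data frame to a validated per-position count table
#'
#' The count table is the package's core input: one row per targeted genomic
#' position carrying the reference base, the strand-specific read depths and
#' the strand-specific read counts for each of the four bases. Counts for the
#' three non-reference bases are the alternative-allele ("noise" or variant)
#' reads used everywhere downstream; the reference-base columns are carried
#' for completeness and may hold either the true reference read count or zero.
#'
#' @param x A data frame with columns `chrom`, `pos` (1-based), `ref` (one of
#'   A/C/G/T), `depth_fwd`, `depth_rev`, and `A_fwd`, `A_rev`, ..., `T_rev`.
#' @param sample_id Sample identifier stored as the `sample_id` attribute.
#' @return A tibble sorted by (`chrom`, `pos`) with the columns above and a
#'   `sample_id` attribute.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   chrom = "chr1", pos = 100L, ref = "A",
#'   depth_fwd = 500L, depth_rev = 480L,
#'   A_fwd = 495L, A_rev = 477L, C_fwd = 2L, C_rev = 1L,
#'   G_fwd = 0L, G_rev = 0L, T_fwd = 3L, T_rev = 2L
#' )
#' as_sample_counts(x, sample_id = "N1")
as_sample_counts <- function(x, sample_id = "sample") {
  x <- as_tibble(x)
  missing_cols <- setdiff(COUNTS_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "count table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- x %>%
    select(all_of(COUNTS_COLS)) %>%
    mutate(
      chrom = as.character(.data$chrom),
      ref = as.character(.data$ref),
      across(all_of(setdiff(COUNTS_COLS, c("chrom", "ref"))), as.integer)
    ) %>%
    arrange(.data$chrom, .data$pos)
  validate_counts(x)
  attr(x, "sample_id") <- sample_id
  x
}

# Invariant checks shared by the constructor and the file reader. `lines`
# maps each row to a source line number for error messages (NULL when the
# table was built in memory).
validate_counts <- function(x, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) {
      paste0(x$chrom[i], ":", x$pos[i])
    } else {
      paste0("line ", lines[i], " (", x$chrom[i], ":", x$pos[i], ")")
    }
  }
  bad <- which(is.na(x$pos) | x$pos < 1L)
  if (length(bad) > 0) {
    abort(paste0("invalid position at ", where(bad[1])))
  }
  bad <- which(!(x$ref %in% BASES))
  if (length(bad) > 0) {
    abort(paste0(
      "reference base must be one of A/C/G/T at ", where(bad[1])
    ))
  }
  count_cols <- setdiff(COUNTS_COLS, c("chrom", "pos", "ref"))
  for (cc in count_cols) {
    bad <- which(is.na(x[[cc]]) | x[[cc]] < 0L)
    if (length(bad) > 0) {
      abort(paste0("negative or missing ", cc, " at ", where(bad[1])))
    }
  }
  sum_fwd <- x$A_fwd + x$C_fwd + x$G_fwd + x$T_fwd
  sum_rev <- x$A_rev + x$C_rev + x$G_rev + x$T_rev
  bad <- which(sum_fwd > x$depth_fwd | sum_rev > x$depth_rev)
  if (length(bad) > 0) {
    abort(paste0(
      "per-base counts exceed strand depth at ", where(bad[1])
    ))
  }
  dup <- duplicated(paste(x$chrom, x$pos))
  if (any(dup)) {
    abort(paste0("duplicated position at ", where(which(dup)[1])))
  }
  invisible(x)
}

#' Read a per-position strand-specific count file
#'
#' Reads the tab-separated count dialect produced by an upstream pileup count
#' extractor (and by [write_counts_file()] and [simulate_normals()]): a header
#' row followed by one row per position with columns `chrom`, `pos` (1-based),
#' `ref`, `depth_fwd`, `depth_rev` and the eight per-base strand counts.
#' Lines starting with `#` are treated as metadata and skipped. All count
#' invariants are verified on load; violations are reported with the
#' offending line number.
#'
#' Base and read quality filtering is the upstream extractor's job: this
#' reader assumes the counts already reflect whatever quality thresholds were
#' applied when the pileup was generated, and positions dropped upstream (for
#' example below its minimum-coverage cutoff) may simply be absent.
#'
#' @param path Path to a count TSV.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A validated count tibble (see [as_sample_counts()]).
#' @export
read_counts_file <- function(path, sample_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("count file not found: ", path))
  }
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  # parse issues are turned into errors below via problems(); readr's own
  # warning would be redundant
  raw <- suppressWarnings(readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed count file ", path, ": parse failure at line ",
      probs$row[1], " (", probs$expected[1], ")"
    ))
  }
  if (!identical(names(raw), COUNTS_COLS)) {
    abort(paste0(
      "count file ", path, " header must be: ",
      paste(COUNTS_COLS, collapse = "\t")
    ))
  }
  # data row i sits on file line i + 1 (header)
  validate_counts(raw, lines = seq_len(nrow(raw)) + 1L)
  as_sample_counts(raw, sample_id = sample_id)
}

#' Write a count table to the TSV dialect
#'
#' Inverse of [read_counts_file()]: the written file round-trips exactly.
#'
#' @param counts A count tibble (see [as_sample_counts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_file <- function(counts, path) {
  counts <- as_sample_counts(counts, sample_id = attr(counts, "sample_id") %||% "sample")
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read an amplicon panel from a BED file
#'
#' Amplicon intervals are used to flag calls near amplicon boundaries, where
#' overlapping amplicon ends are a known artifact source. Standard BED
#' conventions apply: 0-based half-open coordinates, at least three columns;
#' a fourth column, when present, is kept as the amplicon identifier.
#' Intervals may overlap (the overlap is what defines edge zones).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start` (0-based), `end`
#'   (exclusive) and `amplicon_id`.
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("panel BED not found: ", path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t| +")
  if (length(fields) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      amplicon_id = character()
    ))
  }
  parse_one <- function(f, ln) {
    if (length(f) < 3) {
      abort(paste0("malformed BED line ", ln, ": fewer than 3 columns"))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(paste0("malformed BED line ", ln, ": non-integer coordinates"))
    }
    if (start >= end) {
      abort(paste0("invalid BED interval at line ", ln, ": start >= end"))
    }
    tibble(
      chrom = f[1], start = start, end = end,
      amplicon_id = if (length(f) >= 4) f[4] else paste0("amplicon_", ln)
    )
  }
  purrr::map2(fields, line_no, parse_one) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$start, .data$end)
}

#' Extract the reference sequence context around a position
#'
#' Returns the `2 * window + 1` bases of uppercase reference sequence centred
#' on a 1-based position, truncated at contig ends. Used to test whether a
#' call sits in or next to a homopolymer run.
#'
#' @param fasta Path to a FASTA file, or a named character vector / a
#'   `Biostrings::DNAStringSet` of contig sequences.
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param window Number of flanking bases on each side (`window >= 0`).
#' @return The context string, with the index of the centre base within it
#'   stored in the `"centre"` attribute (relevant when left-truncated).
#' @export
reference_context <- function(fasta, chrom, pos, window = 10L) {
  seqs <- load_reference(fasta)
  if (!chrom %in% names(seqs)) {
    abort(paste0("contig not found in reference: ", chrom))
  }
  contig <- seqs[[chrom]]
  len <- nchar(contig)
  if (pos < 1 || pos > len) {
    abort(paste0(
      "position ", pos, " outside contig ", chrom, " (length ", len, ")"
    ))
  }
  lo <- max(1L, pos - window)
  hi <- min(len, pos + window)
  out <- toupper(substr(contig, lo, hi))
  attr(out, "centre") <- pos - lo + 1L
  out
}

# Normalise the accepted reference representations to a named character
# vector of contig sequences. Biostrings does the FASTA parsing.
load_reference <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && is.null(names(fasta))) {
    if (!file.exists(fasta)) {
      abort(paste0("reference FASTA not found: ", fasta))
    }
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("reading FASTA requires the Biostrings package")
    }
    seqs <- Biostrings::readDNAStringSet(fasta)
    out <- as.character(seqs)
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(out)
  }
  if (methods::is(fasta, "DNAStringSet")) {
    out <- as.character(fasta)
    names(out) <- sub("\\s.*$", "", names(fasta))
    return(out)
  }
  if (is.character(fasta) && !is.null(names(fasta))) {
    return(fasta)
  }
  abort("reference must be a FASTA path or a named set of contig sequences")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
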