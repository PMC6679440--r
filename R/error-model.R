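#' Configuration for background error estimation
#'
#' Parameters controlling how the position-, allele- and strand-specific
#' background error is estimated from a cohort of normal samples.
#'
#' @param pseudo_count Additive pseudo-count `C` (fraction) added to every
#'   estimated rate. It regularises positions where the alternative-allele
#'   count may be underestimated and acts downstream as an effective
#'   sensitivity floor: variants at allele fractions at or below `C` are
#'   rarely callable. Default 0.002.
#' @param vaf_cap Allele-fraction threshold separating background noise from
#'   real (mostly germline) variants in the normals: a normal sample whose
#'   strand-combined VAF for an alternative allele exceeds this value is not
#'   used to estimate the error for that allele. Default 0.05.
#' @param min_strand_coverage Minimum read depth required on *each* strand
#'   for a normal sample to contribute at a position (for any allele).
#'   Default 100 reads.
#' @param max_unusable_fraction If at least this fraction of the cohort is
#'   excluded (by either filter, or by the position being absent from a
#'   sample's count file) at a (position, allele), that entry is marked
#'   non-callable. Default 2/3, inclusive.
#' @param constant_rate Fallback error rate used by [constant_error_model()]
#'   when no normal cohort is available. Default 0.01.
#' @return A list of class `error_model_config`.
#' @export
error_model_config <- function(pseudo_count = 0.002,
                               vaf_cap = 0.05,
                               min_strand_coverage = 100L,
                               max_unusable_fraction = 2 / 3,
                               constant_rate = 0.01) {
  stopifnot(
    pseudo_count >= 0, pseudo_count < 1,
    vaf_cap > 0, vaf_cap < 1,
    min_strand_coverage >= 0,
    max_unusable_fraction > 0, max_unusable_fraction <= 1,
    constant_rate > 0, constant_rate < 1
  )
  structure(
    list(
      pseudo_count = pseudo_count,
      vaf_cap = vaf_cap,
      min_strand_coverage = as.integer(min_strand_coverage),
      max_unusable_fraction = max_unusable_fraction,
      constant_rate = constant_rate
    ),
    class = "error_model_config"
  )
}

# Accept either a cohort tibble (count columns plus sample_id) or a list of
# per-sample count tables; return the long cohort representation.
as_cohort <- function(normals) {
  if (is.data.frame(normals)) {
    if (!"sample_id" %in% names(normals)) {
      normals <- mutate(normals, sample_id = attr(normals, "sample_id") %||% "sample_1")
    }
    return(as_tibble(normals))
  }
  if (is.list(normals) && length(normals) > 0) {
    ids <- purrr::imap_chr(normals, function(x, i) {
      attr(x, "sample_id") %||% paste0("sample_", i)
    })
    if (anyDuplicated(ids)) ids <- make.unique(ids)
    return(purrr::map2(normals, ids, function(x, id) {
      mutate(as_tibble(x), sample_id = id)
    }) %>% bind_rows())
  }
  abort("normals must be a cohort data frame or a non-empty list of count tables")
}

# Pivot a count table (or cohort) to one row per (sample, position, alt
# allele) with strand counts k_fwd/k_rev and the strand depths.
counts_to_long <- function(counts) {
  if (!"sample_id" %in% names(counts)) counts <- mutate(counts, sample_id = "sample")
  base_cols <- purrr::map(BASES, function(b) {
    counts %>%
      filter(.data$ref != b) %>%
      select(
        "sample_id", "chrom", "pos", "ref", "depth_fwd", "depth_rev",
        k_fwd = all_of(paste0(b, "_fwd")), k_rev = all_of(paste0(b, "_rev"))
      ) %>%
      mutate(alt = b)
  })
  bind_rows(base_cols) %>%
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)
}

#' Estimate position-, allele- and strand-specific background error
#'
#' For every targeted position and each of its three alternative alleles, the
#' background sequencing error on each strand is estimated by pooling
#' alternative-allele reads across a cohort of normal samples:
#' `s = sum(alt reads on strand) / sum(strand depth) + C`, with the sums taken
#' over the *usable* normals. Two filters define usability: (i) a normal
#' whose strand-combined VAF for an allele exceeds `vaf_cap` is excluded for
#' that allele (likely a germline variant or an unusually noisy read-out);
#' (ii) a normal with coverage below `min_strand_coverage` on either strand
#' at a position is excluded for all alleles at that position. A position
#' absent from a normal's count file counts as excluded for that normal.
#' When the excluded fraction of the cohort reaches `max_unusable_fraction`
#' the (position, allele) is recorded as non-callable.
#'
#' The maximum strand-combined VAF observed among the usable normals is also
#' recorded per entry; the caller uses it to flag calls whose VAF does not
#' exceed the noise level seen in normals.
#'
#' @param normals A cohort: either a single tibble of count rows with a
#'   `sample_id` column, or a list of per-sample count tables (see
#'   [read_counts_file()]). Fewer than 10 normals triggers a warning, since
#'   small cohorts give unstable error estimates.
#' @param config An [error_model_config()].
#' @return An object of class `error_model`: entries per (position, alt)
#'   with `s_fwd`, `s_rev`, `callable`, `max_normal_vaf` and `n_used`, plus
#'   the config and cohort size. Use [tidy()] to get the entry table.
#' @export
#' @examples
#' profile <- sim_noise_profile(n_positions = 5, seed = 1)
#' cohort <- simulate_normals(profile, n = 12, seed = 2)
#' model <- estimate_errors(cohort, error_model_config(pseudo_count = 0.002))
#' glance(model)
estimate_errors <- function(normals, config = error_model_config()) {
  stopifnot(inherits(config, "error_model_config"))
  cohort <- as_cohort(normals)
  if (nrow(cohort) == 0) abort("normal cohort is empty")
  n_normals <- dplyr::n_distinct(cohort$sample_id)
  if (n_normals < 10) {
    warn(paste0(
      "only ", n_normals,
      " normal sample(s) supplied; fewer than 10 normals is likely to give ",
      "low-quality error estimates"
    ))
  }

  ref_check <- cohort %>%
    distinct(.data$chrom, .data$pos, .data$ref) %>%
    dplyr::count(.data$chrom, .data$pos) %>%
    filter(.data$n > 1)
  if (nrow(ref_check) > 0) {
    abort(paste0(
      "inconsistent reference base across samples at ",
      ref_check$chrom[1], ":", ref_check$pos[1]
    ))
  }

  long <- counts_to_long(cohort) %>%
    mutate(
      depth_ok = .data$depth_fwd >= config$min_strand_coverage &
        .data$depth_rev >= config$min_strand_coverage,
      total_depth = .data$depth_fwd + .data$depth_rev,
      vaf = if_else(
        .data$total_depth > 0,
        (.data$k_fwd + .data$k_rev) / .data$total_depth,
        0
      ),
      usable = .data$depth_ok & .data$vaf <= config$vaf_cap
    )

  entries <- long %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      n_used = sum(.data$usable),
      er_fwd = sum(.data$k_fwd[.data$usable]),
      er_rev = sum(.data$k_rev[.data$usable]),
      erd_fwd = sum(.data$depth_fwd[.data$usable]),
      erd_rev = sum(.data$depth_rev[.data$usable]),
      max_normal_vaf = if (any(.data$usable)) max(.data$vaf[.data$usable]) else 0,
      .groups = "drop"
    ) %>%
    mutate(
      # samples missing the position entirely count against callability
      excluded_fraction = (n_normals - .data$n_used) / n_normals,
      callable = .data$excluded_fraction < config$max_unusable_fraction &
        .data$erd_fwd > 0 & .data$erd_rev > 0,
      s_fwd = if_else(.data$callable,
        .data$er_fwd / .data$erd_fwd + config$pseudo_count, NA_real_
      ),
      s_rev = if_else(.data$callable,
        .data$er_rev / .data$erd_rev + config$pseudo_count, NA_real_
      ),
      max_normal_vaf = if_else(.data$callable, .data$max_normal_vaf, NA_real_)
    ) %>%
    select(
      "chrom", "pos", "ref", "alt", "s_fwd", "s_rev",
      "callable", "max_normal_vaf", "n_used"
    ) %>%
    arrange(.data$chrom, .data$pos, .data$alt)

  new_error_model(entries, config, n_normals, constant = FALSE)
}

#' Constant-rate fallback error model
#'
#' When no normal cohort is available, every (position, alternative allele,
#' strand) is assigned the same background error rate. All entries are
#' callable and the recorded maximum normal VAF is zero (so the high-noise
#' flag never fires).
#'
#' @param positions A data frame with columns `chrom`, `pos`, `ref` (a count
#'   table works directly).
#' @param rate Constant error rate in (0, 1); default 0.01.
#' @param config Optional [error_model_config()] whose filter settings are
#'   recorded with the model; its `pseudo_count` is set to `rate` so that the
#'   invariant `s >= C` and the sensitivity-floor interpretation of the
#'   pseudo-count carry over.
#' @return An `error_model`.
#' @export
constant_error_model <- function(positions, rate = 0.01,
                                 config = error_model_config()) {
  stopifnot(rate > 0, rate < 1)
  config$constant_rate <- rate
  config$pseudo_count <- rate
  positions <- as_tibble(positions) %>%
    distinct(.data$chrom, .data$pos, .data$ref)
  if (nrow(positions) > 0 && !all(positions$ref %in% BASES)) {
    abort("reference bases must be one of A/C/G/T")
  }
  entries <- positions %>%
    tidyr::crossing(alt = BASES) %>%
    filter(.data$alt != .data$ref) %>%
    mutate(
      s_fwd = rate, s_rev = rate, callable = TRUE,
      max_normal_vaf = 0, n_used = 0L
    ) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
  if (nrow(entries) == 0) {
    entries <- tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), s_fwd = double(), s_rev = double(),
      callable = logical(), max_normal_vaf = double(), n_used = integer()
    )
  }
  new_error_model(entries, config, n_normals = 0L, constant = TRUE)
}

new_error_model <- function(entries, config, n_normals, constant) {
  structure(
    list(
      entries = as_tibble(entries),
      config = config,
      n_normals = as.integer(n_normals),
      constant = isTRUE(constant)
    ),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model>\n")
  if (x$constant) {
    cat("  constant rate:", x$config$constant_rate, "\n")
  } else {
    cat("  normals:", x$n_normals, "\n")
    cat("  pseudo-count C:", x$config$pseudo_count, "\n")
  }
  cat(
    "  entries:", nrow(x$entries),
    sprintf("(%d callable)", sum(x$entries$callable)), "\n"
  )
  invisible(x)
}

#' Tidy the per-entry table of an error model
#'
#' @param x An `error_model`.
#' @param ... Unused.
#' @return A tibble with one row per (position, alternative allele):
#'   `chrom`, `pos`, `ref`, `alt`, `s_fwd`, `s_rev`, `callable`,
#'   `max_normal_vaf`, `n_used`.
#' @method tidy error_model
#' @export
tidy.error_model <- function(x, ...) {
  x$entries
}

#' One-row summary of an error model
#'
#' @param x An `error_model`.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, numbers of positions/entries,
#'   callable fraction, median strand error and the key config values.
#' @method glance error_model
#' @export
glance.error_model <- function(x, ...) {
  e <- x$entries
  callable <- filter(e, .data$callable)
  tibble(
    n_normals = x$n_normals,
    n_positions = nrow(distinct(e, .data$chrom, .data$pos)),
    n_entries = nrow(e),
    n_callable = nrow(callable),
    prop_callable = if (nrow(e) > 0) nrow(callable) / nrow(e) else NA_real_,
    median_s = if (nrow(callable) > 0) {
      median(c(callable$s_fwd, callable$s_rev))
    } else {
      NA_real_
    },
    pseudo_count = x$config$pseudo_count,
    vaf_cap = x$config$vaf_cap,
    min_strand_coverage = x$config$min_strand_coverage,
    constant = x$constant
  )
}

ERROR_MODEL_FORMAT_VERSION <- "1"

#' Write an error model to a versioned TSV
#'
#' The on-disk format is a plain TSV preceded by `#`-prefixed metadata lines
#' carrying the format version, the configuration and the cohort size, so a
#' model trained once per panel design can be inspected, diffed and reused.
#' [read_error_model()] restores it exactly.
#'
#' @param model An `error_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_model <- function(model, path) {
  stopifnot(inherits(model, "error_model"))
  cfg <- model$config
  num <- function(x) sprintf("%.17g", x)
  header <- c(
    paste0("#amplisnv_error_model\t", ERROR_MODEL_FORMAT_VERSION),
    paste0("#pseudo_count\t", num(cfg$pseudo_count)),
    paste0("#vaf_cap\t", num(cfg$vaf_cap)),
    paste0("#min_strand_coverage\t", cfg$min_strand_coverage),
    paste0("#max_unusable_fraction\t", num(cfg$max_unusable_fraction)),
    paste0("#constant_rate\t", num(cfg$constant_rate)),
    paste0("#n_normals\t", model$n_normals),
    paste0("#constant\t", if (model$constant) "TRUE" else "FALSE")
  )
  readr::write_lines(header, path)
  readr::write_tsv(model$entries, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read an error model written by [write_error_model()]
#'
#' @param path Path to a model TSV.
#' @return An `error_model`.
#' @export
read_error_model <- function(path) {
  if (!file.exists(path)) abort(paste0("error-model file not found: ", path))
  all_lines <- readr::read_lines(path, progress = FALSE)
  meta_lines <- all_lines[startsWith(all_lines, "#")]
  if (length(meta_lines) == 0 ||
      !startsWith(meta_lines[1], "#amplisnv_error_model")) {
    abort(paste0(path, " is not an amplisnv error-model file"))
  }
  meta <- strsplit(sub("^#", "", meta_lines), "\t")
  keys <- purrr::map_chr(meta, 1)
  vals <- purrr::map_chr(meta, function(f) if (length(f) >= 2) f[2] else NA_character_)
  names(vals) <- keys
  if (!identical(vals[["amplisnv_error_model"]], ERROR_MODEL_FORMAT_VERSION)) {
    abort(paste0(
      "unsupported error-model format version '",
      vals[["amplisnv_error_model"]], "' (expected ",
      ERROR_MODEL_FORMAT_VERSION, ")"
    ))
  }
  required <- c(
    "pseudo_count", "vaf_cap", "min_strand_coverage",
    "max_unusable_fraction", "constant_rate", "n_normals", "constant"
  )
  if (!all(required %in% names(vals))) {
    abort(paste0("truncated error-model header in ", path))
  }
  config <- error_model_config(
    pseudo_count = as.numeric(vals[["pseudo_count"]]),
    vaf_cap = as.numeric(vals[["vaf_cap"]]),
    min_strand_coverage = as.integer(vals[["min_strand_coverage"]]),
    max_unusable_fraction = as.numeric(vals[["max_unusable_fraction"]]),
    constant_rate = as.numeric(vals[["constant_rate"]])
  )
  body <- all_lines[!startsWith(all_lines, "#")]
  body <- body[nzchar(body)]
  expected_header <- paste(
    c("chrom", "pos", "ref", "alt", "s_fwd", "s_rev", "callable",
      "max_normal_vaf", "n_used"),
    collapse = "\t"
  )
  if (length(body) == 0 || body[1] != expected_header) {
    abort(paste0("truncated or malformed error-model table in ", path))
  }
  entries <- readr::read_tsv(
    I(paste(body, collapse = "\n")),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      s_fwd = readr::col_double(),
      s_rev = readr::col_double(),
      callable = readr::col_logical(),
      max_normal_vaf = readr::col_double(),
      n_used = readr::col_integer()
    ),
    progress = FALSE
  )
  probs <- readr::problems(entries)
  if (nrow(probs) > 0) {
    abort(paste0("malformed error-model row in ", path))
  }
  new_error_model(
    entries, config,
    n_normals = as.integer(vals[["n_normals"]]),
    constant = identical(vals[["constant"]], "TRUE")
  )
}
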