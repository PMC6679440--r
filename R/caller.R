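# Warning flags in reporting order. PASS is mutually exclusive with all of
# them.
CALL_FLAGS <- c(
  "LowQ", "LowSupportingReads", "AmpliconEdge", "StrandBias",
  "HomoPolymerRegion", "PositionWithHighNoise"
)

#' Configuration for variant calling
#'
#' @param rd_min Minimum per-strand read depth for a position to be
#'   considered; the comparison is strict (`depth > rd_min`). Default 100;
#'   the lenient preset uses 50.
#' @param sb_threshold Two-sided Fisher exact-test p-value below which a call
#'   is flagged as strand-biased. Default 0.05; the lenient preset uses 0.01.
#' @param q_report Per-strand Phred quality threshold for reporting a call:
#'   a substitution is emitted only when both strands reach this Q. Fixed at
#'   5 in the method's definition.
#' @param q_lowq Per-strand Q below which a reported call is flagged `LowQ`
#'   (`Q = 20` corresponds to `p = 0.01`).
#' @param min_supporting Supporting-read floor per strand: fewer than this
#'   many reads on either strand flags `LowSupportingReads`; strictly more
#'   than this many on both strands is one condition of
#'   `PositionWithHighNoise`.
#' @param homopolymer_min_run Run length of identical reference bases at or
#'   adjacent to the call site that triggers `HomoPolymerRegion`.
#' @param edge_window Distance (bp, strict) from an amplicon boundary within
#'   which a call in an amplicon overlap zone is flagged `AmpliconEdge`.
#' @param p_floor P-values are clamped below at this value before the Phred
#'   transform, so Q stays finite when the Poisson tail underflows to 0.
#' @param lenient Apply the lenient preset (`rd_min = 50`,
#'   `sb_threshold = 0.01`); explicit arguments still win.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(rd_min = 100L,
                          sb_threshold = 0.05,
                          q_report = 5,
                          q_lowq = 20,
                          min_supporting = 5L,
                          homopolymer_min_run = 5L,
                          edge_window = 10L,
                          p_floor = 1e-320,
                          lenient = FALSE) {
  if (isTRUE(lenient)) {
    if (missing(rd_min)) rd_min <- 50L
    if (missing(sb_threshold)) sb_threshold <- 0.01
  }
  stopifnot(
    rd_min >= 0,
    sb_threshold > 0, sb_threshold < 1,
    q_report <= q_lowq,
    min_supporting >= 0,
    homopolymer_min_run >= 1,
    edge_window >= 0,
    p_floor > 0, p_floor < 1
  )
  structure(
    list(
      rd_min = as.integer(rd_min),
      sb_threshold = sb_threshold,
      q_report = q_report,
      q_lowq = q_lowq,
      min_supporting = as.integer(min_supporting),
      homopolymer_min_run = as.integer(homopolymer_min_run),
      edge_window = as.integer(edge_window),
      p_floor = p_floor,
      lenient = isTRUE(lenient)
    ),
    class = "caller_config"
  )
}

#' Upper-tail Poisson p-value for observed variant reads
#'
#' Probability of observing `k` or more variant reads on a strand of depth
#' `K` under a background error rate `s`, i.e. `P(X >= k)` for
#' `X ~ Poisson(K * s)`. `K * s` is the expected number of random
#' substitutions on that strand. Computed with the regularised-gamma tail
#' used by [stats::ppois()], which stays accurate where naive term-by-term
#' summation loses precision. Vectorised over all arguments.
#'
#' @param k Observed variant reads on the strand (`k >= 0`).
#' @param K Strand read depth (`K >= 0`).
#' @param s Background error rate (`s >= 0`).
#' @return P-values in `[0, 1]`; `k = 0` gives 1 by convention (zero or more
#'   events are certain), and `s = 0` with `k > 0` gives exactly 0 before
#'   any flooring.
#' @export
#' @examples
#' poisson_tail_pvalue(k = 5, K = 1000, s = 0.001)
poisson_tail_pvalue <- function(k, K, s) {
  if (any(k < 0) || any(K < 0) || any(s < 0)) {
    abort("k, K and s must all be non-negative")
  }
  if (any(k != floor(k))) abort("k must be a whole number of reads")
  ppois(k - 1, lambda = K * s, lower.tail = FALSE)
}

#' Phred-scaled quality score from a p-value
#'
#' `Q = -10 * log10(p)`, after clamping `p` below at `p_floor` so that an
#' underflowed p-value of exactly zero still maps to a finite score.
#' `p = 0.01` maps to `Q = 20`.
#'
#' @param p P-values in `(0, 1]` (values in `(0, p_floor)` are clamped up).
#' @param p_floor Lower clamp; see [caller_config()].
#' @return Non-negative quality scores.
#' @export
qscore <- function(p, p_floor = 1e-320) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  -10 * log10(pmax(p, p_floor))
}

#' Strand-bias p-value (two-sided Fisher exact test)
#'
#' Tests the null hypothesis that the variant reads split between forward
#' and reverse strands in proportion to the total strand depths, using the
#' two-sided Fisher exact test on the 2x2 table
#' `[[k_fwd, K_fwd - k_fwd], [k_rev, K_rev - k_rev]]` (two-sided by the
#' minimum-likelihood rule, as in [stats::fisher.test()]). Vectorised.
#'
#' @param k_fwd,k_rev Variant reads per strand.
#' @param K_fwd,K_rev Strand depths (`>= 1`).
#' @return Two-sided p-values.
#' @export
strand_bias_pvalue <- function(k_fwd, k_rev, K_fwd, K_rev) {
  if (any(K_fwd < 1) || any(K_rev < 1)) {
    abort("strand depths must be at least 1")
  }
  if (any(k_fwd > K_fwd) || any(k_rev > K_rev) || any(k_fwd < 0) || any(k_rev < 0)) {
    abort("variant reads must lie between 0 and the strand depth")
  }
  purrr::pmap_dbl(
    list(k_fwd, k_rev, K_fwd, K_rev),
    function(kf, kr, Kf, Kr) {
      fisher.test(matrix(c(kf, Kf - kf, kr, Kr - kr), nrow = 2, byrow = TRUE))$p.value
    }
  )
}

#' Does a position sit in or next to a homopolymer run?
#'
#' True when the centre base lies inside, or immediately adjacent to, a run
#' of at least `min_run` identical bases within the supplied reference
#' context. Homopolymer tracts are a known artifact hotspot for
#' semiconductor (flow-based) sequencing chemistry.
#'
#' @param context Reference context string (see [reference_context()]).
#' @param centre_index 1-based index of the queried base within `context`.
#' @param min_run Minimum run length; default 5.
#' @return Logical scalar.
#' @export
is_homopolymer <- function(context, centre_index, min_run = 5L) {
  chars <- strsplit(toupper(context), "")[[1]]
  if (centre_index < 1 || centre_index > length(chars)) {
    abort("centre_index outside the context string")
  }
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  long <- runs$lengths >= min_run
  if (!any(long)) return(FALSE)
  any(centre_index >= starts[long] - 1L & centre_index <= ends[long] + 1L)
}

#' Is a position inside an amplicon-edge overlap zone?
#'
#' True when the position is covered by two or more amplicons of the panel
#' and lies strictly within `edge_window` bp of a boundary of at least one
#' covering amplicon. Overlapping amplicon ends are a recognised source of
#' sequencing artifacts in amplicon panels. Vectorised over positions.
#'
#' @param chrom,pos Chromosome and 1-based position vectors.
#' @param panel A panel tibble from [read_panel_bed()].
#' @param edge_window Edge distance in bp (strict comparison); default 10.
#' @return Logical vector.
#' @export
is_amplicon_edge <- function(chrom, pos, panel, edge_window = 10L) {
  purrr::map2_lgl(chrom, pos, function(ch, p) {
    cover <- panel$chrom == ch & panel$start + 1L <= p & p <= panel$end
    if (sum(cover) < 2) return(FALSE)
    dist <- pmin(p - (panel$start[cover] + 1L), panel$end[cover] - p)
    any(dist < edge_window)
  })
}

#' Call SNVs in a sample against a background error model
#'
#' For every position with per-strand depth strictly above `rd_min` and every
#' alternative allele with at least one supporting read at a callable model
#' entry, the per-strand Poisson tail p-value is computed from that strand's
#' background error rate and converted to a Phred Q score. A call is emitted
#' only when both strands reach `q_report`; p-values are not corrected for
#' multiple testing. Emitted calls are then annotated:
#'
#' * `LowQ` — Q below `q_lowq` on at least one strand;
#' * `LowSupportingReads` — fewer than `min_supporting` reads on either
#'   strand;
#' * `AmpliconEdge` — in an amplicon-overlap edge zone (needs `panel`);
#' * `StrandBias` — Fisher exact p-value below `sb_threshold`;
#' * `HomoPolymerRegion` — in/adjacent to a homopolymer run (needs
#'   `reference`);
#' * `PositionWithHighNoise` — more than `min_supporting` reads on both
#'   strands but a VAF not above the maximum VAF seen among usable normals
#'   at this entry;
#' * `PASS` — none of the above.
#'
#' Candidate substitutions at positions the model marks non-callable (or
#' does not cover) are not scored; they are returned as a side table in the
#' `"uncallable"` attribute of the result.
#'
#' @param counts A sample count table ([read_counts_file()]).
#' @param model An `error_model`.
#' @param config A [caller_config()].
#' @param panel Optional panel tibble ([read_panel_bed()]); when absent the
#'   edge flag is not evaluated.
#' @param reference Optional reference (path/named sequences, see
#'   [reference_context()]); when absent the homopolymer flag is not
#'   evaluated.
#' @return A tibble of calls with per-strand counts, depths, p-values,
#'   Q scores, `q_mean`, `vaf`, the Fisher `sb_pvalue` and a semicolon-joined
#'   `flags` column (`"PASS"` when clean), ordered by position. The
#'   `"uncallable"` attribute holds skipped candidate substitutions.
#' @export
call_variants <- function(counts, model, config = caller_config(),
                          panel = NULL, reference = NULL) {
  stopifnot(inherits(model, "error_model"), inherits(config, "caller_config"))
  counts <- as_sample_counts(counts, sample_id = attr(counts, "sample_id") %||% "sample")

  empty_calls <- tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    vaf = double(), k_fwd = integer(), k_rev = integer(),
    K_fwd = integer(), K_rev = integer(),
    p_fwd = double(), p_rev = double(),
    q_fwd = double(), q_rev = double(), q_mean = double(),
    sb_pvalue = double(), flags = character()
  )
  empty_uncallable <- tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    k_fwd = integer(), k_rev = integer(), reason = character()
  )

  cand <- counts_to_long(counts) %>%
    select(-"sample_id") %>%
    rename(K_fwd = "depth_fwd", K_rev = "depth_rev") %>%
    filter(
      .data$K_fwd > config$rd_min, .data$K_rev > config$rd_min,
      .data$k_fwd > 0 | .data$k_rev > 0
    ) %>%
    left_join(
      model$entries %>%
        select("chrom", "pos", "alt",
               model_ref = "ref", "s_fwd", "s_rev", "callable",
               "max_normal_vaf"),
      by = c("chrom", "pos", "alt")
    )

  ref_clash <- cand %>%
    filter(!is.na(.data$model_ref), .data$model_ref != .data$ref)
  if (nrow(ref_clash) > 0) {
    abort(paste0(
      "reference base disagrees between sample and error model at ",
      ref_clash$chrom[1], ":", ref_clash$pos[1]
    ))
  }

  uncallable <- cand %>%
    filter(is.na(.data$callable) | !.data$callable) %>%
    mutate(reason = if_else(is.na(.data$callable),
      "not_in_model", "non_callable"
    )) %>%
    select("chrom", "pos", "ref", "alt", "k_fwd", "k_rev", "reason")
  if (nrow(uncallable) == 0) uncallable <- empty_uncallable

  scored <- cand %>%
    filter(!is.na(.data$callable), .data$callable) %>%
    mutate(
      p_fwd = poisson_tail_pvalue(.data$k_fwd, .data$K_fwd, .data$s_fwd),
      p_rev = poisson_tail_pvalue(.data$k_rev, .data$K_rev, .data$s_rev),
      q_fwd = qscore(.data$p_fwd, p_floor = config$p_floor),
      q_rev = qscore(.data$p_rev, p_floor = config$p_floor)
    ) %>%
    filter(.data$q_fwd >= config$q_report, .data$q_rev >= config$q_report)

  if (nrow(scored) == 0) {
    out <- empty_calls
    attr(out, "uncallable") <- uncallable
    attr(out, "sample_id") <- attr(counts, "sample_id")
    return(out)
  }

  edge_flag <- if (!is.null(panel)) {
    is_amplicon_edge(scored$chrom, scored$pos, panel, config$edge_window)
  } else {
    rep(FALSE, nrow(scored))
  }
  hp_flag <- if (!is.null(reference)) {
    seqs <- load_reference(reference)
    purrr::map2_lgl(scored$chrom, scored$pos, function(ch, p) {
      ctx <- reference_context(seqs, ch, p, window = config$homopolymer_min_run)
      is_homopolymer(ctx, attr(ctx, "centre"), config$homopolymer_min_run)
    })
  } else {
    rep(FALSE, nrow(scored))
  }

  out <- scored %>%
    mutate(
      vaf = (.data$k_fwd + .data$k_rev) / (.data$K_fwd + .data$K_rev),
      q_mean = (.data$q_fwd + .data$q_rev) / 2,
      sb_pvalue = strand_bias_pvalue(
        .data$k_fwd, .data$k_rev, .data$K_fwd, .data$K_rev
      ),
      f_lowq = pmin(.data$q_fwd, .data$q_rev) < config$q_lowq,
      f_lowsupport = .data$k_fwd < config$min_supporting |
        .data$k_rev < config$min_supporting,
      f_edge = edge_flag,
      f_sb = .data$sb_pvalue < config$sb_threshold,
      f_hp = hp_flag,
      f_noise = .data$k_fwd > config$min_supporting &
        .data$k_rev > config$min_supporting &
        .data$vaf < .data$max_normal_vaf,
      flags = join_flags(
        .data$f_lowq, .data$f_lowsupport, .data$f_edge,
        .data$f_sb, .data$f_hp, .data$f_noise
      )
    ) %>%
    select(
      "chrom", "pos", "ref", "alt", "vaf", "k_fwd", "k_rev",
      "K_fwd", "K_rev", "p_fwd", "p_rev", "q_fwd", "q_rev", "q_mean",
      "sb_pvalue", "flags"
    ) %>%
    arrange(.data$chrom, .data$pos, .data$alt)

  attr(out, "uncallable") <- uncallable
  attr(out, "sample_id") <- attr(counts, "sample_id")
  out
}

# Collapse the six per-flag logicals into the semicolon-joined flag string;
# PASS iff no warning fired.
join_flags <- function(lowq, lowsupport, edge, sb, hp, noise) {
  m <- cbind(lowq, lowsupport, edge, sb, hp, noise)
  apply(m, 1, function(row) {
    fl <- CALL_FLAGS[row]
    if (length(fl) == 0) "PASS" else paste(fl, collapse = ";")
  })
}

#' Write variant calls to TSV or a minimal VCF 4.2
#'
#' The TSV carries the columns `chrom`, `pos`, `ref`, `alt`, `vaf`, `k_fwd`,
#' `k_rev`, `K_fwd`, `K_rev`, `q_fwd`, `q_rev`, `q_mean`, `flags` in that
#' order, with Q scores printed to 2 decimals. The VCF output is site-level:
#' `FILTER` holds `PASS` or the warning flags, and `INFO` carries the VAF,
#' per-strand supporting reads, per-strand depths and per-strand Q scores.
#'
#' @param calls A calls tibble from [call_variants()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  q2 <- function(x) sprintf("%.2f", x)
  if (format == "tsv") {
    out <- calls %>%
      mutate(
        vaf = sprintf("%.6g", .data$vaf),
        q_fwd = q2(.data$q_fwd), q_rev = q2(.data$q_rev),
        q_mean = q2(.data$q_mean)
      ) %>%
      select(
        "chrom", "pos", "ref", "alt", "vaf", "k_fwd", "k_rev",
        "K_fwd", "K_rev", "q_fwd", "q_rev", "q_mean", "flags"
      )
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(path))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=amplisnv",
    paste0("##FILTER=<ID=", CALL_FLAGS, ",Description=\"", c(
      "Q score below 20 on at least one strand",
      "Fewer than the minimum supporting reads on at least one strand",
      "Within an overlapping amplicon edge region",
      "Fisher strand-bias test below threshold",
      "Within or adjacent to a homopolymer run",
      "VAF below the maximum VAF observed in the normal cohort"
    ), "\">"),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Strand-combined variant allele fraction\">",
    "##INFO=<ID=KF,Number=1,Type=Integer,Description=\"Variant reads, forward strand\">",
    "##INFO=<ID=KR,Number=1,Type=Integer,Description=\"Variant reads, reverse strand\">",
    "##INFO=<ID=DPF,Number=1,Type=Integer,Description=\"Read depth, forward strand\">",
    "##INFO=<ID=DPR,Number=1,Type=Integer,Description=\"Read depth, reverse strand\">",
    "##INFO=<ID=QF,Number=1,Type=Float,Description=\"Q score, forward strand\">",
    "##INFO=<ID=QR,Number=1,Type=Float,Description=\"Q score, reverse strand\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  rows <- if (nrow(calls) == 0) {
    character()
  } else {
    paste(
      calls$chrom, calls$pos, ".", calls$ref, calls$alt,
      q2(calls$q_mean), calls$flags,
      paste0(
        "VAF=", sprintf("%.6g", calls$vaf),
        ";KF=", calls$k_fwd, ";KR=", calls$k_rev,
        ";DPF=", calls$K_fwd, ";DPR=", calls$K_rev,
        ";QF=", q2(calls$q_fwd), ";QR=", q2(calls$q_rev)
      ),
      sep = "\t"
    )
  }
  readr::write_lines(c(header, rows), path)
  invisible(path)
}
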