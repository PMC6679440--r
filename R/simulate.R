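#' Build a synthetic per-position noise profile
#'
#' Describes the "true" background error landscape of a simulated amplicon
#' panel: one row per (position, alternative allele) with a per-strand error
#' rate and the per-strand depth distribution. Transition-type substitutions
#' (A>G/T>C and, to a lesser extent, C>T/G>A) are elevated by a
#' multiplicative factor, mirroring the systematic substitution-type bias of
#' semiconductor sequencing chemistry; optionally a random subset of
#' (position, allele) entries is made "hot" with a much higher rate, to
#' emulate recurrently noisy sites.
#'
#' @param n_positions Number of panel positions.
#' @param chrom Contig name for all positions.
#' @param start 1-based coordinate of the first position.
#' @param ref Reference bases; recycled or sampled uniformly when `NULL`.
#' @param base_error Baseline per-strand error rate (fraction). Default
#'   5e-4, a typical transversion-level amplicon noise floor.
#' @param transition_factor Multiplier applied to A>G, T>C, C>T and G>A
#'   errors. Default 3.
#' @param hot_fraction Fraction of (position, allele) entries elevated to
#'   `hot_error`. Default 0.
#' @param hot_error Error rate of hot entries; must stay below the usual 5%
#'   noise/germline separation threshold. Default 0.02.
#' @param depth_mean Mean per-strand read depth. Default 1000.
#' @param depth_dispersion Negative-binomial size parameter for per-strand
#'   depth; `Inf` (default) gives constant depth, smaller values give the
#'   uneven coverage typical of amplicon panels.
#' @param seed Optional seed used for reference-base and hot-entry draws.
#' @return A tibble with one row per (position, alt):
#'   `chrom`, `pos`, `ref`, `alt`, `e_fwd`, `e_rev`, `depth_mean`,
#'   `depth_dispersion`.
#' @export
sim_noise_profile <- function(n_positions = 100,
                              chrom = "chr1",
                              start = 1000L,
                              ref = NULL,
                              base_error = 5e-4,
                              transition_factor = 3,
                              hot_fraction = 0,
                              hot_error = 0.02,
                              depth_mean = 1000,
                              depth_dispersion = Inf,
                              seed = NULL) {
  stopifnot(
    n_positions >= 1, base_error >= 0, transition_factor >= 0,
    hot_fraction >= 0, hot_fraction <= 1, hot_error >= 0, hot_error < 0.05,
    depth_mean > 0
  )
  if (!is.null(seed)) set.seed(seed)
  pos <- seq.int(start, length.out = n_positions)
  if (is.null(ref)) {
    ref <- sample(BASES, n_positions, replace = TRUE)
  } else {
    ref <- rep_len(ref, n_positions)
  }
  transitions <- c("A>G", "T>C", "C>T", "G>A")
  profile <- tibble(chrom = chrom, pos = as.integer(pos), ref = ref) %>%
    tidyr::crossing(alt = BASES) %>%
    filter(.data$alt != .data$ref) %>%
    mutate(
      e = if_else(
        paste0(.data$ref, ">", .data$alt) %in% transitions,
        base_error * transition_factor,
        base_error
      )
    )
  if (hot_fraction > 0) {
    n_hot <- round(hot_fraction * nrow(profile))
    hot_idx <- sample.int(nrow(profile), n_hot)
    profile$e[hot_idx] <- hot_error
  }
  if (any(profile$e >= 0.05)) {
    abort("noise rates must stay below the 5% noise/germline threshold")
  }
  profile %>%
    mutate(
      e_fwd = .data$e, e_rev = .data$e,
      depth_mean = depth_mean, depth_dispersion = depth_dispersion
    ) %>%
    select(-"e") %>%
    arrange(.data$chrom, .data$pos, .data$alt)
}

#' Simulate a cohort of normal samples
#'
#' Draws per-strand depths from the profile's depth distribution and
#' alternative-allele reads as `Binomial(depth, e_true)` per strand,
#' independently per sample and position. Sites listed in `het_sites`
#' represent germline heterozygous variants segregating in the population:
#' each sample carries the variant with probability `carrier_prob`, and in
#' carriers the allele's reads are drawn as `Binomial(depth, het_vaf)` per
#' strand instead of the noise draw.
#'
#' @param profile A noise profile from [sim_noise_profile()].
#' @param n Number of normal samples.
#' @param seed Random seed (required: every simulated cohort is
#'   reproducible by construction).
#' @param het_sites Optional tibble with columns `chrom`, `pos`, `alt` and
#'   optionally `carrier_prob` (default 0.3 per site).
#' @param het_vaf Expected allele fraction in carriers. Default 0.5.
#' @return A cohort tibble: `sample_id` plus the count-table columns, valid
#'   per the count-file invariants; ready for [estimate_errors()] or,
#'   per sample, for [call_variants()]. Split with [split_cohort()].
#' @export
simulate_normals <- function(profile, n, seed, het_sites = NULL,
                             het_vaf = 0.5) {
  stopifnot(n >= 1)
  if (missing(seed) || is.null(seed)) abort("simulate_normals requires a seed")
  set.seed(seed)

  positions <- distinct(
    profile, .data$chrom, .data$pos, .data$ref,
    .data$depth_mean, .data$depth_dispersion
  )
  sample_ids <- sprintf("sim_normal_%03d", seq_len(n))

  depths <- tidyr::crossing(sample_id = sample_ids, positions) %>%
    mutate(
      depth_fwd = draw_depth(n(), .data$depth_mean, .data$depth_dispersion),
      depth_rev = draw_depth(n(), .data$depth_mean, .data$depth_dispersion)
    ) %>%
    select("sample_id", "chrom", "pos", "ref", "depth_fwd", "depth_rev")

  long <- tidyr::crossing(sample_id = sample_ids,
                          select(profile, "chrom", "pos", "alt",
                                 "e_fwd", "e_rev")) %>%
    inner_join(depths, by = c("sample_id", "chrom", "pos")) %>%
    mutate(
      k_fwd = rbinom(n(), .data$depth_fwd, .data$e_fwd),
      k_rev = rbinom(n(), .data$depth_rev, .data$e_rev)
    )

  if (!is.null(het_sites) && nrow(het_sites) > 0) {
    het_sites <- as_tibble(het_sites)
    if (!"carrier_prob" %in% names(het_sites)) het_sites$carrier_prob <- 0.3
    long <- long %>%
      left_join(select(het_sites, "chrom", "pos", "alt", "carrier_prob"),
                by = c("chrom", "pos", "alt")) %>%
      mutate(
        is_het = !is.na(.data$carrier_prob) &
          runif(n()) < dplyr::coalesce(.data$carrier_prob, 0),
        k_fwd = if_else(.data$is_het,
          rbinom(n(), .data$depth_fwd, het_vaf), .data$k_fwd
        ),
        k_rev = if_else(.data$is_het,
          rbinom(n(), .data$depth_rev, het_vaf), .data$k_rev
        )
      ) %>%
      select(-"carrier_prob", -"is_het")
  }

  wide <- long %>%
    select("sample_id", "chrom", "pos", "alt", "k_fwd", "k_rev") %>%
    tidyr::pivot_wider(
      names_from = "alt", values_from = c("k_fwd", "k_rev"),
      names_glue = "{alt}_{sub('k_', '', .value)}", values_fill = 0L
    ) %>%
    inner_join(depths, by = c("sample_id", "chrom", "pos"))

  for (b in BASES) {
    for (strand in c("fwd", "rev")) {
      col <- paste0(b, "_", strand)
      if (!col %in% names(wide)) wide[[col]] <- 0L
    }
  }

  cohort <- wide %>%
    mutate(
      alt_sum_fwd = .data$A_fwd + .data$C_fwd + .data$G_fwd + .data$T_fwd,
      alt_sum_rev = .data$A_rev + .data$C_rev + .data$G_rev + .data$T_rev,
      # in the vanishingly rare event the draws exceed depth, depth is bumped
      depth_fwd = pmax(.data$depth_fwd, .data$alt_sum_fwd),
      depth_rev = pmax(.data$depth_rev, .data$alt_sum_rev)
    )
  # reference-base columns carry the remaining (reference-supporting) reads
  for (b in BASES) {
    sel <- cohort$ref == b
    cohort[[paste0(b, "_fwd")]][sel] <-
      cohort$depth_fwd[sel] - cohort$alt_sum_fwd[sel] +
      cohort[[paste0(b, "_fwd")]][sel]
    cohort[[paste0(b, "_rev")]][sel] <-
      cohort$depth_rev[sel] - cohort$alt_sum_rev[sel] +
      cohort[[paste0(b, "_rev")]][sel]
  }
  cohort %>%
    mutate(across(all_of(c(
      "pos", "depth_fwd", "depth_rev",
      paste0(rep(BASES, each = 2), c("_fwd", "_rev"))
    )), as.integer)) %>%
    select("sample_id", all_of(COUNTS_COLS)) %>%
    arrange(.data$sample_id, .data$chrom, .data$pos)
}

draw_depth <- function(n, mu, size) {
  constant <- is.infinite(size)
  out <- integer(n)
  out[constant] <- as.integer(round(mu[constant]))
  if (any(!constant)) {
    out[!constant] <- rnbinom(sum(!constant), mu = mu[!constant],
                              size = size[!constant])
  }
  out
}

#' Split a cohort tibble into per-sample count tables
#'
#' @param cohort A cohort tibble with a `sample_id` column.
#' @return A named list of validated count tables.
#' @export
split_cohort <- function(cohort) {
  stopifnot("sample_id" %in% names(cohort))
  split(select(as_tibble(cohort), -"sample_id"), cohort$sample_id) %>%
    purrr::imap(function(x, id) as_sample_counts(x, sample_id = id))
}

#' Construct a symmetric synthetic variant
#'
#' Spike-in design for sensitivity benchmarking: total depth is fixed at
#' `cov_total` split evenly between strands, and the variant is supported by
#' `a = cov_total * vaf / 2` reads on each strand (`2a` in total). The
#' depth/VAF grids used in practice are chosen so that `a` is whole.
#'
#' @param cov_total Total (both-strand) read depth `COV`.
#' @param vaf Target allele fraction.
#' @return A one-row tibble: `cov`, `vaf`, `a`, `k_fwd`, `k_rev`, `K_fwd`,
#'   `K_rev`.
#' @export
#' @examples
#' make_synthetic_variant(800, 0.005) # a = 2 reads per strand
make_synthetic_variant <- function(cov_total, vaf) {
  stopifnot(cov_total > 0, vaf > 0, vaf <= 1)
  if (abs(cov_total / 2 - round(cov_total / 2)) > 1e-9) {
    abort(paste0("COV must split evenly between strands: COV=", cov_total))
  }
  a <- cov_total * vaf / 2
  if (abs(a - round(a)) > 1e-9) {
    abort(paste0(
      "supporting reads per strand must be whole: COV=", cov_total,
      ", VAF=", vaf, " gives a=", a
    ))
  }
  tibble(
    cov = as.integer(cov_total), vaf = vaf, a = as.integer(round(a)),
    k_fwd = as.integer(round(a)), k_rev = as.integer(round(a)),
    K_fwd = as.integer(cov_total / 2), K_rev = as.integer(cov_total / 2)
  )
}

#' Sensitivity benchmark on synthetic spike-in variants
#'
#' For every combination of total depth `COV` and allele fraction on the
#' grids, a synthetic variant is injected at every panel position for each
#' of its three alternative alleles (`a` supporting reads per strand at
#' per-strand depth `COV/2`), and the fraction recovered as PASS calls is
#' the TPR for that cell. Every injected variant is a positive, so no FDR is
#' defined in this design. Deterministic: no random draws are involved.
#'
#' @param model An `error_model` covering the panel positions.
#' @param cov_grid Total-depth values, e.g. `c(800, 1600, 3200, 6400)`.
#' @param vaf_grid Allele-fraction values, e.g.
#'   `c(0.005, 0.01, 0.0125, 0.02, 0.03, 0.04)`.
#' @param config A [caller_config()].
#' @return A tibble with one row per (cov, vaf): `n_variants`, `n_pass`,
#'   `tpr`.
#' @export
run_synthetic_variant_experiment <- function(model, cov_grid, vaf_grid,
                                             config = caller_config()) {
  stopifnot(inherits(model, "error_model"))
  positions <- distinct(model$entries, .data$chrom, .data$pos, .data$ref)
  if (nrow(positions) == 0) abort("error model covers no positions")

  # slot i holds the i-th alternative allele of each position; alleles are
  # spiked one per synthetic sample so high-VAF draws cannot exceed depth
  alt_slots <- purrr::map(1:3, function(i) {
    positions %>%
      tidyr::crossing(alt = BASES) %>%
      filter(.data$alt != .data$ref) %>%
      group_by(.data$chrom, .data$pos) %>%
      filter(row_number() == i) %>%
      ungroup()
  })

  tidyr::crossing(cov = cov_grid, vaf = vaf_grid) %>%
    purrr::pmap(function(cov, vaf) {
      sv <- make_synthetic_variant(cov, vaf)
      n_pass <- 0L
      n_total <- 0L
      for (slot in alt_slots) {
        counts <- synthetic_counts(slot, sv)
        calls <- call_variants(counts, model, config)
        pass <- filter(calls, .data$flags == "PASS")
        n_pass <- n_pass + nrow(semi_join(
          pass, slot, by = c("chrom", "pos", "alt")
        ))
        n_total <- n_total + nrow(slot)
      }
      tibble(
        cov = as.integer(cov), vaf = vaf,
        n_variants = n_total, n_pass = n_pass,
        tpr = n_pass / n_total
      )
    }) %>%
    bind_rows()
}

# Wide count table with one spiked alternative allele per position.
synthetic_counts <- function(slot, sv) {
  wide <- slot %>%
    mutate(depth_fwd = sv$K_fwd, depth_rev = sv$K_rev)
  for (b in BASES) {
    wide[[paste0(b, "_fwd")]] <- if_else(
      wide$alt == b, sv$k_fwd,
      if_else(wide$ref == b, sv$K_fwd - sv$k_fwd, 0L)
    )
    wide[[paste0(b, "_rev")]] <- if_else(
      wide$alt == b, sv$k_rev,
      if_else(wide$ref == b, sv$K_rev - sv$k_rev, 0L)
    )
  }
  as_sample_counts(select(wide, all_of(COUNTS_COLS)),
                   sample_id = paste0("synthetic_cov", sv$cov, "_vaf", sv$vaf))
}

#' Self-consistency benchmark on a cohort of normals
#'
#' Train/test protocol run entirely within a normal cohort: in each repeat,
#' `m` samples are drawn at random to train the error model (with the given
#' pseudo-count), variants are called in the held-out samples, and calls are
#' scored against a VAF-threshold truth labelling — alternative alleles with
#' strand-combined VAF at or above `truth_vaf` (germline variants) are
#' positives, all other observed alleles (noise) are negatives. FDR and TPR
#' are computed two ways: counting calls with Q >= 20 on both strands, and
#' counting only PASS calls. With `baseline = TRUE` the error-estimation
#' step is skipped and a constant model `s = pseudo-count` is used instead,
#' giving the reference point that position-specific estimation is measured
#' against.
#'
#' @param normals A cohort tibble or list of count tables.
#' @param m_grid Training-set sizes (each strictly below the cohort size).
#' @param pseudo_grid Pseudo-count values `C` to evaluate.
#' @param repeats Random train/test splits per (m, C) cell. Default 50.
#' @param seed Random seed for the subset draws.
#' @param config A [caller_config()].
#' @param model_config An [error_model_config()]; its `pseudo_count` is
#'   overridden by each `pseudo_grid` value in turn.
#' @param truth_vaf Truth-labelling threshold. Default 0.2.
#' @param baseline Use the constant-rate model instead of training.
#' @return A tibble with one row per (repeat, m, pseudo_count): confusion
#'   counts and `tpr`/`fdr` for both the Q>=20 and the PASS definition of a
#'   call. Summarise with [summarise_self_consistency()].
#' @export
run_self_consistency <- function(normals, m_grid, pseudo_grid,
                                 repeats = 50, seed = 1,
                                 config = caller_config(),
                                 model_config = error_model_config(),
                                 truth_vaf = 0.2,
                                 baseline = FALSE) {
  cohort <- as_cohort(normals)
  samples <- split_cohort(cohort)
  ids <- names(samples)
  n <- length(ids)
  if (any(m_grid >= n)) {
    abort(paste0(
      "every training size must be below the cohort size (n = ", n, ")"
    ))
  }
  positions <- distinct(cohort, .data$chrom, .data$pos, .data$ref)
  set.seed(seed)

  results <- list()
  for (r in seq_len(repeats)) {
    for (m in m_grid) {
      train_ids <- sample(ids, m)
      test_ids <- setdiff(ids, train_ids)
      base_model <- if (baseline) {
        NULL
      } else {
        cfg0 <- model_config
        cfg0$pseudo_count <- 0
        suppressWarnings(
          estimate_errors(filter(cohort, .data$sample_id %in% train_ids), cfg0)
        )
      }
      # truth labelling on the held-out samples only
      test_truth <- purrr::map(test_ids, function(id) {
        counts_to_long(samples[[id]]) %>%
          mutate(sample_id = id) %>%
          filter(.data$k_fwd + .data$k_rev >= 1) %>%
          mutate(
            total = .data$depth_fwd + .data$depth_rev,
            vaf = (.data$k_fwd + .data$k_rev) / .data$total,
            positive = .data$vaf >= truth_vaf
          ) %>%
          select("sample_id", "chrom", "pos", "alt", "positive")
      }) %>% bind_rows()

      for (cc in pseudo_grid) {
        model <- if (baseline) {
          cfg <- model_config
          constant_error_model(positions, rate = cc, config = cfg)
        } else {
          with_pseudo_count(base_model, cc)
        }
        calls <- purrr::map(test_ids, function(id) {
          call_variants(samples[[id]], model, config) %>%
            mutate(sample_id = id)
        }) %>% bind_rows()

        scored <- score_against_truth(calls, test_truth, config$q_lowq)
        results[[length(results) + 1L]] <- scored %>%
          mutate(repeat_id = r, m = m, pseudo_count = cc,
                 baseline = baseline) %>%
          select("repeat_id", "m", "pseudo_count", "baseline",
                 dplyr::everything())
      }
    }
  }
  bind_rows(results)
}

# Shift a zero-pseudo-count model to pseudo-count cc; callability and
# max_normal_vaf do not depend on the pseudo-count, so the accumulation is
# reused across the pseudo-count grid.
with_pseudo_count <- function(model, cc) {
  model$config$pseudo_count <- cc
  model$entries <- model$entries %>%
    mutate(
      s_fwd = if_else(.data$callable, .data$s_fwd + cc, .data$s_fwd),
      s_rev = if_else(.data$callable, .data$s_rev + cc, .data$s_rev)
    )
  model
}

score_against_truth <- function(calls, truth, q_threshold) {
  truth_pos <- filter(truth, .data$positive)
  by <- c("sample_id", "chrom", "pos", "alt")
  one <- function(call_set) {
    cc <- confusion(call_set, truth_pos, by = by)
    perf <- performance(cc)
    select(perf, "tp", "fp", "fn", "tpr", "fdr")
  }
  q20 <- calls %>%
    filter(pmin(.data$q_fwd, .data$q_rev) >= q_threshold)
  pass <- filter(calls, .data$flags == "PASS")
  bind_rows(
    mutate(one(q20), call_rule = "q20"),
    mutate(one(pass), call_rule = "pass")
  ) %>%
    tidyr::pivot_wider(
      names_from = "call_rule",
      values_from = c("tp", "fp", "fn", "tpr", "fdr"),
      names_glue = "{.value}_{call_rule}"
    )
}

#' Median FDR and TPR over self-consistency repeats
#'
#' @param results A tibble from [run_self_consistency()].
#' @return One row per (m, pseudo_count, baseline) with median TPR and FDR
#'   under both call definitions.
#' @export
summarise_self_consistency <- function(results) {
  results %>%
    group_by(.data$m, .data$pseudo_count, .data$baseline) %>%
    summarise(
      n_repeats = dplyr::n(),
      median_tpr_q20 = median(.data$tpr_q20),
      median_fdr_q20 = median(.data$fdr_q20),
      median_tpr_pass = median(.data$tpr_pass),
      median_fdr_pass = median(.data$fdr_pass),
      .groups = "drop"
    )
}
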