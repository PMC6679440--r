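test_that("the Poisson tail matches pinned brute-force values and limits", {
  # oracle values computed by direct summation before the implementation
  expect_equal(poisson_tail_pvalue(5, 1000, 0.001), 0.00365984682734366,
               tolerance = 1e-12)
  expect_equal(poisson_tail_pvalue(20, 2000, 0.001), 6.42819131257966e-14,
               tolerance = 1e-6) # relative; value itself is ~1e-13
  expect_equal(poisson_tail_pvalue(0, 5000, 0.01), 1)
  expect_equal(poisson_tail_pvalue(1, 1000, 0), 0)
  expect_error(poisson_tail_pvalue(-1, 10, 0.1), "non-negative")
  expect_error(poisson_tail_pvalue(1.5, 10, 0.1), "whole")
})

test_that("the Poisson tail is monotone in k, s and K", {
  ks <- 0:30
  p_k <- poisson_tail_pvalue(ks, 1000, 0.002)
  expect_true(all(diff(p_k) <= 0))
  ss <- seq(0.0005, 0.02, by = 0.0005)
  p_s <- poisson_tail_pvalue(5, 1000, ss)
  expect_true(all(diff(p_s) >= 0))
  Ks <- seq(100, 5000, by = 100)
  p_K <- poisson_tail_pvalue(5, Ks, 0.002)
  expect_true(all(diff(p_K) >= 0))
})

test_that("Q scores are the Phred transform with a floor", {
  expect_equal(qscore(0.01), 20)
  expect_equal(qscore(1), 0)
  expect_equal(qscore(1e-6), 60)
  expect_equal(qscore(0), 3200, tolerance = 1e-6) # clamped at the 1e-320 floor
  expect_error(qscore(-0.1), "\\[0, 1\\]")
  expect_error(qscore(1.1), "\\[0, 1\\]")
})

test_that("strand bias matches the pinned enumeration oracle and edge cases", {
  expect_equal(strand_bias_pvalue(10, 0, 1000, 1000), 0.00190946516534162,
               tolerance = 1e-10)
  expect_equal(strand_bias_pvalue(5, 5, 1000, 1000), 1)
  expect_equal(strand_bias_pvalue(0, 0, 500, 900), 1)
  expect_error(strand_bias_pvalue(5, 1, 4, 100), "between 0 and")
  expect_error(strand_bias_pvalue(0, 0, 0, 10), "at least 1")
})

test_that("strand bias agrees with hypergeometric enumeration on a table grid", {
  set.seed(99)
  for (i in 1:80) {
    K_fwd <- sample(1:40, 1)
    K_rev <- sample(1:40, 1)
    k_fwd <- sample(0:K_fwd, 1)
    k_rev <- sample(0:K_rev, 1)
    expect_equal(
      strand_bias_pvalue(k_fwd, k_rev, K_fwd, K_rev),
      fisher_oracle(k_fwd, k_rev, K_fwd, K_rev),
      tolerance = 1e-10
    )
  }
})

test_that("homopolymer detection covers inside, adjacent and absent runs", {
  expect_false(is_homopolymer("ACGTACGTA", 5, min_run = 5))
  ctx <- "TTAAAAACC"
  for (i in 3:7) expect_true(is_homopolymer(ctx, i, min_run = 5))
  expect_true(is_homopolymer(ctx, 2, min_run = 5))  # immediately left
  expect_true(is_homopolymer(ctx, 8, min_run = 5))  # immediately right
  expect_false(is_homopolymer(ctx, 1, min_run = 5)) # two away
  expect_true(is_homopolymer("AAAA", 2, min_run = 4))
  expect_false(is_homopolymer("AAAA", 2, min_run = 5))
  expect_error(is_homopolymer("AAAA", 9, min_run = 2), "outside")
})

test_that("amplicon edge needs both an overlap and boundary proximity", {
  panel <- tibble::tibble(
    chrom = c("chr1", "chr1"),
    start = c(100L, 230L), end = c(250L, 400L),
    amplicon_id = c("amp1", "amp2")
  )
  # single-amplicon coverage is never an edge
  expect_false(is_amplicon_edge("chr1", 150, panel, 10))
  # in the overlap (231..250), 3 bp from amp1's end
  expect_true(is_amplicon_edge("chr1", 247, panel, 10))
  # in the overlap but >= 10 bp from every boundary of covering amplicons
  wide <- tibble::tibble(
    chrom = "chr1", start = c(0L, 0L), end = c(1000L, 1000L),
    amplicon_id = c("a", "b")
  )
  expect_false(is_amplicon_edge("chr1", 500, wide, 10))
  expect_true(is_amplicon_edge("chr1", 995, wide, 10))
})

test_that("call emission follows the per-strand reporting rules", {
  counts <- clean_counts(n_pos = 3, depth = 2000L)
  model <- uniform_model(counts, rate = 0.001)
  config <- caller_config()

  # no substitution reads -> no output row
  expect_equal(nrow(call_variants(counts, model, config)), 0)

  # strong symmetric variant: lambda = 2 per strand, k = 20
  counts2 <- set_alt(counts, 101, "C", 20, 20)
  calls <- call_variants(counts2, model, config)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 101L)
  expect_equal(calls$alt, "C")
  # pinned oracle: P(X>=20 | lambda=2)
  expect_equal(calls$p_fwd, 6.42819131257966e-14, tolerance = 1e-6)
  expect_equal(calls$q_fwd, -10 * log10(calls$p_fwd))
  expect_gt(min(calls$q_fwd, calls$q_rev), 20)
  expect_equal(calls$flags, "PASS")
  expect_equal(calls$vaf, 40 / 4000)
  expect_equal(calls$q_mean, (calls$q_fwd + calls$q_rev) / 2)

  # one strand below the Q >= 5 reporting threshold -> not reported
  counts3 <- set_alt(counts, 101, "C", 20, 3) # rev: P(X>=3|2)=0.32, Q=4.9
  calls3 <- call_variants(counts3, model, config)
  expect_equal(nrow(calls3), 0)
})

test_that("depth gating is strict and per strand", {
  counts <- clean_counts(n_pos = 2, depth = 100L)
  counts <- set_alt(counts, 100, "T", 10, 10)
  model <- uniform_model(counts, rate = 0.001)
  # depth 100 is not above rd_min = 100 -> skipped
  expect_equal(nrow(call_variants(counts, model, caller_config())), 0)
  # lenient preset (rd_min = 50) lets it through
  lenient <- caller_config(lenient = TRUE)
  expect_equal(lenient$rd_min, 50L)
  expect_equal(lenient$sb_threshold, 0.01)
  expect_equal(nrow(call_variants(counts, model, lenient)), 1)
})

test_that("warning flags fire on their defining conditions", {
  counts <- clean_counts(n_pos = 3, depth = 2000L)
  model <- uniform_model(counts, rate = 0.001)
  config <- caller_config()

  # LowQ + LowSupportingReads: k = 4 per strand, lambda = 2 -> Q in [5, 20)
  weak <- set_alt(counts, 100, "G", 4, 4)
  calls <- call_variants(weak, model, config)
  expect_equal(nrow(calls), 1)
  fl <- strsplit(calls$flags, ";")[[1]]
  expect_setequal(fl, c("LowQ", "LowSupportingReads"))

  # StrandBias: all variant reads on one strand
  biased <- set_alt(counts, 100, "G", 40, 0)
  # rev strand would fail Q>=5 with k=0; give it a trickle that still biases
  biased <- set_alt(counts, 100, "G", 40, 7)
  calls <- call_variants(biased, model, config)
  expect_equal(nrow(calls), 1)
  expect_true(grepl("StrandBias", calls$flags))
  expect_lt(calls$sb_pvalue, 0.05)

  # HomoPolymerRegion from reference context
  hp_ref <- c(chr1 = paste0(strrep("C", 99), "GAAAAAT", strrep("C", 99)))
  hp_counts <- clean_counts(n_pos = 1, depth = 2000L, start = 101L, ref = "A")
  hp_counts <- set_alt(hp_counts, 101, "T", 25, 25)
  hp_model <- uniform_model(hp_counts, rate = 0.001)
  calls <- call_variants(hp_counts, hp_model, config, reference = hp_ref)
  expect_equal(nrow(calls), 1)
  expect_true(grepl("HomoPolymerRegion", calls$flags))
  # without a reference the flag is not evaluated
  calls <- call_variants(hp_counts, hp_model, config)
  expect_equal(calls$flags, "PASS")

  # AmpliconEdge with a panel
  panel <- tibble::tibble(
    chrom = "chr1", start = c(0L, 95L), end = c(103L, 300L),
    amplicon_id = c("a", "b")
  )
  edge <- set_alt(counts, 100, "T", 25, 25)
  calls <- call_variants(edge, model, config, panel = panel)
  expect_true(grepl("AmpliconEdge", calls$flags))

  # PositionWithHighNoise: VAF below the maximum normal VAF, k > 5 per strand
  noisy_model <- uniform_model(counts, rate = 0.001)
  noisy_model$entries$max_normal_vaf <- 0.02
  noisy <- set_alt(counts, 100, "T", 25, 25) # VAF 50/4000 = 1.25% < 2%
  calls <- call_variants(noisy, noisy_model, config)
  expect_true(grepl("PositionWithHighNoise", calls$flags))
  # exactly min_supporting reads per strand: neither LowSupportingReads
  # (k < 5) nor the high-noise condition (k > 5) applies
  at5 <- set_alt(counts, 100, "T", 5, 5)
  calls <- call_variants(at5, noisy_model, config)
  expect_false(grepl("LowSupportingReads", calls$flags))
  expect_false(grepl("PositionWithHighNoise", calls$flags))
})

test_that("PASS is present exactly when no warning fires (full truth table)", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  flag_strings <- amplisnv:::join_flags(
    combos[[1]], combos[[2]], combos[[3]], combos[[4]], combos[[5]], combos[[6]]
  )
  for (i in seq_len(nrow(combos))) {
    any_warning <- any(unlist(combos[i, ]))
    expect_equal(flag_strings[i] == "PASS", !any_warning)
    expect_equal(grepl("PASS", flag_strings[i]), !any_warning)
    # every fired warning appears by name
    fired <- c("LowQ", "LowSupportingReads", "AmpliconEdge", "StrandBias",
               "HomoPolymerRegion", "PositionWithHighNoise")[unlist(combos[i, ])]
    expect_true(all(vapply(fired, grepl, logical(1), x = flag_strings[i],
                           fixed = TRUE)))
  }
})

test_that("raising the strand-bias threshold never removes the flag", {
  counts <- clean_counts(n_pos = 1, depth = 2000L)
  counts <- set_alt(counts, 100, "C", 30, 12)
  model <- uniform_model(counts, rate = 0.001)
  thresholds <- c(0.001, 0.01, 0.05, 0.2)
  flagged <- vapply(thresholds, function(th) {
    calls <- call_variants(counts, model,
                           caller_config(sb_threshold = th))
    grepl("StrandBias", calls$flags)
  }, logical(1))
  expect_true(all(diff(flagged) >= 0)) # once flagged, stays flagged
})

test_that("candidates at non-callable or uncovered entries go to the side
          report", {
  counts <- clean_counts(n_pos = 3, depth = 2000L)
  counts <- set_alt(counts, 100, "C", 50, 50)
  counts <- set_alt(counts, 101, "C", 50, 50)
  model <- uniform_model(counts, rate = 0.001)
  model$entries <- dplyr::mutate(
    model$entries,
    callable = !(pos == 100 & alt == "C"),
    s_fwd = ifelse(callable, s_fwd, NA_real_),
    s_rev = ifelse(callable, s_rev, NA_real_)
  )
  # and remove position 101 from the model entirely
  model$entries <- dplyr::filter(model$entries, pos != 101)
  calls <- call_variants(counts, model, caller_config())
  expect_equal(nrow(calls), 0)
  side <- attr(calls, "uncallable")
  expect_equal(sort(side$reason), c("non_callable", "not_in_model"))
  expect_setequal(side$pos, c(100L, 101L))
})

test_that("calls are written as TSV in the documented column order", {
  counts <- set_alt(clean_counts(n_pos = 1, depth = 2000L), 100, "C", 20, 20)
  model <- uniform_model(counts, rate = 0.001)
  calls <- call_variants(counts, model, caller_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, path, format = "tsv")
  out <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(
    names(out),
    c("chrom", "pos", "ref", "alt", "vaf", "k_fwd", "k_rev",
      "K_fwd", "K_rev", "q_fwd", "q_rev", "q_mean", "flags")
  )
  expect_equal(out$flags, "PASS")
  expect_equal(out$q_fwd, round(calls$q_fwd, 2))
  # empty calls -> header-only file
  write_calls(calls[0, ], path, format = "tsv")
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 0)
  expect_error(write_calls(calls, path, format = "xlsx"), "should be one of")
})

test_that("VCF output is readable by an independent VCF parser", {
  skip_if_not_installed("VariantAnnotation")
  counts <- clean_counts(n_pos = 3, depth = 2000L)
  counts <- set_alt(counts, 100, "C", 20, 20)
  counts <- set_alt(counts, 102, "G", 4, 4)
  model <- uniform_model(counts, rate = 0.001)
  calls <- call_variants(counts, model, caller_config())
  expect_equal(nrow(calls), 2)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls(calls, path, format = "vcf")
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  expect_equal(length(vcf), 2)
  expect_equal(as.character(VariantAnnotation::fixed(vcf)$FILTER),
               calls$flags)
  expect_equal(VariantAnnotation::info(vcf)$VAF, calls$vaf, tolerance = 1e-4)
  expect_equal(VariantAnnotation::info(vcf)$KF, calls$k_fwd)
})
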