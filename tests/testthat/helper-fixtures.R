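# In-code fixture builders shared across test files.

# A minimal valid count row; override any field.
count_row <- function(chrom = "chr1", pos = 100L, ref = "A",
                      depth_fwd = 500L, depth_rev = 480L,
                      A_fwd = 0L, A_rev = 0L, C_fwd = 0L, C_rev = 0L,
                      G_fwd = 0L, G_rev = 0L, T_fwd = 0L, T_rev = 0L) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    depth_fwd = as.integer(depth_fwd), depth_rev = as.integer(depth_rev),
    A_fwd = as.integer(A_fwd), A_rev = as.integer(A_rev),
    C_fwd = as.integer(C_fwd), C_rev = as.integer(C_rev),
    G_fwd = as.integer(G_fwd), G_rev = as.integer(G_rev),
    T_fwd = as.integer(T_fwd), T_rev = as.integer(T_rev)
  )
}

# A clean sample: every position fully reference-supporting at given depth.
# `ref` may be a vector, recycled across positions.
clean_counts <- function(n_pos = 3, depth = 1000L, ref = "A",
                         chrom = "chr1", start = 100L, sample_id = "n") {
  ref <- rep_len(ref, n_pos)
  rows <- dplyr::bind_rows(lapply(seq_len(n_pos), function(i) {
    r <- count_row(
      chrom = chrom, pos = start + i - 1L, ref = ref[i],
      depth_fwd = depth, depth_rev = depth
    )
    r[[paste0(ref[i], "_fwd")]] <- as.integer(depth)
    r[[paste0(ref[i], "_rev")]] <- as.integer(depth)
    r
  }))
  as_sample_counts(rows, sample_id = sample_id)
}

# Set the read count of one alternative allele (both depth columns stay).
set_alt <- function(counts, pos, alt, k_fwd, k_rev) {
  i <- which(counts$pos == pos)
  ref <- counts$ref[i]
  counts[[paste0(alt, "_fwd")]][i] <- as.integer(k_fwd)
  counts[[paste0(alt, "_rev")]][i] <- as.integer(k_rev)
  counts[[paste0(ref, "_fwd")]][i] <-
    counts$depth_fwd[i] - sum_alts(counts, i, "fwd")
  counts[[paste0(ref, "_rev")]][i] <-
    counts$depth_rev[i] - sum_alts(counts, i, "rev")
  as_sample_counts(counts, sample_id = attr(counts, "sample_id"))
}

sum_alts <- function(counts, i, strand) {
  ref <- counts$ref[i]
  bases <- setdiff(c("A", "C", "G", "T"), ref)
  sum(vapply(paste0(bases, "_", strand), function(cc) counts[[cc]][i],
             integer(1)))
}

# Error model with a single uniform rate over given positions, built through
# the constant-rate constructor.
uniform_model <- function(counts, rate) {
  constant_error_model(counts, rate = rate)
}
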