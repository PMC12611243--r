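# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (enumeration / brute-force / textbook DP)
# and never share code with the implementation they check.

# A 60-nt reference: 9 nt noncoding + ORFA (10 codons) + 3 nt spacer +
# ORFB (6 codons). No stop codons anywhere in the ORFs.
toy_reference <- function() {
  orfa <- paste0("ATG", "AAA", "CCC", "GGG", "TTT", "ACT", "CAT", "CAG",
                 "GAC", "TGC")
  orfb <- paste0("ATG", "CTT", "GAA", "TGC", "TAC", "AGA")
  seq <- paste0("GATTACAGA", orfa, "ACG", orfb)
  reference_genome(
    "toyref", seq,
    regions = data.frame(
      name = c("ORFA", "ORFB"), start = c(10L, 43L), end = c(39L, 60L),
      frame_offset = c(0L, 0L), stringsAsFactors = FALSE
    )
  )
}

toy_amplicon <- function(ref = toy_reference()) {
  amplicon_region(1L, nchar(ref$sequence))
}

# Replace single reference bases (1-based positions) in a sequence string.
with_snps <- function(seq, pos, base) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- base[i]
  seq
}

# Frequency-weighted mean pairwise Hamming distance per coding site:
# the direct oracle that the codon accumulator must reproduce exactly on
# SNP-only (equal-length, gap-free) populations.
pi_hamming_oracle <- function(pop, coding_cols) {
  x <- pop$haplotypes$read_count / pop$total_reads
  subs <- vapply(pop$haplotypes$sequence, function(s) {
    paste(strsplit(s, "", fixed = TRUE)[[1L]][coding_cols], collapse = "")
  }, "", USE.NAMES = FALSE)
  tot <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (i != j) tot <- tot + x[i] * x[j] * hamming_distance(subs[i], subs[j])
    }
  }
  tot / length(coding_cols)
}

# Coding columns (reference coordinates of complete codons) of a reference,
# restricted to an amplicon.
coding_columns <- function(ref, amplicon) {
  cols <- integer(0)
  for (ri in seq_len(nrow(ref$regions))) {
    r <- ref$regions[ri, ]
    first <- r$start + r$frame_offset
    starts <- seq.int(first, r$end - 2L, by = 3L)
    starts <- starts[starts >= amplicon$start & starts + 2L <= amplicon$end]
    cols <- c(cols, as.vector(vapply(starts, function(s) s:(s + 2L),
                                     integer(3L))))
  }
  sort(cols)
}

# Textbook Gotoh affine-gap global alignment, score only; a gap of length
# L costs open + ext * L.
affine_score_oracle <- function(a, b, match = 2, mismatch = -4,
                                open = -12, ext = -1) {
  a <- strsplit(a, "", fixed = TRUE)[[1L]]
  b <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consume a)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consume b)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- open + ext * i
  for (j in seq_len(m)) Iy[1L, j + 1L] <- open + ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1L, j + 1L] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + open + ext,
                                Ix[i, j + 1L] + ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + open + ext,
                                Iy[i + 1L, j] + ext)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

# Full choose()-based enumeration of a 2x2 Fisher two-sided p-value.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  prob <- function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }
  ps <- vapply(lo:hi, prob, 0)
  min(1, sum(ps[ps <= prob(a) * (1 + 1e-12)]))
}

# Small simulated SNP-only population plus its reference, for oracle
# equivalence checks (stop-free coding by construction of the generator).
small_sim_population <- function(seed, n_variants = 8L, reads = 200L) {
  cfg <- simulation_config(
    seed = seed, amplicon_length = 150L, noncoding_length = 21L,
    orfa_length = 60L, n_variants = n_variants, expansion_reads = reads,
    snps_per_variant = 2
  )
  mr <- make_reference(cfg)
  pop <- make_parental_population(mr$ref, cfg, sample_id = paste0("p", seed))
  list(cfg = cfg, ref = mr$ref, amplicon = mr$amplicon, pop = pop)
}

# A quick config for pipeline-scale tests: short amplicon, small depth.
# Overrides in ... replace the small-study defaults.
small_study_config <- function(seed = 7L, ...) {
  defaults <- list(
    seed = seed, amplicon_length = 600L, noncoding_length = 30L,
    orfa_length = 300L, n_variants = 12L, expansion_reads = 300L,
    post_mutation_rate = 0.002
  )
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
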