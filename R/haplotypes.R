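# Variant-level algebra: Hamming distance, read collapsing, gene diversity,
# frequency spectra and shared-variant identification. A "viral variant" is
# a unique haplotype: two sequences belong to the same variant iff their
# Hamming distance is 0, i.e. they are identical strings.

#' Hamming distance between two equal-length sequences
#'
#' `dH(a, b) = sum_i [a_i != b_i]`: the number of positions at which the two
#' sequences differ. Defined only for equal lengths; sequences of unequal
#' length (indel-bearing haplotypes) are distinct variants by definition and
#' have no finite distance.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Non-negative integer; 0 iff the strings are identical.
#' @export
#' @examples
#' hamming_distance("ACGT", "ACGA")  # 1
hamming_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) != nchar(b)) {
    stop("Hamming distance is undefined for sequences of unequal length (",
         nchar(a), " vs ", nchar(b), ")")
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Collapse reads into viral variants
#'
#' Merges all sequences at Hamming distance 0 (i.e. identical strings),
#' summing their read counts, so each remaining haplotype is a distinct
#' viral variant. Total read count is conserved and the operation is
#' idempotent. Sequences of unequal length never merge.
#'
#' @param sequences Character vector of A/C/G/T reads or haplotypes.
#' @param counts Positive integer read counts (default 1 per sequence).
#' @param ids Optional ids; the first id of each merged group is kept.
#' @param sample_id,role,strain,subtype Passed to [viral_population()].
#' @return A [viral_population()].
#' @export
collapse_reads <- function(sequences, counts = NULL, ids = NULL,
                           sample_id = "pop", role = "pooled",
                           strain = NA_character_, subtype = NA_character_) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("cannot collapse an empty read set")
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("read counts must be positive integers")
  }
  first <- !duplicated(sequences)
  key <- match(sequences, sequences[first])
  merged <- vapply(split(counts, key), sum, 0L)
  uniq <- sequences[first]
  ids <- if (is.null(ids)) NULL else as.character(ids)[first]
  viral_population(
    sample_id, uniq, merged[as.character(seq_along(uniq))], ids = ids,
    role = role, strain = strain, subtype = subtype
  )
}

#' Gene diversity 1 - sum(x^2)
#'
#' The probability that two reads drawn with replacement are different
#' variants; the uncorrected core of Nei's H and the quantity whose expected
#' loss under k-founder sampling is `1/k` (see [estimate_founders()]).
#'
#' @param pop A [viral_population()] or a numeric frequency vector.
#' @return Value in `[0, 1)`.
#' @export
gene_diversity <- function(pop) {
  x <- if (inherits(pop, "viral_population")) variant_frequencies(pop) else pop
  1 - sum(x^2)
}

#' Nei's gene diversity H
#'
#' Computes `h = n * (1 - sum(x_i^2)) / (n - 1)` with `x_i` the variant
#' frequencies. By default `n` is the number of distinct viral variants
#' (the convention used for denoised amplicon populations where read depth
#' is arbitrary); `n_mode = "reads"` uses the total read count instead
#' (the classical finite-sample correction over sequences). A monomorphic
#' population (`n = 1`, where the formula is 0/0) has `h = 0` by
#' convention, the limit of the unbiased estimator.
#'
#' @param pop A [viral_population()].
#' @param n_mode `"variants"` (default) or `"reads"`: what plays the role
#'   of `n` in the correction factor.
#' @return Value in `[0, 1]`, with attribute `n_mode`.
#' @export
#' @examples
#' p <- viral_population("s", c("AAAA", "AAAT"), c(8, 2))
#' neis_h(p)  # 2 * (1 - 0.68) / 1 = 0.64
neis_h <- function(pop, n_mode = c("variants", "reads")) {
  stopifnot(inherits(pop, "viral_population"))
  n_mode <- match.arg(n_mode)
  x <- variant_frequencies(pop)
  n <- if (n_mode == "variants") length(x) else pop$total_reads
  h <- if (n <= 1L) 0 else n * (1 - sum(x^2)) / (n - 1)
  structure(h, n_mode = n_mode)
}

#' Variant frequency spectrum and dominant-variant count
#'
#' Returns the sorted (descending) variant frequencies and the number of
#' dominant variants, i.e. variants represented with at least
#' `dominance_threshold` of the population (boundary inclusive; the
#' conventional cut is 5%).
#'
#' @param pop A [viral_population()].
#' @param dominance_threshold Fraction in (0, 1); default 0.05.
#' @return List with `frequencies` (descending) and `n_dominant`.
#' @export
variant_spectrum <- function(pop, dominance_threshold = 0.05) {
  stopifnot(inherits(pop, "viral_population"))
  if (!is.numeric(dominance_threshold) || length(dominance_threshold) != 1L ||
      dominance_threshold <= 0 || dominance_threshold >= 1) {
    stop("dominance_threshold must be in (0, 1)")
  }
  freqs <- sort(variant_frequencies(pop), decreasing = TRUE)
  list(frequencies = freqs, n_dominant = sum(freqs >= dominance_threshold))
}

#' Shared viral variants between a source and its recipient population(s)
#'
#' A variant is shared iff a sequence identical to it (Hamming distance 0)
#' occurs both in the source and in at least one recipient. With several
#' recipients the recipient side is the union of their variant sets, and
#' the sequences present in every population (source and all recipients)
#' are reported as well. Because the denominator of a "percent transmitted"
#' statement is ambiguous, all three fractions are reported: of the source
#' variant set, of the recipient set and of the union.
#'
#' @param source A [viral_population()].
#' @param recipients A [viral_population()] or list of them.
#' @return An object of class `shared_variant_result`: list with
#'   `shared_sequences`, `present_in_all`, `n_shared`, `n_source_only`,
#'   `n_recipient_only`, `frac_of_source`, `frac_of_recipient`,
#'   `frac_of_union`.
#' @export
shared_variants <- function(source, recipients) {
  stopifnot(inherits(source, "viral_population"))
  if (inherits(recipients, "viral_population")) recipients <- list(recipients)
  stopifnot(length(recipients) >= 1L,
            all(vapply(recipients, inherits, TRUE, "viral_population")))
  s <- source$haplotypes$sequence
  rec_sets <- lapply(recipients, function(p) p$haplotypes$sequence)
  r <- unique(unlist(rec_sets))
  shared <- intersect(s, r)
  in_all <- Reduce(intersect, rec_sets, accumulate = FALSE)
  in_all <- intersect(s, in_all)
  n_shared <- length(shared)
  n_source_only <- length(setdiff(s, r))
  n_recipient_only <- length(setdiff(r, s))
  structure(
    list(
      shared_sequences = shared,
      present_in_all = in_all,
      n_shared = n_shared,
      n_source_only = n_source_only,
      n_recipient_only = n_recipient_only,
      frac_of_source = n_shared / length(s),
      frac_of_recipient = n_shared / length(r),
      frac_of_union = n_shared / (n_shared + n_source_only + n_recipient_only)
    ),
    class = "shared_variant_result"
  )
}

#' Per-population variant summary table
#'
#' One row per population: sample id, variant and read totals, Nei's H,
#' dominant-variant count and the top-5 variant frequencies.
#'
#' @param pops List of [viral_population()] objects.
#' @param dominance_threshold Passed to [variant_spectrum()].
#' @return data.frame, one row per population.
#' @export
variant_table <- function(pops, dominance_threshold = 0.05) {
  if (inherits(pops, "viral_population")) pops <- list(pops)
  rows <- lapply(pops, function(p) {
    sp <- variant_spectrum(p, dominance_threshold)
    top <- c(sp$frequencies, rep(NA_real_, 5L))[1:5]
    data.frame(
      sample_id = p$sample_id, role = p$role,
      n_variants = nrow(p$haplotypes), total_reads = p$total_reads,
      neis_h = as.numeric(neis_h(p)), n_dominant = sp$n_dominant,
      f1 = top[1], f2 = top[2], f3 = top[3], f4 = top[4], f5 = top[5],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
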