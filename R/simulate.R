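# Synthetic quasispecies generator: reference/amplicon layout, parental
# intra-host populations (a few dominant variants plus many rare ones),
# founder-sampled vertical and vic-locus-gated horizontal transmission,
# sequencing noise and a toy abundance-threshold denoiser. A single global
# seed is stream-split by operation name and replicate index, so every
# replicate is independently reproducible.

#' Simulation configuration
#'
#' Defaults emulate the structure of an intra-host CHV1 amplicon study: a
#' 5 kb amplicon made of a 5' noncoding stretch, a complete ORFA and the
#' amplicon-truncated 5' part of ORFB; populations of tens of variants with
#' a few dominant (>= 5% frequency) and many rare ones; founder counts
#' around 2 (zero-truncated Poisson, matching mycovirus founder estimates
#' of about 1.99 +/- 1.51 genomes); and horizontal transmission success
#' probabilities gated by the heteroallelic vic locus (none 100%, vic2 6%,
#' vic3 17% — the midpoint of reported 12.5–25% assays — vic4 97%).
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param amplicon_length Total amplicon length in nt (default 5000).
#' @param noncoding_length Leading noncoding stretch (default 450; must
#'   leave room for the 20-nt forward-primer site).
#' @param orfa_length ORFA length in nt, multiple of 3 (default 1380). The
#'   remaining length (rounded down to a codon multiple) becomes the
#'   truncated ORFB.
#' @param n_variants Number of distinct variants in a parental population.
#' @param spectrum_alpha Dirichlet concentration of variant frequencies
#'   (small values give a few dominant plus many rare variants).
#' @param snps_per_variant Poisson mean of SNPs carried by each non-master
#'   variant (zero-truncated so variants are distinct).
#' @param founder_k Fixed founder count, or `NULL` to draw from a
#'   zero-truncated Poisson with mean `founder_lambda`.
#' @param founder_lambda Poisson mean for stochastic founder counts.
#' @param expansion_reads Total read count of every output population.
#' @param post_mutation_rate Per-site probability that the recipient
#'   population acquires a new private SNP after transmission.
#' @param vic_success Named success probabilities for horizontal
#'   transmission by heteroallelic locus.
#' @param founder_lambda_by_locus Founder-count Poisson means by locus
#'   (barrier loci vic2/vic3 pass fewer genomes).
#' @param vertical_success Probability a conidium is infected (vertical
#'   assays score this Bernoulli per spore).
#' @param error_rate Per-base sequencing error rate in `[0, 0.01]`.
#' @param strain Strain label used by the study presets.
#' @param subtype Viral subtype label (`"F1"` or `"I"`).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              amplicon_length = 5000L,
                              noncoding_length = 450L,
                              orfa_length = 1380L,
                              n_variants = 40L,
                              spectrum_alpha = 0.3,
                              snps_per_variant = 2,
                              founder_k = NULL,
                              founder_lambda = 2,
                              expansion_reads = 2000L,
                              post_mutation_rate = 0.004,
                              vic_success = c(none = 1.0, vic2 = 0.06,
                                              vic3 = 0.17, vic4 = 0.97),
                              founder_lambda_by_locus = c(none = 5, vic2 = 2,
                                                          vic3 = 2, vic4 = 5),
                              vertical_success = 1.0,
                              error_rate = 0.002,
                              strain = "SIM",
                              subtype = "I") {
  amplicon_length <- as.integer(amplicon_length)
  noncoding_length <- as.integer(noncoding_length)
  orfa_length <- as.integer(orfa_length)
  if (orfa_length %% 3L != 0L) stop("orfa_length must be a multiple of 3")
  if (noncoding_length < 20L) {
    stop("noncoding_length must fit the 20-nt forward-primer site")
  }
  orfb_length <- ((amplicon_length - noncoding_length - orfa_length) %/% 3L) * 3L
  if (orfb_length < 3L) {
    stop("layout lengths exceed amplicon_length (no room for ORFB)")
  }
  stopifnot(all(vic_success >= 0 & vic_success <= 1),
            all(VALID_LOCI %in% names(vic_success)),
            all(VALID_LOCI %in% names(founder_lambda_by_locus)),
            vertical_success >= 0, vertical_success <= 1)
  if (error_rate < 0 || error_rate > 0.01) {
    stop("error_rate must be in [0, 0.01]")
  }
  if (!is.null(founder_k)) {
    founder_k <- as.integer(founder_k)
    stopifnot(founder_k >= 1L)
  }
  structure(
    list(seed = as.integer(seed), amplicon_length = amplicon_length,
         noncoding_length = noncoding_length, orfa_length = orfa_length,
         orfb_length = orfb_length, n_variants = as.integer(n_variants),
         spectrum_alpha = spectrum_alpha,
         snps_per_variant = snps_per_variant,
         founder_k = founder_k, founder_lambda = founder_lambda,
         expansion_reads = as.integer(expansion_reads),
         post_mutation_rate = post_mutation_rate,
         vic_success = vic_success,
         founder_lambda_by_locus = founder_lambda_by_locus,
         vertical_success = vertical_success,
         error_rate = error_rate, strain = strain, subtype = subtype),
    class = "simulation_config"
  )
}

# Deterministic stream-splitting: a child seed from the master seed, an
# operation name and a replicate index (kept inside 32-bit integer range).
child_seed <- function(seed, op, index = 0L) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(op)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + as.double(index)) %% 2147483647
  as.integer(h) + 1L
}

# Evaluate code under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Zero-truncated Poisson draw (a successful transmission has >= 1 founder).
ztpois <- function(lambda) {
  k <- 0L
  while (k < 1L) k <- rpois(1L, lambda)
  k
}

# Largest-remainder rounding of frequencies to integer counts summing to
# `total`, with every class kept at >= 1 read (counts are read counts).
largest_remainder <- function(freqs, total) {
  if (total < length(freqs)) {
    stop("cannot give every variant at least one read (", total,
         " reads for ", length(freqs), " variants)")
  }
  quota <- freqs / sum(freqs) * total
  counts <- floor(quota)
  short <- total - sum(counts)
  if (short > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  for (z in which(counts == 0)) {
    donor <- which.max(counts)
    counts[z] <- 1
    counts[donor] <- counts[donor] - 1
  }
  as.integer(counts)
}

FWD_PRIMER_SITE <- "ATCCGGAGAAAGTGATTTGC"          # one expansion of the
REV_PRIMER_SITE_RC <- "CCTCGCAGCTACATCAACAAG"      # study primer pair

# TRUE when the base at position p of seq_chars sits in a stop codon of its
# coding region.
creates_stop <- function(seq_chars, p, regions) {
  for (ri in seq_len(nrow(regions))) {
    r <- regions[ri, ]
    first <- r$start + r$frame_offset
    if (p < first || p > r$end) next
    cs <- first + 3L * ((p - first) %/% 3L)
    if (cs + 2L > r$end) return(FALSE)
    codon <- paste(seq_chars[cs:(cs + 2L)], collapse = "")
    return(translate_codon(codon) == "*")
  }
  FALSE
}

# Apply n random SNPs to a sequence, rejecting changes that create a
# premature in-frame stop codon (the generator models viable genomes).
apply_random_snps <- function(seq_chars, n, regions) {
  used <- integer(0)
  tries <- 0L
  while (length(used) < n && tries < 10000L) {
    tries <- tries + 1L
    p <- sample.int(length(seq_chars), 1L)
    if (p %in% used) next
    new_base <- sample(BASES[BASES != seq_chars[p]], 1L)
    cand <- seq_chars
    cand[p] <- new_base
    if (creates_stop(cand, p, regions)) next
    seq_chars <- cand
    used <- c(used, p)
  }
  seq_chars
}

#' Generate a synthetic reference genome and amplicon
#'
#' Deterministic for a given seed. The sequence is the amplicon itself:
#' a noncoding 5' stretch carrying the forward-primer site, a complete
#' ORFA, the amplicon-truncated 5' part of ORFB ending in the
#' reverse-primer site, and at most two trailing noncoding bases. Both
#' ORFs are built codon-wise with no internal stop codons.
#'
#' @param cfg A [simulation_config()].
#' @return List with `ref` (a [reference_genome()] with ORFA/ORFB regions)
#'   and `amplicon` (an [amplicon_region()] carrying the primer pair).
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  for (attempt in 0:19) {
    ref <- with_seed(child_seed(cfg$seed, "reference", attempt), {
      nc <- sample(BASES, cfg$noncoding_length, replace = TRUE)
      draw_orf <- function(len) {
        codons <- character(len %/% 3L)
        for (i in seq_along(codons)) {
          repeat {
            cdn <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
            if (translate_codon(cdn) != "*") break
          }
          codons[i] <- cdn
        }
        paste(codons, collapse = "")
      }
      orfa <- draw_orf(cfg$orfa_length)
      orfb <- draw_orf(cfg$orfb_length)
      trailing <- cfg$amplicon_length - cfg$noncoding_length -
        cfg$orfa_length - cfg$orfb_length
      seq <- paste0(paste(nc, collapse = ""), orfa, orfb,
                    paste(sample(BASES, trailing, replace = TRUE),
                          collapse = ""))
      # primer sites: forward at the 5' end (noncoding), reverse-complement
      # site at the 3' end (its codon frames are stop-free in ORFB)
      substr(seq, 1L, nchar(FWD_PRIMER_SITE)) <- FWD_PRIMER_SITE
      substr(seq, nchar(seq) - nchar(REV_PRIMER_SITE_RC) + 1L,
             nchar(seq)) <- REV_PRIMER_SITE_RC
      orfa_start <- cfg$noncoding_length + 1L
      orfb_start <- orfa_start + cfg$orfa_length
      reference_genome(
        "CHV1sim", seq,
        regions = data.frame(
          name = c("ORFA", "ORFB"),
          start = c(orfa_start, orfb_start),
          end = c(orfa_start + cfg$orfa_length - 1L,
                  orfb_start + cfg$orfb_length - 1L),
          frame_offset = c(0L, 0L), stringsAsFactors = FALSE
        )
      )
    })
    amp <- tryCatch(
      find_amplicon(ref, "ATCYGGAGAARGTGATTTGC", "YTTRTTGATGTAGCTGCGAGG"),
      error = function(e) NULL
    )
    if (!is.null(amp)) return(list(ref = ref, amplicon = amp))
  }
  stop("could not draw a reference with a unique primer pair match")
}

#' Generate a parental intra-host viral population
#'
#' Variant frequencies are drawn once from a Dirichlet(`spectrum_alpha`)
#' and sorted descending, giving a few dominant variants and many rare
#' ones. The master variant is the reference amplicon; every other variant
#' carries a zero-truncated Poisson number of random SNPs relative to it
#' (no premature stop codons). Read counts are the frequencies rounded to
#' `expansion_reads` total by largest-remainder rounding, every variant
#' keeping at least one read.
#'
#' @param ref A [reference_genome()] from [make_reference()].
#' @param cfg A [simulation_config()].
#' @param sample_id,role Identity of the generated population.
#' @return A [viral_population()].
#' @export
make_parental_population <- function(ref, cfg, sample_id = "parental",
                                     role = "parental") {
  stopifnot(inherits(ref, "reference_genome"),
            inherits(cfg, "simulation_config"))
  if (cfg$expansion_reads < cfg$n_variants) {
    stop("expansion_reads < n_variants: cannot give every variant one read")
  }
  with_seed(child_seed(cfg$seed, paste0("parental:", sample_id), 0L), {
    freqs <- sort(rgamma(cfg$n_variants, cfg$spectrum_alpha, 1),
                  decreasing = TRUE)
    freqs <- freqs / sum(freqs)
    master <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
    seqs <- character(cfg$n_variants)
    seqs[1L] <- ref$sequence
    for (i in seq_len(cfg$n_variants)[-1L]) {
      for (try in 1:100) {
        nmut <- ztpois(cfg$snps_per_variant)
        cand <- paste(apply_random_snps(master, nmut, ref$regions),
                      collapse = "")
        if (!cand %in% seqs[seq_len(i - 1L)]) break
      }
      seqs[i] <- cand
    }
    counts <- largest_remainder(freqs, cfg$expansion_reads)
    viral_population(sample_id, seqs, counts, role = role,
                     strain = cfg$strain, subtype = cfg$subtype)
  })
}

# Founder sampling plus proportional expansion shared by both transmission
# modes: draw k genomes multinomially from the source frequencies, expand
# the founder multiset to expansion_reads preserving proportions, then add
# private post-transmission SNPs (each a new rare variant of one read).
expand_founders <- function(source, k, cfg, ref, sample_id, role) {
  idx <- sample.int(nrow(source$haplotypes), k, replace = TRUE,
                    prob = variant_frequencies(source))
  founder_sequences <- source$haplotypes$sequence[idx]
  tab <- table(idx)
  seqs <- source$haplotypes$sequence[as.integer(names(tab))]
  counts <- largest_remainder(as.numeric(tab) / k, cfg$expansion_reads)
  n_new <- rbinom(1L, nchar(ref$sequence), cfg$post_mutation_rate)
  for (i in seq_len(n_new)) {
    parent <- sample.int(length(seqs), 1L, prob = counts)
    if (counts[parent] < 2L) next   # keep every existing variant at >= 1 read
    mutated <- paste(
      apply_random_snps(strsplit(seqs[parent], "", fixed = TRUE)[[1L]],
                        1L, ref$regions),
      collapse = ""
    )
    counts[parent] <- counts[parent] - 1L
    seqs <- c(seqs, mutated)
    counts <- c(counts, 1L)
  }
  pop <- collapse_reads(seqs, counts, sample_id = sample_id, role = role,
                        strain = cfg$strain, subtype = cfg$subtype)
  list(pop = pop, founder_sequences = founder_sequences)
}

#' Simulate vertical transmission into a conidial spore
#'
#' Draws `k` founder genomes by multinomial sampling (with replacement:
#' virions vastly outnumber founders) from the source variant frequencies
#' — `k` fixed via `cfg$founder_k` or zero-truncated
#' Poisson(`founder_lambda`) — and expands the founder multiset to
#' `expansion_reads` reads preserving founder proportions, plus private
#' SNPs at `post_mutation_rate`. The spore-infection Bernoulli itself is
#' the caller's concern; the outcome here is always a population.
#'
#' @param source A [viral_population()].
#' @param cfg A [simulation_config()].
#' @param replicate Replicate index (stream-splits the seed).
#' @param k Founder-count override.
#' @param sample_id Recipient sample id (default `<source>_S<replicate>`).
#' @return Object of class `transmission_outcome`: list with `success`,
#'   `k`, `founder_sequences`, `recipient`.
#' @export
simulate_vertical <- function(source, cfg, replicate = 1L, k = NULL,
                              sample_id = NULL) {
  stopifnot(inherits(source, "viral_population"),
            inherits(cfg, "simulation_config"))
  if (is.null(sample_id)) {
    sample_id <- paste0(source$sample_id, "_S", replicate)
  }
  with_seed(child_seed(cfg$seed, paste0("vertical:", source$sample_id),
                       replicate), {
    if (is.null(k)) {
      k <- if (!is.null(cfg$founder_k)) cfg$founder_k
           else ztpois(cfg$founder_lambda)
    }
    ex <- expand_founders(source, k, cfg, make_ref_proxy(source), sample_id,
                          role = "progeny")
    structure(
      list(success = TRUE, k = k,
           founder_sequences = ex$founder_sequences, recipient = ex$pop),
      class = "transmission_outcome"
    )
  })
}

# post-transmission mutation needs reference length and coding regions; the
# simulator threads them through the config environment when available,
# falling back to the master haplotype with no coding annotation.
make_ref_proxy <- function(source) {
  ref <- attr(source, "sim_reference")
  if (!is.null(ref)) return(ref)
  list(sequence = source$haplotypes$sequence[1L],
       regions = data.frame(name = character(), start = integer(),
                            end = integer(), frame_offset = integer()))
}

#' Attach the generating reference to a simulated population
#'
#' Post-transmission mutation draws respect the coding annotation (no
#' premature stops); attaching the reference lets transmission simulations
#' inherit it.
#'
#' @param pop A [viral_population()].
#' @param ref A [reference_genome()].
#' @return `pop` with the reference attached.
#' @export
attach_reference <- function(pop, ref) {
  attr(pop, "sim_reference") <- ref
  pop
}

#' Simulate horizontal transmission through a vic-locus barrier
#'
#' Success is Bernoulli with the locus-specific probability from
#' `cfg$vic_success` (compatible pairings transmit with probability 1).
#' On success, founder sampling proceeds as in [simulate_vertical()] but
#' with the locus-specific founder mean from `founder_lambda_by_locus`
#' (the vic2/vic3 barriers pass fewer genomes, reducing shared-variant
#' fractions). A failed transmission has no recipient population.
#'
#' @param source A [viral_population()] (the donor).
#' @param het_locus `"none"`, `"vic2"`, `"vic3"` or `"vic4"`.
#' @param cfg A [simulation_config()].
#' @param replicate Replicate index.
#' @param condition_on_success Skip the Bernoulli and force success (used
#'   when emulating a study that only sequences successful recipients).
#' @param sample_id Recipient sample id.
#' @return Object of class `transmission_outcome`; `recipient` is `NULL`
#'   on failure.
#' @export
simulate_horizontal <- function(source, het_locus, cfg, replicate = 1L,
                                condition_on_success = FALSE,
                                sample_id = NULL) {
  stopifnot(inherits(source, "viral_population"),
            inherits(cfg, "simulation_config"))
  het_locus <- match.arg(het_locus, VALID_LOCI)
  if (is.null(sample_id)) {
    sample_id <- paste0(source$sample_id, "_", het_locus, "_R", replicate)
  }
  with_seed(child_seed(cfg$seed,
                       paste0("horizontal:", source$sample_id, ":", het_locus),
                       replicate), {
    success <- condition_on_success ||
      runif(1L) < cfg$vic_success[[het_locus]]
    if (!success) {
      return(structure(
        list(success = FALSE, k = NA_integer_,
             founder_sequences = character(0), recipient = NULL),
        class = "transmission_outcome"
      ))
    }
    k <- if (!is.null(cfg$founder_k)) cfg$founder_k
         else ztpois(cfg$founder_lambda_by_locus[[het_locus]])
    ex <- expand_founders(source, k, cfg, make_ref_proxy(source), sample_id,
                          role = "recipient")
    structure(
      list(success = TRUE, k = k,
           founder_sequences = ex$founder_sequences, recipient = ex$pop),
      class = "transmission_outcome"
    )
  })
}

#' Emit noisy sequencing reads from a population
#'
#' Each haplotype is emitted with its read multiplicity and every base is
#' flipped independently with probability `error_rate`. Deterministic per
#' seed and replicate; exactly `total_reads` reads are emitted.
#'
#' @param pop A [viral_population()].
#' @param cfg A [simulation_config()].
#' @param replicate Replicate index.
#' @return data.frame with columns `sequence` and `count` (all 1).
#' @export
add_sequencing_noise <- function(pop, cfg, replicate = 1L) {
  stopifnot(inherits(pop, "viral_population"),
            inherits(cfg, "simulation_config"))
  with_seed(child_seed(cfg$seed, paste0("noise:", pop$sample_id), replicate), {
    reads <- rep(pop$haplotypes$sequence, pop$haplotypes$read_count)
    if (cfg$error_rate > 0) {
      lens <- nchar(reads)
      n_err <- rbinom(length(reads), lens, cfg$error_rate)
      for (i in which(n_err > 0L)) {
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        pos <- sample.int(lens[i], n_err[i])
        for (p in pos) chars[p] <- sample(BASES[BASES != chars[p]], 1L)
        reads[i] <- paste(chars, collapse = "")
      }
    }
    data.frame(sequence = reads, count = 1L, stringsAsFactors = FALSE)
  })
}

#' Toy abundance-threshold denoiser
#'
#' A deliberately simple stand-in for a full amplicon-denoising pipeline,
#' used to clean the simulator's own sequencing noise: after collapsing,
#' variants with fewer than `min_count` reads are absorbed into their
#' nearest retained variant by Hamming distance (ties broken toward the
#' higher-count variant, then lexicographically). Low-count variants with
#' no equal-length retained variant are kept and flagged. If every variant
#' is below the threshold, only the most abundant is kept (flagged) and
#' absorbs all reads. Total read count is always conserved.
#'
#' @param reads data.frame with `sequence` and `count` columns (as from
#'   [add_sequencing_noise()]), or a character vector of reads.
#' @param min_count Abundance threshold (default 2); `min_count = 1` is the
#'   identity.
#' @param sample_id Sample id of the resulting population.
#' @return A [viral_population()] with attribute `denoise_flags`.
#' @export
denoise_reads <- function(reads, min_count = 2L, sample_id = "denoised") {
  if (is.data.frame(reads)) {
    pop <- collapse_reads(reads$sequence, reads$count, sample_id = sample_id)
  } else if (inherits(reads, "viral_population")) {
    pop <- reads
  } else {
    pop <- collapse_reads(reads, sample_id = sample_id)
  }
  seqs <- pop$haplotypes$sequence
  counts <- pop$haplotypes$read_count
  flags <- character(0)
  keep <- counts >= min_count
  if (!any(keep)) {
    flags <- c(flags, "all_below_threshold_kept_most_abundant")
    out <- viral_population(sample_id, seqs[1L], sum(counts),
                            role = pop$role)
    attr(out, "denoise_flags") <- flags
    return(out)
  }
  if (all(keep)) {
    attr(pop, "denoise_flags") <- flags
    return(pop)
  }
  kept_idx <- which(keep)       # already sorted: count desc, then sequence
  kept_len <- nchar(seqs[kept_idx])
  acc <- counts
  dropped <- logical(length(seqs))
  for (i in which(!keep)) {
    cands <- kept_idx[kept_len == nchar(seqs[i])]
    if (length(cands) == 0L) {
      flags <- c(flags, sprintf("unabsorbed_variant_%d", i))
      next
    }
    dists <- vapply(seqs[cands], hamming_distance, 0, b = seqs[i])
    best <- cands[which.min(dists)]   # first minimum = higher count / lex
    acc[best] <- acc[best] + acc[i]
    dropped[i] <- TRUE
  }
  sel <- !dropped
  out <- viral_population(sample_id, seqs[sel], acc[sel], role = pop$role)
  attr(out, "denoise_flags") <- flags
  out
}
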