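# The quasispecies simulator: reference layout, parental populations,
# founder-sampled transmission, sequencing noise and the toy denoiser.

test_that("the generated reference is deterministic with stop-free, codon-sized ORFs", {
  cfg <- small_study_config()
  a <- make_reference(cfg)
  b <- make_reference(cfg)
  expect_identical(a$ref$sequence, b$ref$sequence)
  expect_identical(a$ref$regions, b$ref$regions)

  expect_equal(nrow(a$ref$regions), 2L)
  lens <- a$ref$regions$end - a$ref$regions$start + 1L
  expect_true(all(lens %% 3L == 0L))

  # no internal stop codons in either ORF
  for (ri in 1:2) {
    r <- a$ref$regions[ri, ]
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(a$ref$sequence, r$start, r$end)
    )))
    expect_false(grepl("*", aa, fixed = TRUE))
  }

  # the embedded primer sites are located by the degenerate study primers
  expect_equal(a$amplicon$start, 1L)
  expect_equal(a$amplicon$end, nchar(a$ref$sequence))
})

test_that("parental populations honour the configured spectrum and depth", {
  cfg <- small_study_config()
  mr <- make_reference(cfg)
  p1 <- make_parental_population(mr$ref, cfg, sample_id = "P")
  p2 <- make_parental_population(mr$ref, cfg, sample_id = "P")
  expect_identical(p1$haplotypes, p2$haplotypes)   # same seed, same stream

  expect_equal(nrow(p1$haplotypes), cfg$n_variants)
  expect_equal(p1$total_reads, cfg$expansion_reads)
  expect_true(all(p1$haplotypes$read_count >= 1L))
  expect_true(mr$ref$sequence %in% p1$haplotypes$sequence)

  # a single-variant population is monomorphic with pi = 0
  cfg1 <- small_study_config(n_variants = 1L)
  mono <- make_parental_population(make_reference(cfg1)$ref, cfg1,
                                   sample_id = "M")
  expect_equal(nrow(mono$haplotypes), 1L)
  expect_equal(as.numeric(neis_h(mono)), 0)

  cfg_bad <- small_study_config(n_variants = 50L, expansion_reads = 40L)
  expect_error(
    make_parental_population(make_reference(cfg_bad)$ref, cfg_bad),
    "expansion_reads"
  )
})

test_that("parental SNPs never create premature stop codons", {
  cfg <- small_study_config(seed = 21L, n_variants = 20L,
                            snps_per_variant = 4)
  mr <- make_reference(cfg)
  pop <- make_parental_population(mr$ref, cfg, sample_id = "P")
  for (s in pop$haplotypes$sequence) {
    for (ri in 1:2) {
      r <- mr$ref$regions[ri, ]
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(
        substr(s, r$start, r$end)
      )))
      expect_false(grepl("*", aa, fixed = TRUE))
    }
  }
})

test_that("a single founder with no post-mutation yields a monomorphic spore population", {
  cfg <- small_study_config(post_mutation_rate = 0)
  mr <- make_reference(cfg)
  parent <- attach_reference(
    make_parental_population(mr$ref, cfg, sample_id = "P"), mr$ref
  )
  out <- simulate_vertical(parent, cfg, replicate = 1L, k = 1L)
  expect_true(out$success)
  expect_length(out$founder_sequences, 1L)
  expect_equal(nrow(out$recipient$haplotypes), 1L)
  expect_equal(out$recipient$total_reads, cfg$expansion_reads)
  expect_equal(as.numeric(neis_h(out$recipient)), 0)
  expect_equal(population_pi(out$recipient, mr$ref, mr$amplicon)$pi, 0)
})

test_that("huge founder counts recover the source frequencies", {
  cfg <- small_study_config(post_mutation_rate = 0,
                            expansion_reads = 10000L, n_variants = 6L)
  mr <- make_reference(cfg)
  parent <- attach_reference(
    make_parental_population(mr$ref, cfg, sample_id = "P"), mr$ref
  )
  out <- simulate_vertical(parent, cfg, replicate = 3L, k = 1000000L)
  src_f <- setNames(variant_frequencies(parent), parent$haplotypes$sequence)
  rec_f <- setNames(variant_frequencies(out$recipient),
                    out$recipient$haplotypes$sequence)
  tv <- 0.5 * sum(abs(src_f - rec_f[names(src_f)]), na.rm = TRUE) +
    0.5 * sum(rec_f[!names(rec_f) %in% names(src_f)])
  expect_lt(tv, 0.01)
})

test_that("transmission outcomes are reproducible per seed and replicate", {
  cfg <- small_study_config()
  mr <- make_reference(cfg)
  parent <- attach_reference(
    make_parental_population(mr$ref, cfg, sample_id = "P"), mr$ref
  )
  a <- simulate_vertical(parent, cfg, replicate = 2L)
  b <- simulate_vertical(parent, cfg, replicate = 2L)
  expect_identical(a$recipient$haplotypes, b$recipient$haplotypes)
  c <- simulate_vertical(parent, cfg, replicate = 3L)
  expect_false(identical(a$recipient$haplotypes, c$recipient$haplotypes))
})

test_that("horizontal transmission is gated by the heteroallelic locus", {
  cfg <- small_study_config()
  mr <- make_reference(cfg)
  donor <- attach_reference(
    make_parental_population(mr$ref, cfg, sample_id = "D", role = "donor"),
    mr$ref
  )
  # compatible pairing always transmits
  out <- simulate_horizontal(donor, "none", cfg, replicate = 1L)
  expect_true(out$success)
  expect_s3_class(out$recipient, "viral_population")

  # an impassable barrier never transmits
  cfg0 <- small_study_config(vic_success = c(none = 1, vic2 = 0,
                                             vic3 = 0.17, vic4 = 0.97))
  fail <- simulate_horizontal(donor, "vic2", cfg0, replicate = 1L)
  expect_false(fail$success)
  expect_null(fail$recipient)

  expect_error(simulate_horizontal(donor, "vic9", cfg), "arg")

  # empirical success fraction tracks the configured probability
  hits <- vapply(1:400, function(r) {
    simulate_horizontal(donor, "vic4", cfg, replicate = r)$success
  }, TRUE)
  phat <- mean(hits)
  se <- sqrt(0.97 * 0.03 / 400)
  expect_lt(abs(phat - 0.97), 4 * se + 1e-9)
})

test_that("sequencing noise emits exactly the population's reads", {
  cfg <- small_study_config(expansion_reads = 60L, n_variants = 4L)
  mr <- make_reference(cfg)
  pop <- make_parental_population(mr$ref, cfg, sample_id = "P")

  clean_cfg <- small_study_config(expansion_reads = 60L, n_variants = 4L,
                                  error_rate = 0)
  clean <- add_sequencing_noise(pop, clean_cfg)
  expect_equal(nrow(clean), pop$total_reads)
  expect_identical(sort(clean$sequence),
                   sort(rep(pop$haplotypes$sequence,
                            pop$haplotypes$read_count)))

  noisy <- add_sequencing_noise(pop, cfg)
  expect_equal(nrow(noisy), pop$total_reads)
  # collapsing the clean reads recovers the population exactly
  back <- collapse_reads(clean$sequence, clean$count)
  expect_identical(back$haplotypes$sequence, pop$haplotypes$sequence)
  expect_identical(back$haplotypes$read_count, pop$haplotypes$read_count)
})

test_that("the toy denoiser reassigns rare variants to their nearest neighbour", {
  # noiseless collapsed input with all counts above threshold: identity
  pop <- collapse_reads(c("AAAA", "CCCC"), c(500L, 400L))
  out <- denoise_reads(pop, min_count = 2L)
  expect_identical(out$haplotypes$sequence, pop$haplotypes$sequence)

  # a singleton one mismatch from a dominant variant is absorbed
  reads <- data.frame(sequence = c(rep("AAAA", 500L), "AAAT"), count = 1L)
  dn <- denoise_reads(reads, min_count = 2L)
  expect_equal(nrow(dn$haplotypes), 1L)
  expect_equal(dn$total_reads, 501L)

  # min_count = 1 is the identity
  id <- denoise_reads(reads, min_count = 1L)
  expect_equal(nrow(id$haplotypes), 2L)

  # everything below threshold: keep the single most abundant, flagged
  rare <- data.frame(sequence = c("AAAA", "CCCC", "GGGG"), count = 1L)
  kept <- denoise_reads(rare, min_count = 5L)
  expect_equal(nrow(kept$haplotypes), 1L)
  expect_equal(kept$total_reads, 3L)
  expect_match(attr(kept, "denoise_flags"), "most_abundant", all = FALSE)

  # nearest retained neighbour wins; exact ties go to the higher count
  reads2 <- data.frame(
    sequence = c(rep("AAAA", 10L), rep("AATT", 5L), "AATG", "AATA"),
    count = 1L
  )
  dn2 <- denoise_reads(reads2, min_count = 2L)
  # AATG: distance 2 from AAAA, 1 from AATT -> absorbed by AATT
  expect_equal(
    dn2$haplotypes$read_count[dn2$haplotypes$sequence == "AATT"], 6L
  )
  # AATA: distance 1 from both -> tie broken toward the more abundant AAAA
  expect_equal(
    dn2$haplotypes$read_count[dn2$haplotypes$sequence == "AAAA"], 11L
  )
})

test_that("noiseless simulate-collapse round trip reproduces the generator metrics", {
  cfg <- small_study_config(seed = 13L, error_rate = 0)
  mr <- make_reference(cfg)
  pop <- make_parental_population(mr$ref, cfg, sample_id = "P")
  reads <- add_sequencing_noise(pop, cfg)
  back <- collapse_reads(reads$sequence, reads$count, sample_id = "P")
  expect_equal(as.numeric(neis_h(back)), as.numeric(neis_h(pop)),
               tolerance = 1e-12)
  expect_equal(population_pi(back, mr$ref, mr$amplicon)$pi,
               population_pi(pop, mr$ref, mr$amplicon)$pi,
               tolerance = 1e-12)
})

test_that("expected shared-variant fraction grows with the founder count", {
  cfg <- small_study_config(seed = 29L, post_mutation_rate = 0,
                            n_variants = 30L, expansion_reads = 600L)
  mr <- make_reference(cfg)
  parent <- attach_reference(
    make_parental_population(mr$ref, cfg, sample_id = "P"), mr$ref
  )
  mean_shared <- function(k) {
    mean(vapply(1:60, function(r) {
      out <- simulate_vertical(parent, cfg, replicate = r, k = k)
      shared_variants(parent, out$recipient)$frac_of_source
    }, 0))
  }
  s1 <- mean_shared(1L)
  s5 <- mean_shared(5L)
  s50 <- mean_shared(50L)
  expect_lt(s1, s5)
  expect_lt(s5, s50)
})
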