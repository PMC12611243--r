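# Amplicon location, pairwise alignment, mutation calling, effect
# annotation and consensus construction.

test_that("IUPAC primer matching finds the amplicon and degenerate bases behave", {
  # Y matches C or T; R matches A or G
  pad <- function(...) paste0(...)
  fwd_site <- "ATCCGGAGAAAGTGATTTGC"          # Y->C, R->A expansion
  rev_site_rc <- "CCTCGCAGCTACATCAACAAG"      # revcomp of a Y/R expansion
  ref <- reference_genome("r", pad(strrep("ACGT", 25L), fwd_site,
                                   strrep("GATC", 30L), rev_site_rc,
                                   strrep("TTAA", 10L)))
  amp <- find_amplicon(ref, "ATCYGGAGAARGTGATTTGC", "YTTRTTGATGTAGCTGCGAGG")
  expect_equal(amp$start, 101L)
  expect_equal(amp$end, 100L + 20L + 120L + 21L)

  # no expansion present
  ref2 <- reference_genome("r2", strrep("ACGT", 50L))
  expect_error(find_amplicon(ref2, "ATCYGGAGAARGTGATTTGC",
                             "YTTRTTGATGTAGCTGCGAGG"), "no amplicon")

  # Y matches C and T but not A
  refC <- reference_genome("rc", "AAAAGCCTTTTTTGATC")
  ampC <- find_amplicon(refC, "GYC", "GATC")
  expect_equal(c(ampC$start, ampC$end), c(5L, 17L))
  refT <- reference_genome("rt", "AAAAGTCTTTTTTGATC")
  expect_equal(find_amplicon(refT, "GYC", "GATC")$start, 5L)
  refA <- reference_genome("ra", "AAAAGACTTTTTTGATC")
  expect_error(find_amplicon(refA, "GYC", "GATC"), "no amplicon")

  # ambiguous double match
  ref3 <- reference_genome("r3", paste0("AACCGGTT", "AACCGGTT"))
  expect_error(find_amplicon(ref3, "AACC", "AACC"), "ambiguous")
})

test_that("global alignment handles identity, substitutions and long deletions", {
  region <- strrep("ACGTTGCA", 10L)   # 80 nt

  ident <- align_haplotype(region, region)
  expect_equal(ident$aligned_hap, region)
  expect_equal(ident$score, 2 * nchar(region))

  sub <- with_snps(region, 35L, "A")   # a G in the repeat becomes A
  aln <- align_haplotype(sub, region)
  expect_false(grepl("-", aln$aligned_hap, fixed = TRUE))
  expect_equal(aln$score, 2 * 79 - 4)

  # one contiguous internal deletion stays one gap run
  del <- paste0(substr(region, 1L, 30L), substr(region, 40L, 80L))
  aln2 <- align_haplotype(del, region)
  runs <- rle(strsplit(aln2$aligned_hap, "", fixed = TRUE)[[1L]] == "-")
  expect_equal(sum(runs$values), 1L)
  expect_equal(runs$lengths[runs$values], 9L)
  # ungap round trip
  expect_equal(gsub("-", "", aln2$aligned_hap, fixed = TRUE), del)
  expect_equal(gsub("-", "", aln2$aligned_ref, fixed = TRUE), region)
})

test_that("alignment scores agree with a textbook affine-gap DP oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(8:16, 1L)
    a <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    # perturb a into b: substitutions and a possible indel
    b <- a
    for (k in seq_len(sample(0:2, 1L))) {
      p <- sample(nchar(b), 1L)
      substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1L)
    }
    if (runif(1) < 0.5 && nchar(b) > 6L) {
      cut <- sample(2:(nchar(b) - 3L), 1L)
      b <- paste0(substr(b, 1L, cut - 1L), substr(b, cut + 2L, nchar(b)))
    }
    got <- align_haplotype(b, a)
    expect_equal(got$score, affine_score_oracle(b, a), tolerance = 1e-9)
  }
})

test_that("a 237-nt contiguous deletion aligns as a single gap at full length", {
  set.seed(5)
  region <- paste(sample(c("A", "C", "G", "T"), 1200L, replace = TRUE),
                  collapse = "")
  hap <- paste0(substr(region, 1L, 500L), substr(region, 738L, 1200L))
  aln <- align_haplotype(hap, region)
  runs <- rle(strsplit(aln$aligned_hap, "", fixed = TRUE)[[1L]] == "-")
  expect_equal(sum(runs$lengths[runs$values]), 237L)
  expect_equal(sum(runs$values), 1L)
})

test_that("mutation calling aggregates haplotype frequencies per change", {
  ref <- toy_reference()
  amp <- toy_amplicon(ref)

  # monomorphic population identical to the reference
  mono <- viral_population("m", ref$sequence, 10L)
  expect_equal(nrow(call_mutations(mono, ref, amp)), 0L)

  # one haplotype at frequency 0.25 with one substitution
  alt <- with_snps(ref$sequence, 15L, "T")   # ORFA codon 2, AAA -> AAT
  pop <- viral_population("p", c(ref$sequence, alt), c(3L, 1L))
  muts <- call_mutations(pop, ref, amp)
  expect_equal(nrow(muts), 1L)
  expect_equal(muts$position, 15L)
  expect_equal(muts$frequency, 0.25)
  expect_equal(muts$kind, "SNP")

  # two haplotypes sharing the same substitution: frequencies add
  alt2 <- with_snps(alt, 55L, "G")
  pop2 <- viral_population("q", c(ref$sequence, alt, alt2), c(5L, 3L, 2L))
  muts2 <- call_mutations(pop2, ref, amp)
  shared <- muts2[muts2$position == 15L, ]
  expect_equal(shared$frequency, 0.5)
  expect_equal(nrow(muts2), 2L)
})

test_that("indels are left-aligned in homopolymer runs and VCF-anchored", {
  # reference with an A4 homopolymer: deletion of any one A left-aligns
  seq <- paste0("GGCC", "AAAA", "TTGG")
  ref <- reference_genome("hp", seq)
  amp <- amplicon_region(1L, nchar(seq))
  hap <- paste0("GGCC", "AAA", "TTGG")   # one A deleted
  pop <- viral_population("d", c(seq, hap), c(1L, 1L))
  muts <- call_mutations(pop, ref, amp)
  expect_equal(nrow(muts), 1L)
  expect_equal(muts$kind, "deletion")
  expect_equal(muts$position, 4L)         # anchored on the C before the run
  expect_equal(muts$ref_allele, "CA")
  expect_equal(muts$alt_allele, "C")

  # insertion into the same run left-aligns to the same anchor
  hap_ins <- paste0("GGCC", "AAAAA", "TTGG")
  pop_ins <- viral_population("i", c(seq, hap_ins), c(1L, 1L))
  mi <- call_mutations(pop_ins, ref, amp)
  expect_equal(mi$kind, "insertion")
  expect_equal(mi$position, 4L)
  expect_equal(mi$ref_allele, "C")
  expect_equal(mi$alt_allele, "CA")
})

test_that("effect annotation follows codon translation and indel length", {
  ref <- toy_reference()
  # ORFA codon 5 is TTT at 22-24; third-position T->C is synonymous
  snp <- data.frame(position = 24L, ref_allele = "T", alt_allele = "C",
                    kind = "SNP", stringsAsFactors = FALSE)
  expect_equal(annotate_effect(snp, ref)$effect, "synonymous")

  # first-position T->C gives CTT (Leu): missense
  mis <- data.frame(position = 22L, ref_allele = "T", alt_allele = "C",
                    kind = "SNP", stringsAsFactors = FALSE)
  expect_equal(annotate_effect(mis, ref)$effect, "missense")

  # codon 2 AAA -> TAA: nonsense
  non <- data.frame(position = 13L, ref_allele = "A", alt_allele = "T",
                    kind = "SNP", stringsAsFactors = FALSE)
  expect_equal(annotate_effect(non, ref)$effect, "nonsense")

  # SNP in the 5' noncoding region
  nc <- data.frame(position = 3L, ref_allele = "T", alt_allele = "C",
                   kind = "SNP", stringsAsFactors = FALSE)
  expect_equal(annotate_effect(nc, ref)$effect, "noncoding")

  # 1-nt deletion inside ORFA: frameshift (anchored at 12, deleting 13)
  fs <- data.frame(position = 12L, ref_allele = "GA", alt_allele = "G",
                   kind = "deletion", stringsAsFactors = FALSE)
  got <- annotate_effect(fs, ref)
  expect_equal(got$effect, "frameshift")
  expect_equal(got$region, "ORFA")

  # 9-nt codon-aligned deletion inside ORFA: inframe
  del9 <- data.frame(position = 12L,
                     ref_allele = substr(ref$sequence, 12L, 21L),
                     alt_allele = substr(ref$sequence, 12L, 12L),
                     kind = "deletion", stringsAsFactors = FALSE)
  expect_equal(annotate_effect(del9, ref)$effect, "inframe_deletion")

  # 3-nt insertion inside ORFB: inframe
  ins <- data.frame(position = 45L, ref_allele = "G",
                    alt_allele = "GACT", kind = "insertion",
                    stringsAsFactors = FALSE)
  expect_equal(annotate_effect(ins, ref)$effect, "inframe_insertion")
})

test_that("mutations spanning a region boundary are majority-classified and flagged", {
  ref <- toy_reference()
  # deletion anchored at 38, removing 39-44: 1 nt ORFA + 3 spacer + 2 ORFB
  del <- data.frame(position = 38L,
                    ref_allele = substr(ref$sequence, 38L, 44L),
                    alt_allele = substr(ref$sequence, 38L, 38L),
                    kind = "deletion", stringsAsFactors = FALSE)
  got <- annotate_effect(del, ref)
  expect_true(got$boundary_flag)
  expect_equal(got$region, "noncoding")  # the 3-nt spacer is the plurality
})

test_that("consensus applies strict-majority mutations on the backbone", {
  ref <- toy_reference()
  expect_equal(build_consensus(ref, NULL), ref$sequence)

  muts <- data.frame(
    position = c(15L, 20L), ref_allele = c("A", "G"),
    alt_allele = c("T", "A"), kind = "SNP",
    frequency = c(0.8, 0.5), stringsAsFactors = FALSE
  )
  cons <- build_consensus(ref, muts)
  expect_equal(substr(cons, 15L, 15L), "T")    # 0.8 > 0.5 applied
  expect_equal(substr(cons, 20L, 20L), "G")    # exactly 0.5 keeps reference

  # a majority deletion shortens the consensus
  del <- data.frame(position = 12L,
                    ref_allele = substr(ref$sequence, 12L, 21L),
                    alt_allele = substr(ref$sequence, 12L, 12L),
                    kind = "deletion", frequency = 0.9,
                    stringsAsFactors = FALSE)
  expect_equal(nchar(build_consensus(ref, del)), nchar(ref$sequence) - 9L)

  # overlapping above-threshold mutations are inconsistent
  bad <- rbind(del, data.frame(position = 15L, ref_allele = "A",
                               alt_allele = "G", kind = "SNP",
                               frequency = 0.9, stringsAsFactors = FALSE))
  expect_error(build_consensus(ref, bad), "overlap")
})

test_that("the VCF writer emits well-formed v4.2 site records", {
  ref <- toy_reference()
  alt <- with_snps(ref$sequence, 15L, "T")
  pop <- viral_population("v", c(ref$sequence, alt), c(3L, 1L))
  muts <- call_mutations(pop, ref, toy_amplicon(ref))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(muts, ref$id, path)
  lines <- readLines(path)
  expect_equal(lines[1L], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  fields <- strsplit(body, "\t")[[1L]]
  expect_length(fields, 8L)
  expect_equal(fields[2L], "15")
  expect_match(fields[8L], "AF=0\\.25")
})
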