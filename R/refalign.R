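# Locating the amplicon on the reference, aligning haplotypes to it,
# calling intra-host mutations with aggregate frequencies, annotating
# mutational effects (SnpEff-style categories) and building consensus
# sequences on the reference backbone.

EFFECT_LEVELS <- c("synonymous", "missense", "nonsense", "frameshift",
                   "inframe_deletion", "inframe_insertion", "noncoding")

#' Construct an amplicon region
#'
#' @param start,end 1-based inclusive reference coordinates, `start < end`.
#' @param fwd_primer,rev_primer Optional IUPAC primer strings (the reverse
#'   primer in primer orientation).
#' @return Object of class `amplicon_region`.
#' @export
amplicon_region <- function(start, end, fwd_primer = NA_character_,
                            rev_primer = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end) {
    stop("amplicon needs start < end")
  }
  structure(
    list(start = start, end = end,
         fwd_primer = fwd_primer, rev_primer = rev_primer),
    class = "amplicon_region"
  )
}

#' Locate an amplicon on a reference via its primer pair
#'
#' Matches the forward primer on the plus strand and the reverse primer as
#' its reverse complement, both under IUPAC-superset semantics (e.g. primer
#' `Y` matches reference `C` or `T`). The amplicon runs from the start of
#' the forward-primer match to the end of the reverse-complement match,
#' primers included. Exactly one match per primer is required.
#'
#' @param ref A [reference_genome()].
#' @param fwd,rev IUPAC primer strings; `rev` is given in primer
#'   orientation.
#' @return An [amplicon_region()].
#' @export
find_amplicon <- function(ref, fwd, rev) {
  stopifnot(inherits(ref, "reference_genome"))
  if (!nzchar(fwd) || !nzchar(rev)) stop("primers must be non-empty")
  subject <- Biostrings::DNAString(ref$sequence)
  fwd_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subject,
                                       fixed = FALSE)
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  rev_hits <- Biostrings::matchPattern(rev_rc, subject, fixed = FALSE)
  if (length(fwd_hits) == 0L || length(rev_hits) == 0L) {
    stop("primer pair does not match the reference (no amplicon found)")
  }
  if (length(fwd_hits) > 1L || length(rev_hits) > 1L) {
    stop("primer match is ambiguous (multiple candidate amplicons)")
  }
  s <- Biostrings::start(fwd_hits)[1L]
  e <- Biostrings::end(rev_hits)[1L]
  if (s >= e) stop("primer matches are inverted; no forward amplicon")
  amplicon_region(s, e, fwd_primer = fwd, rev_primer = rev)
}

#' Global pairwise alignment of a haplotype against the amplicon sequence
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap costs
#' (defaults: match +2, mismatch -4, gap open -12, gap extend -1 per
#' position), computed with [Biostrings::pairwiseAlignment()]. The gap
#' costs keep one long contiguous gap cheaper than many short ones, which
#' suits amplicon haplotypes carrying long deletions. Equal-length
#' sequence pairs with at most 2% mismatches take a gapless fast path
#' (equal length implies no net indel; scattered substitutions then make
#' the gapless alignment optimal under these scores).
#'
#' @param hap Haplotype sequence (string) or a one-row of
#'   `viral_population` haplotypes.
#' @param region_seq Reference amplicon sequence (string).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return List of class `pairwise_alignment` with `aligned_ref`,
#'   `aligned_hap` (equal-length gapped strings) and `score`. Ungapping
#'   either string reproduces the input exactly.
#' @export
align_haplotype <- function(hap, region_seq, match = 2, mismatch = -4,
                            gap_open = -12, gap_extend = -1) {
  hap <- toupper(as.character(hap))
  region_seq <- toupper(as.character(region_seq))
  if (!nzchar(hap) || !nzchar(region_seq)) stop("empty sequence")
  if (nchar(hap) > 20000L || nchar(region_seq) > 20000L) {
    stop("sequence longer than 20 kb; this aligner is desk-scale only")
  }
  if (nchar(hap) == nchar(region_seq)) {
    d <- hamming_distance(hap, region_seq)
    if (d <= 0.02 * nchar(hap)) {
      return(structure(
        list(aligned_ref = region_seq, aligned_hap = hap,
             score = match * (nchar(hap) - d) + mismatch * d),
        class = "pairwise_alignment"
      ))
    }
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(hap),
    subject = Biostrings::DNAString(region_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend)
  )
  structure(
    list(
      aligned_ref = as.character(Biostrings::alignedSubject(aln)),
      aligned_hap = as.character(Biostrings::alignedPattern(aln)),
      score = Biostrings::score(aln)
    ),
    class = "pairwise_alignment"
  )
}

# Project an alignment onto reference coordinates: for each reference
# position of the region, the haplotype character ("-" when deleted), plus
# the list of insertions (position = reference coordinate of the next
# reference base, i.e. the base the insertion precedes).
project_alignment <- function(aln) {
  r <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1L]]
  h <- strsplit(aln$aligned_hap, "", fixed = TRUE)[[1L]]
  ref_gap <- r == "-"
  proj <- h[!ref_gap]
  insertions <- list()
  if (any(ref_gap)) {
    runs <- rle(ref_gap)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    refpos_at <- cumsum(!ref_gap)   # ref coord (within region) of each column
    for (k in which(runs$values)) {
      cols <- starts[k]:ends[k]
      before <- refpos_at[starts[k]]   # ref bases consumed before the run
      insertions[[length(insertions) + 1L]] <- list(
        at = before + 1L,               # insertion precedes this ref position
        seq = paste(h[cols], collapse = "")
      )
    }
  }
  list(projected = paste(proj, collapse = ""), insertions = insertions)
}

# Left-align a deletion of k bases starting at region position p (1-based):
# deleting p..p+k-1 equals deleting p-1..p+k-2 whenever ref[p+k-1]==ref[p-1].
left_align_deletion <- function(region_chars, p, k) {
  while (p > 1L && region_chars[p + k - 1L] == region_chars[p - 1L]) {
    p <- p - 1L
  }
  p
}

# Left-align an insertion of seq placed before region position p.
left_align_insertion <- function(region_chars, p, seq) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  k <- length(s)
  while (p > 1L && s[k] == region_chars[p - 1L]) {
    s <- c(region_chars[p - 1L], s[-k])
    p <- p - 1L
  }
  list(at = p, seq = paste(s, collapse = ""))
}

# Extract the (position, ref, alt, kind) differences of one aligned
# haplotype, VCF-style: indels left-aligned and anchored on the previous
# reference base; positions are region-relative (1-based).
haplotype_diffs <- function(aln, region_chars) {
  pr <- project_alignment(aln)
  p <- strsplit(pr$projected, "", fixed = TRUE)[[1L]]
  stopifnot(length(p) == length(region_chars))
  out <- list()
  # SNPs
  snp <- which(p != region_chars & p != "-")
  for (i in snp) {
    out[[length(out) + 1L]] <- list(pos = i, ref = region_chars[i],
                                    alt = p[i], kind = "SNP")
  }
  # deletions: runs of "-" in the projected haplotype
  del <- p == "-"
  if (any(del)) {
    runs <- rle(del)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      dp <- left_align_deletion(region_chars, starts[k], runs$lengths[k])
      len <- runs$lengths[k]
      if (dp > 1L) {
        anchor <- dp - 1L
        ref_al <- paste(region_chars[anchor:(dp + len - 1L)], collapse = "")
        alt_al <- region_chars[anchor]
        pos <- anchor
      } else {
        # deletion at the very start: right-anchor on the following base
        anchor <- dp + len
        ref_al <- paste(region_chars[dp:anchor], collapse = "")
        alt_al <- region_chars[anchor]
        pos <- dp
      }
      out[[length(out) + 1L]] <- list(pos = pos, ref = ref_al, alt = alt_al,
                                      kind = "deletion")
    }
  }
  # insertions
  for (ins in pr$insertions) {
    la <- left_align_insertion(region_chars, ins$at, ins$seq)
    if (la$at > 1L) {
      anchor <- la$at - 1L
      out[[length(out) + 1L]] <- list(
        pos = anchor, ref = region_chars[anchor],
        alt = paste0(region_chars[anchor], la$seq), kind = "insertion"
      )
    } else {
      out[[length(out) + 1L]] <- list(
        pos = 1L, ref = region_chars[1L],
        alt = paste0(la$seq, region_chars[1L]), kind = "insertion"
      )
    }
  }
  out
}

# Align every haplotype of a population to the amplicon region once;
# returns projections (ref-coordinate haplotype strings), per-haplotype
# diff lists and frequencies. Shared by call_mutations and population_pi.
align_population <- function(pop, ref, amplicon, ...) {
  stopifnot(inherits(pop, "viral_population"),
            inherits(ref, "reference_genome"),
            inherits(amplicon, "amplicon_region"))
  region_seq <- substr(ref$sequence, amplicon$start, amplicon$end)
  region_chars <- strsplit(region_seq, "", fixed = TRUE)[[1L]]
  alns <- lapply(pop$haplotypes$sequence, align_haplotype, region_seq, ...)
  projections <- vapply(alns, function(a) project_alignment(a)$projected, "")
  diffs <- lapply(alns, haplotype_diffs, region_chars)
  list(
    region_seq = region_seq, region_chars = region_chars,
    alignments = alns, projections = projections, diffs = diffs,
    frequencies = variant_frequencies(pop)
  )
}

#' Call intra-host mutations of a population against the reference
#'
#' Every haplotype is globally aligned to the amplicon sequence; a
#' mutation's frequency is the sum of the frequencies of all haplotypes
#' carrying the identical ref-to-alt change at that position. Indels are
#' left-aligned within homopolymer runs and anchored VCF-style on the
#' previous reference base. Positions are reported on the reference
#' coordinate system (not amplicon-relative).
#'
#' @param pop A [viral_population()].
#' @param ref A [reference_genome()].
#' @param amplicon An [amplicon_region()].
#' @param aligned Optional precomputed result of the internal population
#'   alignment (used by the pipeline to avoid re-aligning).
#' @return data.frame with columns `position`, `ref_allele`, `alt_allele`,
#'   `kind` (`SNP`/`insertion`/`deletion`), `frequency`, `region`,
#'   `effect`, `boundary_flag`; ordered by position. Zero rows for a
#'   population identical to the reference.
#' @export
call_mutations <- function(pop, ref, amplicon, aligned = NULL) {
  if (is.null(aligned)) aligned <- align_population(pop, ref, amplicon)
  freqs <- aligned$frequencies
  recs <- list()
  for (i in seq_along(aligned$diffs)) {
    for (d in aligned$diffs[[i]]) {
      key <- paste(d$pos, d$ref, d$alt, sep = "|")
      if (is.null(recs[[key]])) {
        recs[[key]] <- list(pos = d$pos, ref = d$ref, alt = d$alt,
                            kind = d$kind, freq = 0)
      }
      recs[[key]]$freq <- recs[[key]]$freq + freqs[i]
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(
      position = integer(), ref_allele = character(),
      alt_allele = character(), kind = character(), frequency = numeric(),
      region = character(), effect = character(), boundary_flag = logical(),
      stringsAsFactors = FALSE
    ))
  }
  out <- data.frame(
    position = vapply(recs, function(r) r$pos, 0L) + amplicon$start - 1L,
    ref_allele = vapply(recs, function(r) r$ref, ""),
    alt_allele = vapply(recs, function(r) r$alt, ""),
    kind = vapply(recs, function(r) r$kind, ""),
    frequency = pmin(1, vapply(recs, function(r) r$freq, 0)),
    stringsAsFactors = FALSE
  )
  ann <- annotate_effect(out, ref)
  out$region <- ann$region
  out$effect <- ann$effect
  out$boundary_flag <- ann$boundary_flag
  out <- out[order(out$position, out$ref_allele, out$alt_allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate the coding effect of mutations
#'
#' SnpEff-style categories: SNPs inside a CDS are classified by codon
#' translation as `synonymous`, `missense` or `nonsense` (stop gained);
#' indels inside a CDS are `frameshift` unless the inserted/deleted length
#' is a multiple of 3 (`inframe_insertion` / `inframe_deletion`); anything
#' outside the CDS regions is `noncoding`. A mutation spanning a CDS
#' boundary is classified by the majority-overlap region and flagged.
#'
#' @param mutations data.frame with `position`, `ref_allele`, `alt_allele`,
#'   `kind` (reference coordinates, VCF-anchored indels).
#' @param ref A [reference_genome()] carrying the coding regions.
#' @return data.frame with columns `region`, `effect`, `boundary_flag`
#'   aligned to the input rows.
#' @export
annotate_effect <- function(mutations, ref) {
  stopifnot(inherits(ref, "reference_genome"))
  n <- nrow(mutations)
  region <- character(n); effect <- character(n); flag <- logical(n)
  regions <- ref$regions
  for (i in seq_len(n)) {
    pos <- mutations$position[i]
    ra <- mutations$ref_allele[i]
    aa <- mutations$alt_allele[i]
    kind <- mutations$kind[i]
    # affected reference span: for anchored indels the anchor base is
    # unchanged, the event spans the bases after it
    if (kind == "SNP") {
      span <- c(pos, pos)
    } else if (kind == "deletion") {
      span <- c(pos + 1L, pos + nchar(ra) - 1L)
    } else {
      span <- c(pos, pos)   # insertion: point event between bases
    }
    ov <- region_overlap(span[1L], span[2L], regions)
    region[i] <- ov$name
    flag[i] <- ov$partial
    if (ov$name == "noncoding") {
      effect[i] <- "noncoding"
      next
    }
    if (kind == "SNP") {
      effect[i] <- classify_snp(pos, aa, ref, regions[regions$name == ov$name, ][1L, ])
    } else {
      indel_len <- abs(nchar(ra) - nchar(aa))
      if (indel_len %% 3L == 0L) {
        effect[i] <- if (kind == "deletion") "inframe_deletion" else "inframe_insertion"
      } else {
        effect[i] <- "frameshift"
      }
    }
  }
  data.frame(region = region, effect = effect, boundary_flag = flag,
             stringsAsFactors = FALSE)
}

# Majority-overlap region of a reference span; "noncoding" when no CDS
# overlaps more than any other source. partial = TRUE when the span is not
# fully contained in the winning region.
region_overlap <- function(s, e, regions) {
  if (nrow(regions) == 0L) return(list(name = "noncoding", partial = FALSE))
  ov <- pmax(0L, pmin(e, regions$end) - pmax(s, regions$start) + 1L)
  span_len <- e - s + 1L
  best <- which.max(ov)
  if (ov[best] == 0L) return(list(name = "noncoding", partial = FALSE))
  noncoding_len <- span_len - sum(ov)
  if (noncoding_len > max(ov)) {
    return(list(name = "noncoding", partial = TRUE))
  }
  list(name = regions$name[best], partial = ov[best] < span_len)
}

classify_snp <- function(pos, alt, ref, region) {
  cds_start <- region$start + region$frame_offset
  if (pos < cds_start) return("noncoding")   # bases before the frame offset
  idx <- pos - cds_start                      # 0-based within the frame
  codon_start <- cds_start + 3L * (idx %/% 3L)
  if (codon_start + 2L > region$end) return("noncoding")  # trailing partial codon
  codon <- substr(ref$sequence, codon_start, codon_start + 2L)
  within <- idx %% 3L + 1L
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  if (aa_alt == aa_ref) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Build a consensus sequence from the reference backbone and mutations
#'
#' Applies every mutation with frequency strictly greater than `threshold`
#' to the reference sequence (majority rule; a frequency of exactly the
#' threshold keeps the reference allele). Mutations are applied in
#' descending-position order so coordinates stay valid; two above-threshold
#' mutations overlapping the same reference bases make the consensus
#' inconsistent and raise an error.
#'
#' @param ref A [reference_genome()] (the backbone).
#' @param mutations data.frame as returned by [call_mutations()].
#' @param threshold Frequency threshold, default 0.5.
#' @return The consensus nucleotide string.
#' @export
build_consensus <- function(ref, mutations, threshold = 0.5) {
  stopifnot(inherits(ref, "reference_genome"))
  seq <- ref$sequence
  if (is.null(mutations) || nrow(mutations) == 0L) return(seq)
  keep <- mutations$frequency > threshold
  muts <- mutations[keep, , drop = FALSE]
  if (nrow(muts) == 0L) return(seq)
  ends <- muts$position + nchar(muts$ref_allele) - 1L
  ord <- order(muts$position)
  if (nrow(muts) > 1L &&
      any(muts$position[ord][-1L] <= ends[ord][-nrow(muts)])) {
    stop("two above-threshold mutations overlap; consensus is inconsistent")
  }
  for (i in order(muts$position, decreasing = TRUE)) {
    p <- muts$position[i]
    rl <- nchar(muts$ref_allele[i])
    stopifnot(substr(seq, p, p + rl - 1L) == muts$ref_allele[i])
    seq <- paste0(substr(seq, 1L, p - 1L), muts$alt_allele[i],
                  substr(seq, p + rl, nchar(seq)))
  }
  seq
}

#' Write mutation calls as a VCF v4.2 file
#'
#' One site record per mutation with INFO fields `AF` (aggregate
#' frequency), `EFF` (effect category), `REGION` and, for multi-sample
#' output, `SAMPLE`.
#'
#' @param mutations data.frame as returned by [call_mutations()],
#'   optionally with a `sample_id` column for pooled output.
#' @param ref_id Reference accession used as CHROM.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(mutations, ref_id, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=quasipop_%s", as.character(packageVersion("quasipop"))),
    sprintf("##contig=<ID=%s>", ref_id),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Aggregate variant frequency\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Mutational effect category\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Coding region\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Population sample id\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (!is.null(mutations) && nrow(mutations) > 0L) {
    info <- sprintf("AF=%.6g;EFF=%s;REGION=%s", mutations$frequency,
                    mutations$effect, mutations$region)
    if (!is.null(mutations$sample_id)) {
      info <- paste0(info, ";SAMPLE=", mutations$sample_id)
    }
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", ref_id,
                    mutations$position, mutations$ref_allele,
                    mutations$alt_allele, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
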