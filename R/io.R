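# Domain types and file ingest: reference genomes with coding annotations,
# count-annotated haplotype FASTA (USEARCH-style ";size=N" dialect), and the
# sample-pairing manifest that encodes a transmission study layout.

VALID_ROLES <- c("parental", "progeny", "donor", "recipient", "pooled")
VALID_LOCI <- c("none", "vic2", "vic3", "vic4")
VALID_SUBTYPES <- c("F1", "I")

#' Construct a reference genome
#'
#' A reference genome is the coordinate backbone for mutation calling and
#' diversity computation: an accession id, an uppercase A/C/G/T sequence and
#' an ordered set of non-overlapping coding regions (plus-strand CDS only;
#' CHV1 coding is single-stranded message sense). Everything outside the
#' annotated CDS regions is treated as noncoding.
#'
#' @param id Accession string (e.g. `"DQ861913"`).
#' @param sequence Nucleotide string; coerced to upper case and validated to
#'   contain only A/C/G/T.
#' @param regions `data.frame` with columns `name`, `start`, `end`,
#'   `frame_offset` (1-based inclusive coordinates; `frame_offset` in 0..2),
#'   or `NULL` for an unannotated (all-noncoding) genome.
#' @return An object of class `reference_genome`.
#' @export
#' @examples
#' ref <- reference_genome("toy", "ATGAAATTTGGGTAG",
#'   regions = data.frame(name = "ORFA", start = 1, end = 15, frame_offset = 0))
reference_genome <- function(id, sequence, regions = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("reference sequence must be non-empty")
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence contains non-A/C/G/T characters")
  }
  regions <- validate_regions(regions, nchar(sequence))
  structure(
    list(id = id, sequence = sequence, regions = regions),
    class = "reference_genome"
  )
}

validate_regions <- function(regions, seq_len) {
  if (is.null(regions) || nrow(as.data.frame(regions)) == 0L) {
    return(data.frame(
      name = character(), start = integer(), end = integer(),
      frame_offset = integer(), stringsAsFactors = FALSE
    ))
  }
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  needed <- c("name", "start", "end")
  if (!all(needed %in% names(regions))) {
    stop("regions need columns name, start, end")
  }
  if (is.null(regions$frame_offset)) regions$frame_offset <- 0L
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$frame_offset <- as.integer(regions$frame_offset)
  if (any(regions$start > regions$end)) {
    stop("coding region with start > end")
  }
  if (any(regions$start < 1L) || any(regions$end > seq_len)) {
    stop("coding region outside the reference sequence [1, ", seq_len, "]")
  }
  if (any(regions$frame_offset < 0L | regions$frame_offset > 2L)) {
    stop("frame_offset must be 0, 1 or 2")
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] <= regions$end[-nrow(regions)])) {
    stop("overlapping coding regions are not supported")
  }
  rownames(regions) <- NULL
  regions
}

#' Construct a viral population
#'
#' A viral population is one sample's set of collapsed viral variants
#' (unique haplotypes, i.e. pairwise Hamming distance > 0) with read counts.
#' Variant frequencies are derived from the counts and are the `x_i` of
#' every diversity metric. Haplotypes are stored sorted by descending read
#' count, ties broken by sequence (lexicographic), so populations have a
#' canonical, reproducible order.
#'
#' @param sample_id Sample identifier.
#' @param sequences Character vector of A/C/G/T haplotype sequences; must be
#'   pairwise distinct (use [collapse_reads()] to merge duplicates first).
#' @param read_counts Positive integer read counts, one per sequence.
#' @param ids Optional haplotype ids (defaults to `hap1`, `hap2`, ...
#'   assigned after sorting).
#' @param role One of `"parental"`, `"progeny"`, `"donor"`, `"recipient"`,
#'   `"pooled"`.
#' @param strain,subtype Optional strain label and viral subtype
#'   (`"F1"` or `"I"`).
#' @return An object of class `viral_population` with elements `sample_id`,
#'   `role`, `strain`, `subtype`, `haplotypes` (data.frame `id`, `sequence`,
#'   `read_count`) and `total_reads`.
#' @export
viral_population <- function(sample_id, sequences, read_counts, ids = NULL,
                             role = "pooled", strain = NA_character_,
                             subtype = NA_character_) {
  role <- match.arg(role, VALID_ROLES)
  if (!is.na(subtype)) subtype <- match.arg(subtype, VALID_SUBTYPES)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("a population needs at least one haplotype")
  if (any(!nzchar(sequences))) stop("empty haplotype sequence")
  if (any(grepl("[^ACGT]", sequences))) {
    stop("haplotype sequences must contain only A/C/G/T ",
         "(ambiguity codes are rejected: Hamming semantics must be exact)")
  }
  read_counts <- as.integer(read_counts)
  if (length(read_counts) != length(sequences)) {
    stop("read_counts must match sequences in length")
  }
  if (any(is.na(read_counts)) || any(read_counts < 1L)) {
    stop("read counts must be positive integers")
  }
  if (anyDuplicated(sequences)) {
    stop("identical sequences must be collapsed before construction ",
         "(see collapse_reads)")
  }
  ord <- order(-read_counts, sequences, method = "radix")
  sequences <- sequences[ord]
  read_counts <- read_counts[ord]
  if (is.null(ids)) {
    ids <- paste0("hap", seq_along(sequences))
  } else {
    ids <- as.character(ids)[ord]
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      role = role,
      strain = as.character(strain),
      subtype = as.character(subtype),
      haplotypes = data.frame(
        id = ids, sequence = sequences, read_count = read_counts,
        stringsAsFactors = FALSE
      ),
      total_reads = sum(read_counts)
    ),
    class = "viral_population"
  )
}

#' Variant frequencies of a population
#'
#' @param pop A [viral_population()].
#' @return Numeric vector of `read_count / total_reads`, in haplotype order;
#'   sums to 1.
#' @export
variant_frequencies <- function(pop) {
  stopifnot(inherits(pop, "viral_population"))
  pop$haplotypes$read_count / pop$total_reads
}

#' @export
print.viral_population <- function(x, ...) {
  cat(sprintf(
    "<viral_population> %s (%s): %d variants, %d reads\n",
    x$sample_id, x$role, nrow(x$haplotypes), x$total_reads
  ))
  top <- utils::head(x$haplotypes, 3L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %s  n=%d  f=%.4f  %s...\n", top$id[i], top$read_count[i],
                top$read_count[i] / x$total_reads,
                substr(top$sequence[i], 1, 24)))
  }
  invisible(x)
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %d nt, %d coding region(s)\n",
              x$id, nchar(x$sequence), nrow(x$regions)))
  invisible(x)
}

#' Read a count-annotated haplotype FASTA into a viral population
#'
#' Reads denoised amplicon haplotypes whose headers carry read counts in the
#' USEARCH-style dialect `id;size=N` (a record without a size tag counts as
#' one read). Identical sequences are merged with counts summed, so the
#' result always satisfies the no-duplicate invariant of
#' [viral_population()].
#'
#' @param path FASTA file path.
#' @param sample_id Sample id; defaults to the file name without extension.
#' @param role,strain,subtype Passed to [viral_population()].
#' @return A [viral_population()], haplotypes sorted by descending count.
#' @export
read_haplotype_fasta <- function(path, sample_id = NULL, role = "pooled",
                                 strain = NA_character_,
                                 subtype = NA_character_) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  headers <- names(seqs)
  ids <- headers
  counts <- rep(1L, length(seqs))
  has_size <- grepl(";size=", headers, fixed = TRUE)
  if (any(has_size)) {
    m <- regmatches(headers, regexec("^(.*?);size=([^;]*)", headers))
    for (i in which(has_size)) {
      tag <- m[[i]][3L]
      if (!grepl("^[0-9]+$", tag) || as.numeric(tag) < 1) {
        stop("malformed or non-positive size tag in header: ", headers[i])
      }
      counts[i] <- as.integer(tag)
      ids[i] <- m[[i]][2L]
    }
  }
  sequences <- toupper(as.character(seqs))
  names(sequences) <- NULL
  if (any(grepl("[^ACGT]", sequences))) {
    stop("non-A/C/G/T characters in ", path,
         " (denoised haplotypes must be unambiguous)")
  }
  collapse_reads(sequences, counts, ids = ids, sample_id = sample_id,
                 role = role, strain = strain, subtype = subtype)
}

#' Write a viral population to a count-annotated FASTA
#'
#' Headers use the same `id;size=N` dialect read by
#' [read_haplotype_fasta()], so write-then-read round-trips exactly.
#'
#' @param pop A [viral_population()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(pop, path) {
  stopifnot(inherits(pop, "viral_population"))
  x <- Biostrings::DNAStringSet(pop$haplotypes$sequence)
  names(x) <- paste0(pop$haplotypes$id, ";size=", pop$haplotypes$read_count)
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' Read a reference FASTA (first record)
#'
#' @param path FASTA path; the first record is used.
#' @param annotation Optional GFF3 annotation path, forwarded to
#'   [read_annotation()].
#' @return A [reference_genome()].
#' @export
read_reference_fasta <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  id <- sub("\\s.*$", "", names(seqs)[1L])
  ref <- reference_genome(id, as.character(seqs[[1L]]))
  if (!is.null(annotation)) ref <- read_annotation(annotation, ref)
  ref
}

#' Read a GFF3-like coding annotation onto a reference genome
#'
#' CDS features (plus strand, 1-based inclusive) become coding regions named
#' by their `Name=` (or `ID=`) attribute, conventionally `ORFA` / `ORFB`.
#' Everything outside the CDS features is implicitly noncoding. An empty
#' annotation yields an all-noncoding genome (diversity over zero coding
#' sites is then reported as zero sites with a warning downstream).
#'
#' @param path GFF3 file path.
#' @param ref A [reference_genome()] the coordinates are validated against.
#' @return `ref` with its `regions` replaced.
#' @export
read_annotation <- function(path, ref) {
  stopifnot(inherits(ref, "reference_genome"))
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  gff <- ape::read.gff(path, GFF3 = TRUE)
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) {
    ref$regions <- validate_regions(NULL, nchar(ref$sequence))
    return(ref)
  }
  if (any(cds$strand == "-")) {
    stop("reverse-strand CDS is not supported (plus-strand message-sense only)")
  }
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  nm <- get_attr(cds$attributes, "Name")
  id <- get_attr(cds$attributes, "ID")
  nm[is.na(nm)] <- id[is.na(nm)]
  nm[is.na(nm)] <- paste0("CDS", seq_len(nrow(cds)))[is.na(nm)]
  phase <- suppressWarnings(as.integer(as.character(cds$phase)))
  phase[is.na(phase)] <- 0L
  ref$regions <- validate_regions(
    data.frame(name = nm, start = cds$start, end = cds$end,
               frame_offset = phase, stringsAsFactors = FALSE),
    nchar(ref$sequence)
  )
  ref
}

#' Write a reference genome's coding regions as GFF3
#'
#' @param ref A [reference_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ref, path) {
  stopifnot(inherits(ref, "reference_genome"))
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", ref$id, nchar(ref$sequence))
  )
  if (nrow(ref$regions) > 0L) {
    lines <- c(lines, sprintf(
      "%s\tquasipop\tCDS\t%d\t%d\t.\t+\t%d\tID=%s;Name=%s",
      ref$id, ref$regions$start, ref$regions$end, ref$regions$frame_offset,
      ref$regions$name, ref$regions$name
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a transmission pair
#'
#' Links one source population to its recipient population(s) with the
#' heteroallelic vegetative-incompatibility locus (if any) and the
#' transmission attempt/success counts of the underlying pairing assay.
#'
#' @param source_id Source (parental or donor) sample id.
#' @param recipient_ids Character vector of recipient/progeny sample ids.
#' @param mode `"vertical"` (into conidia) or `"horizontal"` (anastomosis).
#' @param het_locus `"none"`, `"vic2"`, `"vic3"` or `"vic4"`.
#' @param n_attempts,n_success Pairing replicate counts,
#'   `0 <= n_success <= n_attempts`; may be `NA` when not recorded.
#' @param pair_id Optional label.
#' @return An object of class `transmission_pair`.
#' @export
transmission_pair <- function(source_id, recipient_ids,
                              mode = c("vertical", "horizontal"),
                              het_locus = "none",
                              n_attempts = NA_integer_,
                              n_success = NA_integer_,
                              pair_id = NULL) {
  mode <- match.arg(mode)
  het_locus <- match.arg(het_locus, VALID_LOCI)
  n_attempts <- as.integer(n_attempts)
  n_success <- as.integer(n_success)
  if (!is.na(n_attempts) && !is.na(n_success) &&
      (n_success < 0L || n_success > n_attempts)) {
    stop("need 0 <= n_success <= n_attempts")
  }
  structure(
    list(
      pair_id = if (is.null(pair_id)) source_id else as.character(pair_id),
      source_id = as.character(source_id),
      recipient_ids = as.character(recipient_ids),
      mode = mode, het_locus = het_locus,
      n_attempts = n_attempts, n_success = n_success
    ),
    class = "transmission_pair"
  )
}

#' Read a sample-pairing manifest
#'
#' The manifest is a TSV with columns `sample_id`, `role`, `strain`,
#' `subtype`, `pair_id`, `mode`, `het_locus`, `fasta_path` and optionally
#' `n_attempts`, `n_success`. On a `progeny`/`recipient` row, `pair_id`
#' names the sample id of its source (a `parental` or `donor` row); source
#' and `pooled` rows leave it blank. Recipients of one source are grouped
#' into one transmission pair per heteroallelic locus, so a donor tested
#' against several vic testers yields several pairs. Relative
#' `fasta_path`s are resolved against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @return A list with `samples` (validated data.frame, one row per
#'   population) and `pairs` (list of [transmission_pair()]).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  man <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("sample_id", "role", "strain", "subtype", "pair_id", "mode",
              "het_locus", "fasta_path")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(man$n_attempts)) man$n_attempts <- NA_integer_
  if (is.null(man$n_success)) man$n_success <- NA_integer_
  if (anyDuplicated(man$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(man$sample_id[duplicated(man$sample_id)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(man$role), VALID_ROLES)
  if (length(bad_role)) stop("unknown role value(s): ", paste(bad_role, collapse = ", "))
  loci <- man$het_locus
  loci[is.na(loci) | loci == ""] <- "none"
  bad_locus <- setdiff(unique(loci), VALID_LOCI)
  if (length(bad_locus)) stop("unknown het_locus value(s): ", paste(bad_locus, collapse = ", "))
  man$het_locus <- loci
  man$fasta_path <- ifelse(
    grepl("^(/|[A-Za-z]:)", man$fasta_path), man$fasta_path,
    file.path(dirname(path), man$fasta_path)
  )

  is_rec <- man$role %in% c("progeny", "recipient")
  src_ids <- man$sample_id[man$role %in% c("parental", "donor")]
  dangling <- man$sample_id[
    is_rec & (is.na(man$pair_id) | man$pair_id == "" |
                !man$pair_id %in% src_ids)
  ]
  if (length(dangling)) {
    stop("progeny/recipient sample(s) without a resolvable parental/donor ",
         "source: ", paste(dangling, collapse = ", "))
  }
  pairs <- list()
  rec <- man[is_rec, , drop = FALSE]
  if (nrow(rec) > 0L) {
    key <- paste(rec$pair_id, rec$het_locus, sep = ":")
    for (kk in unique(key)) {
      grp <- rec[key == kk, , drop = FALSE]
      mode <- unique(grp$mode[!is.na(grp$mode) & grp$mode != ""])
      if (length(mode) != 1L || !mode %in% c("vertical", "horizontal")) {
        stop("pair '", kk, "' needs a single mode, vertical or horizontal")
      }
      na_or_single <- function(x) {
        if (all(is.na(x))) NA_integer_ else unique(x[!is.na(x)])[1L]
      }
      pairs[[kk]] <- transmission_pair(
        source_id = grp$pair_id[1L], recipient_ids = grp$sample_id,
        mode = mode, het_locus = grp$het_locus[1L],
        n_attempts = na_or_single(grp$n_attempts),
        n_success = na_or_single(grp$n_success),
        pair_id = kk
      )
    }
  }
  list(samples = man, pairs = pairs)
}

#' Write a sample manifest TSV
#'
#' @param samples data.frame in the layout documented in [read_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
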