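# End-to-end orchestration: run a full diversity + transmission analysis
# from a manifest, or generate a simulated study and analyse it. Outputs
# are deterministic given inputs (samples processed in sorted order):
# diversity.tsv, transmission.tsv, mutations.vcf, consensus.fasta,
# summary.json and run.log.

DEFAULT_FWD_PRIMER <- "ATCYGGAGAARGTGATTTGC"
DEFAULT_REV_PRIMER <- "YTTRTTGATGTAGCTGCGAGG"

log_line <- function(lines, level, msg) {
  c(lines, sprintf("%s [%s] %s",
                   format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, msg))
}

sanitize_num <- function(x) {
  if (is.numeric(x)) x[!is.finite(x)] <- NA_real_
  x
}

#' Run the full intra-host diversity and transmission analysis
#'
#' Reads the manifest, reference and annotation, locates the amplicon via
#' the primer pair, and for every population (in sorted sample order)
#' computes the diversity report and mutation calls; for every
#' source-recipient pair it computes shared-variant fractions, log-ratio
#' diversity changes, transmission rates and founder estimates; and it
#' summarises the piS-versus-piN selection signal across all populations.
#' Writes `diversity.tsv`, `transmission.tsv`, `mutations.vcf`,
#' `consensus.fasta`, `summary.json` and `run.log` into `out_dir`.
#'
#' @param manifest Manifest TSV path (see [read_manifest()]).
#' @param reference Reference FASTA path.
#' @param annotation GFF3 annotation path (optional; unannotated references
#'   are all-noncoding).
#' @param out_dir Output directory, created if needed.
#' @param fwd_primer,rev_primer IUPAC primer pair used to locate the
#'   amplicon (defaults: the CHV1 5-kb amplicon primers).
#' @param amplicon Optional [amplicon_region()] overriding primer search.
#' @param dominance_threshold Dominant-variant frequency cut (default 0.05).
#' @param consensus_threshold Consensus majority threshold (default 0.5).
#' @param corrected Apply the finite-sample pi correction (default FALSE).
#' @param neis_n_mode `"variants"` or `"reads"` for Nei's H.
#' @return The run summary (list), invisibly: `run_id`, `options`,
#'   `populations` (diversity table), `pairs` (transmission table),
#'   `selection`, `warnings`, `reports` (full per-population reports).
#' @export
run_analysis <- function(manifest, reference, annotation = NULL,
                         out_dir = "quasipop-out",
                         fwd_primer = DEFAULT_FWD_PRIMER,
                         rev_primer = DEFAULT_REV_PRIMER,
                         amplicon = NULL,
                         dominance_threshold = 0.05,
                         consensus_threshold = 0.5,
                         corrected = FALSE,
                         neis_n_mode = "variants") {
  lines <- character(0)
  lines <- log_line(lines, "INFO", paste("manifest:", manifest))
  man <- read_manifest(manifest)
  ref <- read_reference_fasta(reference, annotation)
  if (is.null(amplicon)) {
    amplicon <- find_amplicon(ref, fwd_primer, rev_primer)
  }
  lines <- log_line(lines, "INFO", sprintf(
    "reference %s (%d nt), amplicon %d-%d, %d populations",
    ref$id, nchar(ref$sequence), amplicon$start, amplicon$end,
    nrow(man$samples)
  ))

  samples <- man$samples[order(man$samples$sample_id), , drop = FALSE]
  warnings <- character(0)
  reports <- list()
  pops <- list()
  all_muts <- list()
  consensi <- character(0)
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    if (!file.exists(samples$fasta_path[i])) {
      stop("sample ", sid, ": FASTA not found at ", samples$fasta_path[i])
    }
    pop <- tryCatch(
      read_haplotype_fasta(samples$fasta_path[i], sample_id = sid,
                           role = samples$role[i],
                           strain = samples$strain[i],
                           subtype = samples$subtype[i]),
      error = function(e) stop("sample ", sid, ": ", conditionMessage(e))
    )
    rep_i <- withCallingHandlers(
      population_pi(pop, ref, amplicon, corrected = corrected),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (neis_n_mode != "variants") {
      rep_i$neis_h <- as.numeric(neis_h(pop, n_mode = neis_n_mode))
    }
    pops[[sid]] <- pop
    reports[[sid]] <- rep_i
    if (length(rep_i$warnings)) {
      warnings <- c(warnings, paste0(sid, ":", rep_i$warnings))
    }
    if (nrow(rep_i$mutations)) {
      m <- rep_i$mutations
      m$sample_id <- sid
      all_muts[[sid]] <- m
    }
    consensi[sid] <- build_consensus(ref, rep_i$mutations,
                                     threshold = consensus_threshold)
    lines <- log_line(lines, "INFO", sprintf(
      "sample %s: %d variants, %d mutations, pi=%.6g", sid,
      rep_i$n_variants, rep_i$n_mutations, rep_i$pi
    ))
  }

  pair_rows <- list()
  pair_ids <- sort(names(man$pairs))
  for (pid in pair_ids) {
    pr <- man$pairs[[pid]]
    src_pop <- pops[[pr$source_id]]
    rec_pops <- pops[pr$recipient_ids]
    sv <- shared_variants(src_pop, rec_pops)
    dc_pi <- diversity_change(reports[[pr$source_id]],
                              reports[pr$recipient_ids], metric = "pi")
    dc_nv <- diversity_change(reports[[pr$source_id]],
                              reports[pr$recipient_ids],
                              metric = "n_variants")
    warnings <- c(warnings, paste0(pid, ":", c(dc_pi$flags, dc_nv$flags)))
    rate <- if (!is.na(pr$n_attempts) && !is.na(pr$n_success)) {
      transmission_rate(pr)
    } else NA_real_
    khat <- function(method) {
      vals <- vapply(pr$recipient_ids, function(rid) {
        est <- tryCatch({
          if (method == "gene_diversity_ratio") {
            estimate_founders(src_pop, pops[[rid]], method = method)
          } else {
            estimate_founders(
              method = method,
              d_source = reports[[pr$source_id]]$pi,
              d_recipient = reports[[rid]]$pi
            )
          }
        }, error = function(e) NULL)
        if (is.null(est)) NA_real_ else est$k_hat
      }, 0)
      fin <- vals[is.finite(vals)]
      if (length(fin)) mean(fin) else NA_real_
    }
    pair_rows[[pid]] <- data.frame(
      pair_id = pid, mode = pr$mode, het_locus = pr$het_locus,
      source_id = pr$source_id, n_recipients = length(pr$recipient_ids),
      n_attempts = pr$n_attempts, n_success = pr$n_success, rate = rate,
      n_shared = sv$n_shared, frac_of_source = sv$frac_of_source,
      frac_of_recipient = sv$frac_of_recipient,
      frac_of_union = sv$frac_of_union,
      mean_log_ratio_pi = dc_pi$mean_log_ratio,
      mean_log_ratio_n_variants = dc_nv$mean_log_ratio,
      k_hat_gene_diversity = khat("gene_diversity_ratio"),
      k_hat_pi = khat("pi_ratio"),
      stringsAsFactors = FALSE
    )
  }
  pair_table <- if (length(pair_rows)) {
    do.call(rbind, pair_rows)
  } else {
    data.frame(pair_id = character(0))
  }
  rownames(pair_table) <- NULL

  div_table <- diversity_table(unname(reports))
  sel <- selection_summary(unname(reports))
  mut_table <- if (length(all_muts)) do.call(rbind, all_muts) else NULL
  if (!is.null(mut_table)) rownames(mut_table) <- NULL

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(div_table, file.path(out_dir, "diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pair_table, file.path(out_dir, "transmission.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_vcf(mut_table, ref$id, file.path(out_dir, "mutations.vcf"))
  cons <- Biostrings::DNAStringSet(consensi)
  Biostrings::writeXStringSet(cons, file.path(out_dir, "consensus.fasta"),
                              width = 80L)
  run_id <- sprintf("qp-%s-%d", sub("\\.tsv$", "", basename(manifest)),
                    nrow(samples))
  options <- list(
    reference = ref$id, amplicon_start = amplicon$start,
    amplicon_end = amplicon$end,
    dominance_threshold = dominance_threshold,
    consensus_threshold = consensus_threshold, corrected = corrected,
    neis_n_mode = neis_n_mode
  )
  summary <- list(
    run_id = run_id, options = options,
    populations = as.data.frame(lapply(div_table, sanitize_num)),
    pairs = as.data.frame(lapply(pair_table, sanitize_num)),
    selection = lapply(sel, sanitize_num),
    warnings = sort(warnings)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  lines <- log_line(lines, "INFO", paste("outputs written to", out_dir))
  writeLines(lines, file.path(out_dir, "run.log"))
  summary$reports <- reports
  invisible(summary)
}

#' Write a simulated transmission study to disk
#'
#' Generates the reference, annotation, populations and manifest of one of
#' two scenario presets, in the same FASTA/GFF3/TSV formats the empirical
#' ingest reads:
#' * `"vertical-study"`: one parental population and 6 conidial progeny
#'   populations from founder-sampled vertical transmission (the layout of
#'   a single-strain spore assay).
#' * `"horizontal-study"`: one donor population and 3 sequenced recipients
#'   for each heteroallelic locus (none/vic2/vic3/vic4). Recipients are
#'   generated conditional on success (only successful transmissions get
#'   sequenced) while `n_attempts`/`n_success` come from Bernoulli trials
#'   at the locus success rates (25 attempts per heteroallelic pairing,
#'   10 for the compatible control).
#'
#' @param cfg A [simulation_config()].
#' @param preset `"vertical-study"` or `"horizontal-study"`.
#' @param out_dir Output directory for the dataset files.
#' @return List with `reference`, `annotation`, `manifest` (paths),
#'   `ref`, `amplicon`, `populations`.
#' @export
simulate_dataset <- function(cfg, preset = c("vertical-study",
                                             "horizontal-study"),
                             out_dir) {
  preset <- match.arg(preset)
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mr <- make_reference(cfg)
  ref_path <- file.path(out_dir, "reference.fasta")
  rs <- Biostrings::DNAStringSet(mr$ref$sequence)
  names(rs) <- mr$ref$id
  Biostrings::writeXStringSet(rs, ref_path, width = 80L)
  ann_path <- file.path(out_dir, "annotation.gff3")
  write_annotation(mr$ref, ann_path)

  rows <- list()
  pops <- list()
  add_pop <- function(pop, pair_id, mode, het_locus, n_attempts, n_success) {
    write_haplotype_fasta(pop, file.path(out_dir,
                                         paste0(pop$sample_id, ".fasta")))
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = pop$sample_id, role = pop$role, strain = pop$strain,
      subtype = pop$subtype, pair_id = pair_id, mode = mode,
      het_locus = het_locus,
      fasta_path = paste0(pop$sample_id, ".fasta"),
      n_attempts = n_attempts, n_success = n_success,
      stringsAsFactors = FALSE
    )
    pops[[pop$sample_id]] <<- pop
  }

  if (preset == "vertical-study") {
    parent <- make_parental_population(
      mr$ref, cfg, sample_id = paste0(cfg$strain, "_M"), role = "parental"
    )
    parent <- attach_reference(parent, mr$ref)
    n_attempts <- 12L
    n_success <- with_seed(child_seed(cfg$seed, "vertical_assay", 0L),
                           rbinom(1L, n_attempts, cfg$vertical_success))
    add_pop(parent, "", "vertical", "none", n_attempts, n_success)
    for (r in 1:6) {
      out <- simulate_vertical(parent, cfg, replicate = r)
      add_pop(out$recipient, parent$sample_id, "vertical", "none",
              n_attempts, n_success)
    }
  } else {
    donor <- make_parental_population(
      mr$ref, cfg, sample_id = paste0(cfg$strain, "_D"), role = "donor"
    )
    donor <- attach_reference(donor, mr$ref)
    add_pop(donor, "", "horizontal", "none", NA_integer_, NA_integer_)
    for (locus in VALID_LOCI) {
      n_attempts <- if (locus == "none") 10L else 25L
      n_success <- with_seed(
        child_seed(cfg$seed, paste0("assay:", locus), 0L),
        rbinom(1L, n_attempts, cfg$vic_success[[locus]])
      )
      for (r in 1:3) {
        out <- simulate_horizontal(donor, locus, cfg, replicate = r,
                                   condition_on_success = TRUE)
        add_pop(out$recipient, donor$sample_id, "horizontal", locus,
                n_attempts, n_success)
      }
    }
  }
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  man_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(man, man_path)
  list(reference = ref_path, annotation = ann_path, manifest = man_path,
       ref = mr$ref, amplicon = mr$amplicon, populations = pops)
}

#' Generate and analyse a simulated study end-to-end
#'
#' Writes the simulated dataset with [simulate_dataset()] and then runs
#' [run_analysis()] on it; a single seed in the configuration reproduces
#' the dataset and the analysis byte-identically.
#'
#' @param cfg A [simulation_config()].
#' @param preset `"vertical-study"` or `"horizontal-study"`.
#' @param out_dir Root output directory; the dataset goes to
#'   `<out_dir>/data`, analysis outputs to `<out_dir>`.
#' @return The run summary from [run_analysis()], invisibly, with the
#'   dataset paths attached as `dataset`.
#' @export
run_simulation_study <- function(cfg, preset = c("vertical-study",
                                                 "horizontal-study"),
                                 out_dir) {
  preset <- match.arg(preset)
  ds <- simulate_dataset(cfg, preset, file.path(out_dir, "data"))
  summary <- run_analysis(
    manifest = ds$manifest, reference = ds$reference,
    annotation = ds$annotation, out_dir = out_dir
  )
  summary$dataset <- ds[c("reference", "annotation", "manifest")]
  invisible(summary)
}
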