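# Codon-aware nucleotide diversity over the amplicon's coding sites,
# partitioned into synonymous and nonsynonymous components by Nei-Gojobori
# counting: per-codon synonymous/nonsynonymous site fractions from the nine
# single-nucleotide neighbours, pairwise codon differences averaged over
# mutational pathways, and the population accumulator
# pi = (Ndiffs + Sdiffs) / (NSites + SSites).

BASES <- c("A", "C", "G", "T")

.codon_cache <- new.env(parent = emptyenv())

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Each of the nine single-nucleotide neighbours of the codon contributes
#' one third of a site, classified synonymous iff the encoded amino acid is
#' unchanged; changes creating a stop codon count as nonsynonymous. The two
#' counts always partition the codon: `N_sites + S_sites = 3`. Stop codons
#' are excluded from site totals and are rejected.
#'
#' @param codon A 3-mer over A/C/G/T encoding a sense codon.
#' @return Named numeric vector `c(N_sites = , S_sites = )`.
#' @export
#' @examples
#' ns_sites("TTT")  # Phe: c(N_sites = 8/3, S_sites = 1/3)
ns_sites <- function(codon) {
  codon <- toupper(codon)
  key <- paste0("S", codon)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!grepl("^[ACGT]{3}$", codon)) stop("not an A/C/G/T codon: ", codon)
  aa <- translate_codon(codon)
  if (aa == "*") stop("stop codon ", codon, " is excluded from site counting")
  syn <- 0L
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  for (p in 1:3) {
    for (b in BASES[BASES != chars[p]]) {
      nb <- chars; nb[p] <- b
      if (translate_codon(paste(nb, collapse = "")) == aa) syn <- syn + 1L
    }
  }
  out <- c(N_sites = 3 - syn / 3, S_sites = syn / 3)
  assign(key, out, envir = .codon_cache)
  out
}

#' Nonsynonymous/synonymous differences between two codons
#'
#' For codons differing at `d` positions, the per-step classification is
#' averaged over all `d!` orderings of the changes (the Nei-Gojobori
#' equal-weight pathway rule). Orderings passing through a stop codon are
#' excluded from the average; in the degenerate case where every pathway
#' passes through a stop, all pathways are used (stop steps counted as
#' nonsynonymous) and the result carries attribute `stop_fallback = TRUE`.
#' `N_diffs + S_diffs` always equals `d`.
#'
#' @param a,b Sense codons over A/C/G/T.
#' @return Named numeric vector `c(N_diffs = , S_diffs = )`.
#' @export
#' @examples
#' codon_diffs("TTT", "GTA")  # average of two pathways: c(1.5, 0.5)
codon_diffs <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  key <- paste0("D", a, b)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!grepl("^[ACGT]{3}$", a) || !grepl("^[ACGT]{3}$", b)) {
    stop("codon_diffs needs A/C/G/T codons")
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  pos <- which(ca != cb)
  d <- length(pos)
  if (d == 0L) {
    out <- c(N_diffs = 0, S_diffs = 0)
    assign(key, out, envir = .codon_cache)
    return(out)
  }
  perms <- permutations_of(pos)
  walk <- function(order_, allow_stop) {
    cur <- ca
    n <- 0; s <- 0
    for (p in order_) {
      nxt <- cur; nxt[p] <- cb[p]
      aa_cur <- translate_codon(paste(cur, collapse = ""))
      aa_nxt <- translate_codon(paste(nxt, collapse = ""))
      if (aa_nxt == "*" && !allow_stop && !identical(nxt, cb)) {
        return(NULL)   # pathway passes through a premature stop
      }
      if (aa_cur == aa_nxt && aa_cur != "*") s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(n, s)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  fallback <- FALSE
  if (length(res) == 0L) {
    res <- lapply(perms, walk, allow_stop = TRUE)
    fallback <- TRUE
  }
  m <- Reduce(`+`, res) / length(res)
  out <- c(N_diffs = m[1L], S_diffs = m[2L])
  if (fallback) attr(out, "stop_fallback") <- TRUE
  assign(key, out, envir = .codon_cache)
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# Codon start positions (reference coordinates) of a CDS region restricted
# to codons fully inside [from, to].
codon_starts <- function(region, from, to) {
  first <- region$start + region$frame_offset
  if (first + 2L > region$end) return(integer(0))
  starts <- seq.int(first, region$end - 2L, by = 3L)
  starts[starts >= from & (starts + 2L) <= to]
}

#' Codon-aware nucleotide diversity of a population over the amplicon
#'
#' For every codon of the annotated coding regions that lies fully inside
#' the amplicon, haplotypes are projected onto reference coordinates and
#' the frequency-weighted pairwise codon differences
#' `sum_i sum_j x_i x_j (N_diffs + S_diffs)` are accumulated, together with
#' frequency-weighted Nei-Gojobori site counts per haplotype codon. Then
#' `pi = (Ndiffs + Sdiffs) / (NSites + SSites)`,
#' `piN = Ndiffs / NSites` and `piS = Sdiffs / SSites`, with a per-region
#' breakdown from the same accumulators. All variants enter the sums (no
#' minimum allele frequency, no sliding window). Codon columns containing
#' an alignment gap in any haplotype are excluded from both differences and
#' sites (deletions are reported as mutations with effects instead), as are
#' columns where any haplotype codon is a stop; both exclusions are
#' counted and flagged. Weighting is with replacement by default (read
#' depths are large); `corrected = TRUE` applies the `n/(n-1)` finite-
#' sample factor with `n` the total read count.
#'
#' @param pop A [viral_population()].
#' @param ref A [reference_genome()] with coding regions.
#' @param amplicon An [amplicon_region()].
#' @param corrected Apply the finite-sample correction (default `FALSE`).
#' @param aligned Optional precomputed population alignment (internal).
#' @return An object of class `diversity_report`: list with `sample_id`,
#'   `pi`, `piN`, `piS`, `Ndiffs`, `Sdiffs`, `NSites`, `SSites`, `neis_h`,
#'   `n_variants`, `n_mutations`, `per_region` (data.frame), codon counts
#'   (`codons_evaluated`, `codons_excluded_gap`, `codons_excluded_stop`)
#'   and `warnings`.
#' @export
population_pi <- function(pop, ref, amplicon, corrected = FALSE,
                          aligned = NULL) {
  if (is.null(aligned)) aligned <- align_population(pop, ref, amplicon)
  x <- aligned$frequencies
  n_hap <- length(x)
  warnings <- character(0)

  acc <- list()  # per region name: c(Nd, Sd, Ns, Ss)
  add_acc <- function(acc, name, v) {
    if (is.null(acc[[name]])) acc[[name]] <- c(0, 0, 0, 0)
    acc[[name]] <- acc[[name]] + v
    acc
  }
  n_eval <- 0L; n_gap <- 0L; n_stop <- 0L

  for (ri in seq_len(nrow(ref$regions))) {
    region <- ref$regions[ri, ]
    for (cs in codon_starts(region, amplicon$start, amplicon$end)) {
      rel <- cs - amplicon$start + 1L
      codons <- substr(aligned$projections, rel, rel + 2L)
      if (any(grepl("-", codons, fixed = TRUE))) {
        n_gap <- n_gap + 1L
        next
      }
      is_stop <- vapply(unique(codons),
                        function(cdn) translate_codon(cdn) == "*", TRUE)
      if (any(is_stop)) {
        n_stop <- n_stop + 1L
        next
      }
      n_eval <- n_eval + 1L
      uniq <- unique(codons)
      w <- vapply(uniq, function(u) sum(x[codons == u]), 0,
                  USE.NAMES = FALSE)
      sites <- Reduce(`+`, Map(function(u, wi) wi * ns_sites(u), uniq, w))
      dNs <- 0; dSs <- 0
      if (length(uniq) > 1L) {
        for (i in seq_along(uniq)) {
          for (j in seq_along(uniq)) {
            if (i == j) next
            cd <- codon_diffs(uniq[i], uniq[j])
            dNs <- dNs + w[i] * w[j] * cd[["N_diffs"]]
            dSs <- dSs + w[i] * w[j] * cd[["S_diffs"]]
          }
        }
      }
      acc <- add_acc(acc, region$name,
                     c(dNs, dSs, sites[["N_sites"]], sites[["S_sites"]]))
    }
  }

  if (n_gap > 0L) {
    warnings <- c(warnings, sprintf("gap_excluded_codons=%d", n_gap))
  }
  if (n_stop > 0L) {
    warnings <- c(warnings, sprintf("stop_excluded_codons=%d", n_stop))
  }
  tot <- Reduce(`+`, acc, accumulate = FALSE)
  if (is.null(tot)) tot <- c(0, 0, 0, 0)
  corr <- if (corrected && pop$total_reads > 1L) {
    pop$total_reads / (pop$total_reads - 1L)
  } else 1
  ratio <- function(num, den) {
    if (den > 0) unname(corr * num / den) else 0
  }
  if (tot[3] + tot[4] == 0) {
    warnings <- c(warnings, "zero_coding_sites")
    warning("population ", pop$sample_id,
            ": zero coding sites in the amplicon; pi reported as 0")
  }
  per_region <- do.call(rbind, lapply(names(acc), function(nm) {
    v <- acc[[nm]]
    data.frame(
      region = nm,
      pi = ratio(v[1] + v[2], v[3] + v[4]),
      piN = ratio(v[1], v[3]), piS = ratio(v[2], v[4]),
      Ndiffs = v[1], Sdiffs = v[2], NSites = v[3], SSites = v[4],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(per_region)) {
    per_region <- data.frame(region = character(), pi = numeric(),
                             piN = numeric(), piS = numeric(),
                             Ndiffs = numeric(), Sdiffs = numeric(),
                             NSites = numeric(), SSites = numeric(),
                             stringsAsFactors = FALSE)
  }
  mutations <- call_mutations(pop, ref, amplicon, aligned = aligned)
  structure(
    list(
      sample_id = pop$sample_id, role = pop$role, strain = pop$strain,
      subtype = pop$subtype,
      pi = ratio(tot[1] + tot[2], tot[3] + tot[4]),
      piN = ratio(tot[1], tot[3]), piS = ratio(tot[2], tot[4]),
      Ndiffs = unname(tot[1]), Sdiffs = unname(tot[2]),
      NSites = unname(tot[3]), SSites = unname(tot[4]),
      neis_h = as.numeric(neis_h(pop)),
      n_variants = n_hap, n_mutations = nrow(mutations),
      mutations = mutations, per_region = per_region,
      codons_evaluated = n_eval, codons_excluded_gap = n_gap,
      codons_excluded_stop = n_stop,
      corrected = corrected, warnings = warnings
    ),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    "<diversity_report> %s: pi=%.6g piN=%.6g piS=%.6g H=%.4f (%d variants, %d mutations)\n",
    x$sample_id, x$pi, x$piN, x$piS, x$neis_h, x$n_variants, x$n_mutations
  ))
  invisible(x)
}

#' Tabulate diversity reports
#'
#' @param reports List of `diversity_report` objects.
#' @return data.frame, one row per population, with overall and per-ORF
#'   diversity columns.
#' @export
diversity_table <- function(reports) {
  if (inherits(reports, "diversity_report")) reports <- list(reports)
  region_names <- sort(unique(unlist(
    lapply(reports, function(r) r$per_region$region)
  )))
  rows <- lapply(reports, function(r) {
    row <- data.frame(
      sample_id = r$sample_id, role = r$role, strain = r$strain,
      subtype = r$subtype, pi = r$pi, piN = r$piN, piS = r$piS,
      neis_h = r$neis_h, n_variants = r$n_variants,
      n_mutations = r$n_mutations,
      codons_excluded_gap = r$codons_excluded_gap,
      codons_excluded_stop = r$codons_excluded_stop,
      stringsAsFactors = FALSE
    )
    for (nm in region_names) {
      hit <- r$per_region[r$per_region$region == nm, , drop = FALSE]
      row[[paste0("pi_", nm)]] <- if (nrow(hit)) hit$pi[1L] else NA_real_
      row[[paste0("piN_", nm)]] <- if (nrow(hit)) hit$piN[1L] else NA_real_
      row[[paste0("piS_", nm)]] <- if (nrow(hit)) hit$piS[1L] else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Selection summary: piS versus piN across populations
#'
#' Counts populations with `piS > piN` (purifying-selection signal),
#' `piN > piS` (positive selection or mutation-load accumulation) and ties,
#' reports means and standard deviations of both components, the mean
#' difference `mean(piS) - mean(piN)` (positive under purifying selection)
#' and a two-sided paired t test on `piN - piS`.
#'
#' @param reports List of `diversity_report` objects, or a data.frame with
#'   columns `piN` and `piS`.
#' @return List with `n`, `n_piS_gt_piN`, `n_piN_gt_piS`, `n_tie`,
#'   `mean_piS`, `sd_piS`, `mean_piN`, `sd_piN`, `mean_difference`,
#'   `t`, `p_value`, `flags`.
#' @export
selection_summary <- function(reports) {
  if (inherits(reports, "diversity_report")) reports <- list(reports)
  df <- if (is.data.frame(reports)) reports else data.frame(
    piN = vapply(reports, function(r) r$piN, 0),
    piS = vapply(reports, function(r) r$piS, 0)
  )
  n <- nrow(df)
  if (n < 1L) stop("selection_summary needs at least one report")
  flags <- character(0)
  diffs <- df$piN - df$piS
  t_stat <- NA_real_; p_val <- NA_real_
  if (n < 2L) {
    flags <- c(flags, "single_population_test_skipped")
  } else if (sd(diffs) == 0) {
    flags <- c(flags, "all_tie_t_undefined")
    t_stat <- NaN; p_val <- NaN
  } else {
    tt <- t.test(df$piN, df$piS, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  list(
    n = n,
    n_piS_gt_piN = sum(df$piS > df$piN),
    n_piN_gt_piS = sum(df$piN > df$piS),
    n_tie = sum(df$piN == df$piS),
    mean_piS = mean(df$piS), sd_piS = if (n > 1L) sd(df$piS) else NA_real_,
    mean_piN = mean(df$piN), sd_piN = if (n > 1L) sd(df$piN) else NA_real_,
    mean_difference = mean(df$piS) - mean(df$piN),
    t = t_stat, p_value = p_val, flags = flags
  )
}
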