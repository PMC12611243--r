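# Transmission-success statistics, diversity-change comparisons between
# paired populations and moment-based founder (bottleneck) size estimation.

#' Transmission success rate of a pairing assay
#'
#' @param pair A [transmission_pair()], or the number of successes when
#'   `n_attempts` is given directly.
#' @param n_attempts Number of attempts when `pair` is a success count.
#' @return Percentage `100 * n_success / n_attempts`.
#' @export
#' @examples
#' transmission_rate(23, 25)  # 92
transmission_rate <- function(pair, n_attempts = NULL) {
  if (inherits(pair, "transmission_pair")) {
    n_success <- pair$n_success
    n_attempts <- pair$n_attempts
  } else {
    n_success <- pair
  }
  if (is.na(n_attempts) || n_attempts < 1L) {
    stop("transmission_rate needs n_attempts >= 1")
  }
  if (is.na(n_success) || n_success < 0L || n_success > n_attempts) {
    stop("need 0 <= n_success <= n_attempts")
  }
  100 * n_success / n_attempts
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, whose probability does not exceed
#' that of the observed table (within a 1e-12 relative slack against
#' floating-point ties). A table with a zero row or column margin admits a
#' single feasible table and has `p = 1` by convention.
#'
#' @param table 2x2 matrix of non-negative counts, or the count `a` when
#'   `b`, `c`, `d` are given.
#' @param b,c,d Remaining cells (row-wise: `a b / c d`).
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(0, 10, 10, 0)  # 2 / choose(20, 10)
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    a <- table[1L, 1L]; b <- table[1L, 2L]
    cc <- table[2L, 1L]; d <- table[2L, 2L]
  } else {
    a <- table; cc <- c
  }
  cells <- c(a, b, cc, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_exact_2x2 needs four non-negative integers")
  }
  m <- a + b            # row 1 margin (white balls)
  n <- cc + d           # row 2 margin (black balls)
  k <- a + cc           # column 1 margin (balls drawn)
  lo <- max(0, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Log-ratio diversity change from a source to its recipients
#'
#' Natural-log ratios `ln(recipient / source)` of a diversity metric, one
#' per recipient, with a pseudocount `eps` added to both terms (and the
#' pair flagged) whenever either value is zero; the mean log-ratio; and,
#' for two or more recipients, a two-sided one-sample t test of the
#' log-ratios against zero.
#'
#' @param source_report A `diversity_report` (or a single numeric value).
#' @param recipient_reports List of `diversity_report`s (or numeric vector).
#' @param metric `"pi"`, `"n_variants"` or `"neis_h"`.
#' @param eps Pseudocount for zero values, default 1e-6.
#' @return List with `metric`, `log_ratios`, `mean_log_ratio`, `t`,
#'   `p_value`, `flags`.
#' @export
diversity_change <- function(source_report, recipient_reports,
                             metric = c("pi", "n_variants", "neis_h"),
                             eps = 1e-6) {
  metric <- match.arg(metric)
  pick <- function(x) {
    if (inherits(x, "diversity_report")) x[[metric]] else as.numeric(x)
  }
  src <- pick(source_report)
  if (inherits(recipient_reports, "diversity_report")) {
    recipient_reports <- list(recipient_reports)
  }
  rec <- if (is.list(recipient_reports)) {
    vapply(recipient_reports, pick, 0)
  } else {
    as.numeric(recipient_reports)
  }
  if (length(rec) < 1L) stop("needs at least one recipient")
  flags <- character(0)
  lr <- numeric(length(rec))
  for (i in seq_along(rec)) {
    s <- src; r <- rec[i]
    if (s == 0 || r == 0) {
      s <- s + eps; r <- r + eps
      flags <- c(flags, sprintf("pseudocount_recipient_%d", i))
    }
    lr[i] <- log(r / s)
  }
  t_stat <- NA_real_; p_val <- NA_real_
  if (length(lr) >= 2L && sd(lr) > 0) {
    tt <- t.test(lr, mu = 0)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  } else if (length(lr) >= 2L) {
    flags <- c(flags, "zero_variance_t_undefined")
  } else {
    flags <- c(flags, "single_recipient_test_skipped")
  }
  list(metric = metric, log_ratios = lr, mean_log_ratio = mean(lr),
       t = t_stat, p_value = p_val, flags = flags)
}

#' Moment estimate of the founder (bottleneck) size
#'
#' Under multinomial sampling of `k` founder genomes from the source
#' population, the expected recipient diversity is
#' `E[D_rec] = (1 - 1/k) * D_src` for `D` the gene diversity `1 - sum x^2`
#' (and the same first-order law for pi). Inverting gives the moment
#' estimator `k_hat = 1 / (1 - D_rec / D_src)`. When the recipient is at
#' least as diverse as the source the estimate is unbounded (no detectable
#' bottleneck) and `k_hat = Inf` with the `unbounded` flag set.
#'
#' @param source,recipient [viral_population()] objects, or numeric
#'   diversity values when `method = "values"` semantics are wanted via
#'   `d_source` / `d_recipient`.
#' @param method `"gene_diversity_ratio"` (default) or `"pi_ratio"`; the
#'   latter needs `ref` and `amplicon` (or precomputed `d_*` values).
#' @param ref,amplicon Needed for `method = "pi_ratio"` on populations.
#' @param d_source,d_recipient Optional precomputed diversity values that
#'   bypass the population objects.
#' @return Object of class `bottleneck_estimate`: list with `k_hat`,
#'   `unbounded`, `method`, `inputs`.
#' @export
estimate_founders <- function(source = NULL, recipient = NULL,
                              method = c("gene_diversity_ratio", "pi_ratio"),
                              ref = NULL, amplicon = NULL,
                              d_source = NULL, d_recipient = NULL) {
  method <- match.arg(method)
  if (is.null(d_source) || is.null(d_recipient)) {
    stopifnot(inherits(source, "viral_population"),
              inherits(recipient, "viral_population"))
    if (method == "gene_diversity_ratio") {
      d_source <- gene_diversity(source)
      d_recipient <- gene_diversity(recipient)
    } else {
      stopifnot(inherits(ref, "reference_genome"),
                inherits(amplicon, "amplicon_region"))
      d_source <- population_pi(source, ref, amplicon)$pi
      d_recipient <- population_pi(recipient, ref, amplicon)$pi
    }
  }
  if (d_source <= 0) {
    stop("founder size is undefined for a zero-diversity source population")
  }
  r <- d_recipient / d_source
  unbounded <- r >= 1
  k_hat <- if (unbounded) Inf else 1 / (1 - r)
  structure(
    list(k_hat = k_hat, unbounded = unbounded, method = method,
         inputs = c(source = d_source, recipient = d_recipient)),
    class = "bottleneck_estimate"
  )
}

#' @export
print.bottleneck_estimate <- function(x, ...) {
  cat(sprintf("<bottleneck_estimate> k_hat=%s (%s; D_src=%.4g, D_rec=%.4g)\n",
              if (x$unbounded) "unbounded" else sprintf("%.3f", x$k_hat),
              x$method, x$inputs[["source"]], x$inputs[["recipient"]]))
  invisible(x)
}
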