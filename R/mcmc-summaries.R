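# Summaries of posterior tree samples across independent runs: burn-in,
# clade support with Monte-Carlo error, the average standard deviation
# of split frequencies (ASDSF), the Gelman-Rubin potential scale
# reduction factor (PSRF) for scalar traces, and posterior probabilities
# of monophyly hypotheses estimated as constraint frequencies.

#' Discard burn-in from a tree sample
#'
#' Removes the initial `fraction` of samples from every run (ceiling
#' rule: with n samples, the first `ceiling(fraction * n)` are
#' dropped). The default 0.25 discards the initial 25% of samples.
#'
#' @param ts A [tree_sample()].
#' @param fraction Proportion in `[0, 1)` of each run to discard.
#' @return A [tree_sample()] with attribute `burnin_applied = TRUE`.
#' @export
apply_burnin <- function(ts, fraction = 0.25) {
  stopifnot(inherits(ts, "tree_sample"))
  if (fraction < 0 || fraction >= 1)
    stop("burn-in fraction must be in [0, 1)")
  runs <- ts$runs; gens <- ts$generations
  for (i in seq_along(runs)) {
    n <- length(runs[[i]])
    drop <- ceiling(fraction * n)
    if (drop >= n) stop(sprintf("run %d empty after burn-in", i))
    keep <- seq.int(drop + 1L, n)
    runs[[i]] <- runs[[i]][keep]
    gens[[i]] <- gens[[i]][keep]
  }
  out <- tree_sample(runs, gens)
  attr(out, "burnin_applied") <- TRUE
  out
}

# per-run split relative frequencies over the union of observed splits
split_frequencies <- function(ts) {
  per_run <- lapply(ts$runs, function(run) {
    counts <- table(unlist(lapply(run, bipartitions)))
    as.numeric(counts) / length(run) -> f
    setNames(f, names(counts))
  })
  keys <- sort(unique(unlist(lapply(per_run, names))))
  mat <- vapply(per_run, function(f) {
    v <- f[keys]; v[is.na(v)] <- 0; unname(v)
  }, numeric(length(keys)))
  if (length(keys) == 1L) mat <- matrix(mat, nrow = 1L)
  rownames(mat) <- keys
  mat  # splits x runs
}

#' Clade support across independent runs
#'
#' For every split observed in any run: its relative frequency per run,
#' the across-run mean (the reported posterior probability), and the
#' across-run sample standard deviation (the Monte-Carlo error). The
#' `flag_sd` column marks splits whose SD meets the display rule of
#' showing the across-run standard deviation when it is >= `sd_flag`.
#'
#' @param ts A [tree_sample()] with burn-in already applied.
#' @param sd_flag Display threshold for the SD flag (default 0.01).
#' @return A data frame (class `clade_support_table`) with columns
#'   `split`, one `run<i>` frequency per run, `mean_pp`, `sd_pp`
#'   (`NA` for a single run) and `flag_sd`.
#' @export
clade_support <- function(ts, sd_flag = 0.01) {
  stopifnot(inherits(ts, "tree_sample"))
  mat <- split_frequencies(ts)
  nruns <- ncol(mat)
  means <- rowMeans(mat)
  sds <- if (nruns >= 2L) apply(mat, 1L, sd) else rep(NA_real_, nrow(mat))
  out <- data.frame(split = rownames(mat), stringsAsFactors = FALSE)
  for (i in seq_len(nruns)) out[[paste0("run", i)]] <- mat[, i]
  out$mean_pp <- means
  out$sd_pp <- sds
  out$flag_sd <- !is.na(sds) & sds >= sd_flag
  out <- out[order(-out$mean_pp, out$split), ]
  rownames(out) <- NULL
  class(out) <- c("clade_support_table", "data.frame")
  out
}

#' Average standard deviation of split frequencies
#'
#' The standard MCMC topological convergence diagnostic: for every split
#' reaching relative frequency `min_freq` in at least one run, take the
#' across-run sample standard deviation of its frequencies, and average
#' those SDs. Runs drawn from the same posterior give values near zero;
#' values below 0.05 are the customary convergence rule.
#'
#' @param ts A [tree_sample()] with >= 2 runs, burn-in applied.
#' @param min_freq Minimum frequency (default 0.10) a split must reach
#'   in at least one run to be included.
#' @return Non-negative scalar.
#' @export
asdsf <- function(ts, min_freq = 0.10) {
  stopifnot(inherits(ts, "tree_sample"))
  if (length(ts$runs) < 2L) stop("ASDSF needs at least two runs")
  mat <- split_frequencies(ts)
  qual <- apply(mat, 1L, max) >= min_freq
  if (!any(qual)) stop("no splits reach min_freq in any run")
  mean(apply(mat[qual, , drop = FALSE], 1L, sd))
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Classic PSRF for a scalar parameter sampled by m independent runs of
#' length n: with W the mean within-run variance and B the
#' between-run variance (n times the variance of run means),
#' PSRF = sqrt(((n-1)/n * W + B/n) / W). Values near 1 indicate
#' convergence; the customary rule requires < 1.01.
#'
#' @param traces A list of numeric vectors (one per run, equal length),
#'   or a `trace_set` from [read_trace()] together with `parameter`.
#' @param parameter Column name to extract when `traces` is a
#'   `trace_set`.
#' @return Scalar PSRF value (>= ~1).
#' @export
psrf <- function(traces, parameter = NULL) {
  if (inherits(traces, "trace_set")) {
    if (is.null(parameter)) stop("parameter name required for a trace_set")
    traces <- lapply(traces, function(df) df[[parameter]])
  }
  m <- length(traces)
  if (m < 2L) stop("PSRF needs at least two runs")
  n <- unique(vapply(traces, length, 1L))
  if (length(n) != 1L) stop("runs must have equal length")
  if (n < 2L) stop("runs must have length >= 2")
  W <- mean(vapply(traces, var, 1))
  if (W == 0) stop("zero within-run variance")
  B <- n * var(vapply(traces, mean, 1))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior probability of a monophyly hypothesis
#'
#' Estimates the posterior probability that a constraint (required clade
#' plus floating taxa) holds, as the fraction of pooled post-burn-in
#' trees satisfying it, with a binomial Monte-Carlo standard error. When
#' no sampled tree satisfies the constraint the estimate is reported as
#' an upper bound below 1/(N+1).
#'
#' @param ts A [tree_sample()] with burn-in applied.
#' @param constraint A [monophyly_constraint()].
#' @return A list with elements `prob`, `se`, `n_trees`, `n_satisfied`,
#'   `upper_bound` (`NA` unless `n_satisfied` is zero) and a
#'   `format`ted character rendering.
#' @export
hypothesis_posterior <- function(ts, constraint) {
  stopifnot(inherits(ts, "tree_sample"))
  pooled <- do.call(c, lapply(ts$runs, as.list))
  hits <- vapply(pooled, satisfies_constraint, TRUE, constraint = constraint)
  n <- length(hits); k <- sum(hits)
  p <- k / n
  se <- sqrt(p * (1 - p) / n)
  ub <- if (k == 0L) 1 / (n + 1) else NA_real_
  fmt <- if (k == 0L) sprintf("< %.4g", ub) else sprintf("%.4g +/- %.2g", p, se)
  list(prob = p, se = se, n_trees = n, n_satisfied = k,
       upper_bound = ub, format = fmt)
}
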