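# Population-coding statistics: kurtosis sparseness index, adjacency /
# uniqueness curves, and log-log rate correlations.

#' Kurtosis sparseness index of a spike-rate matrix
#'
#' For each target electrode i, the spike rates it shows across stimulation
#' sites are standardised by their own mean and (population) SD; the excess
#' kurtosis `mean(z^4) - 3` is computed per electrode and averaged over
#' electrodes:
#' `K = (1/Ne) * sum_i [ (1/Nstim) * sum_j ((SR[j,i] - mu_i)/sigma_i)^4 - 3 ]`.
#' The per-electrode subtraction of 3 makes K zero for Gaussian-distributed
#' rates.  Large K means electrodes are strongly driven by few sites and
#' quiet otherwise -- a sparse code.  Electrodes with zero rate variance are
#' excluded (the standardisation is undefined) and counted; masked cells
#' are excluded from the per-electrode moments.
#'
#' @param sr spike-rate matrix, stimulation sites in rows, electrodes in
#'   columns (`NA` = masked).
#' @return List of class `kurtosis_result`: `K`, `per_electrode`
#'   (named excess-kurtosis contributions), `n_excluded_degenerate`,
#'   `n_e_effective`.
#' @examples
#' sr <- matrix(rnorm(22 * 200, 50, 5), 200, 22)
#' kurtosis_sparseness(sr)$K   # near 0: Gaussian rates are not sparse
#' @export
kurtosis_sparseness <- function(sr) {
  sr <- as.matrix(sr)
  if (nrow(sr) < 2) stop("need at least 2 stimulation sites")
  contrib <- vapply(seq_len(ncol(sr)), function(i) {
    x <- sr[, i]
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    mu <- mean(x)
    sig <- sqrt(mean((x - mu)^2))     # population SD, moment form
    if (sig == 0) return(NA_real_)
    mean(((x - mu) / sig)^4) - 3
  }, numeric(1))
  names(contrib) <- colnames(sr)
  degenerate <- is.na(contrib)
  if (all(degenerate))
    stop("all electrodes have zero rate variance; kurtosis undefined")
  structure(list(K = mean(contrib[!degenerate]),
                 per_electrode = contrib,
                 n_excluded_degenerate = sum(degenerate),
                 n_e_effective = sum(!degenerate)),
            class = "kurtosis_result")
}

#' Top-n adjacency matrix of a spike-rate matrix
#'
#' For each stimulation site (row), marks with 1 the electrodes holding the
#' `n_highest` largest spike rates; any electrode tied with the n-th value
#' is also marked (ties expand the selection, so a row can carry more than
#' `n_highest` marks).  Under `"exclude_zeros"`, zero-rate electrodes are
#' never marked, even if that leaves fewer than `n_highest` marks.  Masked
#' (`NA`) cells are treated as absent, not zero.
#'
#' @param sr spike-rate matrix (sites x electrodes).
#' @param n_highest selection depth n, 1..number of electrodes.
#' @param zero_policy `"include_zeros"` (zeros rank and tie like any value)
#'   or `"exclude_zeros"`.
#' @return Binary matrix of class `adjacency_matrix` with attributes
#'   `n_highest` and `zero_policy`.
#' @examples
#' sr <- rbind(c(5, 3, 0, 0))
#' build_adjacency(sr, 3, "include_zeros")   # 1 1 1 1 (zeros tie at rank 3)
#' build_adjacency(sr, 3, "exclude_zeros")   # 1 1 0 0
#' @export
build_adjacency <- function(sr, n_highest,
                            zero_policy = c("include_zeros", "exclude_zeros")) {
  zero_policy <- match.arg(zero_policy)
  sr <- as.matrix(sr)
  ne <- ncol(sr)
  if (n_highest < 1 || n_highest > ne)
    stop("n_highest must lie in 1..", ne)
  A <- matrix(0L, nrow(sr), ne, dimnames = dimnames(sr))
  for (j in seq_len(nrow(sr))) {
    v <- sr[j, ]
    eligible <- !is.na(v)
    if (zero_policy == "exclude_zeros") eligible <- eligible & (v > 0)
    vals <- v[eligible]
    if (!length(vals)) next
    k <- min(n_highest, length(vals))
    nth <- sort(vals, decreasing = TRUE)[k]
    A[j, eligible & (v >= nth)] <- 1L
  }
  structure(A, n_highest = n_highest, zero_policy = zero_policy,
            class = c("adjacency_matrix", class(A)))
}

#' Per-electrode uniqueness indices
#'
#' From an adjacency matrix (sites x electrodes), the uniqueness of
#' electrode i with column sum s is `1 - (s - 1) / (Nstim - 1)` when
#' `s > 0` and 0 otherwise: 1 means the electrode is selected for exactly
#' one stimulation site, 0 for all sites (or none).
#'
#' @param A an [build_adjacency()] matrix (or any binary sites x electrodes
#'   matrix).
#' @return Named numeric vector of indices in `[0, 1]`.
#' @examples
#' A <- matrix(0L, 22, 1); A[1:2, 1] <- 1L
#' uniqueness_indices(A)    # 1 - (2-1)/(22-1) = 0.952...
#' @export
uniqueness_indices <- function(A) {
  A <- as.matrix(A)
  n_stim <- nrow(A)
  if (n_stim < 2) stop("need at least 2 stimulation sites")
  s <- colSums(A)
  ifelse(s == 0, 0, 1 - (s - 1) / (n_stim - 1))
}

#' Regional uniqueness
#'
#' The mean of the per-electrode uniqueness indices over all target
#' electrodes (zeros included), as a percentage.
#'
#' @param u vector of [uniqueness_indices()].
#' @return Scalar percentage in `[0, 100]`.
#' @export
regional_uniqueness <- function(u) {
  if (!length(u)) stop("need at least 1 electrode")
  mean(u) * 100
}

#' Uniqueness curve of a spike-rate matrix
#'
#' Sweeps the selection depth n from 1 to the number of electrodes,
#' computing the regional uniqueness of the top-n adjacency at each depth.
#' The peak (smallest n attaining the maximum) gives the number of most
#' active target electrodes that optimally specifies the stimulation site.
#' Including zeros drives the curve to 0 at n = Ne (every electrode is then
#' selected for every site); excluding zeros produces a plateau once n
#' exceeds the number of nonzero rates per site.
#'
#' @param sr spike-rate matrix (sites x electrodes).
#' @param zero_policy `"include_zeros"` or `"exclude_zeros"`.
#' @return List of class `uniqueness_curve`: `n`, `pct_u`, `peak_n`,
#'   `peak_value`, `zero_policy`.
#' @export
uniqueness_curve <- function(sr,
                             zero_policy = c("include_zeros", "exclude_zeros")) {
  zero_policy <- match.arg(zero_policy)
  sr <- as.matrix(sr)
  ne <- ncol(sr)
  pct <- vapply(seq_len(ne), function(n)
    regional_uniqueness(uniqueness_indices(build_adjacency(sr, n, zero_policy))),
    numeric(1))
  peak_n <- which.max(pct)    # smallest n attaining the max
  structure(list(n = seq_len(ne), pct_u = pct,
                 peak_n = peak_n, peak_value = pct[peak_n],
                 zero_policy = zero_policy),
            class = "uniqueness_curve")
}

#' Pearson correlation of log-transformed rate pairs
#'
#' Correlates two paired rate aggregates on log10 scale (the mass-action
#' relation between a source region's drive and tunnel transmission is
#' linear on log-log axes).  Pairs with a non-positive member are dropped
#' and counted.
#'
#' @param x,y paired positive rate aggregates (e.g. per-site regional
#'   means and per-site tunnel means).
#' @return List of class `loglog_correlation`: `r`, `p`, `n_pairs`,
#'   `n_dropped`.
#' @export
loglog_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(keep) < 3) stop("fewer than 3 usable positive pairs")
  ct <- cor.test(log10(x[keep]), log10(y[keep]))
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n_pairs = sum(keep), n_dropped = sum(!keep)),
            class = "loglog_correlation")
}

#' @export
print.kurtosis_result <- function(x, ...) {
  cat(sprintf("<kurtosis_result> K = %.3f over %d electrodes (%d degenerate excluded)\n",
              x$K, x$n_e_effective, x$n_excluded_degenerate))
  invisible(x)
}

#' @export
print.uniqueness_curve <- function(x, ...) {
  cat(sprintf("<uniqueness_curve> %s: peak %%U = %.1f%% at n = %d (of %d)\n",
              x$zero_policy, x$peak_value, x$peak_n, max(x$n)))
  invisible(x)
}

#' @export
plot.uniqueness_curve <- function(x, ...) {
  plot(x$n, x$pct_u, type = "b", pch = 16, ylim = c(0, 100),
       xlab = "n highest spike rates", ylab = "regional uniqueness %U",
       main = x$zero_policy, ...)
  points(x$peak_n, x$peak_value, col = "red", pch = 1, cex = 2)
  invisible(x)
}

#' @export
print.loglog_correlation <- function(x, ...) {
  cat(sprintf("<loglog_correlation> r = %.2f (p = %.3g, n = %d, %d dropped)\n",
              x$r, x$p, x$n_pairs, x$n_dropped))
  invisible(x)
}
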