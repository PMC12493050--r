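# MCMC convergence diagnostics: rank-normalized split Gelman-Rubin statistic
# and tail effective sample size, following the rank-normalization /
# folding definitions of Vehtari et al. (2021).

# draws matrix (iterations x chains) -> split each chain in half
split_chains <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  m <- m[seq_len(2 * half), , drop = FALSE]
  cbind(m[seq_len(half), , drop = FALSE],
        m[half + seq_len(half), , drop = FALSE])
}

rank_normalize <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

rhat_basic <- function(m) {
  n <- nrow(m); mch <- ncol(m)
  if (n < 2 || mch < 2) return(NA_real_)
  means <- colMeans(m)
  vars <- apply(m, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W < .Machine$double.eps) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

as_draws_matrix <- function(samples, parameter = NULL) {
  if (inherits(samples, "rlddm_fit")) {
    if (is.null(parameter)) stop("parameter must be given for a fit object")
    return(posterior_draws(samples, parameter))
  }
  m <- as.matrix(samples)
  storage.mode(m) <- "double"
  m
}

#' Rank-normalized split R-hat
#'
#' Each chain is split in half, the pooled draws are rank-normalized (normal
#' quantiles of fractional ranks) and the classic between/within variance
#' ratio computed; the statistic is the maximum of the bulk version and the
#' folded version (absolute deviations from the median), so it is sensitive
#' to both location and scale disagreement between chains.  Values below
#' 1.01 are the conventional acceptance threshold.
#'
#' @param samples an `rlddm_fit` or a draws matrix (iterations x chains).
#' @param parameter parameter name when `samples` is a fit.
#' @return the split R-hat (>= ~1; `NA` for degenerate input).
#' @examples
#' m <- matrix(rnorm(4000), 1000, 4)
#' split_rhat(m) < 1.01
#' @export
split_rhat <- function(samples, parameter = NULL) {
  m <- as_draws_matrix(samples, parameter)
  if (ncol(m) < 2) stop("split_rhat needs at least 2 chains")
  if (nrow(m) < 4) stop("split_rhat needs at least 4 draws per chain")
  sm <- split_chains(m)
  bulk <- rhat_basic(rank_normalize(sm))
  folded <- rhat_basic(rank_normalize(abs(sm - median(sm))))
  max(bulk, folded)
}

# multi-chain effective sample size (Geyer initial monotone sequence),
# operating on split chains
ess_basic <- function(m) {
  sm <- split_chains(m)
  n <- nrow(sm); nch <- ncol(sm)
  if (n < 4) return(NA_real_)
  vars <- apply(sm, 2, var)
  W <- mean(vars)
  if (W < .Machine$double.eps) return(0)
  B <- n * var(colMeans(sm))
  var_plus <- (n - 1) / n * W + B / n
  # per-chain autocovariance via FFT (biased, 1/n normalization)
  L <- 2^ceiling(log2(2 * n))
  acov <- vapply(seq_len(nch), function(j) {
    x <- sm[, j] - mean(sm[, j])
    f <- fft(c(x, rep(0, L - n)))
    Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (L * n)
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotonicity
  max_pairs <- floor((n - 2) / 2)
  # pair sums P_t = rho(2t) + rho(2t+1), t >= 0 (1-based indexing below)
  psum <- c()
  t <- 1
  while (t + 1 <= n) {
    p <- rho[t] + rho[t + 1]
    if (p <= 0 && t > 1) break
    psum <- c(psum, p)
    t <- t + 2
    if (length(psum) > max_pairs) break
  }
  if (length(psum) > 1)
    psum <- cummin(psum)  # initial monotone sequence
  tau <- max(-1 + 2 * sum(psum), 1 / log10(n * nch + 10))
  min(n * nch / tau, n * nch * log10(n * nch))
}

#' Tail effective sample size
#'
#' Effective sample size of the 5% and 95% quantile indicator transforms
#' (computed on split chains with Geyer's initial monotone sequence
#' estimator); the minimum of the two is reported.  Values above 400 are the
#' conventional acceptance threshold.  Constant chains return 0.
#'
#' @inheritParams split_rhat
#' @return the tail-ESS (0 for degenerate draws).
#' @examples
#' m <- matrix(rnorm(4000), 1000, 4)
#' tail_ess(m) > 400
#' @export
tail_ess <- function(samples, parameter = NULL) {
  m <- as_draws_matrix(samples, parameter)
  if (ncol(m) < 2) stop("tail_ess needs at least 2 chains")
  if (nrow(m) < 4) stop("tail_ess needs at least 4 draws per chain")
  if (sd(m) < .Machine$double.eps) return(0)
  ess_q <- function(p) {
    q <- quantile(as.vector(m), p, names = FALSE)
    ess_basic(matrix(as.numeric(m <= q), nrow(m), ncol(m)))
  }
  min(ess_q(0.05), ess_q(0.95))
}

#' Per-parameter convergence diagnostics of a fit
#'
#' @param fit an `rlddm_fit`.
#' @return data frame: `parameter`, `split_rhat`, `tail_ess`.
#' @export
fit_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "rlddm_fit"))
  pars <- dimnames(fit$draws)[[3]]
  data.frame(
    parameter = pars,
    split_rhat = vapply(pars, function(p) split_rhat(fit, p), 0),
    tail_ess = vapply(pars, function(p) tail_ess(fit, p), 0),
    row.names = NULL
  )
}

#' Refuse a non-converged posterior
#'
#' Downstream analyses call this gate; it errors when the fit violates the
#' acceptance rule (max split R-hat < 1.01, min tail-ESS > 400) unless
#' explicitly overridden.
#'
#' @param fit an `rlddm_fit`.
#' @param override proceed despite failed diagnostics.
#' @return the fit, invisibly.
#' @export
assert_converged <- function(fit, override = FALSE) {
  stopifnot(inherits(fit, "rlddm_fit"))
  if (!isTRUE(fit$converged) && !override)
    stop("posterior failed convergence diagnostics; pass override = TRUE ",
         "to proceed anyway")
  invisible(fit)
}
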