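# Convergence diagnostics for MCMC draws stored as an iterations x chains
# matrix: split Gelman-Rubin R-hat and rank-normalized bulk/tail effective
# sample sizes (Vehtari et al. 2021 formulation). Chains are split in half
# so within-chain trends inflate R-hat as they should.

split_chain_matrix <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2L) stop("too few draws to split chains")
  lower <- draws[seq_len(half), , drop = FALSE]
  upper <- draws[seq.int(n - half + 1L, n), , drop = FALSE]
  cbind(lower, upper)
}

rank_normalize <- function(draws) {
  z <- qnorm((rank(draws) - 3 / 8) / (length(draws) + 1 / 4))
  matrix(z, nrow = nrow(draws), ncol = ncol(draws))
}

rhat_basic <- function(draws) {
  m <- ncol(draws); n <- nrow(draws)
  chain_means <- colMeans(draws)
  chain_vars <- apply(draws, 2, var)
  w <- mean(chain_vars)
  b <- n * var(chain_means)
  if (w < .Machine$double.eps) return(1)
  sqrt((w * (n - 1) / n + b / n) / w)
}

#' Split R-hat of one parameter
#'
#' Rank-normalized split Gelman-Rubin statistic. Values near 1 indicate
#' the chains agree; values above about 1.01 indicate non-convergence.
#'
#' @param draws Iterations-by-chains numeric matrix (>= 2 chains).
#' @return Scalar R-hat.
#' @export
split_rhat <- function(draws) {
  draws <- split_chain_matrix(draws)
  if (all(abs(draws - draws[1]) < .Machine$double.eps)) return(1)
  max(rhat_basic(rank_normalize(draws)),
      rhat_basic(rank_normalize(abs(draws - median(draws)))))
}

# effective sample size of split chains via Geyer's initial monotone
# positive sequence on the chain-averaged autocorrelations
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  chain_vars <- apply(draws, 2, var)
  w <- mean(chain_vars)
  if (w < .Machine$double.eps) return(NA_real_)
  acov <- sapply(seq_len(m), function(j) {
    if (chain_vars[j] < .Machine$double.eps) return(numeric(n))
    x <- draws[, j] - mean(draws[, j])
    f <- stats::fft(c(x, rep(0, n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (2 * n)
    ac / ac[1] * chain_vars[j] * (n - 1) / n
  })
  mean_var <- w * (n - 1) / n
  var_plus <- mean_var + if (m > 1) var(colMeans(draws)) else 0
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  # Geyer initial monotone positive sequence on paired autocorrelations
  # Gamma_k = rho_{2k} + rho_{2k+1}: stop at the first negative pair,
  # then enforce a monotone decrease; tau = 2 * sum(Gamma) - rho_0
  pair_sums <- numeric(0)
  k <- 0L
  while (2L * k + 2L <= n) {
    ps <- rho[2L * k + 1L] + rho[2L * k + 2L]
    if (ps < 0 && k > 0L) break
    pair_sums <- c(pair_sums, ps)
    k <- k + 1L
  }
  pair_sums <- cummin(pair_sums)
  tau <- max(2 * sum(pair_sums) - rho[1], 1 / log10(n * m))
  min(n * m / tau, n * m * log10(n * m))
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalized split chains; measures sampling efficiency
#' in the bulk of the posterior.
#'
#' @param draws Iterations-by-chains numeric matrix.
#' @return Scalar ESS.
#' @export
ess_bulk <- function(draws) {
  draws <- split_chain_matrix(draws)
  if (all(abs(draws - draws[1]) < .Machine$double.eps)) return(NA_real_)
  ess_basic(rank_normalize(draws))
}

#' Tail effective sample size
#'
#' Minimum of the ESS of the 5% and 95% quantile indicator chains;
#' measures how well the tails are explored.
#'
#' @param draws Iterations-by-chains numeric matrix.
#' @return Scalar ESS.
#' @export
ess_tail <- function(draws) {
  draws <- split_chain_matrix(draws)
  if (all(abs(draws - draws[1]) < .Machine$double.eps)) return(NA_real_)
  q <- quantile(draws, c(0.05, 0.95), names = FALSE)
  ess_q <- function(cut) {
    ind <- matrix(as.numeric(draws <= cut), nrow = nrow(draws))
    if (var(as.vector(ind)) == 0) return(NA_real_)
    ess_basic(ind)
  }
  min(ess_q(q[1]), ess_q(q[2]), na.rm = TRUE)
}
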