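# GTR+I+Gamma substitution model: rate matrix, discrete-gamma categories,
# per-branch transition-probability blocks.

NUC <- c("A", "C", "G", "T")
EXCH_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' GTR+I+Gamma model parameters
#'
#' Bundles the six exchangeabilities, four base frequencies, proportion of
#' invariable sites and gamma shape into a validated parameter object.
#' Branch lengths are in expected substitutions per site, so the rate matrix
#' built from these parameters is normalized to unit mean rate.
#'
#' @param exch Six positive exchangeabilities in order AC, AG, AT, CG, CT,
#'   GT. Rescaled internally to sum to 1 (only the ratios matter).
#' @param freqs Base frequencies (A, C, G, T); must sum to 1.
#' @param pinvar Proportion of invariable sites, in `[0, 1)`.
#' @param alpha Gamma shape of among-site rate variation; positive.
#' @param ncat Number of discrete gamma rate categories (default 4, the
#'   value the per-site storage accounting assumes).
#' @return An object of class `gtr_params`.
#' @examples
#' gtr_params()                      # Jukes-Cantor-like defaults
#' gtr_params(alpha = 0.5, pinvar = 0.2)
#' @export
gtr_params <- function(exch = rep(1, 6), freqs = rep(0.25, 4),
                       pinvar = 0, alpha = 1, ncat = 4L) {
  exch <- as.numeric(exch); freqs <- as.numeric(freqs)
  if (length(exch) != 6L || any(!is.finite(exch)) || any(exch <= 0))
    stop("parameter error: need 6 positive exchangeabilities")
  if (length(freqs) != 4L || any(!is.finite(freqs)) || any(freqs <= 0))
    stop("parameter error: need 4 positive base frequencies")
  if (abs(sum(freqs) - 1) > 1e-12)
    stop("parameter error: base frequencies must sum to 1")
  if (!is.finite(pinvar) || pinvar < 0 || pinvar >= 1)
    stop("parameter error: pinvar must lie in [0, 1)")
  if (!is.finite(alpha) || alpha <= 0)
    stop("parameter error: alpha must be positive")
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("parameter error: ncat must be >= 1")
  structure(
    list(exch = setNames(exch / sum(exch), EXCH_NAMES),
         freqs = setNames(freqs, NUC),
         pinvar = pinvar, alpha = alpha, ncat = ncat),
    class = "gtr_params")
}

#' @export
print.gtr_params <- function(x, ...) {
  cat("GTR+I+Gamma parameters\n")
  cat("  exch:  ", paste(sprintf("%s=%.4f", EXCH_NAMES, x$exch), collapse = " "), "\n")
  cat("  freqs: ", paste(sprintf("%s=%.4f", NUC, x$freqs), collapse = " "), "\n")
  cat(sprintf("  pinvar=%.4f  alpha=%.4f  ncat=%d\n", x$pinvar, x$alpha, x$ncat))
  invisible(x)
}

#' Build the normalized GTR rate matrix
#'
#' Off-diagonals are `q_ij = exch(i,j) * pi_j`; the diagonal makes rows sum
#' to zero and the matrix is rescaled so the mean substitution rate at
#' stationarity, `-sum_i pi_i q_ii`, equals 1. The construction is time
#' reversible: `pi_i q_ij = pi_j q_ji`.
#'
#' @param params A [gtr_params()] object.
#' @return 4x4 numeric matrix of class `rate_matrix` (states A, C, G, T).
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "gtr_params"))
  r <- params$exch; pi <- params$freqs
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  k <- 0L
  for (i in 1:3) for (j in (i + 1):4) {
    k <- k + 1L
    Q[i, j] <- r[k] * pi[j]
    Q[j, i] <- r[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  structure(Q / mu, class = c("rate_matrix", "matrix"))
}

#' Discrete-gamma rate categories
#'
#' Mean rates of `ncat` equal-probability slices of a Gamma(alpha, alpha)
#' distribution (mean-of-slices discretization; the returned rates average
#' to 1 exactly).
#'
#' @param alpha Positive gamma shape.
#' @param ncat Number of categories.
#' @return Numeric vector of `ncat` category rates.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("parameter error: alpha must be positive")
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("parameter error: ncat must be >= 1")
  if (ncat == 1L) return(1)
  # mean of a slice [a,b] of Gamma(shape = alpha, rate = alpha) equals the
  # probability mass of [a,b] under Gamma(shape = alpha + 1, rate = alpha),
  # divided by the slice probability 1/ncat
  q <- qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha, rate = alpha)
  p <- pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- ncat * diff(p)
  rates / mean(rates)  # remove rounding drift; mean is 1 analytically
}

# Eigen-system of the reversible Q for fast transition probabilities.
# Q = D^-1/2 B D^1/2 with B symmetric, so P(t) = C1 exp(Lambda t) C2 with
# C1 = D^-1/2 V, C2 = V' D^1/2.
rate_matrix_eigen <- function(Q, freqs) {
  sp <- sqrt(freqs)
  B <- diag(sp) %*% unclass(Q) %*% diag(1 / sp)
  B <- (B + t(B)) / 2  # symmetrize away rounding noise
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       C1 = diag(1 / sp) %*% e$vectors,
       C2 = t(e$vectors) %*% diag(sp))
}

#' Per-branch transition-probability block
#'
#' Computes the stacked transition matrices `P(r_k * t) = exp(Q r_k t)` for
#' each rate category, via eigendecomposition of the symmetrized reversible
#' rate matrix. At `ncat = 4` the block holds 64 values (4 categories x 16).
#'
#' @param params A [gtr_params()] object (supplies Q and the category rates),
#'   or a `rate_matrix` together with explicit `rates`.
#' @param t Branch length (expected substitutions per site), `>= 0`.
#' @param rates Optional category rates; defaults to
#'   `discrete_gamma_rates(params$alpha, params$ncat)` when `params` is a
#'   `gtr_params`, or a single rate 1 for a bare rate matrix.
#' @param freqs Stationary frequencies; required when `params` is a bare
#'   `rate_matrix`.
#' @return Numeric array `c(4, 4, ncat)` of class `transition_block`; rows of
#'   each slice sum to 1.
#' @export
transition_block <- function(params, t, rates = NULL, freqs = NULL) {
  if (!is.finite(t) || t < 0) stop("parameter error: branch length must be >= 0")
  if (inherits(params, "gtr_params")) {
    Q <- build_rate_matrix(params)
    freqs <- params$freqs
    if (is.null(rates)) rates <- discrete_gamma_rates(params$alpha, params$ncat)
  } else {
    Q <- params
    if (is.null(freqs)) stop("freqs required with a bare rate matrix")
    if (is.null(rates)) rates <- 1
  }
  es <- rate_matrix_eigen(Q, freqs)
  ncat <- length(rates)
  P <- array(0, c(4, 4, ncat), dimnames = list(NUC, NUC, NULL))
  for (k in seq_len(ncat)) {
    Pk <- es$C1 %*% (exp(es$values * rates[k] * t) * es$C2)
    Pk[Pk < 0] <- 0  # clamp eigen round-off
    P[, , k] <- Pk / rowSums(Pk)
  }
  structure(P, class = "transition_block")
}
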