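# Independent reference implementations used as oracles. These share no
# code with the package's evaluators: transition probabilities come from
# Matrix::expm (scaling-and-squaring), rate categories from numerical
# quadrature, and likelihoods either from plain linear-domain pruning in R
# (no scalers) or from exhaustive enumeration of ancestral states.

# GTR rate matrix built independently (same parameterization, other code)
oracle_Q <- function(exch, freqs) {
  Q <- matrix(0, 4, 4)
  Q[lower.tri(Q)] <- 0
  k <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    k <- k + 1
    Q[i, j] <- exch[k] * freqs[j]
    Q[j, i] <- exch[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(freqs * -diag(Q))
}

oracle_pmat <- function(Q, t) {
  as.matrix(Matrix::expm(Q * t))
}

# mean rates of equal-probability gamma slices by adaptive quadrature
oracle_gamma_rates <- function(alpha, ncat) {
  q <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  sapply(seq_len(ncat), function(k) {
    ncat * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                     q[k], q[k + 1], rel.tol = 1e-12)$value
  })
}

mask_bits <- function(mask) which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)

# plain linear-domain pruning without any rescaling machinery, operating on
# ape's edge matrix directly
oracle_pruning_loglik <- function(phy, enc, params, weights = NULL) {
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    phy <- ape::multi2di(phy, random = FALSE)
  n <- length(phy$tip.label)
  enc <- enc[phy$tip.label, , drop = FALSE]
  L <- ncol(enc)
  if (is.null(weights)) weights <- rep(1L, L)
  ncat <- params$ncat
  rates <- oracle_gamma_rates(params$alpha, ncat)
  Q <- oracle_Q(params$exch, params$freqs)
  pi <- as.numeric(params$freqs)
  po <- ape::reorder.phylo(phy, "postorder")
  lnl <- numeric(L)
  for (l in seq_len(L)) {
    mix <- 0
    for (k in seq_len(ncat)) {
      cl <- matrix(0, 4, 2 * n - 1)
      for (i in seq_len(n)) cl[mask_bits(enc[i, l]), i] <- 1
      done <- c(rep(TRUE, n), rep(FALSE, n - 1))
      cl2 <- cl
      for (e in seq_len(nrow(po$edge))) {
        par <- po$edge[e, 1]; ch <- po$edge[e, 2]
        P <- oracle_pmat(Q, rates[k] * po$edge.length[e])
        v <- as.numeric(P %*% cl2[, ch])
        if (!done[par]) { cl2[, par] <- v; done[par] <- TRUE }
        else cl2[, par] <- cl2[, par] * v
      }
      mix <- mix + sum(pi * cl2[, n + 1]) / ncat
    }
    am <- Reduce(bitwAnd, enc[, l])
    inv <- sum(pi[mask_bits(am)])
    lnl[l] <- log((1 - params$pinvar) * mix + params$pinvar * inv)
  }
  sum(weights * lnl)
}

# exhaustive enumeration over all ancestral-state assignments (vectorized
# over the assignment grid); usable up to ~6 taxa
oracle_enum_loglik <- function(phy, enc, params, weights = NULL) {
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    phy <- ape::multi2di(phy, random = FALSE)
  n <- length(phy$tip.label)
  enc <- enc[phy$tip.label, , drop = FALSE]
  L <- ncol(enc)
  if (is.null(weights)) weights <- rep(1L, L)
  ncat <- params$ncat
  rates <- oracle_gamma_rates(params$alpha, ncat)
  Q <- oracle_Q(params$exch, params$freqs)
  pi <- as.numeric(params$freqs)
  nint <- n - 1
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))  # cols: nodes n+1..2n-1
  lnl <- numeric(L)
  for (l in seq_len(L)) {
    mix <- 0
    for (k in seq_len(ncat)) {
      tot <- rep(pi[grid[, 1]], 1)  # root = node n+1 = column 1
      for (e in seq_len(nrow(phy$edge))) {
        par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
        P <- oracle_pmat(Q, rates[k] * phy$edge.length[e])
        gp <- grid[, par - n]
        tot <- tot * if (ch <= n) {
          bits <- mask_bits(enc[ch, l])
          rowSums(matrix(P[gp, bits], ncol = length(bits)))
        } else P[cbind(gp, grid[, ch - n])]
      }
      mix <- mix + sum(tot) / ncat
    }
    am <- Reduce(bitwAnd, enc[, l])
    inv <- sum(pi[mask_bits(am)])
    lnl[l] <- log((1 - params$pinvar) * mix + params$pinvar * inv)
  }
  sum(weights * lnl)
}

# random valid model parameters
rand_params <- function(alpha_range = c(0.3, 2), pinvar_max = 0.4) {
  f <- rgamma(4, 10); f <- f / sum(f)
  gtr_params(exch = runif(6, 0.3, 3), freqs = f,
             pinvar = runif(1, 0, pinvar_max),
             alpha = runif(1, alpha_range[1], alpha_range[2]))
}

# random fixture: tree + encoded data drawn column-wise at random (not
# simulated under the model, so the oracle comparison is not tied to the
# simulator), with a few ambiguity codes sprinkled in
rand_fixture <- function(n_taxa, n_patterns, amb = 0.1) {
  phy <- random_tree(n_taxa, branch_fn = function(n) runif(n, 0.01, 0.6))
  enc <- matrix(sample(c(1L, 2L, 4L, 8L), n_taxa * n_patterns, TRUE),
                n_taxa, dimnames = list(phy$tip.label, NULL))
  namb <- rbinom(1, length(enc), amb)
  if (namb > 0)
    enc[sample(length(enc), namb)] <- sample(c(3L, 5L, 10L, 15L), namb, TRUE)
  weights <- sample(1:5, n_patterns, TRUE)
  list(tree = phy, enc = enc, weights = weights,
       cp = compress_patterns(enc[, rep(seq_len(n_patterns), weights),
                                  drop = FALSE]))
}

rel_err <- function(a, b) abs(a - b) / pmax(1, abs(b))
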