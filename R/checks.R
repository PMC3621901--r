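# Built-in verification suites: the cross-implementation and invariance
# oracles bundled so they can be run from the command line (`check`
# subcommand) as a self-test of an installation.

# Exhaustive ancestral-state enumeration: sums the likelihood over all
# internal-node state assignments. Exponential in the number of internal
# nodes; only usable on small fixtures, which is the point -- it shares no
# code path with the pruning engines.
enum_loglik <- function(tree, data, params) {
  prep <- prepare_eval(tree, data, params)
  tr <- prep$tr
  n <- tr$n_tip
  ints <- tr$postorder
  nint <- length(ints)
  rates <- prep$rates
  ncat <- length(rates)
  pi <- as.numeric(params$freqs)
  Pm <- lapply(seq_len(2L * n - 1L), function(v) {
    if (v == tr$root) return(NULL)
    lapply(seq_len(ncat), function(k) {
      P <- prep$es$C1 %*% (exp(prep$es$values * rates[k] * tr$elen[v]) *
                             prep$es$C2)
      P[P < 0] <- 0
      P
    })
  })
  L <- length(prep$weights)
  masks <- prep$patterns
  lnl <- numeric(L)
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  for (l in seq_len(L)) {
    mix <- 0
    for (k in seq_len(ncat)) {
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(2L * n - 1L)
        st[ints] <- grid[g, ]
        pr <- pi[st[tr$root]]
        for (v in ints) for (ci in 1:2) {
          ch <- tr$child[ci, v]
          if (ch <= n) {
            bits <- which(bitwAnd(masks[ch, l], c(1L, 2L, 4L, 8L)) > 0L)
            pr <- pr * sum(Pm[[ch]][[k]][st[v], bits])
          } else pr <- pr * Pm[[ch]][[k]][st[v], st[ch]]
        }
        tot <- tot + pr
      }
      mix <- mix + tot / ncat
    }
    am <- Reduce(bitwAnd, masks[, l])
    inv <- sum(pi[which(bitwAnd(am, c(1L, 2L, 4L, 8L)) > 0L)])
    lnl[l] <- log((1 - params$pinvar) * mix + params$pinvar * inv)
  }
  sum(prep$weights * lnl)
}

check_fixture <- function(n_taxa, n_columns, seed, alpha = 0.7, pinvar = 0.15) {
  set.seed(seed)
  e <- runif(6, 0.5, 2)
  f <- rdirichlet1(rep(10, 4))
  pars <- gtr_params(e, f, pinvar = pinvar, alpha = alpha)
  sim <- simulate_alignment(sim_spec(n_taxa = n_taxa, n_columns = n_columns,
                                     params = pars))
  list(tree = sim$truth$tree, data = sim$alignment, params = pars)
}

#' Run the built-in verification suites
#'
#' Cross-checks the fused evaluator against its independent oracles:
#' exhaustive ancestral-state enumeration on small fixtures, root-placement
#' invariance (pulley principle), scaler-policy invariance, state-major vs
#' site-major layout equality, fused vs multipass agreement, and the
#' transfer-ledger closed forms.
#'
#' @param suites Which suites to run (default all): subset of
#'   `"brute_force"`, `"pulley"`, `"scaling"`, `"layout"`,
#'   `"fused_multipass"`, `"ledger"`.
#' @param n_fixtures Random fixtures per suite (default 10).
#' @param seed Seed for fixture generation.
#' @param perturb Internal validation hook: a nonzero value perturbs one
#'   transition-matrix entry in the fused evaluator only, which must make
#'   the `fused_multipass` suite fail.
#' @return Data frame with columns `suite`, `pass`, `max_err`; attribute
#'   `"ok"` is `TRUE` when every suite passed.
#' @export
run_checks <- function(suites = c("brute_force", "pulley", "scaling",
                                  "layout", "fused_multipass", "ledger"),
                       n_fixtures = 10L, seed = 1L, perturb = 0) {
  suites <- match.arg(suites, several.ok = TRUE)
  res <- list()
  rel <- function(a, b) abs(a - b) / pmax(1, abs(b))
  for (s in suites) {
    errs <- numeric(0)
    ok <- TRUE
    for (i in seq_len(n_fixtures)) {
      fx <- check_fixture(n_taxa = if (s == "brute_force") 4L + i %% 3L else 6L + i,
                          n_columns = if (s == "brute_force") 12L else 60L,
                          seed = seed * 1000L + i)
      lf <- phylo_loglik(fx$tree, fx$data, fx$params)
      err <- switch(s,
        brute_force = rel(lf, enum_loglik(fx$tree, fx$data, fx$params)),
        pulley = {
          phy2 <- ape::root(ape::unroot(fx$tree),
                            outgroup = fx$tree$tip.label[2L],
                            resolve.root = TRUE)
          rel(lf, phylo_loglik(phy2, fx$data, fx$params))
        },
        scaling = max(rel(lf, phylo_loglik(fx$tree, fx$data, fx$params,
                                           scaler_policy = "none")),
                      rel(lf, phylo_loglik(fx$tree, fx$data, fx$params,
                                           scaler_policy = "every_k"))),
        layout = rel(phylo_loglik(fx$tree, fx$data, fx$params,
                                  layout = "state_major"),
                     phylo_loglik(fx$tree, fx$data, fx$params,
                                  layout = "site_major")),
        fused_multipass = {
          prep <- prepare_eval(fx$tree, fx$data, fx$params)
          st <- new_scaler_state(prep$tr, length(prep$weights))
          sn <- scaler_node_flags(prep$tr, "all")
          f <- eval_engine(prep, st, sn, fx$params, mode = 0L,
                           perturb = perturb)$loglik
          rel(f, evaluate_multipass(fx$tree, fx$data, fx$params)$loglik)
        },
        ledger = {
          v <- verify_ledger(N = 3L + 2L * i, L = 5L * i)
          if (!v$match) ok <- FALSE
          max(abs(v$clp_ratio["measured"] - v$clp_ratio["closed_form"]))
        })
      errs <- c(errs, err)
    }
    tol <- if (s == "ledger") 1e-12 else 1e-10
    pass <- ok && all(errs <= tol)
    res[[s]] <- data.frame(suite = s, pass = pass, max_err = max(errs))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "ok") <- all(out$pass)
  out
}
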