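# Metropolis-coupled MCMC over trees and GTR+I+Gamma parameters: heated
# chains advanced serially within each generation, one swap attempt per
# generation, independent runs, cold-chain sampling and ASDSF diagnostics.

BL_MIN <- 1e-8   # branch-length floor on proposals
BL_MAX <- 100    # abort guard against runaway branches

default_move_weights <- c(blmult = 0.30, nni = 0.30, spr = 0.15,
                          exch = 0.08, freqs = 0.07, alpha = 0.05,
                          pinvar = 0.05)

default_tuning <- list(bl_lambda = 2 * log(2),   # multiplier in [1/2, 2]
                       dir_exch = 100, dir_freq = 100,
                       alpha_lambda = 2 * log(2), pinv_delta = 0.1)

# ---- small numeric helpers ------------------------------------------------

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (any(g == 0)) return(NULL)  # degenerate draw; caller aborts
  g / sum(g)
}

ddirichlet_log <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# log prior: Exp(10) branch lengths, flat Dirichlet on exch and freqs,
# Exp(1) on alpha, Uniform(0,1) on pinvar
log_prior <- function(tr, params) {
  bl <- tr$elen[-tr$root]
  sum(stats::dexp(bl, rate = 10, log = TRUE)) +
    stats::dexp(params$alpha, rate = 1, log = TRUE)
}

# nodes in the subtree rooted at v (including v)
subtree_nodes <- function(tr, v) {
  out <- v
  i <- 1L
  while (i <= length(out)) {
    w <- out[i]
    if (w > tr$n_tip) out <- c(out, tr$child[, w])
    i <- i + 1L
  }
  out
}

#' Metropolis-Hastings acceptance probability for a heated chain
#'
#' `min(1, exp(beta * (lp_new - lp_old) + log_hastings))`: the posterior
#' ratio raised to the chain's heat, times the Hastings ratio.
#'
#' @param lp_new,lp_old Unheated log posteriors of proposed/current state.
#' @param beta Chain heat (cold chain: 1).
#' @param log_hastings Log Hastings ratio of the proposal.
#' @return Acceptance probability in `[0, 1]`.
#' @export
accept_probability <- function(lp_new, lp_old, beta = 1, log_hastings = 0) {
  lr <- beta * (lp_new - lp_old) + log_hastings
  if (!is.finite(lr)) {
    if (is.nan(lr)) stop("non-finite posterior ratio")
    return(if (lr > 0) 1 else 0)
  }
  min(1, exp(lr))
}

# log acceptance probability of swapping the heats of two chains with
# unheated log posteriors lp_i, lp_j and heats beta_i, beta_j
swap_log_accept <- function(lp_i, lp_j, beta_i, beta_j) {
  min(0, (beta_j - beta_i) * (lp_i - lp_j))
}

# ---- proposals ------------------------------------------------------------

# One proposal. Returns list(tr, params, log_hastings, aborted,
# topo_changed, params_changed); `aborted` (the abort flag Q) means no
# state may be committed and no likelihood needs evaluating.
propose_move <- function(kind, tr, params, tun) {
  out <- list(tr = tr, params = params, log_hastings = 0, aborted = FALSE,
              topo_changed = FALSE, params_changed = FALSE)
  n <- tr$n_tip
  abort <- function() { out$aborted <- TRUE; out }
  switch(kind,
    blmult = {
      v <- sample(setdiff(seq_len(2L * n - 1L), tr$root), 1L)
      fac <- exp(tun$bl_lambda * (runif(1) - 0.5))
      nl <- tr$elen[v] * fac
      if (nl < BL_MIN || nl > BL_MAX) return(abort())
      out$tr$elen[v] <- nl
      out$log_hastings <- log(fac)
      out
    },
    nni = {
      if (n < 4L) return(abort())
      edges <- internal_edges(tr)
      e <- edges[sample.int(length(edges), 1L)]
      k <- sample.int(2L, 1L)
      tr2 <- cptree_nni(tr, e, k)
      fac <- exp(tun$bl_lambda * (runif(1) - 0.5))
      nl <- tr2$elen[e] * fac
      if (nl < BL_MIN || nl > BL_MAX) return(abort())
      tr2$elen[e] <- nl
      out$tr <- tr2
      out$log_hastings <- log(fac)
      out$topo_changed <- TRUE
      out
    },
    spr = {
      if (n < 5L) return(abort())
      cand <- setdiff(seq_len(2L * n - 1L), c(tr$root, tr$child[, tr$root]))
      v <- cand[sample.int(length(cand), 1L)]
      p <- tr$parent[v]
      g <- tr$parent[p]
      w <- tr$child[, p][tr$child[, p] != v]
      sub <- subtree_nodes(tr, v)
      targets <- setdiff(seq_len(2L * n - 1L), c(sub, tr$root, p))
      targets <- setdiff(targets, w)  # re-insertion into the merged edge
      if (!length(targets)) return(abort())
      u <- targets[sample.int(length(targets), 1L)]
      len_merged <- tr$elen[w] + tr$elen[p]
      len_target <- tr$elen[u]
      if (len_target <= 0) return(abort())
      # detach: splice w into p's place under g
      tr$child[, g][tr$child[, g] == p] <- w
      tr$parent[w] <- g
      tr$elen[w] <- len_merged
      # re-insert p (carrying v) into the edge above u
      gu <- tr$parent[u]
      tr$child[, gu][tr$child[, gu] == u] <- p
      tr$parent[p] <- gu
      pos <- runif(1) * len_target
      tr$elen[p] <- len_target - pos
      tr$child[, p] <- c(u, v)
      tr$parent[u] <- p
      tr$elen[u] <- pos
      if (any(tr$elen[c(p, u)] < BL_MIN)) return(abort())
      tr$postorder <- cptree_postorder(tr)
      out$tr <- tr
      out$log_hastings <- log(len_target) - log(len_merged)
      out$topo_changed <- TRUE
      out
    },
    exch = {
      a <- tun$dir_exch * params$exch
      newe <- rdirichlet1(a)
      if (is.null(newe) || any(newe < 1e-8)) return(abort())
      out$params$exch <- setNames(newe, EXCH_NAMES)
      out$log_hastings <- ddirichlet_log(params$exch, tun$dir_exch * newe) -
        ddirichlet_log(newe, a)
      out$params_changed <- TRUE
      out
    },
    freqs = {
      a <- tun$dir_freq * params$freqs
      newf <- rdirichlet1(a)
      if (is.null(newf) || any(newf < 1e-8)) return(abort())
      out$params$freqs <- setNames(newf, NUC)
      out$log_hastings <- ddirichlet_log(params$freqs, tun$dir_freq * newf) -
        ddirichlet_log(newf, a)
      out$params_changed <- TRUE
      out
    },
    alpha = {
      fac <- exp(tun$alpha_lambda * (runif(1) - 0.5))
      na <- params$alpha * fac
      if (na < 1e-3 || na > 1e3) return(abort())
      out$params$alpha <- na
      out$log_hastings <- log(fac)
      out$params_changed <- TRUE
      out
    },
    pinvar = {
      np <- params$pinvar + tun$pinv_delta * (runif(1) - 0.5)
      for (i in 1:10) {  # reflect into [0, 1)
        if (np < 0) np <- -np
        else if (np >= 1) np <- 2 - np
        else break
      }
      if (np < 0 || np >= 1) return(abort())
      out$params$pinvar <- np
      out$params_changed <- TRUE
      out
    },
    stop("unknown move kind: ", kind))
}

# ---- chains ---------------------------------------------------------------

new_chain <- function(tr, params, beta, L, rng_seed) {
  e <- new.env(parent = emptyenv())
  e$tr <- tr
  e$params <- params
  e$beta <- beta
  e$es <- rate_matrix_eigen(build_rate_matrix(params), params$freqs)
  e$rates <- discrete_gamma_rates(params$alpha, params$ncat)
  e$scaler <- new_scaler_state(tr, L)
  e$lnL <- NA_real_
  e$lnPr <- log_prior(tr, params)
  e$rng <- rng_seed
  e
}

chain_eval <- function(ch, pats, weights, cfg, tr = ch$tr, es = ch$es,
                       rates = ch$rates, params = ch$params) {
  res <- .eval_tree_cpp(pats, weights, as.integer(tr$postorder),
                        as.integer(tr$child[1L, ]), as.integer(tr$child[2L, ]),
                        as.numeric(tr$elen), es$values, es$C1, es$C2,
                        rates, as.numeric(params$freqs), params$pinvar,
                        cfg$scaler_node, ch$scaler$scalers_set,
                        ch$scaler$stored_scaler, ch$scaler$ln_scaler,
                        cfg$mode, cfg$layout_code, TRUE, FALSE,
                        cfg$count_mask, 0)
  res$loglik
}

# ---- the sampler ----------------------------------------------------------

#' Metropolis-coupled MCMC phylogenetic inference
#'
#' Samples tree topologies, branch lengths and GTR+I+Gamma parameters from
#' their posterior by Metropolis-coupled MCMC: each run carries `nchains`
#' chains at heats `beta = 1 / (1 + heat_lambda * i)` (cold chain `i = 0`),
#' advanced serially within each generation with one proposal per chain,
#' followed by one swap attempt between a random chain pair. The cold chain
#' is sampled every `samplefreq` generations; the average standard deviation
#' of split frequencies (ASDSF) between independent runs is reported at
#' every `diagfreq` generations.
#'
#' Priors: Exp(10) on branch lengths, flat Dirichlet on exchangeabilities
#' and base frequencies, Exp(1) on the gamma shape, Uniform(0,1) on the
#' proportion of invariable sites.
#'
#' @param x Data: a `phyfuse_alignment`, `phyfuse_patterns`,
#'   `sim_alignment`, or a path readable by [read_alignment()].
#' @param ngen Number of generations (0 records only the initial sample).
#' @param nruns Independent runs (default 2).
#' @param nchains Chains per run (default 4: one cold, three heated).
#' @param heat_lambda Heating increment (default 0.1).
#' @param samplefreq,diagfreq Sampling and diagnosis frequencies in
#'   generations (defaults 1000).
#' @param burnin_frac Fraction of samples discarded for diagnostics and
#'   summaries (default 0.25).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param params_init Starting model parameters (a [gtr_params()]).
#' @param tree_init Optional starting tree ([ape::phylo]); default: an
#'   independent random tree per chain.
#' @param evaluator `"fused"` (default) or `"multipass"`; the two produce
#'   identical chains.
#' @param layout,layout_threshold,scaler_policy,scaler_k See
#'   [phylo_loglik()].
#' @param move_weights Named proposal-mix weights (see
#'   `phyfuse:::default_move_weights`).
#' @param tuning Named list of proposal tuning constants (see
#'   `phyfuse:::default_tuning`).
#' @param use_data If `FALSE`, sample from the prior (the likelihood term
#'   is dropped).
#' @param out_prefix If given, write MrBayes-style sample files
#'   `<prefix>.run<k>.p` / `.t` and a diagnostics file `<prefix>.mcmc`.
#' @param verbose Print progress.
#' @return An object of class `mc3_fit`; see [summary.mc3_fit()].
#' @examples
#' \donttest{
#' sim <- simulate_alignment(sim_spec(n_taxa = 6, n_columns = 300, seed = 7,
#'                                    params = gtr_params(alpha = 0.6)))
#' fit <- mc3(sim$alignment, ngen = 2000, nruns = 2, nchains = 2,
#'            samplefreq = 100, diagfreq = 1000, seed = 11)
#' summary(fit)
#' }
#' @export
mc3 <- function(x, ngen = 10000L, nruns = 2L, nchains = 4L,
                heat_lambda = 0.1, samplefreq = 1000L, diagfreq = 1000L,
                burnin_frac = 0.25, seed = NULL,
                params_init = gtr_params(alpha = 1, pinvar = 0.1),
                tree_init = NULL,
                evaluator = c("fused", "multipass"),
                layout = c("auto", "state_major", "site_major"),
                layout_threshold = 512L,
                scaler_policy = c("all", "none", "every_k"), scaler_k = 2L,
                move_weights = NULL, tuning = NULL, use_data = TRUE,
                out_prefix = NULL, verbose = FALSE) {
  evaluator <- match.arg(evaluator)
  layout <- match.arg(layout)
  scaler_policy <- match.arg(scaler_policy)
  stopifnot(ngen >= 0, nruns >= 1, nchains >= 1,
            samplefreq >= 1, diagfreq >= 1)
  mw <- default_move_weights
  if (!is.null(move_weights)) { mw[names(move_weights)] <- move_weights }
  mw <- mw / sum(mw)
  tun <- default_tuning
  if (!is.null(tuning)) tun[names(tuning)] <- tuning

  if (is.character(x)) x <- read_alignment(x)
  if (inherits(x, "sim_alignment")) x <- x$alignment
  cp <- if (inherits(x, "phyfuse_patterns")) x else compress_patterns(x)
  taxa <- rownames(cp$patterns)
  n <- length(taxa)
  L <- cp$L
  betas <- 1 / (1 + heat_lambda * (seq_len(nchains) - 1L))

  # reproducible per-chain RNG streams from one master seed
  old_kind <- RNGkind()
  on.exit(RNGkind(old_kind[1L], old_kind[2L], old_kind[3L]), add = TRUE)
  set.seed(if (is.null(seed)) 1L else as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- .Random.seed
  next_stream <- function() {
    s <<- parallel::nextRNGStream(s)
    s
  }

  runs <- vector("list", nruns)
  for (r in seq_len(nruns)) {
    run_stream <- next_stream()
    chains <- vector("list", nchains)
    assign(".Random.seed", run_stream, globalenv())
    for (j in seq_len(nchains)) {
      tr0 <- if (is.null(tree_init)) {
        as_cptree(random_tree(n, labels = taxa))
      } else as_cptree(tree_init)
      if (!setequal(tr0$tip_label, taxa)) stop("taxon mismatch in tree_init")
      chains[[j]] <- new_chain(tr0, params_init, betas[j], L, next_stream())
    }
    run_stream <- .Random.seed  # after tree initialization

    cfg <- list(mode = if (evaluator == "fused") 0L else 1L,
                layout_code = resolve_layout(layout, L, layout_threshold),
                scaler_node = scaler_node_flags(chains[[1L]]$tr,
                                                scaler_policy, scaler_k),
                count_mask = integer(2L * n - 1L))
    pats <- cp$patterns[match(chains[[1L]]$tr$tip_label, rownames(cp$patterns)), ,
                        drop = FALSE]
    w <- as.integer(cp$weights)

    for (j in seq_len(nchains)) {
      ch <- chains[[j]]
      ch$lnL <- if (use_data) chain_eval(ch, pats, w, cfg) else 0
    }

    cold <- 1L
    nsamp <- ngen %/% samplefreq + 1L
    pnames <- c("Gen", "LnL", "TL", paste0("r_", EXCH_NAMES),
                paste0("pi_", NUC), "alpha", "pinvar")
    ptab <- matrix(NA_real_, nsamp, length(pnames),
                   dimnames = list(NULL, pnames))
    ttab <- character(nsamp)
    acc <- rej <- abo <- setNames(numeric(length(mw)), names(mw))
    nswap_acc <- nswap_try <- 0L
    si <- 0L
    take_sample <- function(gen) {
      ch <- chains[[cold]]
      si <<- si + 1L
      ptab[si, ] <<- c(gen, ch$lnL, sum(ch$tr$elen[-ch$tr$root]),
                       ch$params$exch, ch$params$freqs,
                       ch$params$alpha, ch$params$pinvar)
      ttab[si] <<- write_newick(as_phylo(ch$tr))
    }
    take_sample(0L)

    if (ngen > 0) for (gen in seq_len(ngen)) {
      for (j in seq_len(nchains)) {
        ch <- chains[[j]]
        assign(".Random.seed", ch$rng, globalenv())
        kind <- sample(names(mw), 1L, prob = mw)
        prop <- propose_move(kind, ch$tr, ch$params, tun)
        if (prop$aborted) {
          abo[kind] <- abo[kind] + 1
        } else {
          es2 <- if (prop$params_changed) {
            rate_matrix_eigen(build_rate_matrix(prop$params),
                              prop$params$freqs)
          } else ch$es
          rates2 <- if (prop$params_changed) {
            discrete_gamma_rates(prop$params$alpha, prop$params$ncat)
          } else ch$rates
          lnL2 <- if (use_data) {
            chain_eval(ch, pats, w, cfg, tr = prop$tr, es = es2,
                       rates = rates2, params = prop$params)
          } else 0
          lnPr2 <- log_prior(prop$tr, prop$params)
          a <- accept_probability(lnL2 + lnPr2, ch$lnL + ch$lnPr,
                                  ch$beta, prop$log_hastings)
          if (runif(1) < a) {
            ch$tr <- prop$tr
            ch$params <- prop$params
            ch$es <- es2
            ch$rates <- rates2
            ch$lnL <- lnL2
            ch$lnPr <- lnPr2
            acc[kind] <- acc[kind] + 1
          } else rej[kind] <- rej[kind] + 1
        }
        ch$rng <- .Random.seed
      }
      if (nchains >= 2L) {
        assign(".Random.seed", run_stream, globalenv())
        pair <- sample.int(nchains, 2L)
        ci <- chains[[pair[1L]]]; cj <- chains[[pair[2L]]]
        la <- swap_log_accept(ci$lnL + ci$lnPr, cj$lnL + cj$lnPr,
                              ci$beta, cj$beta)
        nswap_try <- nswap_try + 1L
        if (log(runif(1)) < la) {
          b <- ci$beta; ci$beta <- cj$beta; cj$beta <- b
          if (cold == pair[1L]) cold <- pair[2L]
          else if (cold == pair[2L]) cold <- pair[1L]
          nswap_acc <- nswap_acc + 1L
        }
        run_stream <- .Random.seed
      }
      if (gen %% samplefreq == 0L) take_sample(gen)
      if (verbose && gen %% max(1L, diagfreq) == 0L)
        message(sprintf("run %d gen %d lnL %.3f", r, gen, chains[[cold]]$lnL))
    }

    runs[[r]] <- list(params = as.data.frame(ptab[seq_len(si), , drop = FALSE]),
                      trees = ttab[seq_len(si)],
                      accepted = acc, rejected = rej, aborted = abo,
                      swap_accept = c(accepted = nswap_acc, tried = nswap_try))
  }

  diag <- asdsf_trace(runs, taxa, diagfreq, samplefreq, ngen, burnin_frac)
  fit <- structure(
    list(runs = runs, asdsf = diag, taxa = taxa,
         config = list(ngen = ngen, nruns = nruns, nchains = nchains,
                       heat_lambda = heat_lambda, samplefreq = samplefreq,
                       diagfreq = diagfreq, burnin_frac = burnin_frac,
                       seed = seed, evaluator = evaluator, layout = layout,
                       layout_threshold = layout_threshold,
                       scaler_policy = scaler_policy,
                       move_weights = mw, tuning = tun, use_data = use_data),
         data_info = list(n_taxa = n, n_columns = cp$n_columns, L = L)),
    class = "mc3_fit")
  if (!is.null(out_prefix)) write_mc3_files(fit, out_prefix)
  fit
}

# ASDSF at each diagnosis point, from the samples accumulated to that point
# (burn-in fraction of those removed), between runs 1 and 2.
asdsf_trace <- function(runs, taxa, diagfreq, samplefreq, ngen, burnin_frac) {
  if (length(runs) < 2L || ngen == 0L)
    return(data.frame(gen = integer(0), asdsf = numeric(0)))
  gens <- runs[[1L]]$params$Gen
  pts <- seq_len(ngen %/% diagfreq) * diagfreq
  if (!length(pts))
    return(data.frame(gen = integer(0), asdsf = numeric(0)))
  splits_by_run <- lapply(runs[1:2], function(r)
    lapply(r$trees, function(t) tree_splits(read_newick(t), labels = sort(taxa))))
  out <- data.frame(gen = pts, asdsf = NA_real_)
  for (i in seq_along(pts)) {
    keep <- which(gens <= pts[i])
    keep <- keep[keep > floor(burnin_frac * length(keep))]
    if (length(keep) < 2L) next
    f1 <- split_freq_from_list(splits_by_run[[1L]][keep])
    f2 <- split_freq_from_list(splits_by_run[[2L]][keep])
    out$asdsf[i] <- asdsf(f1, f2)
  }
  out
}

split_freq_from_list <- function(split_sets) {
  all <- unlist(split_sets, use.names = FALSE)
  if (!length(all)) return(setNames(numeric(0), character(0)))
  tab <- table(all) / length(split_sets)
  setNames(as.numeric(tab), names(tab))
}

#' Posterior split frequencies
#'
#' Frequency of each non-trivial bipartition among sampled trees, after
#' discarding a burn-in fraction.
#'
#' @param trees Sampled trees: a character vector of newick strings, a list
#'   of [ape::phylo], an `ape::multiPhylo`, or one run of an [mc3()] fit
#'   (`fit$runs[[k]]`).
#' @param burnin_frac Fraction of initial samples discarded (default 0.25).
#' @param labels Optional taxon label set (defaults to the first tree's).
#' @return Named numeric vector: split key (see [tree_splits()]) ->
#'   frequency in `[0, 1]`.
#' @export
split_frequencies <- function(trees, burnin_frac = 0.25, labels = NULL) {
  if (is.list(trees) && !is.null(trees$trees)) trees <- trees$trees
  if (inherits(trees, "multiPhylo")) trees <- lapply(trees, identity)
  if (is.character(trees)) trees <- lapply(trees, read_newick)
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  if (is.null(labels)) labels <- sort(trees[[1L]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, labels))
      stop("split_frequencies: samples over different taxon sets")
  keep <- seq_along(trees)
  keep <- keep[keep > floor(burnin_frac * length(keep))]
  split_freq_from_list(lapply(trees[keep], tree_splits, labels = labels))
}

#' Average standard deviation of split frequencies
#'
#' Convergence diagnostic between two independent runs: the mean, over
#' splits reaching `min_freq` in at least one run, of the sample standard
#' deviation (n-1 denominator) of the split's frequency across runs.
#'
#' @param f1,f2 Split-frequency maps from [split_frequencies()].
#' @param min_freq Inclusion threshold (default 0.1).
#' @return The ASDSF (numeric scalar).
#' @export
asdsf <- function(f1, f2, min_freq = 0.1) {
  keys <- union(names(f1), names(f2))
  if (!length(keys)) return(0)
  a <- ifelse(keys %in% names(f1), f1[keys], 0)
  b <- ifelse(keys %in% names(f2), f2[keys], 0)
  sel <- pmax(a, b) >= min_freq
  if (!any(sel)) stop("asdsf: no splits reach min_freq")
  mean(vapply(which(sel), function(i) sd(c(a[i], b[i])), 0))
}

# MrBayes-style sample files: .p (tab-separated parameters), .t (one newick
# per sampled generation), .mcmc (diagnostics).
write_mc3_files <- function(fit, prefix) {
  for (r in seq_along(fit$runs)) {
    run <- fit$runs[[r]]
    p <- run$params
    pf <- sprintf("%s.run%d.p", prefix, r)
    con <- file(pf, "w")
    writeLines(paste(colnames(p), collapse = "\t"), con)
    for (i in seq_len(nrow(p)))
      writeLines(paste(c(sprintf("%d", as.integer(p$Gen[i])),
                         sprintf("%.8f", as.numeric(p[i, -1L]))),
                       collapse = "\t"), con)
    close(con)
    tf <- sprintf("%s.run%d.t", prefix, r)
    writeLines(sprintf("%d\t%s", as.integer(p$Gen), run$trees), tf)
  }
  if (nrow(fit$asdsf)) {
    df <- file(sprintf("%s.mcmc", prefix), "w")
    writeLines("Gen\tASDSF", df)
    writeLines(sprintf("%d\t%.6f", fit$asdsf$gen, fit$asdsf$asdsf), df)
    close(df)
  }
  invisible(prefix)
}
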