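# Proposals, acceptance rule, chain swaps, reproducibility, diagnostics.

test_that("the heated acceptance rule behaves at its fixed points", {
  # identical posteriors, symmetric proposal: always accept
  expect_equal(accept_probability(-10, -10), 1)
  expect_equal(accept_probability(-10, -10, beta = 0.5), 1)
  # worse proposal tempered by heat
  expect_equal(accept_probability(-12, -10, beta = 0.5), exp(-1))
  # Hastings correction enters linearly in log space
  expect_equal(accept_probability(-12, -10, beta = 1, log_hastings = 2), 1)
  expect_error(accept_probability(NaN, 0), "non-finite")
})

test_that("a Metropolis chain driven by the rule attains its target", {
  set.seed(103)
  target <- c(0.3, 0.7)
  s <- 1L
  n <- 20000L
  hits <- integer(2)
  for (i in seq_len(n)) {
    cand <- 3L - s
    if (runif(1) < accept_probability(log(target[cand]), log(target[s])))
      s <- cand
    hits[s] <- hits[s] + 1L
  }
  # 3 Monte-Carlo standard errors of an autocorrelated two-state chain
  se <- sqrt(0.3 * 0.7 / n) * 3  # switching is fast; chain is near-iid
  expect_lt(abs(hits[2] / n - 0.7), 3 * se + 0.01)
})

test_that("swap acceptance is symmetric in the stated fixed points", {
  expect_equal(phyfuse:::swap_log_accept(-5, -5, 1, 0.8), 0)    # equal posteriors
  expect_equal(phyfuse:::swap_log_accept(-5, -50, 0.9, 0.9), 0) # equal heats
  expect_equal(phyfuse:::swap_log_accept(-10, -20, 1, 0.5), -5) # (0.5-1)*(−10+20)
})

test_that("proposals respect their supports and report aborts", {
  set.seed(107)
  tr <- phyfuse:::as_cptree(random_tree(8))
  p <- gtr_params(alpha = 0.8, pinvar = 0.2)
  tun <- phyfuse:::default_tuning
  for (i in 1:200) {
    pr <- phyfuse:::propose_move("exch", tr, p, tun)
    expect_equal(sum(pr$params$exch), 1, tolerance = 1e-12)
    expect_true(all(pr$params$exch > 0))
    pr <- phyfuse:::propose_move("freqs", tr, p, tun)
    expect_equal(sum(pr$params$freqs), 1, tolerance = 1e-12)
    pr <- phyfuse:::propose_move("pinvar", tr, p, tun)
    expect_true(pr$params$pinvar >= 0 && pr$params$pinvar < 1)
    pr <- phyfuse:::propose_move("blmult", tr, p, tun)
    if (!pr$aborted) {
      changed <- which(pr$tr$elen != tr$elen)
      expect_length(changed, 1L)
      expect_equal(pr$log_hastings,
                   log(pr$tr$elen[changed] / tr$elen[changed]),
                   tolerance = 1e-12)
    }
    pr <- phyfuse:::propose_move("spr", tr, p, tun)
    if (!pr$aborted) {
      p2 <- phyfuse:::as_phylo(pr$tr)
      expect_true(ape::is.binary(p2))
      expect_setequal(p2$tip.label, tr$tip_label)
      # total tree length is preserved by prune-regraft bookkeeping
      expect_equal(sum(pr$tr$elen[-pr$tr$root]), sum(tr$elen[-tr$root]),
                   tolerance = 1e-9)
    }
  }
  # NNI on a 3-taxon tree cannot proceed: abort flag raised, state untouched
  tr3 <- phyfuse:::as_cptree(random_tree(3))
  pr <- phyfuse:::propose_move("nni", tr3, p, tun)
  expect_true(pr$aborted)
  expect_identical(pr$tr, tr3)
})

test_that("prior-only sampling recovers the prior means", {
  sim <- simulate_alignment(sim_spec(n_taxa = 6, n_columns = 50, seed = 109))
  # wide proposal windows: with the likelihood disabled the posterior is the
  # prior, so mixing speed is set purely by the proposal scale
  fit <- mc3(sim$alignment, ngen = 30000, nruns = 1, nchains = 1,
             samplefreq = 20, seed = 109, use_data = FALSE,
             move_weights = c(blmult = 0.1, nni = 0.05, spr = 0.05,
                              exch = 0.2, freqs = 0.2, alpha = 0.2,
                              pinvar = 0.2),
             tuning = list(pinv_delta = 0.8, dir_exch = 12, dir_freq = 12,
                           alpha_lambda = 3))
  p <- fit$runs[[1]]$params
  keep <- seq_len(nrow(p)) > nrow(p) / 4
  # batch-means standard errors guard against autocorrelation
  bse <- function(x, nb = 15) {
    bm <- tapply(x, cut(seq_along(x), nb), mean)
    sd(bm) / sqrt(nb)
  }
  for (v in paste0("r_", c("AC", "AG", "GT")))
    expect_lt(abs(mean(p[[v]][keep]) - 1 / 6), 3 * bse(p[[v]][keep]))
  for (v in paste0("pi_", c("A", "T")))
    expect_lt(abs(mean(p[[v]][keep]) - 1 / 4), 3 * bse(p[[v]][keep]))
  expect_lt(abs(mean(p$alpha[keep]) - 1), 3 * bse(p$alpha[keep]))
  expect_lt(abs(mean(p$pinvar[keep]) - 0.5), 3 * bse(p$pinvar[keep]))
})

test_that("runs are reproducible from the seed, including sample files", {
  sim <- simulate_alignment(sim_spec(n_taxa = 6, n_columns = 120, seed = 113))
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- mc3(sim$alignment, ngen = 300, nruns = 2, nchains = 2,
            samplefreq = 50, diagfreq = 150, seed = 19, out_prefix = d1)
  f2 <- mc3(sim$alignment, ngen = 300, nruns = 2, nchains = 2,
            samplefreq = 50, diagfreq = 150, seed = 19, out_prefix = d2)
  expect_identical(f1$runs[[1]]$params, f2$runs[[1]]$params)
  expect_identical(f1$runs[[2]]$trees, f2$runs[[2]]$trees)
  for (suf in c(".run1.p", ".run1.t", ".run2.p", ".run2.t", ".mcmc"))
    expect_identical(readLines(paste0(d1, suf)), readLines(paste0(d2, suf)))
  # a different seed decouples the chains
  f3 <- mc3(sim$alignment, ngen = 300, nruns = 2, nchains = 2,
            samplefreq = 50, diagfreq = 150, seed = 23)
  expect_false(identical(f1$runs[[1]]$params$LnL, f3$runs[[1]]$params$LnL))
})

test_that("zero generations yields only the initial sample", {
  sim <- simulate_alignment(sim_spec(n_taxa = 5, n_columns = 60, seed = 127))
  fit <- mc3(sim$alignment, ngen = 0, nruns = 1, nchains = 2, seed = 3)
  expect_equal(nrow(fit$runs[[1]]$params), 1L)
  expect_equal(fit$runs[[1]]$params$Gen, 0)
  expect_length(fit$runs[[1]]$trees, 1L)
})

test_that("split frequencies count bipartitions among sampled trees", {
  t1 <- "((a:1,b:1):1,(c:1,d:1):1);"            # split ab|cd
  t2 <- "((a:1,c:1):1,(b:1,d:1):1);"            # split ac|bd
  # all samples identical: every split at frequency 1
  f <- split_frequencies(rep(t1, 8), burnin_frac = 0)
  expect_equal(unname(f), 1)
  # two topologies in equal proportion: distinguishing splits at 0.5
  f2 <- split_frequencies(c(rep(t1, 4), rep(t2, 4)), burnin_frac = 0)
  expect_equal(sort(unname(f2)), c(0.5, 0.5))
  # hand count over a mixed set of ten trees (burn-in removes the first 2)
  trees <- c(rep(t1, 5), rep(t2, 5))
  f3 <- split_frequencies(trees, burnin_frac = 0.2)
  expect_equal(unname(f3[["b|d"]]), 5 / 8)      # t2 split, 5 of 8 kept
  expect_equal(unname(f3[["c|d"]]), 3 / 8)      # t1 split, 3 of 8 kept
  expect_error(split_frequencies(c(t1, "((a:1,b:1):1,(c:1,x:1):1);")),
               "different taxon sets")
})

test_that("ASDSF matches its defining formula", {
  f1 <- c("s1" = 1.0, "s2" = 0.6)
  f2 <- c("s1" = 1.0, "s2" = 0.4)
  expect_equal(asdsf(f1, f1), 0)
  # sd with n-1 denominator: sd(c(0.6, 0.4)) = 0.1414...
  expect_equal(asdsf(f1, f2), mean(c(0, sd(c(0.6, 0.4)))))
  # a split present in only one run at full frequency: sd = 1/sqrt(2)
  expect_equal(asdsf(c(a = 1), setNames(numeric(0), character(0))),
               1 / sqrt(2), tolerance = 1e-6)
  # splits below the inclusion threshold in both runs do not contribute
  expect_equal(asdsf(c(f1, weak = 0.05), c(f2, weak = 0.01)), asdsf(f1, f2))
  expect_error(asdsf(c(a = 0.01), c(a = 0.02)), "min_freq")
})

test_that("posterior sampling concentrates on the generating tree", {
  pars <- gtr_params(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3),
                     pinvar = 0.1, alpha = 0.6)
  sim <- simulate_alignment(sim_spec(n_taxa = 8, n_columns = 800,
                                     params = pars, seed = 131))
  fit <- mc3(sim$alignment, ngen = 3000, nruns = 2, nchains = 4,
             samplefreq = 50, diagfreq = 1000, seed = 37)
  truth <- tree_splits(sim$truth$tree)
  for (r in 1:2) {
    f <- split_frequencies(fit$runs[[r]])
    expect_true(all(truth %in% names(f)))
    expect_true(all(f[truth] > 0.5))
  }
  # summaries expose the sampled posterior
  s <- summary(fit)
  expect_true(all(c("mean", "sd") %in% colnames(s$params)))
  expect_lt(s$params["pi_A", "mean"] - 0.3, 0.1)
  expect_equal(unname(coef(fit)[paste0("pi_", c("A", "C", "G", "T"))]),
               unname(s$params[paste0("pi_", c("A", "C", "G", "T")), "mean"]))
  expect_true(is.finite(logLik(fit)))
})
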