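# Fused evaluator: prelike, conditional likelihoods, rescaling, root
# combination, layouts, and its independent oracles.

test_that("prelike pre-sums transition rows over compatible states", {
  p <- gtr_params(exch = runif(6, 0.5, 2), freqs = c(0.4, 0.3, 0.2, 0.1),
                  alpha = 0.8)
  tb <- transition_block(p, 0.2)
  pl <- prelike(tb, c(A = 1L, N = 15L, R = 5L))
  for (k in 1:4) {
    expect_equal(pl[k, , "A"], tb[, "A", k])               # single bit
    expect_equal(unname(pl[k, , "N"]), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(pl[k, , "R"]),
                 unname(tb[, "A", k] + tb[, "G", k]))      # A|G
  }
  expect_error(prelike(tb, 0L), "mask")
})

test_that("zero-length branches to identical tips concentrate the likelihood", {
  # two taxa at t = 0, single pattern 'A': lnL = ln(pi_A)
  p <- gtr_params(freqs = c(0.4, 0.3, 0.2, 0.1))
  enc <- matrix(1L, 2, 1, dimnames = list(c("a", "b"), NULL))
  ll <- phylo_loglik(read_newick("(a:0,b:0);"), enc, p)
  expect_equal(ll, log(0.4), tolerance = 1e-12)
  # with weight w the total scales to w * ln(pi_A)
  enc6 <- enc[, rep(1, 6), drop = FALSE]
  expect_equal(phylo_loglik(read_newick("(a:0,b:0);"), enc6, p),
               6 * log(0.4), tolerance = 1e-12)
})

test_that("a fully ambiguous taxon contributes a factor of one", {
  set.seed(53)
  fx <- rand_fixture(5, 8)
  p <- rand_params()
  base <- phylo_loglik(fx$tree, fx$cp, p)
  # graft an all-'N' taxon onto the root branch
  phy2 <- fx$tree
  nwk <- sub(";", "", write_newick(phy2))
  phy3 <- read_newick(paste0("(", nwk, ":0.13,ghost:0.21);"))
  enc2 <- rbind(fx$enc, ghost = rep(15L, ncol(fx$enc)))
  cp2 <- compress_patterns(enc2[, rep(seq_len(ncol(fx$enc)), fx$weights)])
  expect_equal(phylo_loglik(phy3, cp2, p), base, tolerance = 1e-10)
})

test_that("fused likelihood equals exhaustive ancestral-state enumeration", {
  set.seed(59)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    fx <- rand_fixture(n, sample(1:4, 1))
    p <- rand_params()
    lf <- phylo_loglik(fx$tree, fx$cp, p)
    le <- oracle_enum_loglik(fx$tree, fx$enc, p, fx$weights)
    expect_lt(rel_err(lf, le), 1e-10)
  }
})

test_that("likelihood on compressed patterns equals the uncompressed one", {
  set.seed(61)
  fx <- rand_fixture(7, 40)
  p <- rand_params()
  full <- fx$enc[, rep(seq_len(40), fx$weights), drop = FALSE]
  l_cp <- phylo_loglik(fx$tree, fx$cp, p)
  # column-by-column evaluation with unit weights, no collapsing
  cp_unit <- structure(list(patterns = full, weights = rep(1L, ncol(full)),
                            L = ncol(full), n_columns = ncol(full),
                            column_map = seq_len(ncol(full))),
                       class = "phyfuse_patterns")
  l_unit <- phylo_loglik(fx$tree, cp_unit, p)
  expect_lt(rel_err(l_cp, l_unit), 1e-12)
  # duplicating all columns exactly doubles the log-likelihood
  cp2 <- compress_patterns(cbind(full, full))
  expect_equal(phylo_loglik(fx$tree, cp2, p), 2 * l_cp, tolerance = 1e-12)
})

test_that("rescaling, scaler policies and switch timing leave lnL unchanged", {
  set.seed(67)
  fx <- rand_fixture(6, 25)
  p <- rand_params()
  base <- phylo_loglik(fx$tree, fx$cp, p, scaler_policy = "none")
  for (pol in c("all", "every_k"))
    expect_equal(phylo_loglik(fx$tree, fx$cp, p, scaler_policy = pol),
                 base, tolerance = 1e-10)
  # steady state (old scalers present) and deferred vs immediate commits
  expect_equal(phylo_loglik(fx$tree, fx$cp, p, passes = 3), base,
               tolerance = 1e-10)
  expect_identical(phylo_loglik(fx$tree, fx$cp, p, passes = 2,
                                defer_switches = TRUE),
                   phylo_loglik(fx$tree, fx$cp, p, passes = 2,
                                defer_switches = FALSE))
})

test_that("both data layouts return identical values", {
  set.seed(71)
  sim <- simulate_alignment(sim_spec(n_taxa = 60, n_columns = 400,
                                     params = gtr_params(alpha = 0.5),
                                     seed = 71))
  p <- rand_params()
  l_state <- phylo_loglik(sim$truth$tree, sim$alignment, p,
                          layout = "state_major")
  l_site <- phylo_loglik(sim$truth$tree, sim$alignment, p,
                         layout = "site_major")
  expect_identical(l_state, l_site)
  # auto layout picks by the unique-site threshold
  expect_identical(phylo_loglik(sim$truth$tree, sim$alignment, p,
                                layout = "auto", layout_threshold = 2L),
                   l_site)
})

test_that("the likelihood is invariant to root placement (pulley principle)", {
  set.seed(73)
  fx <- rand_fixture(8, 30)
  p <- rand_params()
  base <- phylo_loglik(fx$tree, fx$cp, p)
  un <- ape::unroot(fx$tree)
  for (tip in c(1, 4, 7)) {
    re <- ape::root(un, outgroup = fx$tree$tip.label[tip],
                    resolve.root = TRUE)
    expect_lt(rel_err(phylo_loglik(re, fx$cp, p), base), 1e-10)
  }
})

test_that("invariable-site mixture matches a scaler-free reference", {
  set.seed(79)
  for (i in 1:4) {
    fx <- rand_fixture(5, 6)
    p <- gtr_params(exch = runif(6, 0.5, 2),
                    freqs = {f <- rgamma(4, 8); f / sum(f)},
                    pinvar = 0.3, alpha = 0.9)
    lf <- phylo_loglik(fx$tree, fx$cp, p)
    lo <- oracle_pruning_loglik(fx$tree, fx$enc, p, fx$weights)
    expect_lt(rel_err(lf, lo), 1e-9)
    # pinvar = 0 collapses to the pure gamma mixture
    p0 <- gtr_params(p$exch, p$freqs, pinvar = 0, alpha = p$alpha)
    expect_lt(rel_err(phylo_loglik(fx$tree, fx$cp, p0),
                      oracle_pruning_loglik(fx$tree, fx$enc, p0, fx$weights)),
              1e-9)
  }
  # constant pattern, pinvar -> 1 limit: lnL -> w * ln(pi_A)
  pc <- gtr_params(freqs = c(0.4, 0.3, 0.2, 0.1), pinvar = 1 - 1e-9)
  encA <- matrix(1L, 4, 1, dimnames = list(paste0("t", 1:4), NULL))
  phyA <- read_newick("((t1:0.2,t2:0.2):0.1,(t3:0.2,t4:0.2):0.1);")
  expect_equal(phylo_loglik(phyA, encA[, c(1, 1, 1)], pc), 3 * log(0.4),
               tolerance = 1e-6)
  expect_error(gtr_params(pinvar = 1), "pinvar")
})

test_that("agreement with an external GTR+G+I implementation", {
  skip_if_not_installed("phangorn")
  set.seed(83)
  sim <- simulate_alignment(sim_spec(n_taxa = 10, n_columns = 300,
                                     params = gtr_params(alpha = 0.7),
                                     seed = 83))
  p <- gtr_params(exch = runif(6, 0.5, 2),
                  freqs = {f <- rgamma(4, 10); f / sum(f)},
                  pinvar = 0.2, alpha = 0.7)
  pd <- phangorn::phyDat(t(sapply(strsplit(sim$alignment$rows, ""),
                                  identity)), type = "DNA")
  # phangorn's +I convention rescales the substitution process so the total
  # mean rate is 1; ours keeps the gamma mean at 1 (the invariable class
  # enters only at the root combination). Dividing branch lengths by
  # (1 - pinvar) converts between them.
  tr2 <- sim$truth$tree
  tr2$edge.length <- tr2$edge.length / (1 - p$pinvar)
  ext <- phangorn::pml(sim$truth$tree, pd, bf = p$freqs, Q = p$exch,
                       k = 4, shape = p$alpha, inv = p$pinvar)$logLik
  expect_lt(rel_err(phylo_loglik(tr2, sim$alignment, p), ext), 1e-9)
})

test_that("rescaling keeps deep trees finite where the linear domain underflows", {
  # deep ladder tree with long branches: the per-site conditional
  # likelihoods shrink below the double-precision floor unless rescaled
  phy <- caterpillar_tree(192, branch_length = 10)
  # every taxon carries the rare state: each pruning step multiplies by
  # roughly its stationary frequency
  enc <- matrix(2L, 192, 10, dimnames = list(paste0("t", 1:192), NULL))
  p <- gtr_params(freqs = c(0.985, 0.005, 0.005, 0.005), alpha = 50)
  scaled <- phylo_loglik(phy, enc, p)
  unscaled <- phylo_loglik(phy, enc, p, scaler_policy = "none")
  expect_true(is.finite(scaled))
  expect_identical(unscaled, -Inf)  # linear-domain underflow to zero
})

test_that("the dispatch exercises all sixteen node variants", {
  phy <- read_newick(paste0("(((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1):0.1,",
                            "((e:0.1,(f:0.1,g:0.1):0.1):0.1,h:0.1):0.1);"))
  enc <- matrix(sample(c(1L, 2L, 4L, 8L), 8 * 10, TRUE), 8,
                dimnames = list(letters[1:8], NULL))
  p <- gtr_params(alpha = 0.6)
  prep <- phyfuse:::prepare_eval(phy, compress_patterns(enc), p)
  st <- phyfuse:::new_scaler_state(prep$tr, length(prep$weights))
  down <- seq_len(length(prep$tr$postorder) - 1L)
  vt <- variant_table()
  seen <- character(0)
  grab <- function(res) vt$id[res$variants[down] + 1L]
  sn_all <- phyfuse:::scaler_node_flags(prep$tr, "all")
  sn_none <- phyfuse:::scaler_node_flags(prep$tr, "none")
  # pass 1, no scalers anywhere: T = 0
  st0 <- phyfuse:::new_scaler_state(prep$tr, length(prep$weights))
  seen <- c(seen, grab(phyfuse:::eval_engine(prep, st0, sn_none, p)))
  # pass 1 with scaler nodes: S=0, N=1 -> T = 1
  seen <- c(seen, grab(phyfuse:::eval_engine(prep, st, sn_all, p)))
  # pass 2 with scaler nodes: S=1, N=1 -> T = 3
  seen <- c(seen, grab(phyfuse:::eval_engine(prep, st, sn_all, p)))
  # scaler designation withdrawn while old scalers remain: S=1, N=0 -> T = 2
  seen <- c(seen, grab(phyfuse:::eval_engine(prep, st, sn_none, p)))
  expect_setequal(unique(seen), variant_table()$id)
})
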