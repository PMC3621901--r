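# R interface to the fused and multipass conditional-likelihood engines.

# Normalize (tree, data) into engine inputs: computation tree, compressed
# patterns with rows ordered like the tree's tips, eigensystem and rates.
prepare_eval <- function(tree, data, params) {
  stopifnot(inherits(params, "gtr_params"))
  tr <- as_cptree(tree)
  cp <- if (inherits(data, "phyfuse_patterns")) data else compress_patterns(data)
  pat <- cp$patterns
  if (is.null(rownames(pat)))
    stop("taxon mismatch: pattern matrix has no taxon names")
  idx <- match(tr$tip_label, rownames(pat))
  if (anyNA(idx))
    stop("taxon mismatch: tree tips not found in alignment: ",
         paste(setdiff(tr$tip_label, rownames(pat)), collapse = ", "))
  if (nrow(pat) != tr$n_tip)
    stop("taxon mismatch: alignment has ", nrow(pat), " taxa, tree has ",
         tr$n_tip)
  Q <- build_rate_matrix(params)
  list(tr = tr, patterns = pat[idx, , drop = FALSE], weights = cp$weights,
       es = rate_matrix_eigen(Q, params$freqs),
       rates = discrete_gamma_rates(params$alpha, params$ncat))
}

# Scaler-node designation over node ids.
scaler_node_flags <- function(tr, policy = c("all", "none", "every_k"), k = 2L) {
  policy <- match.arg(policy)
  flags <- logical(2L * tr$n_tip - 1L)
  ints <- tr$postorder
  flags[ints] <- switch(policy,
    all = TRUE,
    none = FALSE,
    every_k = seq_along(ints) %% as.integer(k) == 0L)
  flags
}

# Fresh persistent scaler state for an evaluation or a chain.
new_scaler_state <- function(tr, L) {
  list(ln_scaler = numeric(L),
       stored_scaler = matrix(0, L, tr$n_tip - 1L),
       scalers_set = logical(2L * tr$n_tip - 1L))
}

# Low-level engine call; `state` buffers are modified in place.
eval_engine <- function(prep, state, scaler_node, params,
                        mode = 0L, layout = 0L, defer_switches = TRUE,
                        want_sites = FALSE, count_mask = NULL, perturb = 0) {
  tr <- prep$tr
  if (is.null(count_mask)) {
    count_mask <- integer(2L * tr$n_tip - 1L)
    count_mask[tr$postorder] <- 1L
    count_mask[tr$root] <- 2L
  }
  res <- .eval_tree_cpp(prep$patterns, as.integer(prep$weights),
                        as.integer(tr$postorder),
                        as.integer(tr$child[1L, ]), as.integer(tr$child[2L, ]),
                        as.numeric(tr$elen),
                        prep$es$values, prep$es$C1, prep$es$C2,
                        prep$rates, as.numeric(params$freqs), params$pinvar,
                        scaler_node, state$scalers_set, state$stored_scaler,
                        state$ln_scaler,
                        as.integer(mode), as.integer(layout), defer_switches,
                        want_sites, count_mask, perturb)
  rownames(res$ledger) <- c("clp_w", "clp_r", "tip_w", "tip_r", "ls_w", "ls_r")
  colnames(res$ledger) <- c("down", "root")
  res
}

resolve_layout <- function(layout, L, threshold) {
  switch(layout,
         auto = if (L < threshold) 0L else 1L,
         state_major = 0L,
         site_major = 1L)
}

#' Total log-likelihood of a tree (fused single-pass evaluator)
#'
#' Evaluates the GTR+I+Gamma log-likelihood of an alignment on a tree by
#' Felsenstein pruning in a single fused pass per internal node: terminal
#' transition matrices are transformed inline, and per-site rescaling (with
#' deferred scaler-flag switches) is merged into the same pass. Each down
#' node is dispatched to one of the 16 variants of [variant_table()].
#'
#' @param tree An [ape::phylo] (rooted or unrooted; the likelihood is
#'   invariant to rooting) whose tip labels match the alignment.
#' @param data A `phyfuse_alignment`, `phyfuse_patterns`, or encoded state
#'   matrix with taxon rownames.
#' @param params A [gtr_params()] object.
#' @param layout `"auto"`, `"state_major"` (all 16 per-site values handled
#'   together, site by site) or `"site_major"` (sites innermost). The two
#'   layouts return identical values; `"auto"` picks state-major when the
#'   number of unique patterns is below `layout_threshold`.
#' @param layout_threshold Pattern-count threshold for `layout = "auto"`
#'   (default 512).
#' @param scaler_policy Which internal nodes rescale: `"all"` (default),
#'   `"none"`, or `"every_k"`.
#' @param scaler_k Step for `scaler_policy = "every_k"`.
#' @param site If `TRUE`, attach the per-pattern log-likelihoods as
#'   attribute `"sites"` (ordered like the compressed patterns).
#' @param passes Number of evaluation passes over the tree (default 1; a
#'   second pass exercises the old-scaler-removal path and leaves the same
#'   log-likelihood).
#' @param defer_switches Commit scaler flag switches after the pass
#'   (default) or immediately; both give identical results.
#' @return The total log-likelihood (numeric scalar).
#' @examples
#' aln <- local({
#'   f <- tempfile(); writeLines(c(">a","ACGTAC",">b","ACGTAC",
#'                                 ">c","ACGTTT",">d","ACGTTT"), f)
#'   read_alignment(f)
#' })
#' tr <- read_newick("((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
#' phylo_loglik(tr, aln, gtr_params(alpha = 0.5))
#' @export
phylo_loglik <- function(tree, data, params = gtr_params(),
                         layout = c("auto", "state_major", "site_major"),
                         layout_threshold = 512L,
                         scaler_policy = c("all", "none", "every_k"),
                         scaler_k = 2L, site = FALSE, passes = 1L,
                         defer_switches = TRUE) {
  layout <- match.arg(layout)
  scaler_policy <- match.arg(scaler_policy)
  prep <- prepare_eval(tree, data, params)
  L <- length(prep$weights)
  state <- new_scaler_state(prep$tr, L)
  sn <- scaler_node_flags(prep$tr, scaler_policy, scaler_k)
  lay <- resolve_layout(layout, L, layout_threshold)
  res <- NULL
  for (p in seq_len(max(1L, passes)))
    res <- eval_engine(prep, state, sn, params, mode = 0L, layout = lay,
                       defer_switches = defer_switches, want_sites = site)
  out <- res$loglik
  if (site) attr(out, "sites") <- res$sites
  out
}

#' Multipass reference evaluation with transfer ledger
#'
#' Runs the five-stage reference pipeline (prelike transform, clp
#' computation, old-scaler subtraction, rescaling, root combination) with
#' materialized intermediates, and returns the log-likelihood together with
#' the measured ledger of simulated global-store traffic. The arithmetic is
#' identical to the fused evaluator's, so the log-likelihoods agree exactly.
#'
#' @inheritParams phylo_loglik
#' @param passes Number of passes; the ledger and stage counts reported are
#'   from the final pass (default 2, so the old-scaler-removal stage is
#'   active, the steady state of a running chain).
#' @return A list of class `phyfuse_multipass`: `loglik`, `ledger` (a
#'   [transfer_ledger()]), `stages` (kernels executed per internal node in
#'   the final pass, postorder), and `variants` (dispatch variant ids).
#' @export
evaluate_multipass <- function(tree, data, params = gtr_params(),
                               layout = c("auto", "state_major", "site_major"),
                               layout_threshold = 512L,
                               scaler_policy = c("all", "none", "every_k"),
                               scaler_k = 2L, passes = 2L) {
  layout <- match.arg(layout)
  scaler_policy <- match.arg(scaler_policy)
  prep <- prepare_eval(tree, data, params)
  L <- length(prep$weights)
  state <- new_scaler_state(prep$tr, L)
  sn <- scaler_node_flags(prep$tr, scaler_policy, scaler_k)
  lay <- resolve_layout(layout, L, layout_threshold)
  res <- NULL
  for (p in seq_len(max(1L, passes)))
    res <- eval_engine(prep, state, sn, params, mode = 1L, layout = lay)
  vt <- variant_table()
  structure(
    list(loglik = res$loglik,
         ledger = transfer_ledger(res$ledger, L = L),
         stages = res$stages,
         variants = vt$id[res$variants + 1L],
         nodes = prep$tr$postorder),
    class = "phyfuse_multipass")
}

#' @export
print.phyfuse_multipass <- function(x, ...) {
  cat("multipass evaluation: lnL =", format(x$loglik, digits = 10), "\n")
  print(x$ledger)
  invisible(x)
}

#' Prelike lookup block for a terminal child
#'
#' Pre-sums a transition block over the states compatible with each observed
#' (possibly ambiguous) character mask, so a terminal child's contribution
#' becomes a table lookup: `prelike[cat, parent, mask] =
#' sum over states s in mask of P_cat[parent, s]`.
#'
#' @param block A [transition_block()] (4 x 4 x ncat).
#' @param masks Integer state masks in 1..15 (see [encode_states()]).
#' @return Numeric array `c(ncat, 4, length(masks))`; a single-bit mask
#'   reproduces the corresponding transition-matrix column, and mask 15
#'   gives 1 for every entry (rows are stochastic).
#' @export
prelike <- function(block, masks) {
  stopifnot(inherits(block, "transition_block"))
  mnames <- names(masks)
  masks <- as.integer(masks)
  if (any(masks < 1L | masks > 15L))
    stop("prelike: masks must be in 1..15 (mask 0 matches no state)")
  ncat <- dim(block)[3]
  out <- array(0, c(ncat, 4, length(masks)),
               dimnames = list(NULL, NUC, mnames))
  for (k in seq_len(ncat))
    for (m in 1:4)
      for (i in seq_along(masks)) {
        bits <- which(bitwAnd(masks[i], c(1L, 2L, 4L, 8L)) > 0L)
        out[k, m, i] <- sum(block[m, bits, k])
      }
  out
}
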