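# Sequence simulation along a tree under GTR+I+Gamma, with truth records,
# plus presets mirroring the rDNA dataset shapes and the scalability grid
# used for benchmarking fixtures.

#' Simulation specification
#'
#' Describes one simulated dataset: tree (given or random), dimensions,
#' model parameters and seed. Presets reproduce the shapes of the empirical
#' rDNA benchmark alignments (26 taxa x 1546 nt up to 288 taxa x 3386 nt)
#' and the 60-taxon scalability grid.
#'
#' @param n_taxa Number of taxa (>= 3); ignored when `tree` is given.
#' @param n_columns Alignment length in sites.
#' @param params A [gtr_params()] object.
#' @param tree Optional [ape::phylo]; default: a fresh [random_tree()].
#' @param branch_fn Branch-length sampler for random trees (default
#'   `rexp(n, 10)`).
#' @param seed Optional integer seed making the simulation reproducible.
#' @param preset Optional shape preset; one of `"rdna26"` (26 x 1546),
#'   `"rdna37"` (37 x 2238), `"rdna111"` (111 x 1506), `"rdna234"`
#'   (234 x 1790), `"rdna288"` (288 x 3386), or `"scalability"` (60 taxa;
#'   set `n_columns` to the wanted length, grid 1000..10000).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_taxa = 12L, n_columns = 1000L, params = gtr_params(),
                     tree = NULL, branch_fn = function(n) rexp(n, rate = 10),
                     seed = NULL, preset = NULL) {
  if (!is.null(preset)) {
    shapes <- list(rdna26 = c(26L, 1546L), rdna37 = c(37L, 2238L),
                   rdna111 = c(111L, 1506L), rdna234 = c(234L, 1790L),
                   rdna288 = c(288L, 3386L), scalability = c(60L, n_columns))
    sh <- shapes[[match.arg(preset, names(shapes))]]
    n_taxa <- sh[1L]; n_columns <- sh[2L]
  }
  if (!is.null(tree)) n_taxa <- length(tree$tip.label)
  stopifnot(n_taxa >= 3L, n_columns >= 1L, inherits(params, "gtr_params"))
  structure(list(n_taxa = as.integer(n_taxa),
                 n_columns = as.integer(n_columns),
                 params = params, tree = tree, branch_fn = branch_fn,
                 seed = seed),
            class = "sim_spec")
}

#' Simulate an alignment along a tree
#'
#' Evolves nucleotide columns down the tree under the spec's GTR+I+Gamma
#' model: each column is invariable with probability `pinvar` (the root
#' state, drawn from the stationary frequencies, is copied to every taxon);
#' otherwise a gamma rate category is drawn and every branch transition is
#' sampled from the corresponding row of `P(r_k t)`.
#'
#' @param spec A [sim_spec()] (or arguments forwarded to one).
#' @param ... Passed to [sim_spec()] when `spec` is not already one.
#' @return A list of class `sim_alignment`: `alignment` (a
#'   `phyfuse_alignment`), and `truth` with `tree`, `params`, `categories`
#'   (per-column gamma category; 0 marks invariable columns) and
#'   `root_states`.
#' @examples
#' sim <- simulate_alignment(sim_spec(n_taxa = 6, n_columns = 100, seed = 1))
#' sim$alignment
#' @export
simulate_alignment <- function(spec = NULL, ...) {
  if (!inherits(spec, "sim_spec"))
    spec <- if (is.null(spec)) sim_spec(...) else sim_spec(spec, ...)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  phy <- if (is.null(spec$tree)) {
    random_tree(spec$n_taxa, spec$branch_fn)
  } else spec$tree
  tr <- as_cptree(phy)
  pars <- spec$params
  ncol <- spec$n_columns
  ncat <- pars$ncat
  rates <- discrete_gamma_rates(pars$alpha, ncat)
  es <- rate_matrix_eigen(build_rate_matrix(pars), pars$freqs)

  # per-column mixture component: 0 = invariable, else gamma category
  cats <- ifelse(runif(ncol) < pars$pinvar, 0L, sample.int(ncat, ncol, TRUE))
  root_states <- sample.int(4L, ncol, TRUE, prob = pars$freqs)

  nnode <- 2L * tr$n_tip - 1L
  states <- matrix(0L, nnode, ncol)
  states[tr$root, ] <- root_states
  preorder <- rev(tr$postorder)
  pmat <- function(t, r) {  # transition matrix, clamped rows renormalized
    P <- es$C1 %*% (exp(es$values * r * t) * es$C2)
    P[P < 0] <- 0
    P / rowSums(P)
  }
  for (v in preorder) for (ci in 1:2) {
    ch <- tr$child[ci, v]
    t <- tr$elen[ch]
    st <- states[v, ]
    out <- st  # invariable columns copy the parent state
    for (k in seq_len(ncat)) {
      idx <- which(cats == k)
      if (!length(idx)) next
      P <- pmat(t, rates[k])
      for (s in 1:4) {
        j <- idx[st[idx] == s]
        if (length(j)) out[j] <- sample.int(4L, length(j), TRUE, prob = P[s, ])
      }
    }
    states[ch, ] <- out
  }
  rows <- apply(states[seq_len(tr$n_tip), , drop = FALSE], 1L,
                function(s) paste(NUC[s], collapse = ""))
  names(rows) <- tr$tip_label
  structure(list(alignment = new_alignment(rows),
                 truth = list(tree = as_phylo(tr), params = pars,
                              categories = cats, root_states = root_states)),
            class = "sim_alignment")
}

#' @export
print.sim_alignment <- function(x, ...) {
  cat("simulated alignment:", x$alignment$n_taxa, "taxa x",
      x$alignment$n_columns, "columns",
      sprintf("(pinvar=%.2f, alpha=%.2f)\n",
              x$truth$params$pinvar, x$truth$params$alpha))
  invisible(x)
}

#' Write a simulation with its truth record
#'
#' Writes the alignment (FASTA), the generating tree (newick) and the model
#' parameters plus per-column categories (tab-separated) next to each other.
#'
#' @param sim A `sim_alignment`.
#' @param prefix Output path prefix; creates `<prefix>.fasta`,
#'   `<prefix>.tree`, `<prefix>.truth.tsv`.
#' @return The three paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_alignment"))
  fa <- paste0(prefix, ".fasta")
  tre <- paste0(prefix, ".tree")
  tsv <- paste0(prefix, ".truth.tsv")
  write_fasta(sim$alignment, fa)
  write_newick(sim$truth$tree, tre)
  p <- sim$truth$params
  hdr <- c(paste0("r_", EXCH_NAMES), paste0("pi_", NUC), "alpha", "pinvar")
  con <- file(tsv, "w")
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(paste(c(p$exch, p$freqs, p$alpha, p$pinvar), collapse = "\t"), con)
  writeLines(paste(c("column_categories",
                     paste(sim$truth$categories, collapse = ",")),
                   collapse = "\t"), con)
  close(con)
  invisible(c(fa, tre, tsv))
}
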