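# Methods for mc3_fit objects.

pooled_params <- function(fit) {
  bf <- fit$config$burnin_frac
  do.call(rbind, lapply(fit$runs, function(r) {
    p <- r$params
    keep <- seq_len(nrow(p))
    keep <- keep[keep > floor(bf * length(keep))]
    p[keep, , drop = FALSE]
  }))
}

#' @export
print.mc3_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("MC3 fit: %d taxa, %d columns (%d unique patterns)\n",
              x$data_info$n_taxa, x$data_info$n_columns, x$data_info$L))
  cat(sprintf("  %d run(s) x %d chain(s), %d generations, %s evaluator\n",
              cfg$nruns, cfg$nchains, cfg$ngen, cfg$evaluator))
  lnl <- vapply(x$runs, function(r) max(r$params$LnL), 0)
  cat("  best sampled lnL per run:", paste(sprintf("%.3f", lnl),
                                           collapse = ", "), "\n")
  if (nrow(x$asdsf) && any(is.finite(x$asdsf$asdsf)))
    cat(sprintf("  final ASDSF: %.6f\n", tail(x$asdsf$asdsf[
      is.finite(x$asdsf$asdsf)], 1L)))
  invisible(x)
}

#' Summarize an MC3 fit
#'
#' Posterior means and credible intervals of the sampled parameters (runs
#' pooled, burn-in removed), split frequencies of the cold-chain trees, and
#' the ASDSF trace.
#'
#' @param object An `mc3_fit`.
#' @param prob Credible-interval mass (default 0.9).
#' @param ... Unused.
#' @return A list of class `summary.mc3_fit` with elements `params` (mean,
#'   sd, lower, upper per parameter), `splits` (per-run frequency maps),
#'   `asdsf` and `config`.
#' @export
summary.mc3_fit <- function(object, prob = 0.9, ...) {
  p <- pooled_params(object)
  vars <- setdiff(colnames(p), "Gen")
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  tab <- t(vapply(vars, function(v) {
    x <- p[[v]]
    c(mean = mean(x), sd = sd(x), quantile(x, qs[1L]), quantile(x, qs[2L]))
  }, numeric(4)))
  colnames(tab) <- c("mean", "sd", sprintf("q%g", 100 * qs))
  splits <- lapply(object$runs, function(r)
    split_frequencies(r$trees, object$config$burnin_frac,
                      labels = sort(object$taxa)))
  structure(list(params = tab, splits = splits, asdsf = object$asdsf,
                 prob = prob, config = object$config),
            class = "summary.mc3_fit")
}

#' @export
print.summary.mc3_fit <- function(x, ...) {
  cat("Posterior parameter summaries (runs pooled, burn-in removed):\n")
  print(round(x$params, 5))
  f <- x$splits[[1L]]
  if (length(f)) {
    cat("\nTop splits (run 1):\n")
    f <- sort(f, decreasing = TRUE)
    print(round(head(f, 8L), 3))
  }
  if (nrow(x$asdsf) && any(is.finite(x$asdsf$asdsf)))
    cat(sprintf("\nFinal ASDSF: %.6f\n",
                tail(x$asdsf$asdsf[is.finite(x$asdsf$asdsf)], 1L)))
  invisible(x)
}

#' @export
coef.mc3_fit <- function(object, ...) {
  p <- pooled_params(object)
  vars <- setdiff(colnames(p), c("Gen", "LnL"))
  colMeans(p[, vars, drop = FALSE])
}

#' @export
logLik.mc3_fit <- function(object, ...) {
  p <- pooled_params(object)
  structure(max(p$LnL), df = NA_integer_, class = "logLik")
}

#' @export
plot.mc3_fit <- function(x, ...) {
  has_diag <- nrow(x$asdsf) > 0 && any(is.finite(x$asdsf$asdsf))
  op <- graphics::par(mfrow = c(if (has_diag) 2 else 1, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  p1 <- x$runs[[1L]]$params
  graphics::plot(p1$Gen, p1$LnL, type = "l", xlab = "generation",
                 ylab = "cold-chain lnL", main = "trace", ...)
  if (length(x$runs) > 1L) {
    p2 <- x$runs[[2L]]$params
    graphics::lines(p2$Gen, p2$LnL, col = 2)
    graphics::legend("bottomright", legend = c("run 1", "run 2"),
                     col = 1:2, lty = 1, bty = "n")
  }
  if (has_diag)
    graphics::plot(x$asdsf$gen, x$asdsf$asdsf, type = "b",
                   xlab = "generation", ylab = "ASDSF", main = "convergence")
  invisible(x)
}
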