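# S3 methods for the "tucker3" model object and the grid-search table.

#' @export
print.tucker3 <- function(x, ...) {
  cat(sprintf("Tucker3 model, ranks (P, Q, R) = (%d, %d, %d)\n",
              x$ranks[1L], x$ranks[2L], x$ranks[3L]))
  cat(sprintf("  tensor: %d genotypes x %d genes x %d internodes\n",
              x$dims[1L], x$dims[2L], x$dims[3L]))
  cat(sprintf("  explained variance: %.1f%%  (%s after %d sweep%s)\n",
              100 * x$explained_fraction,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations, if (x$iterations == 1L) "" else "s"))
  invisible(x)
}

#' @describeIn tucker3 summary with the leading core-element contributions.
#' @param object,... method arguments.
#' @param n_core number of leading core elements to display.
#' @export
summary.tucker3 <- function(object, n_core = 6L, ...) {
  cc <- core_contributions(object)
  structure(list(model = object,
                 core = utils::head(cc, n_core),
                 n_core_total = nrow(cc)),
            class = "summary.tucker3")
}

#' @export
print.summary.tucker3 <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nLeading core elements (%d of %d):\n",
              nrow(x$core), x$n_core_total))
  tab <- x$core
  tab$fitted_share <- sprintf("%.1f%%", 100 * tab$fitted_share)
  tab$total_share <- sprintf("%.1f%%", 100 * tab$total_share)
  print(tab)
  invisible(x)
}

#' @describeIn tucker3 component (loading) matrices; `mode` selects
#'   genotypes (1/"genotype"), genes (2/"gene") or internodes
#'   (3/"internode"), default all three as a list.
#' @param mode which mode's loadings to return.
#' @export
coef.tucker3 <- function(object, mode = NULL, ...) {
  mats <- list(genotype = object$A, gene = object$B,
               internode = object$C)
  if (!is.null(object$dimnames)) {
    for (m in 1:3) if (!is.null(object$dimnames[[m]]))
      rownames(mats[[m]]) <- object$dimnames[[m]]
  }
  for (m in 1:3)
    colnames(mats[[m]]) <- paste0(c("A", "B", "C")[m],
                                  seq_len(ncol(mats[[m]])))
  if (is.null(mode)) return(mats)
  if (is.numeric(mode)) mode <- c("genotype", "gene", "internode")[mode]
  mats[[match.arg(mode, names(mats))]]
}

#' @describeIn tucker3 model reconstruction `X-hat` as a 3-d array.
#' @export
fitted.tucker3 <- function(object, ...) {
  xh <- .reconstruct(object)
  if (!is.null(object$dimnames)) dimnames(xh) <- object$dimnames
  xh
}

#' @describeIn tucker3 residual array `X - X-hat` (needs the stored data).
#' @export
residuals.tucker3 <- function(object, ...) {
  if (is.null(object$data))
    .stopf("model carries no data; fit with tucker3() to keep residuals")
  object$data - .reconstruct(object)
}

#' @describeIn tucker3 diagnostic plot: residual-SS trace over ALS sweeps
#'   and the sorted core-element fitted-SS shares.
#' @export
plot.tucker3 <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  if (length(x$loss_trace))
    plot(seq_along(x$loss_trace), x$loss_trace, type = "b", pch = 16,
         xlab = "ALS sweep", ylab = "residual SS", main = "Convergence", ...)
  cc <- core_contributions(x)
  graphics::barplot(cc$fitted_share, names.arg = rownames(cc), las = 2,
                    ylab = "share of fitted SS", main = "Core elements")
  invisible(x)
}

#' @describeIn tucker3 draw noisy tensors from the fitted model; the noise
#'   standard deviation defaults to the residual RMS of the fit.
#' @param nsim number of tensors to simulate.
#' @param seed optional integer seed.
#' @param noise_sd Gaussian noise SD on the reconstruction scale.
#' @export
simulate.tucker3 <- function(object, nsim = 1L, seed = NULL,
                             noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd))
    noise_sd <- sqrt(max(object$total_ss - object$fitted_ss, 0) /
                     prod(object$dims))
  xh <- .reconstruct(object)
  lapply(seq_len(nsim), function(i)
    xh + array(stats::rnorm(length(xh), sd = noise_sd), dim(xh)))
}

#' @export
print.tucker3_grid <- function(x, n = 6L, ...) {
  cat(sprintf("Tucker3 grid search: %d candidate models\n", nrow(x)))
  if (all(is.na(x$explained_fraction))) {
    cat("  (enumeration only; not fitted)\n")
  } else {
    ord <- order(-x$explained_fraction)
    cat("  best models:\n")
    print(as.data.frame(x)[utils::head(ord, n), , drop = FALSE])
  }
  invisible(x)
}

#' Scree plot of a Tucker3 grid search
#'
#' Explained variance against total component count `S = P + Q + R`, with
#' the Pareto frontier highlighted — the plot the elbow rule in
#' [choose_model()] automates.
#'
#' @param x a fitted `"tucker3_grid"`.
#' @param ... passed to [plot()].
#' @export
plot.tucker3_grid <- function(x, ...) {
  plot(x$n_components, x$explained_fraction, pch = 1, col = "grey50",
       xlab = "total components P + Q + R",
       ylab = "explained variance fraction", ...)
  s_levels <- sort(unique(x$n_components))
  frontier <- cummax(vapply(s_levels, function(s)
    max(x$explained_fraction[x$n_components == s]), numeric(1L)))
  graphics::lines(s_levels, frontier, type = "b", pch = 16)
  invisible(x)
}
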