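#' Matricise (unfold) a three-way array
#'
#' Mode-n unfolding with a fixed, documented column ordering so that cores
#' and loadings are byte-reproducible across runs:
#' \describe{
#'   \item{mode 1}{`I x JK`, column index `(k-1)*J + j` (j fast, k major)}
#'   \item{mode 2}{`J x IK`, column index `(k-1)*I + i` (i fast, k major)}
#'   \item{mode 3}{`K x IJ`, column index `(j-1)*I + i` (i fast, j major)}
#' }
#'
#' @param x a 3-d array or [threeway_array()].
#' @param mode 1 (genotypes), 2 (genes) or 3 (internodes).
#' @return the unfolded matrix.
#' @seealso [refold()]
#' @export
unfold <- function(x, mode) {
  x <- .tensor_values(x)
  d <- dim(x)
  switch(as.integer(mode),
         matrix(x, d[1L], d[2L] * d[3L]),
         matrix(aperm(x, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L]),
         matrix(aperm(x, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L]),
         .stopf("mode must be 1, 2 or 3"))
}

#' Refold a matricised array
#'
#' Inverse of [unfold()]: rebuilds the `dims` array from its mode-n
#' unfolding (same column ordering conventions).
#'
#' @param m unfolded matrix.
#' @param mode the mode `m` was unfolded along.
#' @param dims integer vector `c(I, J, K)` of the original array.
#' @return a 3-d array.
#' @export
refold <- function(m, mode, dims) {
  mode <- as.integer(mode)
  if (mode == 1L) return(array(m, dims))
  if (mode == 2L) return(aperm(array(m, dims[c(2L, 1L, 3L)]), c(2L, 1L, 3L)))
  if (mode == 3L) return(aperm(array(m, dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L)))
  .stopf("mode must be 1, 2 or 3")
}

#' Higher-order SVD initialisation
#'
#' Per-mode leading left singular vectors of the three unfoldings; the
#' standard starting point for the alternating least squares fit.
#'
#' @param x a 3-d array or [threeway_array()].
#' @param ranks integer vector `c(P, Q, R)`.
#' @return list of orthonormal matrices `A` (I x P), `B` (J x Q),
#'   `C` (K x R).
#' @export
hosvd_init <- function(x, ranks) {
  x <- .tensor_values(x)
  d <- dim(x)
  ranks <- .check_ranks(ranks, d)
  out <- lapply(1:3, function(m) svd(unfold(x, m), nu = ranks[m])$u)
  names(out) <- c("A", "B", "C")
  out
}

.check_ranks <- function(ranks, dims) {
  if (length(ranks) != 3L || any(ranks != round(ranks)) || any(ranks < 1))
    .stopf("ranks must be three positive integers (P, Q, R)")
  ranks <- as.integer(ranks)
  if (any(ranks > dims))
    .stopf("rank (%s) exceeds tensor dimension (%s)",
           paste(ranks, collapse = ","), paste(dims, collapse = ","))
  ranks
}

#' Fit a Tucker3 model to an expression tensor
#'
#' Decomposes a (centred) genotype x gene x internode array as
#' \deqn{x_{ijk} = \sum_{p=1}^{P}\sum_{q=1}^{Q}\sum_{r=1}^{R}
#'   a_{ip} b_{jq} c_{kr} g_{pqr} + e_{ijk},}
#' with orthonormal component matrices `A`, `B`, `C` and core array `G`
#' whose element \eqn{g_{pqr}} weighs the (p, q, r) component triple.  The
#' fit is orthonormal-loading alternating least squares (TUCKALS3): each
#' sweep replaces a mode's loadings by the leading left singular vectors of
#' the unfolded tensor projected on the other two modes, which maximises
#' the fitted sum of squares; iteration stops when the relative change of
#' fitted SS drops below `tol`.  Initialisation is the higher-order SVD;
#' additional random-orthonormal restarts can be requested and the best fit
#' is kept.  After convergence every loading column is flipped so its
#' largest-magnitude entry is positive, with the sign absorbed into the
#' core.
#'
#' Genes are expected centred but not scaled, so highly expressed genes
#' carry more weight in the decomposition.
#'
#' @param x a 3-d array or [threeway_array()] (typically from
#'   [build_threeway_array()]).
#' @param ranks integer vector `c(P, Q, R)` of component counts per mode.
#' @param tol relative fitted-SS convergence tolerance (default `1e-8`).
#' @param max_iter maximum ALS sweeps (default 500); exceeding it flags
#'   `converged = FALSE` rather than failing.
#' @param n_restarts number of starts (first is HOSVD, the rest random
#'   orthonormal).
#' @param seed integer seed for the random restarts.
#' @return an object of class `"tucker3"`: component matrices `A`, `B`,
#'   `C`, core `G`, `explained_fraction`, `loss_trace` (residual SS per
#'   sweep, non-increasing), `iterations`, `converged`, plus the data and
#'   dimension labels for the methods.
#' @examples
#' sim <- simulate_tucker_tensor(sim_config(
#'   n_genotypes = 6, n_genes = 40, n_internodes = 4,
#'   true_ranks = c(2, 2, 2), noise_sd = 0, seed = 1))
#' fit <- tucker3(sim$tensor, ranks = c(2, 2, 2))
#' fit$explained_fraction
#' @export
tucker3 <- function(x, ranks, tol = 1e-8, max_iter = 500L,
                    n_restarts = 1L, seed = NULL) {
  xv <- .tensor_values(x)
  d <- dim(xv)
  ranks <- .check_ranks(ranks, d)
  tot_ss <- sum(xv^2)
  if (tot_ss == 0) .stopf("tensor has zero sum of squares")
  n_restarts <- .check_count(n_restarts, "n_restarts")
  best <- NULL
  for (s in seq_len(n_restarts)) {
    init <- if (s == 1L) hosvd_init(xv, ranks) else {
      if (!is.null(seed)) set.seed(.sub_seed(seed, "restart") + s)
      list(A = .orthonormalise(matrix(stats::rnorm(d[1L] * ranks[1L]), d[1L])),
           B = .orthonormalise(matrix(stats::rnorm(d[2L] * ranks[2L]), d[2L])),
           C = .orthonormalise(matrix(stats::rnorm(d[3L] * ranks[3L]), d[3L])))
    }
    fit <- .tuckals3(xv, ranks, init, tol, max_iter, tot_ss)
    if (is.null(best) || fit$fitted_ss > best$fitted_ss) best <- fit
  }
  best <- .fix_signs(best)
  dn <- dimnames(xv)
  model <- structure(c(best, list(
    ranks = ranks, dims = d, total_ss = tot_ss,
    explained_fraction = best$fitted_ss / tot_ss,
    dimnames = dn, data = xv, call = match.call()
  )), class = "tucker3")
  model
}

# One ALS run from a given orthonormal start.
.tuckals3 <- function(x, ranks, init, tol, max_iter, tot_ss) {
  d <- dim(x)
  x1 <- unfold(x, 1L); x2 <- unfold(x, 2L); x3 <- unfold(x, 3L)
  a <- init$A; b <- init$B; cc <- init$C
  loss_trace <- numeric(0L)
  fit_ss <- -Inf; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    a <- svd(x1 %*% kronecker(cc, b), nu = ranks[1L])$u
    b <- svd(x2 %*% kronecker(cc, a), nu = ranks[2L])$u
    cc <- svd(x3 %*% kronecker(b, a), nu = ranks[3L])$u
    g1 <- crossprod(a, x1 %*% kronecker(cc, b))   # P x QR
    new_ss <- sum(g1^2)
    loss_trace <- c(loss_trace, tot_ss - new_ss)
    if (is.finite(fit_ss) &&
        abs(new_ss - fit_ss) <= tol * max(fit_ss, .Machine$double.eps)) {
      fit_ss <- new_ss
      converged <- TRUE
      break
    }
    fit_ss <- new_ss
  }
  g <- refold(g1, 1L, ranks)
  list(A = a, B = b, C = cc, G = g, fitted_ss = fit_ss,
       iterations = it, converged = converged, loss_trace = loss_trace)
}

# Flip each loading column so its largest-|.| entry is positive; compensate
# in the core so the reconstruction is unchanged.
.fix_signs <- function(fit) {
  flips <- lapply(list(fit$A, fit$B, fit$C), function(m)
    vapply(seq_len(ncol(m)), function(j) {
      v <- m[which.max(abs(m[, j])), j]
      if (v < 0) -1 else 1
    }, numeric(1L)))
  fit$A <- sweep(fit$A, 2L, flips[[1L]], `*`)
  fit$B <- sweep(fit$B, 2L, flips[[2L]], `*`)
  fit$C <- sweep(fit$C, 2L, flips[[3L]], `*`)
  sg <- outer(outer(flips[[1L]], flips[[2L]]), flips[[3L]])
  fit$G <- fit$G * sg
  fit
}

#' Assemble a Tucker3 model from known components
#'
#' Builds a `"tucker3"` object directly from component matrices and a core
#' array, e.g. for planted-structure validation or for reconstructing a
#' model read back from disk.  Loading columns must be orthonormal.
#'
#' @param A,B,C orthonormal component matrices (I x P, J x Q, K x R).
#' @param G core array (P x Q x R).
#' @param total_ss optional total SS of the data the model refers to
#'   (defaults to the fitted SS, i.e. a perfect-fit model).
#' @return a `"tucker3"` object (without `data`, so residual methods are
#'   unavailable).
#' @export
tucker3_model <- function(A, B, C, G, total_ss = NULL) {
  G <- .tensor_values(G)
  ranks <- dim(G)
  for (m in list(A, B, C)) {
    gram <- crossprod(m)
    if (max(abs(gram - diag(ncol(m)))) > 1e-8)
      .stopf("loading columns must be orthonormal")
  }
  if (ncol(A) != ranks[1L] || ncol(B) != ranks[2L] || ncol(C) != ranks[3L])
    .stopf("core dimensions must match loading column counts")
  fit_ss <- sum(G^2)
  if (is.null(total_ss)) total_ss <- fit_ss
  structure(list(A = A, B = B, C = C, G = G, fitted_ss = fit_ss,
                 iterations = 0L, converged = TRUE, loss_trace = numeric(0L),
                 ranks = as.integer(ranks),
                 dims = c(nrow(A), nrow(B), nrow(C)),
                 total_ss = total_ss,
                 explained_fraction = fit_ss / total_ss,
                 dimnames = NULL, data = NULL, call = match.call()),
            class = "tucker3")
}

# Reconstruction X-hat from components.
.reconstruct <- function(model) {
  g1 <- unfold(model$G, 1L)
  refold(model$A %*% g1 %*% t(kronecker(model$C, model$B)), 1L, model$dims)
}

#' Explained variance of a Tucker3 model
#'
#' Fraction of total sum of squares captured by the model,
#' `1 - ||X - Xhat||^2 / ||X||^2`.  With orthonormal loadings this equals
#' `sum(G^2) / ||X||^2`.
#'
#' @param model a `"tucker3"` object.
#' @param x the tensor the model was fitted to (defaults to the data stored
#'   in the model).
#' @return a fraction in `[0, 1]`.
#' @export
explained_variance <- function(model, x = NULL) {
  if (is.null(x)) x <- model$data
  if (is.null(x)) .stopf("no tensor available; pass 'x'")
  xv <- .tensor_values(x)
  tot <- sum(xv^2)
  if (tot == 0) .stopf("tensor has zero sum of squares")
  1 - sum((xv - .reconstruct(model))^2) / tot
}

#' Core-element variance contributions
#'
#' For every core element \eqn{g_{pqr}}: its share of the fitted sum of
#' squares (`g^2 / sum(G^2)`) and of the total data SS (`g^2 / ||X||^2`),
#' sorted by decreasing magnitude.  The dominant elements identify which
#' component triples drive expression variation.
#'
#' @param model a `"tucker3"` object.
#' @return data.frame with columns `p`, `q`, `r`, `g`, `fitted_share`,
#'   `total_share`.
#' @export
core_contributions <- function(model) {
  g <- model$G
  idx <- which(array(TRUE, dim(g)), arr.ind = TRUE)
  out <- data.frame(p = idx[, 1L], q = idx[, 2L], r = idx[, 3L],
                    g = g[idx],
                    fitted_share = g[idx]^2 / sum(g^2),
                    total_share = g[idx]^2 / model$total_ss)
  out <- out[order(-out$g^2, out$p, out$q, out$r), , drop = FALSE]
  rownames(out) <- sprintf("g%d%d%d", out$p, out$q, out$r)
  out
}

#' Grid search over Tucker3 component numbers
#'
#' Fits every combination `(P, Q, R)` in `1..Pmax x 1..Qmax x 1..Rmax` and
#' records the explained variance of each, the basis for scree-style model
#' selection.  `dry_run = TRUE` enumerates the grid without fitting
#' (explained fractions `NA`), useful to inspect the candidate set.
#'
#' @param x a 3-d array or [threeway_array()].
#' @param pmax,qmax,rmax per-mode maxima (defaults 5, 20, 3).
#' @param tol,max_iter,n_restarts,seed passed to [tucker3()].
#' @param dry_run enumerate only, without fitting.
#' @return data.frame of class `"tucker3_grid"` with one row per
#'   combination: `P`, `Q`, `R`, `n_components`, `explained_fraction`,
#'   `converged`.
#' @export
tucker3_grid <- function(x, pmax = 5L, qmax = 20L, rmax = 3L,
                         tol = 1e-8, max_iter = 500L, n_restarts = 1L,
                         seed = NULL, dry_run = FALSE) {
  xv <- if (dry_run && !is.array(x) && !inherits(x, "threeway_array")) NULL
        else .tensor_values(x)
  pmax <- .check_count(pmax, "pmax"); qmax <- .check_count(qmax, "qmax")
  rmax <- .check_count(rmax, "rmax")
  if (!is.null(xv) && any(c(pmax, qmax, rmax) > dim(xv)))
    .stopf("grid maxima (%d, %d, %d) exceed tensor dimensions (%s)",
           pmax, qmax, rmax, paste(dim(xv), collapse = ", "))
  grid <- expand.grid(P = seq_len(pmax), Q = seq_len(qmax),
                      R = seq_len(rmax), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$P, grid$Q, grid$R), , drop = FALSE]
  rownames(grid) <- NULL
  grid$n_components <- grid$P + grid$Q + grid$R
  if (dry_run) {
    grid$explained_fraction <- NA_real_
    grid$converged <- NA
  } else {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      fit <- tucker3(xv, c(grid$P[i], grid$Q[i], grid$R[i]), tol = tol,
                     max_iter = max_iter, n_restarts = n_restarts,
                     seed = seed)
      c(fit$explained_fraction, fit$converged)
    })
    grid$explained_fraction <- vapply(res, `[`, numeric(1L), 1L)
    grid$converged <- as.logical(vapply(res, `[`, numeric(1L), 2L))
  }
  class(grid) <- c("tucker3_grid", "data.frame")
  grid
}

#' Choose component numbers from a grid search
#'
#' Automated stand-in for visual scree inspection.  The default `"elbow"`
#' rule orders candidate models by total component count
#' `S = P + Q + R`, keeps the Pareto frontier (best explained fraction
#' per S), and picks the smallest S beyond which every per-step
#' explained-variance gain stays below `eps` — the point where the scree
#' curve flattens for good.  (Looking at all later gains, not just the
#' next one, matters because explained-variance curves over S can
#' plateau and then jump once components in several modes combine.)
#' Ties at the chosen S are broken lexicographically by `(P, Q, R)`.
#'
#' @param grid a `"tucker3_grid"` (fitted, not dry-run).
#' @param rule `"elbow"` (default) or `"manual"`.
#' @param eps minimum worthwhile gain per step of S (default 0.01).
#' @param ranks for `rule = "manual"`, the `(P, Q, R)` to pass through.
#' @return integer vector `c(P, Q, R)`.
#' @export
choose_model <- function(grid, rule = c("elbow", "manual"), eps = 0.01,
                         ranks = NULL) {
  rule <- match.arg(rule)
  if (nrow(grid) == 0L) .stopf("empty grid")
  if (rule == "manual") {
    if (is.null(ranks) || length(ranks) != 3L)
      .stopf("manual rule needs ranks = c(P, Q, R)")
    return(as.integer(ranks))
  }
  if (!is.numeric(eps) || length(eps) != 1L || eps < 0)
    .stopf("'eps' must be a single non-negative number")
  if (anyNA(grid$explained_fraction))
    .stopf("grid has unfitted rows; rerun without dry_run")
  s_levels <- sort(unique(grid$n_components))
  best <- vapply(s_levels, function(s)
    max(grid$explained_fraction[grid$n_components == s]), numeric(1L))
  frontier <- cummax(best)  # Pareto frontier over S
  gains <- c(diff(frontier), 0)
  # largest remaining gain at or after each S; flat-for-good when < eps
  suffix_max <- rev(cummax(rev(gains)))
  hit <- which(suffix_max < eps)
  chosen_s <- if (length(hit)) s_levels[hit[1L]] else s_levels[length(s_levels)]
  cand <- grid[grid$n_components == chosen_s, , drop = FALSE]
  target <- max(cand$explained_fraction)
  cand <- cand[cand$explained_fraction >= target - 1e-12, , drop = FALSE]
  cand <- cand[order(cand$P, cand$Q, cand$R), , drop = FALSE]
  as.integer(unlist(cand[1L, c("P", "Q", "R")]))
}

#' Attribute core variance to main effects and interaction
#'
#' A mode component is "constant" when, after flipping its sign so the mean
#' loading is positive, the coefficient of variation of its loadings is
#' below `cv_threshold` — i.e. all genotypes (or all internodes) load
#' almost equally on it.  A core element whose genotype component is
#' constant expresses variation among internodes only (an internode main
#' effect); one whose internode component is constant is a genotype main
#' effect; all others are genotype-by-internode interaction.  Fitted-SS
#' shares are summed per class; a high combined main-effect share indicates
#' little genotype-by-stage interaction in expression.
#'
#' @param model a `"tucker3"` object.
#' @param contributions optional precomputed [core_contributions()] table.
#' @param cv_threshold coefficient-of-variation cut-off for "constant"
#'   (default 0.2).
#' @return list with the per-element classification table (`table`), the
#'   per-class fitted-SS shares (`shares`), the combined `main_effect_share`
#'   and the per-mode constancy flags.
#' @export
partition_main_effects <- function(model, contributions = NULL,
                                   cv_threshold = 0.2) {
  if (is.null(contributions)) contributions <- core_contributions(model)
  const_flag <- function(m) apply(m, 2L, function(col) {
    if (mean(col) < 0) col <- -col
    mu <- mean(col)
    if (mu <= 0) return(FALSE)
    stats::sd(col) / mu < cv_threshold
  })
  a_const <- const_flag(model$A)
  c_const <- const_flag(model$C)
  cls <- ifelse(a_const[contributions$p], "internode_main",
                ifelse(c_const[contributions$r], "genotype_main",
                       "interaction"))
  tab <- cbind(contributions, class = cls)
  shares <- vapply(c("genotype_main", "internode_main", "interaction"),
                   function(k) sum(tab$fitted_share[tab$class == k]),
                   numeric(1L))
  list(table = tab, shares = shares,
       main_effect_share = shares[["genotype_main"]] +
         shares[["internode_main"]],
       genotype_component_constant = a_const,
       internode_component_constant = c_const)
}
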