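#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample normalisation factors for count libraries following the
#' Robinson-Oshlack trimmed-mean algorithm: log-ratios (M) and average
#' log-abundances (A) are computed against a reference library on
#' library-size-normalised counts, doubly trimmed (30% on M, 5% on A by
#' default), and combined with inverse-variance precision weights.  The
#' reference is the library whose upper-quartile fraction is closest to the
#' mean upper-quartile fraction; ties go to the first such library.  Factors
#' are normalised to geometric mean 1.
#'
#' With `effective = TRUE` the function instead returns relative *effective*
#' size factors, `library size x TMM factor` normalised to geometric mean 1,
#' which fold sequencing depth and composition into a single per-sample
#' scale (the normalised effective library size).
#'
#' @param counts an [expression_matrix()] with unit `"counts"` and at least
#'   two samples.
#' @param logratio_trim,abundance_trim two-sided trim fractions applied to
#'   the M and A values.
#' @param effective if `TRUE`, return normalised effective size factors
#'   (library size times composition factor) instead of pure composition
#'   factors.
#' @return named numeric vector, one positive factor per sample, geometric
#'   mean 1.
#' @references Robinson MD, Oshlack A (2010) A scaling normalization method
#'   for differential expression analysis of RNA-seq data.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abundance_trim = 0.05,
                        effective = FALSE) {
  .assert_unit(counts, "counts", "tmm_factors")
  x <- unclass(counts)
  if (ncol(x) < 2L) .stopf("TMM needs at least 2 samples")
  lib <- colSums(x)
  zero <- lib == 0
  if (any(zero))
    .stopf("all-zero sample(s): %s", paste(colnames(x)[zero], collapse = ", "))
  f75 <- apply(x, 2L, function(col) stats::quantile(col, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(s) {
    .tmm_pair(x[, s], x[, ref], lib[s], lib[ref],
              logratio_trim, abundance_trim)
  }, numeric(1L))
  if (effective) f <- f * lib
  f <- f / .geomean(f)
  names(f) <- colnames(x)
  f
}

# Composition factor of obs relative to ref (Robinson-Oshlack weighted
# trimmed mean of library-normalised M-values).
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  if (length(o) == 0L) return(1)
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra_ <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2) || sum(w[keep2]) == 0) return(1)
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' Log2 normalisation to CPM or TPM scale
#'
#' Converts counts to `log2(CPM + 1)` (counts per million, optionally using
#' TMM-scaled effective library sizes) or applies `log2(TPM + 1)` to a TPM
#' matrix, which needs no further between-sample scaling.
#'
#' @param expr an [expression_matrix()]; unit `"counts"` for `mode = "CPM"`,
#'   unit `"TPM"` for `mode = "TPM"`.
#' @param factors optional named per-sample TMM factors (composition
#'   factors; the effective library size used is `library size x factor`).
#' @param mode `"CPM"` or `"TPM"`.
#' @return an [expression_matrix()] with unit `"log2CPM1"` or `"log2TPM1"`.
#' @export
normalize_log <- function(expr, factors = NULL, mode = c("CPM", "TPM")) {
  mode <- match.arg(mode)
  x <- unclass(expr)
  if (any(x < 0)) .stopf("negative expression values")
  if (mode == "TPM") {
    .assert_unit(expr, "TPM", "normalize_log(mode = 'TPM')")
    if (!is.null(factors)) .stopf("TPM mode is scaling-free; drop 'factors'")
    return(.retag(log2(x + 1), "log2TPM1"))
  }
  .assert_unit(expr, "counts", "normalize_log(mode = 'CPM')")
  lib <- colSums(x)
  if (!is.null(factors)) {
    if (length(factors) != ncol(x))
      .stopf("need one factor per sample")
    if (!is.null(names(factors))) factors <- factors[colnames(x)]
    lib <- lib * as.numeric(factors)
  }
  cpm <- sweep(x, 2L, lib / 1e6, `/`)
  .retag(log2(cpm + 1), "log2CPM1")
}

#' Low-count prevalence filter
#'
#' Keeps a gene when it reaches `min_count` reads in at least a fraction
#' `min_fraction` of the samples (inclusive boundary: a gene observed at the
#' threshold in exactly that fraction of samples is retained).
#'
#' @param counts an [expression_matrix()] with unit `"counts"`.
#' @param min_count minimum read count per sample (default 10).
#' @param min_fraction minimum fraction of samples reaching `min_count`
#'   (default 0.70).
#' @return the filtered [expression_matrix()]; removed gene ids in attribute
#'   `"removed"`.
#' @export
filter_min_count <- function(counts, min_count = 10, min_fraction = 0.70) {
  .assert_unit(counts, "counts", "filter_min_count")
  min_fraction <- .check_fraction(min_fraction, "min_fraction")
  x <- unclass(counts)
  frac <- rowMeans(x >= min_count)
  keep <- frac >= min_fraction
  out <- .retag(x[keep, , drop = FALSE], "counts")
  attr(out, "removed") <- rownames(x)[!keep]
  out
}

#' Zero-prevalence filter
#'
#' Removes a gene when *more than* `max_zero_fraction` of its values are
#' zero (strict boundary: a gene with exactly that fraction of zeros is
#' kept).
#'
#' @param expr an [expression_matrix()] (any unit).
#' @param max_zero_fraction maximum tolerated zero fraction (default 0.80).
#' @return the filtered [expression_matrix()]; removed gene ids in attribute
#'   `"removed"`.
#' @export
filter_zero_fraction <- function(expr, max_zero_fraction = 0.80) {
  max_zero_fraction <- .check_fraction(max_zero_fraction, "max_zero_fraction",
                                       lo = 0, lo_open = FALSE)
  x <- unclass(expr)
  zf <- rowMeans(x == 0)
  keep <- zf <= max_zero_fraction
  out <- .retag(x[keep, , drop = FALSE], expr_unit(expr))
  attr(out, "removed") <- rownames(x)[!keep]
  out
}

#' Build the genotype x gene x internode array
#'
#' Averages replicate samples within each (genotype, internode) cell of a
#' log-scale expression matrix and centres each gene to grand mean zero
#' across all I x K cells ("centred but not scaled": gene profiles keep
#' their natural scale, so highly expressed genes carry more weight in the
#' three-way fit).
#'
#' @param expr an [expression_matrix()] with unit `"log2CPM1"` or
#'   `"log2TPM1"`.
#' @param meta a [sample_metadata()] covering every column of `expr`; every
#'   (genotype, internode) cell must contain at least one sample.
#' @param center `"grand"` (default; per-gene grand mean over all cells),
#'   `"internode"` (per-gene mean within each internode) or `"none"`.
#' @return a [threeway_array()].
#' @export
build_threeway_array <- function(expr, meta,
                                 center = c("grand", "internode", "none")) {
  center <- match.arg(center)
  .assert_unit(expr, c("log2CPM1", "log2TPM1"), "build_threeway_array")
  x <- unclass(expr)
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    .stopf("metadata is missing sample(s): %s",
           paste(setdiff(colnames(x), meta$sample_id), collapse = ", "))
  gt <- sort(unique(meta$genotype))
  it <- sort(unique(meta$internode))
  grid <- expand.grid(genotype = gt, internode = it,
                      stringsAsFactors = FALSE)
  have <- paste(meta$genotype, meta$internode, sep = "\r")
  want <- paste(grid$genotype, grid$internode, sep = "\r")
  missing_cells <- !want %in% have
  if (any(missing_cells))
    .stopf("empty (genotype, internode) cell(s): %s",
           paste(sprintf("(%s, %s)", grid$genotype[missing_cells],
                         grid$internode[missing_cells]), collapse = ", "))
  arr <- array(NA_real_, dim = c(length(gt), nrow(x), length(it)),
               dimnames = list(gt, rownames(x), it))
  for (k in seq_along(it)) {
    for (i in seq_along(gt)) {
      cols <- meta$genotype == gt[i] & meta$internode == it[k]
      arr[i, , k] <- rowMeans(x[, cols, drop = FALSE])
    }
  }
  if (center == "grand") {
    gmean <- apply(arr, 2L, mean)
    arr <- arr - rep(gmean, each = length(gt))  # recycles over k as well
    desc <- "per-gene grand mean over all genotype x internode cells"
  } else if (center == "internode") {
    for (k in seq_along(it)) {
      slice <- arr[, , k]
      arr[, , k] <- sweep(slice, 2L, colMeans(slice))
    }
    desc <- "per-gene mean within each internode"
  } else desc <- "none"
  threeway_array(arr, centering = desc)
}

#' Principal component analysis of samples
#'
#' PCA of samples on gene-centred expression: each gene (variable) is
#' centred across samples, and sample scores on the leading components are
#' returned together with the fraction of variance each explains.
#'
#' @param expr an [expression_matrix()].
#' @param n_components number of leading components.
#' @return list with `scores` (samples x components) and `explained`
#'   (non-increasing variance fractions).
#' @export
sample_pca <- function(expr, n_components = 2L) {
  x <- unclass(expr)
  n_components <- .check_count(n_components, "n_components")
  if (ncol(x) < 2L) .stopf("need at least 2 samples")
  if (n_components > min(dim(x)))
    .stopf("n_components exceeds min(genes, samples) = %d", min(dim(x)))
  xc <- x - rowMeans(x)
  sv <- svd(xc, nu = 0L, nv = n_components)
  scores <- sv$v * rep(sv$d[seq_len(n_components)], each = ncol(x))
  # deterministic sign: largest-|score| entry of each component positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(n_components)]
  list(scores = scores, explained = explained)
}

#' Hierarchical clustering of expression profiles
#'
#' Ward-linkage (classical `ward.D`) agglomeration on Euclidean distances
#' between expression profiles: either individual samples or replicate-mean
#' genotype-by-stage profiles.  For TPM input the Fig-style
#' `log10(mean TPM + 1)` transform is available (a global sign flip of the
#' transform leaves Euclidean distances unchanged, so the magnitude
#' transform is used).  Profiles are ordered by id before clustering so the
#' tree is reproducible.
#'
#' @param expr an [expression_matrix()].
#' @param meta optional [sample_metadata()]; required for
#'   `profiles = "genotype_stage"`.
#' @param profiles cluster `"samples"` or replicate-mean
#'   `"genotype_stage"` profiles.
#' @param transform `"none"` (use values as-is; suits log2 units) or
#'   `"log10_mean1"` (`log10(value + 1)`, applied after replicate
#'   averaging; suits TPM).
#' @return an object of class `"hclust"`.
#' @export
expression_dendrogram <- function(expr, meta = NULL,
                                  profiles = c("samples", "genotype_stage"),
                                  transform = c("none", "log10_mean1")) {
  profiles <- match.arg(profiles)
  transform <- match.arg(transform)
  x <- unclass(expr)
  if (profiles == "genotype_stage") {
    if (is.null(meta)) .stopf("genotype_stage profiles need metadata")
    meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
    grp <- paste(meta$genotype, meta$internode, sep = ".")
    x <- vapply(sort(unique(grp)), function(g)
      rowMeans(x[, grp == g, drop = FALSE]), numeric(nrow(x)))
  }
  if (transform == "log10_mean1") x <- log10(x + 1)
  if (ncol(x) < 2L) .stopf("need at least 2 profiles to cluster")
  prof <- t(x)[order(colnames(x)), , drop = FALSE]
  stats::hclust(stats::dist(prof, method = "euclidean"), method = "ward.D")
}

#' Standardise trait columns (auto scaling)
#'
#' Centres and scales every numeric trait column to mean 0 and unit sample
#' standard deviation.
#'
#' @param traits data.frame with a `sample_id` (or id) first column and
#'   numeric trait columns, or a plain numeric data.frame/matrix.
#' @return object of the same shape with standardised trait columns.
#' @export
autoscale_traits <- function(traits) {
  if (!is.data.frame(traits)) traits <- as.data.frame(traits)
  num <- vapply(traits, is.numeric, logical(1L))
  for (j in which(num)) {
    v <- traits[[j]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      .stopf("constant trait: %s", colnames(traits)[j])
    traits[[j]] <- (v - mean(v)) / s
  }
  traits
}
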