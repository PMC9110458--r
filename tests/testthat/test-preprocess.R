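# Normalisation, filtering, tensor construction and exploratory
# clustering.

make_counts <- function(m) {
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  expression_matrix(m, "counts")
}

test_that("TMM factors: identical and purely scaled libraries", {
  set.seed(3)
  base <- rpois(300, 60)
  em <- make_counts(cbind(base, base))
  expect_equal(unname(tmm_factors(em)), c(1, 1), tolerance = 1e-12)
  # library B = 2 x library A gene-wise: composition identical, effective
  # size factors reflect the depth ratio after geometric-mean scaling
  em2 <- make_counts(cbind(base, 2L * base))
  expect_equal(unname(tmm_factors(em2)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(tmm_factors(em2, effective = TRUE)),
               c(2^-0.5, 2^0.5), tolerance = 1e-12)
})

test_that("TMM matches the independently coded trimmed-mean oracle", {
  set.seed(11)
  mu <- rexp(200, 0.002) + 50
  x <- sapply(1:5, function(s) rnbinom(200, mu = mu * runif(1, 0.5, 2),
                                       size = 5))
  em <- make_counts(x)
  expect_equal(unname(tmm_factors(em)), oracle_tmm(unclass(em)),
               tolerance = 1e-10)
  # scaled copies of one library return the scaling ratios exactly
  y <- make_counts(cbind(4L * mu %/% 1 + 1L, (4L * mu %/% 1 + 1L) * 3L))
  sf <- tmm_factors(y, effective = TRUE)
  expect_equal(unname(sf[2] / sf[1]), 3, tolerance = 1e-12)
  # all-zero sample names the culprit
  z <- unclass(em); z[, 2] <- 0L
  expect_error(tmm_factors(make_counts(z)), "s02")
})

test_that("log2 CPM/TPM transforms follow the direct arithmetic", {
  m <- rbind(g1 = c(50, 50), g2 = c(999950, 999950))
  colnames(m) <- c("a", "b")
  em <- expression_matrix(m, "counts")
  lc <- normalize_log(em, NULL, "CPM")
  expect_equal(unclass(lc)["g1", "a"], log2(51), tolerance = 1e-12)
  expect_identical(expr_unit(lc), "log2CPM1")
  # TMM factor 2 halves the CPM
  lc2 <- normalize_log(em, c(a = 2, b = 1), "CPM")
  expect_equal(unclass(lc2)["g1", "a"], log2(26), tolerance = 1e-12)
  # zero count stays zero after transform
  m0 <- rbind(g1 = c(0, 2), g2 = c(10, 8))
  colnames(m0) <- c("a", "b")
  l0 <- normalize_log(expression_matrix(m0, "counts"), NULL, "CPM")
  expect_identical(unclass(l0)["g1", 1][[1]], 0)
  # TPM passes through scaling-free, monotone per sample
  tp <- rand_expr(50, 6, "TPM", seed = 2)
  lt <- normalize_log(tp, mode = "TPM")
  expect_identical(expr_unit(lt), "log2TPM1")
  for (s in 1:6)
    expect_identical(order(unclass(tp)[, s]), order(unclass(lt)[, s]))
})

test_that("prevalence filters honour their boundary semantics", {
  m <- rbind(keep = c(rep(10, 7), rep(9, 3)),
             drop = c(rep(10, 6), rep(9, 4)))
  colnames(m) <- sprintf("s%02d", 1:10)
  f <- filter_min_count(expression_matrix(m, "counts"))
  expect_identical(rownames(f), "keep")      # 7/10 at the threshold kept
  expect_identical(attr(f, "removed"), "drop")

  z2 <- matrix(0, 2, 100,
               dimnames = list(c("keep", "drop"), sprintf("s%03d", 1:100)))
  z2["keep", 81:100] <- 1
  z2["drop", 82:100] <- 1                    # 81% zeros: removed
  fz <- filter_zero_fraction(expression_matrix(z2, "TPM"))
  expect_identical(rownames(fz), "keep")
  expect_error(filter_min_count(expression_matrix(z2, "TPM")), "unit")
  expect_error(filter_min_count(expression_matrix(m, "counts"),
                                min_fraction = 1.2), "min_fraction")
})

test_that("filters equal the exhaustive per-gene oracle and are idempotent", {
  set.seed(5)
  x <- matrix(rpois(500 * 12, 12), 500, 12,
              dimnames = list(sprintf("g%03d", 1:500),
                              sprintf("s%02d", 1:12)))
  em <- expression_matrix(x, "counts")
  f <- filter_min_count(em, 10, 0.7)
  keep_oracle <- vapply(seq_len(nrow(x)), function(g)
    sum(x[g, ] >= 10) / ncol(x) >= 0.7, logical(1))
  expect_identical(rownames(f), rownames(x)[keep_oracle])
  expect_identical(rownames(filter_min_count(f, 10, 0.7)), rownames(f))

  x[sample(length(x), 3000)] <- 0
  em <- expression_matrix(x, "counts")
  fz <- filter_zero_fraction(em, 0.4)
  zo <- vapply(seq_len(nrow(x)), function(g)
    mean(x[g, ] == 0) <= 0.4, logical(1))
  expect_identical(rownames(fz), rownames(x)[zo])
  expect_identical(rownames(filter_zero_fraction(fz, 0.4)), rownames(fz))
})

test_that("three-way array equals replicate means and is grand-centred", {
  # 3 genotypes x 2 internodes x 2 replicates, hand-checkable values
  gt <- rep(c("A", "B", "C"), each = 4)
  it <- rep(rep(c("I1", "I2"), each = 2), 3)
  rp <- rep(1:2, 6)
  ids <- paste(gt, it, rp, sep = "_")
  set.seed(9)
  x <- matrix(round(runif(5 * 12, 1, 9), 1), 5, 12,
              dimnames = list(sprintf("g%d", 1:5), ids))
  em <- expression_matrix(x, "TPM")
  lt <- normalize_log(em, mode = "TPM")
  meta <- sample_metadata(ids, gt, it, rp)
  tw <- build_threeway_array(lt, meta)
  # spreadsheet-style oracle for one cell and one gene
  for (g in c("g1", "g4")) for (gg in c("A", "C")) for (kk in c("I1", "I2")) {
    cell <- mean(unclass(lt)[g, gt == gg & it == kk])
    grand <- mean(vapply(unique(gt), function(a)
      mean(vapply(unique(it), function(b)
        mean(unclass(lt)[g, gt == a & it == b]), numeric(1))), numeric(1)))
    expect_equal(tw$values[gg, g, kk], cell - grand, tolerance = 1e-12)
  }
  expect_lt(max(abs(apply(tw$values, 2, mean))), 1e-9)
  # identical replicates: the cell equals the replicate value
  x2 <- x; x2[, rp == 2] <- x2[, rp == 1]
  tw2 <- build_threeway_array(normalize_log(expression_matrix(x2, "TPM"),
                                            mode = "TPM"), meta,
                              center = "none")
  expect_equal(tw2$values["A", "g1", "I1"],
               log2(x2["g1", "A_I1_1"] + 1), tolerance = 1e-12)
  # missing cell is reported by name
  lt10 <- expression_matrix(unclass(lt)[, 1:10], "log2TPM1")
  expect_error(build_threeway_array(lt10, meta[1:10, ]), "\\(C, I2\\)")
})

test_that("tensor construction commutes with gene subsetting", {
  sim <- small_two_module_sim(seed = 8, n_genes = 60, module_size = 20)
  lc <- normalize_log(sim$counts, NULL, "CPM")
  sub <- rownames(lc)[c(3, 10, 41)]
  full <- build_threeway_array(lc, sim$metadata)
  subset_first <- build_threeway_array(
    expression_matrix(unclass(lc)[sub, ], "log2CPM1"), sim$metadata)
  expect_equal(full$values[, sub, ], subset_first$values,
               tolerance = 1e-12)
})

test_that("sample PCA matches the covariance eigendecomposition", {
  em <- rand_expr(20, 8, "TPM", seed = 4)
  p <- sample_pca(em, 4)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  # eigen oracle on the gene-centred cross-product
  x <- unclass(em) - rowMeans(unclass(em))
  ev <- eigen(crossprod(x), symmetric = TRUE)
  for (j in 1:4) {
    sc <- ev$vectors[, j] * sqrt(ev$values[j])
    expect_equal(abs(p$scores[, j]), abs(sc), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # duplicated sample gets identical scores
  xx <- cbind(unclass(em), dup = unclass(em)[, 3])
  colnames(xx) <- c(colnames(em), "dup")
  p2 <- sample_pca(expression_matrix(xx, "TPM"), 2)
  expect_equal(p2$scores["s003", ], p2$scores["dup", ], tolerance = 1e-10)
  expect_error(sample_pca(em, 50), "n_components")
})

test_that("ward dendrogram reproduces a from-scratch agglomeration", {
  em <- rand_expr(15, 10, "TPM", seed = 6)
  tree <- expression_dendrogram(em)
  d <- dist(t(unclass(em))[order(colnames(em)), ])
  expect_equal(tree$height, oracle_ward_heights(d), tolerance = 1e-8)
  # identical profiles merge at height zero, an outlier joins last
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), z = c(40, 50, 60))
  rownames(m) <- c("g1", "g2", "g3")
  t2 <- expression_dendrogram(expression_matrix(m, "TPM"))
  expect_equal(t2$height[1], 0, tolerance = 1e-12)
  expect_true(-match("z", t2$labels) %in% t2$merge[2, ])
  expect_error(expression_dendrogram(em[, 1, drop = FALSE]), "profiles")
})

test_that("autoscaling gives exact z-scores and flags constants", {
  tr <- data.frame(sample_id = c("a", "b", "c"), x = c(1, 2, 3),
                   y = c(4, 0, 2))
  sc <- autoscale_traits(tr)
  expect_equal(sc$x, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(sc$y, (tr$y - mean(tr$y)) / sd(tr$y), tolerance = 1e-12)
  expect_equal(autoscale_traits(sc)$x, sc$x, tolerance = 1e-12)
  tr$z <- 5
  expect_error(autoscale_traits(tr), "z")
})
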