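# Independent oracles and small fixture builders.  Every oracle here is a
# from-scratch re-derivation (brute force or closed form) of the quantity
# the package computes by its production path.

# Robinson-Oshlack trimmed mean of M-values, coded independently of
# tmm_factors(): sort-based double trim, precision weights, library-
# normalised log-ratios.
oracle_tmm <- function(x, logratio_trim = 0.30, abundance_trim = 0.05) {
  lib <- colSums(x)
  uq <- vapply(seq_len(ncol(x)),
               function(s) stats::quantile(x[, s], 0.75) / lib[s],
               numeric(1L))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(x))
  for (s in seq_len(ncol(x))) {
    pos <- which(x[, s] > 0 & x[, ref] > 0)
    o <- x[pos, s]; r <- x[pos, ref]
    m <- log2(o / lib[s]) - log2(r / lib[ref])
    a <- (log2(o / lib[s]) + log2(r / lib[ref])) / 2
    w <- (lib[s] - o) / (lib[s] * o) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abundance_trim) + 1; hi_a <- n + 1 - lo_a
    # mid-ranks by explicit counting (average over ties)
    midrank <- function(v) vapply(v, function(vi)
      sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1L))
    rm_ <- midrank(m); ra_ <- midrank(a)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    f[s] <- 2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# Topological overlap by definition, triple loop.
oracle_tom <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + adj[i, u] * adj[u, j]
    tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  tom
}

# Classical ward.D agglomeration via the Lance-Williams update, O(n^3).
oracle_ward_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1L, n)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      dd <- d[active[ii], active[jj]]
      if (dd < bestd) { bestd <- dd; best <- c(ii, jj) }
    }
    i <- active[best[1L]]; j <- active[best[2L]]
    heights[step] <- bestd
    ni <- sizes[i]; nj <- sizes[j]
    for (kk in active) {
      if (kk == i || kk == j) next
      nk <- sizes[kk]
      dn <- ((ni + nk) * d[i, kk] + (nj + nk) * d[j, kk] - nk * d[i, j]) /
        (ni + nj + nk)
      d[i, kk] <- dn; d[kk, i] <- dn
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Scale-free fit statistic coded from first principles: equal-width bins
# with the same 0.1%-extended break convention as base cut(), closed-form
# least squares.
oracle_scale_free <- function(k, n_bins = 10L) {
  rng <- range(k)
  pad <- diff(rng) / 1000
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  breaks[1L] <- breaks[1L] - pad
  breaks[n_bins + 1L] <- breaks[n_bins + 1L] + pad
  bin <- findInterval(k, breaks, left.open = TRUE)  # (b_j, b_{j+1}] bins
  km <- fq <- numeric(0L)
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b)
    if (!length(idx)) next
    km <- c(km, mean(k[idx]))
    fq <- c(fq, length(idx) / length(k))
  }
  ok <- km > 0 & fq > 0
  x <- log10(km[ok]); y <- log10(fq[ok])
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * sum((y - mean(y))^2))
  list(r2 = r2, signed_r2 = if (slope < 0) r2 else -r2, slope = slope)
}

# Full trilinear reconstruction by definition (quadruple loop).
oracle_reconstruct <- function(A, B, C, G) {
  dims <- c(nrow(A), nrow(B), nrow(C))
  rk <- dim(G)
  x <- array(0, dims)
  for (i in seq_len(dims[1L])) for (j in seq_len(dims[2L]))
    for (k in seq_len(dims[3L])) {
      s <- 0
      for (p in seq_len(rk[1L])) for (q in seq_len(rk[2L]))
        for (r in seq_len(rk[3L]))
          s <- s + A[i, p] * B[j, q] * C[k, r] * G[p, q, r]
      x[i, j, k] <- s
    }
  x
}

# Random genes-x-samples expression fixture.
rand_expr <- function(n_genes, n_samples, unit = "TPM", seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_genes * n_samples, rate = 0.1),
              n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  if (unit == "counts") m[] <- stats::rpois(length(m), lambda = m + 1)
  expression_matrix(m, unit)
}

# A small planted two-module experiment used by several end-to-end tests.
small_two_module_sim <- function(seed, n_genes = 300L, module_size = 60L) {
  cfg <- sim_config(n_genotypes = 8L, n_genes = n_genes,
                    n_internodes = 4L, n_replicates = 2L,
                    true_ranks = c(2L, 3L, 2L), seed = seed,
                    module_spec = list(
                      list(size = module_size, trait_effect = 1,
                           inter_gene_cor = 0.9),
                      list(size = module_size, trait_effect = -1,
                           inter_gene_cor = 0.9)))
  simulate_experiment(cfg)
}

# Majority-label recovery of a planted module under an assignment.
module_recovery <- function(assignment, membership, module_id) {
  genes <- names(membership)[!is.na(membership) & membership == module_id]
  lab <- unclass(assignment)[genes]
  lab <- lab[lab != "grey"]
  if (!length(lab)) return(list(label = NA_character_, recovery = 0))
  tab <- sort(table(lab), decreasing = TRUE)
  list(label = names(tab)[1L], recovery = tab[[1L]] / length(genes))
}

# Orthonormal matrix deterministic in its seed.
rand_orth <- function(n, p, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(n * p), n, p)))
}

# Twenty seeded end-to-end runs at the full study design (24 genotypes x
# 5 internodes x 3 replicates, 2,000 genes, two antagonistic 200-gene
# modules).  Expensive, so computed once and shared by the property
# tests that consume different aspects of the same runs.
.prop_cache <- new.env(parent = emptyenv())
two_module_full_runs <- function(n_runs = 20L) {
  if (!is.null(.prop_cache$runs)) return(.prop_cache$runs)
  runs <- lapply(seq_len(n_runs), function(s) {
    sim <- simulate_experiment(sim_config(seed = 100L + s))
    lc <- normalize_log(sim$counts, NULL, "CPM")
    mod <- detect_modules(tom_similarity(adjacency(lc, 4)),
                          network_config(min_module_size = 50))
    mm <- sim$truth$module_membership
    r1 <- module_recovery(mod, mm, "module_1")
    r2 <- module_recovery(mod, mm, "module_2")
    out <- list(rec1 = r1$recovery, rec2 = r2$recovery,
                distinct = !is.na(r1$label) && !is.na(r2$label) &&
                  !identical(r1$label, r2$label),
                r_pos = NA_real_, r_neg = NA_real_, disjoint = NA)
    if (!out$distinct) return(out)
    eig <- module_eigengene(lc, mod)
    mt <- module_trait_relation(eig, sim$traits)
    out$r_pos <- mt$r[mt$module == r1$label]
    out$r_neg <- mt$r[mt$module == r2$label]
    trait <- setNames(sim$traits$trait, sim$traits$sample_id)
    gs_sugar <- gene_significance(lc, trait, "sugar")
    gs_fibre <- gene_significance(lc, -trait, "fibre")
    cs <- trait_specific_candidates(top_k_by_significance(gs_sugar, 100),
                                    mod, r1$label, r2$label)
    cf <- trait_specific_candidates(top_k_by_significance(gs_fibre, 100),
                                    mod, r2$label, r1$label)
    out$disjoint <- module_overlap(cs$gene, cf$gene)$n == 0L
    out
  })
  .prop_cache$runs <- runs
  runs
}
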