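# Weighted co-expression: soft threshold, adjacency, TOM, module
# detection, eigengenes and trait statistics.

test_that("network defaults match the analysis conventions", {
  cfg <- network_config()
  expect_identical(cfg$power, 4)
  expect_true(4 %in% cfg$candidate_powers)
  expect_identical(cfg$min_module_size, 500L)
  expect_identical(cfg$network_type, "unsigned")
  expect_identical(cfg$linkage, "ward.D")
})

test_that("scale-free fit equals the independently coded oracle", {
  sim <- small_two_module_sim(seed = 9, n_genes = 150, module_size = 40)
  lc <- normalize_log(sim$counts, NULL, "CPM")
  cfg <- network_config(min_module_size = 30,
                        candidate_powers = c(1, 2, 4, 6, 8))
  st <- pick_soft_threshold(lc, cfg)
  acor <- abs(cor(t(unclass(lc))))
  diag(acor) <- 0
  for (i in seq_len(nrow(st$fit_table))) {
    k <- colSums(acor^st$fit_table$power[i])
    o <- oracle_scale_free(k, cfg$n_bins)
    expect_equal(st$fit_table$signed_r2[i], o$signed_r2,
                 tolerance = 1e-10)
    expect_equal(st$fit_table$slope[i], o$slope, tolerance = 1e-10)
  }
  # the selection rule: smallest power reaching the target, else argmax
  tab <- st$fit_table
  hit <- tab$power[!is.na(tab$signed_r2) & tab$signed_r2 >= cfg$target_r2]
  expect_identical(st$power,
                   if (length(hit)) hit[1] else
                     tab$power[which.max(tab$signed_r2)])
})

test_that("identical genes give a flagged degenerate scale-free fit", {
  set.seed(8)
  prof <- rexp(12, 0.1) * 10
  # every gene = shifted copy of one profile: all pairwise cor exactly 1,
  # so all connectivities coincide and the log-log fit is undefined
  m2 <- matrix(rep(prof, each = 6) + rep(1:6, 12), 6, 12,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:12)))
  em <- expression_matrix(m2, "TPM")
  st <- pick_soft_threshold(em, network_config(min_module_size = 2))
  expect_true(all(st$fit_table$degenerate))
  expect_true(all(is.na(st$fit_table$signed_r2)))
})

test_that("unsigned adjacency is |cor|^beta with zero diagonal", {
  s <- seq(-3, 3, length.out = 9)
  m <- rbind(up = s, down = -s, flat = s^2)
  colnames(m) <- paste0("s", 1:9)
  em <- expression_matrix(m - min(m), "TPM")
  for (beta in c(1, 4, 7)) {
    a <- adjacency(em, beta)
    expect_equal(a["up", "down"], 1, tolerance = 1e-12)  # anticorrelated
    expect_identical(unname(diag(a)), rep(0, 3))
  }
  em15 <- rand_expr(15, 12, "TPM", seed = 31)
  a <- adjacency(em15, 4)
  r <- cor(t(unclass(em15)))
  for (i in 1:15) for (j in 1:15)
    expect_equal(a[i, j], if (i == j) 0 else abs(r[i, j])^4,
                 tolerance = 1e-12)
  cm <- unclass(em15); cm[3, ] <- 5
  expect_error(adjacency(expression_matrix(cm, "TPM"), 4), "zero-variance")
})

test_that("topological overlap matches the definition", {
  # no edge, no shared neighbours: TOM 0
  a0 <- matrix(0, 4, 4)
  expect_identical(unname(tom_similarity(a0)[1, 2]), 0)
  # complete unit-weight graph: all off-diagonal TOM 1
  a1 <- matrix(1, 5, 5) - diag(5)
  t1 <- tom_similarity(a1)
  expect_equal(unname(t1[upper.tri(t1)]), rep(1, 10), tolerance = 1e-12)
  expect_identical(unname(diag(t1)), rep(1, 5))
  # random adjacency vs the triple-loop oracle
  set.seed(41)
  for (rep in 1:5) {
    r <- matrix(runif(100), 10)
    adj <- (r + t(r)) / 2
    diag(adj) <- 0
    expect_equal(tom_similarity(adj), oracle_tom(adj), tolerance = 1e-12)
  }
  expect_error(tom_similarity(matrix(2, 3, 3) - 2 * diag(3)), "\\[0, 1\\]")
})

test_that("planted blocks are detected whole; noise stays grey", {
  # two perfectly co-expressed blocks over a noise background
  set.seed(13)
  base <- matrix(rnorm(2 * 40), 2, 40)
  m <- rbind(base[rep(1, 35), ], base[rep(2, 35), ],
             matrix(rnorm(50 * 40), 50)) +
    matrix(rnorm(120 * 40, sd = 1e-6), 120)
  dimnames(m) <- list(sprintf("g%03d", 1:120), sprintf("s%02d", 1:40))
  em <- expression_matrix(abs(m) + 5, "TPM")
  tom <- tom_similarity(adjacency(normalize_log(em, mode = "TPM"), 6))
  mod <- detect_modules(tom, network_config(min_module_size = 30))
  expect_identical(attr(mod, "n_modules"), 2L)
  lab1 <- unique(unclass(mod)[1:35]); lab2 <- unique(unclass(mod)[36:70])
  expect_length(lab1, 1L); expect_length(lab2, 1L)
  expect_false(lab1 %in% c("grey", lab2))
  expect_true(all(unclass(mod)[71:120] == "grey"))
  # every non-grey module respects the minimum size
  sizes <- table(unclass(mod))
  expect_true(all(sizes[names(sizes) != "grey"] >= 30))

  # independent noise only: everything grey
  set.seed(14)
  nz <- abs(matrix(rnorm(120 * 40), 120, 40,
                   dimnames = dimnames(m))) * 10
  tomn <- tom_similarity(adjacency(normalize_log(
    expression_matrix(nz, "TPM"), mode = "TPM"), 6))
  modn <- detect_modules(tomn, network_config(min_module_size = 30))
  expect_identical(attr(modn, "n_modules"), 0L)
  expect_true(all(unclass(modn) == "grey"))

  # fewer genes than the minimum size: grey with a warning
  expect_warning(
    small <- detect_modules(tomn[1:10, 1:10],
                            network_config(min_module_size = 30)),
    "grey")
  expect_true(all(unclass(small) == "grey"))
})

test_that("module eigengene is the first PC with the sign convention", {
  # identical genes: eigengene is the standardised common profile
  prof <- cumsum(rnorm(20)) + 10
  m <- matrix(rep(prof, each = 8), 8, 20,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  em <- expression_matrix(abs(m), "TPM")
  assign <- structure(setNames(rep("turquoise", 8), rownames(m)),
                      class = "module_assignment")
  eig <- module_eigengene(em, assign)
  expect_equal(abs(cor(eig["turquoise", ], prof)), 1, tolerance = 1e-10)
  expect_gte(cor(eig["turquoise", ], prof), 0)   # sign convention
  expect_equal(unname(attr(eig, "explained")["turquoise"]), 1,
               tolerance = 1e-12)
  # random module vs direct SVD oracle
  em2 <- rand_expr(30, 15, "TPM", seed = 51)
  a2 <- structure(setNames(rep("blue", 30), rownames(em2)),
                  class = "module_assignment")
  e2 <- module_eigengene(em2, a2)
  z <- t(scale(t(unclass(em2))))
  v1 <- svd(z)$v[, 1]
  expect_equal(abs(unname(e2["blue", ])), abs(v1), tolerance = 1e-10)
  expect_gte(cor(e2["blue", ], colMeans(unclass(em2))), 0)
})

test_that("module-trait correlation uses the exact t-transform", {
  n <- 27
  u <- scale(rnorm(n)); v <- scale(residuals(lm(rnorm(n) ~ u)))
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  tr_val <- 0.5 * u + sqrt(0.75) * v      # cor(u, trait) = 0.5 exactly
  eig <- matrix(u[, 1], 1, n,
                dimnames = list("black", paste0("s", 1:n)))
  class(eig) <- c("eigengene_matrix", "matrix")
  traits <- data.frame(sample_id = paste0("s", 1:n), ccs = tr_val[, 1])
  mt <- module_trait_relation(eig, traits)
  expect_equal(mt$r, 0.5, tolerance = 1e-10)
  t_stat <- 0.5 * sqrt((n - 2) / (1 - 0.25))
  expect_equal(mt$p, 2 * (1 - pt(t_stat, n - 2)), tolerance = 1e-10)
  # identical trait: r = 1 with the p-value at the numerical floor
  t2 <- data.frame(sample_id = paste0("s", 1:n), same = u[, 1])
  mt2 <- module_trait_relation(eig, t2)
  expect_equal(mt2$r, 1, tolerance = 1e-12)
  expect_lt(mt2$p, 1e-100); expect_gt(mt2$p, 0)
  # orthogonal-by-construction trait at n = 50
  n2 <- 50
  e3 <- matrix(rnorm(n2), 1, n2,
               dimnames = list("pink", paste0("q", 1:n2)))
  resid_tr <- residuals(lm(rnorm(n2) ~ e3[1, ]))
  mt3 <- module_trait_relation(e3, data.frame(sample_id = paste0("q", 1:n2),
                                              x = resid_tr))
  expect_lt(abs(mt3$r), 1e-10)
  expect_error(module_trait_relation(eig[, 1:3, drop = FALSE],
                                     traits[1:3, ]), "4")
})

test_that("gene significance is a per-gene correlation with valid null", {
  em <- rand_expr(40, 20, "TPM", seed = 61)
  trait <- setNames(unclass(em)[7, ] * 2 + 3, colnames(em))
  gs <- gene_significance(em, trait)
  expect_equal(gs$gs[gs$gene == "g0007"], 1, tolerance = 1e-12)
  # brute-force loop oracle
  for (g in c(1, 13, 40)) {
    r <- cor(unclass(em)[g, ], trait)
    expect_equal(gs$r[g], r, tolerance = 1e-12)
    expect_equal(gs$gs[g], abs(r), tolerance = 1e-12)
  }
  expect_error(gene_significance(em, setNames(rep(1, 20), colnames(em))),
               "constant")
  # null calibration: ~5% of genes significant under a permuted trait
  set.seed(17)
  big <- rand_expr(1000, 30, "TPM", seed = 17)
  perm <- setNames(sample(rnorm(30)), colnames(big))
  gsn <- gene_significance(big, perm)
  expect_gte(mean(gsn$p < 0.05), 0.03)
  expect_lte(mean(gsn$p < 0.05), 0.07)
})

test_that("module significance is the group mean of |GS|", {
  gs <- data.frame(gene = paste0("g", 1:6), trait = "t",
                   r = c(0.4, -0.4, 0.4, 0.1, -0.3, 0.8),
                   gs = abs(c(0.4, -0.4, 0.4, 0.1, -0.3, 0.8)),
                   p = rep(0.01, 6))
  assign <- structure(setNames(c("black", "black", "black", "grey",
                                 "grey", "pink"), gs$gene),
                      class = "module_assignment")
  ms <- module_significance(gs, assign)
  expect_equal(ms$mean_gs[ms$module == "black"], 0.4, tolerance = 1e-12)
  expect_equal(ms$mean_gs[ms$module == "grey"], 0.2, tolerance = 1e-12)
  expect_true(ms$unassigned[ms$module == "grey"])
  expect_identical(ms$module[1], "pink")     # sorted by significance
  # group means match a brute-force tapply on a random table
  set.seed(71)
  gs2 <- data.frame(gene = paste0("g", 1:50), trait = "t",
                    r = runif(50, -1, 1), p = runif(50))
  gs2$gs <- abs(gs2$r)
  lab <- sample(c("blue", "brown", "grey"), 50, replace = TRUE)
  a2 <- structure(setNames(lab, gs2$gene), class = "module_assignment")
  ms2 <- module_significance(gs2, a2)
  for (m in unique(lab))
    expect_equal(ms2$mean_gs[ms2$module == m],
                 mean(gs2$gs[lab == m]), tolerance = 1e-12)
})

test_that("antagonistic planted modules get opposite trait signs", {
  runs <- two_module_full_runs()
  hits <- sum(vapply(runs, function(r)
    isTRUE(r$distinct) && r$rec1 >= 0.9 && r$rec2 >= 0.9 &&
      r$r_pos > 0 && r$r_neg < 0, logical(1)))
  expect_gte(hits, 19L)
})
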