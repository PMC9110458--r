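#' Configuration for the synthetic multi-factor RNA-seq generator
#'
#' Defines a simulated experiment shaped like a multi-genotype culm
#' development study: `n_genotypes x n_internodes x n_replicates` libraries
#' over `n_genes` genes, with (i) a planted Tucker3 (genotype, gene,
#' internode) structure of known ranks on the log2 scale, (ii) planted
#' co-expressed gene modules driven by per-sample latent factors, and
#' (iii) quantitative traits linearly tied to module activity.  The
#' defaults mirror a 24-genotype, 5-stage, 3-replicate design with 2,000
#' genes and two antagonistic 200-gene modules.
#'
#' @param n_genotypes,n_genes,n_internodes,n_replicates design dimensions.
#' @param true_ranks integer `c(P, Q, R)` of the planted Tucker3 structure;
#'   each must not exceed the matching dimension.
#' @param module_spec list of planted modules, each a list with `size`
#'   (gene count), `trait_effect` (real, the module's loading on the
#'   simulated trait) and `inter_gene_cor` (target intra-module correlation
#'   in `[0, 1]`).  Module sizes must sum to at most `n_genes`.
#' @param noise_sd Gaussian cell noise SD on the log2 scale added to the
#'   tensor signal (default 0.1).
#' @param nb_dispersion negative-binomial size (shape) parameter of the
#'   count draws, `variance = mu + mu^2 / size`; `Inf` gives the Poisson
#'   limit (default 10, moderate biological overdispersion).
#' @param library_size_range min/max of the uniform library-size draw
#'   (default 5e6 to 15e6 reads).
#' @param signal_sd root-mean-square amplitude of the planted tensor signal
#'   on the log2 scale (default 1: typical two-fold genotype-by-stage
#'   effects).
#' @param main_effect_share fraction of planted core SS assigned to the
#'   leading `g[1,1,1]` element before canonicalisation (default 0.55,
#'   a dominant-main-effect regime).
#' @param module_effect_sd log2-scale SD of the module latent-factor effect
#'   (default 2: module activity spans roughly 16-fold).
#' @param baseline_log2_range range of per-gene baseline abundance on the
#'   log2-CPM scale (default 3 to 10).
#' @param internode_main_effect if `TRUE` (default) the leading genotype
#'   component is the constant direction `1/sqrt(I)`, so the dominant
#'   core element describes expression changing along internodes
#'   identically in every genotype — the internode-main-effect regime
#'   typical of developmental series.
#' @param module_genotype_var fraction of module-activity variance that
#'   is a stable genotype effect (default 0.5); the rest is per-sample.
#'   A genotype-level phenotype can only be linked to module expression
#'   through this component.
#' @param seed integer root seed; every generator operation derives its own
#'   sub-stream from it, so outputs are byte-identical for a fixed config.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genotypes = 24L, n_genes = 2000L,
                       n_internodes = 5L, n_replicates = 3L,
                       true_ranks = c(2L, 3L, 2L),
                       module_spec = list(
                         list(size = 200L, trait_effect = 1,
                              inter_gene_cor = 0.9),
                         list(size = 200L, trait_effect = -1,
                              inter_gene_cor = 0.9)),
                       noise_sd = 0.1, nb_dispersion = 10,
                       library_size_range = c(5e6, 15e6),
                       signal_sd = 1, main_effect_share = 0.55,
                       module_effect_sd = 2,
                       baseline_log2_range = c(3, 10),
                       internode_main_effect = TRUE,
                       module_genotype_var = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genotypes = .check_count(n_genotypes, "n_genotypes"),
    n_genes = .check_count(n_genes, "n_genes"),
    n_internodes = .check_count(n_internodes, "n_internodes"),
    n_replicates = .check_count(n_replicates, "n_replicates"),
    true_ranks = true_ranks, module_spec = module_spec,
    noise_sd = noise_sd, nb_dispersion = nb_dispersion,
    library_size_range = library_size_range, signal_sd = signal_sd,
    main_effect_share = main_effect_share,
    module_effect_sd = module_effect_sd,
    baseline_log2_range = baseline_log2_range,
    internode_main_effect = isTRUE(internode_main_effect),
    module_genotype_var = .check_fraction(module_genotype_var,
                                          "module_genotype_var", lo = 0,
                                          lo_open = FALSE),
    seed = .check_count(seed, "seed", min = 0L))
  dims <- c(cfg$n_genotypes, cfg$n_genes, cfg$n_internodes)
  cfg$true_ranks <- .check_ranks(true_ranks, dims)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    .stopf("'noise_sd' must be >= 0")
  if (!(is.numeric(nb_dispersion) && nb_dispersion > 0))
    .stopf("'nb_dispersion' must be > 0 (Inf for Poisson)")
  if (length(library_size_range) != 2L ||
      any(library_size_range <= 0) || diff(library_size_range) < 0)
    .stopf("'library_size_range' must be an increasing pair of positive sizes")
  sizes <- vapply(module_spec, function(m) as.numeric(m$size), numeric(1L))
  if (length(sizes) && sum(sizes) > cfg$n_genes)
    .stopf("module sizes (%d) exceed n_genes (%d)", sum(sizes), cfg$n_genes)
  for (m in module_spec) {
    .check_fraction(m$inter_gene_cor, "inter_gene_cor", lo = 0,
                    lo_open = FALSE)
    if (!is.numeric(m$trait_effect)) .stopf("'trait_effect' must be numeric")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a tensor with planted Tucker3 structure
#'
#' Draws orthonormalised Gaussian loading matrices and a Gaussian core,
#' boosts the leading `g[1,1,1]` element to `main_effect_share` of core SS,
#' canonicalises the truth to the all-orthogonal (HOSVD) form — the form in
#' which core-element shares are identifiable, so a fitter can recover the
#' planted shares — and returns the signal tensor plus Gaussian cell noise.
#'
#' @param config a [sim_config()].
#' @return list with `tensor` (I x J x K array, dimnames set) and `truth`
#'   (list: `A_true`, `B_true`, `C_true`, `G_true`, `signal` array,
#'   `module_membership`, `trait_loadings`).
#' @export
simulate_tucker_tensor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, "tensor"))
  dims <- c(config$n_genotypes, config$n_genes, config$n_internodes)
  rk <- config$true_ranks
  a <- if (config$internode_main_effect) {
    # leading genotype component constant: the dominant core element is
    # an internode main effect shared by all genotypes
    const <- rep(1 / sqrt(dims[1L]), dims[1L])
    if (rk[1L] == 1L) matrix(const) else {
      rest <- matrix(stats::rnorm(dims[1L] * (rk[1L] - 1L)), dims[1L])
      rest <- rest - const %o% drop(crossprod(const, rest))
      cbind(const, .orthonormalise(rest))
    }
  } else .orthonormalise(matrix(stats::rnorm(dims[1L] * rk[1L]), dims[1L]))
  b <- .orthonormalise(matrix(stats::rnorm(dims[2L] * rk[2L]), dims[2L]))
  cc <- .orthonormalise(matrix(stats::rnorm(dims[3L] * rk[3L]), dims[3L]))
  g <- array(stats::rnorm(prod(rk)), rk)
  # plant a dominant leading core element
  share <- config$main_effect_share
  if (prod(rk) > 1L && share > 0) {
    rest <- sum(g^2) - g[1L, 1L, 1L]^2
    g[1L, 1L, 1L] <- sqrt(share / (1 - share) * rest)
  }
  # canonicalise to the all-orthogonal (HOSVD) form of the core
  for (m in 1:3) {
    u <- svd(unfold(g, m))$u
    rot <- list(a, b, cc)[[m]] %*% u
    if (m == 1L) a <- rot else if (m == 2L) b <- rot else cc <- rot
    g1 <- crossprod(u, unfold(g, m))
    g <- refold(g1, m, dim(g))
  }
  # scale so the signal entries have RMS = signal_sd (orthonormal loadings
  # conserve SS: signal SS == sum(G^2))
  rms <- sqrt(sum(g^2) / prod(dims))
  if (rms > 0) g <- g * (config$signal_sd / rms)
  truth <- .fix_signs(list(A = a, B = b, C = cc, G = g))
  dn <- list(sprintf("G%02d", seq_len(dims[1L])),
             sprintf("gene_%04d", seq_len(dims[2L])),
             sprintf("I%d", seq_len(dims[3L])))
  model <- tucker3_model(truth$A, truth$B, truth$C, truth$G)
  model$dims <- dims
  signal <- .reconstruct(model)
  tensor <- signal +
    array(stats::rnorm(prod(dims), sd = config$noise_sd), dims)
  dimnames(tensor) <- dn
  dimnames(signal) <- dn
  membership <- .module_membership(config)
  loadings <- vapply(config$module_spec,
                     function(m) as.numeric(m$trait_effect), numeric(1L))
  if (length(loadings))
    names(loadings) <- paste0("module_", seq_along(loadings))
  list(tensor = tensor,
       truth = list(A_true = truth$A, B_true = truth$B, C_true = truth$C,
                    G_true = truth$G, signal = signal,
                    module_membership = membership,
                    trait_loadings = loadings))
}

# gene -> module id ("module_1", ...) or NA; planted modules occupy
# consecutive gene blocks from the start of the gene index.
.module_membership <- function(config) {
  membership <- rep(NA_character_, config$n_genes)
  names(membership) <- sprintf("gene_%04d", seq_len(config$n_genes))
  at <- 1L
  for (m in seq_along(config$module_spec)) {
    sz <- as.integer(config$module_spec[[m]]$size)
    membership[at:(at + sz - 1L)] <- paste0("module_", m)
    at <- at + sz
  }
  membership
}

#' Simulate negative-binomial counts from a planted tensor
#'
#' Builds the per-library log2 mean as
#' `baseline(gene) + tensor value(genotype, gene, internode) + module
#' effect`, where the module effect for a gene in module m is
#' `module_effect_sd * (sqrt(rho) * z[sample, m] + sqrt(1 - rho) * noise)`
#' with a shared per-sample latent factor `z` — genes of one module
#' therefore co-vary with target intra-module correlation `rho`.  Counts
#' are drawn as NB(mean = 2^log2mean x library size / 1e6, size =
#' `nb_dispersion`), or Poisson when `nb_dispersion = Inf`.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` component of [simulate_tucker_tensor()].
#' @param tensor optional tensor whose values to use as the
#'   genotype-by-internode signal (defaults to the noise-free
#'   reconstruction stored in `truth$signal`).
#' @return list with `counts` (an [expression_matrix()], unit counts),
#'   `metadata` (a [sample_metadata()]) and `truth` augmented with
#'   `module_scores` (sample x module latent factors).
#' @export
simulate_counts <- function(config, truth, tensor = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, "counts"))
  sig <- if (is.null(tensor)) truth$signal else .tensor_values(tensor)
  dims <- dim(sig)
  if (!all(dims == c(config$n_genotypes, config$n_genes,
                     config$n_internodes)))
    .stopf("truth tensor does not match config dimensions")
  meta <- sample_metadata(
    sample_id = sprintf("G%02d_I%d_R%d",
                        rep(seq_len(dims[1L]),
                            each = dims[3L] * config$n_replicates),
                        rep(rep(seq_len(dims[3L]),
                                each = config$n_replicates), dims[1L]),
                        rep(seq_len(config$n_replicates),
                            dims[1L] * dims[3L])),
    genotype = sprintf("G%02d", rep(seq_len(dims[1L]),
                                    each = dims[3L] * config$n_replicates)),
    internode = sprintf("I%d", rep(rep(seq_len(dims[3L]),
                                       each = config$n_replicates),
                                   dims[1L])),
    replicate = rep(seq_len(config$n_replicates), dims[1L] * dims[3L]))
  n_samples <- nrow(meta)
  gi <- match(meta$genotype, dimnames(sig)[[1L]])
  ki <- match(meta$internode, dimnames(sig)[[3L]])
  baseline <- stats::runif(dims[2L], config$baseline_log2_range[1L],
                           config$baseline_log2_range[2L])
  log2mu <- matrix(baseline, dims[2L], n_samples)
  for (s in seq_len(n_samples))
    log2mu[, s] <- log2mu[, s] + sig[gi[s], , ki[s]]
  n_mod <- length(config$module_spec)
  # module activity: stable genotype component + per-sample variation
  fg <- config$module_genotype_var
  u <- matrix(stats::rnorm(dims[1L] * max(n_mod, 1L)), dims[1L],
              dimnames = list(dimnames(sig)[[1L]], NULL))
  z <- sqrt(fg) * u[gi, , drop = FALSE] +
    sqrt(1 - fg) * matrix(stats::rnorm(n_samples * max(n_mod, 1L)),
                          n_samples)
  mod_names <- if (n_mod) paste0("module_", seq_len(n_mod)) else NULL
  dimnames(z) <- list(meta$sample_id, mod_names)
  dimnames(u) <- list(dimnames(sig)[[1L]], mod_names)
  membership <- truth$module_membership
  for (m in seq_len(n_mod)) {
    rho <- config$module_spec[[m]]$inter_gene_cor
    genes <- which(membership == paste0("module_", m))
    eps <- matrix(stats::rnorm(length(genes) * n_samples), length(genes))
    eff <- config$module_effect_sd *
      (sqrt(rho) * matrix(z[, m], length(genes), n_samples, byrow = TRUE) +
         sqrt(1 - rho) * eps)
    log2mu[genes, ] <- log2mu[genes, ] + eff
  }
  lib <- round(stats::runif(n_samples, config$library_size_range[1L],
                            config$library_size_range[2L]))
  mu <- sweep(2^log2mu, 2L, lib / 1e6, `*`)
  counts <- if (is.finite(config$nb_dispersion)) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
           nrow(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow(mu))
  }
  dimnames(counts) <- list(names(membership), meta$sample_id)
  truth$module_scores <- z[, seq_len(n_mod), drop = FALSE]
  truth$module_genotype_scores <- u[, seq_len(n_mod), drop = FALSE]
  list(counts = expression_matrix(counts, "counts"), metadata = meta,
       truth = truth)
}

#' Simulate traits tied to module activity
#'
#' The trait value of a sample is the loading-weighted sum of the
#' standardised module latent factors plus Gaussian noise.  With
#' `level = "genotype"` (the default, matching per-genotype phenotyping)
#' the trait is built from the stable genotype component of module
#' activity and one noisy value per genotype is replicated across its
#' samples; with `level = "sample"` the per-sample activity is used
#' directly.
#'
#' @param truth a truth list carrying `module_scores` (from
#'   [simulate_counts()]) and `trait_loadings`.
#' @param metadata a [sample_metadata()].
#' @param noise_sd Gaussian trait noise SD on the standardised scale
#'   (default 0.2).
#' @param loadings optional module x trait loading matrix (rownames are
#'   module ids); defaults to the single-column `truth$trait_loadings`.
#' @param level `"genotype"` (trait constant across a genotype's samples)
#'   or `"sample"`.
#' @param seed integer seed (defaults to a sub-stream derived from 1).
#' @return data.frame with `sample_id` and one numeric column per trait.
#' @export
simulate_traits <- function(truth, metadata, noise_sd = 0.2,
                            loadings = NULL, level = c("genotype", "sample"),
                            seed = 1L) {
  level <- match.arg(level)
  if (is.null(truth$module_scores))
    .stopf("truth has no module_scores; run simulate_counts() first")
  if (is.null(loadings)) {
    loadings <- matrix(truth$trait_loadings, ncol = 1L,
                       dimnames = list(names(truth$trait_loadings), "trait"))
  }
  z <- truth$module_scores
  unknown <- setdiff(rownames(loadings), colnames(z))
  if (length(unknown))
    .stopf("unknown module id(s) in loadings: %s",
           paste(unknown, collapse = ", "))
  set.seed(.sub_seed(seed, "traits"))
  if (level == "genotype" && !is.null(truth$module_genotype_scores)) {
    z <- truth$module_genotype_scores[metadata$genotype,
                                      rownames(loadings), drop = FALSE]
    rownames(z) <- metadata$sample_id
  } else {
    z <- z[metadata$sample_id, rownames(loadings), drop = FALSE]
    if (level == "genotype") {
      gt <- metadata$genotype
      for (m in colnames(z))
        z[, m] <- stats::ave(z[, m], gt)
    }
  }
  zs <- apply(z, 2L, function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  })
  zs <- matrix(zs, nrow = nrow(z), dimnames = dimnames(z))
  vals <- zs %*% loadings
  if (noise_sd > 0) {
    if (level == "genotype") {
      gl <- unique(metadata$genotype)
      e <- matrix(stats::rnorm(length(gl) * ncol(vals), sd = noise_sd),
                  length(gl), dimnames = list(gl, colnames(vals)))
      vals <- vals + e[metadata$genotype, , drop = FALSE]
    } else {
      vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                            nrow(vals))
    }
  }
  out <- data.frame(sample_id = metadata$sample_id, vals,
                    row.names = NULL, check.names = FALSE)
  out
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: [simulate_tucker_tensor()], [simulate_counts()] and
#' [simulate_traits()] under one config, returning every ground-truth
#' object the downstream pipeline can be validated against.
#'
#' @param config a [sim_config()].
#' @param trait_noise_sd,trait_level,trait_loadings passed to
#'   [simulate_traits()].
#' @return list with `tensor`, `counts`, `metadata`, `traits`, `truth`.
#' @export
simulate_experiment <- function(config, trait_noise_sd = 0.2,
                                trait_level = "genotype",
                                trait_loadings = NULL) {
  sim <- simulate_tucker_tensor(config)
  cnt <- simulate_counts(config, sim$truth, tensor = sim$tensor)
  traits <- simulate_traits(cnt$truth, cnt$metadata,
                            noise_sd = trait_noise_sd,
                            loadings = trait_loadings,
                            level = trait_level, seed = config$seed)
  list(tensor = sim$tensor, counts = cnt$counts, metadata = cnt$metadata,
       traits = traits, truth = cnt$truth)
}
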