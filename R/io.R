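# File formats: TSV expression matrices (genes in rows, header of sample
# ids), CSV metadata/traits, JSON model manifests, Newick trees.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Ragged rows, non-numeric cells and duplicate ids produce descriptive
#' errors with line numbers.
#'
#' @param path TSV file path.
#' @param unit unit tag to attach (see [expression_matrix()]).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, unit = "counts") {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) .stopf("%s: need a header and at least one gene",
                                 path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  width <- length(header)
  body <- fields[-1L]
  bad <- which(lengths(body) != width)
  if (length(bad))
    .stopf("%s: ragged row at line %d (%d fields, expected %d)",
           path, bad[1L] + 1L, lengths(body)[bad[1L]], width)
  genes <- vapply(body, `[`, character(1L), 1L)
  dup <- genes[duplicated(genes)]
  if (length(dup)) .stopf("%s: duplicate gene id '%s'", path, dup[1L])
  if (anyDuplicated(samples))
    .stopf("%s: duplicate sample id '%s'", path,
           samples[duplicated(samples)][1L])
  vals <- matrix(NA_real_, length(body), width - 1L,
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      .stopf("%s: non-numeric value '%s' at line %d, column %d",
             path, body[[i]][j + 1L], i + 1L, j + 1L)
    }
    vals[i, ] <- v
  }
  expression_matrix(vals, unit)
}

#' Write an expression matrix as TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output path; the first column header is `gene_id`.
#' @return the path, invisibly.
#' @export
write_expression <- function(expr, path) {
  x <- unclass(expr)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' @param path CSV with columns `sample_id`, `genotype`, `internode`,
#'   `replicate`.
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "internode", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .stopf("%s: missing column(s) %s", path,
                           paste(miss, collapse = ", "))
  sample_metadata(df$sample_id, df$genotype, df$internode, df$replicate)
}

#' Write sample metadata as CSV
#' @param meta a [sample_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trait table from CSV
#'
#' @param path CSV with a `sample_id` column and numeric trait columns.
#' @return data.frame of traits.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    .stopf("%s: missing 'sample_id' column", path)
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write a trait table as CSV
#' @param traits trait data.frame.
#' @param path output path.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' @param tree an `"hclust"` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Export a Tucker3 model
#'
#' Writes a JSON manifest (ranks, explained fraction, convergence) next to
#' TSV files of the three loading matrices and the core-contribution table.
#'
#' @param model a `"tucker3"` object.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_tucker3 <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loadings <- coef(model)
  for (nm in names(loadings)) {
    m <- loadings[[nm]]
    utils::write.table(
      data.frame(id = if (is.null(rownames(m)))
        seq_len(nrow(m)) else rownames(m), m, check.names = FALSE),
      file.path(dir, paste0("loadings_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cc <- core_contributions(model)
  utils::write.table(cbind(element = rownames(cc), cc),
                     file.path(dir, "core_contributions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(ranks = model$ranks, dims = model$dims,
                   explained_fraction = model$explained_fraction,
                   converged = model$converged,
                   iterations = model$iterations,
                   total_ss = model$total_ss, fitted_ss = model$fitted_ss)
  path <- file.path(dir, "model.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end workflow on files: read counts, metadata and traits;
#' prevalence-filter and TMM/CPM-normalise; build and centre the
#' genotype x gene x internode tensor; grid-search and fit the Tucker3
#' model; build the co-expression network, detect modules, compute
#' eigengenes and module/gene-trait statistics; and emit trait-specific
#' candidate lists.  Every artifact is written under `outdir` and recorded
#' in a JSON manifest holding the seed, the configuration, and md5 hashes
#' of inputs and outputs, sufficient to verify bit-identical reruns.
#'
#' @param config list with paths `counts`, `metadata`, `traits`, `outdir`,
#'   and optional settings: `min_count` (10), `min_fraction` (0.7),
#'   `max_zero_fraction` (0.8), `tmm` (TRUE), `pmax`/`qmax`/`rmax`
#'   (5, 20, 3), `tol` (1e-8), `n_restarts` (1), `seed` (1), `power` (4),
#'   `min_module_size` (500), `trait` (first trait column), `target`
#'   (`"auto"` = top module significance), `exclude` (`"auto"` = most
#'   negatively correlated module, or `"none"`), `top_k` (100).
#' @return the manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(
    min_count = 10, min_fraction = 0.7, max_zero_fraction = 0.8,
    tmm = TRUE, pmax = 5L, qmax = 20L, rmax = 3L, tol = 1e-8,
    n_restarts = 1L, seed = 1L, power = 4, min_module_size = 500L,
    trait = NULL, target = "auto", exclude = "auto", top_k = 100L),
    config)
  for (p in c("counts", "metadata", "traits"))
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
      .stopf("stage 'input': missing %s file: %s", p,
             if (is.null(cfg[[p]])) "(unset)" else cfg[[p]])
  if (is.null(cfg$outdir)) .stopf("stage 'input': 'outdir' is unset")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  out <- file.path
  counts <- stage("read", read_expression(cfg$counts, "counts"))
  meta <- stage("read", read_metadata(cfg$metadata))
  traits <- stage("read", read_traits(cfg$traits))

  filtered <- stage("preprocess",
                    filter_min_count(counts, cfg$min_count,
                                     cfg$min_fraction))
  factors <- if (isTRUE(cfg$tmm)) stage("preprocess", tmm_factors(filtered))
             else NULL
  logcpm <- stage("preprocess", normalize_log(filtered, factors, "CPM"))
  write_expression(logcpm, out(cfg$outdir, "log2cpm.tsv"))

  tensor <- stage("tensor", build_threeway_array(logcpm, meta))
  grid <- stage("tucker3",
                tucker3_grid(tensor, cfg$pmax, cfg$qmax, cfg$rmax,
                             tol = cfg$tol, n_restarts = cfg$n_restarts,
                             seed = cfg$seed))
  utils::write.table(as.data.frame(grid), out(cfg$outdir, "grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ranks <- stage("tucker3", choose_model(grid))
  model <- stage("tucker3",
                 tucker3(tensor, ranks, tol = cfg$tol,
                         n_restarts = cfg$n_restarts, seed = cfg$seed))
  write_tucker3(model, out(cfg$outdir, "tucker3"))

  net_expr <- stage("network",
                    filter_zero_fraction(logcpm, cfg$max_zero_fraction))
  net_cfg <- network_config(power = cfg$power,
                            min_module_size = cfg$min_module_size)
  adj <- stage("network", adjacency(net_expr, net_cfg$power))
  tom <- stage("network", tom_similarity(adj))
  modules <- stage("network", detect_modules(tom, net_cfg))
  utils::write.table(
    data.frame(gene = names(modules), module = unclass(modules)),
    out(cfg$outdir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  eig <- stage("network", module_eigengene(net_expr, modules))
  utils::write.table(
    data.frame(module = rownames(eig), unclass(eig), check.names = FALSE),
    out(cfg$outdir, "eigengenes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  mt <- stage("network", module_trait_relation(eig, traits))
  utils::write.table(mt, out(cfg$outdir, "module_trait.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  trait_name <- if (is.null(cfg$trait))
    setdiff(colnames(traits), "sample_id")[1L] else cfg$trait
  gs <- stage("selection",
              gene_significance(net_expr,
                                traits[, c("sample_id", trait_name)]))
  utils::write.table(gs, out(cfg$outdir, "gene_significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ms <- stage("selection", module_significance(gs, modules))
  utils::write.table(ms, out(cfg$outdir, "module_significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  target <- cfg$target
  if (identical(target, "auto")) {
    non_grey <- ms[!ms$unassigned, , drop = FALSE]
    if (!nrow(non_grey)) .stopf("stage 'selection': no non-grey modules")
    target <- non_grey$module[1L]
  }
  exclude <- cfg$exclude
  if (identical(exclude, "auto")) {
    mt_t <- mt[mt$trait == trait_name & mt$module != target, , drop = FALSE]
    exclude <- if (nrow(mt_t) && min(mt_t$r) < 0)
      mt_t$module[which.min(mt_t$r)] else "none"
  }
  top <- stage("selection",
               top_k_by_significance(gs, min(cfg$top_k, nrow(gs))))
  cand <- stage("selection",
                trait_specific_candidates(top, modules, target, exclude))
  utils::write.table(as.data.frame(cand),
                     out(cfg$outdir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- c("log2cpm.tsv", "grid.tsv", "tucker3/model.json",
               "tucker3/core_contributions.tsv", "modules.tsv",
               "eigengenes.tsv", "module_trait.tsv",
               "gene_significance.tsv", "module_significance.tsv",
               "candidates.tsv")
  manifest <- list(
    package = "triomics",
    version = as.character(utils::packageVersion("triomics")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "outdir")],
    chosen_ranks = ranks,
    explained_fraction = model$explained_fraction,
    n_modules = attr(modules, "n_modules"),
    target_module = target, exclude_module = exclude,
    input_md5 = as.list(tools::md5sum(c(counts = cfg$counts,
                                        metadata = cfg$metadata,
                                        traits = cfg$traits))),
    output_md5 = as.list(tools::md5sum(file.path(cfg$outdir, outputs))))
  names(manifest$input_md5) <- c("counts", "metadata", "traits")
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, out(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
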