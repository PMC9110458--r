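#' Network construction settings
#'
#' Bundles the co-expression parameters: soft-threshold power, network
#' type, minimum module size, candidate powers and the scale-free fit
#' target used to select the power.
#'
#' @param power soft-threshold exponent beta (default 4).
#' @param min_module_size smallest gene count for a detected module
#'   (default 500).
#' @param candidate_powers powers scanned by [pick_soft_threshold()].
#' @param target_r2 scale-free fit threshold for power selection
#'   (default 0.80).
#' @param n_bins connectivity bins for the scale-free regression.
#' @return list of class `"network_config"`.
#' @export
network_config <- function(power = 4, min_module_size = 500L,
                           candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                           target_r2 = 0.80, n_bins = 10L) {
  if (!is.numeric(power) || power < 1) .stopf("'power' must be >= 1")
  structure(list(power = power,
                 network_type = "unsigned",
                 correlation = "pearson",
                 linkage = "ward.D",
                 min_module_size = .check_count(min_module_size,
                                               "min_module_size", min = 2L),
                 candidate_powers = candidate_powers,
                 target_r2 = .check_fraction(target_r2, "target_r2"),
                 n_bins = .check_count(n_bins, "n_bins", min = 2L)),
            class = "network_config")
}

.gene_cor <- function(expr) {
  x <- unclass(expr)
  v <- apply(x, 1L, stats::var)
  if (any(v == 0))
    .stopf("zero-variance gene(s): %s",
           paste(utils::head(rownames(x)[v == 0], 5L), collapse = ", "))
  stats::cor(t(x))
}

# Scale-free topology fit of a connectivity vector: equal-width bins on k,
# regress log10(mean bin frequency) on log10(mean bin k).  R2 is signed by
# the slope (scale-free requires a negative slope).
.scale_free_fit <- function(k, n_bins = 10L) {
  if (stats::sd(k) == 0)
    return(list(r2 = NA_real_, signed_r2 = NA_real_, slope = NA_real_,
                degenerate = TRUE))
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  kmean <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length) / length(k)
  ok <- !is.na(kmean) & kmean > 0 & !is.na(freq) & freq > 0
  if (sum(ok) < 2L)
    return(list(r2 = NA_real_, signed_r2 = NA_real_, slope = NA_real_,
                degenerate = TRUE))
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[[2L]]
  list(r2 = r2, signed_r2 = if (slope < 0) r2 else -r2, slope = slope,
       degenerate = FALSE)
}

#' Select the soft-threshold power by scale-free fit
#'
#' For each candidate power, builds the unsigned adjacency, computes the
#' per-gene connectivity `k_i = sum_j a_ij`, and fits the scale-free
#' topology model: log10 connectivity-bin frequency against log10 mean bin
#' connectivity.  The chosen power is the smallest whose signed fit R2
#' reaches `target_r2`; if none qualifies, the power with the largest
#' signed R2 is taken.
#'
#' @param expr an [expression_matrix()] with at least 3 genes and 4
#'   samples; zero-variance genes are an error.
#' @param config a [network_config()].
#' @return list with `power` (the selection) and `fit_table` (per-power
#'   `r2`, `signed_r2`, `slope`, mean/median/max connectivity).
#' @export
pick_soft_threshold <- function(expr, config = network_config()) {
  x <- unclass(expr)
  if (nrow(x) < 3L) .stopf("need at least 3 genes")
  if (ncol(x) < 4L) .stopf("need at least 4 samples")
  acor <- abs(.gene_cor(expr))
  diag(acor) <- 0
  rows <- lapply(config$candidate_powers, function(beta) {
    k <- colSums(acor^beta)
    sf <- .scale_free_fit(k, config$n_bins)
    data.frame(power = beta, r2 = sf$r2, signed_r2 = sf$signed_r2,
               slope = sf$slope, degenerate = sf$degenerate,
               mean_k = mean(k), median_k = stats::median(k),
               max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$signed_r2) & tab$signed_r2 >= config$target_r2
  power <- if (any(ok)) tab$power[which(ok)[1L]]
           else if (all(is.na(tab$signed_r2))) NA_real_
           else tab$power[which.max(tab$signed_r2)]
  list(power = power, fit_table = tab)
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(g_i, g_j)|^power` with the diagonal set to 0 (a gene does
#' not contribute to its own connectivity).
#'
#' @param expr an [expression_matrix()].
#' @param power soft-threshold exponent.
#' @return symmetric gene x gene matrix with entries in `[0, 1]`.
#' @export
adjacency <- function(expr, power = 4) {
  a <- abs(.gene_cor(expr))^power
  diag(a) <- 0
  a
}

#' Topological overlap similarity
#'
#' Smooths an adjacency by shared-neighbour structure:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`; the diagonal is reported as 1.
#'
#' @param adj symmetric adjacency with zero diagonal and entries in
#'   `[0, 1]`.
#' @return symmetric TOM matrix, entries in `[0, 1]`, unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    .stopf("adjacency must be a square matrix")
  if (max(abs(adj - t(adj))) > 1e-12) .stopf("adjacency must be symmetric")
  if (any(diag(adj) != 0)) .stopf("adjacency diagonal must be 0")
  if (min(adj) < 0 || max(adj) > 1)
    .stopf("adjacency entries must lie in [0, 1]")
  k <- colSums(adj)
  l <- adj %*% adj
  tom <- (l + adj) / (outer(k, k, pmin) + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules
#'
#' Clusters genes on the dissimilarity `1 - TOM` with Ward (`ward.D`)
#' linkage and selects modules as cohesive, well-separated branches of
#' the tree, walking it from the top.  A branch qualifies when it
#' (i) holds at least `min_module_size` genes, (ii) is *cohesive* (mean
#' intra-branch TOM at least `min_cohesion`), and (iii) is *separated*:
#' the merge absorbing it into the rest of the tree is at least
#' `separation_ratio` times higher than its own topmost internal merge,
#' so the branch is markedly tighter than its surroundings rather than
#' an arbitrary slice of a continuously agglomerating background.  A
#' qualifying branch whose two sides are much less connected across than
#' within (cross-side TOM below `1/separation_ratio` of the tighter
#' side's cohesion) is a merger of distinct modules and is split
#' recursively; otherwise the most inclusive qualifying branch wins, so
#' tight modules are never reported as fragments.  Modules are named
#' from a fixed colour palette in decreasing size order; all other genes
#' are labelled `"grey"`.  A background of independent genes yields no
#' cohesive separated branch, hence all grey.  The colour names are
#' deterministic labels, not claims about any particular dataset's
#' modules.
#'
#' @param tom a TOM (or any similarity in `[0, 1]` with unit diagonal).
#' @param config a [network_config()]; `min_module_size` defaults to 500.
#' @param separation_ratio how much looser the absorbing merge must be
#'   than the branch's internal structure (default 2 — a module must be
#'   at least twice as tight as its separation from the rest).
#' @param min_cohesion absolute floor on the mean intra-branch topological
#'   overlap (default 0.05): a set of mutually unconnected genes can sit
#'   far from every real module and look "separated" in the tree without
#'   being co-expressed at all, so candidate branches below this mean TOM
#'   are not reported as modules.
#' @return named character vector gene -> module label, class
#'   `"module_assignment"`, with attribute `n_modules`.
#' @export
detect_modules <- function(tom, config = network_config(),
                           separation_ratio = 2, min_cohesion = 0.05) {
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("gene", seq_len(n))
  min_size <- config$min_module_size
  all_grey <- function(warn) {
    if (!is.null(warn)) warning(warn)
    out <- rep("grey", n)
    names(out) <- genes
    structure(out, class = "module_assignment", n_modules = 0L)
  }
  if (n < min_size)
    return(all_grey("fewer genes than min_module_size; all genes grey"))
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "ward.D")
  nodes <- .tree_nodes(tree)
  cohesion <- function(mem) {
    m <- length(mem)
    (sum(tom[mem, mem]) - m) / (m * (m - 1))
  }
  side_members <- function(i, side) {
    k <- tree$merge[i, side]
    if (k < 0) -k else nodes$members[[k]]
  }
  # Walk the tree from the top.  A branch is a module candidate when it
  # is large enough, cohesive, and separated (its absorbing merge — in
  # the tree as pruned so far — sits well above its internal root).  A
  # candidate whose two sides are much less connected across than within
  # (mean cross-side TOM below 1/separation_ratio of the tighter side's
  # cohesion) looks like a merger of distinct modules: its sides,
  # inheriting its separation context, are searched for modules of their
  # own, and only if at least one side yields some is the branch
  # dissolved (a side that yields none — e.g. unconnected background
  # genes riding along with a real module — goes grey; if neither side
  # can stand alone the branch is one heterogeneous module and is kept
  # whole).  A branch that fails the candidate test passes its children
  # on, to be judged against its own merge height.
  walk <- function(i, parent_h) {
    h <- nodes$height[i]
    children <- function(php) {
      out <- integer(0L)
      for (k in tree$merge[i, ])
        if (k > 0 && nodes$size[k] >= min_size)
          out <- c(out, walk(k, php))
      out
    }
    is_candidate <- parent_h > h &&
      parent_h >= separation_ratio * h &&
      cohesion(nodes$members[[i]]) >= min_cohesion
    if (!is_candidate) return(children(h))
    s1 <- side_members(i, 1L)
    s2 <- side_members(i, 2L)
    within <- max(if (length(s1) > 1L) cohesion(s1) else 0,
                  if (length(s2) > 1L) cohesion(s2) else 0)
    if (mean(tom[s1, s2]) >= within / separation_ratio) return(i)
    sub <- children(parent_h)      # merger: sides inherit the context
    if (length(sub)) sub else i
  }
  keep <- walk(nrow(tree$merge), Inf)
  if (!length(keep)) return(all_grey(NULL))
  keep <- keep[order(-nodes$size[keep], nodes$height[keep])]
  labels <- rep("grey", n)
  pal <- c(.module_palette,
           sprintf("module%02d", seq_len(max(0L, length(keep) -
                                               length(.module_palette)))))
  for (i in seq_along(keep))
    labels[nodes$members[[keep[i]]]] <- pal[i]
  names(labels) <- genes
  structure(labels, class = "module_assignment",
            n_modules = length(keep))
}

# Internal-node table of an hclust tree: member leaves, subtree size, own
# merge height, parent index and the height of the merge that absorbs the
# node.
.tree_nodes <- function(tree) {
  m <- tree$merge
  n_merge <- nrow(m)
  members <- vector("list", n_merge)
  parent <- rep(NA_integer_, n_merge)
  parent_height <- rep(Inf, n_merge)
  for (i in seq_len(n_merge)) {
    kids <- m[i, ]
    mem <- integer(0L)
    for (k in kids) {
      if (k < 0) mem <- c(mem, -k)
      else {
        mem <- c(mem, members[[k]])
        parent[k] <- i
        parent_height[k] <- tree$height[i]
      }
    }
    members[[i]] <- mem
  }
  list(members = members,
       size = lengths(members),
       height = tree$height,
       parent = parent,
       parent_height = parent_height)
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- sort(table(unclass(x)), decreasing = TRUE)
  cat(sprintf("Module assignment: %d genes, %d module(s) + grey\n",
              length(x), attr(x, "n_modules")))
  print(tab)
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardised expression: a unit-norm per-sample profile summarising
#' the module, sign-fixed so it correlates non-negatively with the module's
#' mean expression.  Grey (unassigned) genes are excluded.
#'
#' @param expr an [expression_matrix()] covering the assigned genes.
#' @param assignment a [detect_modules()] result (or named gene -> label
#'   vector).
#' @return matrix module x sample of class `"eigengene_matrix"` with an
#'   `explained` attribute (per-module fraction of standardised variance
#'   captured).
#' @export
module_eigengene <- function(expr, assignment) {
  x <- unclass(expr)
  labels <- unclass(assignment)[rownames(x)]
  mods <- setdiff(unique(labels[!is.na(labels)]), "grey")
  if (!length(mods)) .stopf("no non-grey modules to summarise")
  mods <- mods[order(-table(factor(labels, mods))[mods], mods)]
  eig <- matrix(NA_real_, length(mods), ncol(x),
                dimnames = list(mods, colnames(x)))
  expl <- numeric(length(mods))
  for (i in seq_along(mods)) {
    gx <- x[which(labels == mods[i]), , drop = FALSE]
    v <- apply(gx, 1L, stats::var)
    if (any(v == 0))
      .stopf("module '%s' contains zero-variance gene(s)", mods[i])
    z <- sweep(gx - rowMeans(gx), 1L, apply(gx, 1L, stats::sd), `/`)
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    if (stats::cor(e, colMeans(gx)) < 0) e <- -e
    eig[i, ] <- e
    expl[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  names(expl) <- mods
  structure(eig, class = c("eigengene_matrix", "matrix"),
            explained = expl)
}

# Pearson r -> two-sided p via the exact t transform on n - 2 df, floored
# away from 0 so p stays in (0, 1].
.cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  pmin(pmax(p, 1e-300), 1)
}

#' Module eigengene to trait correlations
#'
#' Pearson correlation of every module eigengene with every trait, with a
#' two-sided p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param eigengenes a [module_eigengene()] matrix (modules x samples).
#' @param traits data.frame with `sample_id` and numeric trait columns.
#' @return data.frame with columns `module`, `trait`, `r`, `p`, `n`.
#' @export
module_trait_relation <- function(eigengenes, traits) {
  ids <- intersect(colnames(eigengenes), traits$sample_id)
  if (length(ids) < 4L) .stopf("need at least 4 shared samples")
  e <- t(unclass(eigengenes)[, ids, drop = FALSE])
  tr <- traits[match(ids, traits$sample_id), , drop = FALSE]
  num <- vapply(tr, is.numeric, logical(1L)) & names(tr) != "sample_id"
  tv <- as.matrix(tr[, num, drop = FALSE])
  r <- stats::cor(e, tv)
  out <- expand.grid(module = rownames(r), trait = colnames(r),
                     stringsAsFactors = FALSE)
  out$r <- r[cbind(out$module, out$trait)]
  out$p <- .cor_pvalue(out$r, length(ids))
  out$n <- length(ids)
  out
}

#' Per-gene trait significance
#'
#' Signed Pearson correlation of each gene with a trait, its absolute value
#' (gene significance, GS) and the two-sided p-value.
#'
#' @param expr an [expression_matrix()].
#' @param trait named numeric vector (names = sample ids) or a 2-column
#'   data.frame `sample_id`, value.
#' @param trait_name label stored in the output.
#' @return data.frame of class `"gene_significance"`: `gene`, `trait`,
#'   `r`, `gs`, `p`.
#' @export
gene_significance <- function(expr, trait, trait_name = "trait") {
  x <- unclass(expr)
  if (is.data.frame(trait)) {
    tn <- setdiff(colnames(trait), "sample_id")[1L]
    trait_name <- tn
    trait <- stats::setNames(trait[[tn]], trait$sample_id)
  }
  if (!is.null(names(trait))) {
    ids <- intersect(colnames(x), names(trait))
    x <- x[, ids, drop = FALSE]
    trait <- trait[ids]
  } else if (length(trait) != ncol(x)) {
    .stopf("trait length does not match sample count")
  }
  if (stats::sd(trait) == 0) .stopf("constant trait")
  r <- as.vector(stats::cor(t(x), trait))
  out <- data.frame(gene = rownames(x), trait = trait_name, r = r,
                    gs = abs(r), p = .cor_pvalue(r, length(trait)),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_significance", "data.frame")
  out
}

#' Module significance
#'
#' The significance of a module for a trait is the arithmetic mean of the
#' absolute gene significance over the module's genes.  The grey
#' (unassigned) pool is included but flagged.
#'
#' @param gs a [gene_significance()] table.
#' @param assignment a module assignment covering the GS genes.
#' @return data.frame `module`, `trait`, `n_genes`, `mean_gs`,
#'   `unassigned`, sorted by decreasing `mean_gs`.
#' @export
module_significance <- function(gs, assignment) {
  labels <- unclass(assignment)[gs$gene]
  if (anyNA(labels))
    .stopf("assignment is missing gene(s): %s",
           paste(utils::head(gs$gene[is.na(labels)], 5L), collapse = ", "))
  mods <- unique(labels)
  empty <- setdiff(unique(unclass(assignment)), mods)
  if (length(empty))
    warning("module(s) without GS genes skipped: ",
            paste(empty, collapse = ", "))
  out <- data.frame(
    module = mods,
    trait = gs$trait[1L],
    n_genes = as.integer(table(labels)[mods]),
    mean_gs = as.numeric(tapply(gs$gs, labels, mean)[mods]),
    unassigned = mods == "grey",
    stringsAsFactors = FALSE)
  out[order(-out$mean_gs, out$module), , drop = FALSE]
}
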