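#' Positively correlated genes of a module
#'
#' Genes of one module whose signed trait correlation is positive and
#' significant at `alpha` (unadjusted by default; Benjamini-Hochberg
#' adjustment optional — the counts-of-genes convention reported for such
#' lists typically uses raw p-values).
#'
#' @param assignment a module assignment (gene -> label).
#' @param gs a [gene_significance()] table.
#' @param module module label to subset.
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return character vector of gene ids, ordered by decreasing GS with
#'   lexicographic gene-id tie-break.
#' @export
positive_subset <- function(assignment, gs, module, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- unclass(assignment)
  if (!module %in% labels) .stopf("unknown module: %s", module)
  p <- if (adjust == "BH") stats::p.adjust(gs$p, "BH") else gs$p
  keep <- labels[gs$gene] == module & gs$r > 0 & p < alpha
  keep[is.na(keep)] <- FALSE
  sel <- gs[keep, , drop = FALSE]
  sel <- sel[order(-sel$gs, sel$gene), , drop = FALSE]
  sel$gene
}

#' Top genes by significance
#'
#' The `k` genes with the highest gene significance `GS = |r|` to a trait,
#' across all modules; ties at the cut are broken lexicographically by gene
#' id.  With `use = "signed"` the ranking is by signed correlation instead.
#'
#' @param gs a [gene_significance()] table.
#' @param k list length (default 100).
#' @param use `"absolute"` (default) or `"signed"` ranking.
#' @return the top-k rows of `gs`, ordered.
#' @export
top_k_by_significance <- function(gs, k = 100L, use = c("absolute",
                                                        "signed")) {
  use <- match.arg(use)
  k <- .check_count(k, "k")
  if (k > nrow(gs)) .stopf("k = %d exceeds the %d available genes",
                           k, nrow(gs))
  key <- if (use == "absolute") gs$gs else gs$r
  out <- gs[order(-key, gs$gene), , drop = FALSE][seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trait-specific candidate genes
#'
#' Restricts a top-significance gene list to the module associated with the
#' trait of interest while excluding genes that also belong to the module
#' of an antagonistic trait: `top  intersect  target-module  minus
#' exclude-module`, preserving the GS ordering.  Use `exclude = "none"`
#' for plain intersection.
#'
#' @param top a [top_k_by_significance()] table (or any ordered GS table).
#' @param assignment a module assignment.
#' @param target module whose genes to keep.
#' @param exclude module whose genes to drop, or `"none"`.
#' @return data.frame of class `"candidate_genes"`: `rank`, `gene`,
#'   `module`, `r`, `gs`, `p`, with `target`/`exclude` attributes.
#' @export
trait_specific_candidates <- function(top, assignment, target,
                                      exclude = "none") {
  if (identical(target, exclude)) .stopf("target and exclude must differ")
  labels <- unclass(assignment)
  if (!target %in% labels) .stopf("unknown target module: %s", target)
  if (!identical(exclude, "none") && !exclude %in% labels)
    .stopf("unknown exclude module: %s", exclude)
  mod <- labels[top$gene]
  keep <- mod == target
  if (!identical(exclude, "none")) keep <- keep & mod != exclude
  keep[is.na(keep)] <- FALSE
  out <- top[keep, , drop = FALSE]
  out$module <- unname(mod[keep])
  out <- cbind(rank = seq_len(nrow(out)),
               out[, c("gene", "module", "r", "gs", "p"), drop = FALSE])
  rownames(out) <- NULL
  structure(out, target = target, exclude = exclude,
            class = c("candidate_genes", "data.frame"))
}

#' Overlap of two gene sets
#'
#' Exact intersection with a deterministic (sorted) ordering.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list with `n` (intersection size) and `genes` (sorted ids).
#' @export
module_overlap <- function(set_a, set_b) {
  ids <- sort(intersect(unique(set_a), unique(set_b)))
  list(n = length(ids), genes = ids)
}
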