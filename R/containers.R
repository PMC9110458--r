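#' Expression matrix with a unit tag
#'
#' A thin container for a genes-by-samples numeric matrix.  Rows are genes,
#' columns are samples; a mandatory unit tag records what the values are so
#' that downstream operations can refuse inputs on the wrong scale.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param unit one of `"counts"`, `"TPM"`, `"CPM"`, `"log2TPM1"`,
#'   `"log2CPM1"`.
#' @return a matrix of class `"expr_matrix"` carrying a `unit` attribute.
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_matrix(m, "counts")
#' @export
expression_matrix <- function(values,
                              unit = c("counts", "TPM", "CPM",
                                       "log2TPM1", "log2CPM1")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.numeric(values)) .stopf("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicate gene ids: %s",
           paste(unique(rownames(values)[duplicated(rownames(values))]),
                 collapse = ", "))
  if (anyDuplicated(colnames(values)))
    .stopf("duplicate sample ids: %s",
           paste(unique(colnames(values)[duplicated(colnames(values))]),
                 collapse = ", "))
  if (any(!is.finite(values))) .stopf("expression values must be finite")
  if (any(values < 0)) .stopf("expression values must be non-negative")
  if (unit == "counts" && any(values != round(values)))
    .stopf("unit 'counts' requires integer-valued entries")
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x), ncol(x), attr(x, "unit")))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param x an [expression_matrix()].
#' @return the unit string.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) .stopf("not an expression matrix (no unit tag)")
  u
}

# Re-tag after a transformation, preserving the class.
.retag <- function(values, unit) {
  structure(values, unit = unit,
            class = c("expr_matrix", class(unclass(values))))
}

.assert_unit <- function(x, allowed, what) {
  u <- expr_unit(x)
  if (!u %in% allowed)
    .stopf("%s expects unit %s, got '%s'", what,
           paste(sQuote(allowed), collapse = " or "), u)
  invisible(u)
}

#' Sample metadata constructor
#'
#' Validates a per-sample design table: one row per RNA-seq library with its
#' genotype, internode (developmental stage) and replicate index.  The
#' (genotype, internode, replicate) triple must be unique.
#'
#' @param sample_id character vector of unique sample ids.
#' @param genotype,internode factor-like labels.
#' @param replicate integer replicate index within a genotype-internode cell.
#' @return a `data.frame` of class `"sample_metadata"`.
#' @export
sample_metadata <- function(sample_id, genotype, internode, replicate) {
  df <- data.frame(sample_id = as.character(sample_id),
                   genotype = as.character(genotype),
                   internode = as.character(internode),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) .stopf("duplicate sample ids in metadata")
  key <- paste(df$genotype, df$internode, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    .stopf("duplicate (genotype, internode, replicate) combinations")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Three-way expression array
#'
#' Holds the I x J x K (genotype x gene x internode) array of replicate-mean
#' expression together with its dimension labels and a record of the
#' centering applied.
#'
#' @param values numeric 3-d array with dimnames (genotypes, genes,
#'   internodes).
#' @param centering free-text descriptor of the centering applied.
#' @return an object of class `"threeway_array"`.
#' @export
threeway_array <- function(values, centering = "none") {
  if (length(dim(values)) != 3L) .stopf("values must be a 3-d array")
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1L))))
    .stopf("all three dimensions must be labelled")
  if (any(!is.finite(values))) .stopf("array values must be finite")
  structure(list(values = values, genotype_ids = dn[[1L]],
                 gene_ids = dn[[2L]], internode_ids = dn[[3L]],
                 centering = centering),
            class = "threeway_array")
}

#' @export
print.threeway_array <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<threeway_array> %d genotypes x %d genes x %d internodes (centering: %s)\n",
    d[1L], d[2L], d[3L], x$centering))
  invisible(x)
}

# Accept either a raw 3-d array or a threeway_array.
.tensor_values <- function(x) {
  if (inherits(x, "threeway_array")) x$values
  else if (is.array(x) && length(dim(x)) == 3L) x
  else .stopf("expected a 3-d array or a threeway_array")
}
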