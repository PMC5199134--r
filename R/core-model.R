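#' Aggregate sample-level expression to facet level
#'
#' Collapses the columns of a sample-level \linkS4class{ExpressionMatrix} to
#' one column per facet, summing (default) or averaging the member samples of
#' each facet. Summing preserves total tag counts for count-derived units
#' such as TPM, which makes the downstream percentage contributions
#' insensitive to how many libraries a facet happens to be split into.
#' Samples absent from the map are dropped; samples named in the map must
#' exist in the matrix.
#'
#' @param matrix an \linkS4class{ExpressionMatrix} (samples as columns)
#' @param facets a \linkS4class{FacetMap} naming each sample's facet
#' @param method \code{"sum"} (default) or \code{"mean"}
#' @return an \linkS4class{ExpressionMatrix} with one column per facet, in
#'   the map's facet order; feature order and unit are preserved
#' @examples
#' em <- ExpressionMatrix(matrix(c(3, 7), 1, 2,
#'   dimnames = list("g", c("s1", "s2"))), unit = "TPM")
#' fm <- FacetMap(c(s1 = "F", s2 = "F"), "demo")
#' exprValues(aggregateFacets(em, fm))            # 10
#' exprValues(aggregateFacets(em, fm, "mean"))    # 5
#' @export
aggregateFacets <- function(matrix, facets, method = c("sum", "mean")) {
  stopifnot(is(matrix, "ExpressionMatrix"), is(facets, "FacetMap"))
  method <- match.arg(method)
  x <- exprValues(matrix)
  mp <- facetMapping(facets)
  unknown <- setdiff(names(mp), colnames(x))
  if (length(unknown))
    stopMapping(sprintf("facet map names sample(s) absent from the matrix: %s",
                        paste(unknown, collapse = ", ")))
  fo <- facetOrder(facets)
  agg <- vapply(fo, function(f) {
    members <- names(mp)[mp == f]
    if (!length(members))
      stopConfig(sprintf("facet '%s' has no member samples", f))
    sub <- x[, members, drop = FALSE]
    if (method == "sum") rowSums(sub) else rowMeans(sub)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L)  # vapply collapses single-row output to a vector
    agg <- base::matrix(agg, nrow = 1L, dimnames = list(rownames(x), fo))
  ExpressionMatrix(agg, unit = exprUnit(matrix))
}

#' Normalize expression to percentage contributions
#'
#' Transforms each feature's expression values into the percentage of its
#' total expression contributed by each column (facet or sample) of the
#' panel: p_ij = 100 * x_ij / sum_j x_ij. Each defined row sums to 100.
#' Features with zero total expression over the panel have no defined
#' contributions; their rows are stored as all zeros with
#' \code{definedMask = FALSE}, which excludes them from any selection that
#' applies a non-default constraint.
#'
#' Normalization is idempotent (normalizing the percentages again returns
#' them unchanged) and scale-invariant (multiplying all of a row's values by
#' a positive constant does not change its contributions).
#'
#' @param matrix an \linkS4class{ExpressionMatrix} (typically facet-level,
#'   from [aggregateFacets()])
#' @return a \linkS4class{ContributionMatrix} over the same rows and columns
#' @examples
#' cm <- normalizeContributions(exampleExpression())
#' rowSums(contributions(cm))    # 100 for every defined gene
#' @export
normalizeContributions <- function(matrix) {
  stopifnot(is(matrix, "ExpressionMatrix"))
  x <- exprValues(matrix)
  totals <- rowSums(x)
  defined <- totals > 0
  p <- x
  p[defined, ] <- 100 * x[defined, , drop = FALSE] / totals[defined]
  p[!defined, ] <- 0
  se <- SummarizedExperiment(
    assays = list(contribution = p),
    rowData = DataFrame(defined = unname(defined), row.names = rownames(x)),
    metadata = list(unit = "percent"))
  new("ContributionMatrix", se)
}

#' Validate an expression matrix and report findings
#'
#' Non-destructive diagnostics: reports duplicate feature/sample identifiers,
#' negative values, and all-zero rows or columns as a machine-readable table.
#' An empty table means the matrix is clean. Intended for quality checks
#' before normalization; nothing is modified.
#'
#' @param values a numeric matrix with dimnames, or an
#'   \linkS4class{ExpressionMatrix} (which by construction can only yield
#'   zero-sum findings)
#' @return a data.frame with columns \code{kind} (one of
#'   \code{"duplicate feature id"}, \code{"duplicate sample id"},
#'   \code{"negative value"}, \code{"zero-sum feature"},
#'   \code{"zero-sum sample"}) and \code{id} (the offending identifier)
#' @examples
#' m <- rbind(g1 = c(1, 2), g2 = c(0, 0))
#' colnames(m) <- c("s1", "s2")
#' validateMatrix(m)   # one "zero-sum feature" finding for g2
#' @export
validateMatrix <- function(values) {
  if (is(values, "ExpressionMatrix"))
    values <- exprValues(values)
  stopifnot(is.matrix(values))
  findings <- list()
  add <- function(kind, id)
    findings[[length(findings) + 1L]] <<- data.frame(kind = kind, id = id)
  fid <- rownames(values); sid <- colnames(values)
  for (d in unique(fid[duplicated(fid)])) add("duplicate feature id", d)
  for (d in unique(sid[duplicated(sid)])) add("duplicate sample id", d)
  neg <- which(rowSums(values < 0) > 0)
  for (i in neg) add("negative value", fid[i])
  zr <- which(rowSums(values != 0) == 0)
  for (i in zr) add("zero-sum feature", fid[i])
  zc <- which(colSums(values != 0) == 0)
  for (j in zc) add("zero-sum sample", sid[j])
  if (!length(findings))
    return(data.frame(kind = character(), id = character()))
  do.call(rbind, findings)
}
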