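#' @include AllClasses.R
NULL

#' Accessors for sliderSelect objects
#'
#' Small accessor generics: \code{exprValues}/\code{exprUnit} return the raw
#' expression matrix and its unit label; \code{contributions} returns the
#' feature-by-facet percentage matrix and \code{definedMask} the per-feature
#' flag saying whether contributions are defined (total expression over the
#' panel was positive); \code{selectedIds} and \code{selectedCount} return a
#' selection's identifiers and their number.
#'
#' @param x an object of the appropriate class
#' @return \code{exprValues} and \code{contributions}: a numeric matrix;
#'   \code{exprUnit}: a character label; \code{definedMask}: a named logical
#'   vector; \code{selectedIds}: a character vector; \code{selectedCount}: an
#'   integer.
#' @examples
#' cm <- normalizeContributions(exampleExpression())
#' contributions(cm)
#' definedMask(cm)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x)
  SummarizedExperiment::assay(x, "expression"))

#' @rdname accessors
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @rdname accessors
#' @export
setMethod("exprUnit", "ExpressionMatrix", function(x) metadata(x)$unit)

#' @rdname accessors
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))

#' @rdname accessors
#' @export
setMethod("contributions", "ContributionMatrix", function(x)
  SummarizedExperiment::assay(x, "contribution"))

#' @rdname accessors
#' @export
setGeneric("definedMask", function(x) standardGeneric("definedMask"))

#' @rdname accessors
#' @export
setMethod("definedMask", "ContributionMatrix", function(x)
  stats::setNames(rowData(x)$defined, rownames(x)))

#' @rdname accessors
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))

#' @rdname accessors
#' @export
setMethod("selectedIds", "SelectionResult", function(x) x@selectedIds)

#' @rdname accessors
#' @export
setGeneric("selectedCount", function(x) standardGeneric("selectedCount"))

#' @rdname accessors
#' @export
setMethod("selectedCount", "SelectionResult", function(x)
  length(x@selectedIds))

#' @rdname accessors
#' @export
setGeneric("constraintSnapshot", function(x)
  standardGeneric("constraintSnapshot"))

#' @rdname accessors
#' @export
setMethod("constraintSnapshot", "SelectionResult", function(x)
  x@constraintSnapshot)

#' @rdname accessors
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @rdname accessors
#' @export
setMethod("panelName", "FacetMap", function(x) x@panelName)

#' @rdname accessors
#' @export
setMethod("panelName", "ConstraintPanel", function(x) x@panelName)

#' @rdname accessors
#' @export
setGeneric("facetMapping", function(x) standardGeneric("facetMapping"))

#' @rdname accessors
#' @export
setMethod("facetMapping", "FacetMap", function(x) x@mapping)

#' @rdname accessors
#' @export
setGeneric("facetOrder", function(x) standardGeneric("facetOrder"))

#' @rdname accessors
#' @export
setMethod("facetOrder", "FacetMap", function(x) x@facetOrder)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d feature(s) selected\n",
              selectedCount(object)))
  ids <- selectedIds(object)
  if (length(ids)) {
    shown <- utils::head(ids, 10L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(ids) > 10L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "FacetMap", function(object) {
  cat(sprintf("FacetMap '%s': %d sample(s) in %d facet(s)\n",
              object@panelName, length(object@mapping),
              length(object@facetOrder)))
})

setMethod("show", "SliderConstraint", function(object) {
  cat(sprintf("SliderConstraint: %s in [%g%%, %g%%]\n",
              object@facetId, object@minPct, object@maxPct))
})

setMethod("show", "ConstraintPanel", function(object) {
  cat(sprintf("ConstraintPanel '%s' (%s): %d constraint(s)\n",
              object@panelName,
              if (object@enabled) "enabled" else "disabled",
              length(object@constraints)))
  for (ct in object@constraints)
    cat(sprintf("  %s in [%g%%, %g%%]\n", ct@facetId, ct@minPct, ct@maxPct))
})

setMethod("show", "ConstraintSet", function(object) {
  cat(sprintf("ConstraintSet: %d panel(s), combiner %s\n",
              length(object@panels), object@combiner))
  for (p in object@panels) show(p)
})

setMethod("show", "OrdinalConstraint", function(object) {
  cat(sprintf("OrdinalConstraint: %s in [%s, %s]\n",
              object@facetId, object@minLevel, object@maxLevel))
})
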