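#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData rowData<-
NULL

# Absolute tolerance for all percentage comparisons after normalization.
.PCT_TOL <- 1e-9

# The four-step immunohistochemistry staining scale, in ascending order.
.ORDINAL_LEVELS <- c("None", "Low", "Medium", "High")

#' ExpressionMatrix: non-negative feature-by-sample expression values
#'
#' A thin \linkS4class{SummarizedExperiment} wrapper holding one assay named
#' \code{"expression"} (features as rows, samples as columns) plus the unit of
#' measurement (e.g. \code{"TPM"}, \code{"RPKM"}, \code{"arbitrary"}) in its
#' metadata. Validity requires finite non-negative values with no missing
#' entries and unique, non-empty feature and sample identifiers.
#'
#' @slot .Data inherited SummarizedExperiment representation
#' @seealso [ExpressionMatrix()], [normalizeContributions()], [aggregateFacets()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msgs <- character()
  if (!"expression" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'expression' is required")
  else {
    x <- SummarizedExperiment::assay(object, "expression")
    if (!is.numeric(x))
      msgs <- c(msgs, "expression values must be numeric")
    else {
      if (anyNA(x)) msgs <- c(msgs, "expression values must not contain NA")
      else if (any(x < 0)) msgs <- c(msgs, "expression values must be non-negative")
    }
  }
  fid <- rownames(object); sid <- colnames(object)
  if (is.null(fid) || anyDuplicated(fid) || any(!nzchar(fid)))
    msgs <- c(msgs, "feature ids must be present, unique and non-empty")
  if (is.null(sid) || anyDuplicated(sid) || any(!nzchar(sid)))
    msgs <- c(msgs, "sample ids must be present, unique and non-empty")
  if (!is.character(metadata(object)$unit) || length(metadata(object)$unit) != 1L)
    msgs <- c(msgs, "metadata unit must be a single character label")
  if (length(msgs)) msgs else TRUE
})

#' ContributionMatrix: per-feature percentage contributions over one panel
#'
#' Holds one assay named \code{"contribution"} with values in \[0, 100\]:
#' each row is a feature's expression expressed as percentages of its total
#' over the facets of one panel, so defined rows sum to 100. Features whose
#' total expression over the panel is zero have no defined contributions;
#' they carry \code{defined = FALSE} in \code{rowData} and all-zero
#' percentages, and are excluded from any selection that applies a
#' non-default constraint.
#'
#' @seealso [normalizeContributions()], [applyPanel()], [contributions()]
#' @exportClass ContributionMatrix
setClass("ContributionMatrix", contains = "SummarizedExperiment")

setValidity("ContributionMatrix", function(object) {
  msgs <- character()
  if (!"contribution" %in% SummarizedExperiment::assayNames(object))
    return("assay 'contribution' is required")
  p <- SummarizedExperiment::assay(object, "contribution")
  if (!is.numeric(p) || anyNA(p))
    return("contributions must be numeric with no missing values")
  if (any(p < -.PCT_TOL) || any(p > 100 + .PCT_TOL))
    msgs <- c(msgs, "contributions must lie in [0, 100]")
  def <- rowData(object)$defined
  if (is.null(def) || !is.logical(def) || anyNA(def))
    return("rowData column 'defined' (logical, no NA) is required")
  if (nrow(p)) {
    rs <- rowSums(p)
    if (any(abs(rs[def] - 100) > 1e-6 * 100))  # sums accumulate rounding; 1e-9 per entry
      msgs <- c(msgs, "defined rows must sum to 100")
    if (any(rs[!def] != 0))
      msgs <- c(msgs, "undefined rows must be all zero")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "feature ids must be present and unique")
  if (length(msgs)) msgs else TRUE
})

#' FacetMap: grouping of samples into facets for one panel
#'
#' Maps each sample identifier to a facet (a named group of libraries of the
#' same cell type or tissue, e.g. \code{"neutrophils"}) and fixes the facet
#' display order for one panel (e.g. \code{"primary_cells"} or
#' \code{"tissues"}).
#'
#' @slot panelName single character panel label
#' @slot mapping named character vector: names are sample ids, values facet ids
#' @slot facetOrder character vector of facet ids in display order
#' @seealso [FacetMap()], [aggregateFacets()], [readFacetMap()]
#' @exportClass FacetMap
setClass("FacetMap",
  representation(panelName = "character", mapping = "character",
                 facetOrder = "character"))

setValidity("FacetMap", function(object) {
  msgs <- character()
  if (length(object@panelName) != 1L || !nzchar(object@panelName))
    msgs <- c(msgs, "panelName must be a single non-empty label")
  smp <- names(object@mapping)
  if (is.null(smp) || anyDuplicated(smp) || any(!nzchar(smp)))
    msgs <- c(msgs, "mapping must be named by unique, non-empty sample ids")
  if (anyDuplicated(object@facetOrder))
    msgs <- c(msgs, "facetOrder must not contain duplicates")
  if (!setequal(unique(object@mapping), object@facetOrder))
    msgs <- c(msgs, "facetOrder must list exactly the facets present in mapping (every facet needs >= 1 sample)")
  if (length(msgs)) msgs else TRUE
})

#' SliderConstraint: a closed percentage interval for one facet
#'
#' A feature passes the constraint when its contribution from the facet lies
#' in \[minPct, maxPct\] (both bounds inclusive, with absolute tolerance
#' 1e-9). \code{[0, 100]} is the default slider state and imposes nothing;
#' \code{[0, 0]} excludes any activity in the facet (negative selection).
#'
#' @slot facetId facet the constraint applies to
#' @slot minPct,maxPct numeric bounds in \[0, 100\], minPct <= maxPct
#' @seealso [SliderConstraint()], [ConstraintPanel()], [applyPanel()]
#' @exportClass SliderConstraint
setClass("SliderConstraint",
  representation(facetId = "character", minPct = "numeric", maxPct = "numeric"))

setValidity("SliderConstraint", function(object) {
  msgs <- character()
  if (length(object@facetId) != 1L || !nzchar(object@facetId))
    msgs <- c(msgs, "facetId must be a single non-empty id")
  ok <- length(object@minPct) == 1L && length(object@maxPct) == 1L &&
    is.finite(object@minPct) && is.finite(object@maxPct)
  if (!ok)
    msgs <- c(msgs, "minPct and maxPct must be single finite numbers")
  else if (object@minPct < 0 || object@maxPct > 100 || object@minPct > object@maxPct)
    msgs <- c(msgs, "bounds must satisfy 0 <= minPct <= maxPct <= 100")
  if (length(msgs)) msgs else TRUE
})

#' ConstraintPanel: the slider constraints of one panel
#'
#' At most one \linkS4class{SliderConstraint} per facet; constraints within a
#' panel combine conjunctively. A disabled panel imposes no restriction
#' regardless of its constraints (the "Disable" switch).
#'
#' @slot panelName panel label the constraints apply to
#' @slot constraints list of \linkS4class{SliderConstraint}
#' @slot enabled logical switch
#' @seealso [ConstraintPanel()], [ConstraintSet()], [applyPanel()]
#' @exportClass ConstraintPanel
setClass("ConstraintPanel",
  representation(panelName = "character", constraints = "list",
                 enabled = "logical"))

setValidity("ConstraintPanel", function(object) {
  msgs <- character()
  if (length(object@panelName) != 1L || !nzchar(object@panelName))
    msgs <- c(msgs, "panelName must be a single non-empty label")
  if (length(object@enabled) != 1L || is.na(object@enabled))
    msgs <- c(msgs, "enabled must be TRUE or FALSE")
  ok <- vapply(object@constraints, is, logical(1), class2 = "SliderConstraint")
  if (!all(ok))
    msgs <- c(msgs, "constraints must all be SliderConstraint objects")
  else {
    ids <- vapply(object@constraints, slot, character(1), name = "facetId")
    if (anyDuplicated(ids))
      msgs <- c(msgs, "at most one constraint per facet")
  }
  if (length(msgs)) msgs else TRUE
})

#' ConstraintSet: panels plus the cross-panel combiner
#'
#' Combines the selections of the enabled panels with \code{"AND"}
#' (intersection) or \code{"OR"} (union). With zero or one enabled panels the
#' combiner is irrelevant.
#'
#' @slot panels list of \linkS4class{ConstraintPanel}
#' @slot combiner \code{"AND"} or \code{"OR"}
#' @seealso [ConstraintSet()], [selectFeatures()]
#' @exportClass ConstraintSet
setClass("ConstraintSet",
  representation(panels = "list", combiner = "character"))

setValidity("ConstraintSet", function(object) {
  msgs <- character()
  if (length(object@combiner) != 1L || !object@combiner %in% c("AND", "OR"))
    msgs <- c(msgs, "combiner must be \"AND\" or \"OR\"")
  ok <- vapply(object@panels, is, logical(1), class2 = "ConstraintPanel")
  if (!all(ok))
    msgs <- c(msgs, "panels must all be ConstraintPanel objects")
  else {
    nm <- vapply(object@panels, slot, character(1), name = "panelName")
    if (anyDuplicated(nm))
      msgs <- c(msgs, "panel names must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' OrdinalConstraint: an interval on the immunohistochemistry staining scale
#'
#' Protein abundance from immunohistochemistry is recorded on the four-step
#' ordinal scale None < Low < Medium < High. A gene passes when its recorded
#' level at the facet lies in \[minLevel, maxLevel\]; a gene with no recorded
#' level at a constrained facet does not pass.
#'
#' @slot facetId tissue/cell facet the constraint applies to
#' @slot minLevel,maxLevel levels from \code{c("None","Low","Medium","High")}
#' @seealso [OrdinalConstraint()], [applyOrdinal()], [selectDual()]
#' @exportClass OrdinalConstraint
setClass("OrdinalConstraint",
  representation(facetId = "character", minLevel = "character",
                 maxLevel = "character"))

setValidity("OrdinalConstraint", function(object) {
  msgs <- character()
  if (length(object@facetId) != 1L || !nzchar(object@facetId))
    msgs <- c(msgs, "facetId must be a single non-empty id")
  lv <- c(object@minLevel, object@maxLevel)
  if (length(lv) != 2L || !all(lv %in% .ORDINAL_LEVELS))
    msgs <- c(msgs, sprintf("levels must be one of %s",
                            paste(.ORDINAL_LEVELS, collapse = ", ")))
  else if (match(object@minLevel, .ORDINAL_LEVELS) >
           match(object@maxLevel, .ORDINAL_LEVELS))
    msgs <- c(msgs, "minLevel must not exceed maxLevel on the ordinal scale")
  if (length(msgs)) msgs else TRUE
})

#' SelectionResult: the identifier set surviving all constraints
#'
#' Carries the selected feature identifiers in input order, together with a
#' snapshot of the constraints that produced them. The count (the number a
#' user watches update while moving sliders) is \code{selectedCount(x)} and
#' always equals \code{length(selectedIds(x))}.
#'
#' @slot selectedIds character vector of selected feature ids (input order)
#' @slot constraintSnapshot the constraint object that produced the result
#'   (a \linkS4class{ConstraintSet}, \linkS4class{ConstraintPanel}, a list of
#'   \linkS4class{OrdinalConstraint}, or NULL)
#' @seealso [selectedIds()], [selectedCount()], [selectFeatures()]
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(selectedIds = "character", constraintSnapshot = "ANY"))

setValidity("SelectionResult", function(object) {
  if (anyDuplicated(object@selectedIds))
    "selectedIds must not contain duplicates" else TRUE
})

#' TrackSpec: a UCSC custom-track header
#'
#' Describes the single \code{track} line written before BED records so a
#' selection can be uploaded to the UCSC Genome Browser as a custom track.
#'
#' @slot trackName track name (no tab characters)
#' @slot description free-text description
#' @slot color integer RGB triple in 0..255
#' @slot visibility UCSC visibility label (e.g. \code{"dense"}, \code{"full"})
#' @seealso [TrackSpec()], [writeBed()]
#' @exportClass TrackSpec
setClass("TrackSpec",
  representation(trackName = "character", description = "character",
                 color = "integer", visibility = "character"))

setValidity("TrackSpec", function(object) {
  msgs <- character()
  if (length(object@trackName) != 1L || !nzchar(object@trackName) ||
      grepl("\t", object@trackName, fixed = TRUE))
    msgs <- c(msgs, "trackName must be non-empty and contain no tabs")
  if (length(object@color) != 3L || any(is.na(object@color)) ||
      any(object@color < 0L) || any(object@color > 255L))
    msgs <- c(msgs, "color must be an RGB triple in 0..255")
  if (length(msgs)) msgs else TRUE
})
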