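#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, features as rows and samples as columns,
#'   with rownames (feature ids) and colnames (sample ids). Values must be
#'   finite and non-negative; missing values are rejected (impute 0 at read
#'   time via [readExpressionTable()] if that is intended).
#' @param unit unit label for the values, e.g. \code{"TPM"} or \code{"RPKM"}.
#' @return an \linkS4class{ExpressionMatrix}
#' @examples
#' em <- ExpressionMatrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), unit = "TPM")
#' exprUnit(em)
#' @export
ExpressionMatrix <- function(values, unit = "arbitrary") {
  if (!is.matrix(values))
    values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values))
    stopValidation("expression values contain missing entries")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopValidation(sprintf(
      "negative expression value at feature '%s', sample '%s'",
      rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]]))
  se <- SummarizedExperiment(assays = list(expression = values),
                             metadata = list(unit = unit))
  new("ExpressionMatrix", se)
}

#' Construct a FacetMap
#'
#' @param mapping named character vector mapping sample ids (names) to facet
#'   ids (values)
#' @param panelName label for the panel this grouping defines
#' @param facetOrder optional facet display order; defaults to order of first
#'   appearance in \code{mapping}
#' @return a \linkS4class{FacetMap}
#' @examples
#' FacetMap(c(s1 = "brain", s2 = "brain", s3 = "liver"), "tissues")
#' @export
FacetMap <- function(mapping, panelName = "panel",
                     facetOrder = unique(unname(mapping))) {
  new("FacetMap", panelName = panelName,
      mapping = mapping, facetOrder = facetOrder)
}

#' Construct a SliderConstraint
#'
#' @param facetId facet the constraint applies to
#' @param minPct,maxPct closed interval bounds in \[0, 100\]
#' @return a \linkS4class{SliderConstraint}
#' @examples
#' SliderConstraint("brain", 80, 100)   # at least 80% from brain
#' SliderConstraint("brain", 0, 0)      # no activity in brain
#' @export
SliderConstraint <- function(facetId, minPct = 0, maxPct = 100) {
  tryCatch(
    new("SliderConstraint", facetId = as.character(facetId),
        minPct = as.numeric(minPct), maxPct = as.numeric(maxPct)),
    error = function(e) stopConfig(conditionMessage(e)))
}

#' Construct a ConstraintPanel
#'
#' @param panelName panel label
#' @param constraints a list of \linkS4class{SliderConstraint} objects, or a
#'   named list of \code{c(min, max)} pairs keyed by facet id
#' @param enabled if \code{FALSE} the panel imposes no restriction
#' @return a \linkS4class{ConstraintPanel}
#' @examples
#' ConstraintPanel("tissues", list(brain = c(80, 100)))
#' @export
ConstraintPanel <- function(panelName, constraints = list(), enabled = TRUE) {
  if (length(constraints) && !is(constraints[[1L]], "SliderConstraint")) {
    if (is.null(names(constraints)))
      stopConfig("constraints given as intervals must be named by facet id")
    constraints <- mapply(function(facet, bounds) {
      if (length(bounds) != 2L)
        stopConfig(sprintf("facet '%s': interval must be c(min, max)", facet))
      SliderConstraint(facet, bounds[1L], bounds[2L])
    }, names(constraints), constraints, SIMPLIFY = FALSE)
  }
  tryCatch(
    new("ConstraintPanel", panelName = panelName,
        constraints = unname(constraints), enabled = enabled),
    error = function(e) stopConfig(conditionMessage(e)))
}

#' Construct a ConstraintSet
#'
#' @param panels list of \linkS4class{ConstraintPanel} objects (or a single
#'   panel)
#' @param combiner \code{"AND"} (intersection across enabled panels) or
#'   \code{"OR"} (union)
#' @return a \linkS4class{ConstraintSet}
#' @examples
#' cells   <- ConstraintPanel("cells", list(neutrophil = c(20, 100)))
#' tissues <- ConstraintPanel("tissues", list(blood = c(15, 100)))
#' ConstraintSet(list(cells, tissues), combiner = "AND")
#' @export
ConstraintSet <- function(panels = list(), combiner = c("AND", "OR")) {
  if (is(panels, "ConstraintPanel"))
    panels <- list(panels)
  combiner <- match.arg(combiner)
  tryCatch(new("ConstraintSet", panels = panels, combiner = combiner),
           error = function(e) stopConfig(conditionMessage(e)))
}

#' Construct an OrdinalConstraint
#'
#' @param facetId tissue/cell facet
#' @param minLevel,maxLevel bounds on the staining scale
#'   None < Low < Medium < High
#' @return an \linkS4class{OrdinalConstraint}
#' @examples
#' OrdinalConstraint("liver", "Medium", "High")
#' @export
OrdinalConstraint <- function(facetId, minLevel = "None", maxLevel = "High") {
  tryCatch(
    new("OrdinalConstraint", facetId = facetId,
        minLevel = minLevel, maxLevel = maxLevel),
    error = function(e) stopConfig(conditionMessage(e)))
}

#' Construct a TrackSpec for UCSC custom-track export
#'
#' @param trackName track name shown in the browser
#' @param description longer description
#' @param color RGB triple (0..255)
#' @param visibility UCSC visibility label
#' @return a \linkS4class{TrackSpec}
#' @examples
#' TrackSpec("selected_enhancers", color = c(200, 30, 30))
#' @export
TrackSpec <- function(trackName, description = trackName,
                      color = c(0L, 0L, 0L), visibility = "dense") {
  new("TrackSpec", trackName = trackName, description = description,
      color = as.integer(color), visibility = visibility)
}

.selectionResult <- function(ids, snapshot = NULL) {
  new("SelectionResult", selectedIds = as.character(ids),
      constraintSnapshot = snapshot)
}
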