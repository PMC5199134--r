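.isDefaultConstraint <- function(ct) ct@minPct <= 0 && ct@maxPct >= 100

#' Apply one panel of slider constraints
#'
#' A feature is selected when, for every constraint of the panel, its
#' percentage contribution from the constrained facet lies in the closed
#' interval \[minPct, maxPct\] (absolute tolerance 1e-9). Constraints within
#' a panel combine conjunctively; facets without a constraint impose nothing.
#' A disabled panel selects every feature. Features with undefined
#' contributions (zero total expression over the panel) are excluded as soon
#' as any constraint differs from the default \[0, 100\], and included when
#' all constraints are default: they carry no evidence for or against any
#' facet.
#'
#' @param contrib a \linkS4class{ContributionMatrix}
#' @param panel a \linkS4class{ConstraintPanel}; every constrained facet must
#'   be a column of \code{contrib}
#' @return a \linkS4class{SelectionResult} in input feature order
#' @examples
#' cm <- normalizeContributions(exampleExpression())
#' brain <- ConstraintPanel("tissues", list(brain = c(80, 100)))
#' selectedIds(applyPanel(cm, brain))   # "g1"
#' @export
applyPanel <- function(contrib, panel) {
  stopifnot(is(contrib, "ContributionMatrix"), is(panel, "ConstraintPanel"))
  ids <- rownames(contrib)
  if (!panel@enabled)
    return(.selectionResult(ids, panel))
  p <- contributions(contrib)
  unknown <- setdiff(
    vapply(panel@constraints, slot, character(1), name = "facetId"),
    colnames(p))
  if (length(unknown))
    stopConfig(sprintf("constraint on unknown facet(s): %s",
                       paste(unknown, collapse = ", ")))
  keep <- rep(TRUE, nrow(p))
  anyNonDefault <- FALSE
  for (ct in panel@constraints) {
    v <- p[, ct@facetId]
    keep <- keep & v >= ct@minPct - .PCT_TOL & v <= ct@maxPct + .PCT_TOL
    if (!.isDefaultConstraint(ct)) anyNonDefault <- TRUE
  }
  if (anyNonDefault)
    keep <- keep & definedMask(contrib)
  .selectionResult(ids[keep], panel)
}

.enabledPanels <- function(cset)
  Filter(function(p) p@enabled, cset@panels)

#' Select features satisfying a constraint set across panels
#'
#' Evaluates each enabled panel against its own contribution matrix (each
#' panel's contributions are normalized independently and sum to 100 within
#' the panel) and combines the per-panel selections with the set's combiner:
#' \code{"AND"} intersects, \code{"OR"} unites. With zero enabled panels
#' every feature is selected. When the panels' feature universes differ, the
#' selection operates on their intersection and a warning reports the size of
#' the symmetric difference.
#'
#' @param contribByPanel a named list of \linkS4class{ContributionMatrix}
#'   objects keyed by panel name, or a single matrix (then matched to the
#'   set's single panel)
#' @param cset a \linkS4class{ConstraintSet}
#' @return a \linkS4class{SelectionResult}, ordered by the feature order of
#'   the first supplied matrix
#' @examples
#' cm <- normalizeContributions(exampleExpression())
#' cset <- ConstraintSet(ConstraintPanel("tissues",
#'   list(blood = c(30, 45), heart = c(30, 45))))
#' selectedIds(selectFeatures(cm, cset))   # "g2"
#' @export
selectFeatures <- function(contribByPanel, cset) {
  stopifnot(is(cset, "ConstraintSet"))
  if (is(contribByPanel, "ContributionMatrix")) {
    if (length(cset@panels) > 1L)
      stopConfig("a single contribution matrix cannot serve multiple panels; pass a named list")
    nm <- if (length(cset@panels)) cset@panels[[1L]]@panelName else "panel"
    contribByPanel <- stats::setNames(list(contribByPanel), nm)
  }
  if (!length(contribByPanel))
    stopConfig("at least one contribution matrix is required")
  ok <- vapply(contribByPanel, is, logical(1), class2 = "ContributionMatrix")
  if (!all(ok) || is.null(names(contribByPanel)))
    stopConfig("contribByPanel must be a named list of ContributionMatrix objects")

  enabled <- .enabledPanels(cset)
  for (p in enabled)
    if (is.null(contribByPanel[[p@panelName]]))
      stopConfig(sprintf("no contribution matrix supplied for enabled panel '%s'",
                         p@panelName))

  universe <- rownames(contribByPanel[[1L]])
  if (length(enabled) > 1L) {
    sets <- lapply(enabled, function(p) rownames(contribByPanel[[p@panelName]]))
    inter <- Reduce(intersect, sets)
    union_ <- Reduce(union, sets)
    if (length(union_) != length(inter))
      warning(sprintf(
        "panels cover different feature universes (symmetric difference: %d); selecting on the intersection",
        length(union_) - length(inter)), call. = FALSE)
    universe <- universe[universe %in% inter]
  }

  if (!length(enabled))
    return(.selectionResult(universe, cset))

  perPanel <- lapply(enabled, function(p) {
    # evaluate before dispatch so condition classes survive S4 argument wrapping
    r <- applyPanel(contribByPanel[[p@panelName]], p)
    selectedIds(r)
  })
  combined <- if (cset@combiner == "AND")
    Reduce(intersect, perPanel) else Reduce(union, perPanel)
  .selectionResult(universe[universe %in% combined], cset)
}

#' Count the features a constraint set selects
#'
#' The live number a user watches while moving sliders. Returns exactly
#' \code{selectedCount(selectFeatures(contribByPanel, cset))} without
#' materializing any exported artifact.
#'
#' @inheritParams selectFeatures
#' @return a single integer
#' @examples
#' cm <- normalizeContributions(exampleExpression())
#' countSelected(cm, ConstraintSet(ConstraintPanel("tissues",
#'   list(brain = c(80, 100)))))   # 1
#' @export
countSelected <- function(contribByPanel, cset) {
  res <- selectFeatures(contribByPanel, cset)
  selectedCount(res)
}

#' Select genes by ordinal protein-level constraints
#'
#' Immunohistochemistry staining levels are ordinal (None < Low < Medium <
#' High), so constraints are intervals on that scale rather than
#' percentages. A gene is selected when every constrained facet's recorded
#' level lies within its interval; a gene with no recorded level (NA) at a
#' constrained facet is not selected — absence of evidence does not satisfy
#' an evidence requirement.
#'
#' @param levels a character matrix (genes as rows, facets as columns) of
#'   levels from \code{c("None","Low","Medium","High")}, with \code{NA} for
#'   missing annotation (see [readOrdinalTable()])
#' @param constraints a list of \linkS4class{OrdinalConstraint} objects (a
#'   single constraint is accepted)
#' @return a \linkS4class{SelectionResult} in input row order
#' @examples
#' lv <- rbind(g1 = c(liver = "High"), g2 = c(liver = "Low"))
#' selectedIds(applyOrdinal(lv, OrdinalConstraint("liver", "Medium", "High")))
#' @export
applyOrdinal <- function(levels, constraints = list()) {
  if (is(constraints, "OrdinalConstraint"))
    constraints <- list(constraints)
  stopifnot(is.matrix(levels))
  bad <- setdiff(unique(levels[!is.na(levels)]), .ORDINAL_LEVELS)
  if (length(bad))
    stopParse(sprintf("unknown ordinal level label(s): %s",
                      paste(bad, collapse = ", ")))
  unknown <- setdiff(
    vapply(constraints, slot, character(1), name = "facetId"),
    colnames(levels))
  if (length(unknown))
    stopConfig(sprintf("ordinal constraint on unknown facet(s): %s",
                       paste(unknown, collapse = ", ")))
  codes <- matrix(match(levels, .ORDINAL_LEVELS), nrow = nrow(levels),
                  dimnames = dimnames(levels))
  keep <- rep(TRUE, nrow(codes))
  for (ct in constraints) {
    v <- codes[, ct@facetId]
    lo <- match(ct@minLevel, .ORDINAL_LEVELS)
    hi <- match(ct@maxLevel, .ORDINAL_LEVELS)
    keep <- keep & !is.na(v) & v >= lo & v <= hi
  }
  .selectionResult(rownames(codes)[keep], constraints)
}

#' Dual selection on RNA contributions and protein levels
#'
#' Applies percentage slider constraints to RNA expression contributions and
#' ordinal constraints to immunohistochemistry protein levels
#' simultaneously, on the genes shared by both tables — selecting genes that
#' are both transcribed and translated under the requested pattern.
#'
#' @param rnaContrib a \linkS4class{ContributionMatrix} of RNA contributions
#' @param rnaCset a \linkS4class{ConstraintSet} for the RNA sliders
#' @param proteinLevels a character matrix of ordinal staining levels (see
#'   [applyOrdinal()])
#' @param proteinConstraints a list of \linkS4class{OrdinalConstraint};
#'   empty means the protein side imposes nothing
#' @return a \linkS4class{SelectionResult} over the shared gene identifiers,
#'   in the RNA matrix's order
#' @examples
#' cm <- normalizeContributions(exampleExpression())
#' lv <- matrix("High", 3, 4, dimnames = dimnames(contributions(cm)))
#' res <- selectDual(cm, ConstraintSet(ConstraintPanel("tissues",
#'   list(brain = c(80, 100)))), lv, OrdinalConstraint("brain", "Low", "High"))
#' selectedIds(res)
#' @export
selectDual <- function(rnaContrib, rnaCset, proteinLevels,
                       proteinConstraints = list()) {
  stopifnot(is(rnaContrib, "ContributionMatrix"), is.matrix(proteinLevels))
  shared <- intersect(rownames(rnaContrib), rownames(proteinLevels))
  if (!length(shared))
    stopData("RNA and protein tables share no gene identifiers")
  rnaSub <- rnaContrib[rownames(rnaContrib) %in% shared, ]
  rnaRes <- selectFeatures(
    stats::setNames(rep(list(rnaSub), length(rnaCset@panels)),
                    vapply(rnaCset@panels, slot, character(1), "panelName")),
    rnaCset)
  rnaSel <- selectedIds(rnaRes)
  protRes <- applyOrdinal(
    proteinLevels[rownames(proteinLevels) %in% shared, , drop = FALSE],
    proteinConstraints)
  protSel <- selectedIds(protRes)
  ids <- rownames(rnaSub)
  .selectionResult(ids[ids %in% rnaSel & ids %in% protSel],
                   list(rna = rnaCset, protein = proteinConstraints))
}
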