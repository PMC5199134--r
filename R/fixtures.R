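# Default RNG seed for the generators (arbitrary fixed constant, exposed on
# the CLI as --seed).
.DEFAULT_SEED <- 1734L

#' Built-in three-gene demonstration matrix
#'
#' A fixed 3-gene x 4-tissue CAGE-style expression matrix (unit TPM) built so
#' each canonical slider selection picks exactly one gene:
#' \itemize{
#'   \item brain in \[80, 100\] selects only \code{g1} (brain-specific);
#'   \item blood in \[30, 45\] and heart in \[30, 45\] selects only \code{g2};
#'   \item brain in \[0, 0\] and liver in \[50, 100\] selects only \code{g3}
#'     (liver-specific, silent in brain).
#' }
#' The rows already sum to 100, so raw values double as contributions.
#'
#' @return an \linkS4class{ExpressionMatrix} with genes \code{g1..g3} and
#'   tissue columns blood, brain, heart, liver
#' @examples
#' exprValues(exampleExpression())
#' @export
exampleExpression <- function() {
  m <- rbind(
    g1 = c(blood = 5,  brain = 85, heart = 5,  liver = 5),
    g2 = c(blood = 40, brain = 10, heart = 40, liver = 10),
    g3 = c(blood = 20, brain = 0,  heart = 20, liver = 60))
  ExpressionMatrix(m, unit = "TPM")
}

# One draw from a symmetric Dirichlet via normalized gamma variates.
.rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration)
  while (sum(g) == 0)  # guard against all-zero underflow at tiny concentration
    g <- stats::rgamma(k, shape = concentration)
  g / sum(g)
}

#' Simulate an expression matrix with planted facet-specific features
#'
#' Background features draw their contribution vector from a symmetric
#' Dirichlet with the given concentration (concentration 1 is uniform on the
#' simplex; large concentrations approach equal 100/K contributions).
#' Planted features get their designated facet's contribution drawn uniformly
#' in \[minPct, 100\] and the remainder split by a Dirichlet over the other
#' facets, so each planted feature satisfies its own \code{[minPct, 100]}
#' slider constraint by construction. Contribution rows (percent) are then
#' multiplied by a per-feature sequencing depth, log-uniform in
#' \[10, 10^4\] TPM-equivalents, to produce raw expression values; the
#' contributions are unchanged by this scaling.
#'
#' @param nFeatures total number of features
#' @param facets character vector of facet labels (>= 2)
#' @param planted optional data.frame with columns \code{n} (feature count),
#'   \code{facet} and \code{minPct} describing the planted groups; total
#'   \code{n} must not exceed \code{nFeatures}
#' @param concentration Dirichlet concentration of background contributions
#' @param seed RNG seed; identical seeds give identical output
#' @return a list with \code{matrix} (an \linkS4class{ExpressionMatrix}),
#'   \code{truth} (data.frame \code{feature_id}, \code{facet}, \code{minPct}
#'   for the planted features) and \code{facetMap} (identity
#'   \linkS4class{FacetMap}, one facet per column)
#' @examples
#' sim <- simulateExpression(50, c("brain", "liver", "blood"),
#'   planted = data.frame(n = 5, facet = "brain", minPct = 80), seed = 7)
#' sim$truth
#' @export
simulateExpression <- function(nFeatures, facets, planted = NULL,
                               concentration = 1, seed = .DEFAULT_SEED) {
  stopifnot(nFeatures >= 0, length(facets) >= 2L, concentration > 0)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("n", "facet", "minPct") %in% names(planted)))
    if (any(planted$minPct <= 0) || any(planted$minPct > 100))
      stopValidation("planted minPct must lie in (0, 100]")
    if (sum(planted$n) > nFeatures)
      stopValidation(sprintf(
        "planted feature counts (%d) exceed nFeatures (%d)",
        sum(planted$n), nFeatures))
    bad <- setdiff(planted$facet, facets)
    if (length(bad))
      stopValidation(sprintf("planted facet(s) not in panel: %s",
                             paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  k <- length(facets)
  ids <- sprintf("f%04d", seq_len(nFeatures))
  contrib <- matrix(0, nFeatures, k, dimnames = list(ids, facets))
  truth <- data.frame(feature_id = character(), facet = character(),
                      minPct = numeric())
  nPlanted <- if (is.null(planted)) 0L else sum(planted$n)
  plantedRows <- if (nPlanted) sample(nFeatures, nPlanted) else integer()
  cursor <- 0L
  if (!is.null(planted)) for (g in seq_len(nrow(planted))) {
    for (r in plantedRows[cursor + seq_len(planted$n[g])]) {
      j <- match(planted$facet[g], facets)
      c0 <- stats::runif(1, planted$minPct[g], 100)
      rest <- .rdirichlet1(k - 1L, concentration) * (100 - c0)
      contrib[r, j] <- c0
      contrib[r, -j] <- rest
    }
    cursor <- cursor + planted$n[g]
    truth <- rbind(truth, data.frame(
      feature_id = ids[plantedRows[seq_len(planted$n[g]) +
                                     (cursor - planted$n[g])]],
      facet = planted$facet[g], minPct = planted$minPct[g]))
  }
  for (r in setdiff(seq_len(nFeatures), plantedRows))
    contrib[r, ] <- .rdirichlet1(k, concentration) * 100
  depth <- 10^stats::runif(nFeatures, 1, 4)
  values <- contrib / 100 * depth
  truth <- truth[order(match(truth$feature_id, ids)), , drop = FALSE]
  rownames(truth) <- NULL
  list(matrix = ExpressionMatrix(values, unit = "TPM"),
       truth = truth,
       facetMap = FacetMap(stats::setNames(facets, facets),
                           panelName = "simulated"))
}

#' Simulate genomic intervals and SNP positions on one chromosome
#'
#' Draws uniform random non-degenerate intervals (lengths 50-2000 bp) and
#' uniform SNP positions on a single synthetic chromosome. Deterministic
#' under \code{seed}.
#'
#' @param nFeatures number of intervals
#' @param nSnps number of SNPs
#' @param chromLength chromosome length in bp
#' @param seed RNG seed
#' @param chrom chromosome name
#' @return a list with \code{features} and \code{snps}, both \code{GRanges}
#'   with \code{name} columns (from [genomicFeatures()] / [snpRecords()])
#' @examples
#' g <- simulateGenomic(5, 10, 1e5, seed = 1)
#' snpOverlap(g$features, g$snps)
#' @export
simulateGenomic <- function(nFeatures, nSnps, chromLength,
                            seed = .DEFAULT_SEED, chrom = "chrS") {
  stopifnot(nFeatures >= 0, nSnps >= 0, chromLength > 2000)
  set.seed(seed)
  emptyGr <- function() {
    gr <- GRanges()
    mcols(gr)$name <- character()
    gr
  }
  feats <- if (nFeatures > 0) {
    len <- sample(50:2000, nFeatures, replace = TRUE)
    s0 <- vapply(len, function(l) sample.int(chromLength - l, 1L) - 1L,
                 integer(1))
    genomicFeatures(sprintf("e%04d", seq_len(nFeatures)), chrom, s0, s0 + len)
  } else emptyGr()
  snps <- if (nSnps > 0)
    snpRecords(sprintf("rs%05d", seq_len(nSnps)), chrom,
               sample.int(chromLength, nSnps) - 1L)
  else emptyGr()
  list(features = feats, snps = snps)
}
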