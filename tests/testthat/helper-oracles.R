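# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/overlap machinery: plain per-feature and all-pairs loops.

# Row-wise percentage normalization by explicit loop.
oracleNormalize <- function(values) {
  p <- values * 0
  defined <- logical(nrow(values))
  for (i in seq_len(nrow(values))) {
    tot <- sum(values[i, ])
    if (tot > 0) {
      p[i, ] <- 100 * values[i, ] / tot
      defined[i] <- TRUE
    }
  }
  list(pct = p, defined = defined)
}

# Per-feature check of every slider constraint of one panel.
# constraints: named list facet -> c(min, max). tol matches the engine's.
oraclePanelSelect <- function(pct, defined, constraints, tol = 1e-9) {
  sel <- character()
  anyNonDefault <- any(vapply(constraints, function(b)
    b[1] > 0 || b[2] < 100, logical(1)))
  for (i in seq_len(nrow(pct))) {
    ok <- TRUE
    for (facet in names(constraints)) {
      b <- constraints[[facet]]
      v <- pct[i, facet]
      if (v < b[1] - tol || v > b[2] + tol) ok <- FALSE
    }
    if (anyNonDefault && !defined[i]) ok <- FALSE
    if (ok) sel <- c(sel, rownames(pct)[i])
  }
  sel
}

# AND/OR combination across panels, each panel via oraclePanelSelect.
# panelConstraints: named list panel -> (named list facet -> c(min,max));
# enabled: named logical. All panels share one pct/defined here.
oracleSelect <- function(pct, defined, panelConstraints, enabled, combiner) {
  on <- names(panelConstraints)[enabled[names(panelConstraints)]]
  if (!length(on)) return(rownames(pct))
  per <- lapply(on, function(p)
    oraclePanelSelect(pct, defined, panelConstraints[[p]]))
  ids <- if (combiner == "AND") Reduce(intersect, per) else Reduce(union, per)
  rownames(pct)[rownames(pct) %in% ids]
}

# All-pairs midpoint-distance scan.
oracleSnpOverlap <- function(features, snps, maxDist) {
  fc <- as.character(GenomicRanges::seqnames(features))
  fs <- GenomicRanges::start(features) - 1L
  fe <- GenomicRanges::end(features)
  fid <- S4Vectors::mcols(features)$name
  sc <- as.character(GenomicRanges::seqnames(snps))
  sp <- GenomicRanges::start(snps) - 1L
  sid <- S4Vectors::mcols(snps)$name
  rows <- list()
  for (i in seq_along(fid)) {
    mid <- (fs[i] + fe[i]) %/% 2L
    for (j in seq_along(sid)) {
      if (fc[i] == sc[j] && abs(mid - sp[j]) <= maxDist)
        rows[[length(rows) + 1L]] <- data.frame(
          enhancer_id = fid[i], snp_id = sid[j],
          distance = abs(mid - sp[j]))
    }
  }
  if (!length(rows))
    return(data.frame(enhancer_id = character(), snp_id = character(),
                      distance = integer()))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# All-pairs gene-window membership scan (midpoint anchor).
oracleGeneWindow <- function(features, genes, symbol, windowBp) {
  rows <- genes[tolower(genes$symbol) == tolower(symbol), , drop = FALSE]
  fc <- as.character(GenomicRanges::seqnames(features))
  fs <- GenomicRanges::start(features) - 1L
  fe <- GenomicRanges::end(features)
  fid <- S4Vectors::mcols(features)$name
  sel <- character()
  for (i in seq_along(fid)) {
    mid <- (fs[i] + fe[i]) %/% 2L
    hit <- FALSE
    for (k in seq_len(nrow(rows)))
      if (fc[i] == rows$chrom[k] && mid >= rows$tss[k] - windowBp &&
          mid <= rows$tss[k] + windowBp) hit <- TRUE
    if (hit) sel <- c(sel, fid[i])
  }
  sel
}

# Random expression matrix for property tests: a mix of smooth rows, sparse
# rows and occasional all-zero rows.
randomExpression <- function(nFeatures, nFacets) {
  vals <- matrix(stats::rexp(nFeatures * nFacets), nFeatures, nFacets)
  zeroRow <- stats::runif(nFeatures) < 0.05
  vals[zeroRow, ] <- 0
  sparse <- matrix(stats::runif(nFeatures * nFacets) < 0.3,
                   nFeatures, nFacets)
  vals[sparse & !zeroRow] <- 0
  dimnames(vals) <- list(sprintf("f%03d", seq_len(nFeatures)),
                         sprintf("F%02d", seq_len(nFacets)))
  ExpressionMatrix(vals)
}

# Random constraint intervals for a subset of facets: a mix of default,
# minimum-only, maximum-only (incl. exclusion at [0,0]) and two-sided.
randomConstraints <- function(facets, nMax = 4L) {
  k <- sample.int(min(nMax, length(facets)), 1L)
  chosen <- sample(facets, k)
  out <- lapply(chosen, function(f) {
    kind <- sample(4L, 1L)
    switch(kind,
      c(0, 100),
      c(stats::runif(1, 0, 100), 100),
      c(0, stats::runif(1, 0, 100)),
      sort(stats::runif(2, 0, 100)))
  })
  stats::setNames(out, chosen)
}
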