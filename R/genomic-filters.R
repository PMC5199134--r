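#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' Build a GRanges of genomic features from 0-based half-open coordinates
#'
#' Internal coordinates follow the BED convention (0-based, half-open
#' \code{[start, end)}); GRanges storage is 1-based closed, so this helper
#' performs the shift once and consistently. Feature identifiers go in the
#' \code{name} metadata column.
#'
#' @param id feature identifiers
#' @param chrom chromosome names
#' @param start,end 0-based half-open interval bounds (start < end)
#' @param strand \code{"+"}, \code{"-"} or \code{"."} (unstranded)
#' @return a \code{GRanges} with a \code{name} metadata column
#' @examples
#' genomicFeatures("e1", "chr1", 1000, 1400)
#' @export
genomicFeatures <- function(id, chrom, start, end, strand = ".") {
  if (any(start < 0) || any(start >= end))
    stopValidation("intervals must satisfy 0 <= start < end")
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GRanges(chrom, IRanges(start + 1L, end), strand = strand)
  mcols(gr)$name <- as.character(id)
  gr
}

#' SNP records as width-1 GRanges
#'
#' @param id SNP identifiers (e.g. rs numbers)
#' @param chrom chromosome names
#' @param pos 0-based positions (1-based sources are converted at read time,
#'   see [readSnpTable()])
#' @return a width-1 \code{GRanges} with a \code{name} metadata column
#' @examples
#' snpRecords("rs1", "chr1", 1400)
#' @export
snpRecords <- function(id, chrom, pos) {
  if (any(pos < 0))
    stopValidation("SNP positions must be non-negative")
  gr <- GRanges(chrom, IRanges(pos + 1L, width = 1L))
  mcols(gr)$name <- as.character(id)
  gr
}

# 0-based coordinates of a features GRanges
.start0 <- function(gr) start(gr) - 1L
.end0 <- function(gr) end(gr)

# Midpoint in 0-based coordinates: floor((start0 + end0) / 2).
.midpoint0 <- function(gr) (.start0(gr) + .end0(gr)) %/% 2L

#' Select features overlapping a genomic region
#'
#' Returns the identifiers of features whose interval overlaps the query
#' region \code{[start, end)} on \code{chrom} by at least 1 bp (half-open
#' semantics: a feature ending exactly where the query begins does not
#' overlap).
#'
#' @param features a \code{GRanges} from [genomicFeatures()] or [readBed()]
#' @param chrom chromosome of the query region
#' @param start,end 0-based half-open query bounds (start < end)
#' @return character vector of feature identifiers, in input order
#' @examples
#' fx <- genomicFeatures(c("a", "b"), "chr1", c(100, 300), c(200, 400))
#' filterByRegion(fx, "chr1", 150, 160)   # "a"
#' @export
filterByRegion <- function(features, chrom, start, end) {
  if (start < 0 || start >= end)
    stopConfig("region must satisfy 0 <= start < end")
  q <- GRanges(chrom, IRanges(start + 1L, end))
  hits <- findOverlaps(features, q, ignore.strand = TRUE)
  mcols(features)$name[unique(queryHits(hits))]
}

#' Select features within a window around a gene's TSS
#'
#' Finds the features whose anchor point lies within \code{windowBp} bases of
#' the gene's transcription start site, on the gene's chromosome (closed
#' interval \code{[tss - windowBp, tss + windowBp]}). The anchor is the
#' feature midpoint by default, or \code{"start5"} for the strand-aware 5'
#' end. When the gene has several annotated TSSs, the window is the union of
#' the per-TSS windows. Gene symbols match case-insensitively; an unknown
#' symbol raises a lookup error suggesting near matches.
#'
#' @param features a \code{GRanges} of candidate features
#' @param genes a data.frame of gene annotation with columns \code{symbol},
#'   \code{chrom}, \code{tss} (0-based) and \code{strand} (see
#'   [readGeneTable()])
#' @param geneSymbol the gene to anchor on
#' @param windowBp half-width of the window in bp (default 100000, i.e. the
#'   conventional 100 kbp around the annotated TSS)
#' @param anchor \code{"midpoint"} (default) or \code{"start5"}
#' @return character vector of feature identifiers, in input order
#' @examples
#' fx <- genomicFeatures("p1", "chr2", 49000, 50000)
#' genes <- data.frame(symbol = "NEUROD1", chrom = "chr2",
#'                     tss = 50000, strand = "+")
#' filterByGeneWindow(fx, genes, "NEUROD1", windowBp = 1000)
#' @export
filterByGeneWindow <- function(features, genes, geneSymbol,
                               windowBp = 100000L,
                               anchor = c("midpoint", "start5")) {
  anchor <- match.arg(anchor)
  if (windowBp < 0)
    stopConfig("windowBp must be non-negative")
  stopifnot(is.data.frame(genes),
            all(c("symbol", "chrom", "tss", "strand") %in% names(genes)))
  hit <- tolower(genes$symbol) == tolower(geneSymbol)
  if (!any(hit)) {
    sugg <- unique(genes$symbol[agrepl(geneSymbol, genes$symbol,
                                       ignore.case = TRUE, max.distance = 0.3)])
    stopLookup(sprintf("unknown gene symbol '%s'%s", geneSymbol,
                       if (length(sugg))
                         paste0("; did you mean: ",
                                paste(utils::head(sugg, 5L), collapse = ", "))
                       else ""))
  }
  rows <- genes[hit, , drop = FALSE]
  pt <- switch(anchor,
    midpoint = .midpoint0(features),
    start5 = ifelse(as.character(strand(features)) == "-",
                    .end0(features) - 1L, .start0(features)))
  keep <- rep(FALSE, length(features))
  for (k in seq_len(nrow(rows))) {
    keep <- keep |
      (as.character(seqnames(features)) == rows$chrom[k] &
         pt >= rows$tss[k] - windowBp & pt <= rows$tss[k] + windowBp)
  }
  mcols(features)$name[keep]
}

#' Enhancer-SNP overlap by midpoint distance
#'
#' An enhancer-SNP overlap is reported when the SNP lies on the enhancer's
#' chromosome and the distance between the enhancer midpoint and the SNP
#' position is at most \code{maxDist} bp (default 200). The midpoint of an
#' interval \code{[start, end)} is \code{floor((start + end) / 2)} in 0-based
#' coordinates. Each qualifying pair is reported exactly once.
#'
#' @param enhancers a \code{GRanges} of enhancer intervals with a \code{name}
#'   column
#' @param snps a width-1 \code{GRanges} of SNPs from [snpRecords()] or
#'   [readSnpTable()]
#' @param maxDist maximum midpoint-to-SNP distance in bp
#' @return a data.frame with columns \code{enhancer_id}, \code{snp_id},
#'   \code{distance}, ordered by enhancer then SNP input order
#' @examples
#' e <- genomicFeatures("e1", "chr1", 1000, 1400)   # midpoint 1200
#' s <- snpRecords(c("rs1", "rs2"), "chr1", c(1400, 1401))
#' snpOverlap(e, s)   # rs1 at distance 200 qualifies; rs2 at 201 does not
#' @export
snpOverlap <- function(enhancers, snps, maxDist = 200L) {
  if (maxDist < 0)
    stopConfig("maxDist must be non-negative")
  if (!length(enhancers) || !length(snps))
    return(data.frame(enhancer_id = character(), snp_id = character(),
                      distance = integer()))
  mid <- .midpoint0(enhancers)
  # positions p with |mid - p| <= maxDist form the closed 0-based interval
  # [mid - maxDist, mid + maxDist]; shift to 1-based for IRanges
  win <- GRanges(seqnames(enhancers),
                 IRanges(pmax(mid - maxDist, 0L) + 1L, mid + maxDist + 1L))
  hits <- findOverlaps(snps, win, ignore.strand = TRUE)
  ei <- subjectHits(hits); si <- queryHits(hits)
  out <- data.frame(
    enhancer_id = mcols(enhancers)$name[ei],
    snp_id = mcols(snps)$name[si],
    distance = abs(mid[ei] - (start(snps)[si] - 1L)))
  out <- unique(out)
  out[order(ei, si), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Look up predicted target promoters of selected enhancers
#'
#' Pass-through annotation join: for each selected enhancer, returns the
#' associated promoter identifiers and scores from a supplied
#' enhancer-promoter association table (e.g. expression-correlation
#' predictions shipped with an enhancer atlas). No correlation is computed
#' here. Enhancers absent from the table map to an empty (0-row) entry;
#' duplicate table rows are deduplicated.
#'
#' @param selectedEnhancerIds character vector of enhancer identifiers
#' @param associations a data.frame with columns \code{enhancer_id},
#'   \code{promoter_id}, \code{score} (see [readAssociationTable()])
#' @return a named list (one element per selected enhancer, in input order)
#'   of data.frames with columns \code{promoter_id} and \code{score}
#' @examples
#' tab <- data.frame(enhancer_id = "e1", promoter_id = "p1", score = 0.8)
#' linkAssociations(c("e1", "e2"), tab)
#' @export
linkAssociations <- function(selectedEnhancerIds, associations) {
  stopifnot(is.data.frame(associations),
            all(c("enhancer_id", "promoter_id", "score") %in%
                  names(associations)))
  associations <- unique(associations[, c("enhancer_id", "promoter_id",
                                          "score")])
  out <- lapply(selectedEnhancerIds, function(id) {
    sub <- associations[associations$enhancer_id == id,
                        c("promoter_id", "score"), drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  stats::setNames(out, selectedEnhancerIds)
}
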