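#' @importFrom Biostrings readDNAStringSet writeXStringSet subseq DNAStringSet
#' @importFrom rtracklayer import.bed export.bed
NULL

#' Read a feature-by-sample expression table
#'
#' Reads a tab-separated matrix with feature identifiers in the first column
#' and a header row of sample identifiers (features-as-rows convention, as in
#' the CAGE atlas tables). A \code{"gct"} dialect handles GCT files: the two
#' header lines are skipped and the \code{Description} column dropped.
#' \code{transpose = TRUE} covers samples-as-rows sources.
#'
#' @param path path to the table
#' @param missingPolicy \code{"error"} (default; empty/NA cells are a parse
#'   error — never silently fabricate zeros) or \code{"zero"} (impute 0)
#' @param unit unit label to attach (e.g. \code{"TPM"})
#' @param dialect \code{"tsv"} (plain, default) or \code{"gct"}
#' @param transpose read samples-as-rows input
#' @return an \linkS4class{ExpressionMatrix}
#' @examples
#' f <- tempfile()
#' writeLines(c("id\ts1\ts2", "g1\t1\t2", "g2\t0\t3"), f)
#' exprValues(readExpressionTable(f))
#' @export
readExpressionTable <- function(path, missingPolicy = c("error", "zero"),
                                unit = "arbitrary",
                                dialect = c("tsv", "gct"),
                                transpose = FALSE) {
  missingPolicy <- match.arg(missingPolicy)
  dialect <- match.arg(dialect)
  skip <- if (dialect == "gct") 2L else 0L
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, quote = "")
  if (ncol(df) < 2L)
    stopParse(sprintf("'%s': expected a tab-separated table with an id column and at least one sample column", path))
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  if (dialect == "gct") {
    if (!ncol(body))
      stopParse(sprintf("'%s': GCT table lacks a Description column", path))
    body <- body[, -1L, drop = FALSE]  # drop Description
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopValidation(sprintf("duplicate feature id(s): %s",
                           paste(dup, collapse = ", ")))
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    raw <- body[[j]]
    blank <- is.na(raw) | raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    badRow <- which(!blank & is.na(num))
    if (length(badRow))
      stopParse(sprintf(
        "'%s': non-numeric value '%s' at row %d (feature '%s'), column '%s'",
        path, raw[badRow[1L]], badRow[1L] + 1L + skip, ids[badRow[1L]],
        colnames(body)[j]))
    if (any(blank)) {
      if (missingPolicy == "error")
        stopParse(sprintf(
          "'%s': missing value at row %d (feature '%s'), column '%s'",
          path, which(blank)[1L] + 1L + skip, ids[which(blank)[1L]],
          colnames(body)[j]))
      num[blank] <- 0
    }
    m[, j] <- num
  }
  if (transpose)
    m <- t(m)
  ExpressionMatrix(m, unit = unit)
}

#' Write an expression matrix as a tab-separated table
#'
#' @param matrix an \linkS4class{ExpressionMatrix} or
#'   \linkS4class{ContributionMatrix}
#' @param path output path
#' @param idColumn header label for the identifier column
#' @return \code{path}, invisibly
#' @export
writeExpressionTable <- function(matrix, path, idColumn = "id") {
  x <- if (is(matrix, "ContributionMatrix")) contributions(matrix)
       else exprValues(matrix)
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validateBedLines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "track") || startsWith(ln, "browser") ||
        startsWith(ln, "#"))
      next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopParse(sprintf("%s:%d: BED record has %d field(s); at least 3 required",
                        path, i, length(f)))
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      stopParse(sprintf("%s:%d: non-numeric BED coordinates", path, i))
    if (s >= e)
      stopParse(sprintf("%s:%d: start (%s) must be less than end (%s)",
                        path, i, f[2L], f[3L]))
  }
  invisible(TRUE)
}

#' Read genomic features from a BED file
#'
#' Accepts BED3+ with an optional name in column 4, strand in column 6 and an
#' optional leading \code{track} header line. Features without a name get a
#' synthesized \code{chrom:start-end} identifier. Coordinates stay in the BED
#' convention internally (the returned \code{GRanges} is the usual 1-based
#' closed representation of the 0-based half-open records).
#'
#' @param path path to a BED file
#' @return a \code{GRanges} with a \code{name} metadata column
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t1000\t1400\te1", f)
#' readBed(f)
#' @export
readBed <- function(path) {
  .validateBedLines(path)
  gr <- import.bed(path)
  gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                strand = strand(gr),
                name = if (!is.null(mcols(gr)$name)) mcols(gr)$name
                       else NA_character_)
  noName <- is.na(mcols(gr)$name) | !nzchar(mcols(gr)$name)
  if (any(noName))
    mcols(gr)$name[noName] <- sprintf("%s:%d-%d",
                                      as.character(seqnames(gr))[noName],
                                      .start0(gr)[noName], .end0(gr)[noName])
  gr
}

#' Write genomic features as BED, optionally with a UCSC track header
#'
#' Records are written as BED6 (chrom, 0-based start, end, name, score 0,
#' strand). With a \linkS4class{TrackSpec}, a single \code{track} header line
#' precedes the records so the file can be uploaded to the UCSC Genome
#' Browser as a custom track.
#'
#' @param features a \code{GRanges} with a \code{name} metadata column
#' @param path output path
#' @param track optional \linkS4class{TrackSpec}
#' @return \code{path}, invisibly
#' @examples
#' fx <- genomicFeatures("e1", "chr1", 1000, 1400)
#' writeBed(fx, tempfile(fileext = ".bed"), TrackSpec("sel"))
#' @export
writeBed <- function(features, path, track = NULL) {
  if (is.null(mcols(features)$name))
    stopValidation("features must carry a 'name' metadata column")
  if (is.null(track)) {
    export.bed(features, path)
  } else {
    stopifnot(is(track, "TrackSpec"))
    tl <- new("BasicTrackLine", name = track@trackName,
              description = track@description, color = track@color,
              visibility = track@visibility)
    export.bed(features, path, trackLine = tl)
  }
  invisible(path)
}

#' Extract feature sequences from a genome FASTA, with optional flanks
#'
#' For each feature, returns the genomic sequence of
#' \code{[start - flankBp, end + flankBp)} clamped to the chromosome bounds.
#' Record names are \code{"id::chrom:start-end(strand)"} with the clamped
#' 0-based half-open coordinates. Sequences are never reverse-complemented;
#' the strand is only reported in the header. Sequence case is preserved from
#' the source.
#'
#' @param features a \code{GRanges} with a \code{name} metadata column
#' @param genomeFastaPath path to the genome FASTA
#' @param flankBp extra bases on each side (default 0)
#' @param out optional output FASTA path; when given, records are written
#'   there as well
#' @return a \code{DNAStringSet}
#' @examples
#' g <- tempfile(fileext = ".fa"); writeLines(c(">chrT", "ACGTACGT"), g)
#' fx <- genomicFeatures("f1", "chrT", 2, 4)
#' as.character(extractFasta(fx, g))            # "GT"
#' as.character(extractFasta(fx, g, flankBp = 2))  # "ACGTAC"
#' @export
extractFasta <- function(features, genomeFastaPath, flankBp = 0L,
                         out = NULL) {
  if (flankBp < 0)
    stopConfig("flankBp must be non-negative")
  genome <- readDNAStringSet(genomeFastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(seqnames(features))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stopLookup(sprintf("chromosome(s) absent from FASTA: %s",
                       paste(missing, collapse = ", ")))
  len <- stats::setNames(Biostrings::width(genome), names(genome))[chrom]
  s0 <- pmax(.start0(features) - flankBp, 0L)
  e0 <- pmin(.end0(features) + flankBp, len)
  seqs <- DNAStringSet(vapply(seq_along(features), function(i)
    as.character(subseq(genome[[chrom[i]]], s0[i] + 1L, e0[i])),
    character(1)))
  names(seqs) <- sprintf("%s::%s:%d-%d(%s)", mcols(features)$name, chrom,
                         s0, e0,
                         sub("*", ".", as.character(strand(features)),
                             fixed = TRUE))
  if (!is.null(out))
    writeXStringSet(seqs, out)
  seqs
}

#' Read a gene annotation table
#'
#' Tab-separated with header and columns \code{symbol}, \code{chrom},
#' \code{tss}, \code{strand}. The TSS column is a 0-based position. A gene
#' may appear on several rows (alternative TSSs); [filterByGeneWindow()]
#' takes the union of the per-TSS windows.
#'
#' @param path path to the table
#' @return a data.frame with the four columns, typed
#' @export
readGeneTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("symbol", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stopParse(sprintf("'%s': gene table needs columns %s", path,
                      paste(need, collapse = ", ")))
  tss <- suppressWarnings(as.integer(df$tss))
  bad <- which(is.na(tss) | tss < 0)
  if (length(bad))
    stopParse(sprintf("'%s': invalid TSS at line %d", path, bad[1L] + 1L))
  if (!all(df$strand %in% c("+", "-")))
    stopParse(sprintf("'%s': gene strand must be '+' or '-'", path))
  data.frame(symbol = df$symbol, chrom = df$chrom, tss = tss,
             strand = df$strand)
}

#' Read SNP positions from a VCF or a 3-column TSV
#'
#' The TSV layout is \code{id}, \code{chrom}, \code{pos} with a header and
#' 1-based positions; VCF positions are 1-based per the standard. Both are
#' converted to 0-based at read time. A multi-allelic VCF record contributes
#' a single SNP record (only the position is used).
#'
#' @param path path to the file
#' @param format \code{"tsv"} or \code{"vcf"}
#' @return a width-1 \code{GRanges} from [snpRecords()]
#' @export
readSnpTable <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx)))
      fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
    id <- fx[, "ID"]
    id[is.na(id) | id == "."] <-
      sprintf("%s_%s", fx[, "CHROM"], fx[, "POS"])[is.na(id) | id == "."]
    return(snpRecords(id, fx[, "CHROM"], as.integer(fx[, "POS"]) - 1L))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stopParse(sprintf("'%s': SNP table needs columns %s", path,
                      paste(need, collapse = ", ")))
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stopParse(sprintf("'%s': invalid 1-based position at line %d", path,
                      bad[1L] + 1L))
  snpRecords(df$id, df$chrom, pos - 1L)
}

#' Read an enhancer-promoter association table
#'
#' Tab-separated with header and columns \code{enhancer_id},
#' \code{promoter_id}, \code{score} (the association score as supplied, e.g.
#' an expression correlation).
#'
#' @param path path to the table
#' @return a data.frame with the three columns, score numeric
#' @export
readAssociationTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("enhancer_id", "promoter_id", "score")
  if (!all(need %in% names(df)))
    stopParse(sprintf("'%s': association table needs columns %s", path,
                      paste(need, collapse = ", ")))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) | !is.finite(score))
  if (length(bad))
    stopParse(sprintf("'%s': non-finite score at line %d", path, bad[1L] + 1L))
  data.frame(enhancer_id = df$enhancer_id, promoter_id = df$promoter_id,
             score = score)
}

#' Read a sample-to-facet map
#'
#' Tab-separated with header and columns \code{sample}, \code{facet} and
#' optionally \code{panel}. A file may describe several panels; pass
#' \code{panel} to pick one (required when more than one is present).
#'
#' @param path path to the table
#' @param panel panel to extract when the file holds several
#' @return a \linkS4class{FacetMap}
#' @export
readFacetMap <- function(path, panel = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("sample", "facet") %in% names(df)))
    stopParse(sprintf("'%s': facet map needs columns sample, facet", path))
  if ("panel" %in% names(df)) {
    panels <- unique(df$panel)
    if (is.null(panel)) {
      if (length(panels) > 1L)
        stopConfig(sprintf("'%s' defines panels %s; pass panel= to pick one",
                           path, paste(panels, collapse = ", ")))
      panel <- panels
    } else if (!panel %in% panels)
      stopConfig(sprintf("'%s' has no panel '%s'", path, panel))
    df <- df[df$panel == panel, , drop = FALSE]
  } else if (is.null(panel))
    panel <- "panel"
  dup <- unique(df$sample[duplicated(df$sample)])
  if (length(dup))
    stopValidation(sprintf("'%s': sample(s) mapped twice within a panel: %s",
                           path, paste(dup, collapse = ", ")))
  FacetMap(stats::setNames(df$facet, df$sample), panelName = panel)
}

#' Write a sample-to-facet map
#'
#' @param facets a \linkS4class{FacetMap}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeFacetMap <- function(facets, path) {
  mp <- facetMapping(facets)
  utils::write.table(
    data.frame(sample = names(mp), facet = unname(mp),
               panel = panelName(facets)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ordinal protein-level table
#'
#' Long-format, tab-separated with header and columns \code{gene},
#' \code{tissue}, \code{level}, where level is one of \code{None},
#' \code{Low}, \code{Medium}, \code{High} (the immunohistochemistry staining
#' scale) or a missing marker (empty or \code{NA}). Gene/tissue pairs absent
#' from the file are missing (\code{NA}) in the returned matrix.
#'
#' @param path path to the table
#' @return a character matrix, genes as rows and tissues as columns, with
#'   \code{NA} for missing annotation
#' @export
readOrdinalTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          na.strings = NULL)
  need <- c("gene", "tissue", "level")
  if (!all(need %in% names(df)))
    stopParse(sprintf("'%s': ordinal table needs columns %s", path,
                      paste(need, collapse = ", ")))
  lv <- df$level
  lv[lv == "" | lv == "NA"] <- NA_character_
  bad <- which(!is.na(lv) & !lv %in% .ORDINAL_LEVELS)
  if (length(bad))
    stopParse(sprintf(
      "'%s': unknown level '%s' at line %d (scale is %s)",
      path, lv[bad[1L]], bad[1L] + 1L, paste(.ORDINAL_LEVELS, collapse = "/")))
  genes <- unique(df$gene); tissues <- unique(df$tissue)
  m <- matrix(NA_character_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  m[cbind(match(df$gene, genes), match(df$tissue, tissues))] <- lv
  m
}

#' Serialize a ConstraintSet to JSON
#'
#' The JSON layout is \code{{"combiner": "AND", "panels": [{"name": ...,
#' "enabled": true, "constraints": {"facet": [min, max], ...}}]}}. Default
#' \code{[0, 100]} constraints are omitted on write and need not be present
#' on read, so configs round-trip compactly.
#'
#' @param cset a \linkS4class{ConstraintSet}
#' @param path optional file to write; omitted returns the JSON string
#' @return the JSON string (invisibly when \code{path} is given)
#' @examples
#' writeConstraintSet(ConstraintSet(ConstraintPanel("tissues",
#'   list(brain = c(80, 100)))))
#' @export
writeConstraintSet <- function(cset, path = NULL) {
  panels <- lapply(cset@panels, function(p) {
    keep <- Filter(function(ct) !.isDefaultConstraint(ct), p@constraints)
    cts <- stats::setNames(
      lapply(keep, function(ct) c(ct@minPct, ct@maxPct)),
      vapply(keep, slot, character(1), "facetId"))
    list(name = p@panelName, enabled = p@enabled, constraints = cts)
  })
  js <- jsonlite::toJSON(list(combiner = cset@combiner, panels = panels),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path))
    return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Deserialize a ConstraintSet from JSON
#'
#' @param path path to a JSON file, or a JSON string
#' @return a \linkS4class{ConstraintSet}
#' @export
readConstraintSet <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stopParse(conditionMessage(e)))
  combiner <- if (is.null(obj$combiner)) "AND" else obj$combiner
  if (!identical(combiner, "AND") && !identical(combiner, "OR"))
    stopConfig(sprintf("combiner must be \"AND\" or \"OR\", got '%s'",
                       combiner))
  panels <- lapply(obj$panels, function(p) {
    if (is.null(p$name))
      stopConfig("every panel needs a \"name\"")
    cts <- lapply(p$constraints, unlist)
    ConstraintPanel(p$name, constraints = cts,
                    enabled = if (is.null(p$enabled)) TRUE else p$enabled)
  })
  ConstraintSet(panels, combiner = combiner)
}
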