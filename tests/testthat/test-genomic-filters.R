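test_that("region filtering uses half-open overlap semantics", {
  fx <- genomicFeatures(c("a", "b"), c("chr1", "chr2"),
                        c(100, 100), c(200, 200))
  expect_identical(filterByRegion(fx, "chr1", 150, 160), "a")  # containment
  expect_identical(filterByRegion(fx, "chr1", 200, 300),
                   character(0))                               # abutment
  expect_identical(filterByRegion(fx, "chr1", 199, 300), "a")  # 1 bp overlap
  expect_identical(filterByRegion(fx, "chr1", 0, 1e9), "a")    # wrong chrom for b
  expect_error(filterByRegion(fx, "chr1", 10, 10), class = "configError")
})

test_that("gene-window filtering anchors on midpoint with closed bounds", {
  genes <- data.frame(symbol = "NEUROD1", chrom = "chr2", tss = 50000,
                      strand = "+")
  # midpoints 49500, 51000, 51001, 50000
  fx <- genomicFeatures(paste0("p", 1:4), "chr2",
                        c(49400, 50900, 50901, 49900),
                        c(49600, 51100, 51101, 50100))
  expect_identical(filterByGeneWindow(fx, genes, "NEUROD1", 1000),
                   c("p1", "p2", "p4"))   # 51001 is boundary + 1: excluded
  # degenerate window: only the feature whose midpoint equals the TSS
  expect_identical(filterByGeneWindow(fx, genes, "NEUROD1", 0), "p4")
  # case-insensitive symbol match
  expect_identical(filterByGeneWindow(fx, genes, "neurod1", 0), "p4")
})

test_that("unknown gene symbols raise a lookup error with suggestions", {
  genes <- data.frame(symbol = c("NEUROD1", "NEUROD2", "MAPK14"),
                      chrom = "chr2", tss = c(1000, 2000, 3000),
                      strand = "+")
  fx <- genomicFeatures("p1", "chr2", 900, 1100)
  expect_error(filterByGeneWindow(fx, genes, "NEUROD9"),
               class = "lookupError")
  expect_error(filterByGeneWindow(fx, genes, "NEUROD9"), "NEUROD1")
})

test_that("multiple annotated TSSs widen the window to their union", {
  genes <- data.frame(symbol = c("DUAL", "DUAL"), chrom = "chr1",
                      tss = c(1000, 9000), strand = c("+", "+"))
  fx <- genomicFeatures(c("near1", "near2", "far"), "chr1",
                        c(900, 8900, 4900), c(1100, 9100, 5100))
  expect_identical(filterByGeneWindow(fx, genes, "DUAL", 500),
                   c("near1", "near2"))
})

test_that("start5 anchor is strand-aware", {
  genes <- data.frame(symbol = "G", chrom = "chr1", tss = 1000,
                      strand = "+")
  # plus-strand feature: 5' end at start0 = 990; minus-strand: at end0-1 = 1009
  fx <- genomicFeatures(c("plus", "minus"), "chr1", c(990, 400),
                        c(1600, 1010), strand = c("+", "-"))
  expect_identical(filterByGeneWindow(fx, genes, "G", 10, anchor = "start5"),
                   c("plus", "minus"))
  expect_identical(filterByGeneWindow(fx, genes, "G", 9, anchor = "start5"),
                   "minus")   # plus anchor at distance 10 drops out first
})

test_that("SNP overlap honors the midpoint-distance boundary exactly", {
  e <- genomicFeatures("e1", "chr1", 1000, 1400)   # midpoint 1200
  s <- snpRecords(c("rs_at_200", "rs_at_201"), "chr1", c(1400, 1401))
  pairs <- snpOverlap(e, s, maxDist = 200)
  expect_identical(pairs$snp_id, "rs_at_200")
  expect_identical(pairs$distance, 200L)
  # other side of the midpoint
  s2 <- snpRecords(c("lo_ok", "lo_out"), "chr1", c(1000, 999))
  pairs2 <- snpOverlap(e, s2, maxDist = 200)
  expect_identical(pairs2$snp_id, "lo_ok")
})

test_that("SNP overlap matches the all-pairs oracle on random instances", {
  set.seed(201)
  for (rep in 1:5) {
    g <- simulateGenomic(50, 200, 1e5, seed = rep)
    got <- snpOverlap(g$features, g$snps, maxDist = 200)
    want <- oracleSnpOverlap(g$features, g$snps, maxDist = 200)
    ord <- function(d) d[order(d$enhancer_id, d$snp_id), , drop = FALSE]
    expect_equal(unname(as.matrix(ord(got))), unname(as.matrix(ord(want))))
  }
  # empty inputs give empty output
  g0 <- simulateGenomic(0, 0, 1e4, seed = 1)
  expect_identical(nrow(snpOverlap(g0$features, g0$snps)), 0L)
})

test_that("SNP overlap is invariant under input shuffling", {
  g <- simulateGenomic(40, 150, 5e4, seed = 7)
  base <- snpOverlap(g$features, g$snps, maxDist = 300)
  set.seed(8)
  shuffled <- snpOverlap(g$features[sample(length(g$features))],
                         g$snps[sample(length(g$snps))], maxDist = 300)
  key <- function(d) sort(paste(d$enhancer_id, d$snp_id, d$distance))
  expect_identical(key(shuffled), key(base))
})

test_that("gene-window filtering matches an all-pairs oracle on random inputs", {
  set.seed(202)
  for (rep in 1:5) {
    g <- simulateGenomic(200, 0, 1e6, seed = rep + 10)
    genes <- data.frame(symbol = c("A", "A", "B"), chrom = "chrS",
                        tss = sample.int(1e6, 3), strand = "+")
    for (sym in c("A", "B")) {
      w <- sample.int(2e5, 1)
      expect_identical(
        filterByGeneWindow(g$features, genes, sym, w),
        oracleGeneWindow(g$features, genes, sym, w))
    }
  }
})

test_that("expression and location filters commute", {
  set.seed(203)
  sim <- simulateExpression(100, c("neuron", "glia", "blood"), seed = 11)
  cm <- normalizeContributions(sim$matrix)
  g <- simulateGenomic(100, 0, 1e6, seed = 12)
  # align genomic feature names with matrix feature ids
  gr <- g$features
  S4Vectors::mcols(gr)$name <- rownames(cm)
  genes <- data.frame(symbol = "G", chrom = "chrS", tss = 5e5, strand = "+")
  panel <- ConstraintPanel("simulated", list(neuron = c(40, 100)))

  exprFirst <- selectedIds(applyPanel(cm, panel))
  exprFirst <- intersect(exprFirst,
                         filterByGeneWindow(gr, genes, "G", 2e5))
  locFirst <- filterByGeneWindow(gr, genes, "G", 2e5)
  locFirst <- intersect(locFirst, selectedIds(applyPanel(cm, panel)))
  expect_identical(sort(exprFirst), sort(locFirst))
})

test_that("association lookup is a deduplicated pass-through join", {
  tab <- data.frame(
    enhancer_id = c("e1", "e1", "e1", "e3"),
    promoter_id = c("p1", "p2", "p1", "p9"),     # (e1,p1) duplicated
    score = c(0.8, 0.5, 0.8, 0.3))
  out <- linkAssociations(c("e1", "e2"), tab)
  expect_identical(names(out), c("e1", "e2"))
  expect_identical(out$e1$promoter_id, c("p1", "p2"))
  expect_equal(out$e1$score, c(0.8, 0.5))
  expect_identical(nrow(out$e2), 0L)   # absent from the table: empty list
})
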