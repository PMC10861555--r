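make_motif <- function(consensus, id = "M1", tf = "TF1") {
  bases <- c("A", "C", "G", "T")
  pfm <- matrix(2, 4, nchar(consensus), dimnames = list(bases, NULL))
  idx <- match(strsplit(consensus, "")[[1]], bases)
  pfm[cbind(idx, seq_along(idx))] <- 94
  new("MotifSet", pfms = stats::setNames(list(pfm), id),
      tfNames = stats::setNames(tf, id),
      background = stats::setNames(
        list(stats::setNames(rep(0.25, 4), bases)), id))
}

test_that("scanning finds the consensus on either strand", {
  m <- make_motif("ACGTGA")
  hit <- scanMotifs(c(p1 = "TTTTACGTGATTTT"), m, rel_threshold = 0.99)
  expect_equal(as.numeric(hitMatrix(hit)[1, 1]), 1)
  # reverse complement of ACGTGA is TCACGT
  hit_rc <- scanMotifs(c(p1 = "GGGGTCACGTGGGG"), m, rel_threshold = 0.99)
  expect_equal(as.numeric(hitMatrix(hit_rc)[1, 1]), 1)
  none <- scanMotifs(c(p1 = "TTTTTTTTTTTTT"), m, rel_threshold = 0.8)
  expect_equal(as.numeric(hitMatrix(none)[1, 1]), 0)
  # motif wider than sequence: no hit, no error
  short <- scanMotifs(c(p1 = "ACG"), m, rel_threshold = 0.5)
  expect_equal(sum(hitMatrix(short)), 0)
  expect_error(scanMotifs(character(), m), "empty")
})

test_that("hits are monotone non-increasing in the threshold", {
  set.seed(4)
  m <- make_motif("ACGTGACT")
  seqs <- stats::setNames(
    vapply(1:30, function(i)
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
            collapse = ""), ""),
    paste0("p", 1:30))
  counts <- vapply(seq(0.5, 1, 0.1), function(th)
    sum(hitMatrix(scanMotifs(seqs, m, th))), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("scanning is strand-symmetric", {
  set.seed(6)
  m <- make_motif("ACGTCA")
  seqs <- stats::setNames(
    vapply(1:20, function(i)
      paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
            collapse = ""), ""),
    paste0("p", 1:20))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  names(rc) <- names(seqs)
  h1 <- as.matrix(hitMatrix(scanMotifs(seqs, m, 0.8)))
  h2 <- as.matrix(hitMatrix(scanMotifs(rc, m, 0.8)))
  expect_equal(h1, h2)
})

test_that("N bases score as background", {
  m <- make_motif("ACGTGA")
  # consensus with one N still close to max; all-N scores 0 relative ~ mid
  h <- scanMotifs(c(p1 = "TTACGNGATT", p2 = "NNNNNNNNNN"), m,
                  rel_threshold = 0.75)
  expect_equal(as.numeric(hitMatrix(h)[1, 1]), 1)
  expect_equal(as.numeric(hitMatrix(h)[2, 1]), 0)
})

test_that("promoter intervals are strand-aware", {
  gp <- GeneAnnotation("g", "chr1", "+", 10000, 30000)
  ip <- promoterInterval(gp, 2000, 0)
  expect_equal(GenomicRanges::start(ip), 8001)  # 0-based [8000, 10000)
  expect_equal(GenomicRanges::end(ip), 10000)
  gm <- GeneAnnotation("g", "chr1", "-", 1, 10001)  # tss = 10000
  im <- promoterInterval(gm, 2000, 0)
  expect_equal(GenomicRanges::start(im), 10002)  # 0-based [10001, 12001)
  expect_equal(GenomicRanges::end(im), 12001)
  # zero extent -> no promoter peaks
  pk <- PeakSet("chr1", 7000, 13000)
  expect_length(promoterPeaks(gp, pk, upstream = 0, downstream = 0), 0L)
  expect_identical(promoterPeaks(gp, pk), peakIds(pk))
})

test_that("candidate TFs honor significance, promoters and expression", {
  hits <- peakMotifHits(matrix(c(1, 0, 0,
                                 0, 1, 0,
                                 0, 0, 1), 3, 3, byrow = TRUE,
                               dimnames = list(c("pkSig", "pkProm", "pkNS"),
                                               c("m1", "m2", "m3"))))
  motifs <- new("MotifSet",
                pfms = stats::setNames(rep(list(matrix(1, 4, 4)), 3),
                                       c("m1", "m2", "m3")),
                tfNames = c(m1 = "TF_A", m2 = "TF_B", m3 = "TF_C"),
                background = stats::setNames(
                  rep(list(stats::setNames(rep(0.25, 4),
                                           c("A", "C", "G", "T"))), 3),
                  c("m1", "m2", "m3")))
  links <- data.frame(gene_id = "g", peak_id = "pkSig", beta = 1)
  # TF_C's motif sits only in a peak that failed significance -> excluded;
  # TF_B sits in a promoter peak with no CRE -> included
  tfs <- candidateTfs("g", links, hits, "pkProm",
                      expressed_tfs = c("TF_A", "TF_B", "TF_C"), motifs)
  expect_identical(tfs, c("TF_A", "TF_B"))
  # expression filter trumps motifs
  expect_identical(candidateTfs("g", links, hits, "pkProm",
                                expressed_tfs = "TF_B", motifs), "TF_B")
})

test_that("expression prevalence filter works", {
  m <- matrix(0, 100, 2, dimnames = list(sprintf("c%03d", 1:100),
                                         c("TFa", "TFb")))
  m[1:5, 1] <- 1   # 5% of cells
  om <- OmicsMatrix(m, "rna")
  expect_identical(expressedTfs(om, c("TFa", "TFb"), 0.01), "TFa")
  expect_length(expressedTfs(om, c("TFa", "TFb"), 0.10), 0L)
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  for (tab in list(c(5, 3, 2, 40), c(0, 10, 5, 35), c(10, 0, 10, 30),
                   c(2, 2, 2, 2))) {
    p_pkg <- stats::fisher.test(matrix(c(tab[1], tab[2], tab[3], tab[4]), 2),
                                alternative = "greater")$p.value
    p_orc <- fisher_greater_oracle(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p_pkg, p_orc, tolerance = 1e-10)
  }
})

test_that("motif enrichment keeps strong signals and drops flat ones", {
  set.seed(10)
  n_pk <- 300
  all_ids <- sprintf("pk%03d", 1:n_pk)
  cre <- all_ids[1:10]
  h <- matrix(0, n_pk, 2, dimnames = list(all_ids, c("mStrong", "mFlat")))
  h[cre, "mStrong"] <- 1                       # 100% of CREs, 0 elsewhere
  h[sample(all_ids, 30), "mFlat"] <- 1         # ~10% everywhere
  hits <- peakMotifHits(h)
  motifs <- new("MotifSet",
                pfms = stats::setNames(rep(list(matrix(1, 4, 4)), 2),
                                       c("mStrong", "mFlat")),
                tfNames = c(mStrong = "TF_S", mFlat = "TF_F"),
                background = stats::setNames(
                  rep(list(stats::setNames(rep(0.25, 4),
                                           c("A", "C", "G", "T"))), 2),
                  c("mStrong", "mFlat")))
  gc <- stats::setNames(runif(n_pk, 0.3, 0.7), all_ids)
  tfs <- enrichedTfs("g", cre, all_ids, hits, gc, motifs, seed = 1)
  expect_identical(tfs, "TF_S")
  expect_error(enrichedTfs("g", character(), all_ids, hits, gc, motifs),
               "empty CRE set")
})

test_that("GC content is computed per sequence", {
  expect_equal(unname(gcContent(c(a = "GGCC", b = "ATAT", c = "ACGT"))),
               c(1, 0, 0.5))
})
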