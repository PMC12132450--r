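test_that("window GC tiles from zero, drops the tail, excludes N", {
  s <- Biostrings::DNAStringSet(c(chr1 = strrep("ATGC", 2500)))  # 10 kb, 50%
  w <- window_gc(s, 1000)
  expect_equal(nrow(w), 10)
  expect_true(all(w$gc == 50))
  expect_equal(w$start[1], 0)
  expect_equal(w$end[10], 10000)
  ## 2.5 windows -> 2 windows
  s2 <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 2500)))
  expect_equal(nrow(window_gc(s2, 1000)), 2)
  ## an all-N window has no unambiguous bases and NA GC
  s3 <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("N", 1000), strrep("GGCC", 250))))
  w3 <- window_gc(s3, 1000)
  expect_true(is.na(w3$gc[1]))
  expect_equal(w3$unambiguous[1], 0)
  expect_equal(w3$gc[2], 100)
  ## Ns inside a mixed window drop out of numerator and denominator
  s4 <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("G", 500), strrep("N", 500))))
  expect_equal(window_gc(s4, 1000)$gc, 100)
  expect_warning(window_gc(Biostrings::DNAStringSet(c(tiny = "ACGT")), 1000),
                 "shorter")
})

test_that("nested masking partitions the genome and respects masking order", {
  g <- make_toy_genome(seed = 41)
  fc <- nested_feature_gc(g$seqs, g$feats)
  tot <- fc$bases[fc$class == "genome"]
  expect_equal(sum(fc$bases[fc$class != "genome"]), tot)
  expect_equal(tot, sum(Biostrings::width(g$seqs)))
  ## GC targets are recovered within a point at this sequence size
  truth <- g$truth$gc
  expect_lt(abs(fc$gc[fc$class == "exon"] - truth$exon), 1.5)
  expect_lt(abs(fc$gc[fc$class == "intergenic"] - truth$intergenic), 1.5)
  ## a repeat entirely inside an exon is counted as exon, not repeat
  seqs <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 250)))
  feats <- data.frame(seqid = "c1", class = c("gene", "exon", "repeat"),
                      start = c(0, 0, 100), end = c(600, 400, 300),
                      strand = "+", parent = NA)
  fc2 <- nested_feature_gc(seqs, feats)
  expect_equal(fc2$bases[fc2$class == "exon"], 400)
  expect_equal(fc2$bases[fc2$class == "repeat"], 0)
  expect_equal(fc2$bases[fc2$class == "intron"], 200)
  expect_equal(fc2$bases[fc2$class == "intergenic"], 400)
})

test_that("random feature layouts always satisfy the partition invariant", {
  set.seed(42)
  for (rep in 1:20) {
    L <- 5000
    seqs <- Biostrings::DNAStringSet(stats::setNames(
      paste(sample(c("A", "C", "G", "T", "N"), L, TRUE, prob = c(.24, .24, .24, .24, .04)),
            collapse = ""), "c1"))
    rand_feat <- function(cls, n) {
      st <- sort(sample(0:(L - 10), n))
      data.frame(seqid = "c1", class = cls, start = st,
                 end = pmin(st + sample(50:400, n, TRUE), L),
                 strand = "+", parent = NA)
    }
    feats <- rbind(rand_feat("gene", 4), rand_feat("exon", 6), rand_feat("repeat", 5))
    fc <- nested_feature_gc(seqs, feats)
    expect_equal(sum(fc$bases[fc$class != "genome"]), L)
    expect_equal(sum(fc$unambiguous[fc$class != "genome"]),
                 fc$unambiguous[fc$class == "genome"])
  }
})

test_that("GC variance is zero for uniform sequence and permutation-invariant", {
  s <- Biostrings::DNAStringSet(c(chr1 = strrep("ATGC", 5000)))
  v <- gc_variance_profile(s, c(500, 1000, 2000))
  expect_true(all(v$gc_variance == 0))
  ## block genome (10 kb pure GC + 10 kb pure AT): closed forms per scale
  blk <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("GC", 5000), strrep("AT", 5000))))
  vb <- gc_variance_profile(blk, c(1000, 4000))
  ## 1 kb windows never span the boundary: 10 at 100, 10 at 0
  expect_equal(vb$gc_variance[1], var(c(rep(100, 10), rep(0, 10))))
  ## 4 kb windows include one mixed window, shrinking the variance
  expect_equal(vb$gc_variance[2], var(c(100, 100, 50, 0, 0)))
  expect_gt(vb$gc_variance[1], vb$gc_variance[2])
  ## single window -> NA
  expect_true(is.na(gc_variance_profile(s, 20000)$gc_variance))
})

test_that("telomeric repeat runs are counted at the correct oriented ends", {
  mid <- strrep("ATTTAAGCGC", 20)
  s <- Biostrings::DNAStringSet(c(
    both = paste0(strrep("GCCTAA", 5), mid, strrep("TTAGGC", 10)),
    none = mid))
  tc <- count_telomeric_repeats(s)
  expect_equal(tc$left, c(5, 0))
  expect_equal(tc$right, c(10, 0))
  ## forward units at the left end are not telomeric orientation
  s2 <- Biostrings::DNAStringSet(c(x = paste0(strrep("TTAGGC", 4), mid)))
  tc2 <- count_telomeric_repeats(s2)
  expect_equal(tc2$left, 0)
})

test_that("RSCU: uniform usage, single-codon dominance, family sums", {
  ## equal use of all codons of every family
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  cds <- Biostrings::DNAStringSet(paste(sense, collapse = ""))
  r <- rscu(cds)
  expect_true(all(abs(r$rscu - 1) < 1e-12))
  ## one codon of a 4-family used exclusively
  r2 <- rscu(Biostrings::DNAStringSet("GGGGGGGGG"))
  expect_equal(r2$rscu[r2$codon == "GGG"], 4)
  expect_equal(r2$rscu[r2$codon == "GGA"], 0)
  ## the documented two-codon example: GGG + GGA
  r3 <- rscu(Biostrings::DNAStringSet("GGGGGA"))
  expect_equal(r3$rscu[r3$codon %in% c("GGG", "GGA")], c(2, 2))
  expect_equal(r3$rscu[r3$codon %in% c("GGT", "GGC")], c(0, 0))
  ## family sums equal family sizes whenever observed
  g <- make_toy_genome(seed = 43)
  r4 <- rscu(extract_cds(g))
  sums <- tapply(r4$rscu, r4$aa, sum)
  sizes <- tapply(r4$rscu, r4$aa, length)
  obs <- !is.na(sums)
  expect_equal(as.vector(sums[obs]), as.vector(sizes[obs]))
  ## trailing partial codons are trimmed with a warning
  expect_warning(rscu(Biostrings::DNAStringSet("GGGGG")), "trimmed")
  expect_error(rscu(Biostrings::DNAStringSet()), "empty")
})

test_that("amino-acid usage percentages, deviations and codon GC behave", {
  g1 <- extract_cds(make_toy_genome(seed = 44))
  one <- aa_usage(list(sp = g1))
  expect_equal(sum(one$percent), 100, tolerance = 1e-9)
  expect_true(all(one$deviation == 0))
  ## identical CDS in two species: all deviations 0
  two <- aa_usage(list(a = g1, b = g1))
  expect_true(all(abs(two$deviation) < 1e-12))
  ## deviations sum to zero across species per amino acid
  g2 <- extract_cds(make_toy_genome(seed = 45))
  three <- aa_usage(list(a = g1, b = g2))
  dev_sum <- tapply(three$deviation, three$aa, sum)
  expect_true(all(abs(dev_sum) < 1e-9))
  ## codon GC of lysine (AAA, AAG) is 1/6
  expect_equal(unique(three$codon_gc[three$aa == "K"]), 1 / 6)
})
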