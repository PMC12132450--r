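test_that("gametes from a homozygous parent are a single founder segment", {
  chrom <- chromosome_model("I", 10e6)
  A <- ancestry_haplotype(1L, numeric(0), 10e6)
  set.seed(1)
  for (mode in c("complete", "poisson")) {
    g <- meiosis_gamete(A, A, chrom, mode)
    expect_equal(count_crossovers(g), 0)
    expect_equal(hap_segments(g)$founder, "A")
  }
})

test_that("complete interference gives 0/1 crossovers with mean 1/2", {
  chrom <- chromosome_model("I", 10e6)
  A <- ancestry_haplotype(1L, numeric(0), 10e6)
  B <- ancestry_haplotype(2L, numeric(0), 10e6)
  set.seed(42)
  n <- 1e5
  counts <- vapply(seq_len(n), function(i)
    count_crossovers(meiosis_gamete(A, B, chrom, "complete")), 0L)
  expect_true(all(counts %in% c(0L, 1L)))
  ## 3 sigma Monte-Carlo band around 0.5 (sd = 0.5)
  expect_lt(abs(mean(counts) - 0.5), 3 * 0.5 / sqrt(n))
})

test_that("poisson mode matches Poisson(0.5) in mean, variance and tail", {
  chrom <- chromosome_model("I", 10e6)
  A <- ancestry_haplotype(1L, numeric(0), 10e6)
  B <- ancestry_haplotype(2L, numeric(0), 10e6)
  set.seed(7)
  n <- 1e5
  counts <- vapply(seq_len(n), function(i)
    count_crossovers(meiosis_gamete(A, B, chrom, "poisson")), 0L)
  expect_lt(abs(mean(counts) - 0.5), 3 * sqrt(0.5 / n))
  expect_lt(abs(var(counts) - 0.5), 0.02)
  expect_gt(sum(counts >= 2), 0)
  ## frequency of >= 2 close to 1 - ppois(1, 0.5)
  expect_lt(abs(mean(counts >= 2) - (1 - ppois(1, 0.5))), 0.005)
})

test_that("count_crossovers counts founder switch points", {
  L <- 10e6
  expect_equal(count_crossovers(ancestry_haplotype(1L, numeric(0), L)), 0)
  expect_equal(count_crossovers(ancestry_haplotype(1L, 5e6, L)), 1)
  expect_equal(count_crossovers(ancestry_haplotype(1L, c(3e6, 7e6), L)), 2)
  segs <- hap_segments(ancestry_haplotype(1L, c(3e6, 7e6), L))
  expect_equal(segs$founder, c("A", "B", "A"))
})

test_that("pure F1 gamete design (no intercross, no backcross) has mean 0.5", {
  des <- cross_design(intercross = 0, backcross = 0)
  s <- simulate_g4bc2(des, list(chromosome_model("I", 10e6)), 20000, seed = 5)
  expect_true(all(s$per_chrom$I$counts %in% 0:1))
  expect_lt(abs(s$per_chrom$I$mean - 0.5), 0.015)
})

test_that("summary mean equals distribution mean and counts sum to n", {
  s <- simulate_g4bc2(cross_design(), test_chroms(), 500, seed = 2)
  for (pc in s$per_chrom) {
    expect_equal(sum(pc$distribution), pc$n)
    k <- as.integer(names(pc$distribution))
    expect_equal(sum(k * pc$distribution) / pc$n, pc$mean)
  }
})

test_that("identical seed and design give identical summaries", {
  a <- simulate_g4bc2(cross_design(), test_chroms(), 300, seed = 11)
  b <- simulate_g4bc2(cross_design(), test_chroms(), 300, seed = 11)
  expect_identical(a$per_chrom$I$counts, b$per_chrom$I$counts)
  expect_identical(a$per_chrom$X$counts, b$per_chrom$X$counts)
  c <- simulate_g4bc2(cross_design(), test_chroms(), 300, seed = 12)
  expect_false(identical(a$per_chrom$I$counts, c$per_chrom$I$counts))
})

test_that("haplotype tiling invariant holds across random designs", {
  set.seed(99)
  for (rep in 1:400) {
    des <- cross_design(intercross = sample(0:3, 1), backcross = sample(0:2, 1),
                        interference = sample(c("complete", "poisson"), 1),
                        bc1_transmit_sex = sample(c("male", "female", "random"), 1),
                        count_on = sample(c("bc1_haplotype", "final_gamete"), 1))
    for (cc in test_chroms()) {
      h <- wormcross:::sim_counted_hap(des, cc)
      br <- h$br
      expect_true(length(br) == 0 ||
                    (all(diff(br) > 0) && br[1] > 0 && br[length(br)] < cc$length_bp))
      segs <- hap_segments(h)
      expect_equal(segs$start[1], 0)
      expect_equal(segs$end[nrow(segs)], cc$length_bp)
      if (nrow(segs) > 1) {
        expect_true(all(segs$start[-1] == segs$end[-nrow(segs)])) # no gaps
        expect_true(all(segs$founder[-1] != segs$founder[-nrow(segs)]))
      }
    }
  }
})

test_that("finite-pool pedigree keeps tiling, maternal mito and a fair sex ratio", {
  des <- cross_design(pool_size = 6)
  chroms <- list(chromosome_model("I", 5e6), chromosome_model("X", 6e6, kind = "X"))
  ped <- simulate_pool_pedigree(des, chroms, seed = 21)
  check_ind <- function(ind) {
    for (h in c(ind$auto$I, ind$X)) {
      segs <- hap_segments(h)
      expect_equal(segs$start[1], 0)
      expect_true(all(segs$start[-1] == segs$end[-nrow(segs)]))
    }
    ## all pedigree mitochondria descend from the A founder mother
    expect_equal(ind$mito, "A")
  }
  check_ind(ped$final)
  for (p in ped$pools[[length(ped$pools)]][1:4]) check_ind(p)
  expect_equal(length(ped$final$X), 2)  # backcross final individual is female

  ## sperm-determined sex is 1:1 from an X0 father
  momA <- founder_individual("A", "F", chroms)
  dadB <- founder_individual("B", "M", chroms)
  set.seed(3)
  sexes <- vapply(1:2000, function(i)
    cross_individuals(momA, dadB)$sex, "")
  expect_lt(abs(mean(sexes == "M") - 0.5), 3 * 0.5 / sqrt(2000))
})

test_that("male X meiosis yields intact X or nullosome, never recombinants", {
  chroms <- list(chromosome_model("X", 6e6, kind = "X"))
  momA <- founder_individual("A", "F", chroms)
  dadB <- founder_individual("B", "M", chroms)
  set.seed(4)
  son <- cross_individuals(momA, dadB, sex = "M")
  expect_equal(length(son$X), 1)
  xc <- chroms[[1]]
  got_x <- 0; got_null <- 0
  for (i in 1:200) {
    g <- simulate_meiosis(son, xc)
    if (is.null(g)) got_null <- got_null + 1
    else {
      got_x <- got_x + 1
      expect_identical(hap_segments(g), hap_segments(son$X[[1]]))
    }
  }
  expect_gt(got_x, 0); expect_gt(got_null, 0)
})

test_that("crossover count test is calibrated and handles the extremes", {
  des <- cross_design(intercross = 1, backcross = 1)
  chrom <- chromosome_model("I", 10e6)
  ## observed equal to the null mean (0.75 per line here is not exact for
  ## this design, so use a simulated 'observed' draw): p should not be tiny
  set.seed(8)
  obs <- simulate_g4bc2(des, list(chrom), 20, seed = 31)$per_chrom$I$counts
  res <- crossover_count_test(obs, des, chrom, n_sims = 199, seed = 32)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  ## far-below-null observation hits the Monte-Carlo floor 2/(n+1)
  res0 <- crossover_count_test(rep(-1L, 20), des, chrom, n_sims = 199, seed = 33)
  expect_equal(res0$p_value, 2 / 200)
  expect_error(crossover_count_test(integer(0), des, chrom), "non-empty")
  ## calibration: p is roughly uniform under the null
  pvals <- vapply(1:120, function(r) {
    obs <- simulate_g4bc2(des, list(chrom), 10, seed = 1000 + r)$per_chrom$I$counts
    crossover_count_test(obs, des, chrom, n_sims = 99, seed = 5000 + r)$p_value
  }, 0)
  expect_lt(abs(mean(pvals < 0.5) - 0.5), 0.17)
  expect_gt(min(pvals), 0)
})

test_that("X:autosome ratio test centers near 0.5 at the null ratio and has power", {
  des <- cross_design(intercross = 1, backcross = 1)
  cx <- chromosome_model("X", 10e6, kind = "X")
  ca <- chromosome_model("I", 10e6)
  set.seed(13)
  obs <- simulate_g4bc2(des, list(ca, cx), 400, seed = 41)
  res <- xa_ratio_test(obs$per_chrom$X$counts, obs$per_chrom$I$counts,
                       des, cx, ca, n_sims = 199, seed = 42)
  expect_true(res$p_value > 0.05 && res$p_value < 0.95)
  ## doubled X counts are detected
  res2 <- xa_ratio_test(obs$per_chrom$X$counts * 2L, obs$per_chrom$I$counts,
                        des, cx, ca, n_sims = 199, seed = 43)
  expect_lt(res2$p_value, 0.05)
})
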