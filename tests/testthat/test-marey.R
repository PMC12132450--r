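test_that("interpolation is linear, clamped, and exactly n points", {
  m <- marey_map("I", c(0, 10e6), c(0, 50))
  ip <- interpolate_map(m, 5)
  expect_equal(ip$cM, c(0, 12.5, 25, 37.5, 50))
  m2 <- marey_map("I", c(0, 5e6, 10e6), c(0, 25, 25))
  ip2 <- interpolate_map(m2, 21)
  expect_true(all(ip2$cM[ip2$bp >= 5e6] == 25))
  ip3 <- interpolate_map(m2, 200)
  expect_length(ip3$bp, 200)
  expect_true(all(diff(ip3$bp) > 0))
  expect_error(interpolate_map(marey_map("I", 1e6, 3, length_bp = 2e6)),
               "2 markers")
  ## markers not reaching the ends: clamped to terminal cM
  m3 <- marey_map("I", c(2e6, 8e6), c(5, 45), length_bp = 10e6)
  ip4 <- interpolate_map(m3, 11)
  expect_equal(ip4$cM[1], 5)
  expect_equal(ip4$cM[11], 45)
})

test_that("noiseless three-segment maps are recovered to the grid step", {
  L <- 20e6
  x <- seq(0, L, length.out = 200)
  y <- piecewise_cM(x, c(5e6, 15e6), c(8, 0.5, 8) / 1e6)
  fit <- fit_segmented(x, y, end_exclusion = 1e6)
  step <- diff(x)[1]
  expect_lt(abs(fit$LC - 5e6), step + 1e-6)
  expect_lt(abs(fit$CR - 15e6), step + 1e-6)
  expect_lt(abs(fit$slopes[1] * 1e6 - 8), 0.08)
  expect_lt(abs(fit$slopes[2] * 1e6 - 0.5), 0.02)
  expect_lt(abs(fit$slopes[3] * 1e6 - 8), 0.08)
  ## the three per-segment lines, written independently from the reported
  ## slopes and breakpoints, must agree at both breakpoints (continuity)
  y_at <- function(z) {  # piecewise evaluation, left segment anchored at intercept
    y_lc <- fit$intercept + fit$slopes[1] * fit$LC
    y_cr <- y_lc + fit$slopes[2] * (fit$CR - fit$LC)
    ifelse(z <= fit$LC, fit$intercept + fit$slopes[1] * z,
           ifelse(z <= fit$CR, y_lc + fit$slopes[2] * (z - fit$LC),
                  y_cr + fit$slopes[3] * (z - fit$CR)))
  }
  expect_equal(y_at(fit$x), fit$fitted, tolerance = 1e-8)
})

test_that("noisy breakpoint recovery has sub-half-megabase median error", {
  L <- 20e6
  x <- seq(0, L, length.out = 200)
  y0 <- piecewise_cM(x, c(5e6, 15e6), c(8, 0.5, 8) / 1e6)
  set.seed(17)
  errs <- vapply(1:50, function(s) {
    y <- y0 + rnorm(length(y0), 0, 0.5)
    fit <- fit_segmented(x, y, end_exclusion = 1e6)
    max(abs(fit$LC - 5e6), abs(fit$CR - 15e6))
  }, 0)
  expect_lt(median(errs), 0.5e6)
})

test_that("straight-line input takes the deterministic tie-break", {
  x <- seq(0, 20e6, length.out = 200)
  y <- x * 2.5 / 1e6
  fit <- fit_segmented(x, y, end_exclusion = 1e6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(unname(diff(fit$slopes)), c(0, 0), tolerance = 1e-8)
  kept <- x[x >= 1e6 & x <= 19e6]
  expect_equal(fit$LC, kept[3])                 # smallest admissible LC
  expect_equal(fit$CR, kept[length(kept) - 2])  # largest admissible CR
})

test_that("three-segment RSS never exceeds the single-line RSS", {
  set.seed(23)
  x <- seq(0, 20e6, length.out = 120)
  for (rep in 1:5) {
    y <- cummax(rnorm(120, seq(0, 50, length.out = 120), 2))
    fit <- fit_segmented(x, y, end_exclusion = 1e6)
    keep <- x >= 1e6 & x <= 19e6
    line_rss <- sum(lm(y[keep] ~ x[keep])$residuals^2)
    expect_lte(fit$rss, line_rss + 1e-8)
  }
})

test_that("degenerate flat input is flagged with zero slopes", {
  x <- seq(0, 20e6, length.out = 50)
  fit <- fit_segmented(x, rep(7, 50), end_exclusion = 1e6)
  expect_true(fit$degenerate)
  expect_equal(fit$slopes, c(0, 0, 0))
  expect_equal(fit$rss, 0)
  expect_error(fit_segmented(x[1:12], rep(7, 12), end_exclusion = 9e6),
               "fewer than 10")
})

test_that("scale equivariance: rescaling bp rescales breakpoints and divides slopes", {
  x <- seq(0, 20e6, length.out = 200)
  set.seed(31)
  y <- piecewise_cM(x, c(5e6, 15e6), c(8, 0.5, 8) / 1e6) + rnorm(200, 0, 0.2)
  y <- cummax(y)
  f1 <- fit_segmented(x, y, end_exclusion = 1e6)
  k <- 3.7
  f2 <- fit_segmented(x * k, y, end_exclusion = 1e6 * k)
  expect_equal(f2$LC, f1$LC * k, tolerance = 1e-6)
  expect_equal(f2$CR, f1$CR * k, tolerance = 1e-6)
  expect_equal(f2$slopes, f1$slopes / k, tolerance = 1e-6)
})

test_that("domain summary reports rates, percents and the normalization law", {
  m <- marey_map("V", c(0, 20e6), c(0, 100))
  fit <- list(LC = 5e6, CR = 15e6, slopes = c(8, 0.5, 8) / 1e6,
              intercept = 0, rss = 0, degenerate = FALSE)
  ds_raw <- domain_summary(fit, m, normalize_to = NULL)
  ds_norm <- domain_summary(fit, m, normalize_to = 50)
  expect_equal(ds_raw$pct_center, 50)
  expect_equal(ds_raw$pct_left + ds_raw$pct_center + ds_raw$pct_right, 100)
  expect_equal(c(ds_norm$rate_left, ds_norm$rate_center, ds_norm$rate_right),
               c(ds_raw$rate_left, ds_raw$rate_center, ds_raw$rate_right) / 2)
  expect_true(ds_raw$domain_structure)
})

test_that("species report composes per-chromosome summaries and flags failures", {
  tab <- make_marey_fixture(seed = 3)
  rep1 <- species_map_report(list(toy = tab))
  expect_equal(nrow(rep1), length(unique(tab$chrom)))
  expect_true(all(rep1$domain_structure))
  ## a chromosome shorter than the two excluded ends leaves no points to
  ## fit and must be flagged, not fatal
  bad <- structure(data.frame(chrom = "Z", bp = c(0, 1.5e6), cM = c(0, 10)),
                   lengths = list(Z = 1.5e6),
                   class = c("marker_table", "data.frame"))
  rep2 <- species_map_report(list(bad = bad))
  expect_false(rep2$domain_structure[1])
  expect_true(is.na(rep2$rate_center[1]))
})
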