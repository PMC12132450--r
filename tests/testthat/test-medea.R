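test_that("expected affected fractions match brute-force enumeration over the panel", {
  set.seed(5)
  for (rep in 1:20) {
    bI <- runif(1); bIII <- runif(1)
    mode <- sample(c("medea", "peel"), 1)
    model <- medea_model(bI, bIII, mode)
    for (cc in all_cross_classes()) {
      expect_equal(expected_affected_fraction(cc, model),
                   affected_oracle(cc$mother_geno, cc$father_geno, bI, bIII, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("the diagnostic asymmetry holds: homozygous trigger parents, no effect", {
  model <- medea_model(1, 1, "medea")
  peel <- medea_model(1, 1, "peel")
  for (cc in all_cross_classes()) {
    if (cc$mother_geno != "AB")
      expect_equal(expected_affected_fraction(cc, model), 0)
    if (cc$father_geno != "AB")
      expect_equal(expected_affected_fraction(cc, peel), 0)
  }
  ## the canonical fully penetrant fractions
  expect_equal(expected_affected_fraction(cross_class("F1AB", "A"), model), 3 / 4)
  expect_equal(expected_affected_fraction(cross_class("F1AB", "F1BA"), model), 7 / 16)
})

test_that("simulated progeny counts track the model fraction and are seed-stable", {
  cc <- cross_class("F1AB", "A")
  model <- medea_model(1, 1)
  set.seed(61)
  row <- simulate_progeny_counts(cc, model, 1e5)
  aff <- row$unhatched + row$deformed + row$larvae
  expect_lt(abs(aff / row$embryos - 3 / 4), 3 * sqrt(0.75 * 0.25 / 1e5))
  set.seed(62); r1 <- simulate_progeny_counts(cc, model, 500)
  set.seed(62); r2 <- simulate_progeny_counts(cc, model, 500)
  expect_identical(r1, r2)
  ## no distortion, no baseline: everything wild-type
  set.seed(63)
  r0 <- simulate_progeny_counts(cc, medea_model(0, 0), 1000)
  expect_equal(r0$unhatched + r0$deformed + r0$larvae, 0)
})

test_that("difference estimator reproduces closed-form Agresti-Caffo arithmetic", {
  ## equal proportions: D = 0 and a symmetric interval
  e0 <- difference_estimator(50, 100, 50, 100)
  expect_equal(e0$D, 0)
  expect_equal(e0$lower, -e0$upper)
  ## hand-computed adjusted-Wald arithmetic at an extreme table
  e1 <- difference_estimator(100, 100, 0, 100)
  expect_equal(e1$D, 1)
  p1 <- 101 / 102; p2 <- 1 / 102
  se <- sqrt(p1 * (1 - p1) / 102 + p2 * (1 - p2) / 102)
  expect_equal(e1$upper, min(1, (p1 - p2) + 1.959964 * se))
  expect_equal(e1$lower, (p1 - p2) - 1.959964 * se)
  expect_error(difference_estimator(1, 0, 1, 10))
})

test_that("penetrance solvers invert their expectation formulas on a grid", {
  for (b in seq(0, 1, by = 0.05)) {
    expect_equal(solve_equal_penetrance((2 * b + 3 * b^2) / 16)$beta, b,
                 tolerance = 1e-10)
    expect_equal(solve_equal_penetrance((8 * b - 3 * b^2) / 16,
                                        formula = "enumeration")$beta, b,
                 tolerance = 1e-10)
    expect_equal(solve_one_full_penetrance((1 + 4 * b) / 16)$beta, b,
                 tolerance = 1e-10)
  }
  ## boundary and clamping behaviour
  expect_equal(solve_equal_penetrance(0)$beta, 0)
  expect_equal(solve_equal_penetrance(5 / 16)$beta, 1)
  expect_equal(solve_one_full_penetrance(1 / 16)$beta, 0)
  expect_equal(solve_one_full_penetrance(5 / 16)$beta, 1)
  expect_warning(solve_equal_penetrance(-0.05), "clamped")
  expect_warning(solve_one_full_penetrance(0.01), "inconsistent")
})

test_that("classify_and_pool sums plates within classes and applies the toggles", {
  tab <- data.frame(plate = c("p1", "p2"), embryos = c(10, 10),
                    unhatched = c(4, 1), deformed = c(1, 0),
                    adult_female = c(3, 4), adult_male = c(2, 3),
                    L4_female = c(0, 1), L4_male = c(0, 0),
                    larvae = c(0, 1), mother = "F1AB", father = "A",
                    class_id = 3L)
  p <- classify_and_pool(tab, include_delayed = TRUE)
  expect_equal(p$affected, 7)
  expect_equal(p$total, 7 + 13)
  p2 <- classify_and_pool(tab, include_delayed = FALSE)
  expect_equal(p$affected - p2$affected, sum(tab$larvae))
  p3 <- classify_and_pool(tab, denominator = "embryos")
  expect_equal(p3$total, 20)
  ## phenotype proportions plus missing account for every embryo
  props <- p[, grep("^prop_", names(p))]
  expect_equal(unname(rowSums(props)), 1)
  expect_error(classify_and_pool(transform(tab, class_id = 99)), "class id")
})

test_that("allele frequency scan counts alleles, excludes missing", {
  g <- rbind(c("het", "A", "AA"),
             c("het", "B", "BB"),
             c("het", NA,  "het"))
  colnames(g) <- c("m1", "m2", "m3")
  f <- allele_frequency_scan(g)
  expect_equal(f$b_freq, c(0.5, 0.5, 0.5))
  expect_equal(allele_frequency_scan(cbind(m = c("B", "B")))$b_freq, 1)
  expect_true(is.na(allele_frequency_scan(cbind(m = c(NA, "missing")))$b_freq))
})

test_that("panel estimation recovers the simulated truth end to end", {
  cfg <- scenario_preset("medea-16cross")
  cfg$beta_I <- cfg$beta_III <- 0.8
  cfg$baseline <- 0; cfg$missing_rate <- 0
  cfg$n_embryos <- 1000; cfg$replicates <- 1
  tab <- make_medea_table(cfg, seed = 71)
  est <- estimate_medea_penetrance(tab, formula = "enumeration")
  true_d <- (8 * 0.8 - 3 * 0.8^2) / 16
  expect_lt(abs(est$estimate$D - true_d), 0.05)
  expect_lt(abs(est$beta_equal$beta - 0.8), 0.1)
  ## only heterozygous-mother classes show excess affected
  pooled <- est$pooled
  het_mom <- pooled$class_id %in% c(3, 4, 7, 8, 11, 12, 15, 16)
  expect_true(all(pooled$affected[!het_mom] == 0))
  expect_gt(sum(pooled$affected[het_mom]), 0)
})
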