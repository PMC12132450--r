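## Independent oracles used across the suite. These deliberately avoid the
## code paths they check.

## Exhaustive two-sided Fisher p for a 2x2 table by direct hypergeometric
## enumeration with exact binomial-coefficient arithmetic (point-probability
## two-sided rule; ties included with a small relative tolerance).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b      # row 1 total (margin fixed)
  n <- c + d
  k <- a + c      # column 1 total
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p_obs <- exp(logp[support == a])
  sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
}

## Expected affected fraction by brute-force enumeration of offspring
## genotypes at the two unlinked loci under multiplicative survival.
affected_oracle <- function(mother_geno, father_geno, beta_I, beta_III,
                            mode = "medea") {
  trans <- function(g) switch(g, AA = c(A = 1, B = 0),
                              BB = c(A = 0, B = 1),
                              AB = c(A = 0.5, B = 0.5))
  trig <- if (mode == "medea") mother_geno else father_geno
  p_aa <- function() {  # P(offspring AA at one locus)
    trans(mother_geno)[["A"]] * trans(father_geno)[["A"]]
  }
  if (trig != "AB") return(0)  # no maternal (paternal) product deposited
  pI <- p_aa(); pIII <- p_aa()
  tot <- 0
  for (gI in 0:1) for (gIII in 0:1) {
    pr <- (if (gI) pI else 1 - pI) * (if (gIII) pIII else 1 - pIII)
    surv <- (1 - beta_I * gI) * (1 - beta_III * gIII)
    tot <- tot + pr * (1 - surv)
  }
  tot
}

## Small default chromosome set for simulations.
test_chroms <- function() {
  list(chromosome_model("I", 15e6),
       chromosome_model("X", 21e6, kind = "X"))
}

## Piecewise-linear ground truth used by several Marey tests.
piecewise_cM <- function(x, breaks, slopes) {
  knots <- c(0, breaks, max(x))
  y0 <- cumsum(c(0, slopes * diff(knots)))
  seg <- findInterval(x, knots, rightmost.closed = TRUE)
  y0[seg] + slopes[seg] * (x - knots[seg])
}
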