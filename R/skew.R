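#' Autosome-X cosegregation (skew) counts
#'
#' Offspring counts from the skew test cross: an F1 male heterozygous for
#' an autosomal insertion crossed to wild-type females, with offspring
#' classified by insertion presence and sex. Because males are X0, sperm
#' are either X-bearing (daughters) or nullosomic (sons); under the skew
#' model the insertion preferentially cosegregates with the nullosome, so
#' the preferred phase is insertion+ males and insertion- females.
#'
#' @param ins_male,noins_male,ins_female,noins_female counts of
#'   insertion+ males, insertion- males, insertion+ females, insertion-
#'   females.
#' @return a `skew_counts` object.
#' @export
skew_counts <- function(ins_male, noins_male, ins_female, noins_female) {
  k <- c(ins_male = ins_male, noins_male = noins_male,
         ins_female = ins_female, noins_female = noins_female)
  stopifnot(all(k >= 0), sum(k) > 0)
  structure(as.list(k), class = "skew_counts")
}

preferred_count <- function(c) c$ins_male + c$noins_female
unpreferred_count <- function(c) c$noins_male + c$ins_female

#' Transmission Bias Ratio
#'
#' The ratio of preferred-phase (insertion with nullosome: insertion+
#' males plus insertion- females) to unpreferred-phase offspring. 1 means
#' no skew. Returns Inf with a warning when no unpreferred offspring were
#' observed.
#'
#' @param c a [skew_counts()].
#' @return the ratio.
#' @export
tbr <- function(c) {
  u <- unpreferred_count(c)
  if (u == 0) {
    warning("no unpreferred-phase offspring; TBR is infinite")
    return(Inf)
  }
  preferred_count(c) / u
}

#' Fisher exact test of insertion x sex association
#'
#' Two-sided exact test on the 2x2 table (insertion status x offspring
#' sex), with the point-probability two-sided rule: the p-value sums the
#' probabilities of all tables (at fixed margins) whose point probability
#' does not exceed that of the observed table.
#'
#' @param c a [skew_counts()].
#' @return the two-sided p-value.
#' @export
skew_fisher <- function(c) {
  m <- matrix(c(c$ins_male, c$noins_male, c$ins_female, c$noins_female), 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins of the 2x2 table must be positive")
  stats::fisher.test(m)$p.value
}

#' Map distance from the insertion to the X nullosome
#'
#' Treats absence of the X as a locus and the unpreferred-phase offspring
#' as recombinants: the recombination fraction is unpreferred / n, the
#' map distance is that fraction in cM (x100), and the 95 percent
#' confidence interval is the normal approximation for a binomial
#' proportion (z = 1.959964), clipped to [0, 100] cM.
#'
#' @param c a [skew_counts()].
#' @param conf_z normal quantile for the interval.
#' @return list with `cM`, `halfwidth`, `lower`, `upper`, `fraction`, `n`.
#' @export
nullosome_distance <- function(c, conf_z = 1.959964) {
  n <- preferred_count(c) + unpreferred_count(c)
  stopifnot(n > 0)
  f <- unpreferred_count(c) / n
  hw <- conf_z * sqrt(f * (1 - f) / n) * 100
  list(cM = 100 * f, halfwidth = hw,
       lower = max(0, 100 * f - hw), upper = min(100, 100 * f + hw),
       fraction = f, n = n)
}

#' Full skew analysis of a 2x2 offspring table
#'
#' Convenience wrapper printing both phases' counts (so the phase
#' convention is always visible), the Transmission Bias Ratio, the Fisher
#' exact p-value, and the map distance to the nullosome.
#'
#' @param c a [skew_counts()].
#' @return a `skew_result` list.
#' @export
skew_analysis <- function(c) {
  d <- nullosome_distance(c)
  structure(list(counts = c,
                 preferred = preferred_count(c),
                 unpreferred = unpreferred_count(c),
                 tbr = tbr(c), fisher_p = skew_fisher(c), distance = d),
            class = "skew_result")
}

#' @export
print.skew_result <- function(x, ...) {
  cat(sprintf("skew: preferred %d (ins+ male + ins- female), unpreferred %d\n",
              x$preferred, x$unpreferred))
  cat(sprintf("  TBR %.4f, Fisher two-sided p = %.3g\n", x$tbr, x$fisher_p))
  cat(sprintf("  distance to nullosome %.1f cM (95%% CI %.1f-%.1f, halfwidth %.1f)\n",
              x$distance$cM, x$distance$lower, x$distance$upper,
              x$distance$halfwidth))
  invisible(x)
}

#' Simulate a skew 2x2 offspring table
#'
#' Draws `n` offspring with an insertion-nullosome recombination fraction
#' `r` (the unpreferred-phase probability). The phase fixes insertion and
#' sex jointly: a preferred-phase sperm is (insertion, nullosome) or
#' (wild-type, X) — insertion+ male or insertion- female with equal
#' probability — and an unpreferred sperm is the other two classes.
#'
#' @param n offspring count.
#' @param r true recombination fraction (unpreferred-phase probability).
#' @param seed integer seed.
#' @return a [skew_counts()].
#' @export
simulate_skew_counts <- function(n, r = 0.5, seed = 1L) {
  set.seed(seed)
  unpref <- stats::rbinom(1, n, r)
  pref <- n - unpref
  im <- stats::rbinom(1, pref, 0.5)      # insertion+ male (pref)
  ifem <- stats::rbinom(1, unpref, 0.5)  # insertion+ female (unpref)
  skew_counts(ins_male = im, noins_male = unpref - ifem,
              ins_female = ifem, noins_female = pref - im)
}
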