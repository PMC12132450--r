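#' Cross classes of the sixteen-cross Medea panel
#'
#' The panel crosses four genotypes in every mother x father combination:
#' the two founder strains A and B (A is the susceptible strain, B carries
#' the distorter alleles) and the two reciprocal F1s (which differ in
#' mitochondrion and, through the male, in the X). Genotypes at the two
#' distorter loci (chromosome I and chromosome III) are "AA", "BB" or "AB".
#'
#' @param mother,father one of "A", "B", "F1AB" (A mother x B father),
#'   "F1BA".
#' @return a `cross_class` with parental locus genotypes, mitochondrial
#'   and X annotations, and the class id 1..16 (mother varying fastest).
#' @export
cross_class <- function(mother = c("A", "B", "F1AB", "F1BA"),
                        father = c("A", "B", "F1AB", "F1BA")) {
  mother <- match.arg(mother); father <- match.arg(father)
  geno <- function(p) switch(p, A = "AA", B = "BB", F1AB = "AB", F1BA = "AB")
  mito <- function(p) switch(p, A = "A", B = "B", F1AB = "A", F1BA = "B")
  levs <- c("A", "B", "F1AB", "F1BA")
  structure(list(
    mother = mother, father = father,
    mother_geno = geno(mother), father_geno = geno(father),
    mother_mito = mito(mother),
    class_id = match(mother, levs) + 4L * (match(father, levs) - 1L)),
    class = "cross_class")
}

#' All sixteen cross classes
#' @return list of [cross_class()]es indexed by class id.
#' @export
all_cross_classes <- function() {
  levs <- c("A", "B", "F1AB", "F1BA")
  out <- list()
  for (f in levs) for (m in levs) {
    cc <- cross_class(m, f)
    out[[cc$class_id]] <- cc
  }
  out
}

#' Two-locus maternal-effect (Medea) distortion model
#'
#' A Medea element carried by a heterozygous mother damages the offspring
#' that are homozygous for the susceptible (non-Medea, founder-A) allele
#' at that locus, with penetrance beta. The two loci (chromosomes I and
#' III) act independently, i.e. survival is multiplicative. "peel" mode is
#' the paternal-effect mirror image (heterozygous fathers, same genotype
#' rule).
#'
#' @param beta_I,beta_III locus penetrances in \[0, 1\].
#' @param mode "medea" (maternal-effect) or "peel" (paternal-effect).
#' @return a `medea_model`.
#' @export
medea_model <- function(beta_I, beta_III, mode = c("medea", "peel")) {
  mode <- match.arg(mode)
  stopifnot(beta_I >= 0, beta_I <= 1, beta_III >= 0, beta_III <= 1)
  structure(list(beta_I = beta_I, beta_III = beta_III, mode = mode),
            class = "medea_model")
}

## P(offspring homozygous susceptible AA at one locus | parental genotypes),
## given the triggering parent is heterozygous there.
h_susceptible <- function(trigger_geno, other_geno) {
  if (trigger_geno != "AB") return(0)
  switch(other_geno, AA = 1 / 2, AB = 1 / 4, BB = 0)
}

#' Expected affected offspring fraction for a cross class
#'
#' Under the multiplicative (independent-loci) survival model the affected
#' fraction is `1 - (1 - beta_I * h_I) (1 - beta_III * h_III)`, where
#' `h_L` is the probability that an offspring is homozygous susceptible at
#' locus L: 0 unless the triggering parent (mother for Medea, father for
#' Peel) is heterozygous there, 1/2 if the other parent is homozygous
#' susceptible, and 1/4 if both parents are heterozygous. Homozygous
#' mothers (Medea) or fathers (Peel) therefore never produce affected
#' offspring — the diagnostic asymmetry of the reciprocal crosses.
#'
#' @param cc a [cross_class()].
#' @param model a [medea_model()].
#' @return expected affected fraction in \[0, 1\].
#' @export
expected_affected_fraction <- function(cc, model) {
  if (model$mode == "medea") {
    trig <- cc$mother_geno; other <- cc$father_geno
  } else {
    trig <- cc$father_geno; other <- cc$mother_geno
  }
  hI <- h_susceptible(trig, other)
  hIII <- hI  # both loci have the same parental configuration in this panel
  1 - (1 - model$beta_I * hI) * (1 - model$beta_III * hIII)
}

#' Simulate one brood of progeny counts for a cross class
#'
#' Embryos are drawn multinomially over \{affected, wild-type, missing\}.
#' The affected probability composes the Medea model with an independent
#' baseline mortality; "missing" is the count-accounting gap between the
#' embryos counted at laying and the offspring recovered later. Affected
#' embryos are split among unhatched / deformed L1 / delayed larvae, and
#' wild-type survivors among adult and L4 stages by sex.
#'
#' @param cc a [cross_class()].
#' @param model a [medea_model()].
#' @param n_embryos embryos laid.
#' @param baseline baseline (Medea-independent) mortality probability.
#' @param missing_rate probability an offspring goes unaccounted.
#' @param affected_split proportions of affected embryos observed as
#'   unhatched, deformed L1, delayed larva (summing to 1).
#' @param plate_id identifier written to the row.
#' @return one-row data.frame in the progeny-count layout (see
#'   [read_progeny_table()]).
#' @export
simulate_progeny_counts <- function(cc, model, n_embryos, baseline = 0,
                                    missing_rate = 0,
                                    affected_split = c(0.55, 0.25, 0.20),
                                    plate_id = "sim") {
  stopifnot(n_embryos >= 0, baseline >= 0, baseline <= 1,
            missing_rate >= 0, missing_rate < 1,
            abs(sum(affected_split) - 1) < 1e-8)
  pa_model <- expected_affected_fraction(cc, model)
  pa <- 1 - (1 - baseline) * (1 - pa_model)
  p <- c(affected = pa * (1 - missing_rate),
         wildtype = (1 - pa) * (1 - missing_rate),
         missing = missing_rate)
  n3 <- as.vector(stats::rmultinom(1, n_embryos, p))
  aff <- as.vector(stats::rmultinom(1, n3[1], affected_split))
  wt <- as.vector(stats::rmultinom(1, n3[2], c(0.35, 0.35, 0.15, 0.15)))
  data.frame(plate = plate_id, embryos = n_embryos,
             unhatched = aff[1], deformed = aff[2],
             adult_female = wt[1], adult_male = wt[2],
             L4_female = wt[3], L4_male = wt[4],
             larvae = aff[3],
             mother = cc$mother, father = cc$father, class_id = cc$class_id,
             stringsAsFactors = FALSE)
}

#' Agresti-Caffo difference in affected proportions
#'
#' The backcross-minus-F2 difference in affected proportions, with the
#' Agresti-Caffo 95 percent confidence interval: one success and one
#' failure are added to each group and a Wald interval is computed on the
#' adjusted proportions (z = 1.959964). Under the two-Medea model this
#' difference estimates `1/16 beta_I + 1/16 beta_III +
#' 3/16 beta_I beta_III` (the expectation used for the penetrance
#' solutions; see [solve_equal_penetrance()]).
#'
#' @param affected_bc,total_bc affected and total counts in the
#'   susceptible-founder backcross progeny.
#' @param affected_f2,total_f2 affected and total counts in the F2 progeny.
#' @param conf_z normal quantile for the interval.
#' @return list with `D`, `lower`, `upper`, `halfwidth`, and the inputs.
#' @export
difference_estimator <- function(affected_bc, total_bc, affected_f2, total_f2,
                                 conf_z = 1.959964) {
  stopifnot(total_bc > 0, total_f2 > 0,
            affected_bc >= 0, affected_bc <= total_bc,
            affected_f2 >= 0, affected_f2 <= total_f2)
  D <- affected_bc / total_bc - affected_f2 / total_f2
  p1 <- (affected_bc + 1) / (total_bc + 2)
  p2 <- (affected_f2 + 1) / (total_f2 + 2)
  se <- sqrt(p1 * (1 - p1) / (total_bc + 2) + p2 * (1 - p2) / (total_f2 + 2))
  hw <- conf_z * se
  list(D = D, lower = max(-1, (p1 - p2) - hw), upper = min(1, (p1 - p2) + hw),
       halfwidth = hw,
       counts = c(affected_bc = affected_bc, total_bc = total_bc,
                  affected_f2 = affected_f2, total_f2 = total_f2))
}

## The two expectation formulas for D as a function of beta (equal
## penetrance at both loci):
##   paper:       16 D = 2 b + 3 b^2   (the printed two-Medea expectation)
##   enumeration: 16 D = 8 b - 3 b^2   (direct genotype enumeration under
##                                      multiplicative survival; agrees at b = 1)
d_of_beta <- function(beta, formula) {
  switch(formula,
         paper = (2 * beta + 3 * beta^2) / 16,
         enumeration = (8 * beta - 3 * beta^2) / 16)
}

solve_beta_equal <- function(D, formula) {
  if (D <= 0) return(0)
  if (D >= d_of_beta(1, formula)) return(1)
  b <- switch(formula,
              paper = (-2 + sqrt(4 + 192 * D)) / 6,
              enumeration = (8 - sqrt(64 - 192 * D)) / 6)
  min(1, max(0, b))
}

#' Equal-penetrance solution for the Medea penetrance
#'
#' Solves the expectation formula for the common penetrance beta assuming
#' both loci are equally penetrant, and propagates the confidence interval
#' of D through the (monotone) solver by transforming its endpoints.
#' `formula = "paper"` inverts `16 D = 2 beta + 3 beta^2`;
#' `formula = "enumeration"` inverts the multiplicative-model enumeration
#' `16 D = 8 beta - 3 beta^2`. The two agree only at beta = 1; see the
#' methods vignette for why both are exposed.
#'
#' @param est a [difference_estimator()] result, or a bare D value.
#' @param formula "paper" or "enumeration".
#' @return list with `beta`, `lower`, `upper`.
#' @export
solve_equal_penetrance <- function(est, formula = c("paper", "enumeration")) {
  formula <- match.arg(formula)
  if (is.numeric(est)) est <- list(D = est, lower = NA, upper = NA)
  if (!is.na(est$D) && est$D < 0)
    warning("negative difference estimate; penetrance clamped to 0")
  list(beta = solve_beta_equal(est$D, formula),
       lower = if (is.na(est$lower)) NA else solve_beta_equal(est$lower, formula),
       upper = if (is.na(est$upper)) NA else solve_beta_equal(est$upper, formula))
}

solve_beta_single <- function(D) {
  b <- (16 * D - 1) / 4
  min(1, max(0, b))
}

#' One-fully-penetrant solution for the second Medea penetrance
#'
#' Assuming one locus is completely penetrant (beta = 1), the printed
#' expectation reduces to `16 D = 1 + 4 beta`; this solves for the other
#' locus and propagates the interval endpoints.
#'
#' @param est a [difference_estimator()] result, or a bare D value.
#' @return list with `beta`, `lower`, `upper`.
#' @export
solve_one_full_penetrance <- function(est) {
  if (is.numeric(est)) est <- list(D = est, lower = NA, upper = NA)
  if (!is.na(est$D) && 16 * est$D < 1)
    warning("16 D < 1 is inconsistent with a fully penetrant locus; clamped to 0")
  list(beta = solve_beta_single(est$D),
       lower = if (is.na(est$lower)) NA else solve_beta_single(est$lower),
       upper = if (is.na(est$upper)) NA else solve_beta_single(est$upper))
}

#' Pool progeny counts into affected / total per cross class
#'
#' "Affected" is unhatched + deformed L1 + (optionally) developmentally
#' delayed L1-L3 larvae; the denominator is affected + wild-type (adult
#' and L4) offspring by default ("accounted", the missing class excluded)
#' or the embryos laid (`denominator = "embryos"`).
#'
#' @param tab a progeny-count table (see [read_progeny_table()]).
#' @param include_delayed count delayed larvae as affected.
#' @param denominator "accounted" or "embryos".
#' @return data.frame per class id with affected, total, and the phenotype
#'   proportions (of embryos laid) used for stacked-bar summaries.
#' @export
classify_and_pool <- function(tab, include_delayed = TRUE,
                              denominator = c("accounted", "embryos")) {
  denominator <- match.arg(denominator)
  if (!all(tab$class_id %in% 1:16)) stop("unknown cross class id")
  agg <- function(v) tapply(v, factor(tab$class_id, levels = 1:16), sum)
  unh <- agg(tab$unhatched); def <- agg(tab$deformed); lar <- agg(tab$larvae)
  wt <- agg(tab$adult_female + tab$adult_male + tab$L4_female + tab$L4_male)
  emb <- agg(tab$embryos)
  present <- !is.na(emb)
  affected <- unh + def + if (include_delayed) lar else 0
  total <- if (denominator == "accounted") affected + wt else emb
  miss <- pmax(emb - (unh + def + lar + wt), 0)
  out <- data.frame(class_id = 1:16, affected = as.vector(affected),
                    total = as.vector(total), embryos = as.vector(emb),
                    prop_unhatched = as.vector(unh / emb),
                    prop_deformed = as.vector(def / emb),
                    prop_delayed = as.vector(lar / emb),
                    prop_wildtype = as.vector(wt / emb),
                    prop_missing = as.vector(miss / emb))
  out[present, , drop = FALSE]
}

#' Estimate Medea penetrances from a progeny-count table
#'
#' Pools the susceptible-founder backcross classes (heterozygous F1
#' mother x founder-A father) and the F2 classes (F1 x F1), computes the
#' Agresti-Caffo difference in affected proportions, and solves the
#' expectation formula for the equal-penetrance and one-fully-penetrant
#' cases.
#'
#' @param tab a progeny-count table.
#' @param formula passed to [solve_equal_penetrance()].
#' @inheritParams classify_and_pool
#' @return list with the pooled counts, the [difference_estimator()]
#'   result, and the two penetrance solutions.
#' @export
estimate_medea_penetrance <- function(tab, include_delayed = TRUE,
                                      denominator = "accounted",
                                      formula = "paper") {
  pooled <- classify_and_pool(tab, include_delayed, denominator)
  bc_ids <- c(3, 4)            # F1 mother x founder-A father
  f2_ids <- c(11, 12, 15, 16)  # F1 mother x F1 father
  bc <- pooled[pooled$class_id %in% bc_ids, ]
  f2 <- pooled[pooled$class_id %in% f2_ids, ]
  est <- difference_estimator(sum(bc$affected), sum(bc$total),
                              sum(f2$affected), sum(f2$total))
  list(pooled = pooled, estimate = est,
       beta_equal = solve_equal_penetrance(est, formula),
       beta_single = solve_one_full_penetrance(est))
}

#' Founder-B allele frequency along the genome
#'
#' Per-marker frequency of the founder-B allele among mapping lines, the
#' genome scan used to detect transmission-ratio distortion (a distorted
#' region shows an excess of the driving founder's alleles).
#'
#' @param genotypes matrix or data.frame of founder calls (lines x
#'   markers), values in \{"A", "B", "het", NA\} ("missing" is also
#'   accepted). Haploid founder calls count one allele each, "het" counts
#'   one of each.
#' @param markers optional data.frame with chrom and bp per marker.
#' @return data.frame with per-marker B-allele frequency (NA where all
#'   lines are missing).
#' @export
allele_frequency_scan <- function(genotypes, markers = NULL) {
  g <- as.matrix(genotypes)
  if (is.null(colnames(g))) colnames(g) <- paste0("m", seq_len(ncol(g)))
  g[g == "missing"] <- NA
  ## haploid calls A/B count as one allele; diploid AA/BB/het as two
  freq <- apply(g, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    b <- sum(col == "B") + 2 * sum(col == "BB") + sum(col == "het")
    n <- sum(col %in% c("A", "B")) + 2 * sum(col %in% c("AA", "BB", "het"))
    b / n
  })
  out <- data.frame(marker = colnames(g), b_freq = as.vector(freq),
                    stringsAsFactors = FALSE)
  if (!is.null(markers)) out <- cbind(markers, out["b_freq"])
  out
}
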