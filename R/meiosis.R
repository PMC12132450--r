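#' Simulate one meiosis for a pair of homologs
#'
#' Under complete crossover interference a tetrad receives exactly one
#' obligate crossover, so a transmitted chromatid carries 0 or 1 crossovers,
#' each with probability 1/2, and the genetic length is 50 cM. Under the
#' "poisson" null the chromatid crossover count is Poisson(length_cM / 100)
#' with independent uniform positions. Crossover positions are uniform on
#' the genetic map and mapped to bp; the default map is linear, or supply
#' `cM_to_bp`, a function mapping a fraction of genetic length in [0, 1] to
#' bp, to place crossovers non-uniformly.
#'
#' @param h1,h2 parental ancestry haplotypes.
#' @param chrom chromosome model (supplies genetic length).
#' @param mode "complete" or "poisson".
#' @param cM_to_bp optional map from genetic-length fraction to bp.
#' @return an ancestry haplotype (the gamete).
#' @export
meiosis_gamete <- function(h1, h2, chrom, mode = c("complete", "poisson"),
                           cM_to_bp = NULL) {
  mode <- match.arg(mode)
  n_co <- if (mode == "complete") (stats::runif(1) < 0.5) else
    stats::rpois(1, chrom$length_cM / 100)
  if (stats::runif(1) < 0.5) { tmp <- h1; h1 <- h2; h2 <- tmp }
  if (n_co == 0) return(h1)
  u <- sort(stats::runif(n_co))
  xs <- if (is.null(cM_to_bp)) u * h1$L else cM_to_bp(u)
  splice_many(h1, h2, xs)
}

#' Simulate meiosis for one chromosome of a parent individual
#'
#' Autosomes recombine in both sexes. The X recombines only in females;
#' an X0 male transmits his single X intact to half his gametes and a
#' nullosome (no X, returned as NULL) to the other half.
#'
#' @param parent a `sim_individual`.
#' @param chrom chromosome model.
#' @param mode interference mode, see [meiosis_gamete()].
#' @param force_x for male X meiosis: "none" (fair coin), "X" (condition on
#'   an X-bearing gamete) or "nullo".
#' @inheritParams meiosis_gamete
#' @return an ancestry haplotype, or NULL for a nullosomic gamete.
#' @export
simulate_meiosis <- function(parent, chrom, mode = c("complete", "poisson"),
                             cM_to_bp = NULL, force_x = c("none", "X", "nullo")) {
  mode <- match.arg(mode)
  force_x <- match.arg(force_x)
  if (chrom$kind == "X" && parent$sex == "M") {
    carry <- switch(force_x, none = stats::runif(1) < 0.5, X = TRUE, nullo = FALSE)
    return(if (carry) parent$X[[1]] else NULL)
  }
  haps <- if (chrom$kind == "X") parent$X else parent$auto[[chrom$name]]
  meiosis_gamete(haps[[1]], haps[[2]], chrom, mode, cM_to_bp)
}

#' Advanced-intercross cross design
#'
#' The pedigree plan behind the G4BC2 mapping panel: a founder cross
#' A female x B male makes the F1; `intercross` further generations of
#' random mating within a pool produce G_{1+intercross}; then `backcross`
#' generations to the recurrent founder (A) produce the mapping lines.
#'
#' `pool_size = Inf` (the default) draws every individual's parents as
#' independent fresh members of the previous generation — the random-mating
#' limit, under which the expected crossover counts on the counted
#' haplotype are exactly 1.25 (autosome) and 0.75 (X) for the default
#' design. Finite pools are simulated explicitly by
#' [simulate_pool_pedigree()].
#'
#' `bc1_transmit_sex` fixes the sex of the non-recurrent parent entering
#' the first backcross; "male" (default) means a G4 male is crossed to a
#' recurrent-founder female, so his X enters the backcross intact.
#'
#' `count_on` selects the haplotype whose founder-label switch points are
#' counted: "bc1_haplotype" (default) is the non-recurrent haplotype
#' transmitted into the first backcross — pooled sequencing of the final
#' backcross brood recovers exactly this mosaic, so later backcross
#' meioses add nothing — while "final_gamete" follows the haplotype through
#' every backcross meiosis.
#'
#' @param intercross intercross generations after the F1 (>= 0).
#' @param backcross backcross generations (>= 0).
#' @param interference "complete" or "poisson".
#' @param pool_size per-generation pool size; Inf for the random-mating limit.
#' @param bc1_transmit_sex "male", "female" or "random".
#' @param count_on "bc1_haplotype" or "final_gamete".
#' @return a `cross_design` object.
#' @export
cross_design <- function(intercross = 3, backcross = 2,
                         interference = c("complete", "poisson"),
                         pool_size = Inf,
                         bc1_transmit_sex = c("male", "female", "random"),
                         count_on = c("bc1_haplotype", "final_gamete")) {
  interference <- match.arg(interference)
  bc1_transmit_sex <- match.arg(bc1_transmit_sex)
  count_on <- match.arg(count_on)
  stopifnot(intercross >= 0, backcross >= 0, pool_size >= 1)
  structure(list(intercross = as.integer(intercross),
                 backcross = as.integer(backcross),
                 interference = interference, pool_size = pool_size,
                 bc1_transmit_sex = bc1_transmit_sex, count_on = count_on),
            class = "cross_design")
}

## ---- random-mating (infinite pool) lineage sampling -----------------------
##
## Only the direct gametic ancestry of the counted haplotype is simulated;
## every ancestor is an independent fresh draw from its generation, which is
## the pool_size = Inf limit of the explicit pool pedigree.
##
## ctx carries everything the hot loop needs: complete (logical), rate
## (Poisson crossover rate), and pre-built pure founder haplotypes. The
## validating constructors and match.arg stay out of the per-line path.

## Lean meiosis used by the lineage sampler (uniform crossover placement).
meiosis_fast <- function(h1, h2, ctx) {
  u <- stats::runif(2L)
  n_co <- if (ctx$complete) (u[1L] < 0.5) else stats::rpois(1L, ctx$rate)
  if (u[2L] < 0.5) { tmp <- h1; h1 <- h2; h2 <- tmp }
  if (n_co == 0) return(h1)
  if (n_co == 1) return(splice1(h1, h2, stats::runif(1L) * h1$L))
  splice_many(h1, h2, sort(stats::runif(n_co)) * h1$L)
}

## Autosome gamete of a generation-g intercross individual (g = 1 is F1).
auto_gamete <- function(g, ctx) {
  if (g == 1L) return(meiosis_fast(ctx$pureA, ctx$pureB, ctx))
  meiosis_fast(auto_gamete(g - 1L, ctx), auto_gamete(g - 1L, ctx), ctx)
}

## X gamete of a generation-g female, whose X pair is her mother's
## recombinant X gamete plus her father's intact X.
female_x_gamete <- function(g, ctx) {
  if (g == 1L) return(meiosis_fast(ctx$pureA, ctx$pureB, ctx))
  meiosis_fast(female_x_gamete(g - 1L, ctx), male_x(g - 1L, ctx), ctx)
}

## A male's single X is his mother's recombinant X gamete; the F1 male's X
## is the A founder's (the founder cross is A female x B male).
male_x <- function(g, ctx) {
  if (g == 1L) return(ctx$pureA)
  female_x_gamete(g - 1L, ctx)
}

lineage_ctx <- function(design, chrom) {
  L <- chrom$length_bp
  list(complete = design$interference == "complete",
       rate = chrom$length_cM / 100,
       pureA = list(first = 1L, br = numeric(0), L = L),
       pureB = list(first = 2L, br = numeric(0), L = L))
}

## The counted recombinant haplotype for one line and one chromosome.
sim_counted_hap <- function(design, chrom, ctx = lineage_ctx(design, chrom)) {
  G <- 1L + design$intercross
  sex <- design$bc1_transmit_sex
  if (sex == "random") sex <- if (stats::runif(1) < 0.5) "male" else "female"
  h <- if (chrom$kind == "X") {
    if (sex == "male") male_x(G, ctx) else female_x_gamete(G, ctx)
  } else {
    auto_gamete(G, ctx)
  }
  if (design$backcross >= 2L && design$count_on == "final_gamete") {
    for (b in seq_len(design$backcross - 1L))
      h <- meiosis_fast(h, ctx$pureA, ctx)
  }
  h
}

#' Simulate the G4BC2 advanced-intercross design and count crossovers
#'
#' Runs `n_lines` independent lineages through the configured pedigree and
#' counts founder-label switch points on the counted recombinant haplotype
#' of each chromosome (see [cross_design()] for the counting convention).
#'
#' @param design a [cross_design()].
#' @param chromosomes list of [chromosome_model()]s.
#' @param n_lines number of independent lineages (>= 1).
#' @param seed integer seed; the run is reproducible given the seed.
#' @param keep_haplotypes if TRUE, the per-line mosaics are returned too.
#' @return a `crossover_count_summary`: per chromosome, the per-line counts,
#'   their mean, and the count distribution.
#' @export
simulate_g4bc2 <- function(design, chromosomes, n_lines, seed = 1L,
                           keep_haplotypes = FALSE) {
  stopifnot(n_lines >= 1, length(chromosomes) >= 1)
  if (is.null(names(chromosomes)))
    names(chromosomes) <- vapply(chromosomes, `[[`, "", "name")
  set.seed(seed)
  ctxs <- lapply(chromosomes, function(cc) lineage_ctx(design, cc))
  counts <- matrix(0L, nrow = n_lines, ncol = length(chromosomes),
                   dimnames = list(NULL, names(chromosomes)))
  haps <- if (keep_haplotypes) vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    hs <- lapply(seq_along(chromosomes), function(j)
      sim_counted_hap(design, chromosomes[[j]], ctxs[[j]]))
    names(hs) <- names(chromosomes)
    counts[i, ] <- vapply(hs, function(h) length(h$br), 0L)
    if (keep_haplotypes) haps[[i]] <- hs
  }
  per_chrom <- lapply(seq_along(chromosomes), function(j) {
    k <- counts[, j]
    list(chrom = names(chromosomes)[j], counts = k, mean = mean(k),
         distribution = table(k), n = n_lines)
  })
  names(per_chrom) <- names(chromosomes)
  structure(list(per_chrom = per_chrom, design = design, seed = seed,
                 n_lines = n_lines, haplotypes = haps),
            class = "crossover_count_summary")
}

#' @export
print.crossover_count_summary <- function(x, ...) {
  cat(sprintf("G4BC2 crossover-count summary (%d lines, seed %d)\n",
              x$n_lines, x$seed))
  for (pc in x$per_chrom)
    cat(sprintf("  %-4s mean %.4f crossovers per transmitted chromosome\n",
                pc$chrom, pc$mean))
  invisible(x)
}

#' Monte-Carlo test of observed crossover counts against the simulated null
#'
#' Simulates the null distribution of the total crossover count over
#' `length(observed)` lines and returns the two-sided Monte-Carlo p-value,
#' `min(1, 2 * min(tails))` with the (k+1)/(n+1) tail estimator.
#'
#' @param observed integer vector of per-line crossover counts for one
#'   chromosome.
#' @param design a [cross_design()].
#' @param chrom the chromosome model.
#' @param n_sims number of null replicates (>= 1000 recommended).
#' @param seed integer seed.
#' @return list with the p-value, observed total/mean, and null mean.
#' @export
crossover_count_test <- function(observed, design, chrom, n_sims = 2000, seed = 1L) {
  if (length(observed) == 0) stop("'observed' must be non-empty")
  N <- length(observed)
  set.seed(seed)
  ctx <- lineage_ctx(design, chrom)
  null_tot <- vapply(seq_len(n_sims), function(s)
    sum(vapply(seq_len(N), function(i)
      length(sim_counted_hap(design, chrom, ctx)$br), 0L)),
    0)
  obs <- sum(observed)
  p_lo <- (sum(null_tot <= obs) + 1) / (n_sims + 1)
  p_hi <- (sum(null_tot >= obs) + 1) / (n_sims + 1)
  list(p_value = min(1, 2 * min(p_lo, p_hi)),
       observed_total = obs, observed_mean = obs / N,
       null_mean = mean(null_tot) / N, n_sims = n_sims)
}

#' Monte-Carlo test of the X : autosome crossover ratio
#'
#' Tests whether the observed ratio of mean X to mean autosome crossovers
#' exceeds what the null pedigree simulation produces — the framing used to
#' ask whether crossover interference on the X is complete. One-sided
#' toward excess X. Null replicates with zero autosome crossovers get an
#' infinite ratio (they count as at least as extreme).
#'
#' @param observed_x,observed_auto per-line crossover counts.
#' @param design a [cross_design()].
#' @param chrom_x,chrom_auto chromosome models for the two classes.
#' @param n_sims number of null replicates.
#' @param seed integer seed.
#' @return list with the p-value and the observed and null-mean ratios.
#' @export
xa_ratio_test <- function(observed_x, observed_auto, design, chrom_x, chrom_auto,
                          n_sims = 2000, seed = 1L) {
  stopifnot(length(observed_x) > 0, length(observed_auto) > 0)
  nx <- length(observed_x); na <- length(observed_auto)
  obs_ratio <- mean(observed_x) / mean(observed_auto)
  set.seed(seed)
  ctx_x <- lineage_ctx(design, chrom_x)
  ctx_a <- lineage_ctx(design, chrom_auto)
  null_ratio <- vapply(seq_len(n_sims), function(s) {
    mx <- mean(vapply(seq_len(nx), function(i)
      length(sim_counted_hap(design, chrom_x, ctx_x)$br), 0L))
    ma <- mean(vapply(seq_len(na), function(i)
      length(sim_counted_hap(design, chrom_auto, ctx_a)$br), 0L))
    if (ma == 0) Inf else mx / ma
  }, 0)
  p <- (sum(null_ratio >= obs_ratio) + 1) / (n_sims + 1)
  list(p_value = p, observed_ratio = obs_ratio,
       null_mean_ratio = mean(null_ratio[is.finite(null_ratio)]),
       n_sims = n_sims)
}
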