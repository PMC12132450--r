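#' Construct a founder individual
#'
#' @param label founder label, "A" or "B" (A is the recurrent, susceptible
#'   reference strain of the cross).
#' @param sex "F" (XX) or "M" (X0).
#' @param chromosomes list of [chromosome_model()]s.
#' @return a `sim_individual`.
#' @export
founder_individual <- function(label = c("A", "B"), sex = c("F", "M"), chromosomes) {
  label <- match.arg(label); sex <- match.arg(sex)
  lab <- if (label == "A") 1L else 2L
  if (is.null(names(chromosomes)))
    names(chromosomes) <- vapply(chromosomes, `[[`, "", "name")
  autos <- chromosomes[vapply(chromosomes, function(c) c$kind == "autosome", TRUE)]
  xs <- chromosomes[vapply(chromosomes, function(c) c$kind == "X", TRUE)]
  auto <- lapply(autos, function(cc) list(hap_pure(lab, cc$length_bp),
                                          hap_pure(lab, cc$length_bp)))
  X <- if (length(xs)) {
    cc <- xs[[1]]
    if (sex == "F") list(hap_pure(lab, cc$length_bp), hap_pure(lab, cc$length_bp))
    else list(hap_pure(lab, cc$length_bp))
  }
  structure(list(sex = sex, auto = auto, X = X, mito = label,
                 chromosomes = chromosomes),
            class = "sim_individual")
}

#' Cross two individuals
#'
#' Produces one offspring. Sex is decided by the sperm: X-bearing sperm
#' make XX daughters, nullosomic sperm make X0 sons (1:1 on average).
#' The mitochondrion is always maternal. `sex` conditions on an offspring
#' sex instead of leaving it to the sperm draw.
#'
#' @param mother,father `sim_individual`s.
#' @param mode interference mode.
#' @param sex NULL, "F" or "M".
#' @return a `sim_individual`.
#' @export
cross_individuals <- function(mother, father, mode = "complete", sex = NULL) {
  stopifnot(mother$sex == "F", father$sex == "M")
  chroms <- mother$chromosomes
  autos <- chroms[vapply(chroms, function(c) c$kind == "autosome", TRUE)]
  xs <- chroms[vapply(chroms, function(c) c$kind == "X", TRUE)]
  auto <- lapply(autos, function(cc)
    list(simulate_meiosis(mother, cc, mode), simulate_meiosis(father, cc, mode)))
  X <- NULL; osex <- sex
  if (length(xs)) {
    cc <- xs[[1]]
    mat_x <- simulate_meiosis(mother, cc, mode)
    pat_x <- if (is.null(sex)) simulate_meiosis(father, cc, mode)
             else simulate_meiosis(father, cc, mode,
                                   force_x = if (sex == "F") "X" else "nullo")
    if (is.null(osex)) osex <- if (is.null(pat_x)) "M" else "F"
    X <- if (is.null(pat_x)) list(mat_x) else list(mat_x, pat_x)
  } else if (is.null(osex)) {
    osex <- if (stats::runif(1) < 0.5) "F" else "M"
  }
  structure(list(sex = osex, auto = auto, X = X, mito = mother$mito,
                 chromosomes = chroms),
            class = "sim_individual")
}

#' Simulate an explicit finite-pool G4BC2 pedigree
#'
#' The fully explicit version of the design: an F1 pool from the founder
#' cross (A females x B males), `design$intercross` generations of random
#' pair mating within a pool of `pool_size` individuals, then
#' `design$backcross` backcrosses to fresh recurrent-founder (A) mates,
#' the first through a transmitting parent of sex
#' `design$bc1_transmit_sex`. Used for property tests and for finite-pool
#' variants of the design; [simulate_g4bc2()] is the fast random-mating
#' limit.
#'
#' @param design a [cross_design()] with finite `pool_size`.
#' @param chromosomes list of [chromosome_model()]s.
#' @param seed integer seed.
#' @return list with the final individual (`final`), the transmitting
#'   parent of the first backcross (`bc1_parent`), and the intercross
#'   pools (`pools`, one list of individuals per generation).
#' @export
simulate_pool_pedigree <- function(design, chromosomes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.finite(design$pool_size)) design$pool_size else 50
  mode <- design$interference
  if (is.null(names(chromosomes)))
    names(chromosomes) <- vapply(chromosomes, `[[`, "", "name")
  momA <- founder_individual("A", "F", chromosomes)
  dadB <- founder_individual("B", "M", chromosomes)
  pool <- lapply(seq_len(2 * n), function(i)
    cross_individuals(momA, dadB, mode, sex = if (i <= n) "F" else "M"))
  pools <- list(pool)
  for (g in seq_len(design$intercross)) {
    fem <- pool[vapply(pool, `[[`, "", "sex") == "F"]
    mal <- pool[vapply(pool, `[[`, "", "sex") == "M"]
    pool <- lapply(seq_len(2 * n), function(i)
      cross_individuals(fem[[sample.int(length(fem), 1)]],
                        mal[[sample.int(length(mal), 1)]], mode,
                        sex = if (i <= n) "F" else "M"))
    pools <- c(pools, list(pool))
  }
  tsex <- switch(design$bc1_transmit_sex,
                 male = "M", female = "F",
                 random = if (stats::runif(1) < 0.5) "M" else "F")
  same_sex <- pool[vapply(pool, `[[`, "", "sex") == tsex]
  bc1_parent <- same_sex[[sample.int(length(same_sex), 1)]]
  ind <- bc1_parent
  for (b in seq_len(design$backcross)) {
    if (ind$sex == "M")
      ind <- cross_individuals(founder_individual("A", "F", chromosomes), ind,
                               mode, sex = "F")
    else
      ind <- cross_individuals(ind, founder_individual("A", "M", chromosomes),
                               mode, sex = "F")
  }
  list(final = ind, bc1_parent = bc1_parent, pools = pools)
}

## Validate the tiling invariant of a haplotype: segments tile [0, L) with
## alternating labels (internal representation guarantees alternation; this
## checks junction ordering and bounds).
hap_is_valid <- function(h) {
  if (is.null(h)) return(TRUE)
  br <- h$br
  length(br) == 0 ||
    (all(diff(br) > 0) && br[1] > 0 && br[length(br)] < h$L)
}
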