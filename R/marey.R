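#' Marey map
#'
#' Genetic position (cM) as a function of physical position (bp) for the
#' markers of one chromosome. The slope of the map is the local
#' recombination rate, and Caenorhabditis maps show the characteristic
#' tip / arm / center domain structure: near-zero recombination at the
#' tips, high rates on the arms, strong crossover suppression in the
#' center.
#'
#' @param chrom chromosome name.
#' @param bp marker physical positions (bp, >= 0).
#' @param cM marker genetic positions (cM, >= 0, non-decreasing in bp).
#' @param length_bp chromosome physical length; defaults to max(bp).
#' @param normalize if TRUE, rescale genetic length to `normalize_to` cM
#'   before any fitting (the single-obligate-crossover convention).
#' @param normalize_to target genetic length in cM.
#' @return a `marey_map` object.
#' @export
marey_map <- function(chrom, bp, cM, length_bp = max(bp),
                      normalize = FALSE, normalize_to = 50) {
  ord <- order(bp)
  bp <- as.numeric(bp[ord]); cM <- as.numeric(cM[ord])
  stopifnot(length(bp) == length(cM), all(bp >= 0), all(cM >= 0),
            length_bp >= max(bp))
  if (any(diff(cM) < 0))
    stop("genetic positions must be non-decreasing in physical position")
  normalized <- FALSE
  if (normalize) {
    span <- max(cM) - min(cM)
    if (span > 0) cM <- (cM - min(cM)) * normalize_to / span
    normalized <- TRUE
  }
  structure(list(chrom = as.character(chrom), bp = bp, cM = cM,
                 length_bp = as.numeric(length_bp), normalized = normalized),
            class = "marey_map")
}

#' Interpolate a Marey map on an even physical grid
#'
#' Linear interpolation of genetic position at `n_points` evenly spaced
#' physical positions spanning `[0, length_bp]`; positions outside the
#' marker span are clamped to the terminal marker's genetic position.
#'
#' @param m a [marey_map()].
#' @param n_points number of grid points (200 by default).
#' @return list with numeric vectors `bp` and `cM`.
#' @export
interpolate_map <- function(m, n_points = 200) {
  if (length(m$bp) < 2) stop("at least 2 markers are required")
  x <- seq(0, m$length_bp, length.out = n_points)
  y <- stats::approx(m$bp, m$cM, xout = x, rule = 2, ties = "ordered")$y
  list(bp = x, cM = y)
}

#' Continuous three-segment least-squares fit of a Marey map
#'
#' Fits genetic position on physical position with the constraint that
#' there be three joined linear segments (two breakpoints: LC, the left
#' arm/center boundary, and CR, the center/right boundary), after
#' excluding `end_exclusion` bp from each chromosome end (tip regions have
#' suppressed recombination and poorly resolved boundaries). The fit is a
#' globally optimal exhaustive search: every ordered pair of interior grid
#' points is a candidate breakpoint pair, and at fixed breakpoints the
#' segment fit is a linear least-squares problem in the hinge basis
#' \{1, x, (x-LC)+, (x-CR)+\}, which enforces continuity by construction.
#' Ties in residual sum of squares are broken toward the smallest LC, then
#' the largest CR, so degenerate (e.g. straight-line) inputs are
#' deterministic.
#'
#' @param bp,cM interpolated map coordinates (e.g. from [interpolate_map()]).
#' @param end_exclusion bp excluded from each end before fitting.
#' @return a `segmented_fit`: breakpoints `LC`, `CR` (bp), `slopes` (three
#'   values, cM per bp), `intercept`, `rss`, the fitted grid, and a
#'   `degenerate` flag for all-equal input.
#' @export
fit_segmented <- function(bp, cM, end_exclusion = 1e6) {
  keep <- bp >= min(bp) + end_exclusion & bp <= max(bp) - end_exclusion
  x <- bp[keep]; y <- cM[keep]
  n <- length(x)
  if (n < 10) stop("fewer than 10 usable points after end exclusion")
  if (max(y) - min(y) == 0) {
    return(structure(list(LC = x[2], CR = x[n - 1],
                          slopes = c(0, 0, 0), intercept = y[1], rss = 0,
                          x = x, y = y, fitted = y, degenerate = TRUE,
                          end_exclusion = end_exclusion, n_points = n),
                     class = "segmented_fit"))
  }
  ## candidate breakpoints: interior grid points, at least 2 points per segment
  cand <- x[3:(n - 2)]
  hinges <- outer(x, cand, function(xx, b) pmax(xx - b, 0))
  best <- list(rss = Inf, i = NA, j = NA, coef = NULL, b1 = Inf, b2 = -Inf)
  tol <- 1e-9 * sum((y - mean(y))^2) + 1e-12
  nc <- length(cand)
  for (i in seq_len(nc - 1)) {
    Xi <- cbind(1, x, hinges[, i])
    for (j in (i + 1):nc) {
      f <- stats::.lm.fit(cbind(Xi, hinges[, j]), y)
      rss <- sum(f$residuals^2)
      better <- rss < best$rss - tol ||
        (rss < best$rss + tol &&
           (cand[i] < best$b1 - 1e-9 ||
              (cand[i] <= best$b1 + 1e-9 && cand[j] > best$b2 + 1e-9)))
      if (better) {
        best <- list(rss = rss, i = i, j = j, coef = f$coefficients,
                     b1 = cand[i], b2 = cand[j])
      }
    }
  }
  b1 <- best$b1; b2 <- best$b2; cf <- best$coef
  slopes <- c(cf[2], cf[2] + cf[3], cf[2] + cf[3] + cf[4])
  fitted <- cf[1] + cf[2] * x + cf[3] * pmax(x - b1, 0) + cf[4] * pmax(x - b2, 0)
  structure(list(LC = b1, CR = b2, slopes = unname(slopes),
                 intercept = unname(cf[1]), rss = best$rss,
                 x = x, y = y, fitted = fitted, degenerate = FALSE,
                 end_exclusion = end_exclusion, n_points = n),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("3-segment fit: LC = %.3g bp, CR = %.3g bp, rss = %.4g\n",
              x$LC, x$CR, x$rss))
  cat(sprintf("  slopes (cM/Mb): %.3f | %.3f | %.3f%s\n",
              x$slopes[1] * 1e6, x$slopes[2] * 1e6, x$slopes[3] * 1e6,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Recombination-domain summary of a fitted Marey map
#'
#' Reports per-domain recombination rates (cM/Mb) and the fraction of the
#' chromosome in each domain. When `normalize_to` is non-NULL the genetic
#' map is rescaled so the chromosome totals that many cM (50 by default,
#' the complete-interference assumption) before rates are reported. Rates
#' are clamped at zero from below: least squares on a monotone map can
#' return slopes that are negative within numerical noise.
#'
#' @param fit a [fit_segmented()] result.
#' @param m the [marey_map()] the fit came from.
#' @param normalize_to genetic length (cM) to rescale to, or NULL for raw.
#' @return a `domain_summary`: one-row data.frame with boundaries, domain
#'   rates, percent of chromosome length in left arm+tip / center / right
#'   arm+tip, and a `domain_structure` flag that is FALSE when the fit is
#'   degenerate or the center is not the low-recombination domain.
#' @export
domain_summary <- function(fit, m, normalize_to = 50) {
  span <- max(m$cM) - min(m$cM)
  scale <- if (!is.null(normalize_to) && !m$normalized && span > 0)
    normalize_to / span else 1
  rates <- pmax(fit$slopes, 0) * scale * 1e6
  L <- m$length_bp
  left_pct <- fit$LC / L * 100
  center_pct <- (fit$CR - fit$LC) / L * 100
  right_pct <- (L - fit$CR) / L * 100
  structure(data.frame(
    chrom = m$chrom, length_bp = L, LC = fit$LC, CR = fit$CR,
    rate_left = rates[1], rate_center = rates[2], rate_right = rates[3],
    pct_left = left_pct, pct_center = center_pct, pct_right = right_pct,
    domain_structure = !fit$degenerate &&
      fit$slopes[2] <= min(fit$slopes[1], fit$slopes[3]),
    stringsAsFactors = FALSE), class = c("domain_summary", "data.frame"))
}

#' Per-chromosome domain report for one or more species
#'
#' Runs the full Marey pipeline (normalize to 50 cM, interpolate on a
#' 200-point grid, exclude 1 Mb ends, three-segment fit, domain summary)
#' for every chromosome of every species in a marker table, mirroring the
#' per-species domain tables of comparative map studies. Chromosomes whose
#' fit fails or lacks the low-center domain structure are flagged, not
#' dropped.
#'
#' @param tables named list of marker tables (see [read_marker_table()]),
#'   one per species.
#' @param n_points interpolation grid size.
#' @param end_exclusion bp excluded from each end.
#' @param normalize_to genetic length to rescale to (NULL for raw).
#' @return data.frame with one row per species x chromosome; also carries
#'   the normalized Marey coordinates as attribute "marey" for plotting.
#' @export
species_map_report <- function(tables, n_points = 200, end_exclusion = 1e6,
                               normalize_to = 50) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)))
    names(tables) <- paste0("species", seq_along(tables))
  rows <- list(); marey <- list()
  for (sp in names(tables)) {
    tab <- tables[[sp]]
    for (chr in unique(tab$chrom)) {
      sub <- tab[tab$chrom == chr, ]
      len <- attr(tab, "lengths")[[chr]]
      if (is.null(len)) len <- max(sub$bp)
      m <- marey_map(chr, sub$bp, sub$cM, length_bp = len,
                     normalize = !is.null(normalize_to),
                     normalize_to = if (is.null(normalize_to)) 50 else normalize_to)
      row <- tryCatch({
        ip <- interpolate_map(m, n_points)
        fit <- fit_segmented(ip$bp, ip$cM, end_exclusion)
        domain_summary(fit, m, normalize_to = NULL)
      }, error = function(e) {
        data.frame(chrom = chr, length_bp = len, LC = NA, CR = NA,
                   rate_left = NA, rate_center = NA, rate_right = NA,
                   pct_left = NA, pct_center = NA, pct_right = NA,
                   domain_structure = FALSE, stringsAsFactors = FALSE)
      })
      row <- cbind(species = sp, row, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- row
      marey[[length(marey) + 1L]] <-
        data.frame(species = sp, chrom = chr,
                   bp_frac = m$bp / m$length_bp, cM = m$cM,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "marey") <- do.call(rbind, marey)
  out
}
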