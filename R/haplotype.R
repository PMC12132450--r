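#' Chromosome model
#'
#' Describes one chromosome of the cross: its physical length, its genetic
#' length (50 cM by default, the single-obligate-crossover assumption used
#' throughout Caenorhabditis map work), and whether it is an autosome or the
#' X. X chromosomes do not recombine in males (males are X0 and hemizygous).
#'
#' @param name chromosome name, e.g. "I" or "X".
#' @param length_bp physical length in bp (> 0).
#' @param length_cM genetic length in cM (> 0); 50 under complete
#'   crossover interference.
#' @param kind "autosome" or "X".
#' @return A `chromosome_model` object.
#' @export
chromosome_model <- function(name, length_bp, length_cM = 50, kind = c("autosome", "X")) {
  kind <- match.arg(kind)
  stopifnot(length_bp > 0, length_cM > 0)
  structure(list(name = as.character(name), length_bp = as.numeric(length_bp),
                 length_cM = as.numeric(length_cM), kind = kind),
            class = "chromosome_model")
}

#' Ancestry haplotype
#'
#' An ordered mosaic of founder-labelled segments tiling `[0, L)`. Stored
#' compactly as the label of the first segment plus the vector of internal
#' junction positions; labels alternate between the two founders (1 = "A",
#' 2 = "B"), so adjacent segments always differ after construction.
#'
#' @param first integer founder label (1 or 2) of the leftmost segment.
#' @param br strictly increasing junction positions in bp, all in (0, L).
#' @param L chromosome physical length in bp.
#' @return An `ancestry_haplotype` object.
#' @export
ancestry_haplotype <- function(first, br = numeric(0), L) {
  stopifnot(first %in% c(1L, 2L), L > 0)
  if (length(br)) stopifnot(all(diff(br) > 0), br[1] > 0, br[length(br)] < L)
  structure(list(first = as.integer(first), br = as.numeric(br), L = as.numeric(L)),
            class = "ancestry_haplotype")
}

hap_pure <- function(label, L) ancestry_haplotype(label, numeric(0), L)

#' @export
print.ancestry_haplotype <- function(x, ...) {
  cat(sprintf("ancestry_haplotype: %d segment(s) over [0, %g)\n",
              length(x$br) + 1L, x$L))
  print(hap_segments(x))
  invisible(x)
}

#' Founder label at a physical position
#' @param h ancestry haplotype.
#' @param x position in bp (0-based).
#' @return integer label (1 or 2).
#' @export
hap_label_at <- function(h, x) {
  k <- sum(h$br <= x)
  if (k %% 2 == 0) h$first else 3L - h$first
}

#' Segments of an ancestry haplotype
#' @param h ancestry haplotype.
#' @return data.frame with columns founder ("A"/"B"), start, end (bp,
#'   0-based half-open).
#' @export
hap_segments <- function(h) {
  bounds <- c(0, h$br, h$L)
  n <- length(bounds) - 1L
  labs <- rep_len(c(h$first, 3L - h$first), n)
  data.frame(founder = c("A", "B")[labs],
             start = bounds[-length(bounds)], end = bounds[-1])
}

#' Count crossovers on an ancestry haplotype
#'
#' Crossovers are the founder-label switch points of the mosaic; adjacent
#' segments always carry different labels, so this is simply the number of
#' internal junctions.
#'
#' @param h ancestry haplotype.
#' @return integer count.
#' @export
count_crossovers <- function(h) {
  if (is.null(h)) return(NA_integer_)
  length(h$br)
}

## Splice h1[0, x) + h2[x, L), dropping the junction at x when the two
## parental labels agree there.  Keeps the alternating-label normal form.
splice1 <- function(h1, h2, x) {
  brL <- h1$br[h1$br < x]
  labL <- if (length(brL) %% 2 == 0) h1$first else 3L - h1$first
  kR <- sum(h2$br <= x)
  labR <- if (kR %% 2 == 0) h2$first else 3L - h2$first
  brR <- h2$br[h2$br > x]
  br <- if (labL == labR) c(brL, brR) else c(brL, x, brR)
  list(first = h1$first, br = br, L = h1$L)
}

## Multi-crossover splice: alternate strands at each sorted position.
splice_many <- function(h1, h2, xs) {
  g <- h1
  other <- list(h2, h1)
  for (i in seq_along(xs)) g <- splice1(g, other[[(i - 1L) %% 2L + 1L]], xs[i])
  g
}
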