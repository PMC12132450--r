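#' GC content in non-overlapping windows
#'
#' Tiles each sequence with non-overlapping windows from position 0,
#' dropping the trailing partial window (equal-length windows keep
#' variance comparisons across scales honest). N bases are excluded from
#' both numerator and denominator; windows with no unambiguous base get
#' GC = NA.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or a `sequence_set`).
#' @param window window size in bp (>= 1).
#' @return data.frame with seqid, start, end (0-based half-open), gc
#'   (percent) and unambiguous base count.
#' @export
window_gc <- function(seqs, window) {
  stopifnot(window >= 1)
  seqs <- as_dnastringset(seqs)
  out <- list()
  for (i in seq_along(seqs)) {
    L <- Biostrings::width(seqs)[i]
    nwin <- L %/% window
    if (nwin == 0) {
      warning(sprintf("sequence '%s' shorter than one window; no windows",
                      names(seqs)[i]))
      next
    }
    v <- IRanges::successiveViews(seqs[[i]], rep(window, nwin))
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    unamb <- rowSums(f)
    gc <- ifelse(unamb > 0, (f[, "C"] + f[, "G"]) / unamb * 100, NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      seqid = names(seqs)[i],
      start = (seq_len(nwin) - 1) * window, end = seq_len(nwin) * window,
      gc = gc, unambiguous = unamb, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(seqid = character(), start = numeric(), end = numeric(),
                      gc = numeric(), unambiguous = numeric()))
  do.call(rbind, out)
}

#' Per-feature-class GC under nested masking
#'
#' Partitions every base of the genome into exon, repeat, intron and
#' intergenic classes by nested masking: exon bases are the union of exon
#' features; repeat bases are repeat features minus their exon overlap;
#' intron bases are gene spans minus exon and repeat bases; intergenic is
#' the remainder. The four classes are disjoint and together tile the
#' genome, so their base counts always sum to the genome length. GC is
#' computed per class over unambiguous bases only.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or `sequence_set`).
#' @param feats a `feature_set` (see [read_genome()]): data.frame with
#'   seqid, class ("gene", "exon", "CDS", "repeat"), start, end (0-based
#'   half-open), strand.
#' @return data.frame per class (exon, repeat, intron, intergenic, genome)
#'   with total bases, unambiguous bases, and GC percent.
#' @export
nested_feature_gc <- function(seqs, feats) {
  seqs <- as_dnastringset(seqs)
  seqlens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  gr <- function(cls) {
    f <- feats[feats$class == cls, , drop = FALSE]
    if (!nrow(f)) return(GenomicRanges::GRanges(seqlengths = seqlens))
    GenomicRanges::reduce(GenomicRanges::GRanges(
      f$seqid, IRanges::IRanges(f$start + 1, f$end), seqlengths = seqlens))
  }
  genome <- GenomicRanges::GRanges(names(seqs), IRanges::IRanges(1, seqlens),
                                   seqlengths = seqlens)
  exon <- gr("exon")
  rep_ <- GenomicRanges::setdiff(gr("repeat"), exon)
  gene <- gr("gene")
  intron <- GenomicRanges::setdiff(GenomicRanges::setdiff(gene, exon), rep_)
  intergenic <- GenomicRanges::setdiff(
    genome, GenomicRanges::union(GenomicRanges::union(exon, rep_), intron))
  class_gc <- function(g) {
    if (!length(g)) return(c(bases = 0, unambiguous = 0, gc = NA_real_))
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    for (sq in unique(as.character(GenomicRanges::seqnames(g)))) {
      r <- IRanges::ranges(g[GenomicRanges::seqnames(g) == sq])
      v <- Biostrings::Views(seqs[[sq]], r)
      counts <- counts + colSums(Biostrings::letterFrequency(v, c("A", "C", "G", "T")))
    }
    unamb <- sum(counts)
    c(bases = sum(IRanges::width(GenomicRanges::ranges(g))),
      unambiguous = unamb,
      gc = if (unamb > 0) (counts[["C"]] + counts[["G"]]) / unamb * 100 else NA_real_)
  }
  classes <- list(exon = exon, "repeat" = rep_, intron = intron,
                  intergenic = intergenic, genome = genome)
  res <- t(vapply(classes, class_gc, c(bases = 0, unambiguous = 0, gc = 0)))
  data.frame(class = rownames(res), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Variance of window GC across measurement scales
#'
#' Sample variance of per-window GC at each window size, the statistic
#' used to compare base-composition heterogeneity along chromosomes
#' between genomes independent of the scale of measurement.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or `sequence_set`).
#' @param scales window sizes in bp.
#' @return data.frame with scale, n windows, and GC variance (NA when
#'   fewer than 2 windows have unambiguous bases).
#' @export
gc_variance_profile <- function(seqs, scales) {
  rows <- lapply(scales, function(w) {
    gc <- window_gc(seqs, w)$gc
    gc <- gc[!is.na(gc)]
    data.frame(scale = w, n_windows = length(gc),
               gc_variance = if (length(gc) >= 2) stats::var(gc) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Count oriented telomeric repeat units at chromosome ends
#'
#' Counts maximal tandem runs of the telomeric unit at each sequence end,
#' in the biologically oriented sense: the G-rich unit (default "TTAGGC",
#' the nematode telomere) runs 5'->3' toward the right end, so the right
#' end is scanned for tandem copies of the unit and the left end for
#' tandem copies of its reverse complement.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or `sequence_set`).
#' @param unit telomeric repeat unit.
#' @return data.frame with seqid, left and right tandem unit counts.
#' @export
count_telomeric_repeats <- function(seqs, unit = "TTAGGC") {
  stopifnot(nchar(unit) >= 1)
  seqs <- as_dnastringset(seqs)
  runit <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  k <- nchar(unit)
  count_right <- function(s, u) {
    n <- nchar(s); cnt <- 0
    while ((cnt + 1) * k <= n &&
           substr(s, n - (cnt + 1) * k + 1, n - cnt * k) == u) cnt <- cnt + 1
    cnt
  }
  count_left <- function(s, u) {
    n <- nchar(s); cnt <- 0
    while ((cnt + 1) * k <= n &&
           substr(s, cnt * k + 1, (cnt + 1) * k) == u) cnt <- cnt + 1
    cnt
  }
  ch <- as.character(seqs)
  data.frame(seqid = names(seqs),
             left = vapply(ch, count_left, 0, u = runit),
             right = vapply(ch, count_right, 0, u = unit),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Codon table of the standard nuclear code, stop codons excluded.
standard_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

#' Relative synonymous codon usage
#'
#' RSCU for each sense codon: the observed codon count divided by the mean
#' count over its synonymous family (count x family size / family total).
#' 1 means the codon is used exactly as expected were all synonymous
#' codons used equally; single-codon families (Met, Trp) are therefore 1
#' whenever observed. Codons containing ambiguous bases are skipped; a
#' trailing partial codon is trimmed with a warning. Stop codons are
#' excluded.
#'
#' @param cds a [Biostrings::DNAStringSet] of coding-strand CDS (or a
#'   `sequence_set`).
#' @return data.frame per codon with amino acid (one-letter), count and
#'   rscu (NA for unobserved families), ordered by amino acid.
#' @export
rscu <- function(cds) {
  cds <- as_dnastringset(cds)
  if (!length(cds)) stop("empty CDS set")
  w <- Biostrings::width(cds)
  if (any(w %% 3 != 0)) {
    warning(sprintf("%d CDS length(s) not divisible by 3; trailing bases trimmed",
                    sum(w %% 3 != 0)))
    cds <- Biostrings::subseq(cds, 1, w - w %% 3)
  }
  counts <- colSums(Biostrings::trinucleotideFrequency(cds, step = 3))
  code <- standard_code()
  counts <- counts[names(code)]
  fam <- split(names(code), code)
  rows <- lapply(names(fam), function(aa) {
    cods <- fam[[aa]]
    tot <- sum(counts[cods])
    val <- if (tot > 0) counts[cods] * length(cods) / tot else NA_real_
    data.frame(aa = aa, codon = cods, count = as.vector(counts[cods]),
               rscu = as.vector(val), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$aa, out$codon), ]
}

#' Amino-acid usage and cross-species deviations
#'
#' Per-species amino-acid composition of the coding genome: codons are
#' mapped to amino acids and summed over all CDS, giving the percent of
#' residues per amino acid (stops excluded). Deviations are taken from the
#' unweighted across-species mean, so they sum to zero over species for
#' each amino acid. The codon GC column is the mean fraction of G/C bases
#' across the codons encoding each amino acid in the standard code — a
#' property of the code, identical for all species.
#'
#' @param cds_sets named list of CDS sets, one per species.
#' @return data.frame with species, amino acid, percent, deviation from
#'   the cross-species mean, and codon GC fraction.
#' @export
aa_usage <- function(cds_sets) {
  stopifnot(length(cds_sets) >= 1)
  if (is.null(names(cds_sets)))
    names(cds_sets) <- paste0("species", seq_along(cds_sets))
  code <- standard_code()
  aas <- sort(unique(code))
  codon_gc <- vapply(aas, function(aa) {
    cods <- names(code)[code == aa]
    mean(vapply(strsplit(cods, ""), function(b) mean(b %in% c("G", "C")), 0))
  }, 0)
  pct <- lapply(names(cds_sets), function(sp) {
    r <- rscu(cds_sets[[sp]])
    tot <- tapply(r$count, r$aa, sum)[aas]
    n <- sum(tot)
    if (n == 0) {
      warning(sprintf("species '%s' has no residues; excluded", sp))
      return(NULL)
    }
    stats::setNames(as.vector(tot) / n * 100, aas)
  })
  names(pct) <- names(cds_sets)
  pct <- pct[!vapply(pct, is.null, TRUE)]
  mat <- do.call(rbind, pct)
  mu <- colMeans(mat)
  out <- do.call(rbind, lapply(rownames(mat), function(sp)
    data.frame(species = sp, aa = aas, percent = mat[sp, ],
               deviation = mat[sp, ] - mu, codon_gc = codon_gc,
               row.names = NULL, stringsAsFactors = FALSE)))
  out
}
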