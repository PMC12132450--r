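## Internal coordinate convention: 0-based half-open everywhere. GFF3
## (1-based inclusive) and BED (0-based half-open) are converted at the I/O
## boundary and nowhere else.

as_dnastringset <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  if (is.list(x) && !is.null(x$seqs)) return(x$seqs)
  stop("cannot interpret input as a DNA sequence set")
}

#' Read a genetic-map marker table
#'
#' Reads a TSV/CSV of markers (chromosome, physical bp, genetic cM).
#' Published maps use heterogeneous headers, so the three columns are
#' named explicitly through `columns` (or a YAML file with fields chrom,
#' bp, cM) rather than guessed. Rows are sorted by chromosome and
#' physical position; rows where the genetic position decreases are
#' reported in the `violations` attribute (chromosome and row) and the
#' table is rejected unless `repair = TRUE`, which drops them.
#'
#' @param path file path (tab- or comma-separated, with header).
#' @param columns named character vector or list mapping chrom/bp/cM to
#'   file column names, or the path of a YAML file with those fields.
#' @param lengths optional named vector of per-chromosome physical
#'   lengths (bp); defaults to the last marker position per chromosome.
#' @param repair drop non-monotone rows instead of failing.
#' @return a `marker_table`: data.frame with chrom, bp, cM, per-chromosome
#'   lengths in attribute "lengths", flagged rows in attribute
#'   "violations".
#' @export
read_marker_table <- function(path, columns = c(chrom = "chrom", bp = "bp", cM = "cM"),
                              lengths = NULL, repair = FALSE) {
  if (is.character(columns) && length(columns) == 1 && file.exists(columns))
    columns <- unlist(yaml::read_yaml(columns))
  columns <- unlist(columns)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(columns[c("chrom", "bp", "cM")]), names(raw))
  if (length(miss))
    stop(sprintf("marker table '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  d <- data.frame(chrom = as.character(raw[[columns[["chrom"]]]]),
                  bp = raw[[columns[["bp"]]]], cM = raw[[columns[["cM"]]]],
                  stringsAsFactors = FALSE)
  for (col in c("bp", "cM")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v) && !anyNA(d[[col]]))
      stop(sprintf("non-numeric %s value at row %d of '%s'",
                   col, which(is.na(v))[1], path))
    d[[col]] <- v
  }
  if (any(d$bp < 0) || any(d$cM < 0))
    stop("physical and genetic positions must be >= 0")
  d <- d[order(d$chrom, d$bp), ]
  rownames(d) <- NULL
  viol <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$chrom), function(idx) {
    bad <- idx[which(diff(d$cM[idx]) < 0) + 1L]
    if (length(bad)) data.frame(chrom = d$chrom[bad], row = bad)
  }))
  if (!is.null(viol) && nrow(viol)) {
    if (!repair)
      stop(sprintf("genetic position decreases at %d row(s) (chromosome %s); see attr 'violations' or use repair = TRUE",
                   nrow(viol), paste(unique(viol$chrom), collapse = ", ")))
    warning(sprintf("dropped %d row(s) with decreasing genetic position", nrow(viol)))
    d <- d[-viol$row, ]
    rownames(d) <- NULL
  }
  if (is.null(lengths))
    lengths <- tapply(d$bp, d$chrom, max)
  structure(d, lengths = as.list(lengths), violations = viol,
            class = c("marker_table", "data.frame"))
}

#' Write a marker table
#' @param tab a `marker_table` (or data.frame with chrom, bp, cM).
#' @param path output TSV path.
#' @export
write_marker_table <- function(tab, path) {
  utils::write.table(tab[, c("chrom", "bp", "cM")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

progeny_cols <- c("plate", "embryos", "unhatched", "deformed",
                  "adult_female", "adult_male", "L4_female", "L4_male",
                  "larvae", "mother", "father", "class_id")

#' Read a progeny-count table
#'
#' Reads the per-plate brood counts of the sixteen-cross panel: embryos
#' laid, then unhatched embryos, deformed arrested L1s, wild-type adults
#' and L4s by sex, and developmentally delayed L1-L3 larvae, plus parental
#' genotype labels and the cross class id (1-16). A derived `missing`
#' column records embryos never accounted for (embryos minus all observed
#' classes), floored at 0 with a warning when the categories overcount.
#'
#' @param path TSV path with the columns plate, embryos, unhatched,
#'   deformed, adult_female, adult_male, L4_female, L4_male, larvae,
#'   mother, father, class_id.
#' @return a `progeny_count_table` data.frame with the derived `missing`
#'   column.
#' @export
read_progeny_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(progeny_cols, names(d))
  if (length(miss))
    stop(sprintf("progeny table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  cnt <- c("embryos", "unhatched", "deformed", "adult_female", "adult_male",
           "L4_female", "L4_male", "larvae")
  for (col in cnt) {
    if (!is.numeric(d[[col]]) || any(d[[col]] < 0) || any(d[[col]] %% 1 != 0))
      stop(sprintf("column '%s' must contain non-negative integer counts", col))
  }
  if (!all(d$class_id %in% 1:16)) stop("class_id must be in 1..16")
  accounted <- rowSums(d[, cnt[-1]])
  if (any(accounted > d$embryos))
    warning(sprintf("%d row(s) overcount embryos; missing floored at 0",
                    sum(accounted > d$embryos)))
  d$missing <- pmax(d$embryos - accounted, 0)
  structure(d, class = c("progeny_count_table", "data.frame"))
}

#' Write a progeny-count table
#' @param tab a progeny-count data.frame.
#' @param path output TSV path.
#' @export
write_progeny_table <- function(tab, path) {
  utils::write.table(tab[, intersect(c(progeny_cols, "missing"), names(tab))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome: FASTA sequences, GFF3 features, BED repeats
#'
#' Loads the three composition-analysis inputs and normalizes every
#' coordinate to the internal 0-based half-open convention (GFF3 is
#' 1-based inclusive; BED already matches). Features on sequences absent
#' from the FASTA, or extending beyond their sequence, are rejected.
#'
#' @param fasta FASTA path.
#' @param gff3 optional GFF3 path (gene/exon/CDS features are kept).
#' @param repeats optional BED path of repeat intervals.
#' @return list with `seqs` (a [Biostrings::DNAStringSet]) and `feats`
#'   (a `feature_set` data.frame: seqid, class, start, end, strand).
#' @export
read_genome <- function(fasta, gff3 = NULL, repeats = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in FASTA")
  feats <- list()
  if (!is.null(gff3)) {
    g <- rtracklayer::import(gff3)
    keep <- as.character(g$type) %in% c("gene", "exon", "CDS")
    g <- g[keep]
    parent <- if (!is.null(g$Parent))
      vapply(as.list(g$Parent), function(p) if (length(p)) p[1] else NA_character_, "")
    else rep(NA_character_, length(g))
    feats[[length(feats) + 1L]] <- data.frame(
      seqid = as.character(GenomicRanges::seqnames(g)),
      class = as.character(g$type),
      start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      parent = parent, stringsAsFactors = FALSE)
  }
  if (!is.null(repeats)) {
    b <- rtracklayer::import(repeats, format = "BED")
    feats[[length(feats) + 1L]] <- data.frame(
      seqid = as.character(GenomicRanges::seqnames(b)),
      class = "repeat",
      start = GenomicRanges::start(b) - 1L, end = GenomicRanges::end(b),
      strand = "*", parent = NA_character_, stringsAsFactors = FALSE)
  }
  feats <- if (length(feats)) do.call(rbind, feats) else
    data.frame(seqid = character(), class = character(), start = integer(),
               end = integer(), strand = character(), parent = character())
  bad_id <- setdiff(unique(feats$seqid), names(seqs))
  if (length(bad_id))
    stop(sprintf("feature sequence id(s) not in FASTA: %s",
                 paste(bad_id, collapse = ", ")))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  oob <- feats$end > lens[feats$seqid] | feats$start < 0
  if (any(oob))
    stop(sprintf("%d feature(s) extend beyond their sequence", sum(oob)))
  if (any(feats$start > feats$end)) stop("feature start > end")
  list(seqs = seqs, feats = structure(feats,
                                      class = c("feature_set", "data.frame")))
}

#' Extract coding-strand CDS sequences
#'
#' Concatenates the CDS features of each gene (grouped by their GFF3
#' Parent) in genomic order and reverse-complements minus-strand genes,
#' yielding the coding-strand sequence codon counting needs. CDS rows
#' without a Parent are grouped by sequence and strand.
#'
#' @param genome a [read_genome()] result.
#' @return a [Biostrings::DNAStringSet] of CDS sequences.
#' @export
extract_cds <- function(genome) {
  feats <- genome$feats
  cds <- feats[feats$class == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(Biostrings::DNAStringSet())
  key <- ifelse(is.na(cds$parent), paste(cds$seqid, cds$strand), cds$parent)
  out <- lapply(split(cds, key), function(f) {
    f <- f[order(f$start), ]
    v <- Biostrings::Views(genome$seqs[[f$seqid[1]]],
                           IRanges::IRanges(f$start + 1, f$end))
    s <- Biostrings::DNAString(paste(as.character(v), collapse = ""))
    if (f$strand[1] == "-") s <- Biostrings::reverseComplement(s)
    s
  })
  Biostrings::DNAStringSet(out)
}
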