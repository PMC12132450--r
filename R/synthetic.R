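## Synthetic-data generators. Every generator is deterministic under its
## seed and returns (or writes alongside its files) the ground truth used
## by the recovery tests, so truth is never re-derived from the data.

#' Scenario presets
#'
#' Named parameter bundles for the experiments the package models:
#' \describe{
#'   \item{becei-map}{six-chromosome genome with domain-structured Marey
#'     maps. Every chromosome carries exactly 50 cM (the obligate single
#'     crossover), so the symmetric arm rates are derived from the domain
#'     geometry: `(50 - center cM) / (2 arm Mb)`. The autosome domain
#'     parameters put arm rates at a mean of 8.1 cM/Mb (spread 6.5-9.4),
#'     center rates in 0.1-0.6 cM/Mb, centers about half the chromosome
#'     except chromosome V at 63 percent, plus a long, low-arm-rate X.}
#'   \item{medea-16cross}{the sixteen-cross distortion panel with both
#'     Medea penetrances 0.77 and brood sizes around 60 embryos.}
#'   \item{skew-1719}{the autosome-X cosegregation cross at n = 1719
#'     offspring and true recombination fraction 0.457.}
#'   \item{gc-heterogeneity}{a toy genome with GC-contrasted feature
#'     classes and telomeric ends.}
#' }
#'
#' @param name preset name.
#' @return list of parameters, serializable to YAML.
#' @export
scenario_preset <- function(name = c("becei-map", "medea-16cross",
                                     "skew-1719", "gc-heterogeneity")) {
  name <- match.arg(name)
  switch(name,
    "becei-map" = list(
      chromosomes = list(
        list(name = "I",   length_bp = 13.4e6, center_rate = 0.3, center_frac = 0.50, tip_bp = 4e5),
        list(name = "II",  length_bp = 14.6e6, center_rate = 0.1, center_frac = 0.52, tip_bp = 4e5),
        list(name = "III", length_bp = 12.0e6, center_rate = 0.2, center_frac = 0.50, tip_bp = 4e5),
        list(name = "IV",  length_bp = 15.4e6, center_rate = 0.4, center_frac = 0.48, tip_bp = 4e5),
        list(name = "V",   length_bp = 17.0e6, center_rate = 0.3, center_frac = 0.63, tip_bp = 4e5),
        list(name = "X",   length_bp = 21.0e6, center_rate = 0.3, center_frac = 0.55, tip_bp = 4e5)),
      genetic_length_cM = 50, n_markers = 120, noise_cM = 0.5),
    "medea-16cross" = list(beta_I = 0.77, beta_III = 0.77, baseline = 0.05,
                           missing_rate = 0.05, n_embryos = 60,
                           replicates = 12),
    "skew-1719" = list(n = 1719, r = 0.457),
    "gc-heterogeneity" = list(n_chrom = 2, length_bp = 2e5,
                              gc = c(exon = 60, intron = 40, repeat_ = 35,
                                     intergenic = 30),
                              n_genes = 20, telomere_units = 10))
}

## True piecewise-linear Marey position (cM) at bp x for one chromosome
## parameterized by tip size, arm/center rates and center fraction. Tips
## are flat (zero recombination).
true_marey_cM <- function(x, p) {
  L <- p$length_bp
  center_len <- p$center_frac * L
  arm_len <- (L - 2 * p$tip_bp - center_len) / 2
  if (arm_len <= 0) stop("tip and center sizes leave no room for arms")
  b <- cumsum(c(p$tip_bp, arm_len, center_len, arm_len))  # tipL|armL|center|armR|tipR
  s <- c(0, p$arm_rates[1], p$center_rate, p$arm_rates[2], 0) / 1e6
  knots <- c(0, b, L)
  y0 <- cumsum(c(0, s * diff(knots)))
  seg <- findInterval(x, knots, rightmost.closed = TRUE)
  y0[seg] + s[seg] * (x - knots[seg])
}

#' Generate a Marey-map marker fixture with known domain truth
#'
#' Markers are placed evenly along each chromosome and their genetic
#' positions sampled from a piecewise-linear true map (flat tips,
#' high-rate arms, low-rate center) plus Gaussian noise; the noisy
#' positions are made monotone with a running maximum so the fixture
#' always passes marker-table validation. Truth (breakpoints and rates)
#' is recorded per chromosome.
#'
#' @param cfg a scenario list (see [scenario_preset()], "becei-map").
#' @param seed integer seed.
#' @param dir optional directory; when given, the marker TSV and a truth
#'   YAML sidecar are written there.
#' @return a `marker_table` with attribute "truth": per-chromosome true
#'   LC/CR (bp), domain rates (cM/Mb of the 50 cM-normalized map) and
#'   center fraction.
#' @export
make_marey_fixture <- function(cfg = scenario_preset("becei-map"), seed = 1L,
                               dir = NULL) {
  set.seed(seed)
  rows <- list(); truth <- list(); lengths <- list()
  for (p in cfg$chromosomes) {
    if (p$center_rate < 0 || (!is.null(p$arm_rates) && any(p$arm_rates < 0)))
      stop("negative recombination rates would make the true map non-monotone")
    L <- p$length_bp
    center_len <- p$center_frac * L
    arm_len <- (L - 2 * p$tip_bp - center_len) / 2
    if (is.null(p$arm_rates)) {
      ## symmetric arm rates chosen so the chromosome totals the target
      ## genetic length (50 cM: one obligate crossover per meiosis)
      gl_target <- if (is.null(cfg$genetic_length_cM)) 50 else cfg$genetic_length_cM
      center_cM <- p$center_rate * center_len / 1e6
      if (center_cM >= gl_target)
        stop("center alone exceeds the target genetic length")
      p$arm_rates <- rep((gl_target - center_cM) / (2 * arm_len / 1e6), 2)
    }
    bp <- seq(0, L, length.out = cfg$n_markers)
    cM <- true_marey_cM(bp, p)
    cM <- cM + stats::rnorm(length(cM), 0, cfg$noise_cM)
    cM <- cummax(pmax(cM, 0))
    rows[[p$name]] <- data.frame(chrom = p$name, bp = bp, cM = cM,
                                 stringsAsFactors = FALSE)
    lengths[[p$name]] <- L
    LC <- p$tip_bp + arm_len
    CR <- LC + center_len
    gl <- max(true_marey_cM(L, p))
    truth[[p$name]] <- list(LC = LC, CR = CR,
                            arm_rates = as.numeric(p$arm_rates) * 50 / gl,
                            center_rate = p$center_rate * 50 / gl,
                            center_frac = p$center_frac,
                            genetic_length_cM = gl)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- structure(tab, lengths = lengths, truth = truth,
                   class = c("marker_table", "data.frame"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_marker_table(tab, file.path(dir, "markers.tsv"))
    yaml::write_yaml(truth, file.path(dir, "markers.truth.yaml"))
  }
  tab
}

#' Simulate a panel of G4BC2 mapping lines with genotype calls
#'
#' Runs the advanced-intercross pedigree for `n_lines` lines and emits
#' haploid founder calls for the counted recombinant haplotype of each
#' line on an even marker grid, plus the aggregated genetic map implied by
#' the crossover mosaic (cumulative crossover fraction per interval,
#' scaled to the chromosome's genetic length).
#'
#' @param design a [cross_design()].
#' @param chromosomes list of [chromosome_model()]s.
#' @param n_lines number of lines (>= 2).
#' @param n_markers markers per chromosome.
#' @param seed integer seed.
#' @return list with `genotypes` (named list per chromosome: lines x
#'   markers character matrix of "A"/"B"), `markers` (per-chromosome bp
#'   grids), `map` (marker table of the derived genetic map), and the
#'   simulation summary.
#' @export
make_g4bc2_lines <- function(design = cross_design(), chromosomes, n_lines = 92,
                             n_markers = 50, seed = 1L) {
  stopifnot(n_lines >= 2)
  sim <- simulate_g4bc2(design, chromosomes, n_lines, seed = seed,
                        keep_haplotypes = TRUE)
  if (is.null(names(chromosomes)))
    names(chromosomes) <- vapply(chromosomes, `[[`, "", "name")
  genos <- list(); markers <- list(); map_rows <- list()
  for (cn in names(chromosomes)) {
    L <- chromosomes[[cn]]$length_bp
    grid <- seq(0, L - 1, length.out = n_markers)
    gm <- t(vapply(sim$haplotypes, function(hs) {
      h <- hs[[cn]]
      labs <- vapply(grid, function(x) hap_label_at(h, x), 0L)
      c("A", "B")[labs]
    }, character(n_markers)))
    genos[[cn]] <- gm
    markers[[cn]] <- grid
    ## derived map: cumulative crossover fraction along the chromosome
    allbr <- sort(unlist(lapply(sim$haplotypes, function(hs) hs[[cn]]$br)))
    cum <- vapply(grid, function(x) sum(allbr <= x), 0)
    tot <- length(allbr)
    ## cumulative crossover fraction, on the 50 cM single-chromosome scale
    cM <- if (tot > 0) cum / tot * 50 else rep(0, n_markers)
    map_rows[[cn]] <- data.frame(chrom = cn, bp = grid, cM = cM,
                                 stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map_rows)
  rownames(map) <- NULL
  lengths <- lapply(chromosomes, `[[`, "length_bp")
  list(genotypes = genos, markers = markers,
       map = structure(map, lengths = lengths,
                       class = c("marker_table", "data.frame")),
       summary = sim)
}

#' Simulate the sixteen-cross Medea panel count table
#'
#' Every cross class is replicated `replicates` times with
#' [simulate_progeny_counts()]; the Medea truth is recorded in attribute
#' "truth".
#'
#' @param cfg scenario list (see [scenario_preset()], "medea-16cross").
#' @param seed integer seed.
#' @param mode "medea" or "peel".
#' @return a `progeny_count_table` with attribute "truth".
#' @export
make_medea_table <- function(cfg = scenario_preset("medea-16cross"), seed = 1L,
                             mode = "medea") {
  set.seed(seed)
  model <- medea_model(cfg$beta_I, cfg$beta_III, mode)
  classes <- all_cross_classes()
  rows <- list()
  for (cc in classes) for (r in seq_len(cfg$replicates)) {
    rows[[length(rows) + 1L]] <- simulate_progeny_counts(
      cc, model, cfg$n_embryos, baseline = cfg$baseline,
      missing_rate = cfg$missing_rate,
      plate_id = sprintf("c%02d_r%02d", cc$class_id, r))
  }
  tab <- do.call(rbind, rows)
  cnt <- c("unhatched", "deformed", "adult_female", "adult_male",
           "L4_female", "L4_male", "larvae")
  tab$missing <- pmax(tab$embryos - rowSums(tab[, cnt]), 0)
  structure(tab, truth = list(beta_I = cfg$beta_I, beta_III = cfg$beta_III,
                              baseline = cfg$baseline, mode = mode),
            class = c("progeny_count_table", "data.frame"))
}

## Random DNA of length n with a target GC percent.
random_dna <- function(n, gc_pct) {
  p <- gc_pct / 100
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - p) / 2, (1 - p) / 2, p / 2, p / 2)),
        collapse = "")
}

#' Generate a toy genome with prescribed feature composition
#'
#' Builds small chromosomes with GC-contrasted feature classes (exons,
#' introns, repeats, intergenic), a GFF3/BED annotation consistent with
#' the sequence, coding CDS with a configurable codon-usage profile, and
#' optional oriented telomeric ends. Written files (FASTA, GFF3, BED and
#' a truth YAML) go to `dir` when given.
#'
#' @param cfg scenario list (see [scenario_preset()], "gc-heterogeneity").
#' @param seed integer seed.
#' @param dir optional output directory.
#' @param codon_profile optional named numeric vector of codon weights
#'   used to build CDS (defaults to uniform synonymous usage).
#' @return list with `seqs`, `feats` (as from [read_genome()]), file
#'   paths when written, and the truth list.
#' @export
make_toy_genome <- function(cfg = scenario_preset("gc-heterogeneity"),
                            seed = 1L, dir = NULL, codon_profile = NULL) {
  if (any(cfg$gc < 0 | cfg$gc > 100)) stop("GC targets must be in [0, 100]")
  set.seed(seed)
  unit <- "TTAGGC"
  lunit <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  gene_len <- 1200; exon_len <- 300; rep_len <- 400
  seqs <- character(cfg$n_chrom); feats <- list()
  for (ci in seq_len(cfg$n_chrom)) {
    sq <- random_dna(cfg$length_bp, cfg$gc[["intergenic"]])
    pos <- 2000  # leave a telomere-free margin before the first gene
    genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
    for (gi in seq_len(genes_per_chrom)) {
      if (pos + gene_len + rep_len + 2000 > cfg$length_bp) break
      ## gene: exon - intron - exon; exons carry the CDS. Without a codon
      ## profile the exon sequence targets the exon GC directly (composition
      ## recovery mode); with one, codons are sampled from the profile and
      ## exon GC follows the profile instead.
      cds_seq <- if (is.null(codon_profile)) {
        random_dna(2 * exon_len, cfg$gc[["exon"]])
      } else {
        paste(sample(names(codon_profile), exon_len * 2 / 3, replace = TRUE,
                     prob = codon_profile), collapse = "")
      }
      e1 <- substr(cds_seq, 1, exon_len)
      e2 <- substr(cds_seq, exon_len + 1, 2 * exon_len)
      intron_len <- gene_len - 2 * exon_len
      intr <- random_dna(intron_len, cfg$gc[["intron"]])
      gene_seq <- paste0(e1, intr, e2)
      substr(sq, pos + 1, pos + gene_len) <- gene_seq
      sqid <- paste0("chr", ci)
      feats[[length(feats) + 1L]] <- data.frame(
        seqid = sqid,
        class = c("gene", "exon", "CDS", "exon", "CDS"),
        start = c(pos, pos, pos, pos + exon_len + intron_len,
                  pos + exon_len + intron_len),
        end = c(pos + gene_len, pos + exon_len, pos + exon_len,
                pos + gene_len, pos + gene_len),
        strand = "+",
        parent = c(NA, NA, sprintf("gene%d_%d", ci, gi), NA,
                   sprintf("gene%d_%d", ci, gi)),
        stringsAsFactors = FALSE)
      ## a repeat between genes
      rpos <- pos + gene_len + 500
      substr(sq, rpos + 1, rpos + rep_len) <- random_dna(rep_len, cfg$gc[["repeat_"]])
      feats[[length(feats) + 1L]] <- data.frame(
        seqid = sqid, class = "repeat", start = rpos, end = rpos + rep_len,
        strand = "*", parent = NA, stringsAsFactors = FALSE)
      pos <- rpos + rep_len + 1500
    }
    if (cfg$telomere_units > 0) {
      tl <- strrep(lunit, cfg$telomere_units)
      tr <- strrep(unit, cfg$telomere_units)
      substr(sq, 1, nchar(tl)) <- tl
      substr(sq, cfg$length_bp - nchar(tr) + 1, cfg$length_bp) <- tr
    }
    seqs[ci] <- sq
  }
  names(seqs) <- paste0("chr", seq_len(cfg$n_chrom))
  dna <- Biostrings::DNAStringSet(seqs)
  feats <- do.call(rbind, feats)
  feats <- structure(feats, class = c("feature_set", "data.frame"))
  truth <- list(gc = as.list(cfg$gc), telomere_units = cfg$telomere_units)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(dna, fa)
    gff <- file.path(dir, "genome.gff3")
    write_gff3(feats[feats$class != "repeat", ], gff)
    bed <- file.path(dir, "repeats.bed")
    rp <- feats[feats$class == "repeat", ]
    utils::write.table(data.frame(rp$seqid, rp$start, rp$end), bed,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    yaml::write_yaml(truth, file.path(dir, "genome.truth.yaml"))
    paths <- list(fasta = fa, gff3 = gff, bed = bed)
  }
  list(seqs = dna, feats = feats, truth = truth, paths = paths)
}

## Minimal GFF3 writer for the internal feature_set (0-based half-open ->
## 1-based inclusive at the boundary).
write_gff3 <- function(feats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ids <- sprintf("feat%d", seq_len(nrow(feats)))
  attrs <- ifelse(is.na(feats$parent),
                  sprintf("ID=%s", ids),
                  sprintf("ID=%s;Parent=%s", ids, feats$parent))
  writeLines(sprintf("%s\twormcross\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     feats$seqid, feats$class, feats$start + 1L, feats$end,
                     ifelse(feats$strand == "*", ".", feats$strand), attrs),
             con)
  invisible(path)
}
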