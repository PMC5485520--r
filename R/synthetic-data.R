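#' Simulation design for synthetic small-RNA libraries
#'
#' Describes a two-condition (salt vs control) small-RNA sequencing
#' experiment: replication, sequencing depth, count overdispersion, adapter
#' sequences and the fraction of contaminating ncRNA fragments.
#'
#' Counts are negative binomial with a dispersion shared across miRNAs
#' (mean/dispersion parameterization); `nb_dispersion = 0` degenerates to
#' Poisson.  Reads carry uniform high quality scores: quality filtering is
#' modeled as a pass-through because size selection and adapter removal are
#' the filters the pipeline actually exercises.
#'
#' @param n_replicates replicates per condition (>= 2).
#' @param library_depth total reads per library (miRNA reads + contaminants).
#' @param nb_dispersion nonnegative negative-binomial dispersion.
#' @param adapter3,adapter5 adapter sequences; `adapter3` is appended to
#'   synthesized reads (read-through), `adapter5` is assumed already removed
#'   by the base caller and is kept for trimming configuration only.
#' @param contaminant_fraction fraction of reads that are ncRNA fragments.
#' @param seed integer seed; all randomness downstream derives from it.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_replicates = 2L,
                       library_depth = 200000L,
                       nb_dispersion = 0.05,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       contaminant_fraction = 0.1,
                       seed = 1L) {
  if (!is_count(n_replicates) || n_replicates < 1)
    stop("n_replicates must be a positive integer")
  if (!is_count(library_depth) || library_depth <= 0)
    stop("library_depth must be a positive integer")
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0)
    stop("nb_dispersion must be nonnegative")
  stopifnot_scalar_prob(contaminant_fraction, "contaminant_fraction")
  structure(list(n_conditions = 2L,
                 n_replicates = as.integer(n_replicates),
                 library_depth = as.integer(library_depth),
                 nb_dispersion = nb_dispersion,
                 adapter3 = toupper(adapter3),
                 adapter5 = toupper(adapter5),
                 contaminant_fraction = contaminant_fraction,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate a random genome sequence
#'
#' @param length genome length in bases (>= 1000).
#' @param gc GC fraction in (0, 1); the degenerate values 0 and 1 are
#'   allowed for testing.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return named character vector of length 1 (a one-chromosome genome).
#' @export
generate_genome <- function(length, gc = 0.44, seed = 1L, chrom = "chr1") {
  if (!is_count(length) || length < 1000)
    stop("length must be an integer >= 1000")
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  withr::with_seed(seed, {
    g <- random_dna(length, gc)
  })
  stats::setNames(g, chrom)
}

#' Plant pre-miRNA hairpins into a genome
#'
#' Inserts `n` perfect-stem hairpins (stem + loop + reverse-complement stem)
#' at disjoint positions, on either strand with probability 1/2.  Each
#' mature miRNA lies entirely on one arm; the star is its reverse complement
#' on the opposite arm.  The recorded precursor interval extends `flank`
#' bases into the surrounding genome on both sides so that the interval is
#' a realistic pre-miRNA length (>= 2*stem + loop + 2*flank).
#'
#' @param genome named character vector (or DNAStringSet) of chromosomes.
#' @param n number of hairpins to plant.
#' @param stem_len,loop_len,mature_len integer ranges `c(min, max)`.
#' @param seed integer seed.
#' @param mature_ref optional named character vector of known mature miRNAs
#'   (U or T alphabet); used for conserved plants.
#' @param conserved_fraction fraction of hairpins whose mature is drawn from
#'   `mature_ref` (rounded down).
#' @param fold_changes salt/control fold change, a single value recycled or
#'   a vector of length `n`; strictly positive.
#' @param base_abundance relative abundance weights, length `n`; defaults to
#'   log-normal draws (sdlog 1).
#' @param min_gap minimum gap between planted hairpins in bases.
#' @param flank flank recorded inside the precursor interval.
#' @return list with elements `genome` (modified) and `truth` (a
#'   `truth_set`: `mirnas` data frame, `fold_changes`, `base_abundance`).
#' @export
plant_hairpins <- function(genome, n,
                           stem_len = c(18L, 25L),
                           loop_len = c(4L, 15L),
                           mature_len = c(20L, 24L),
                           seed = 1L,
                           mature_ref = NULL,
                           conserved_fraction = 0,
                           fold_changes = 1,
                           base_abundance = NULL,
                           min_gap = 300L,
                           flank = 10L) {
  genome <- as_genome(genome)
  if (!is_count(n) || n < 1) stop("n must be a positive integer")
  if (any(fold_changes <= 0)) stop("fold_changes must be strictly positive")
  fold_changes <- rep_len(fold_changes, n)
  n_cons <- floor(n * conserved_fraction)
  if (n_cons > 0 && is.null(mature_ref))
    stop("mature_ref is required when conserved_fraction > 0")

  withr::with_seed(seed, {
    # assign hairpins to chromosomes proportional to length
    chrom_of <- sample(names(genome), n, replace = TRUE,
                       prob = nchar(genome) / sum(nchar(genome)))
    rows <- vector("list", n)
    is_cons <- rep(c(TRUE, FALSE), c(n_cons, n - n_cons))
    if (!is.null(mature_ref)) mature_ref <- normalize_u(mature_ref)

    # draw hairpin composition first so placement knows the core lengths
    mature <- character(n); family <- rep(NA_character_, n)
    stem <- integer(n); loop <- integer(n)
    for (i in seq_len(n)) {
      if (is_cons[i]) {
        k <- sample(length(mature_ref), 1L)
        mature[i] <- mature_ref[[k]]
        family[i] <- names(mature_ref)[k]
      } else {
        mature[i] <- random_dna(resample(mature_len[1]:mature_len[2]), gc = 0.5)
      }
      stem[i] <- resample(max(stem_len[1], nchar(mature[i])):max(stem_len[2], nchar(mature[i])))
      loop[i] <- resample(loop_len[1]:loop_len[2])
    }
    core_len <- 2L * stem + loop
    ins_len <- core_len + 2L * flank  # vetted flanks are planted too

    # per-chromosome disjoint placement with random slack gaps
    starts <- integer(n)  # 1-based insert start
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      glen <- nchar(genome[[ch]])
      m <- length(idx)
      need <- sum(ins_len[idx]) + (m + 1L) * min_gap
      if (need > glen)
        stop(sprintf("genome too small on %s to plant %d disjoint precursors", ch, m))
      slack <- glen - need
      extra <- as.vector(stats::rmultinom(1L, slack, rep(1 / (m + 1L), m + 1L)))
      gaps <- min_gap + extra
      pos <- cumsum(gaps[seq_len(m)] + c(0L, ins_len[idx][-m])) + 1L
      starts[idx] <- pos
    }

    ids <- character(n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    mature_arm <- sample(c("5p", "3p"), n, replace = TRUE)
    star <- character(n)
    n_novel <- 0L
    crit <- hairpin_criteria()
    for (i in seq_len(n)) {
      ml <- nchar(mature[i])
      # rejection-sample arm padding, loop and flank context until the
      # planted precursor passes the stem-loop criteria when folded AND
      # survives window-scale discovery in its genomic context (the
      # properties the truth set promises downstream stages)
      pre <- substr(genome[[chrom_of[i]]], max(1L, starts[i] - 200L),
                    starts[i] - 1L)
      post <- substr(genome[[chrom_of[i]]], starts[i] + ins_len[i],
                     min(nchar(genome[[chrom_of[i]]]),
                         starts[i] + ins_len[i] + 199L))
      for (try in 1:100) {
        off <- sample.int(stem[i] - ml + 1L, 1L) - 1L
        if (mature_arm[i] == "5p") {
          arm5 <- paste0(substr(random_dna(stem[i], 0.5), 1L, off), mature[i],
                         random_dna(stem[i] - ml - off, 0.5))
          arm5 <- substr(arm5, 1L, stem[i])
          moff <- flank + off + 1L
        } else {
          # mature sits on the 3' arm: the 5' arm is its reverse complement
          a3 <- paste0(substr(random_dna(stem[i], 0.5), 1L, off), mature[i],
                       random_dna(stem[i] - ml - off, 0.5))
          a3 <- substr(a3, 1L, stem[i])
          arm5 <- revcomp(a3)
          moff <- flank + stem[i] + loop[i] + off + 1L
        }
        hairpin <- paste0(arm5, random_dna(loop[i], 0.5), revcomp(arm5))
        construct <- paste0(random_dna(flank, 0.5), hairpin,
                            random_dna(flank, 0.5))
        ev <- evaluate_hairpin(fold_hairpin(construct), moff, moff + ml - 1L,
                               criteria = crit)
        if (!ev$pass) next
        window <- if (strand[i] == "+") paste0(pre, construct, post)
                  else revcomp(paste0(pre, revcomp(construct), post))
        if (window_yields_hairpin(window, mature[i])) break
        ev$pass <- FALSE
      }
      if (!ev$pass)
        stop(sprintf("could not construct a passing hairpin for plant %d", i))
      star[i] <- revcomp(mature[i])
      ins <- if (strand[i] == "+") construct else revcomp(construct)
      g <- genome[[chrom_of[i]]]
      substr(g, starts[i], starts[i] + ins_len[i] - 1L) <- ins
      genome[[chrom_of[i]]] <- g
      if (is_cons[i]) {
        ids[i] <- paste0(family[i], "_planted", i)
      } else {
        n_novel <- n_novel + 1L
        ids[i] <- sprintf("novel-planted-%02d", n_novel)
      }
    }
    if (is.null(base_abundance)) base_abundance <- rlnorm(n, 0, 1)
  })

  mirnas <- data.frame(id = ids, mature_seq = mature, star_seq = star,
                       chrom = chrom_of, start = starts,
                       end = starts + ins_len - 1L,
                       core_start = starts + flank,
                       core_end = starts + flank + core_len - 1L,
                       strand = strand, is_conserved = is_cons,
                       family = family, stringsAsFactors = FALSE)
  truth <- structure(list(genome_id = paste(names(genome), collapse = ","),
                          mirnas = mirnas,
                          fold_changes = stats::setNames(fold_changes, ids),
                          base_abundance = stats::setNames(base_abundance, ids)),
                     class = "truth_set")
  list(genome = genome, truth = truth)
}

#' Minimal truth set for count-level simulations
#'
#' Builds a `truth_set` without genomic coordinates, for simulations that
#' exercise only the count model (e.g. differential-expression calibration).
#'
#' @param ids miRNA identifiers.
#' @param base_abundance positive weights, recycled.
#' @param fold_changes positive salt/control fold changes, recycled.
#' @return a `truth_set` with an empty coordinate table.
#' @export
count_truth <- function(ids, base_abundance = 1, fold_changes = 1) {
  if (any(fold_changes <= 0)) stop("fold_changes must be strictly positive")
  structure(list(genome_id = NA_character_,
                 mirnas = data.frame(id = ids, stringsAsFactors = FALSE),
                 fold_changes = stats::setNames(rep_len(fold_changes, length(ids)), ids),
                 base_abundance = stats::setNames(rep_len(base_abundance, length(ids)), ids)),
            class = "truth_set")
}

#' Simulate a miRNA x library count matrix
#'
#' Expected count of miRNA i in a library is
#' `depth * (1 - contaminant_fraction) * w_i / sum(w)` where
#' `w_i = base_abundance[i] * fold_change[i]` in salt libraries and
#' `base_abundance[i]` in control libraries (so strong induction produces a
#' realistic compositional shift).  Counts are negative binomial with the
#' design's shared dispersion; dispersion 0 gives Poisson counts.
#'
#' @param truth a `truth_set`.
#' @param design a [sim_design()].
#' @return integer matrix (miRNA x library) with a `condition` attribute
#'   (`"salt"`/`"control"` per column).
#' @export
simulate_counts <- function(truth, design) {
  stopifnot(inherits(truth, "truth_set"), inherits(design, "sim_design"))
  ids <- truth$mirnas$id
  ab <- truth$base_abundance[ids]
  fc <- truth$fold_changes[ids]
  if (any(fc <= 0)) stop("fold_changes must be strictly positive")
  nr <- design$n_replicates
  libs <- c(paste0("S", seq_len(nr)), paste0("Ck", seq_len(nr)))
  cond <- rep(c("salt", "control"), each = nr)
  depth_mirna <- design$library_depth * (1 - design$contaminant_fraction)
  counts <- matrix(0L, nrow = length(ids), ncol = length(libs),
                   dimnames = list(ids, libs))
  withr::with_seed(design$seed + 1L, {
    for (j in seq_along(libs)) {
      w <- if (cond[j] == "salt") ab * fc else ab
      mu <- depth_mirna * w / sum(w)
      counts[, j] <- if (design$nb_dispersion == 0) rpois(length(mu), mu)
                     else rnbinom(length(mu), mu = mu, size = 1 / design$nb_dispersion)
    }
  })
  attr(counts, "condition") <- cond
  counts
}

#' Synthesize FASTQ libraries from a count matrix
#'
#' Each miRNA read is the mature sequence, with the 3' adapter appended when
#' the design has one (sequencing read-through).  Contaminant reads are
#' random 18-30 nt fragments of the supplied ncRNA references, added so that
#' they make up `contaminant_fraction` of each library.  Qualities are
#' uniform Sanger "I".
#'
#' @param counts miRNA x library count matrix (rows named by miRNA id).
#' @param truth the `truth_set` the counts were simulated from.
#' @param design a [sim_design()].
#' @param ncrna optional named character vector of ncRNA reference
#'   sequences; required when the design plants contaminants.
#' @param dir output directory (created if needed).
#' @return named character vector of FASTQ paths, one per library.
#' @export
synthesize_reads <- function(counts, truth, design, ncrna = NULL, dir = tempdir()) {
  stopifnot(inherits(truth, "truth_set"), inherits(design, "sim_design"))
  if (nrow(truth$mirnas) == 0) stop("empty truth set")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  mature <- stats::setNames(truth$mirnas$mature_seq, truth$mirnas$id)
  cf <- design$contaminant_fraction
  if (cf > 0 && is.null(ncrna))
    stop("ncrna references required when contaminant_fraction > 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ncol(counts))
  names(paths) <- colnames(counts)
  withr::with_seed(design$seed + 2L, {
    for (j in seq_len(ncol(counts))) {
      reads <- rep(mature[rownames(counts)], counts[, j])
      n_cont <- if (cf > 0) round(sum(counts[, j]) * cf / (1 - cf)) else 0L
      if (n_cont > 0) {
        ref <- sample(ncrna, n_cont, replace = TRUE)
        len <- pmin(nchar(ref), sample(18:30, n_cont, replace = TRUE))
        beg <- floor(runif(n_cont) * (nchar(ref) - len + 1)) + 1L
        reads <- c(reads, substr(ref, beg, beg + len - 1L))
      }
      if (nzchar(design$adapter3)) reads <- paste0(reads, design$adapter3)
      reads <- sample(reads)
      names(reads) <- sprintf("%s_read%07d", colnames(counts)[j], seq_along(reads))
      paths[j] <- file.path(dir, paste0(colnames(counts)[j], ".fastq"))
      write_fastq(reads, paths[j])
    }
  })
  paths
}

#' Synthetic ncRNA reference sets
#'
#' Random rRNA/tRNA/snoRNA/other reference sequences used to plant and then
#' annotate contaminating fragments.
#'
#' @param seed integer seed.
#' @param n_per_class sequences per class.
#' @param len_range reference length range.
#' @return named list of named character vectors, in triage priority order
#'   (rRNA, tRNA, snoRNA, other).
#' @export
synthetic_ncrna_refs <- function(seed = 1L, n_per_class = 3L,
                                 len_range = c(120L, 300L)) {
  withr::with_seed(seed, {
    mk <- function(prefix) {
      lens <- resample(len_range[1]:len_range[2], n_per_class, replace = TRUE)
      stats::setNames(vapply(lens, random_dna, "", gc = 0.5),
                      paste0(prefix, seq_len(n_per_class)))
    }
    list(rRNA = mk("rRNA_"), tRNA = mk("tRNA_"),
         snoRNA = mk("snoRNA_"), other = mk("otherRNA_"))
  })
}

#' Synthetic mature miRNA reference set
#'
#' A miRBase-like named set of mature sequences in the RNA alphabet (U), to
#' exercise U/T normalization in conserved matching.
#'
#' @param n number of reference matures.
#' @param seed integer seed.
#' @param len_range mature length range.
#' @return named character vector (RNA alphabet).
#' @export
synthetic_mature_reference <- function(n = 20L, seed = 1L, len_range = c(20L, 22L)) {
  withr::with_seed(seed, {
    lens <- resample(len_range[1]:len_range[2], n, replace = TRUE)
    seqs <- vapply(lens, random_dna, "", gc = 0.5)
    stats::setNames(chartr("T", "U", seqs),
                    sprintf("tdi-miR%d%s", 150L + seq_len(n),
                            sample(letters[1:3], n, replace = TRUE)))
  })
}

#' Write a truth set to disk
#'
#' Writes the planted-miRNA table as TSV and the precursor intervals as
#' GFF3 (1-based, inclusive).
#'
#' @param truth a `truth_set` with genomic coordinates.
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "truth_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- truth$mirnas
  tab$fold_change <- truth$fold_changes[tab$id]
  tab$base_abundance <- truth$base_abundance[tab$id]
  tsv <- file.path(dir, "truth_mirnas.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  gff <- file.path(dir, "truth_precursors.gff3")
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand,
    type = "miRNA_primary_transcript",
    ID = tab$id)
  rtracklayer::export.gff3(gr, gff)
  invisible(c(tsv = tsv, gff3 = gff))
}
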