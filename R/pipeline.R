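#' Pipeline configuration
#'
#' Collects every stage parameter (defaults are the pipeline's canonical
#' values) together with input paths.  A YAML file with the same keys can
#' be loaded with [load_config()].
#'
#' @param genome path to the reference genome FASTA.
#' @param mature_ref path to the mature miRNA reference FASTA.
#' @param ncrna named character vector of ncRNA reference FASTAs in triage
#'   priority order (e.g. `c(rRNA = ..., tRNA = ...)`).
#' @param transcripts path to the transcript (cDNA) FASTA for target
#'   scanning (optional).
#' @param libraries data.frame with columns `library_id`, `condition`
#'   (`"salt"`/`"control"`) and `fastq` (paths).
#' @param qpcr_ct optional path to a long-format Ct TSV.
#' @param out_dir output directory.
#' @param min_len,max_len tag length window (defaults 18, 30 nt).
#' @param min_overlap minimum adapter overlap (default 6).
#' @param adapter3,adapter5 adapter sequences.
#' @param k index word size (default 12).
#' @param max_hits mapping hit cap (default 100).
#' @param max_repeat_hits high-repeat threshold (default 20).
#' @param conserved_max_mm conserved-assignment mismatches (default 2).
#' @param cluster_max_gap locus clustering distance (default 200 bp).
#' @param precursor_flank precursor extraction flank (default 200 nt).
#' @param ir_threshold,ir_match,ir_mismatch,ir_gap,ir_max_span
#'   inverted-repeat parameters (defaults 40, 3, -3, 6, 240).
#' @param extend_pad repeat extension (default 10 nt).
#' @param fold_min_loop folding minimum loop (default 3).
#' @param alpha differential-expression threshold (default 0.05).
#' @param target_max_mm,target_protected target-scan rule (defaults 3 and
#'   positions 10, 11).
#' @param qpcr_reference,qpcr_control reference gene id and control sample
#'   for the qPCR stage.
#' @param seed integer seed.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome = NULL, mature_ref = NULL, ncrna = NULL,
                            transcripts = NULL, libraries = NULL,
                            qpcr_ct = NULL, out_dir = "mirseek_out",
                            min_len = 18L, max_len = 30L, min_overlap = 6L,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            k = 12L, max_hits = 100L, max_repeat_hits = 20L,
                            conserved_max_mm = 2L, cluster_max_gap = 200L,
                            precursor_flank = 200L, ir_threshold = 40,
                            ir_match = 3, ir_mismatch = -3, ir_gap = 6,
                            ir_max_span = 240L, extend_pad = 10L,
                            fold_min_loop = 3L, alpha = 0.05,
                            target_max_mm = 3L, target_protected = c(10L, 11L),
                            qpcr_reference = "18S", qpcr_control = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$libraries)) y$libraries <- as.data.frame(y$libraries)
  do.call(pipeline_config, y)
}

#' Write a demonstration synthetic dataset to disk
#'
#' Generates a genome with planted hairpins (a fraction of them carrying
#' conserved matures), synthesizes the FASTQ libraries, writes the truth
#' files, ncRNA and mature references, target transcripts, and a ready
#' config YAML.
#'
#' @param dir output directory.
#' @param n_mirnas planted hairpins (default 50).
#' @param genome_length genome size in bases.
#' @param conserved_fraction fraction of planted matures drawn from the
#'   mature reference.
#' @param frac_up,frac_down fractions of miRNAs planted with `fold_up`
#'   and `fold_down` salt/control fold changes (the rest are null).
#' @param fold_up,fold_down the planted fold changes.
#' @param design a [sim_design()].
#' @param seed integer seed.
#' @return invisibly, a [pipeline_config()] pointing at the files.
#' @export
simulate_dataset <- function(dir, n_mirnas = 50L, genome_length = 120000L,
                             conserved_fraction = 0.3, frac_up = 0.15,
                             frac_down = 0.10, fold_up = 8, fold_down = 0.125,
                             design = sim_design(), seed = design$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome0 <- generate_genome(genome_length, gc = 0.44, seed = seed)
  mature_ref <- synthetic_mature_reference(n = max(10L, ceiling(n_mirnas / 2)),
                                           seed = seed + 10L)
  n_up <- round(n_mirnas * frac_up); n_dn <- round(n_mirnas * frac_down)
  fc <- c(rep(fold_up, n_up), rep(fold_down, n_dn),
          rep(1, n_mirnas - n_up - n_dn))
  planted <- plant_hairpins(genome0, n = n_mirnas, seed = seed + 20L,
                            mature_ref = mature_ref,
                            conserved_fraction = conserved_fraction,
                            fold_changes = fc)
  ncrna <- synthetic_ncrna_refs(seed = seed + 30L)
  counts <- simulate_counts(planted$truth, design)
  fastq <- synthesize_reads(counts, planted$truth, design,
                            ncrna = unlist(unname(lapply(ncrna, identity))),
                            dir = file.path(dir, "reads"))
  tx <- simulate_transcripts(planted$truth, seed = seed + 40L)

  write_fasta(planted$genome, file.path(dir, "genome.fa"))
  write_fasta(stats::setNames(normalize_u(mature_ref), names(mature_ref)),
              file.path(dir, "mature_ref.fa"))
  ncrna_paths <- vapply(names(ncrna), function(cls) {
    p <- file.path(dir, paste0("ncrna_", cls, ".fa"))
    write_fasta(ncrna[[cls]], p)
    p
  }, "")
  write_fasta(tx, file.path(dir, "transcripts.fa"))
  write_truth(planted$truth, dir)
  utils::write.table(data.frame(mirna_id = rownames(counts), counts,
                                check.names = FALSE),
                     file.path(dir, "true_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  libraries <- data.frame(
    library_id = colnames(counts),
    condition = attr(counts, "condition"),
    fastq = unname(fastq[colnames(counts)]),
    stringsAsFactors = FALSE)
  cfg <- pipeline_config(genome = file.path(dir, "genome.fa"),
                         mature_ref = file.path(dir, "mature_ref.fa"),
                         ncrna = ncrna_paths,
                         transcripts = file.path(dir, "transcripts.fa"),
                         libraries = libraries,
                         out_dir = file.path(dir, "out"),
                         adapter3 = design$adapter3,
                         adapter5 = design$adapter5,
                         seed = seed)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.data.frame(x)) as.list(x) else x),
    file.path(dir, "config.yaml"))
  invisible(cfg)
}

#' Synthetic transcripts carrying miRNA target sites
#'
#' One transcript per planted miRNA containing the exact reverse
#' complement of the mature (a perfect target site), plus unrelated decoy
#' transcripts.
#'
#' @param truth a `truth_set`.
#' @param tx_len transcript length.
#' @param n_decoys decoy transcripts without planted sites.
#' @param seed integer seed.
#' @return named character vector of transcript sequences.
#' @export
simulate_transcripts <- function(truth, tx_len = 500L, n_decoys = 10L,
                                 seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  withr::with_seed(seed, {
    mk_site <- function(id, mature) {
      site <- revcomp(mature)
      pos <- resample(seq_len(tx_len - nchar(site) + 1L))
      tx <- random_dna(tx_len, 0.5)
      substr(tx, pos, pos + nchar(site) - 1L) <- site
      tx
    }
    tx <- vapply(seq_len(nrow(truth$mirnas)), function(i)
      mk_site(truth$mirnas$id[i], truth$mirnas$mature_seq[i]), "")
    names(tx) <- paste0("tx_", truth$mirnas$id)
    decoys <- vapply(seq_len(n_decoys), function(i) random_dna(tx_len, 0.5), "")
    names(decoys) <- sprintf("tx_decoy%02d", seq_len(n_decoys))
    c(tx, decoys)
  })
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages in order: preprocess (trim, collapse), map/annotate, discover
#' (conserved + novel), quantify (TPM, exact test), targets, reports;
#' optionally the qPCR stage when a Ct table is configured.  Every output
#' is written under `config$out_dir` together with a manifest of input
#' hashes and parameters.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results (`tags`, `hits`,
#'   `classes`, `conserved`, `novel`, `de`, `targets`, `tables`, `bias`,
#'   `paths`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  libs <- config$libraries
  if (is.null(libs) || nrow(libs) == 0) stop("config$libraries is required")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  genome <- run_stage("load_inputs",
                      as_genome(Biostrings::readDNAStringSet(config$genome)))

  # --- preprocess ---------------------------------------------------------
  tags <- run_stage("preprocess", {
    raw <- lapply(libs$fastq, read_seqs, format = "fastq")
    names(raw) <- libs$library_id
    trimmed <- lapply(raw, function(r)
      trim_adapters(r, adapter3 = config$adapter3, adapter5 = config$adapter5,
                    min_overlap = config$min_overlap))
    ts <- collapse_tags(lapply(trimmed, `[[`, "reads"),
                        min_len = config$min_len, max_len = config$max_len)
    ts$stats$total_reads <- vapply(trimmed, function(t) t$stats[["n_in"]], 0)
    ts
  })

  # --- map / annotate -----------------------------------------------------
  index <- run_stage("map", build_index(genome, k = config$k))
  hits <- run_stage("map", map_tags(tags, index, max_mismatches = 0L,
                                    max_hits = config$max_hits))
  mapped_ids <- unique(hits$tag_id)
  tags$stats$mapped_reads <- vapply(seq_len(nrow(tags$stats)), function(j)
    sum(tags$counts[mapped_ids, j]), 0)
  tags$stats$unique_mapped <- vapply(seq_len(nrow(tags$stats)), function(j)
    sum(tags$counts[mapped_ids, j] > 0), 0)
  ncrna_refs <- run_stage("annotate", lapply(config$ncrna, function(p)
    as.character(Biostrings::readDNAStringSet(p))))
  annotation <- run_stage("annotate", annotate_ncrna(tags, ncrna_refs))
  classes <- run_stage("annotate",
                       classify_tags(tags, hits, annotation,
                                     max_repeat_hits = config$max_repeat_hits))

  # --- discovery ----------------------------------------------------------
  cand_ids <- classes$tag_id[classes$category == "candidate"]
  mature_ref <- run_stage("discover",
                          as.character(Biostrings::readDNAStringSet(config$mature_ref)))
  cand_seqs <- stats::setNames(tags$tags$sequence, tags$tags$tag_id)[cand_ids]
  assignments <- run_stage("discover",
                           match_conserved(cand_seqs, mature_ref,
                                           max_mismatches = config$conserved_max_mm))
  conserved <- run_stage("discover", call_conserved(tags, assignments))
  novel_ids <- setdiff(cand_ids, assignments$tag_id)
  novel <- run_stage("discover",
                     call_novel(tags, hits[hits$tag_id %in% novel_ids, ],
                                genome,
                                max_gap = config$cluster_max_gap,
                                flank = config$precursor_flank,
                                threshold = config$ir_threshold,
                                match = config$ir_match,
                                mismatch = config$ir_mismatch,
                                gap_penalty = config$ir_gap,
                                max_span = config$ir_max_span,
                                pad = config$extend_pad,
                                min_loop = config$fold_min_loop))

  # --- quantify -----------------------------------------------------------
  de <- run_stage("quantify", {
    counts <- rbind(conserved$counts, novel$counts)
    if (nrow(counts) == 0) NULL
    else {
      totals <- stats::setNames(tags$stats$high_quality_reads,
                                tags$stats$library_id)[colnames(counts)]
      cond <- stats::setNames(libs$condition, libs$library_id)[colnames(counts)]
      res <- call_differential(counts, cond, totals = totals,
                               alpha = config$alpha)
      list(results = res, counts = counts, totals = totals, condition = cond,
           scaled = if (any(res$mark != "NS"))
             scaled_matrix(tpm_matrix(counts, totals)[res$mark != "NS", ,
                                                      drop = FALSE])
           else NULL)
    }
  })

  # --- targets ------------------------------------------------------------
  target_res <- NULL
  if (!is.null(config$transcripts)) {
    target_res <- run_stage("targets", {
      tx <- as.character(Biostrings::readDNAStringSet(config$transcripts))
      matures <- c(stats::setNames(conserved$records$mature_seq,
                                   conserved$records$id),
                   stats::setNames(novel$records$mature_seq,
                                   novel$records$id))
      if (length(matures) == 0) NULL
      else {
        h <- find_targets(matures, tx, max_mm = config$target_max_mm,
                          protected = config$target_protected)
        list(hits = h, summary = target_summary(h, names(matures)))
      }
    })
  }

  # --- reports ------------------------------------------------------------
  tables <- run_stage("report", {
    cond <- stats::setNames(libs$condition, libs$library_id)
    list(table1 = table1_summary(tags$stats, cond[tags$stats$library_id]),
         table2 = table2_summary(classes))
  })
  bias <- run_stage("report", {
    matures <- c(conserved$records$mature_seq, novel$records$mature_seq)
    if (length(matures)) nucleotide_bias(matures) else NULL
  })

  # --- qPCR ---------------------------------------------------------------
  qpcr <- NULL
  if (!is.null(config$qpcr_ct)) {
    qpcr <- run_stage("qpcr", {
      ct <- utils::read.delim(config$qpcr_ct, stringsAsFactors = FALSE)
      relative_expression(ct, reference_id = config$qpcr_reference,
                          control_sample = config$qpcr_control)
    })
  }

  # --- write outputs ------------------------------------------------------
  paths <- run_stage("write", {
    p <- c(tags_fasta = file.path(out, "tags.fa"),
           tag_counts = file.path(out, "tag_counts.tsv"),
           stats = file.path(out, "library_stats.tsv"),
           hits_bed = file.path(out, "genome_hits.bed"),
           classes = file.path(out, "tag_classes.tsv"),
           table1 = file.path(out, "table1_summary.tsv"),
           table2 = file.path(out, "table2_categories.tsv"),
           conserved = file.path(out, "conserved_mirnas.tsv"),
           novel = file.path(out, "novel_mirnas.tsv"),
           novel_fa = file.path(out, "novel_precursors.fa"),
           novel_gff = file.path(out, "novel_precursors.gff3"),
           novel_db = file.path(out, "novel_precursors.dotbracket.txt"),
           de = file.path(out, "de_results.tsv"),
           manifest = file.path(out, "manifest.json"))
    export_tags(tags, p[["tags_fasta"]], p[["tag_counts"]])
    wt <- function(d, f) utils::write.table(d, f, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    wt(tags$stats, p[["stats"]])
    if (nrow(hits)) export_hits_bed(hits, p[["hits_bed"]])
    wt(classes, p[["classes"]])
    wt(tables$table1, p[["table1"]])
    wt(tables$table2, p[["table2"]])
    wt(conserved$records, p[["conserved"]])
    wt(novel$records, p[["novel"]])
    if (nrow(novel$precursors)) {
      write_fasta(stats::setNames(novel$precursors$sequence,
                                  sprintf("%s|%s:%d-%d(%s)",
                                          novel$precursors$id,
                                          novel$precursors$chrom,
                                          novel$precursors$start + 1L,
                                          novel$precursors$end,
                                          novel$precursors$strand)),
                  p[["novel_fa"]])
      gr <- GenomicRanges::GRanges(
        seqnames = novel$precursors$chrom,
        ranges = IRanges::IRanges(start = novel$precursors$start + 1L,
                                  end = novel$precursors$end),
        strand = novel$precursors$strand,
        type = "miRNA_primary_transcript", ID = novel$precursors$id)
      rtracklayer::export.gff3(gr, p[["novel_gff"]])
      writeLines(paste(novel$precursors$id, novel$precursors$sequence,
                       novel$precursors$dotbracket, sep = "\n"),
                 p[["novel_db"]])
    }
    if (!is.null(de)) {
      wt(de$results, p[["de"]])
      if (!is.null(de$scaled))
        wt(data.frame(mirna_id = rownames(de$scaled), de$scaled,
                      check.names = FALSE),
           file.path(out, "scaled_tpm.tsv"))
    }
    if (!is.null(target_res)) {
      wt(target_res$hits, file.path(out, "target_hits.tsv"))
      wt(target_res$summary, file.path(out, "target_summary.tsv"))
    }
    if (!is.null(bias)) {
      wt(data.frame(position = seq_len(nrow(bias$position_freq)),
                    bias$position_freq, check.names = FALSE),
         file.path(out, "nucleotide_bias.tsv"))
      wt(bias$first_base_by_length, file.path(out, "first_base_by_length.tsv"))
    }
    if (!is.null(qpcr)) wt(qpcr, file.path(out, "qpcr_results.tsv"))

    inputs <- c(genome = config$genome, mature_ref = config$mature_ref,
                config$ncrna, transcripts = config$transcripts,
                stats::setNames(libs$fastq, libs$library_id))
    inputs <- inputs[!vapply(inputs, is.null, TRUE)]
    param_keys <- setdiff(names(config),
                          c("genome", "mature_ref", "ncrna", "transcripts",
                            "libraries", "qpcr_ct", "out_dir"))
    manifest <- list(
      inputs = as.list(tools::md5sum(unlist(inputs))),
      parameters = unclass(config)[param_keys],
      outputs = as.list(tools::md5sum(p[file.exists(p)])))
    jsonlite::write_json(manifest, p[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    p
  })

  invisible(list(tags = tags, hits = hits, classes = classes,
                 conserved = conserved, novel = novel, de = de,
                 targets = target_res, tables = tables, bias = bias,
                 qpcr = qpcr, paths = paths))
}
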