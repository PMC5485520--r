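test_that("genome generation is seeded and matches the requested composition", {
  g1 <- generate_genome(10000, gc = 0.5, seed = 1)
  g2 <- generate_genome(10000, gc = 0.5, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_genome(10000, gc = 0.5, seed = 2)))

  g0 <- generate_genome(10000, gc = 0, seed = 1)
  expect_false(grepl("[GC]", g0[[1]]))

  g <- generate_genome(100000, gc = 0.45, seed = 7)
  obs <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / 100000
  se <- sqrt(0.45 * 0.55 / 100000)
  expect_lt(abs(obs - 0.45), 3 * se)

  expect_error(generate_genome(100, gc = 0.5), "length")
})

test_that("planted hairpins satisfy the stem-loop contract and are disjoint", {
  g <- generate_genome(80000, gc = 0.44, seed = 1)
  pl <- plant_hairpins(g, n = 20, stem_len = c(18, 25), loop_len = c(4, 15),
                       seed = 5)
  tr <- pl$truth$mirnas
  expect_equal(nrow(tr), 20)
  # disjoint precursor intervals
  o <- order(tr$start)
  expect_true(all(tr$start[o][-1] > tr$end[o][-20]))
  # every planted precursor folds into a passing hairpin with the mature
  # on one arm, and mature/star are arm substrings
  for (i in seq_len(nrow(tr))) {
    seqs <- substr(pl$genome[[tr$chrom[i]]], tr$start[i], tr$end[i])
    if (tr$strand[i] == "-") seqs <- revcomp(seqs)
    off <- regexpr(tr$mature_seq[i], seqs, fixed = TRUE)
    expect_gt(off, 0)
    expect_gt(regexpr(tr$star_seq[i], seqs, fixed = TRUE), 0)
    ev <- evaluate_hairpin(fold_hairpin(seqs), off,
                           off + nchar(tr$mature_seq[i]) - 1)
    expect_true(ev$pass)
  }
  # determinism
  expect_identical(pl, plant_hairpins(g, n = 20, stem_len = c(18, 25),
                                      loop_len = c(4, 15), seed = 5))
})

test_that("planting fails cleanly when the genome cannot host the request", {
  small <- c(chr1 = strrep("ACGT", 125))  # 500 bases
  expect_error(plant_hairpins(small, n = 1, stem_len = c(115, 120),
                              loop_len = c(10, 10), seed = 1),
               "too small")
})

test_that("simulated counts follow the design's means and fold changes", {
  # null design, Poisson: condition means agree within sampling error
  tr <- count_truth(sprintf("m%02d", 1:20))
  des <- sim_design(n_replicates = 2, library_depth = 100000,
                    nb_dispersion = 0, contaminant_fraction = 0, seed = 3)
  cnt <- simulate_counts(tr, des)
  cond <- attr(cnt, "condition")
  s_mean <- mean(colSums(cnt[, cond == "salt"]))
  c_mean <- mean(colSums(cnt[, cond == "control"]))
  expect_lt(abs(s_mean - c_mean) / c_mean, 0.02)

  # a single fold-8 miRNA among many nulls recovers its ratio within 20%
  tr8 <- count_truth(sprintf("m%03d", 1:200), fold_changes = c(8, rep(1, 199)))
  des8 <- sim_design(n_replicates = 2, library_depth = 500000,
                     nb_dispersion = 0, contaminant_fraction = 0, seed = 4)
  cnt8 <- simulate_counts(tr8, des8)
  cond8 <- attr(cnt8, "condition")
  ratio <- mean(cnt8[1, cond8 == "salt"]) / mean(cnt8[1, cond8 == "control"])
  expect_lt(abs(ratio - 8) / 8, 0.2)

  # degenerate abundance: all reads land on the only weighted miRNA
  tr1 <- count_truth(c("a", "b", "c"), base_abundance = c(0, 1, 0))
  cnt1 <- simulate_counts(tr1, des)
  expect_true(all(cnt1[c("a", "c"), ] == 0))
  expect_true(all(cnt1["b", ] > 0))
})

test_that("read synthesis round-trips through preprocessing", {
  g <- generate_genome(40000, gc = 0.44, seed = 2)
  pl <- plant_hairpins(g, n = 8, seed = 2)
  des <- sim_design(n_replicates = 2, library_depth = 4000,
                    nb_dispersion = 0, adapter3 = "", adapter5 = "",
                    contaminant_fraction = 0, seed = 2)
  cnt <- simulate_counts(pl$truth, des)
  dir <- withr::local_tempdir()
  paths <- synthesize_reads(cnt, pl$truth, des, dir = dir)
  tags <- collapse_tags(paths)
  # contaminant-free, adapter-free: per-library tag counts equal the matrix
  seq_of <- setNames(pl$truth$mirnas$mature_seq, pl$truth$mirnas$id)
  for (id in names(seq_of)) {
    row <- tags$counts[tags$tags$tag_id[tags$tags$sequence == seq_of[[id]]], ]
    expect_equal(unname(row[colnames(cnt)]), unname(cnt[id, ]))
  }
  expect_equal(sum(tags$counts), sum(cnt))

  # byte-identical FASTQ under a fixed seed
  dir2 <- withr::local_tempdir()
  paths2 <- synthesize_reads(cnt, pl$truth, des, dir = dir2)
  expect_identical(unname(tools::md5sum(paths)), unname(tools::md5sum(paths2)))
})

test_that("adapters and contaminants are planted as configured", {
  g <- generate_genome(40000, gc = 0.44, seed = 2)
  pl <- plant_hairpins(g, n = 8, seed = 2)
  ncrna <- synthetic_ncrna_refs(seed = 9)
  des <- sim_design(n_replicates = 1, library_depth = 5000,
                    nb_dispersion = 0, contaminant_fraction = 0.1, seed = 2)
  cnt <- simulate_counts(pl$truth, des)
  dir <- withr::local_tempdir()
  paths <- synthesize_reads(cnt, pl$truth, des, ncrna = unlist(ncrna),
                            dir = dir)
  reads <- Biostrings::readDNAStringSet(paths[1], format = "fastq")
  # every miRNA read carries the full 3' adapter; trimming restores lengths
  tr <- trim_adapters(as.character(reads), adapter3 = des$adapter3)
  expect_equal(tr$stats[["n_kept"]], length(reads))
  tags <- collapse_tags(list(S1 = tr$reads))
  ann <- annotate_ncrna(tags, ncrna)
  # read-weighted ncRNA fraction is close to the planted 10%
  is_nc <- !is.na(ann$category)
  frac <- sum(tags$tags$total_count[is_nc]) / sum(tags$tags$total_count)
  expect_lt(abs(frac - 0.1), 0.02)
  # every planted mature is recovered intact
  expect_true(all(pl$truth$mirnas$mature_seq %in% tags$tags$sequence))
})
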