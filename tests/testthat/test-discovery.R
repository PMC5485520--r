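test_that("conserved assignment follows the 2-mismatch rule", {
  ref <- c(famA = "UGAGCCGAACCAAUAUCACUC",  # RNA alphabet on purpose
           famB = "UUCCAAAGGGAUCGCAUUGAU")
  refT <- chartr("U", "T", ref)
  # identical tag: family, 0 mismatches
  a <- match_conserved(c(t1 = refT[["famA"]]), ref)
  expect_equal(a$family, "famA")
  expect_equal(a$mismatches, 0L)
  # two substitutions still match; three do not
  t2 <- refT[["famA"]]
  substr(t2, 1, 2) <- "CC"
  expect_equal(match_conserved(c(x = t2), ref)$mismatches, 2L)
  t3 <- refT[["famA"]]
  substr(t3, 1, 3) <- "CCC"
  expect_equal(nrow(match_conserved(c(x = t3), ref)), 0)
  # length +/- 1: overhang bases are not counted
  t4 <- paste0(refT[["famB"]], "A")
  expect_equal(match_conserved(c(x = t4), ref)$family, "famB")
  # ties are recorded and broken by reference order
  refdup <- c(first = ref[["famA"]], second = ref[["famA"]])
  td <- match_conserved(c(x = refT[["famA"]]), refdup)
  expect_true(td$tie)
  expect_equal(td$family, "first")
})

test_that("conserved assignment equals a brute-force Hamming scan", {
  set.seed(51)
  ref <- synthetic_mature_reference(n = 15, seed = 51, len_range = c(21, 21))
  refT <- chartr("U", "T", ref)
  tags <- character(200)
  for (i in 1:200) {
    if (i %% 2 == 0) {
      base <- refT[[sample(15, 1)]]
      nmut <- sample(0:4, 1)
      pos <- sample(21, nmut)
      ch <- strsplit(base, "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      tags[i] <- paste(ch, collapse = "")
    } else {
      tags[i] <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                       collapse = "")
    }
  }
  names(tags) <- sprintf("t%03d", 1:200)
  got <- match_conserved(tags, ref)
  for (i in 1:200) {
    mm <- vapply(refT, function(r) sum(utf8ToInt(tags[[i]]) != utf8ToInt(r)), 0)
    best <- min(mm)
    row <- got[got$tag_id == names(tags)[i], ]
    if (best <= 2) {
      expect_equal(row$mismatches, as.integer(best))
      expect_equal(row$family, names(refT)[which.min(mm)])
    } else {
      expect_equal(nrow(row), 0)
    }
  }
})

test_that("locus clustering chains hits under the 200 bp rule", {
  h <- data.frame(tag_id = c("a", "b"), chrom = "chr1",
                  start = c(100L, 250L), end = c(121L, 271L), strand = "+",
                  stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_loci(h)), 1)  # gap 150 < 200 joins
  h$start <- c(100L, 300L); h$end <- c(121L, 321L)
  expect_equal(nrow(cluster_loci(h)), 2)  # 200 is not < 200

  # equals connected components on 1000 random hits
  set.seed(52)
  hits <- data.frame(
    tag_id = sprintf("t%04d", 1:1000),
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    start = sample.int(50000, 1000, replace = TRUE),
    strand = sample(c("+", "-"), 1000, replace = TRUE),
    stringsAsFactors = FALSE)
  hits$end <- hits$start + 21L
  loci <- cluster_loci(hits)
  envs <- lapply(seq_len(nrow(loci)), function(i)
    c(loci$chrom[i], loci$strand[i], min(loci$members[[i]]$start),
      max(loci$members[[i]]$end)))
  envs <- unname(envs[order(vapply(envs, paste, "", collapse = ":"))])
  expect_equal(envs, lapply(bf_cluster_sets(hits), as.character))
})

test_that("precursor extraction adds flanks, clips, and respects strand", {
  g <- generate_genome(10000, gc = 0.5, seed = 53)
  locus <- list(chrom = "chr1", start = 500L, end = 522L, strand = "+")
  w <- extract_precursor(locus, g)
  expect_equal(c(w$start, w$end), c(300L, 722L))
  expect_equal(nchar(w$sequence), 422L)
  expect_false(w$clipped)

  near <- list(chrom = "chr1", start = 50L, end = 72L, strand = "+")
  wn <- extract_precursor(near, g)
  expect_equal(wn$start, 0L)
  expect_true(wn$clipped)

  minus <- list(chrom = "chr1", start = 500L, end = 522L, strand = "-")
  wm <- extract_precursor(minus, g)
  expect_equal(wm$sequence, revcomp(w$sequence))
})

test_that("a 14 bp stem passes the threshold and a 13 bp stem does not", {
  arm <- "GATTACAGATTACA"                       # 14 bp
  hp <- paste0(arm, "TTTTTT", revcomp(arm))
  seqs <- paste0(strrep("A", 20), hp, strrep("C", 20))
  ir <- find_inverted_repeats(seqs)
  expect_equal(nrow(ir), 1)
  expect_equal(ir$score, 42)                    # 14 x 3
  expect_equal(ir$matches, 14L)
  expect_equal(c(ir$start, ir$end), c(21L, 54L))

  arm13 <- substr(arm, 1, 13)                   # 39 < 40
  hp13 <- paste0(arm13, "TTTTTT", revcomp(arm13))
  expect_equal(nrow(find_inverted_repeats(
    paste0(strrep("A", 20), hp13, strrep("C", 20)))), 0)
})

test_that("inverted-repeat scores equal the exhaustive cut-point oracle", {
  set.seed(54)
  for (i in 1:60) {
    n <- sample(15:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    expect_equal(pkg_invrep_score(s), bf_invrep_score(s), info = s)
  }
})

test_that("repeat extension pads and clips without changing the alignment", {
  ir <- data.frame(start = 50L, end = 150L, score = 60)
  expect_equal(extend_repeat(ir, 400), list(start = 40L, end = 160L))
  ir2 <- data.frame(start = 5L, end = 150L, score = 60)
  expect_equal(extend_repeat(ir2, 155)$start, 1L)
  expect_equal(extend_repeat(ir2, 155)$end, 155L)
})

test_that("folding maximizes pair weight with deterministic structures", {
  st <- fold_hairpin("GGGGAAAACCCC")
  expect_equal(st$dotbracket, "((((....))))")
  expect_equal(st$n_pairs, 4L)
  expect_equal(st$weight, 12L)                 # 4 GC pairs x 3
  expect_equal(st$mfe_proxy, -12L)
  expect_equal(fold_hairpin("AAAAAAA")$dotbracket, ".......")

  # optimal weight equals structure enumeration on random short sequences
  set.seed(55)
  for (i in 1:40) {
    n <- sample(10:14, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    expect_equal(fold_hairpin(s)$weight, bf_fold_weight(s), info = s)
  }
})

test_that("folding weight is monotone under complementary flanking", {
  set.seed(56)
  for (i in 1:20) {
    n <- sample(15:40, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    w0 <- fold_hairpin(s)$weight
    flank <- paste(sample(c("G", "C", "A", "T"), 6, replace = TRUE),
                   collapse = "")
    w1 <- fold_hairpin(paste0(flank, s, revcomp(flank)))$weight
    expect_gte(w1, w0)
  }
})

test_that("hairpin evaluation reports each violated criterion", {
  arm <- "GATTACAGATTACAGATTACAG"               # 22 bp perfect stem
  hp <- paste0(strrep("A", 10), arm, "TTTTTT", revcomp(arm), strrep("A", 10))
  st <- fold_hairpin(hp)
  m0 <- 11L                                     # mature = whole arm
  ev <- evaluate_hairpin(st, m0, m0 + 21L)
  expect_true(ev$pass)

  # mature straddling the terminal loop
  ev2 <- evaluate_hairpin(st, 25L, 44L)
  expect_false(ev2$pass)
  expect_true("mature_arm" %in% ev2$reasons)

  # a bulged arm with 5 unpaired mature positions fails the pairing rule
  hp3 <- paste0(strrep("A", 10), substr(arm, 1, 10), "GGGGG",
                substr(arm, 11, 22), "TTTTTT", revcomp(arm), strrep("A", 10))
  st3 <- fold_hairpin(hp3)
  ev3 <- evaluate_hairpin(st3, 11L, 11L + 26L)  # arm + inserted GGGGG
  expect_false(ev3$pass)
  expect_true(any(c("unpaired", "consecutive_unpaired", "bulge", "mature_arm")
                  %in% ev3$reasons))

  # a short hairpin fails the length floor
  short_arm <- "GCGCGCGCGATATATATAT"
  short_hp <- paste0(short_arm, "AAAA", revcomp(short_arm))  # 42 nt
  ev4 <- evaluate_hairpin(fold_hairpin(short_hp), 1L, 19L)
  expect_false(ev4$pass)
  expect_true("hairpin_length" %in% ev4$reasons)

  # mature outside the structure is an error, not a fail
  expect_error(evaluate_hairpin(st, 200L, 220L), "outside")
})

test_that("novel calling recovers planted matures and deduplicates loci", {
  g <- generate_genome(60000, gc = 0.44, seed = 57)
  pl <- plant_hairpins(g, n = 10, seed = 157)
  tr <- pl$truth$mirnas
  reads <- rep(tr$mature_seq, each = 30)
  tags <- collapse_tags(list(S1 = reads))
  idx <- build_index(pl$genome, k = 12)
  hits <- map_tags(tags, idx)
  nov <- call_novel(tags, hits, pl$genome)
  expect_true(all(tr$mature_seq %in% nov$records$mature_seq))
  # ids are assigned by decreasing abundance deterministically
  expect_equal(nov$records$id, sprintf("novel-%d", seq_len(nrow(nov$records))))

  # two loci sharing one mature collapse to one record with two precursors
  m <- tr[1, ]
  ins <- substr(pl$genome[[m$chrom]], m$start, m$end)
  g2 <- pl$genome
  # copy the full precursor elsewhere (far from any planted locus)
  bare <- generate_genome(20000, gc = 0.44, seed = 58)[[1]]
  g2 <- c(g2, chr2 = paste0(substr(bare, 1, 5000), ins,
                            substr(bare, 5001, 10000)))
  idx2 <- build_index(g2, k = 12)
  hits2 <- map_tags(tags, idx2)
  nov2 <- call_novel(tags, hits2, g2)
  rec <- nov2$records[nov2$records$mature_seq == m$mature_seq, ]
  expect_equal(nrow(rec), 1)
  expect_equal(sum(nov2$precursors$id == rec$id), 2)

  # a hairpin-free genome with mapped tags yields no records
  g0 <- generate_genome(30000, gc = 0.44, seed = 59)
  set.seed(59)
  pos <- sample(25000, 40)
  ctags <- collapse_tags(list(S1 = rep(substring(g0[[1]], pos, pos + 20), 3)))
  idx0 <- build_index(g0, k = 12)
  nov0 <- call_novel(ctags, map_tags(ctags, idx0), g0)
  expect_equal(nrow(nov0$records), 0)
})

test_that("conserved records aggregate family counts", {
  ref <- synthetic_mature_reference(n = 5, seed = 60, len_range = c(21, 21))
  refT <- chartr("U", "T", ref)
  reads <- c(rep(refT[[1]], 10), rep(refT[[2]], 3))
  # add a 1-mismatch variant of family 1
  v <- refT[[1]]; substr(v, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                             substr(v, 5, 5))[1]
  tags <- collapse_tags(list(S1 = c(reads, rep(v, 2))))
  asg <- match_conserved(tags, ref)
  cons <- call_conserved(tags, asg)
  expect_equal(nrow(cons$records), 2)
  r1 <- cons$records[cons$records$family == names(ref)[1], ]
  expect_equal(r1$total_count, 12L)            # 10 exact + 2 variant
  expect_equal(r1$mature_seq, refT[[1]])       # most abundant tag represents
})
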