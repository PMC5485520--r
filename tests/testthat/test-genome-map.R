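test_that("the k-mer index stores every genomic word", {
  idx <- build_index(c(chr1 = "ACGTACGT"), k = 4)
  hit <- lookup_kmer(idx, "ACGT")
  expect_equal(hit$pos, c(0, 4))
  expect_equal(nrow(lookup_kmer(idx, "GGGG")), 0)
  expect_error(build_index(c(chr1 = "ACGTACGT"), k = 3), "k must be")

  # agreement with a naive scan on random queries
  set.seed(21)
  g <- generate_genome(5000, gc = 0.5, seed = 21)
  idx <- build_index(g, k = 8)
  for (i in 1:50) {
    q <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    naive <- which(substring(g[[1]], 1:(nchar(g[[1]]) - 7),
                             8:nchar(g[[1]])) == q) - 1L
    expect_equal(lookup_kmer(idx, q)$pos, naive)
  }
})

test_that("mapping reports all exact hits on both strands", {
  g <- generate_genome(5000, gc = 0.5, seed = 33)
  idx <- build_index(g, k = 12)
  # a tag lifted from the genome maps back uniquely (almost surely)
  tag_plus <- substr(g[[1]], 1001, 1021)
  h <- map_tags(c(t1 = tag_plus), idx)
  expect_true(any(h$start == 1000 & h$strand == "+"))
  # its reverse complement maps to the same interval on the minus strand
  h2 <- map_tags(c(t1 = revcomp(tag_plus)), idx)
  expect_true(any(h2$start == 1000 & h2$strand == "-"))

  # strand symmetry: intervals equal, strands flipped
  hs <- h[, c("chrom", "start", "end")]
  hs2 <- h2[, c("chrom", "start", "end")]
  expect_equal(hs[order(hs$start), ], hs2[order(hs2$start), ],
               ignore_attr = TRUE)

  # full agreement with the exhaustive scan oracle on 100 random tags
  set.seed(34)
  tags <- character(100)
  for (i in 1:100) {
    if (i %% 2 == 0) {
      p <- sample(nchar(g[[1]]) - 21, 1)
      tags[i] <- substr(g[[1]], p, p + 20)
      if (i %% 4 == 0) tags[i] <- revcomp(tags[i])
    } else {
      tags[i] <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                       collapse = "")
    }
  }
  names(tags) <- sprintf("t%03d", 1:100)
  got <- map_tags(tags, idx)
  for (i in 1:100) {
    want <- bf_map(tags[[i]], g)
    have <- got[got$tag_id == names(tags)[i],
                c("chrom", "start", "end", "strand")]
    have <- have[order(have$chrom, have$start, have$strand), , drop = FALSE]
    expect_equal(unname(as.matrix(have)), unname(as.matrix(want)))
  }
})

test_that("ncRNA annotation assigns classes by substring match with priority", {
  refs <- synthetic_ncrna_refs(seed = 40)
  frag <- substr(refs$rRNA[[1]], 10, 30)
  ann <- annotate_ncrna(c(t1 = frag), refs)
  expect_equal(ann$category, "rRNA")
  # minus-strand fragments are found too
  ann2 <- annotate_ncrna(c(t1 = revcomp(frag)), refs)
  expect_equal(ann2$category, "rRNA")
  # a tag present in both rRNA and tRNA references takes the higher class
  shared <- substr(refs$tRNA[[1]], 1, 22)
  refs2 <- refs
  refs2$rRNA <- c(refs2$rRNA, planted = paste0("AAAA", shared, "TTTT"))
  ann3 <- annotate_ncrna(c(t1 = shared), refs2)
  expect_equal(ann3$category, "rRNA")
  # empty reference class assigns nothing
  ann4 <- annotate_ncrna(c(t1 = frag), list(tRNA = character()))
  expect_true(is.na(ann4$category))
})

test_that("residual classification follows the repeat and count boundaries", {
  # build a genome carrying a 21-mer exactly 21 times and another 20 times
  set.seed(41)
  rep21 <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  rep20 <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  once <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  spacer <- function() paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                             collapse = "")
  g <- c(chr1 = paste0(
    paste(vapply(1:21, function(i) paste0(rep21, spacer()), ""), collapse = ""),
    paste(vapply(1:20, function(i) paste0(rep20, spacer()), ""), collapse = ""),
    once, spacer()))
  tags <- collapse_tags(list(L = c(rep(rep21, 5), rep(rep20, 5), once)))
  idx <- build_index(g, k = 12)
  hits <- map_tags(tags, idx)
  cl <- classify_tags(tags, hits)
  by_seq <- setNames(cl$category, tags$tags$sequence[match(cl$tag_id, tags$tags$tag_id)])
  expect_equal(unname(by_seq[rep21]), "high_repeat")   # 21 hits > 20
  expect_equal(unname(by_seq[rep20]), "candidate")     # 20 hits, count 5
  expect_equal(unname(by_seq[once]), "low_expression") # count 1
})
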