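# Independent brute-force oracles used to verify the dynamic-programming
# and scanning implementations.  These deliberately use different
# decompositions from the package code.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

rc_chars <- function(ch) rev(unname(COMP[ch]))

# Best inverted-repeat score by exhaustive cut-point Smith-Waterman:
# for every cut, locally align the prefix against the reverse complement
# of the suffix (match/mismatch/linear gap), and take the best cell over
# all cuts.  Equivalent search space to the banded stem DP when the
# sequence is shorter than the span bound.
bf_invrep_score <- function(s, match = 3, mismatch = -3, gap = 6) {
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  best <- 0
  for (cut in 1:(n - 1)) {
    x <- ch[1:cut]
    y <- rc_chars(ch[(cut + 1):n])
    nx <- length(x); ny <- length(y)
    prev <- numeric(ny + 1)
    for (i in 1:nx) {
      sc <- ifelse(x[i] == y, match, mismatch)
      tmp <- pmax(0, prev[1:ny] + sc, prev[2:(ny + 1)] - gap)
      cur <- numeric(ny + 1)
      run <- 0
      for (k in 1:ny) {
        run <- max(tmp[k], run - gap)
        cur[k + 1] <- run
      }
      best <- max(best, cur)
      prev <- cur
    }
  }
  max(best)
}

# package-side best score over all repeats (threshold 1 reports anything
# with at least one net pair)
pkg_invrep_score <- function(s, ...) {
  r <- find_inverted_repeats(s, threshold = 1, ...)
  if (nrow(r) == 0) 0 else max(r$score)
}

# Maximum folding weight by recursion on the 5' end (i unpaired, or i
# paired with k), no memoization: a different decomposition from the
# package's Nussinov fill on the 3' end.
bf_fold_weight <- function(s, min_loop = 3) {
  ch <- strsplit(toupper(chartr("U", "T", s)), "")[[1]]
  w <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
    0
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      wk <- w(ch[i], ch[k])
      if (wk > 0)
        best <- max(best, wk + rec(i + 1, k - 1) +
                      if (k < j) rec(k + 1, j) else 0)
    }
    best
  }
  if (length(ch) < min_loop + 2) return(0)
  rec(1, length(ch))
}

# Sliding-window target-site oracle (character-wise comparison).
bf_target_hits <- function(mature, tx, max_mm = 3, protected = c(10, 11)) {
  m <- strsplit(toupper(mature), "")[[1]]
  L <- length(m)
  site <- rc_chars(m)  # expected transcript slice = revcomp(mature)
  t <- strsplit(toupper(tx), "")[[1]]
  out <- list()
  if (length(t) < L) return(out)
  for (s in 0:(length(t) - L)) {
    slice <- t[(s + 1):(s + L)]
    mirpos <- sort(L - which(slice != site) + 1L)
    if (length(mirpos) <= max_mm && !any(mirpos %in% protected))
      out[[length(out) + 1L]] <- list(offset = s, n = length(mirpos),
                                      pos = mirpos)
  }
  out
}

# Exhaustive exact-match mapper over every offset of every chromosome.
bf_map <- function(tag, genome) {
  out <- list()
  for (ch in names(genome)) {
    g <- genome[[ch]]; L <- nchar(tag)
    if (nchar(g) < L) next
    offs <- 0:(nchar(g) - L)
    sub <- substring(g, offs + 1L, offs + L)
    for (str in c("+", "-")) {
      q <- if (str == "+") tag else revcomp(tag)
      for (p in offs[sub == q])
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = p, end = p + L, strand = str,
          stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), strand = character())
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

# Connected-components clustering oracle: hits are adjacent when they share
# chromosome and strand and their starts differ by less than max_gap.
bf_cluster_sets <- function(hits, max_gap = 200) {
  n <- nrow(hits)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    hits$chrom[i] == hits$chrom[j] & hits$strand[i] == hits$strand[j] &
      abs(hits$start[i] - hits$start[j]) < max_gap)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  # canonical form: sorted envelopes per component
  envs <- lapply(split(seq_len(n), comp), function(ix)
    c(hits$chrom[ix][1], hits$strand[ix][1],
      min(hits$start[ix]), max(hits$end[ix])))
  unname(envs[order(vapply(envs, paste, "", collapse = ":"))])
}

# small convenience: build a tag_set from explicit per-library reads
make_tags <- function(...) collapse_tags(list(...))
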