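#' Assign tags to conserved miRNA families
#'
#' Compares each tag against a mature miRNA reference set (miRBase-style,
#' U normalized to T) by ungapped end-to-end Hamming comparison.  Only
#' references within +/- 1 nt of the tag length are considered; when the
#' lengths differ by 1 the two possible ungapped alignments covering the
#' shorter sequence are tried and overhang bases are not counted.  The tag
#' is assigned to the reference with the fewest mismatches; no assignment
#' if the best exceeds `max_mismatches`.  Ties are broken by reference
#' order and recorded.
#'
#' @param tags named character vector of tag sequences, or a `tag_set`.
#' @param mature_ref named character vector of mature reference sequences
#'   (U or T alphabet).
#' @param max_mismatches maximum mismatches for an assignment (default 2).
#' @return data.frame `tag_id`, `family`, `mismatches`, `tie` (logical);
#'   one row per tag with a qualifying assignment.
#' @export
match_conserved <- function(tags, mature_ref, max_mismatches = 2L) {
  if (inherits(tags, "tag_set"))
    tags <- stats::setNames(tags$tags$sequence, tags$tags$tag_id)
  if (is.null(names(tags))) names(tags) <- paste0("tag", seq_along(tags))
  mature_ref <- normalize_u(mature_ref)
  tags <- normalize_u(tags)
  ref_len <- nchar(mature_ref)
  out <- vector("list", length(tags))
  for (ti in seq_along(tags)) {
    tag <- tags[[ti]]
    L <- nchar(tag)
    cand <- which(abs(ref_len - L) <= 1L)
    if (!length(cand)) next
    best_mm <- Inf; best_ref <- NA_integer_; tie <- FALSE
    for (ri in cand) {
      ref <- mature_ref[[ri]]; RL <- ref_len[ri]
      if (RL == L) {
        mm <- hamming(tag, ref)
      } else if (RL < L) {
        # tag overhangs by one base on one end; overhang uncounted
        mm <- min(hamming(substr(tag, 1L, RL), ref),
                  hamming(substr(tag, 2L, L), ref))
      } else {
        mm <- min(hamming(tag, substr(ref, 1L, L)),
                  hamming(tag, substr(ref, 2L, RL)))
      }
      if (mm < best_mm) {
        best_mm <- mm; best_ref <- ri; tie <- FALSE
      } else if (mm == best_mm) tie <- TRUE
    }
    if (best_mm <= max_mismatches)
      out[[ti]] <- data.frame(tag_id = names(tags)[ti],
                              family = names(mature_ref)[best_ref],
                              mismatches = as.integer(best_mm), tie = tie,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(tag_id = character(), family = character(),
                      mismatches = integer(), tie = logical(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Cluster genomic hits into candidate loci
#'
#' Single-linkage chaining: consecutive hits on the same chromosome and
#' strand whose start-to-start distance is strictly less than `max_gap`
#' join one locus.
#'
#' @param hits a [map_tags()] result (any data.frame with `tag_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param max_gap clustering distance in bp (default 200).
#' @return data.frame, one row per locus: `locus_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open envelope) and a list column
#'   `members` of per-locus hit data.frames.
#' @export
cluster_loci <- function(hits, max_gap = 200L) {
  if (nrow(hits) == 0)
    return(data.frame(locus_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      n_tags = integer(), stringsAsFactors = FALSE))
  h <- hits[order(hits$chrom, hits$strand, hits$start), , drop = FALSE]
  new_grp <- c(TRUE, h$chrom[-1] != h$chrom[-nrow(h)] |
                     h$strand[-1] != h$strand[-nrow(h)] |
                     (h$start[-1] - h$start[-nrow(h)]) >= max_gap)
  grp <- cumsum(new_grp)
  idx <- split(seq_len(nrow(h)), grp)
  loci <- lapply(seq_along(idx), function(g) {
    rows <- h[idx[[g]], , drop = FALSE]
    data.frame(locus_id = sprintf("locus%05d", g), chrom = rows$chrom[1],
               strand = rows$strand[1], start = min(rows$start),
               end = max(rows$end), n_tags = length(unique(rows$tag_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  out$members <- I(lapply(idx, function(i) h[i, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Extract a precursor candidate window around a locus
#'
#' Takes the locus envelope plus `flank` nt on both sides, clipped at the
#' chromosome bounds, and orients the sequence by strand (minus-strand loci
#' are reverse complemented).
#'
#' @param locus one row of a [cluster_loci()] result (or any list with
#'   `chrom`, `start`, `end`, `strand`; 0-based half-open).
#' @param genome named character vector (or DNAStringSet).
#' @param flank bases added on each side (default 200).
#' @return list: `chrom`, `start`, `end` (0-based half-open window on the
#'   plus strand), `strand`, `sequence` (oriented), `clipped` flag.
#' @export
extract_precursor <- function(locus, genome, flank = 200L) {
  genome <- as_genome(genome)
  g <- genome[[locus$chrom]]
  glen <- nchar(g)
  start <- max(0L, locus$start - flank)
  end <- min(glen, locus$end + flank)
  clipped <- (locus$start - flank < 0L) || (locus$end + flank > glen)
  seq <- substr(g, start + 1L, end)
  if (locus$strand == "-") seq <- revcomp(seq)
  list(chrom = locus$chrom, start = start, end = end,
       strand = locus$strand, sequence = seq, clipped = clipped)
}

#' Find inverted repeats by banded local dynamic programming
#'
#' Aligns the sequence against its own downstream reverse complement
#' (EMBOSS einverted style): Watson-Crick matches score `match`,
#' mismatches `mismatch` (G.T is a mismatch on the DNA alphabet), every
#' gapped base costs `gap_penalty`, and the whole repeat (both arms plus
#' loop) spans at most `max_span` bases.  All repeats scoring at least
#' `threshold` are reported after pruning mutually overlapping repeats to
#' score-maximal ones (ties: leftmost start, then shortest span).
#'
#' @param sequence a DNA string.
#' @param threshold minimum reported score (default 40).
#' @param match,mismatch,gap_penalty alignment scores (defaults 3, -3, 6).
#' @param max_span maximum repeat length (default 240).
#' @return data.frame with 1-based inclusive coordinates: `start`, `end`
#'   (outer repeat boundary), `left_end`, `right_start` (inner arm
#'   boundaries; the loop lies between them), `score`, `matches`,
#'   `mismatches`, `gaps`.
#' @export
find_inverted_repeats <- function(sequence, threshold = 40, match = 3,
                                  mismatch = -3, gap_penalty = 6,
                                  max_span = 240L) {
  sequence <- normalize_u(sequence)
  res <- .invrep_dp(sequence, match, mismatch, gap_penalty,
                    as.integer(max_span), threshold)
  # deterministic report order: by score desc, then leftmost, then shortest
  res[order(-res$score, res$start, res$end - res$start), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Extend an inverted repeat by a fixed pad
#'
#' @param ir one row of a [find_inverted_repeats()] result.
#' @param seq_length length of the parent sequence (for clipping).
#' @param pad bases added on each side (default 10).
#' @return list `start`, `end` (1-based inclusive, clipped).
#' @export
extend_repeat <- function(ir, seq_length, pad = 10L) {
  list(start = max(1L, as.integer(ir$start) - pad),
       end = min(as.integer(seq_length), as.integer(ir$end) + pad))
}

#' Fold a candidate hairpin by maximum weighted base pairing
#'
#' Nussinov-style maximization of total pair weight (G-C = 3, A-U = 2,
#' G-U = 1) over nested structures with at least `min_loop` unpaired bases
#' in every hairpin loop.  This is a deterministic, brute-force-verifiable
#' pairing model, not a thermodynamic free-energy model; `mfe_proxy` is
#' the negated pair weight and is labelled accordingly.
#'
#' @param sequence DNA or RNA string (at most 700 nt).
#' @param min_loop minimum hairpin loop length (default 3).
#' @return object of class `hairpin_structure`: list with `sequence`,
#'   `dotbracket`, `pairing` (0 = unpaired, else 1-based partner),
#'   `n_pairs`, `weight`, `mfe_proxy`.
#' @export
fold_hairpin <- function(sequence, min_loop = 3L) {
  sequence <- normalize_u(sequence)
  if (nchar(sequence) > 700) stop("fold_hairpin: sequence longer than 700 nt")
  res <- .fold_dp(sequence, as.integer(min_loop))
  pairing <- res$pairing
  db <- rep(".", length(pairing))
  db[pairing > seq_along(pairing)] <- "("
  db[pairing != 0 & pairing < seq_along(pairing)] <- ")"
  structure(list(sequence = sequence,
                 dotbracket = paste(db, collapse = ""),
                 pairing = pairing,
                 n_pairs = sum(pairing > 0) %/% 2L,
                 weight = res$weight,
                 mfe_proxy = -res$weight),
            class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  cat(sprintf("%d pairs, weight %d (mfe_proxy %d, non-thermodynamic)\n",
              x$n_pairs, x$weight, x$mfe_proxy))
  invisible(x)
}

#' Default stem-loop acceptance criteria
#'
#' @param mature_len_range allowed mature length (default 18-25 nt).
#' @param max_unpaired maximum unpaired mature positions (default 4).
#' @param max_consecutive_unpaired maximum run of consecutive unpaired
#'   mature positions (default 2).
#' @param bulge_size an asymmetric bulge in the mature/star duplex is
#'   "large" when its asymmetry exceeds this many nt (default 2).
#' @param max_large_bulges maximum number of large asymmetric bulges
#'   (default 1).
#' @param min_hairpin_len minimum hairpin length in nt (default 60).
#' @return named list of criteria.
#' @export
hairpin_criteria <- function(mature_len_range = c(18L, 25L),
                             max_unpaired = 4L,
                             max_consecutive_unpaired = 2L,
                             bulge_size = 2L,
                             max_large_bulges = 1L,
                             min_hairpin_len = 60L) {
  list(mature_len_range = mature_len_range, max_unpaired = max_unpaired,
       max_consecutive_unpaired = max_consecutive_unpaired,
       bulge_size = bulge_size, max_large_bulges = max_large_bulges,
       min_hairpin_len = min_hairpin_len)
}

#' Evaluate a candidate mature placement on a folded hairpin
#'
#' MirCheck-style criteria, all of which must hold:
#' (a) the mature is 18-25 nt and lies entirely on one arm (no base pair
#' joins two mature positions, i.e. the mature does not straddle the
#' terminal loop); (b) at most 4 mature positions are unpaired; (c) at
#' most 2 consecutive mature positions are unpaired; (d) at most one
#' asymmetric bulge larger than 2 nt in the mature/star duplex; (e) the
#' hairpin is at least 60 nt.  The mature/star duplex is read off the
#' dominant partner side; occasional stray pairs between mature edge bases
#' and flanking context (an artifact of greedy weight-maximizing folding)
#' count as unpaired rather than as evidence of a second arm.
#'
#' @param structure a [fold_hairpin()] result.
#' @param mature_start,mature_end 1-based inclusive mature interval on the
#'   structure's sequence.
#' @param criteria a [hairpin_criteria()] list.
#' @return list `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty when passing).
#' @export
evaluate_hairpin <- function(structure, mature_start, mature_end,
                             criteria = hairpin_criteria()) {
  stopifnot(inherits(structure, "hairpin_structure"))
  n <- nchar(structure$sequence)
  if (mature_start < 1 || mature_end > n || mature_start > mature_end)
    stop("mature interval lies outside the structure")
  reasons <- character()
  mlen <- mature_end - mature_start + 1L
  pairing <- structure$pairing
  idx <- mature_start:mature_end
  partners <- pairing[idx]

  # the mature/star duplex is read off the dominant partner side; stray
  # pairs to the opposite side (greedy folding of flanking context) are
  # treated as unpaired
  left <- partners != 0L & partners < mature_start
  right <- partners != 0L & partners > mature_end
  duplex_side <- if (sum(right) >= sum(left)) "right" else "left"
  paired <- if (duplex_side == "right") right else left

  # (a) length window and single-arm placement (no pair may join two
  # mature positions, i.e. the mature must not straddle the terminal loop)
  straddles <- any(partners >= mature_start & partners <= mature_end)
  arm_ok <- mlen >= criteria$mature_len_range[1] &&
    mlen <= criteria$mature_len_range[2] && !straddles
  if (!arm_ok) reasons <- c(reasons, "mature_arm")

  # (b) unpaired mature positions
  if (sum(!paired) > criteria$max_unpaired)
    reasons <- c(reasons, "unpaired")

  # (c) longest run of consecutive unpaired positions
  runs <- rle(!paired)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (max_run > criteria$max_consecutive_unpaired)
    reasons <- c(reasons, "consecutive_unpaired")

  # (d) asymmetric bulges between consecutive paired mature positions
  if (sum(paired) >= 2) {
    pi <- idx[paired]; pp <- partners[paired]
    gap_m <- diff(pi) - 1L
    gap_s <- abs(diff(pp)) - 1L
    n_large <- sum(abs(gap_m - gap_s) > criteria$bulge_size)
    if (n_large > criteria$max_large_bulges)
      reasons <- c(reasons, "bulge")
  }

  # (e) hairpin length
  if (n < criteria$min_hairpin_len)
    reasons <- c(reasons, "hairpin_length")

  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Would this window yield a qualifying hairpin for a given mature?
#'
#' Mirrors [call_novel()]'s per-locus logic: find inverted repeats in the
#' window, extend each by `pad`, fold, place the mature, and evaluate the
#' stem-loop criteria.  Used by the synthetic generator to vet planted
#' precursors in their genomic context, and to construct verified
#' hairpin-free negative controls (random DNA does contain chance
#' inverted repeats, so "hairpin-free" is a property to check, not to
#' assume).
#'
#' @param window_seq the (oriented) candidate window sequence.
#' @param mature the mature sequence to place.
#' @param threshold,match,mismatch,gap_penalty,max_span,pad,min_loop,criteria
#'   as in [call_novel()].
#' @return `TRUE` if any repeat yields a passing hairpin containing the
#'   mature.
#' @export
window_yields_hairpin <- function(window_seq, mature, threshold = 40,
                                  match = 3, mismatch = -3, gap_penalty = 6,
                                  max_span = 240L, pad = 10L, min_loop = 3L,
                                  criteria = hairpin_criteria()) {
  irs <- find_inverted_repeats(window_seq, threshold = threshold,
                               match = match, mismatch = mismatch,
                               gap_penalty = gap_penalty, max_span = max_span)
  for (ri in seq_len(nrow(irs))) {
    ext <- extend_repeat(irs[ri, ], nchar(window_seq), pad = pad)
    cand <- substr(window_seq, ext$start, ext$end)
    if (nchar(cand) > 700) next
    off <- regexpr(mature, cand, fixed = TRUE)
    if (off < 0) next
    st <- fold_hairpin(cand, min_loop = min_loop)
    ev <- evaluate_hairpin(st, off, off + nchar(mature) - 1L,
                           criteria = criteria)
    if (ev$pass) return(TRUE)
  }
  FALSE
}

#' Call novel miRNAs from clustered loci
#'
#' For each locus: extract the flanked precursor window, find inverted
#' repeats, extend each repeat by `pad` nt, fold it, place the most
#' abundant member tag found in the candidate, and evaluate the stem-loop
#' criteria.  The first (highest-scoring) passing candidate yields the
#' locus's record.  Identical matures across loci collapse to one record
#' with multiple precursors; novel ids are assigned in decreasing total
#' count (ties by sequence), so output is deterministic.
#'
#' @param tags a `tag_set`.
#' @param hits a [map_tags()] result restricted to candidate tags (the
#'   caller excludes ncRNA/repeat/low-expression/conserved tags).
#' @param genome named character vector (or DNAStringSet).
#' @param max_gap locus clustering distance (default 200 bp).
#' @param flank precursor extraction flank (default 200 nt).
#' @param threshold,match,mismatch,gap_penalty,max_span inverted-repeat
#'   parameters (defaults 40, 3, -3, 6, 240).
#' @param pad repeat extension (default 10 nt).
#' @param min_loop folding minimum loop (default 3).
#' @param criteria a [hairpin_criteria()] list.
#' @return list with `records` (data.frame: `id`, `mature_seq`,
#'   `mature_tag_id`, `kind`, `family`, `total_count`), `precursors`
#'   (data.frame: `id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `sequence`, `dotbracket`, `score`, `mature_offset`), and
#'   `counts` (matrix, per-library counts of the mature tags).
#' @export
call_novel <- function(tags, hits, genome, max_gap = 200L, flank = 200L,
                       threshold = 40, match = 3, mismatch = -3,
                       gap_penalty = 6, max_span = 240L, pad = 10L,
                       min_loop = 3L, criteria = hairpin_criteria()) {
  stopifnot(inherits(tags, "tag_set"))
  genome <- as_genome(genome)
  loci <- cluster_loci(hits, max_gap = max_gap)
  count_of <- stats::setNames(tags$tags$total_count, tags$tags$tag_id)
  seq_of <- stats::setNames(tags$tags$sequence, tags$tags$tag_id)
  found <- list()
  for (li in seq_len(nrow(loci))) {
    locus <- loci[li, ]
    win <- extract_precursor(locus, genome, flank = flank)
    irs <- find_inverted_repeats(win$sequence, threshold = threshold,
                                 match = match, mismatch = mismatch,
                                 gap_penalty = gap_penalty,
                                 max_span = max_span)
    if (nrow(irs) == 0) next
    member_ids <- unique(loci$members[[li]]$tag_id)
    member_ids <- member_ids[order(-count_of[member_ids], seq_of[member_ids])]
    for (ri in seq_len(nrow(irs))) {
      ext <- extend_repeat(irs[ri, ], nchar(win$sequence), pad = pad)
      cand <- substr(win$sequence, ext$start, ext$end)
      if (nchar(cand) > 700) next
      placed <- NULL
      for (tid in member_ids) {
        off <- regexpr(seq_of[[tid]], cand, fixed = TRUE)
        if (off > 0) { placed <- list(tag_id = tid, offset = as.integer(off)); break }
      }
      if (is.null(placed)) next
      st <- fold_hairpin(cand, min_loop = min_loop)
      mlen <- nchar(seq_of[[placed$tag_id]])
      ev <- evaluate_hairpin(st, placed$offset, placed$offset + mlen - 1L,
                             criteria = criteria)
      if (!ev$pass) next
      # map candidate interval back to plus-strand genome coordinates
      if (win$strand == "+") {
        gstart <- win$start + ext$start - 1L
        gend <- win$start + ext$end
      } else {
        gstart <- win$end - ext$end
        gend <- win$end - ext$start + 1L
      }
      found[[length(found) + 1L]] <- list(
        tag_id = placed$tag_id, mature_seq = seq_of[[placed$tag_id]],
        chrom = win$chrom, start = gstart, end = gend, strand = win$strand,
        sequence = cand, dotbracket = st$dotbracket,
        score = irs$score[ri], mature_offset = placed$offset)
      break
    }
  }
  if (!length(found)) {
    return(list(records = data.frame(id = character(), mature_seq = character(),
                                     mature_tag_id = character(),
                                     kind = character(), family = character(),
                                     total_count = integer(),
                                     stringsAsFactors = FALSE),
                precursors = data.frame(id = character(), chrom = character(),
                                        start = integer(), end = integer(),
                                        strand = character(),
                                        sequence = character(),
                                        dotbracket = character(),
                                        score = numeric(),
                                        mature_offset = integer(),
                                        stringsAsFactors = FALSE),
                counts = tags$counts[0, , drop = FALSE]))
  }
  mature_seqs <- vapply(found, `[[`, "", "mature_seq")
  uniq <- unique(mature_seqs)
  tot <- count_of[vapply(found, `[[`, "", "tag_id")[match(uniq, mature_seqs)]]
  ord <- order(-tot, uniq)
  uniq <- uniq[ord]
  ids <- sprintf("novel-%d", seq_along(uniq))
  id_of <- stats::setNames(ids, uniq)
  records <- data.frame(
    id = ids, mature_seq = uniq,
    mature_tag_id = vapply(uniq, function(s)
      found[[match(s, mature_seqs)]]$tag_id, ""),
    kind = "novel", family = NA_character_,
    total_count = as.integer(tot[ord]), stringsAsFactors = FALSE)
  precursors <- do.call(rbind, lapply(found, function(f)
    data.frame(id = id_of[[f$mature_seq]], chrom = f$chrom, start = f$start,
               end = f$end, strand = f$strand, sequence = f$sequence,
               dotbracket = f$dotbracket, score = f$score,
               mature_offset = f$mature_offset, stringsAsFactors = FALSE)))
  # one genomic hairpin can surface as two stranded loci (the mature maps
  # on one arm, its star image on the other); collapse precursors of the
  # same miRNA that overlap on the genome, keeping the higher score
  # (ties: plus strand, then leftmost)
  precursors <- precursors[order(precursors$id, -precursors$score,
                                 precursors$strand, precursors$start), ,
                           drop = FALSE]
  keep <- rep(TRUE, nrow(precursors))
  for (i in seq_len(nrow(precursors))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(precursors)) > i &
                     precursors$id == precursors$id[i] &
                     precursors$chrom == precursors$chrom[i] &
                     precursors$start < precursors$end[i] &
                     precursors$end > precursors$start[i])
    keep[later] <- FALSE
  }
  precursors <- precursors[keep, , drop = FALSE]
  precursors <- precursors[order(match(precursors$id, ids),
                                 precursors$chrom, precursors$start), ,
                           drop = FALSE]
  rownames(records) <- rownames(precursors) <- NULL
  counts <- tags$counts[records$mature_tag_id, , drop = FALSE]
  rownames(counts) <- records$id
  list(records = records, precursors = precursors, counts = counts)
}

#' Assemble conserved miRNA records from family assignments
#'
#' One record per matched family: the most abundant assigned tag is the
#' representative mature; per-library counts aggregate all tags assigned
#' to the family.
#'
#' @param tags a `tag_set`.
#' @param assignments a [match_conserved()] result.
#' @return list with `records` (data.frame `id`, `mature_seq`,
#'   `mature_tag_id`, `kind`, `family`, `total_count`) and `counts`
#'   (matrix, per-library aggregated counts).
#' @export
call_conserved <- function(tags, assignments) {
  stopifnot(inherits(tags, "tag_set"))
  if (nrow(assignments) == 0)
    return(list(records = data.frame(id = character(), mature_seq = character(),
                                     mature_tag_id = character(),
                                     kind = character(), family = character(),
                                     total_count = integer(),
                                     stringsAsFactors = FALSE),
                counts = tags$counts[0, , drop = FALSE]))
  count_of <- stats::setNames(tags$tags$total_count, tags$tags$tag_id)
  seq_of <- stats::setNames(tags$tags$sequence, tags$tags$tag_id)
  fams <- split(assignments$tag_id, assignments$family)
  fam_tot <- vapply(fams, function(ids) sum(count_of[ids]), 0)
  fams <- fams[order(-fam_tot, names(fams))]
  recs <- lapply(names(fams), function(f) {
    ids <- fams[[f]]
    rep_tag <- ids[order(-count_of[ids], seq_of[ids])][1]
    data.frame(id = f, mature_seq = seq_of[[rep_tag]],
               mature_tag_id = rep_tag, kind = "conserved", family = f,
               total_count = as.integer(sum(count_of[ids])),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  counts <- do.call(rbind, lapply(names(fams), function(f)
    colSums(tags$counts[fams[[f]], , drop = FALSE])))
  rownames(counts) <- records$id
  rownames(records) <- NULL
  list(records = records, counts = counts)
}
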