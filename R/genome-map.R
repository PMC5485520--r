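#' Build a k-mer location index over a genome
#'
#' Indexes every overlapping k-mer of the plus strand with its 0-based
#' offset; minus-strand queries are handled at mapping time by searching
#' the reverse complement of the query.
#'
#' @param genome named character vector (or DNAStringSet) of chromosomes.
#' @param k word size (>= 4, and at most the shortest tag to be mapped).
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(genome, k = 12L) {
  genome <- as_genome(genome)
  if (!is_count(k) || k < 4) stop("k must be an integer >= 4")
  pieces <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    s <- genome[[ci]]
    n <- nchar(s)
    if (n < k) next
    off <- 0:(n - k)
    pieces[[ci]] <- data.table(kmer = substring(s, off + 1L, off + k),
                               chrom = names(genome)[ci], pos = off)
  }
  dt <- rbindlist(pieces[!vapply(pieces, is.null, TRUE)])
  setkey(dt, kmer)
  structure(list(k = k, genome = genome,
                 chrom_len = stats::setNames(nchar(genome), names(genome)),
                 table = dt),
            class = "kmer_index")
}

#' Look up the genomic positions of a k-mer
#'
#' @param index a [build_index()] result.
#' @param kmer a single k-mer (plus strand, exact).
#' @return data.frame with `chrom` and 0-based `pos` (empty if absent).
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"), nchar(kmer) == index$k)
  itab <- data.table(kmer = toupper(kmer))  # built outside the join so the
  hit <- index$table[itab, nomatch = NULL]  # argument shadows the column
  data.frame(chrom = hit$chrom, pos = hit$pos, stringsAsFactors = FALSE)
}

# exact/mismatch verification of a candidate placement
count_mm_at <- function(genome_seq, pos0, tag) {
  slice <- substr(genome_seq, pos0 + 1L, pos0 + nchar(tag))
  if (nchar(slice) < nchar(tag)) return(NA_integer_)
  if (slice == tag) return(0L)
  sum(utf8ToInt(slice) != utf8ToInt(tag))
}

#' Map tags to the genome (all hits, both strands)
#'
#' Seed-and-verify exact mapping: candidate placements come from the k-mer
#' index using the tag's first k-mer (and the first k-mer of its reverse
#' complement for the minus strand), then the full tag is verified.  With
#' `max_mismatches = 0` (the default; mapping is perfect-match) a hit
#' requires string equality.  Hits beyond `max_hits` are dropped and the
#' tag is flagged truncated.
#'
#' @param tags character vector of tag sequences, named by tag id (a
#'   `tag_set` is also accepted).
#' @param index a [build_index()] result.
#' @param max_mismatches maximum substitutions (0 keeps mapping exact; a
#'   nonzero value is only honoured within the seed k-mer's placements).
#' @param max_hits per-tag hit cap.
#' @return data.frame of hits: `tag_id`, `chrom`, `start` (0-based),
#'   `end` (exclusive), `strand`, `mismatches`, plus an attribute
#'   `truncated` (named logical per tag).
#' @export
map_tags <- function(tags, index, max_mismatches = 0L, max_hits = 100L) {
  if (inherits(tags, "tag_set"))
    tags <- stats::setNames(tags$tags$sequence, tags$tags$tag_id)
  if (is.null(names(tags))) names(tags) <- paste0("tag", seq_along(tags))
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  out <- vector("list", length(tags))
  truncated <- stats::setNames(rep(FALSE, length(tags)), names(tags))
  rc_tags <- revcomp(tags)
  for (ti in seq_along(tags)) {
    tag <- toupper(tags[[ti]])
    L <- nchar(tag)
    if (L < k) next
    hits <- list()
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else rc_tags[[ti]]
      itab <- data.table(kmer = substr(q, 1L, k))
      cand <- index$table[itab, nomatch = NULL]
      if (nrow(cand) == 0) next
      for (ri in seq_len(nrow(cand))) {
        chrom <- cand$chrom[ri]; pos <- cand$pos[ri]
        mm <- count_mm_at(index$genome[[chrom]], pos, q)
        if (!is.na(mm) && mm <= max_mismatches)
          hits[[length(hits) + 1L]] <- data.frame(
            tag_id = names(tags)[ti], chrom = chrom, start = pos,
            end = pos + L, strand = strand, mismatches = mm,
            stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      h <- h[order(h$chrom, h$start, h$strand), , drop = FALSE]
      if (nrow(h) > max_hits) {
        truncated[ti] <- TRUE
        h <- h[seq_len(max_hits), , drop = FALSE]
      }
      out[[ti]] <- h
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(tag_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "truncated") <- truncated
  res
}

#' Annotate tags against ncRNA reference sets
#'
#' A tag is assigned to an ncRNA class when it occurs as an exact substring
#' of any reference sequence of that class, on either strand.  Classes are
#' tried in the order given (the triage priority), and a tag keeps its
#' first assignment.
#'
#' @param tags a `tag_set` or named character vector of tag sequences.
#' @param refs named list of reference sets (character vectors or
#'   DNAStringSet), in priority order, e.g. rRNA, tRNA, snoRNA, other.
#' @return data.frame `tag_id`, `category` (`NA` for unannotated tags).
#' @export
annotate_ncrna <- function(tags, refs) {
  if (inherits(tags, "tag_set"))
    tags <- stats::setNames(tags$tags$sequence, tags$tags$tag_id)
  category <- stats::setNames(rep(NA_character_, length(tags)), names(tags))
  if (length(tags)) {
    ds <- Biostrings::DNAStringSet(toupper(unname(tags)))
    # trusted band allows a variable-width dictionary with exact matching
    pd <- Biostrings::PDict(ds, tb.start = 1L, tb.width = min(Biostrings::width(ds)))
    for (cls in names(refs)) {
      ref <- refs[[cls]]
      if (length(ref) == 0) next
      subj <- Biostrings::DNAStringSet(as.character(ref))
      subj <- c(subj, Biostrings::reverseComplement(subj))
      matched <- unique(unlist(Biostrings::vwhichPDict(pd, subj)))
      newly <- matched[is.na(category[matched])]
      category[newly] <- cls
    }
  }
  data.frame(tag_id = names(tags), category = unname(category),
             stringsAsFactors = FALSE)
}

#' Classify tags into the summary categories
#'
#' Applies the triage priority: ncRNA classes (as annotated) first, then
#' `high_repeat` (more than `max_repeat_hits` genomic hits), then
#' `low_expression` (total count 1), and finally `candidate`.  Tags with no
#' genomic hit get category `unmapped`.
#'
#' @param tags a `tag_set`.
#' @param hits a [map_tags()] result.
#' @param ncrna_annotation an [annotate_ncrna()] result (optional).
#' @param max_repeat_hits repeat threshold; category `high_repeat` requires
#'   strictly more hits than this (default 20).
#' @return data.frame `tag_id`, `category`, `n_hits`, `total_count`.
#' @export
classify_tags <- function(tags, hits, ncrna_annotation = NULL,
                          max_repeat_hits = 20L) {
  stopifnot(inherits(tags, "tag_set"))
  tab <- tags$tags
  n_hits <- stats::setNames(rep(0L, nrow(tab)), tab$tag_id)
  if (nrow(hits)) {
    cnt <- table(hits$tag_id)
    n_hits[names(cnt)] <- as.integer(cnt)
  }
  category <- rep(NA_character_, nrow(tab))
  if (!is.null(ncrna_annotation)) {
    m <- match(tab$tag_id, ncrna_annotation$tag_id)
    category <- ncrna_annotation$category[m]
  }
  unassigned <- is.na(category)
  category[unassigned & n_hits == 0L] <- "unmapped"
  unassigned <- is.na(category)
  category[unassigned & n_hits > max_repeat_hits] <- "high_repeat"
  unassigned <- is.na(category)
  category[unassigned & tab$total_count == 1L] <- "low_expression"
  category[is.na(category)] <- "candidate"
  data.frame(tag_id = tab$tag_id, category = category,
             n_hits = unname(n_hits), total_count = tab$total_count,
             stringsAsFactors = FALSE)
}

#' Export genome hits as BED6
#'
#' @param hits a [map_tags()] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_hits_bed <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand, name = hits$tag_id, score = 0L)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}
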