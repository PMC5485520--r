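#' Trim adapter sequences from reads
#'
#' Removes, from each read's 3' end, the longest suffix that is a prefix of
#' `adapter3` of at least `min_overlap` bases (exact match); symmetrically,
#' removes from the 5' end the longest prefix that is a suffix of
#' `adapter5`.  A read that is adapter only (empty after trimming) is
#' rejected.  Reads containing characters outside A/C/G/T/N are rejected
#' (counted, not fatal).
#'
#' @param reads character vector of read sequences.
#' @param adapter3,adapter5 adapter sequences; `NULL` or `""` disables the
#'   respective trim.
#' @param min_overlap minimum exact adapter overlap (default 6 nt).
#' @return list with `reads` (trimmed, rejected reads dropped) and `stats`
#'   (`n_in`, `n_kept`, `n_adapter_only`, `n_bad_alphabet`).
#' @export
trim_adapters <- function(reads, adapter3 = NULL, adapter5 = NULL,
                          min_overlap = 6L) {
  n_in <- length(reads)
  reads <- toupper(reads)
  bad <- grepl("[^ACGTN]", reads)
  n_bad <- sum(bad)
  reads <- reads[!bad]
  if (!is.null(adapter3) && nzchar(adapter3)) {
    adapter3 <- toupper(adapter3)
    la <- nchar(adapter3)
    L <- nchar(reads)
    trim <- integer(length(reads))
    hi <- min(la, if (length(L)) max(L) else 0L)
    if (hi >= min_overlap) for (k in hi:min_overlap) {
      cand <- trim == 0L & L >= k
      if (!any(cand)) next
      hit <- cand & substr(reads, L - k + 1L, L) == substr(adapter3, 1L, k)
      trim[hit] <- k
    }
    reads <- substr(reads, 1L, nchar(reads) - trim)
  }
  if (!is.null(adapter5) && nzchar(adapter5)) {
    adapter5 <- toupper(adapter5)
    la <- nchar(adapter5)
    L <- nchar(reads)
    trim <- integer(length(reads))
    hi <- min(la, if (length(L)) max(L) else 0L)
    if (hi >= min_overlap) for (k in hi:min_overlap) {
      cand <- trim == 0L & L >= k
      if (!any(cand)) next
      hit <- cand & substr(reads, 1L, k) == substr(adapter5, la - k + 1L, la)
      trim[hit] <- k
    }
    reads <- substr(reads, trim + 1L, nchar(reads))
  }
  empty <- !nzchar(reads)
  n_adapter_only <- sum(empty)
  reads <- reads[!empty]
  list(reads = reads,
       stats = c(n_in = n_in, n_kept = length(reads),
                 n_adapter_only = n_adapter_only, n_bad_alphabet = n_bad))
}

#' Collapse reads into unique sequence tags
#'
#' Applies the length window and N filter, then collapses identical
#' sequences across libraries into unique tags with per-library counts
#' ("sequence tags").  Tag ids are assigned in decreasing total count
#' (ties by sequence) so output is deterministic.
#'
#' @param reads_by_library named list of character vectors of trimmed reads
#'   (one element per library), or named vector of FASTQ paths.
#' @param min_len minimum tag length (default 18 nt).
#' @param max_len maximum tag length (default 30 nt).
#' @return an object of class `tag_set`: list with
#'   * `tags`: data.frame (`tag_id`, `sequence`, `length`, `total_count`);
#'   * `counts`: integer matrix tags x libraries;
#'   * `stats`: data.frame of per-library `LibraryStats` (total reads,
#'     high-quality reads, unique reads; mapping columns filled later).
#' @export
collapse_tags <- function(reads_by_library, min_len = 18L, max_len = 30L) {
  if (is.character(reads_by_library))
    reads_by_library <- lapply(reads_by_library, read_seqs, format = "fastq")
  if (is.null(names(reads_by_library)) || anyNA(names(reads_by_library)))
    names(reads_by_library) <- paste0("lib", seq_along(reads_by_library))
  libs <- names(reads_by_library)
  per_lib <- vector("list", length(libs))
  stats <- data.frame(library_id = libs, total_reads = 0L,
                      high_quality_reads = 0L, unique_reads = 0L,
                      mapped_reads = NA_integer_, unique_mapped = NA_integer_,
                      stringsAsFactors = FALSE)
  for (j in seq_along(libs)) {
    r <- toupper(reads_by_library[[j]])
    stats$total_reads[j] <- length(r)
    len <- nchar(r)
    keep <- len >= min_len & len <= max_len & !grepl("N", r, fixed = TRUE)
    r <- r[keep]
    stats$high_quality_reads[j] <- length(r)
    if (length(r)) {
      dt <- data.table(sequence = r)[, .(count = .N), by = sequence]
      dt[, library_id := libs[j]]
      per_lib[[j]] <- dt
    }
    stats$unique_reads[j] <- if (length(r)) nrow(per_lib[[j]]) else 0L
  }
  all_dt <- rbindlist(per_lib[!vapply(per_lib, is.null, TRUE)])
  if (is.null(all_dt) || nrow(all_dt) == 0) {
    tags <- data.frame(tag_id = character(), sequence = character(),
                       length = integer(), total_count = integer(),
                       stringsAsFactors = FALSE)
    counts <- matrix(0L, 0, length(libs), dimnames = list(NULL, libs))
    return(structure(list(tags = tags, counts = counts, stats = stats),
                     class = "tag_set"))
  }
  wide <- data.table::dcast(all_dt, sequence ~ library_id,
                            value.var = "count", fill = 0L)
  missing_libs <- setdiff(libs, colnames(wide))
  for (ml in missing_libs) wide[, (ml) := 0L]
  counts <- as.matrix(wide[, libs, with = FALSE])
  total <- as.integer(rowSums(counts))
  ord <- order(-total, wide$sequence)
  counts <- counts[ord, , drop = FALSE]
  sequence <- wide$sequence[ord]
  tag_id <- sprintf("tag%06d", seq_along(sequence))
  rownames(counts) <- tag_id
  tags <- data.frame(tag_id = tag_id, sequence = sequence,
                     length = nchar(sequence), total_count = total[ord],
                     stringsAsFactors = FALSE)
  structure(list(tags = tags, counts = counts, stats = stats),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set: %d unique tags across %d libraries (%s reads kept)\n",
              nrow(x$tags), ncol(x$counts),
              format(sum(x$stats$high_quality_reads), big.mark = ",")))
  invisible(x)
}

#' Read-length distribution of a tag set
#'
#' @param tags a `tag_set`.
#' @param by `"total"` (weight each tag by its read count) or `"unique"`
#'   (each tag counts once).
#' @return data.frame with `length` and `count`, sorted by length.
#' @export
length_distribution <- function(tags, by = c("total", "unique")) {
  by <- match.arg(by)
  stopifnot(inherits(tags, "tag_set"))
  if (nrow(tags$tags) == 0)
    return(data.frame(length = integer(), count = integer()))
  w <- if (by == "total") tags$tags$total_count else rep(1L, nrow(tags$tags))
  agg <- tapply(w, tags$tags$length, sum)
  data.frame(length = as.integer(names(agg)), count = as.integer(agg),
             row.names = NULL)
}

#' Export collapsed tags as FASTA with count headers
#'
#' Headers follow the `>tag{serial}_x{total_count}` convention; per-library
#' counts go to a companion TSV.
#'
#' @param tags a `tag_set`.
#' @param fasta_path,counts_path output paths.
#' @return invisibly, the two paths.
#' @export
export_tags <- function(tags, fasta_path, counts_path) {
  stopifnot(inherits(tags, "tag_set"))
  seqs <- stats::setNames(tags$tags$sequence,
                          sprintf("%s_x%d", tags$tags$tag_id, tags$tags$total_count))
  write_fasta(seqs, fasta_path)
  out <- data.frame(tag_id = tags$tags$tag_id, sequence = tags$tags$sequence,
                    tags$counts, check.names = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, counts = counts_path))
}
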