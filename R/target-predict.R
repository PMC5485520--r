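#' Scan transcripts for miRNA target sites
#'
#' Patscan-style rule: a site at transcript offset `s` (0-based, sense
#' strand) is the reverse complement of the mature miRNA with at most
#' `max_mm` substitutions, no insertions or deletions, and no mismatch
#' opposite a protected miRNA position.  miRNA positions are numbered
#' 1-based from the miRNA 5' end; position `p` faces transcript index
#' `s + L - p`.  G.U wobble counts as a mismatch.
#'
#' @param mature named character vector of mature miRNA sequences (U or T
#'   alphabet); a single unnamed sequence is also accepted.
#' @param transcripts named character vector of transcript (cDNA)
#'   sequences, or a DNAStringSet.
#' @param max_mm maximum substitutions (default 3).
#' @param protected miRNA positions that must pair perfectly (default
#'   10 and 11).
#' @return data.frame: `mirna_id`, `transcript_id`, `site_start` (0-based),
#'   `n_mismatches`, `mismatch_positions` (comma-separated 1-based miRNA
#'   positions, `""` for perfect sites).
#' @export
find_targets <- function(mature, transcripts, max_mm = 3L,
                         protected = c(10L, 11L)) {
  if (is(transcripts, "DNAStringSet")) transcripts <- as.character(transcripts)
  if (is.null(names(mature)))
    names(mature) <- paste0("mirna", seq_along(mature))
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("tx", seq_along(transcripts))
  mature <- normalize_u(mature)
  transcripts <- toupper(transcripts)
  if (any(grepl("N", mature, fixed = TRUE)))
    stop("mature sequences containing N are rejected")
  out <- list()
  for (mi in seq_along(mature)) {
    for (ti in seq_along(transcripts)) {
      hit <- .target_scan(mature[[mi]], transcripts[[ti]],
                          as.integer(max_mm), as.integer(protected))
      if (length(hit$offset) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = names(mature)[mi],
        transcript_id = names(transcripts)[ti],
        site_start = hit$offset,
        n_mismatches = hit$n_mismatches,
        mismatch_positions = vapply(hit$mismatch_positions,
                                    paste, "", collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer(), n_mismatches = integer(),
                      mismatch_positions = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Per-miRNA target counts
#'
#' Transcript-level counts deduplicate transcripts with multiple sites;
#' site-level counts report every site.
#'
#' @param hits a [find_targets()] result.
#' @param mirna_ids optional ids to include with zero counts.
#' @return data.frame: `mirna_id`, `n_targets` (distinct transcripts),
#'   `n_sites`.
#' @export
target_summary <- function(hits, mirna_ids = NULL) {
  ids <- unique(c(mirna_ids, hits$mirna_id))
  if (length(ids) == 0)
    return(data.frame(mirna_id = character(), n_targets = integer(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  n_targets <- vapply(ids, function(id)
    length(unique(hits$transcript_id[hits$mirna_id == id])), 0L)
  n_sites <- vapply(ids, function(id) sum(hits$mirna_id == id), 0L)
  data.frame(mirna_id = ids, n_targets = n_targets, n_sites = n_sites,
             stringsAsFactors = FALSE, row.names = NULL)
}
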