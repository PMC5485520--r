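#' Percentage with half-up rounding to two decimals
#'
#' `100 * count / denominator`, rounded half-up (the convention printed
#' summary tables use; banker's rounding gives different cells).
#'
#' @param count nonnegative count (vectorized).
#' @param denominator positive denominator (vectorized, recycled).
#' @return numeric percentage with two decimals.
#' @export
percent <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  floor(100 * count / denominator * 100 + 0.5) / 100
}

#' Sequencing summary table (per-condition read accounting)
#'
#' Aggregates per-library statistics by condition and applies the
#' percentage conventions of small-RNA sequencing reports: high-quality
#' reads as a share of raw reads, mapped reads as a share of high-quality
#' reads, unique reads as a share of high-quality reads, and unique mapped
#' reads as a share of unique reads.
#'
#' @param stats per-library stats data.frame (`library_id`, `total_reads`,
#'   `high_quality_reads`, `unique_reads`, `mapped_reads`,
#'   `unique_mapped`), e.g. from a `tag_set`.
#' @param condition per-library condition labels aligned with `stats`
#'   rows.
#' @return data.frame, one row per summary label with per-condition count
#'   and percent columns.
#' @export
table1_summary <- function(stats, condition) {
  stopifnot(nrow(stats) == length(condition))
  conds <- unique(condition)
  out <- data.frame(row_label = c("Total reads", "High quality (size >= 18 nt)",
                                  "Total of perfectly matched", "Unique reads",
                                  "Unique reads matched"),
                    stringsAsFactors = FALSE)
  for (cd in conds) {
    rows <- condition == cd
    tot <- sum(stats$total_reads[rows])
    hq <- sum(stats$high_quality_reads[rows])
    mapped <- sum(stats$mapped_reads[rows])
    uniq <- sum(stats$unique_reads[rows])
    um <- sum(stats$unique_mapped[rows])
    out[[paste0(cd, "_reads")]] <- c(tot, hq, mapped, uniq, um)
    out[[paste0(cd, "_pct")]] <- c(100,
                                   percent(hq, tot),
                                   percent(mapped, hq),
                                   percent(uniq, hq),
                                   percent(um, uniq))
  }
  out
}

#' Category distribution table (unique and total reads)
#'
#' Fractions of unique tags and of total reads across the triage
#' categories, each as a percent of the mapped totals.
#'
#' @param classes a [classify_tags()] result.
#' @param include_unmapped keep the `unmapped` row (default drops it, so
#'   categories partition the mapped totals).
#' @return data.frame: `category`, `unique_reads`, `unique_pct`,
#'   `total_reads`, `total_pct`, with a leading `Total reads` row.
#' @export
table2_summary <- function(classes, include_unmapped = FALSE) {
  cl <- classes
  if (!include_unmapped) cl <- cl[cl$category != "unmapped", , drop = FALSE]
  cats <- c("rRNA", "tRNA", "snoRNA", "other", "high_repeat",
            "low_expression", "candidate")
  cats <- c(cats[cats %in% cl$category],
            setdiff(unique(cl$category), cats))
  u_tot <- nrow(cl)
  t_tot <- sum(cl$total_count)
  rows <- lapply(cats, function(cc) {
    sel <- cl$category == cc
    data.frame(category = cc, unique_reads = sum(sel),
               unique_pct = if (u_tot > 0) percent(sum(sel), u_tot) else 0,
               total_reads = sum(cl$total_count[sel]),
               total_pct = if (t_tot > 0) percent(sum(cl$total_count[sel]), t_tot) else 0,
               stringsAsFactors = FALSE)
  })
  rbind(data.frame(category = "Total reads", unique_reads = u_tot,
                   unique_pct = if (u_tot > 0) 100 else 0,
                   total_reads = t_tot,
                   total_pct = if (t_tot > 0) 100 else 0,
                   stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Positional nucleotide composition of a sequence set
#'
#' Per-position base frequencies (rows sum to 1 over sequences long
#' enough to reach the position) and the first-base distribution by
#' sequence length.  T is reported as U.
#'
#' @param seqs character vector of sequences (e.g. mature miRNAs), or a
#'   `tag_set` (its unique tag sequences are used).
#' @return list: `position_freq` (position x base matrix, bases
#'   A/C/G/U), `first_base_by_length` (data.frame: `length`, `n`,
#'   frequencies per base, `mode_base`).
#' @export
nucleotide_bias <- function(seqs) {
  if (inherits(seqs, "tag_set")) seqs <- seqs$tags$sequence
  if (length(seqs) == 0) stop("seqs must be nonempty")
  seqs <- chartr("T", "U", toupper(seqs))
  bases <- c("A", "C", "G", "U")
  maxlen <- max(nchar(seqs))
  mat <- matrix(0, nrow = maxlen, ncol = 4,
                dimnames = list(position = seq_len(maxlen), base = bases))
  for (p in seq_len(maxlen)) {
    ch <- substr(seqs[nchar(seqs) >= p], p, p)
    tab <- table(factor(ch, levels = bases))
    if (sum(tab) > 0) mat[p, ] <- as.numeric(tab) / sum(tab)
  }
  first <- substr(seqs, 1L, 1L)
  lens <- sort(unique(nchar(seqs)))
  fb <- lapply(lens, function(L) {
    ch <- first[nchar(seqs) == L]
    tab <- table(factor(ch, levels = bases))
    freq <- as.numeric(tab) / sum(tab)
    data.frame(length = L, n = length(ch),
               A = freq[1], C = freq[2], G = freq[3], U = freq[4],
               mode_base = bases[which.max(freq)],
               stringsAsFactors = FALSE)
  })
  list(position_freq = mat,
       first_base_by_length = do.call(rbind, fb))
}
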