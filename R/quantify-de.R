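#' Transcripts-per-million normalization
#'
#' `tpm = count / total_mapped * 1e6`.
#'
#' @param count nonnegative count (vectorized).
#' @param total_mapped positive library total (vectorized, recycled).
#' @return numeric TPM values.
#' @export
tpm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  count / total_mapped * 1e6
}

#' TPM matrix from a count matrix
#'
#' @param counts miRNA x library count matrix.
#' @param totals per-library totals; defaults to the per-library count
#'   sums, in which case every TPM column sums to 1e6.
#' @return numeric matrix of TPM values.
#' @export
tpm_matrix <- function(counts, totals = colSums(counts)) {
  if (any(totals <= 0)) stop("totals must be positive")
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Method-of-moments common dispersion
#'
#' Columns are scaled to the geometric mean library size; for every miRNA
#' the within-condition sample mean and variance give a moment estimate
#' `(v - m) / m^2`, and the common dispersion is the average over miRNAs
#' with positive mean, floored at zero.
#'
#' @param counts miRNA x library count matrix.
#' @param condition per-library condition labels (two levels).
#' @param totals per-library sizes (default: count sums).
#' @return a single nonnegative dispersion.
#' @export
estimate_dispersion <- function(counts, condition,
                                totals = colSums(counts)) {
  stopifnot(ncol(counts) == length(condition))
  if (any(totals <= 0)) stop("totals must be positive")
  gm <- exp(mean(log(totals)))
  scaled <- sweep(counts, 2L, gm / totals, "*")
  conds <- unique(condition)
  m <- v <- matrix(0, nrow(counts), length(conds))
  w <- numeric(length(conds))
  for (ci in seq_along(conds)) {
    cols <- condition == conds[ci]
    w[ci] <- sum(cols) - 1L
    m[, ci] <- rowMeans(scaled[, cols, drop = FALSE])
    v[, ci] <- apply(scaled[, cols, drop = FALSE], 1L, stats::var)
  }
  if (all(w == 0)) return(0)
  mm <- rowSums(sweep(m, 2L, w / sum(w), "*"))
  vv <- rowSums(sweep(v, 2L, w / sum(w), "*"))
  ok <- mm > 0.5 & !is.na(vv)
  if (!any(ok)) return(0)
  max(0, mean((vv[ok] - mm[ok]) / mm[ok]^2))
}

#' Exact two-group count test
#'
#' Two-sided exact test of equal relative abundance between conditions.
#' Replicate counts are scaled to the geometric mean library size and
#' pooled per condition (rounded); conditional on the pooled total, the
#' salt count follows a negative binomial convolution with per-condition
#' size `n_reps / dispersion` (the Poisson/binomial limit when dispersion
#' is 0), and the p-value sums all outcomes at most as probable as the
#' observed one.
#'
#' @param salt_counts,control_counts per-replicate counts.
#' @param salt_totals,control_totals per-replicate library totals.
#' @param dispersion common negative-binomial dispersion (>= 0).
#' @return two-sided p-value in (0, 1]; an all-zero row returns 1.
#' @export
exact_count_test <- function(salt_counts, control_counts,
                             salt_totals, control_totals,
                             dispersion = 0) {
  stopifnot(length(salt_counts) == length(salt_totals),
            length(control_counts) == length(control_totals))
  totals <- c(salt_totals, control_totals)
  if (any(totals <= 0)) stop("library totals must be positive")
  gm <- exp(mean(log(totals)))
  y1 <- round(sum(salt_counts * gm / salt_totals))
  y2 <- round(sum(control_counts * gm / control_totals))
  t <- y1 + y2
  if (t == 0) return(1)
  n1 <- length(salt_counts); n2 <- length(control_counts)
  k <- 0:t
  if (dispersion == 0) {
    logp <- dbinom(k, t, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- t / (n1 + n2)
    logp <- dnbinom(k, size = n1 / dispersion, mu = n1 * mu, log = TRUE) +
      dnbinom(t - k, size = n2 / dispersion, mu = n2 * mu, log = TRUE)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  obs <- logp[y1 + 1L]
  min(1, sum(exp(logp[logp <= obs + 1e-8])))
}

#' Call differentially expressed miRNAs
#'
#' Runs the exact count test per miRNA and computes the salt/control TPM
#' ratio.  The ratio uses per-condition aggregates with a pseudocount of
#' 0.5 raw counts added to numerator and denominator before
#' normalization, so it is always finite; p-values use the unadjusted
#' counts.  A Benjamini-Hochberg column is reported but the UP/DOWN marks
#' threshold the raw p-values, matching the analysis convention.
#'
#' @param counts miRNA x library count matrix.
#' @param condition per-library labels, `"salt"` and `"control"`.
#' @param totals per-library totals used for TPM (default: count sums).
#' @param alpha significance threshold (default 0.05).
#' @param dispersion common dispersion; `NULL` estimates it with
#'   [estimate_dispersion()].
#' @return data.frame: `mirna_id`, `salt_tpm`, `control_tpm`, `ratio`,
#'   `p_value`, `padj`, `mark` (`UP`/`DOWN`/`NS`).
#' @export
call_differential <- function(counts, condition, totals = colSums(counts),
                              alpha = 0.05, dispersion = NULL) {
  stopifnot(ncol(counts) == length(condition),
            all(condition %in% c("salt", "control")))
  if (nrow(counts) == 0)
    return(data.frame(mirna_id = character(), salt_tpm = numeric(),
                      control_tpm = numeric(), ratio = numeric(),
                      p_value = numeric(), padj = numeric(),
                      mark = character(), stringsAsFactors = FALSE))
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, condition, totals)
  s <- condition == "salt"; ctl <- !s
  tpms <- tpm_matrix(counts, totals)
  salt_tpm <- rowMeans(tpms[, s, drop = FALSE])
  control_tpm <- rowMeans(tpms[, ctl, drop = FALSE])
  ratio <- ((rowSums(counts[, s, drop = FALSE]) + 0.5) / sum(totals[s])) /
    ((rowSums(counts[, ctl, drop = FALSE]) + 0.5) / sum(totals[ctl]))
  p <- vapply(seq_len(nrow(counts)), function(i)
    exact_count_test(counts[i, s], counts[i, ctl],
                     totals[s], totals[ctl], dispersion), 0)
  mark <- rep("NS", nrow(counts))
  mark[p <= alpha & ratio > 1] <- "UP"
  mark[p <= alpha & ratio < 1] <- "DOWN"
  data.frame(mirna_id = rownames(counts), salt_tpm = salt_tpm,
             control_tpm = control_tpm, ratio = ratio, p_value = p,
             padj = stats::p.adjust(p, "BH"), mark = mark,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Row-scaled expression matrix for heatmap export
#'
#' Per-row z-scaling (mean 0, sd 1); constant rows map to zeros.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return matrix of the same shape.
#' @export
scaled_matrix <- function(m) {
  if (ncol(m) < 2) stop("need at least 2 columns")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  out <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  out[sdv == 0, ] <- 0
  out
}
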