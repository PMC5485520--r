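#' Relative expression by the 2^-ddCt method
#'
#' `dCt = mean(Ct_target) - mean(Ct_reference)` per sample;
#' `ddCt = dCt_treatment - dCt_control`; `fold = 2^-ddCt`.
#'
#' @param target_treatment,reference_treatment Ct replicate vectors for the
#'   treated sample.
#' @param target_control,reference_control Ct replicate vectors for the
#'   control sample.
#' @return list: `fold`, `ddct`, `dct_treatment`, `dct_control`.
#' @export
delta_delta_ct <- function(target_treatment, reference_treatment,
                           target_control, reference_control) {
  for (v in list(target_treatment, reference_treatment,
                 target_control, reference_control))
    if (any(v <= 0 | v >= 45)) stop("Ct values must lie in (0, 45)")
  dct_t <- mean(target_treatment) - mean(reference_treatment)
  dct_c <- mean(target_control) - mean(reference_control)
  ddct <- dct_t - dct_c
  list(fold = 2^(-ddct), ddct = ddct,
       dct_treatment = dct_t, dct_control = dct_c)
}

#' Two-sample t-test on per-replicate dCt values
#'
#' Student's pooled-variance t-test by default (`var_equal = FALSE` gives
#' the Welch variant).  Degenerate inputs (zero variance in both groups)
#' return 1 for equal means and 0 otherwise.
#'
#' @param dct_treatment,dct_control per-replicate dCt values (>= 2 each).
#' @param var_equal pooled variance if `TRUE` (default).
#' @return two-sided p-value.
#' @export
replicate_ttest <- function(dct_treatment, dct_control, var_equal = TRUE) {
  if (length(dct_treatment) < 2 || length(dct_control) < 2)
    stop("need at least 2 replicates per group")
  if (stats::var(dct_treatment) == 0 && stats::var(dct_control) == 0)
    return(if (mean(dct_treatment) == mean(dct_control)) 1 else 0)
  stats::t.test(dct_treatment, dct_control, var.equal = var_equal)$p.value
}

#' Relative expression table from a long Ct data frame
#'
#' Expects columns `target_id`, `sample_id`, `replicate`, `ct`.  The
#' reference gene's rows (matching `reference_id`) normalize each sample;
#' per-replicate dCt values pair target and reference wells by replicate
#' index within a sample.  Folds are relative to `control_sample`
#' (fold 1 there by construction); p-values compare each sample's dCt
#' replicates with the control's.
#'
#' @param ct_data long-format data.frame of Ct triplicates.
#' @param reference_id reference gene id (e.g. `"18S"`).
#' @param control_sample the sample every fold is normalized against.
#' @param var_equal passed to [replicate_ttest()].
#' @return data.frame: `target_id`, `sample_id`, `ddct`, `fold`,
#'   `p_value` (`NA` for the control sample itself).
#' @export
relative_expression <- function(ct_data, reference_id = "18S",
                                control_sample, var_equal = TRUE) {
  need <- c("target_id", "sample_id", "replicate", "ct")
  if (!all(need %in% names(ct_data)))
    stop("ct_data needs columns: ", paste(need, collapse = ", "))
  dct_of <- function(target, sample) {
    tgt <- ct_data[ct_data$target_id == target & ct_data$sample_id == sample, ]
    ref <- ct_data[ct_data$target_id == reference_id &
                     ct_data$sample_id == sample, ]
    if (nrow(ref) == 0)
      stop(sprintf("no reference (%s) record for sample '%s'",
                   reference_id, sample))
    tgt <- tgt[order(tgt$replicate), ]; ref <- ref[order(ref$replicate), ]
    if (nrow(tgt) != nrow(ref))
      stop(sprintf("replicate mismatch for %s in sample '%s'", target, sample))
    tgt$ct - ref$ct
  }
  targets <- setdiff(unique(ct_data$target_id), reference_id)
  samples <- unique(ct_data$sample_id)
  if (!control_sample %in% samples) stop("control_sample not present")
  rows <- list()
  for (tg in targets) {
    dct_c <- dct_of(tg, control_sample)
    for (sm in samples) {
      dct_s <- dct_of(tg, sm)
      ddct <- mean(dct_s) - mean(dct_c)
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tg, sample_id = sm, ddct = ddct, fold = 2^(-ddct),
        p_value = if (sm == control_sample) NA_real_
                  else replicate_ttest(dct_s, dct_c, var_equal = var_equal),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
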