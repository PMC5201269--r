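#' Per-replicate delta-Ct values
#'
#' ΔCt = Ct_target - Ct_reference, paired by replicate id; replicates
#' present in only one series are dropped with a warning.
#'
#' @param ct_target,ct_reference numeric Ct vectors.
#' @param rep_target,rep_reference replicate identifiers (default
#'   positional).
#' @return named numeric vector of ΔCt keyed by replicate id.
#' @export
delta_ct <- function(ct_target, ct_reference,
                     rep_target = seq_along(ct_target),
                     rep_reference = seq_along(ct_reference)) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  common <- intersect(rep_target, rep_reference)
  dropped <- length(ct_target) + length(ct_reference) - 2 * length(common)
  if (dropped > 0)
    warning(dropped, " unmatched replicate measurement(s) dropped")
  if (!length(common)) stop("no matched replicates")
  stats::setNames(
    ct_target[match(common, rep_target)] -
      ct_reference[match(common, rep_reference)],
    common)
}

#' Relative fold change by the 2^-ddCt method
#'
#' ΔΔCt is the difference of mean ΔCt between treated and control;
#' fold = 2^(-ΔΔCt), assuming amplification efficiency 2. The SEM is
#' propagated from per-replicate folds computed against the control mean
#' (each replicate contributes one fold, matching the
#' one-fold-per-experiment convention of replicate summaries).
#'
#' @param dct_treated,dct_control numeric ΔCt vectors (non-empty).
#' @return `chap_qpcr`: list with `ddct`, `fold`, `replicate_folds`, `sem`.
#' @export
fold_change <- function(dct_treated, dct_control) {
  if (!length(dct_treated) || !length(dct_control))
    stop("empty delta-Ct list")
  ddct <- mean(dct_treated) - mean(dct_control)
  folds <- 2^(-(dct_treated - mean(dct_control)))
  sem <- if (length(folds) > 1) stats::sd(folds) / sqrt(length(folds))
         else NA_real_
  structure(list(ddct = ddct, fold = 2^(-ddct),
                 replicate_folds = folds, sem = sem),
            class = "chap_qpcr")
}

#' @export
print.chap_qpcr <- function(x, ...) {
  cat(sprintf("fold = %.3g (ddCt = %.3g, SEM %.3g, n = %d)\n",
              x$fold, x$ddct, x$sem, length(x$replicate_folds)))
  invisible(x)
}

#' Full relative quantification for one gene from a Ct table
#'
#' Normalizes the target to the reference gene within each condition
#' (ΔCt per replicate), then compares treated to control (ΔΔCt).
#' Reference genes stably expressed during embryogenesis (e.g. T07A9.15 or
#' tbc-10) are supplied per dataset.
#'
#' @param ct `chap_ct` table.
#' @param gene target gene id.
#' @param reference_gene reference (normalizer) gene id.
#' @param treated,control condition labels.
#' @return `chap_qpcr` with the condition pair recorded.
#' @export
qpcr_quantify <- function(ct, gene, reference_gene, treated, control) {
  stopifnot(inherits(ct, "chap_ct"))
  pick <- function(g, cond) {
    rows <- ct[gene_key(ct$gene_id) == gene_key(g) & ct$condition == cond, ]
    if (!nrow(rows)) stop("no Ct rows for ", g, " / ", cond)
    rows
  }
  dct <- function(cond) {
    tg <- pick(gene, cond)
    rf <- pick(reference_gene, cond)
    delta_ct(tg$ct, rf$ct, tg$replicate, rf$replicate)
  }
  out <- fold_change(dct(treated), dct(control))
  out$gene_id <- gene
  out$reference_gene <- reference_gene
  out$conditions <- c(treated = treated, control = control)
  out
}

#' Compare per-replicate folds between two conditions or strains
#'
#' Delegates to the exact Mann-Whitney test and annotates significance
#' stars (* p < 0.05, ** p < 0.01).
#'
#' @param folds_a,folds_b numeric per-replicate fold vectors (or
#'   `chap_qpcr` objects).
#' @return `chap_test`.
#' @export
compare_conditions <- function(folds_a, folds_b) {
  fa <- if (inherits(folds_a, "chap_qpcr")) folds_a$replicate_folds
        else folds_a
  fb <- if (inherits(folds_b, "chap_qpcr")) folds_b$replicate_folds
        else folds_b
  res <- mann_whitney(fa, fb)
  res$stars <- significance_stars(res$p_value)
  res
}
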