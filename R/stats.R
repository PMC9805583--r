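#' Combine per-batch imputation quality via Fisher's z-transformation
#'
#' Imputation Rsq is the estimated squared correlation between imputed
#' dosage and true genotype. Squared correlations must not be averaged
#' directly: the correlation scale is variance-unstable. Instead each
#' batch's \eqn{r_i = \sqrt{R^2_i}} is mapped through Fisher's
#' variance-stabilising transform \eqn{z_i = \mathrm{artanh}(r_i)}, the
#' \eqn{z_i} are averaged with the supplied weights, and the mean is
#' back-transformed: \eqn{R^2_{comb} = \tanh(\bar z)^2}.
#'
#' Only the nonnegative root is available (info files report \eqn{R^2},
#' not the signed dosage-genotype correlation). \eqn{r} is clamped at
#' \eqn{1 - 10^{-6}} before `artanh` so that genotyped variants with
#' \eqn{R^2 = 1} stay finite. Pairs where `rsq` is `NA` (placeholder in the
#' info file) are dropped together with their weights; batches lacking the
#' variant entirely must not be passed in.
#'
#' @param rsq Numeric vector of per-batch Rsq values in \[0, 1\]; `NA`
#'   allowed (dropped).
#' @param weights Positive weights, one per batch — conventionally the
#'   batch sample count (see `weight_mode` in [merge_config()]).
#' @return The combined Rsq in \[0, 1\], or `NA_real_` if no batch
#'   supplies a quality value. Deterministic and independent of input
#'   order.
#' @examples
#' combine_rsq(c(0.81, 0.25), c(100, 300))
#' combine_rsq(c(NA, 0.5), c(10, 90))  # NA pair dropped
#' @export
combine_rsq <- function(rsq, weights) {
  if (length(rsq) != length(weights)) {
    stop("rsq and weights must have equal length", call. = FALSE)
  }
  if (length(rsq) == 0L) return(NA_real_)
  if (anyNA(weights) || any(weights <= 0)) {
    stop("all weights must be positive", call. = FALSE)
  }
  keep <- !is.na(rsq)
  if (!any(keep)) return(NA_real_)
  rsq <- rsq[keep]
  weights <- weights[keep]
  if (any(rsq < 0 | rsq > 1)) {
    stop("rsq values must lie in [0, 1]", call. = FALSE)
  }
  r <- pmin(sqrt(rsq), 1 - 1e-6)
  z <- atanh(r)
  zbar <- sum(weights * z) / sum(weights)
  tanh(zbar)^2
}

#' Weighted-mean, minimum and maximum of per-batch frequencies
#'
#' Summarises a frequency (ALT allele frequency or MAF) across the batches
#' containing a variant as the sample-size-weighted mean plus the extremes.
#' When per-batch frequencies were computed from dosages and weights equal
#' batch sample counts, the weighted mean equals the frequency of the
#' pooled cohort exactly.
#'
#' @param values Numeric vector of per-batch frequencies.
#' @param weights Positive weights (batch sample counts).
#' @return Named numeric vector `c(weighted=, min=, max=)`; all `NA` for
#'   empty input.
#' @examples
#' combine_af(c(0.1, 0.2), c(100, 300))
#' @export
combine_af <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights must have equal length", call. = FALSE)
  }
  if (length(values) == 0L) {
    return(c(weighted = NA_real_, min = NA_real_, max = NA_real_))
  }
  if (anyNA(weights) || any(weights <= 0)) {
    stop("all weights must be positive", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("frequency values must not be NA", call. = FALSE)
  }
  c(weighted = sum(weights * values) / sum(weights),
    min = min(values), max = max(values))
}

#' Combine per-batch genotyped flags into an all/some/none status
#'
#' A variant can be directly assayed ("genotyped"/"typed") in some batches
#' and imputed in others. The merged record reports `"all"` when every
#' contributing batch genotyped it, `"none"` when no batch did, and
#' `"some"` otherwise. Only batches containing the variant contribute.
#'
#' @param flags Logical vector, one per contributing batch.
#' @return One of `"all"`, `"some"`, `"none"`.
#' @export
combine_genotyped_status <- function(flags) {
  if (length(flags) == 0L) {
    stop("at least one contributing batch is required", call. = FALSE)
  }
  if (anyNA(flags)) stop("genotyped flags must not be NA", call. = FALSE)
  if (all(flags)) "all" else if (!any(flags)) "none" else "some"
}

# Cross-batch summary for one variant. af/maf/rsq/genotyped are per-batch
# vectors over contributing batches only; n the matching sample counts.
combine_variant <- function(af, maf, rsq, genotyped, n,
                            weight_mode = c("n", "n-3")) {
  weight_mode <- match.arg(weight_mode)
  w <- if (weight_mode == "n") n else n - 3
  if (any(w <= 0)) {
    stop("weight mode 'n-3' requires every batch to have more than 3 samples",
         call. = FALSE)
  }
  afc <- combine_af(af, w)
  mafc <- combine_af(maf, w)
  has_rsq <- !is.na(rsq)
  list(
    rsq_combined = combine_rsq(rsq, w),
    rsq_min = if (any(has_rsq)) min(rsq[has_rsq]) else NA_real_,
    rsq_max = if (any(has_rsq)) max(rsq[has_rsq]) else NA_real_,
    af_weighted = unname(afc["weighted"]),
    af_min = unname(afc["min"]),
    af_max = unname(afc["max"]),
    maf_weighted = unname(mafc["weighted"]),
    maf_min = unname(mafc["min"]),
    maf_max = unname(mafc["max"]),
    genotyped_status = combine_genotyped_status(genotyped),
    n_effective = sum(n)
  )
}
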