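#' Detection filter for paired counts
#'
#' Excludes RNAs undetected (zero count) in at least `min_detect_frac` of
#' all samples; equivalently, retains RNAs detected in more than
#' `1 - min_detect_frac` of samples. An RNA zero in exactly half of the
#' samples is excluded at the default threshold.
#'
#' @param pc a [paired_counts()] object.
#' @param min_detect_frac exclusion threshold on the undetected fraction
#'   (default 0.5).
#' @return the filtered [paired_counts()] object, with a `filter_audit`
#'   attribute: data.frame of removed RNAs (`rna`, `biotype`,
#'   `detect_frac`).
#' @export
detection_filter <- function(pc, min_detect_frac = 0.5) {
  stopifnot(inherits(pc, "paired_counts"))
  if (ncol(pc$counts) < 2) stop("need at least 2 samples")
  detect_frac <- rowMeans(pc$counts > 0)
  keep <- (1 - detect_frac) < min_detect_frac
  if (!any(keep))
    stop("detection filter removed every RNA; review `min_detect_frac`")
  audit <- data.frame(rna = rownames(pc$counts)[!keep],
                      biotype = unname(pc$biotype[!keep]),
                      detect_frac = unname(detect_frac[!keep]),
                      stringsAsFactors = FALSE)
  out <- paired_counts(pc$counts[keep, , drop = FALSE],
                       pc$biotype[keep], pc$pairs)
  attr(out, "filter_audit") <- audit
  out
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors for count libraries. Unless supplied,
#' the reference is the sample whose upper-quartile count (relative to
#' library size) is closest to the mean upper-quartile. For each sample,
#' M-values (log2 relative abundance ratios vs the reference) are doubly
#' trimmed — the most extreme `logratio_trim` of M and `sum_trim` of A
#' (average log abundance) — and combined as a precision-weighted mean
#' with asymptotic binomial weights. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param pc a [paired_counts()] object (usually after
#'   [detection_filter()]) or a plain count matrix with sample columns.
#' @param ref_sample optional sample id used as reference.
#' @param logratio_trim,sum_trim fraction of M-values and A-values trimmed
#'   from each tail (defaults 0.3 and 0.05).
#' @return named numeric vector of per-sample normalization factors with
#'   geometric mean 1; the reference sample id is kept in the
#'   `ref_sample` attribute.
#' @export
tmm_factors <- function(pc, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  x <- if (inherits(pc, "paired_counts")) pc$counts
  else if (is.matrix(pc)) pc
  else stop("`pc` must be a paired_counts object or a count matrix")
  if (ncol(x) < 2) stop("need at least 2 samples")
  lib <- colSums(x)
  zero <- lib == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(x)[zero], collapse = ", "))
  if (is.null(ref_sample)) {
    f75 <- apply(x, 2, quantile, probs = 0.75) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(ref_sample, colnames(x))
    if (is.na(ref)) stop("unknown ref_sample: ", ref_sample)
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], x[, ref], lib[j], lib[ref], logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  attr(f, "ref_sample") <- colnames(x)[ref]
  f
}

# One sample vs reference: doubly trimmed, precision-weighted mean of
# M-values on the log2 scale.
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Per-patient log2 fold changes of normalized abundances
#'
#' For patient p and RNA r, computes
#' `log2((a_post + pc) / (a_pre + pc))` where `a = count / (libsize *
#' factor)` is the normalized relative abundance and `pc` is a small
#' pseudocount guarding against zero counts (default: 0.5 divided by the
#' mean effective library size).
#'
#' @param pc a [paired_counts()] object.
#' @param factors per-sample normalization factors from [tmm_factors()]
#'   (default: recomputed from `pc`).
#' @param pseudocount pseudocount on the relative-abundance scale;
#'   `NULL` = `0.5 / mean(effective library sizes)`.
#' @return matrix of log2 fold changes, patients in rows, RNAs in
#'   columns, with attributes `biotype`, `factors`, `pseudocount`.
#' @export
paired_log2fc <- function(pc, factors = tmm_factors(pc), pseudocount = NULL) {
  stopifnot(inherits(pc, "paired_counts"))
  miss <- setdiff(colnames(pc$counts), names(factors))
  if (length(miss))
    stop("no normalization factor for sample(s): ", paste(miss, collapse = ", "))
  lib <- colSums(pc$counts)
  eff <- lib * factors[colnames(pc$counts)]
  if (is.null(pseudocount)) pseudocount <- 0.5 / mean(eff)
  abund <- sweep(pc$counts, 2, eff, "/")
  pre <- t(abund[, pc$pairs$pre, drop = FALSE])
  post <- t(abund[, pc$pairs$post, drop = FALSE])
  lfc <- log2((post + pseudocount) / (pre + pseudocount))
  dimnames(lfc) <- list(pc$pairs$patient_id, rownames(pc$counts))
  attr(lfc, "biotype") <- pc$biotype
  attr(lfc, "factors") <- factors
  attr(lfc, "pseudocount") <- pseudocount
  lfc
}
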