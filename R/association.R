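#' RNA-CBC-outcome Pearson correlation matrix
#'
#' Correlates every RNA's per-patient log2 fold change with every CBC
#' dynamics variable and with the binary early-death (ED) and
#' early-progression (EP) indicators. Pairwise-complete Pearson
#' coefficients with two-sided p-values from the t distribution
#' (`t = R * sqrt(n - 2) / sqrt(1 - R^2)`). A constant column yields an
#' undefined coefficient, recorded as `NA` (never 0). The cohort-level
#' correlation matrix among the CBC/outcome variables themselves is kept
#' alongside (needed by the homeostasis screen).
#'
#' @param lfc patients x RNAs log2 fold-change matrix from
#'   [paired_log2fc()] (rownames = patient ids).
#' @param dyn per-patient CBC dynamics from [derive_cbc_dynamics()].
#' @param outcomes data.frame with `patient_id`, `ED`, `EP` (0/1), e.g.
#'   from [outcome_indicators()].
#' @return object of class `edrna_assoc`: list with matrices `R`, `P`,
#'   `N` (RNAs x variables), `var_cor` (variables x variables),
#'   `biotype`, and `variables`.
#' @export
correlate_all <- function(lfc, dyn, outcomes) {
  ids <- rownames(lfc)
  if (is.null(ids)) stop("`lfc` must have patient rownames")
  if (length(ids) < 4) stop("need at least 4 patients")
  mi <- setdiff(ids, dyn$patient_id)
  if (length(mi)) stop("no CBC dynamics for patient(s): ", paste(mi, collapse = ", "))
  mo <- setdiff(ids, outcomes$patient_id)
  if (length(mo)) stop("no outcomes for patient(s): ", paste(mo, collapse = ", "))

  dv <- dyn[match(ids, dyn$patient_id), setdiff(names(dyn), "patient_id"), drop = FALSE]
  ov <- outcomes[match(ids, outcomes$patient_id), c("ED", "EP"), drop = FALSE]
  Y <- as.matrix(cbind(dv, ov))
  rownames(Y) <- ids

  R <- suppressWarnings(cor(lfc, Y, use = "pairwise.complete.obs"))
  N <- crossprod(!is.na(lfc), !is.na(Y))
  tt <- R * sqrt(pmax(N - 2, 0)) / sqrt(pmax(1 - R^2, 0))
  P <- 2 * pt(-abs(tt), pmax(N - 2, 1))
  P[N <= 2] <- NA
  P[!is.finite(tt) & !is.na(R)] <- 0   # |R| = 1 exactly
  P[is.na(R)] <- NA

  structure(list(R = R, P = P, N = N,
                 var_cor = suppressWarnings(cor(Y, use = "pairwise.complete.obs")),
                 biotype = attr(lfc, "biotype"),
                 variables = colnames(Y)),
            class = "edrna_assoc")
}

#' @export
print.edrna_assoc <- function(x, ...) {
  cat("edrna_assoc:", nrow(x$R), "RNAs x", ncol(x$R), "variables\n")
  invisible(x)
}

# Variable lists defining "linked with cell type c" per flag variant.
.link_vars <- function(cell, variant) {
  switch(variant,
         network_admission = c(paste0(cell, "0"), paste0("min", cell),
                               paste0(cell, "1")),
         network_annotation = c(paste0(cell, "0"), paste0(cell, "1"),
                                paste0(cell, "2"), paste0(cell, "3"),
                                paste0("min", cell)),
         stop("unknown variant: ", variant))
}

#' CBC link flags per RNA
#'
#' Declares an RNA "linked" with a cell type if it is significantly
#' correlated (p < `alpha`) with at least one of the cell type's feature
#' variables. Two variants are used at different pipeline stages:
#' `network_admission` tests the baseline-side features
#' (c0, min c, c1), as used when admitting RNAs into the network;
#' `network_annotation` tests all five features (c0, c1, c2, c3, min c),
#' as used for node annotation and the all-CBC coverage criterion. Ratio
#' flags (NLR/PLR/LMR) use the 0- and 1-suffixed variants in both
#' variants.
#'
#' @param assoc an `edrna_assoc` object from [correlate_all()].
#' @param alpha significance threshold (screening, uncorrected).
#' @param variant `"network_admission"` or `"network_annotation"`.
#' @return object of class `edrna_flags`: list with `cell_flags`
#'   (RNAs x 5 cell types, logical), `ratio_flags` (RNAs x 3, logical),
#'   `n_linked_cells`, `n_linked_hema` (count over the 8 hematological
#'   flags), `ed_sig`, `ep_sig`, `r_ed`, `ed_sign`, plus `alpha` and
#'   `variant`.
#' @export
cbc_link_flags <- function(assoc, alpha = 0.05,
                           variant = c("network_admission", "network_annotation")) {
  stopifnot(inherits(assoc, "edrna_assoc"))
  variant <- match.arg(variant)
  sig <- assoc$P < alpha & !is.na(assoc$P)

  cell_flags <- sapply(CBC_CELLS, function(cell) {
    vars <- intersect(.link_vars(cell, variant), colnames(sig))
    rowSums(sig[, vars, drop = FALSE]) > 0
  })
  ratio_flags <- sapply(CBC_RATIOS, function(r) {
    vars <- intersect(paste0(r, c("0", "1")), colnames(sig))
    rowSums(sig[, vars, drop = FALSE]) > 0
  })
  r_ed <- assoc$R[, "ED"]
  structure(list(cell_flags = cell_flags, ratio_flags = ratio_flags,
                 n_linked_cells = rowSums(cell_flags),
                 n_linked_hema = rowSums(cell_flags) + rowSums(ratio_flags),
                 ed_sig = sig[, "ED"], ep_sig = sig[, "EP"],
                 r_ed = r_ed, ed_sign = sign(r_ed),
                 alpha = alpha, variant = variant),
            class = "edrna_flags")
}

#' Homeostasis screen: RNAs explaining a negative baseline-recovery link
#'
#' For each cell type c, the cohort-level correlation between a baseline
#' feature b (c0 or c1) and the recovery ratio c3 is often negative —
#' counts that start high recover proportionally less. The screen flags
#' RNA r for cell type c if (i) the cohort-level corr(b, c3) is negative
#' for some b in \{c0, c1\}, (ii) r is significantly correlated with both
#' b and c3, and (iii) those two correlations have opposite signs, so the
#' RNA tracks the push-pull between baseline level and recovery. Each
#' flagged (RNA, cell) pair is classified by the sign of its ED
#' correlation (positive = "red", negative = "blue") and the cell-type
#' family (ANC/PLT = "solid", Hb/ALC/Mo = "dashed").
#'
#' @inheritParams cbc_link_flags
#' @return data.frame with one row per flagged (RNA, cell, baseline)
#'   combination: `rna`, `cell`, `baseline` (`"c0"` or `"c1"`),
#'   `r_baseline`, `r_c3`, `r_ed`, `ed_sig`, `quadrant` (e.g.
#'   `"red_solid"`); attribute `counts` summarises flags and
#'   ED-associated flags per cell type.
#' @export
homeostasis_screen <- function(assoc, alpha = 0.05) {
  stopifnot(inherits(assoc, "edrna_assoc"))
  sig <- assoc$P < alpha & !is.na(assoc$P)
  rows <- list()
  for (cell in CBC_CELLS) {
    c3 <- paste0(cell, "3")
    if (!c3 %in% colnames(assoc$R)) {
      message("homeostasis screen: no ", c3, " column; cell type skipped")
      next
    }
    for (bl in c("0", "1")) {
      b <- paste0(cell, bl)
      if (!b %in% colnames(assoc$R)) next
      if (is.na(assoc$var_cor[b, c3]) || assoc$var_cor[b, c3] >= 0) next
      hit <- sig[, b] & sig[, c3] &
        sign(assoc$R[, b]) * sign(assoc$R[, c3]) < 0
      if (!any(hit)) next
      rna <- rownames(assoc$R)[hit]
      rows[[length(rows) + 1L]] <- data.frame(
        rna = rna, cell = cell, baseline = paste0("c", bl),
        r_baseline = assoc$R[hit, b], r_c3 = assoc$R[hit, c3],
        r_ed = assoc$R[hit, "ED"], ed_sig = sig[hit, "ED"],
        quadrant = paste(ifelse(assoc$R[hit, "ED"] >= 0, "red", "blue"),
                         ifelse(cell %in% c("ANC", "PLT"), "solid", "dashed"),
                         sep = "_"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(rna = character(0), cell = character(0),
                  baseline = character(0), r_baseline = numeric(0),
                  r_c3 = numeric(0), r_ed = numeric(0),
                  ed_sig = logical(0), quadrant = character(0),
                  stringsAsFactors = FALSE)
  rownames(out) <- NULL
  counts <- do.call(rbind, lapply(CBC_CELLS, function(cell) {
    sub <- out[out$cell == cell, , drop = FALSE]
    data.frame(cell = cell, n_flagged = length(unique(sub$rna)),
               n_ed_associated = length(unique(sub$rna[sub$ed_sig])),
               stringsAsFactors = FALSE)
  }))
  attr(out, "counts") <- counts
  out
}
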