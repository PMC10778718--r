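#' Three-RNA composite score
#'
#' Per patient, `score = lfc(rna_pos) - lfc(rna_neg[1]) - lfc(rna_neg[2])`:
#' the ED-positive RNA enters with a plus sign and the ED-negative RNAs
#' with minus signs. Under this convention a negative score marks the
#' favourable profile (low ED-positive fold change, preserved ED-negative
#' fold changes), and patients are grouped at the absolute threshold 0.
#'
#' @param lfc patients x RNAs log2 fold-change matrix.
#' @param rna_pos id of the ED-positively-correlated RNA.
#' @param rna_neg character vector of the ED-negatively-correlated
#'   RNA id(s) (usually two).
#' @return data.frame `patient_id`, `score`, `group`
#'   (factor `"score<0"` / `"score>=0"`).
#' @examples
#' m <- matrix(c(1, 0, 1, 0, 1, 2), 2, 3,
#'             dimnames = list(c("P1", "P2"), c("a", "b", "c")))
#' composite_score(m, "a", c("b", "c"))$score   # 1-1-1 = -1; 0-0-2 = -2
#' @export
composite_score <- function(lfc, rna_pos, rna_neg) {
  all_rna <- c(rna_pos, rna_neg)
  miss <- setdiff(all_rna, colnames(lfc))
  if (length(miss))
    stop("RNA(s) missing from the log2FC table: ", paste(miss, collapse = ", "))
  score <- lfc[, rna_pos] - rowSums(lfc[, rna_neg, drop = FALSE])
  data.frame(patient_id = rownames(lfc), score = unname(score),
             group = factor(ifelse(score < 0, "score<0", "score>=0"),
                            levels = c("score<0", "score>=0")),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier disease-specific survival by composite-score group
#'
#' Disease-specific survival (DSS): events are disease deaths; deaths
#' from other causes are censored at the death time, survivors at last
#' follow-up. Reports the product-limit survival per group, the survival
#' probability at the horizon (read off the step function, left
#' continuous at event times), the two-group log-rank test on the full
#' follow-up, a Wilcoxon rank-sum comparison of the score by ED status
#' (when ED indicators are supplied), and the median follow-up by
#' reverse Kaplan-Meier.
#'
#' @param scores data.frame from [composite_score()].
#' @param clinical clinical table (see [assign_groups()] for the required
#'   outcome columns).
#' @param horizon months at which group survival is reported (default 30).
#' @param outcomes optional data.frame with `patient_id` and `ED` for the
#'   score-by-ED Wilcoxon comparison.
#' @return object of class `edrna_survival`: list with `fit` (a
#'   [survival::survfit] object), `surv_at_horizon` (named per group),
#'   `logrank_chisq`, `logrank_p`, `wilcoxon_p`, `median_followup`,
#'   `horizon`, `n_groups`, and the assembled `data`.
#' @export
km_logrank <- function(scores, clinical, horizon = 30, outcomes = NULL) {
  idx <- match(scores$patient_id, clinical$patient_id)
  if (anyNA(idx))
    stop("no clinical record for patient(s): ",
         paste(scores$patient_id[is.na(idx)], collapse = ", "))
  cl <- clinical[idx, , drop = FALSE]
  event <- as.integer(!is.na(cl$death_time) & cl$death_cause == "disease")
  time <- ifelse(!is.na(cl$death_time), cl$death_time, cl$follow_up)
  if (anyNA(time)) stop("missing follow-up/death time")
  d <- data.frame(patient_id = scores$patient_id, time = time, event = event,
                  group = scores$group, score = scores$score,
                  stringsAsFactors = FALSE)

  groups_present <- droplevels(factor(d$group))
  single <- nlevels(groups_present) < 2
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)

  sm <- summary(fit, times = horizon, extend = TRUE)
  sv <- sm$surv
  names(sv) <- if (!is.null(sm$strata)) sub("^group=", "", as.character(sm$strata))
  else levels(groups_present)

  if (single) {
    message("single score group; log-rank test skipped")
    lr_chi <- NA_real_; lr_p <- NA_real_
  } else {
    sd2 <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    lr_chi <- sd2$chisq
    lr_p <- pchisq(sd2$chisq, df = length(sd2$n) - 1, lower.tail = FALSE)
  }

  wp <- NA_real_
  if (!is.null(outcomes)) {
    ed <- outcomes$ED[match(d$patient_id, outcomes$patient_id)]
    if (length(unique(ed[!is.na(ed)])) == 2)
      wp <- suppressWarnings(
        wilcox.test(d$score[ed == 1], d$score[ed == 0], exact = FALSE)$p.value)
  }

  rev_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1, data = d)
  med_fu <- unname(summary(rev_fit)$table["median"])

  structure(list(fit = fit, surv_at_horizon = sv,
                 logrank_chisq = lr_chi, logrank_p = lr_p,
                 wilcoxon_p = wp, median_followup = med_fu,
                 horizon = horizon, n_groups = nlevels(groups_present),
                 data = d),
            class = "edrna_survival")
}

#' @export
print.edrna_survival <- function(x, ...) {
  cat("disease-specific survival at", x$horizon, "months:\n")
  print(round(100 * x$surv_at_horizon, 1))
  if (!is.na(x$logrank_p))
    cat("log-rank p =", format.pval(x$logrank_p, digits = 3), "\n")
  if (!is.na(x$wilcoxon_p))
    cat("score by ED, Wilcoxon p =", format.pval(x$wilcoxon_p, digits = 3), "\n")
  cat("median follow-up (reverse KM):", x$median_followup, "months\n")
  invisible(x)
}

#' Local over-representation test for gene sets
#'
#' One-sided Fisher exact test per term on the 2x2 overlap table between
#' the query set and each gene set, with Benjamini-Hochberg correction
#' across terms. Replaces web-based enrichment with a fully local
#' equivalent.
#'
#' @param query character vector of query gene ids.
#' @param collections named list of gene sets (e.g. from [read_gmt()]).
#' @param background_size size of the gene universe.
#' @return data.frame: `term`, `k` (overlap), `term_size`, `query_size`,
#'   `odds_ratio`, `p`, `fdr`, ordered by p.
#' @export
local_ora <- function(query, collections, background_size) {
  if (!length(query)) stop("empty query set")
  if (!length(collections)) stop("empty gene-set collection")
  query <- unique(query)
  n <- length(query)
  if (n > background_size)
    stop("query larger than the background universe")
  rows <- lapply(names(collections), function(term) {
    set <- unique(collections[[term]])
    K <- length(set)
    if (K > background_size)
      stop("term `", term, "` larger than the background universe")
    k <- length(intersect(query, set))
    tab <- matrix(c(k, K - k, n - k, background_size - K - n + k), 2, 2)
    ft <- fisher.test(tab, alternative = "greater")
    data.frame(term = term, k = k, term_size = K, query_size = n,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited gene-set format: term, description, then member
#' genes. Parsing is delegated to `fgsea::gmtPathways`.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the `fgsea` package")
  fgsea::gmtPathways(path)
}
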