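#' Derive per-patient CBC dynamics features
#'
#' For each cell type c in ANC, PLT, Hb, ALC, Mo computes the dynamics
#' features used throughout the pipeline:
#' \describe{
#'   \item{c0}{pretreatment value,}
#'   \item{minc}{nadir: minimum over all on-treatment panels (week >= 1,
#'     including the week-2 draw),}
#'   \item{c1}{geometric mean `sqrt(c0 * minc)`,}
#'   \item{c2}{week-2 on-treatment value,}
#'   \item{c3}{log recovery ratio `log(c2 / c0)` (natural log by default;
#'     the base only rescales c3, all downstream use is sign- and
#'     correlation-based).}
#' }
#' plus the baseline and geometric-mean blood-count ratios
#' NLR = ANC/ALC, PLR = PLT/ALC, LMR = ALC/Mo (suffix 0 from the c0
#' values, suffix 1 from the c1 values).
#'
#' @param cbc long data.frame of serial panels with columns `patient_id`,
#'   `week` (0 = pretreatment) and one column per cell type
#'   (`ANC`, `PLT`, `Hb`, `ALC`, `Mo`).
#' @param log_base base of the logarithm used for c3 (default `exp(1)`).
#' @return data.frame, one row per patient: `patient_id`, then for each
#'   cell type the columns `<c>0`, `min<c>`, `<c>1`, `<c>2`, `<c>3`, and
#'   the six ratio columns `NLR0`, `PLR0`, `LMR0`, `NLR1`, `PLR1`, `LMR1`.
#' @examples
#' cbc <- data.frame(patient_id = "P1", week = c(0, 1, 2),
#'                   ANC = c(4000, 1000, 2000), PLT = c(250, 150, 180),
#'                   Hb = c(12, 11, 11.5), ALC = c(1800, 500, 700),
#'                   Mo = c(450, 300, 350))
#' derive_cbc_dynamics(cbc)$ANC1   # sqrt(4000 * 1000) = 2000
#' @export
derive_cbc_dynamics <- function(cbc, log_base = exp(1)) {
  req <- c("patient_id", "week", CBC_CELLS)
  miss <- setdiff(req, names(cbc))
  if (length(miss))
    stop("`cbc` is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(cbc[CBC_CELLS]))) ||
      any(as.matrix(cbc[CBC_CELLS]) <= 0))
    stop("all CBC values must be positive (required by geometric mean and log ratio)")

  pids <- unique(as.character(cbc$patient_id))
  out <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    p <- pids[i]
    sub <- cbc[cbc$patient_id == p, , drop = FALSE]
    if (!any(sub$week == 0))
      stop("patient ", p, ": missing pretreatment (week 0) panel")
    if (!any(sub$week == 2))
      stop("patient ", p, ": missing week-2 panel")
    on_rx <- sub[sub$week >= 1, , drop = FALSE]
    row <- list(patient_id = p)
    for (cell in CBC_CELLS) {
      c0 <- sub[[cell]][sub$week == 0][1]
      c2 <- sub[[cell]][sub$week == 2][1]
      mn <- min(on_rx[[cell]])
      row[[paste0(cell, "0")]] <- c0
      row[[paste0("min", cell)]] <- mn
      row[[paste0(cell, "1")]] <- sqrt(c0 * mn)
      row[[paste0(cell, "2")]] <- c2
      row[[paste0(cell, "3")]] <- log(c2 / c0, base = log_base)
    }
    for (sfx in c("0", "1")) {
      row[[paste0("NLR", sfx)]] <- row[[paste0("ANC", sfx)]] / row[[paste0("ALC", sfx)]]
      row[[paste0("PLR", sfx)]] <- row[[paste0("PLT", sfx)]] / row[[paste0("ALC", sfx)]]
      row[[paste0("LMR", sfx)]] <- row[[paste0("ALC", sfx)]] / row[[paste0("Mo", sfx)]]
    }
    out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign outcome groups by progression and disease-specific death timing
#'
#' Group 1 ("ED", early death): progression within 12 months of treatment
#' and disease-specific death within 15 months. Group 2 ("progression"):
#' progression observed and survival beyond 30 months. Group 3
#' ("non-progression"): no recurrence and follow-up beyond 60 months.
#' Patients matching none of the rules are unassigned (`NA`).
#'
#' @param clinical data.frame with columns `patient_id`,
#'   `progression_time` (months, `NA` if no progression), `death_time`
#'   (months, `NA` if alive), `death_cause`
#'   (`"disease"`, `"other"`, `"alive"`), `follow_up` (months).
#' @return data.frame `patient_id`, `group` (integer 1/2/3 or `NA`),
#'   `group_label`.
#' @examples
#' cl <- data.frame(patient_id = c("A", "B", "C"),
#'                  progression_time = c(6, NA, 20),
#'                  death_time = c(10, NA, 25),
#'                  death_cause = c("disease", "alive", "disease"),
#'                  follow_up = c(10, 72, 25))
#' assign_groups(cl)$group   # 1, 3, NA
#' @export
assign_groups <- function(clinical) {
  req <- c("patient_id", "progression_time", "death_time", "death_cause",
           "follow_up")
  miss <- setdiff(req, names(clinical))
  if (length(miss))
    stop("`clinical` is missing column(s): ", paste(miss, collapse = ", "))
  pt <- clinical$progression_time
  dt <- clinical$death_time
  fu <- clinical$follow_up
  dead <- !is.na(dt)
  bad <- dead & !is.na(pt) & dt < pt
  if (any(bad))
    stop("death before progression for patient(s): ",
         paste(clinical$patient_id[bad], collapse = ", "))
  surv <- ifelse(dead, dt, fu)

  g1 <- !is.na(pt) & pt <= 12 & dead & clinical$death_cause == "disease" & dt <= 15
  g2 <- !g1 & !is.na(pt) & surv > 30
  g3 <- !g1 & !g2 & is.na(pt) & fu > 60
  group <- ifelse(g1, 1L, ifelse(g2, 2L, ifelse(g3, 3L, NA_integer_)))
  data.frame(patient_id = clinical$patient_id, group = group,
             group_label = c("ED", "progression", "non-progression")[group],
             stringsAsFactors = FALSE)
}

#' Early-death and early-progression indicators
#'
#' ED = outcome group 1 (progression <= 12 months with disease-specific
#' death <= 15 months); EP = progression within 12 months of treatment.
#'
#' @inheritParams assign_groups
#' @return data.frame `patient_id`, `ED` (0/1), `EP` (0/1).
#' @export
outcome_indicators <- function(clinical) {
  grp <- assign_groups(clinical)
  data.frame(patient_id = clinical$patient_id,
             ED = as.integer(!is.na(grp$group) & grp$group == 1L),
             EP = as.integer(!is.na(clinical$progression_time) &
                               clinical$progression_time <= 12),
             stringsAsFactors = FALSE)
}

#' Greedy nearest-neighbour propensity-score matching
#'
#' Estimates the propensity of arm membership by logistic regression on
#' the covariates and matches each treated patient to its `ratio` nearest
#' controls on the logit-propensity scale, greedily and without
#' replacement. Complete separation (or any failure of the logistic fit)
#' triggers a warning and a fallback to exact matching on the joint
#' covariate strata.
#'
#' @param data data.frame containing `patient_id`, the arm variable and
#'   the covariates.
#' @param arm name of the two-level arm column; `treat_label` /
#'   `control_label` name its levels.
#' @param treat_label,control_label values of `data[[arm]]` defining the
#'   treated and control arms.
#' @param covariates character vector of covariate column names (numeric
#'   or categorical).
#' @param ratio controls per treated patient (1 or 2).
#' @param caliper optional maximum logit-propensity distance, expressed as
#'   a multiple of the SD of the logit propensity (`NULL` = no caliper).
#' @return list with `matches` (data.frame `treated`, `control`),
#'   `matched_ids`, `smd_before`, `smd_after` (standardized mean
#'   differences per covariate indicator), and `method`
#'   (`"propensity"` or `"exact_strata"`).
#' @export
propensity_match <- function(data, arm, treat_label, control_label,
                             covariates, ratio = 1, caliper = NULL) {
  stopifnot(ratio %in% c(1, 2))
  miss <- setdiff(c("patient_id", arm, covariates), names(data))
  if (length(miss))
    stop("`data` is missing column(s): ", paste(miss, collapse = ", "))
  keep <- data[[arm]] %in% c(treat_label, control_label)
  d <- data[keep, , drop = FALSE]
  treated <- d[[arm]] == treat_label
  if (sum(treated) < 2 || sum(!treated) < 2)
    stop("need at least 2 patients per arm")
  if (sum(!treated) < ratio)
    stop("insufficient controls: need ", ratio, " per treated patient, have ",
         sum(!treated))

  X <- .covariate_indicators(d, covariates)
  smd_before <- .smd(X, treated)

  fml <- as.formula(paste(".arm ~", paste(sprintf("`%s`", covariates), collapse = "+")))
  d$.arm <- as.integer(treated)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  prob <- fitted(fit)
  if (separated || any(prob > 1 - 1e-10) || any(prob < 1e-10)) {
    warning("complete separation in propensity model; falling back to exact stratum matching")
    return(.exact_stratum_match(d, treated, covariates, ratio, X, smd_before))
  }
  lp <- log(prob / (1 - prob))
  cal_dist <- if (is.null(caliper)) Inf else caliper * sd(lp)

  t_idx <- which(treated)
  c_idx <- which(!treated)
  # deterministic: treated processed in patient_id order, ties in distance
  # broken by control patient_id order
  t_idx <- t_idx[order(d$patient_id[t_idx])]
  c_idx <- c_idx[order(d$patient_id[c_idx])]
  avail <- rep(TRUE, length(c_idx))
  matches <- list()
  for (ti in t_idx) {
    picked <- integer(0)
    for (k in seq_len(ratio)) {
      cand <- which(avail)
      if (!length(cand)) break
      dist <- abs(lp[c_idx[cand]] - lp[ti])
      best <- cand[which.min(dist)]
      if (dist[which.min(dist)] > cal_dist) break
      avail[best] <- FALSE
      picked <- c(picked, c_idx[best])
    }
    if (length(picked))
      matches[[length(matches) + 1L]] <-
        data.frame(treated = d$patient_id[ti],
                   control = d$patient_id[picked],
                   stringsAsFactors = FALSE)
  }
  matches <- if (length(matches)) do.call(rbind, matches)
  else data.frame(treated = character(0), control = character(0))
  ids <- unique(c(matches$treated, matches$control))
  in_match <- d$patient_id %in% ids
  smd_after <- .smd(X[in_match, , drop = FALSE], treated[in_match])
  list(matches = matches, matched_ids = ids,
       smd_before = smd_before, smd_after = smd_after,
       propensity = setNames(prob, d$patient_id), method = "propensity")
}

.covariate_indicators <- function(d, covariates) {
  cols <- lapply(covariates, function(v) {
    x <- d[[v]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      lev <- sort(unique(as.character(x)))
      m <- sapply(lev, function(l) as.numeric(x == l))
      colnames(m) <- paste(v, lev, sep = ".")
    }
    m
  })
  do.call(cbind, cols)
}

.smd <- function(X, treated) {
  apply(X, 2, function(x) {
    mt <- mean(x[treated]); mc <- mean(x[!treated])
    s <- sqrt((var(x[treated]) + var(x[!treated])) / 2)
    if (!is.finite(s) || s == 0) return(0)
    (mt - mc) / s
  })
}

.exact_stratum_match <- function(d, treated, covariates, ratio, X, smd_before) {
  strata <- do.call(paste, c(lapply(covariates, function(v) as.character(d[[v]])),
                             sep = "|"))
  matches <- list()
  for (s in unique(strata[treated])) {
    ts <- which(treated & strata == s)
    cs <- which(!treated & strata == s)
    ts <- ts[order(d$patient_id[ts])]
    cs <- cs[order(d$patient_id[cs])]
    for (ti in ts) {
      take <- utils::head(cs, ratio)
      cs <- setdiff(cs, take)
      if (length(take))
        matches[[length(matches) + 1L]] <-
          data.frame(treated = d$patient_id[ti], control = d$patient_id[take],
                     stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches)
  else data.frame(treated = character(0), control = character(0))
  ids <- unique(c(matches$treated, matches$control))
  in_match <- d$patient_id %in% ids
  smd_after <- if (any(in_match)) .smd(X[in_match, , drop = FALSE], treated[in_match])
  else smd_before * NA
  list(matches = matches, matched_ids = ids, smd_before = smd_before,
       smd_after = smd_after, propensity = NULL, method = "exact_strata")
}

#' Compare variables between two patient groups
#'
#' For each continuous variable, Shapiro-Wilk normality is checked in both
#' arms at alpha = 0.05; if both pass, a Welch t-test is used, otherwise a
#' Wilcoxon rank-sum test. Categorical variables use a chi-square test
#' without continuity correction. Flags mark p < 0.05 (`"*"`) and
#' p < 0.1 (`"."`).
#'
#' @param data data.frame holding the variables and the arm column.
#' @param arm name of a two-level grouping column.
#' @param variables character vector of columns to compare.
#' @return data.frame with one row per variable: `variable`, `type`,
#'   `test`, `summary_A`, `summary_B` (mean for t-tests, median for
#'   Wilcoxon), `direction` (`"A>B"`, `"A<B"`, `""`), `p`, `flag`,
#'   `note`. Arm A is the first level (alphabetical, or factor order).
#' @export
compare_groups <- function(data, arm, variables) {
  g <- data[[arm]]
  if (is.null(g)) stop("no column `", arm, "` in `data`")
  lev <- if (is.factor(g)) levels(droplevels(as.factor(g))) else sort(unique(as.character(g)))
  if (length(lev) != 2) stop("`", arm, "` must have exactly two levels")
  a <- g == lev[1]; b <- g == lev[2]
  if (sum(a) < 3 || sum(b) < 3) stop("need at least 3 patients per arm")

  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("no column `", v, "` in `data`")
    if (is.numeric(x)) {
      xa <- x[a]; xb <- x[b]
      if (sd(xa) == 0 && sd(xb) == 0) {
        return(data.frame(variable = v, type = "continuous", test = "none",
                          summary_A = mean(xa), summary_B = mean(xb),
                          direction = "", p = NA_real_, flag = "",
                          note = "zero variance in both arms; test skipped",
                          stringsAsFactors = FALSE))
      }
      normal <- function(y) {
        if (sd(y) == 0 || length(y) < 3) return(FALSE)
        shapiro.test(y)$p.value >= 0.05
      }
      if (normal(xa) && normal(xb)) {
        p <- t.test(xa, xb)$p.value
        test <- "welch_t"; sa <- mean(xa); sb <- mean(xb)
      } else {
        p <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
        test <- "wilcoxon"; sa <- median(xa); sb <- median(xb)
      }
      dir <- if (sa > sb) "A>B" else if (sa < sb) "A<B" else ""
      data.frame(variable = v, type = "continuous", test = test,
                 summary_A = sa, summary_B = sb, direction = dir, p = p,
                 flag = if (is.na(p)) "" else if (p < 0.05) "*" else if (p < 0.1) "." else "",
                 note = "", stringsAsFactors = FALSE)
    } else {
      tab <- table(as.character(x)[a | b], ifelse(a[a | b], "A", "B"))
      p <- if (nrow(tab) < 2) NA_real_
      else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      data.frame(variable = v, type = "categorical", test = "chisq",
                 summary_A = NA_real_, summary_B = NA_real_, direction = "",
                 p = p,
                 flag = if (is.na(p)) "" else if (p < 0.05) "*" else if (p < 0.1) "." else "",
                 note = if (nrow(tab) < 2) "single level; test skipped" else "",
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  attr(res, "arms") <- setNames(lev, c("A", "B"))
  res
}
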