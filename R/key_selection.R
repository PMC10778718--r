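#' Exhaustive all-subsets regression
#'
#' Enumerates every predictor subset of size 1..`max_k`, fits each by
#' ordinary least squares against the outcome, and keeps the best model
#' per size by adjusted R-squared (plain R-squared is stored as well; only
#' the latter is monotone in size). Ties in adjusted R-squared are broken
#' lexicographically by member names, and predictors are ordered
#' alphabetically internally, so results do not depend on column order.
#' The retained-model pool — over which per-predictor inclusion
#' frequencies are computed — is the set of per-size champions.
#'
#' Exactly collinear predictors are dropped up front with a warning
#' (keeping the alphabetically ordered pivots of a rank-revealing QR).
#'
#' @param x patients x predictors numeric matrix (e.g. the log2
#'   fold-change columns of the network RNAs).
#' @param y numeric outcome, usually the binary early-death indicator fit
#'   as a linear probability model.
#' @param max_k largest subset size; default `min(10, floor(n/4), p)`.
#' @param standardize scale predictors to unit variance before fitting
#'   (fit statistics are invariant to this; default TRUE).
#' @return object of class `edrna_subsets`: list with `per_size`
#'   (data.frame `k`, `members`, `r2`, `adj_r2`), `best_models` (list of
#'   character vectors), `inclusion_freq` (named, over all predictors),
#'   `dropped` (collinear predictors removed), `n`, `max_k`.
#' @export
exhaustive_subsets <- function(x, y, max_k = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("`x` must have predictor column names")
  n <- nrow(x)
  if (length(y) != n) stop("`y` must have one value per row of `x`")
  keep <- complete.cases(x, y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]; n <- nrow(x)

  x <- x[, order(colnames(x)), drop = FALSE]
  all_names <- colnames(x)

  ## drop exactly collinear predictors (rank-revealing QR on centred data)
  Xc <- scale(x, center = TRUE, scale = standardize)
  const <- !is.finite(colSums(Xc)) | apply(x, 2, sd) == 0
  if (any(const)) Xc[, const] <- 0
  qx <- qr(Xc)
  dropped <- character(0)
  if (qx$rank < ncol(Xc)) {
    keep_cols <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- colnames(Xc)[-keep_cols]
    warning("dropping collinear/constant predictor(s): ",
            paste(dropped, collapse = ", "))
    Xc <- Xc[, keep_cols, drop = FALSE]
  }
  p <- ncol(Xc)
  if (p == 0) stop("no usable predictors")
  if (is.null(max_k)) max_k <- min(10L, floor(n / 4), p)
  max_k <- min(max_k, p)
  if (n <= max_k + 1)
    stop("need more patients than max_k + 1 (n = ", n, ", max_k = ", max_k, ")")

  yc <- y - mean(y)
  yy <- sum(yc^2)
  if (yy == 0) stop("outcome is constant")
  G <- crossprod(Xc)
  g <- drop(crossprod(Xc, yc))

  per_size <- vector("list", max_k)
  best_models <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    combos <- combn(p, k)
    best_adj <- -Inf; best_r2 <- NA_real_; best_set <- NULL
    for (j in seq_len(ncol(combos))) {
      S <- combos[, j]
      b <- tryCatch(solve(G[S, S, drop = FALSE], g[S]),
                    error = function(e) NULL)
      if (is.null(b)) next
      r2 <- sum(b * g[S]) / yy
      adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
      if (adj > best_adj + 1e-12) {        # strict improvement; first max
        best_adj <- adj; best_r2 <- r2; best_set <- S
      }
    }
    if (is.null(best_set)) next
    members <- colnames(Xc)[best_set]
    best_models[[k]] <- members
    per_size[[k]] <- data.frame(k = k,
                                members = paste(members, collapse = ","),
                                r2 = best_r2, adj_r2 = best_adj,
                                stringsAsFactors = FALSE)
  }
  per_size <- do.call(rbind, per_size)
  best_models <- best_models[!vapply(best_models, is.null, logical(1))]
  freq <- vapply(all_names, function(nm)
    mean(vapply(best_models, function(m) nm %in% m, logical(1))),
    numeric(1))
  structure(list(per_size = per_size, best_models = best_models,
                 inclusion_freq = freq, dropped = dropped,
                 n = n, max_k = max_k),
            class = "edrna_subsets")
}

#' @export
print.edrna_subsets <- function(x, ...) {
  cat("edrna_subsets: best models for k = 1..", x$max_k,
      " (n = ", x$n, ")\n", sep = "")
  print(x$per_size, row.names = FALSE)
  invisible(x)
}

#' Select key RNAs by inclusion frequency
#'
#' Keeps non-coding RNAs appearing in more than `nc_thresh` of the
#' retained models and mRNAs appearing in more than `m_thresh` of them
#' (strict inequalities: an ncRNA at exactly the threshold is excluded).
#'
#' @param res an `edrna_subsets` object.
#' @param biotype named biotype vector covering the predictors.
#' @param nc_thresh,m_thresh inclusion-frequency thresholds for ncRNAs
#'   (default 0.5) and mRNAs (default 0.6).
#' @return list with `key_nc`, `key_m`, `key` (union) and the
#'   per-predictor `freq`.
#' @export
select_key_rnas <- function(res, biotype, nc_thresh = 0.5, m_thresh = 0.6) {
  stopifnot(inherits(res, "edrna_subsets"))
  freq <- res$inclusion_freq
  bt <- biotype[names(freq)]
  is_m <- !is.na(bt) & bt == "mRNA"
  key_nc <- names(freq)[!is_m & freq > nc_thresh]
  key_m <- names(freq)[is_m & freq > m_thresh]
  list(key_nc = key_nc, key_m = key_m, key = c(key_nc, key_m), freq = freq)
}

#' RNAs linked to all five CBC cell types
#'
#' Among the supplied network nodes, returns the RNAs whose
#' annotation-variant link flags cover all five cell types (ANC, PLT, Hb,
#' ALC, Mo — each via any of c0, c1, c2, c3, min c). The attribute
#' `venn` tabulates nodes by their linked-cell-type combination (a
#' partition: region counts sum to the number of nodes).
#'
#' @param flags an `edrna_flags` object computed with
#'   `variant = "network_annotation"`.
#' @param nodes character vector of network RNA ids.
#' @return character vector of all-CBC RNAs, with attribute `venn`.
#' @export
all_cbc_coverage <- function(flags, nodes) {
  stopifnot(inherits(flags, "edrna_flags"))
  if (flags$variant != "network_annotation")
    stop("`flags` must be computed with variant = \"network_annotation\"")
  nodes <- intersect(as.character(nodes), rownames(flags$cell_flags))
  cf <- flags$cell_flags[nodes, , drop = FALSE]
  combo <- apply(cf, 1, function(z)
    if (!any(z)) "(none)" else paste(CBC_CELLS[z], collapse = "&"))
  out <- nodes[flags$n_linked_cells[nodes] == 5]
  attr(out, "venn") <- table(combo)
  out
}
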