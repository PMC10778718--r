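# Fixtures built in code; all deterministic under fixed seeds.

# Minimal paired count object: r RNAs x 2*np samples.
toy_paired_counts <- function(counts, biotype = NULL) {
  np <- ncol(counts) / 2
  pid <- sprintf("P%d", seq_len(np))
  colnames(counts) <- as.vector(rbind(paste0(pid, "_pre"), paste0(pid, "_post")))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("rna%d", seq_len(nrow(counts)))
  if (is.null(biotype)) biotype <- rep("mRNA", nrow(counts))
  paired_counts(counts, biotype,
                data.frame(patient_id = pid,
                           pre = paste0(pid, "_pre"),
                           post = paste0(pid, "_post")))
}

# One-patient serial CBC table from explicit per-week values.
toy_cbc <- function(patient_id = "P1", weeks = c(0, 1, 2),
                    ANC = c(4000, 1000, 2000), PLT = c(250, 150, 180),
                    Hb = c(12, 11, 11.5), ALC = c(1800, 500, 700),
                    Mo = c(450, 300, 350)) {
  data.frame(patient_id = patient_id,
             time_tag = ifelse(weeks == 0, "pre", paste0("week", weeks)),
             week = weeks, ANC = ANC, PLT = PLT, Hb = Hb, ALC = ALC, Mo = Mo,
             stringsAsFactors = FALSE)
}

# Patients x RNA matrix whose sample correlation matrix is exactly `C`
# (columns built from an orthonormal basis orthogonal to the intercept).
exact_cor_lfc <- function(C, n, seed = 1, prefix = "rna") {
  p <- ncol(C)
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  X <- Q %*% chol(C)
  colnames(X) <- sprintf("%s%d", prefix, seq_len(p))
  rownames(X) <- sprintf("P%d", seq_len(n))
  X
}

# Hand-assembled association object (unit tests of flag logic operate on
# the documented structure directly).
toy_assoc <- function(R, P, biotype = NULL, var_cor = NULL) {
  if (is.null(biotype))
    biotype <- setNames(rep("mRNA", nrow(R)), rownames(R))
  if (is.null(var_cor)) {
    var_cor <- diag(ncol(R))
    dimnames(var_cor) <- list(colnames(R), colnames(R))
  }
  structure(list(R = R, P = P,
                 N = matrix(40, nrow(R), ncol(R), dimnames = dimnames(R)),
                 var_cor = var_cor, biotype = biotype,
                 variables = colnames(R)),
            class = "edrna_assoc")
}

# Full variable name set used by the association stage.
assoc_variables <- function() {
  cells <- c("ANC", "PLT", "Hb", "ALC", "Mo")
  c(as.vector(vapply(cells, function(cl)
    c(paste0(cl, "0"), paste0("min", cl), paste0(cl, "1"),
      paste0(cl, "2"), paste0(cl, "3")), character(5))),
    "NLR0", "PLR0", "LMR0", "NLR1", "PLR1", "LMR1", "ED", "EP")
}
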