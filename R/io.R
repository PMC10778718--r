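#' Read and write paired count tables
#'
#' The count TSV has columns `rna_id`, `biotype`, then one column per
#' sample. Sample columns follow the `<patient>_pre` / `<patient>_post`
#' naming convention, from which the pairing map is reconstructed unless
#' supplied explicitly.
#'
#' @param path file path.
#' @param pairs optional pairing data.frame (`patient_id`, `pre`,
#'   `post`); default: inferred from the sample names.
#' @return [read_counts_tsv()]: a [paired_counts()] object;
#'   [write_counts_tsv()]: `path`, invisibly.
#' @export
read_counts_tsv <- function(path, pairs = NULL) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("rna_id", "biotype") %in% names(d)))
    stop("count TSV must have `rna_id` and `biotype` columns")
  samp <- setdiff(names(d), c("rna_id", "biotype"))
  m <- as.matrix(d[, samp, drop = FALSE])
  rownames(m) <- d$rna_id
  storage.mode(m) <- "integer"
  if (is.null(pairs)) {
    pre <- grep("_pre$", samp, value = TRUE)
    pid <- sub("_pre$", "", pre)
    pairs <- data.frame(patient_id = pid, pre = pre,
                        post = paste0(pid, "_post"), stringsAsFactors = FALSE)
  }
  paired_counts(m, d$biotype, pairs)
}

#' @rdname read_counts_tsv
#' @param pc a [paired_counts()] object.
#' @export
write_counts_tsv <- function(pc, path) {
  stopifnot(inherits(pc, "paired_counts"))
  d <- data.frame(rna_id = rownames(pc$counts),
                  biotype = unname(pc$biotype),
                  pc$counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the clinical table
#'
#' Plain CSV with one row per patient; see [assign_groups()] for the
#' outcome columns and [simulate_cohort()] for the full column set.
#'
#' @param path file path.
#' @return [read_clinical_csv()]: data.frame; [write_clinical_csv()]:
#'   `path`, invisibly.
#' @export
read_clinical_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_clinical_csv
#' @param clinical the clinical data.frame.
#' @export
write_clinical_csv <- function(clinical, path) {
  write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' Write an association matrix in long format
#'
#' One row per (RNA, variable) pair: `rna`, `variable`, `R`, `p`, `n`.
#'
#' @param assoc an `edrna_assoc` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(assoc, path) {
  stopifnot(inherits(assoc, "edrna_assoc"))
  long <- data.frame(rna = rep(rownames(assoc$R), times = ncol(assoc$R)),
                     variable = rep(colnames(assoc$R), each = nrow(assoc$R)),
                     R = as.vector(assoc$R), p = as.vector(assoc$P),
                     n = as.vector(assoc$N), stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a log2 fold-change table (patients x RNAs)
#'
#' @param lfc matrix from [paired_log2fc()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_lfc_tsv <- function(lfc, path) {
  d <- data.frame(patient_id = rownames(lfc), lfc, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
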