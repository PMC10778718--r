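#' Paired RNA count container
#'
#' Bundles an RNA-by-sample read-count matrix with per-RNA biotype labels
#' and the pre/post pairing map. Each patient contributes exactly two
#' samples: one pretreatment (`pre`) and one drawn during the second week
#' of chemoradiotherapy (`post`).
#'
#' @param counts integer matrix, RNAs in rows (rownames = RNA ids),
#'   samples in columns (colnames = sample ids). Counts must be
#'   non-negative integers.
#' @param biotype character vector, one per RNA row; values among
#'   `c("miRNA","piRNA","snoRNA","snRNA","tRNA","yRNA","lncRNA","mRNA")`.
#' @param pairs data.frame with columns `patient_id`, `pre`, `post`
#'   naming, for every patient, the pre and post sample columns.
#' @return an object of class `paired_counts`: a list with elements
#'   `counts`, `biotype` (named by RNA id) and `pairs`.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("rna", 1:3), paste0("s", 1:4)))
#' pc <- paired_counts(m, c("miRNA", "mRNA", "lncRNA"),
#'                     data.frame(patient_id = c("P1", "P2"),
#'                                pre = c("s1", "s3"), post = c("s2", "s4")))
#' @export
paired_counts <- function(counts, biotype, pairs) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must be a matrix with RNA rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must contain non-negative integers")
  if (length(biotype) != nrow(counts))
    stop("`biotype` must have one entry per RNA row")
  bad <- setdiff(unique(biotype), RNA_BIOTYPES)
  if (length(bad))
    stop("unknown biotype(s): ", paste(bad, collapse = ", "))
  req <- c("patient_id", "pre", "post")
  if (!is.data.frame(pairs) || !all(req %in% names(pairs)))
    stop("`pairs` must be a data.frame with columns patient_id, pre, post")
  samp <- c(pairs$pre, pairs$post)
  if (anyDuplicated(samp))
    stop("each sample may appear in exactly one pre/post slot")
  missing_samp <- setdiff(samp, colnames(counts))
  if (length(missing_samp))
    stop("pair map names sample(s) absent from counts: ",
         paste(missing_samp, collapse = ", "))
  extra <- setdiff(colnames(counts), samp)
  if (length(extra))
    stop("unpaired sample(s) in counts: ", paste(extra, collapse = ", "))
  structure(
    list(counts = counts,
         biotype = setNames(as.character(biotype), rownames(counts)),
         pairs = data.frame(patient_id = as.character(pairs$patient_id),
                            pre = as.character(pairs$pre),
                            post = as.character(pairs$post),
                            stringsAsFactors = FALSE)),
    class = "paired_counts")
}

#' @export
print.paired_counts <- function(x, ...) {
  cat("paired_counts:", nrow(x$counts), "RNAs x", ncol(x$counts),
      "samples (", nrow(x$pairs), "patients )\n")
  cat("biotypes:", paste(names(table(x$biotype)), table(x$biotype),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.paired_counts <- function(x) dim(x$counts)

RNA_BIOTYPES <- c("miRNA", "piRNA", "snoRNA", "snRNA",
                  "tRNA", "yRNA", "lncRNA", "mRNA")

CBC_CELLS <- c("ANC", "PLT", "Hb", "ALC", "Mo")
CBC_RATIOS <- c("NLR", "PLR", "LMR")
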