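#' Admit RNAs into the early-death network
#'
#' An RNA enters the network if either of two conditions holds:
#' \enumerate{
#'   \item it is linked (admission-variant flags) with three or more of
#'     the eight hematological factors (ANC, PLT, Hb, ALC, Mo, NLR, PLR,
#'     LMR) \emph{and} significantly correlated with both the ED and EP
#'     indicators; or
#'   \item it is strongly correlated with ED: |R| > `r_ed_strong`.
#' }
#'
#' @param assoc an `edrna_assoc` object.
#' @param flags an `edrna_flags` object computed with
#'   `variant = "network_admission"`.
#' @param r_ed_strong threshold on |R vs ED| for direct admission
#'   (default 0.5).
#' @return data.frame of admitted RNAs: `rna`, `biotype`, `r_ed`,
#'   `by_condition1`, `by_condition2`.
#' @export
admit_rnas <- function(assoc, flags, r_ed_strong = 0.5) {
  stopifnot(inherits(assoc, "edrna_assoc"), inherits(flags, "edrna_flags"))
  if (flags$variant != "network_admission")
    stop("`flags` must be computed with variant = \"network_admission\"")
  cond1 <- flags$n_linked_hema >= 3 & flags$ed_sig & flags$ep_sig
  cond2 <- !is.na(flags$r_ed) & abs(flags$r_ed) > r_ed_strong
  adm <- cond1 | cond2
  out <- data.frame(rna = rownames(assoc$R)[adm],
                    biotype = unname(assoc$biotype[rownames(assoc$R)[adm]]),
                    r_ed = unname(flags$r_ed[adm]),
                    by_condition1 = unname(cond1[adm]),
                    by_condition2 = unname(cond2[adm]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the RNA correlation network
#'
#' Connects admitted RNAs whose per-patient log2 fold-change profiles have
#' pairwise Pearson |R| above the threshold. The absolute value is used
#' so anti-correlated partners connect; the signed coefficient is kept as
#' an edge attribute. Isolated admitted RNAs are dropped, so the reported
#' node count refers to the connected graph.
#'
#' @param lfc patients x RNAs log2 fold-change matrix.
#' @param admitted data.frame from [admit_rnas()] (or a character vector
#'   of RNA ids).
#' @param threshold edge threshold on |R| (the study uses 0.5 and 0.6).
#' @param flags optional `edrna_flags` object (annotation variant) whose
#'   per-cell link flags and ED signs are copied onto the nodes.
#' @return an [igraph::graph] with vertex attributes `name`, `biotype`,
#'   `r_ed`, `ed_sign`, `linked_cells`; edge attributes `r` (signed) and
#'   `weight` (= |r|); graph attribute `threshold`. Empty (no edge above
#'   threshold) yields a warning and an edgeless, vertexless graph.
#' @export
build_graph <- function(lfc, admitted, threshold = 0.5, flags = NULL) {
  rna <- if (is.data.frame(admitted)) admitted$rna else as.character(admitted)
  rna <- intersect(colnames(lfc), rna)
  if (length(rna) < 2) stop("need at least 2 admitted RNAs present in `lfc`")
  C <- suppressWarnings(cor(lfc[, rna, drop = FALSE],
                            use = "pairwise.complete.obs"))
  C[is.na(C)] <- 0
  ut <- which(upper.tri(C) & abs(C) > threshold, arr.ind = TRUE)
  if (!nrow(ut)) {
    warning("no RNA pair exceeds |R| > ", threshold, "; empty network")
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "threshold", threshold)
    return(g)
  }
  edges <- data.frame(from = rna[ut[, 1]], to = rna[ut[, 2]],
                      r = C[ut], weight = abs(C[ut]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  biotype <- attr(lfc, "biotype")
  if (!is.null(biotype))
    g <- igraph::set_vertex_attr(g, "biotype",
                                 value = unname(biotype[igraph::V(g)$name]))
  if (!is.null(flags)) {
    idx <- match(igraph::V(g)$name, names(flags$r_ed))
    g <- igraph::set_vertex_attr(g, "r_ed", value = unname(flags$r_ed[idx]))
    g <- igraph::set_vertex_attr(g, "ed_sign", value = unname(flags$ed_sign[idx]))
    g <- igraph::set_vertex_attr(g, "linked_cells",
                                 value = vapply(idx, function(i)
                                   paste(CBC_CELLS[flags$cell_flags[i, ]],
                                         collapse = ","), character(1)))
  }
  igraph::set_graph_attr(g, "threshold", threshold)
}

#' Export a network to GraphML or a TSV edge list
#'
#' @param net an [igraph::graph] from [build_graph()].
#' @param path output file path.
#' @param format `"graphml"` (lossless round-trip via igraph) or
#'   `"edgelist"` (TSV: from, to, r, weight).
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (igraph::vcount(net) == 0) stop("refusing to export an empty network")
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(net, what = "edges")
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
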