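#' Run the full early-death biomarker pipeline
#'
#' Chains every stage on a cohort: CBC dynamics and outcome groups;
#' detection filtering, TMM normalization, per-patient log2 fold changes;
#' the RNA-CBC-outcome correlation matrix; network admission and graph
#' construction at each |R| threshold; exhaustive-subsets key-RNA
#' selection (union over thresholds); the all-CBC coverage criterion; and
#' finally the three-RNA composite score with disease-specific survival
#' stratification.
#'
#' The final triple is one ED-positive ncRNA and one ED-negative ncRNA
#' from the key-RNA union (falling back to the most strongly ED-correlated
#' admitted ncRNA of the required sign when the union has none), plus one
#' mRNA covering all five CBC cell types (falling back to the most
#' ED-negative key or admitted mRNA). Stages degrade gracefully: with no
#' admissible network the key sets are empty and the score/survival slots
#' are `NULL`.
#'
#' @param clinical clinical table (see [simulate_cohort()]).
#' @param cbc long CBC panel table (see [derive_cbc_dynamics()]).
#' @param counts a [paired_counts()] object.
#' @param alpha screening significance threshold for associations.
#' @param thresholds network edge thresholds on |R|.
#' @param r_ed_strong |R vs ED| for direct network admission.
#' @param max_k largest subset size in the exhaustive search
#'   (default `min(10, floor(n/4), p)`).
#' @param nc_thresh,m_thresh inclusion-frequency thresholds for ncRNAs
#'   and mRNAs.
#' @param min_detect_frac detection-filter threshold.
#' @param horizon survival horizon in months.
#' @return list with elements `dyn`, `groups`, `outcomes`, `lfc`,
#'   `assoc`, `flags_admission`, `flags_annotation`, `admitted`,
#'   `networks`, `subsets`, `keys`, `key_union`, `all_cbc`,
#'   `homeostasis`, `triple`, `scores`, `survival`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 20, seed = 3))
#' res <- run_pipeline(cohort$clinical, cohort$cbc, cohort$counts)
#' res$triple
#' @export
run_pipeline <- function(clinical, cbc, counts, alpha = 0.05,
                         thresholds = c(0.5, 0.6), r_ed_strong = 0.5,
                         max_k = NULL, nc_thresh = 0.5, m_thresh = 0.6,
                         min_detect_frac = 0.5, horizon = 30) {
  dyn <- derive_cbc_dynamics(cbc)
  groups <- assign_groups(clinical)
  outcomes <- outcome_indicators(clinical)

  filtered <- detection_filter(counts, min_detect_frac)
  factors <- tmm_factors(filtered)
  lfc <- paired_log2fc(filtered, factors)

  assoc <- correlate_all(lfc, dyn, outcomes)
  flags_adm <- cbc_link_flags(assoc, alpha, "network_admission")
  flags_ann <- cbc_link_flags(assoc, alpha, "network_annotation")
  homeo <- homeostasis_screen(assoc, alpha)
  admitted <- admit_rnas(assoc, flags_adm, r_ed_strong)

  networks <- list(); subsets <- list(); keys <- list()
  for (th in thresholds) {
    nm <- paste0("R", th)
    net <- if (nrow(admitted) >= 2)
      tryCatch(suppressWarnings(build_graph(lfc, admitted, th, flags_ann)),
               error = function(e) NULL)
    networks[[nm]] <- net
    nodes <- if (!is.null(net)) as.character(igraph::V(net)$name) else character(0)
    if (length(nodes) >= 2) {
      res <- tryCatch(
        suppressWarnings(exhaustive_subsets(lfc[, nodes, drop = FALSE],
                                            outcomes$ED[match(rownames(lfc),
                                                              outcomes$patient_id)],
                                            max_k = max_k)),
        error = function(e) NULL)
      subsets[[nm]] <- res
      keys[[nm]] <- if (!is.null(res))
        select_key_rnas(res, assoc$biotype, nc_thresh, m_thresh)
    } else {
      subsets[nm] <- list(NULL)
      keys[nm] <- list(NULL)
    }
  }
  key_union <- unique(unlist(lapply(keys, function(k) k$key)))

  nodes_main <- if (!is.null(networks[[1]]))
    as.character(igraph::V(networks[[1]])$name) else character(0)
  all_cbc <- all_cbc_coverage(flags_ann, nodes_main)

  triple <- .select_triple(key_union, all_cbc, admitted, assoc$biotype,
                           assoc$R[, "ED"])

  scores <- NULL; surv <- NULL
  if (!anyNA(unlist(triple[c("rna_pos", "rna_neg")]))) {
    scores <- composite_score(lfc, triple$rna_pos, triple$rna_neg)
    surv <- km_logrank(scores, clinical, horizon, outcomes)
  }

  list(dyn = dyn, groups = groups, outcomes = outcomes, factors = factors,
       lfc = lfc, assoc = assoc, flags_admission = flags_adm,
       flags_annotation = flags_ann, admitted = admitted,
       networks = networks, subsets = subsets, keys = keys,
       key_union = key_union, all_cbc = all_cbc, homeostasis = homeo,
       triple = triple, scores = scores, survival = surv)
}

# Deterministic triple selection with documented fallbacks.
.select_triple <- function(key_union, all_cbc, admitted, biotype, r_ed) {
  pick <- function(cands, want_sign) {
    cands <- cands[!is.na(r_ed[cands]) & sign(r_ed[cands]) == want_sign]
    if (!length(cands)) return(NA_character_)
    cands[order(-abs(r_ed[cands]), cands)][1]
  }
  is_m <- function(ids) !is.na(biotype[ids]) & biotype[ids] == "mRNA"
  key_nc <- key_union[!is_m(key_union)]
  key_m <- key_union[is_m(key_union)]
  adm_nc <- admitted$rna[!is_m(admitted$rna)]
  adm_m <- admitted$rna[is_m(admitted$rna)]

  pos_nc <- pick(key_nc, +1)
  if (is.na(pos_nc)) pos_nc <- pick(adm_nc, +1)
  neg_nc <- pick(setdiff(key_nc, pos_nc), -1)
  if (is.na(neg_nc)) neg_nc <- pick(setdiff(adm_nc, pos_nc), -1)

  m_cands <- list(all_cbc[is_m(all_cbc)], key_m, adm_m)
  neg_m <- NA_character_
  for (cands in m_cands) {
    neg_m <- pick(setdiff(cands, c(pos_nc, neg_nc)), -1)
    if (!is.na(neg_m)) break
  }
  list(rna_pos = pos_nc, rna_neg = c(neg_nc, neg_m),
       r_ed = r_ed[c(pos_nc, neg_nc, neg_m)])
}
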