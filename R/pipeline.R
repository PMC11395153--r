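# End-to-end convenience wrapper: QC filtering, prediction, decision-tree
# scoring and funnel reporting for one sample, keeping database-search and
# de novo identifications as separate reports.

#' Run the full Immunopeptidome Score pipeline on one sample
#'
#' Applies the standard processing order: database-search records are
#' deduplicated and decontaminated; de novo records are filtered at the ALC
#' threshold and then deduplicated. Unique scorable 8-12-mers (and only
#' those -- shorter or longer peptides are dismissed at the length stage and
#' are never sent to predictors) are scored for binding and immunogenicity,
#' either through supplied adapter tables (NetMHCpan / IEDB outputs read by
#' the io functions) or with the deterministic stand-in predictors. Each
#' set is then scored with the decision tree and summarized as a funnel.
#'
#' @param records Peptide record tibble (may mix database and de novo rows).
#' @param motifs Named list of [motif_model()] per allele (stand-in
#'   backend). Ignored when `binding` is supplied.
#' @param binding Optional binding call tibble from
#'   [read_netmhcpan_output()]; when `NULL`, the stand-in predictor runs
#'   over `motifs`.
#' @param immuno Optional immunogenicity call tibble from
#'   [read_immunogenicity_output()]; when `NULL`, the stand-in runs.
#' @param contaminants Contaminant table or accession vector for
#'   decontamination (`NULL` for none).
#' @param min_alc ALC threshold for de novo rows (percent, default 80).
#' @param background_n,seed Stand-in background size and seed (one
#'   independent background per allele is drawn from `seed`).
#' @param strong_cutoff,weak_cutoff Rank thresholds for binder classes.
#' @return A list with elements `db` and `de_novo`, each holding `records`
#'   (unique kept records), `scores` ([score_peptides()] output), `funnel`
#'   and `report`; plus the `binding` and `immuno` call tables used.
#' @export
run_immunopeptidome_score <- function(records,
                                      motifs = NULL,
                                      binding = NULL,
                                      immuno = NULL,
                                      contaminants = NULL,
                                      min_alc = 80,
                                      background_n = 100000,
                                      seed = 1,
                                      strong_cutoff = 0.5,
                                      weak_cutoff = 2.0) {
  db_raw <- records[!records$is_de_novo, , drop = FALSE]
  dn_raw <- records[records$is_de_novo, , drop = FALSE]

  db <- deduplicate_and_decontaminate(db_raw, contaminants)
  dn_filt <- filter_de_novo_alc(dn_raw, min_alc)
  dn <- deduplicate_and_decontaminate(dn_filt, NULL)

  to_predict <- unique(c(
    db$records$bare_sequence[db$records$scorable &
                               db$records$length >= 8 & db$records$length <= 12],
    dn$records$bare_sequence[dn$records$scorable &
                               dn$records$length >= 8 & dn$records$length <= 12]
  ))

  if (is.null(binding)) {
    if (is.null(motifs) || length(motifs) == 0) {
      stop("either a binding call table or stand-in motifs must be supplied")
    }
    ord <- order(names(motifs))
    binding <- purrr::list_rbind(lapply(seq_along(ord), function(i) {
      predict_binding_standin(to_predict, motifs[[ord[i]]],
                              background_n = background_n, seed = seed + i,
                              strong_cutoff = strong_cutoff,
                              weak_cutoff = weak_cutoff)
    }))
  }
  if (is.null(immuno)) {
    immuno <- predict_immunogenicity_standin(to_predict)
  }

  score_set <- function(set, label) {
    bundles <- join_predictions(set$records, binding, immuno)
    scores <- score_peptides(set$records, bundles)
    sid <- if (nrow(set$records) > 0) set$records$sample_id[1] else label
    list(
      records = set$records,
      scores = scores,
      funnel = funnel(scores, sample_id = sid),
      report = set$report
    )
  }
  list(
    db = score_set(db, "db"),
    de_novo = score_set(dn, "de_novo"),
    binding = binding,
    immuno = immuno
  )
}
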