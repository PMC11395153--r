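# Uniform prediction contract for MHC-I binding and immunogenicity.
#
# Real predictions enter through file adapters (read_netmhcpan_output,
# read_immunogenicity_output). The *_standin functions are deterministic,
# clearly namespaced surrogates for testing the pipeline without external
# tools; they are simplified position-weight models, not re-implementations
# of the neural-network predictors they stand in for.

#' Classify a binding percentile rank as strong/weak/non binder
#'
#' Strong if the rank is at or below `strong_cutoff`, weak if between
#' `strong_cutoff` (exclusive) and `weak_cutoff` (inclusive), otherwise
#' non-binder. Both boundaries are inclusive on the binder side, matching
#' the SB/WB labeling convention of the NetMHCpan server whose default
#' thresholds (0.5% and 2% rank) these are.
#'
#' @param percent_rank Numeric vector of percentile ranks in (0, 100].
#' @param strong_cutoff,weak_cutoff Thresholds with
#'   `0 < strong_cutoff < weak_cutoff`.
#' @return Character vector in `c("strong", "weak", "non")`; `NA` ranks map
#'   to `"non"`.
#' @examples
#' classify_binding(c(0.5, 2, 2.01))
#' @export
classify_binding <- function(percent_rank, strong_cutoff = 0.5, weak_cutoff = 2.0) {
  if (!(strong_cutoff > 0 && strong_cutoff < weak_cutoff)) {
    stop("configuration error: need 0 < strong_cutoff < weak_cutoff")
  }
  ok <- is.na(percent_rank) | (percent_rank > 0 & percent_rank <= 100)
  if (!all(ok)) stop("percent_rank must lie in (0, 100]")
  dplyr::case_when(
    is.na(percent_rank) ~ "non",
    percent_rank <= strong_cutoff ~ "strong",
    percent_rank <= weak_cutoff ~ "weak",
    TRUE ~ "non"
  )
}

#' Build a stand-in binding motif model for one allele
#'
#' A position-specific scoring model used by [predict_binding_standin()].
#' Log-odds weights are placed on the positions that dominate HLA-I binding
#' -- position 1, the position-2 anchor, and the C-terminal anchor -- with
#' two preferred residues per anchor receiving a large bonus; all internal
#' positions carry weight exactly zero. Restricting weight to the anchor
#' block keeps the model's score distribution exactly enumerable (20^3
#' combinations), which [expected_funnel()] exploits, and leaves the
#' internal positions free to encode independent peptide properties. Weights
#' are drawn deterministically from a seed derived from the allele name, so
#' the same allele always yields the same motif.
#'
#' @param allele Allele name, e.g. `"HLA-A*03:01"`.
#' @param lengths Peptide lengths covered (default 8:12).
#' @param anchor_strength Log-odds bonus added to the preferred anchor
#'   residues (default 2.5).
#' @param background_freqs Background residue frequencies (sum to 1).
#' @param seed Optional integer seed; defaults to a hash of the allele name.
#' @return An object of class `motif_model`: `allele`, `lengths`, `pssm`
#'   (list of 20 x L matrices keyed by length), `background_freqs`.
#' @export
motif_model <- function(allele, lengths = 8:12, anchor_strength = 2.5,
                        background_freqs = aa_background_freqs(),
                        seed = NULL) {
  stopifnot(abs(sum(background_freqs) - 1) < 1e-9)
  aa <- amino_acids()
  if (is.null(seed)) {
    seed <- (sum(utf8ToInt(allele)) * 7919L) %% 2147483647L
  }
  pssm <- with_seed(seed, {
    out <- list()
    for (L in sort(lengths)) {
      m <- matrix(0, nrow = 20, ncol = L, dimnames = list(aa, NULL))
      for (pos in c(1L, 2L, L)) m[, pos] <- stats::rnorm(20, 0, 0.3)
      for (pos in c(2L, L)) {
        preferred <- sample(aa, 2)
        m[preferred, pos] <- m[preferred, pos] + anchor_strength
      }
      out[[as.character(L)]] <- m
    }
    out
  })
  stopifnot(all(vapply(pssm, function(m) all(is.finite(m)), logical(1))))
  structure(
    list(allele = allele, lengths = sort(lengths), pssm = pssm,
         background_freqs = background_freqs),
    class = "motif_model"
  )
}

# Sum of position weights for peptides of a single length under one PSSM.
pssm_scores <- function(peptides, pssm) {
  if (length(peptides) == 0) return(numeric())
  L <- ncol(pssm)
  chars <- matrix(match(unlist(strsplit(peptides, "")), rownames(pssm)),
                  ncol = L, byrow = TRUE)
  sc <- numeric(length(peptides))
  for (j in seq_len(L)) sc <- sc + pssm[chars[, j], j]
  sc
}

#' Stand-in MHC-I binding prediction with empirical percentile ranks
#'
#' Scores each peptide against the motif's position weights and converts
#' the score to a percentile rank against a random background of
#' `background_n` peptides per length, drawn from the motif's background
#' frequencies under the given seed. The rank estimator
#' `100 * (1 + #\{background >= score\}) / (background_n + 1)` never
#' returns 0 and stays in (0, 100]; for a fixed background, the rank is
#' non-increasing in the score. Results are bit-for-bit reproducible given
#' `(peptides, motif, background_n, seed)`.
#'
#' @param peptides Character vector of bare sequences.
#' @param motif A [motif_model()].
#' @param background_n Background sample size per length (default 100000).
#' @param seed Integer seed for the background draw.
#' @param strong_cutoff,weak_cutoff Thresholds for [classify_binding()].
#' @return Tibble with `bare_sequence`, `allele`, `percent_rank`,
#'   `binder_class`, `reason` (`NA`, `"no_motif_for_length"` or
#'   `"non_scorable"`; such calls are class `"non"` with `NA` rank).
#' @export
predict_binding_standin <- function(peptides, motif, background_n = 100000,
                                    seed = 1, strong_cutoff = 0.5,
                                    weak_cutoff = 2.0) {
  stopifnot(inherits(motif, "motif_model"), background_n >= 1)
  n <- length(peptides)
  rank <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  scorable <- is_scorable_sequence(peptides)
  reason[!scorable] <- "non_scorable"
  len <- nchar(peptides)
  covered <- scorable & len %in% motif$lengths
  reason[scorable & !covered] <- "no_motif_for_length"

  bg <- motif$background_freqs[amino_acids()]
  with_seed(seed, {
    for (L in sort(unique(len[covered]))) {
      w <- motif$pssm[[as.character(L)]]
      idx <- matrix(
        sample.int(20, background_n * L, replace = TRUE, prob = bg),
        nrow = background_n, ncol = L
      )
      bg_sc <- numeric(background_n)
      for (j in seq_len(L)) bg_sc <- bg_sc + w[idx[, j], j]
      v <- sort(bg_sc)
      sel <- which(covered & len == L)
      s <- pssm_scores(peptides[sel], w)
      n_below <- findInterval(s, v, left.open = TRUE)  # strictly below s
      n_ge <- background_n - n_below
      rank[sel] <- 100 * (1 + n_ge) / (background_n + 1)
    }
  })
  tibble::tibble(
    bare_sequence = peptides,
    allele = motif$allele,
    percent_rank = rank,
    binder_class = classify_binding(rank, strong_cutoff, weak_cutoff),
    reason = reason
  )
}

#' Stand-in immunogenicity prediction
#'
#' Scores a peptide as the position-weighted sum of per-residue
#' propensities, with positions 1, 2 and the C-terminus given weight zero:
#' those are the MHC anchor positions, which face the binding groove rather
#' than the T-cell receptor, mirroring the anchor masking of the predictor
#' this stands in for. Propensities are centered to sum to zero at load, so
#' the immunogenic/non-immunogenic boundary sits at score 0; a peptide is
#' called immunogenic only for a strictly positive score.
#'
#' @param peptides Character vector of bare sequences.
#' @param weights Per-position weights; default all 1 (anchor positions are
#'   masked regardless). Must cover the longest peptide.
#' @param propensities Named 20-vector of residue propensities; centered
#'   internally.
#' @return Tibble with `bare_sequence`, `score`, `is_immunogenic`
#'   (`NA` score and verdict for non-scorable sequences).
#' @export
predict_immunogenicity_standin <- function(peptides, weights = NULL,
                                           propensities = default_propensities()) {
  stopifnot(all(amino_acids() %in% names(propensities)))
  prop <- propensities[amino_acids()]
  prop <- prop - mean(prop)
  n <- length(peptides)
  len <- nchar(peptides)
  max_len <- if (n > 0) max(len) else 0L
  if (is.null(weights)) weights <- rep(1, max(max_len, 1L))
  if (length(weights) < max_len) {
    stop("weights must cover the longest peptide (", max_len, " residues)")
  }
  score <- rep(NA_real_, n)
  scorable <- is_scorable_sequence(peptides)
  for (L in unique(len[scorable])) {
    sel <- which(scorable & len == L)
    w <- weights[seq_len(L)]
    w[c(1L, 2L, L)] <- 0  # anchor masking
    chars <- matrix(match(unlist(strsplit(peptides[sel], "")), amino_acids()),
                    ncol = L, byrow = TRUE)
    sc <- numeric(length(sel))
    for (j in seq_len(L)) sc <- sc + w[j] * prop[chars[, j]]
    score[sel] <- sc
  }
  tibble::tibble(
    bare_sequence = peptides,
    score = score,
    is_immunogenic = ifelse(is.na(score), NA, score > 0)
  )
}

#' Join binding and immunogenicity calls onto peptide records
#'
#' Builds one prediction bundle per record, keyed by bare sequence. Binding
#' calls (possibly several alleles per peptide) are nested and summarized:
#' whether any allele is a strong binder, and the best (lowest-rank) strong
#' allele. Records without any binding call are flagged `missing_binding`
#' and score 0 at the binding stage; likewise `missing_immunogenicity` for
#' the immunogenicity stage. The result is invariant to the input order of
#' the call tables.
#'
#' @param records Peptide record tibble (one row per unique bare sequence).
#' @param binding Binding call tibble (`bare_sequence`, `allele`,
#'   `percent_rank`, `binder_class`).
#' @param immuno Immunogenicity call tibble (`bare_sequence`, `score`,
#'   `is_immunogenic`).
#' @return Bundle tibble: record identity columns plus `binding_calls`
#'   (list column), `has_strong`, `best_allele`, `best_rank`,
#'   `missing_binding`, `imm_score`, `is_immunogenic`,
#'   `missing_immunogenicity`.
#' @export
join_predictions <- function(records, binding, immuno) {
  b <- binding[order(binding$bare_sequence, binding$percent_rank,
                     binding$allele), , drop = FALSE]
  bsum <- b |>
    dplyr::group_by(.data$bare_sequence) |>
    dplyr::summarise(
      binding_calls = list(dplyr::pick(dplyr::everything())),
      has_strong = any(.data$binder_class == "strong", na.rm = TRUE),
      best_allele = if (any(.data$binder_class == "strong", na.rm = TRUE)) {
        strong <- which(.data$binder_class == "strong")
        .data$allele[strong[which.min(.data$percent_rank[strong])]]
      } else {
        NA_character_
      },
      best_rank = if (any(.data$binder_class == "strong", na.rm = TRUE)) {
        min(.data$percent_rank[.data$binder_class == "strong"], na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  isum <- immuno[order(immuno$bare_sequence), , drop = FALSE]
  isum <- isum[!duplicated(isum$bare_sequence),
               c("bare_sequence", "score", "is_immunogenic")]
  names(isum)[2] <- "imm_score"

  out <- records |>
    dplyr::left_join(bsum, by = "bare_sequence") |>
    dplyr::left_join(isum, by = "bare_sequence")
  out$missing_binding <- vapply(out$binding_calls, is.null, logical(1))
  out$has_strong[out$missing_binding] <- FALSE
  out$missing_immunogenicity <- is.na(out$imm_score)
  out
}
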