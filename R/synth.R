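# Synthetic immunopeptidomics identification tables with planted ground
# truth. The generator emulates the statistical structure of real HLA-I
# identification tables -- a length distribution peaked at 8-12 residues
# with a long tail, charges +1..+6 narrowing to +1..+4 inside the HLA
# window, the two-cluster 1/K0-vs-m/z geometry of singly vs multiply
# charged precursors, a contaminant fraction, de novo rows with ALC in
# [50, 100], and planted strong-binder / immunogenic fractions -- so that
# every pipeline stage can be tested end to end without external data or
# services.

#' Default peptide length distribution
#'
#' Mode at 9 residues, about 78% of the mass on the 8-12 HLA-I window, a
#' small 7-mer fraction, and a geometric tail out to 40 residues. Real runs
#' show occasional identifications beyond 60 residues; the tail is capped at
#' 40 because peptides that long are always dismissed at the length stage
#' and a shorter cap keeps simulations fast.
#'
#' @return Named probability vector over lengths 7..40, summing to 1.
#' @export
default_length_dist <- function() {
  p <- stats::setNames(numeric(34), 7:40)
  p["7"] <- 0.04
  p[as.character(8:12)] <- c(0.13, 0.30, 0.17, 0.10, 0.08)
  tail_len <- 13:40
  tail_w <- 0.8^(tail_len - 13)
  p[as.character(tail_len)] <- 0.18 * tail_w / sum(tail_w)
  p / sum(p)
}

#' Default charge model by length band
#'
#' Categorical charge distributions over +1..+6 per length band: 8-12-mers
#' stay within +1..+4 (mostly +2), shorter peptides within +1..+3, and only
#' long tail peptides reach +5/+6 -- matching the charge structure observed
#' in HLA-I identification tables.
#'
#' @return List of bands, each with `min`, `max` and a 6-vector `probs`.
#' @export
default_charge_model <- function() {
  list(
    list(min = 1L, max = 7L, probs = c(0.30, 0.60, 0.10, 0, 0, 0)),
    list(min = 8L, max = 12L, probs = c(0.15, 0.60, 0.20, 0.05, 0, 0)),
    list(min = 13L, max = 20L, probs = c(0.02, 0.38, 0.40, 0.15, 0.04, 0.01)),
    list(min = 21L, max = 100L, probs = c(0, 0.05, 0.30, 0.35, 0.20, 0.10))
  )
}

#' Configuration for the synthetic sample generator
#'
#' Bundles and validates every generator parameter. Defaults describe a
#' realistic single immunopeptidome run: 5000 identifications, 8% de novo
#' rows, 3% contaminant rows among database hits, 2% planted duplicate
#' rows, ALC drawn from a Beta(5, 1.5) scaled to [50, 100] (so roughly a
#' quarter of de novo rows fall below the 80% filter), three class I
#' alleles with stand-in motifs, 30% planted strong binders among
#' window-length peptides, and 50% planted immunogenic peptides.
#'
#' @param n_peptides Number of primary records (duplicates are extra rows).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param length_dist Named probability vector over integer lengths.
#' @param frac_de_novo Fraction of de novo rows.
#' @param frac_contaminant Fraction of contaminant rows among database rows.
#' @param frac_duplicate Extra duplicate rows as a fraction of `n_peptides`.
#' @param alc_shape1,alc_shape2 Beta parameters of the ALC distribution.
#' @param alleles Class I allele names; stand-in motifs are derived from
#'   them deterministically when `motifs` is `NULL`.
#' @param motifs Optional named list of [motif_model()] objects per allele.
#' @param planted_strong_frac Fraction of 8-12-mers planted as strong
#'   binders (to one allele each).
#' @param planted_immunogenic_frac Fraction of peptides planted immunogenic.
#' @param background_n Background size used for rank calibration.
#' @param plant_margin Planted binders are drawn from anchor combinations
#'   whose exact background tail probability is at most
#'   `plant_margin * strong_cutoff / 100`, keeping their predicted rank
#'   below the strong threshold with near-certainty.
#' @param charge_model Length-banded charge distributions
#'   (see [default_charge_model()]).
#' @param contaminant_accessions Accessions assigned to contaminant rows.
#' @param sample_id,fdr_level Metadata stamped on the records.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_peptides = 5000,
                         seed = 1,
                         length_dist = default_length_dist(),
                         frac_de_novo = 0.08,
                         frac_contaminant = 0.03,
                         frac_duplicate = 0.02,
                         alc_shape1 = 5,
                         alc_shape2 = 1.5,
                         alleles = c("HLA-A*03:01", "HLA-B*07:02", "HLA-C*04:01"),
                         motifs = NULL,
                         planted_strong_frac = 0.30,
                         planted_immunogenic_frac = 0.50,
                         background_n = 100000,
                         plant_margin = 0.8,
                         charge_model = default_charge_model(),
                         contaminant_accessions = bundled_contaminants(),
                         sample_id = "synthetic_sample",
                         fdr_level = 5) {
  fracs <- c(frac_de_novo, frac_contaminant, frac_duplicate,
             planted_strong_frac, planted_immunogenic_frac)
  if (any(fracs < 0 | fracs > 1)) {
    stop("configuration error: fractions must lie in [0, 1]")
  }
  if (abs(sum(length_dist) - 1) > 1e-8) {
    stop("configuration error: length_dist must sum to 1")
  }
  if (is.null(names(length_dist))) {
    stop("configuration error: length_dist must be named by integer length")
  }
  if (planted_strong_frac > 0 && length(alleles) == 0 && is.null(motifs)) {
    stop("configuration error: planted strong binders need at least one allele motif")
  }
  if (is.null(motifs)) {
    motifs <- stats::setNames(lapply(alleles, motif_model), alleles)
  }
  structure(
    list(
      n_peptides = as.integer(n_peptides), seed = as.integer(seed),
      length_dist = length_dist, frac_de_novo = frac_de_novo,
      frac_contaminant = frac_contaminant, frac_duplicate = frac_duplicate,
      alc_shape1 = alc_shape1, alc_shape2 = alc_shape2,
      alleles = names(motifs), motifs = motifs,
      planted_strong_frac = planted_strong_frac,
      planted_immunogenic_frac = planted_immunogenic_frac,
      background_n = as.integer(background_n), plant_margin = plant_margin,
      charge_model = charge_model,
      contaminant_accessions = contaminant_accessions,
      sample_id = sample_id, fdr_level = fdr_level
    ),
    class = "synth_config"
  )
}

# --- exact anchor enumeration -----------------------------------------------
# With stand-in motifs carrying weight only at positions 1, 2 and L, the
# score of a peptide is a function of three residues; all 20^3 combinations
# can be enumerated with their background probabilities. This gives exact
# background tail probabilities per combination, from which both the planted
# sampling region and the expected background strong-binder rate follow
# without Monte Carlo.

anchor_enumeration <- function(motif, L) {
  w <- motif$pssm[[as.character(L)]]
  if (is.null(w)) stop("motif has no slice for length ", L)
  bg <- motif$background_freqs[amino_acids()]
  # combo index = i + 20*(j-1) + 400*(k-1) for residues (pos1, pos2, posL)
  s <- as.vector(outer(outer(w[, 1], w[, 2], `+`), w[, L], `+`))
  q <- as.vector(outer(outer(bg, bg, `*`), bg, `*`))
  ord <- order(s, decreasing = TRUE)
  tail_prob <- numeric(length(s))
  tail_prob[ord] <- cumsum(q[ord])  # P(background score >= s), ties included
  list(scores = s, probs = q, tail_prob = tail_prob)
}

# P(a background-drawn peptide of length L is called a strong binder) under
# the empirical rank estimator with a background of size n: the count of
# background peptides scoring >= s is Binomial(n, T(s)).
p_strong_background <- function(motif, L, background_n, strong_cutoff = 0.5) {
  enum <- anchor_enumeration(motif, L)
  k_max <- floor(strong_cutoff / 100 * (background_n + 1) - 1 + 1e-9)
  if (k_max < 0) return(0)
  sum(enum$probs * stats::pbinom(k_max, background_n, enum$tail_prob))
}

# Residue sets whose centered propensity is strictly positive / negative;
# sampling the non-anchor positions from one set fixes the sign of the
# stand-in immunogenicity score without touching the anchor positions that
# determine binding.
propensity_sets <- function(propensities = default_propensities()) {
  p <- propensities[amino_acids()]
  p <- p - mean(p)
  list(positive = names(p)[p > 0], negative = names(p)[p < 0])
}

#' Generate a synthetic identification table with planted truth
#'
#' Draws a peptide identification table under `config`, deterministic given
#' the seed. Sequences are sampled from background residue frequencies;
#' planted strong binders take their position-1/2/C-terminal residues from
#' anchor combinations in the extreme upper tail of the motif's exact score
#' distribution (tail probability at most
#' `plant_margin * 0.5%`), so their stand-in percentile rank falls at or
#' below 0.5 with near-certainty; planted immunogenic peptides draw their
#' internal residues from positive-propensity letters (others from
#' negative), which fixes the sign of the stand-in immunogenicity score
#' without affecting binding. m/z is computed exactly from the monoisotopic
#' mass (including any modification delta in the raw sequence) and charge;
#' 1/K0 follows a two-cluster model conditioned on charge (singly charged
#' high-m/z vs multiply charged lower-m/z). Contaminant rows carry bundled
#' contaminant accessions; duplicate rows re-emit earlier peptides as charge
#' or oxidation variants.
#'
#' @param config A [synth_config()].
#' @return A list with `records` (peptide record tibble, same schema as
#'   [read_peptide_table()]) and `truth` (list: `per_record` flag tibble
#'   aligned with `records`, and `summary` of realized counts and stage
#'   pass-rates on the unique decontaminated database set).
#' @export
generate_sample <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  aa <- amino_acids()
  bg <- aa_background_freqs()
  psets <- propensity_sets()
  bg_pos <- bg[psets$positive] / sum(bg[psets$positive])
  bg_neg <- bg[psets$negative] / sum(bg[psets$negative])

  with_seed(config$seed, {
    n <- config$n_peptides
    lens <- sort(as.integer(names(config$length_dist)))
    length_v <- sample(lens, n, replace = TRUE,
                       prob = config$length_dist[as.character(lens)])
    is_de_novo <- stats::runif(n) < config$frac_de_novo
    is_contaminant <- !is_de_novo & stats::runif(n) < config$frac_contaminant
    in_window <- length_v >= 8 & length_v <= 12
    is_planted_strong <- in_window & stats::runif(n) < config$planted_strong_frac
    planted_allele <- rep(NA_character_, n)
    if (any(is_planted_strong)) {
      planted_allele[is_planted_strong] <-
        sample(config$alleles, sum(is_planted_strong), replace = TRUE)
    }
    is_planted_immunogenic <- stats::runif(n) < config$planted_immunogenic_frac

    # Accepted anchor-combination pools per (allele, length)
    accept_pool <- list()
    t_max <- config$plant_margin * 0.5 / 100
    for (al in config$alleles) {
      for (L in 8:12) {
        enum <- anchor_enumeration(config$motifs[[al]], L)
        idx <- which(enum$tail_prob <= t_max)
        if (length(idx) == 0) {
          stop("configuration error: no anchor combination reaches the ",
               "planting region for ", al, " length ", L)
        }
        accept_pool[[paste(al, L)]] <-
          list(idx = idx, probs = enum$probs[idx] / sum(enum$probs[idx]))
      }
    }

    bare <- character(n)
    mass <- numeric(n)
    for (L in sort(unique(length_v))) {
      rows <- which(length_v == L)
      m <- matrix("", nrow = length(rows), ncol = L)
      for (pos in unique(c(1L, 2L, L))) {
        m[, pos] <- sample(aa, length(rows), replace = TRUE, prob = bg)
      }
      # planted anchor combinations override positions 1, 2, L
      pl <- is_planted_strong[rows]
      if (any(pl)) {
        for (al in unique(planted_allele[rows][pl])) {
          sel <- which(pl & planted_allele[rows] == al)
          pool <- accept_pool[[paste(al, L)]]
          combo <- pool$idx[sample.int(length(pool$idx), length(sel),
                                       replace = TRUE, prob = pool$probs)]
          i <- (combo - 1L) %% 20L + 1L
          j <- ((combo - 1L) %/% 20L) %% 20L + 1L
          k <- (combo - 1L) %/% 400L + 1L
          m[sel, 1L] <- aa[i]; m[sel, 2L] <- aa[j]; m[sel, L] <- aa[k]
        }
      }
      # internal positions carry the immunogenicity sign
      mid <- setdiff(seq_len(L), c(1L, 2L, L))
      imm <- is_planted_immunogenic[rows]
      for (pos in mid) {
        if (any(imm)) {
          m[imm, pos] <- sample(psets$positive, sum(imm), replace = TRUE,
                                prob = bg_pos)
        }
        if (any(!imm)) {
          m[!imm, pos] <- sample(psets$negative, sum(!imm), replace = TRUE,
                                 prob = bg_neg)
        }
      }
      bare[rows] <- do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
      mass[rows] <- rowSums(matrix(AA_MONO_MASS[m], nrow = length(rows))) +
        MASS_WATER
    }

    charge <- draw_charges(length_v, config$charge_model)
    mz <- (mass + charge * MASS_PROTON) / charge
    ion_mobility <- draw_mobility(mz, charge)
    alc <- rep(NA_real_, n)
    alc[is_de_novo] <- round(
      50 + 50 * stats::rbeta(sum(is_de_novo), config$alc_shape1,
                             config$alc_shape2), 1)

    accessions <- vector("list", n)
    n_db <- sum(!is_de_novo & !is_contaminant)
    syn_acc <- sprintf("SYNP%05d", sample.int(99999, n_db, replace = TRUE))
    accessions[!is_de_novo & !is_contaminant] <- as.list(syn_acc)
    n_ct <- sum(is_contaminant)
    if (n_ct > 0) {
      accessions[is_contaminant] <- as.list(
        sample(config$contaminant_accessions, n_ct, replace = TRUE))
    }
    accessions[is_de_novo] <- rep(list(character()), sum(is_de_novo))

    records <- tibble::tibble(
      sample_id = config$sample_id,
      raw_sequence = bare,
      bare_sequence = bare,
      length = length_v,
      charge = as.integer(charge),
      mz = mz,
      ion_mobility = ion_mobility,
      accessions = accessions,
      is_de_novo = is_de_novo,
      alc = alc,
      fdr_level = config$fdr_level,
      scorable = is_scorable_sequence(bare)
    )
    per_record <- tibble::tibble(
      is_contaminant = is_contaminant,
      is_planted_strong = is_planted_strong,
      planted_allele = planted_allele,
      is_planted_immunogenic = is_planted_immunogenic,
      is_duplicate = FALSE,
      source_row = NA_integer_
    )

    # duplicate rows: charge variants, or oxidation variants when the
    # peptide contains a methionine (m/z recomputed with the mass delta)
    n_dup <- round(config$frac_duplicate * n)
    if (n_dup > 0) {
      src <- sample.int(n, n_dup, replace = n_dup > n)
      dup <- records[src, , drop = FALSE]
      has_m <- grepl("M", dup$bare_sequence)
      dup$raw_sequence[has_m] <- sub("M", "M(+15.99)", dup$bare_sequence[has_m])
      # mass delta matches the printed annotation so m/z can be re-derived
      # exactly from the raw sequence
      dup_mass <- mass[src] + ifelse(has_m, 15.99, 0)
      new_z <- ifelse(has_m, dup$charge, dup$charge %% 4L + 1L)
      dup$charge <- as.integer(new_z)
      dup$mz <- (dup_mass + new_z * MASS_PROTON) / new_z
      dup$ion_mobility <- draw_mobility(dup$mz, new_z)
      records <- dplyr::bind_rows(records, dup)
      per_record <- dplyr::bind_rows(
        per_record,
        dplyr::mutate(per_record[src, , drop = FALSE],
                      is_duplicate = TRUE, source_row = src)
      )
    }

    perm <- sample.int(nrow(records))
    records <- records[perm, , drop = FALSE]
    per_record <- per_record[perm, , drop = FALSE]

    truth <- list(
      per_record = per_record,
      summary = realized_summary(records, per_record),
      config = config
    )
    list(records = records, truth = truth)
  })
}

draw_charges <- function(length_v, charge_model) {
  z <- integer(length(length_v))
  for (band in charge_model) {
    rows <- which(length_v >= band$min & length_v <= band$max)
    if (length(rows) > 0) {
      z[rows] <- sample.int(6, length(rows), replace = TRUE,
                            prob = band$probs)
    }
  }
  if (any(z == 0)) stop("charge model does not cover all generated lengths")
  z
}

# Two-cluster reduced-mobility model: singly charged precursors sit at high
# m/z with high 1/K0, multiply charged ones at lower m/z and lower 1/K0.
draw_mobility <- function(mz, charge) {
  ifelse(charge == 1,
         0.55 + 9e-4 * mz + stats::rnorm(length(mz), 0, 0.02),
         0.40 + 5e-4 * mz + stats::rnorm(length(mz), 0, 0.02))
}

# Realized ground-truth accounting on the generated table: counts the
# pipeline should reproduce exactly (contaminant rows, unique database
# peptides) and the stage pass-rates realized on the unique decontaminated
# database set.
realized_summary <- function(records, per_record) {
  db <- !records$is_de_novo
  contam <- per_record$is_contaminant & db
  kept <- db & !contam
  kept_idx <- which(kept)
  uniq_idx <- kept_idx[!duplicated(records$bare_sequence[kept_idx])]
  len_pass <- records$length[uniq_idx] >= 8 & records$length[uniq_idx] <= 12
  strong <- per_record$is_planted_strong[uniq_idx]
  imm <- per_record$is_planted_immunogenic[uniq_idx]
  dn <- records$is_de_novo
  list(
    n_rows = nrow(records),
    n_db_rows = sum(db),
    n_contaminant_rows = sum(contam),
    n_unique_db = length(uniq_idx),
    n_de_novo_rows = sum(dn),
    n_de_novo_alc_pass = sum(records$alc[dn] >= 80, na.rm = TRUE),
    pass_length_rate = mean(len_pass),
    planted_strong_rate_in_window = if (any(len_pass)) {
      mean(strong[len_pass])
    } else {
      NA_real_
    },
    planted_selected_rate = mean(len_pass & strong & imm)
  )
}

#' Expected funnel pass-rates under a generator configuration
#'
#' Closed-form expectations for the fraction of unique database peptides
#' surviving each decision-tree stage, used as the recovery target for the
#' generator. Length: the mass of the length distribution on 8-12.
#' Binding: planted strong binders pass with probability ~1 by
#' construction, and non-planted peptides pass when the rank against a
#' finite background happens to fall at or below 0.5% for at least one
#' allele -- a probability computed exactly by enumerating the anchor score
#' distribution (alleles treated as independent, a good approximation since
#' their anchor preferences are drawn independently). Selection: the
#' binding pass-rate times the planted immunogenic fraction, immunogenicity
#' being planted independently of binding.
#'
#' @param config A [synth_config()].
#' @param strong_cutoff Strong-binder rank threshold in percent.
#' @return A list with `pass_length`, `pass_binding`, `pass_selected`
#'   (expected fractions of unique input) and the background component
#'   `p_background_strong`.
#' @export
expected_funnel <- function(config, strong_cutoff = 0.5) {
  stopifnot(inherits(config, "synth_config"))
  ld <- config$length_dist
  win <- intersect(names(ld), as.character(8:12))
  p_len <- sum(ld[win])
  # length-conditional background strong rate, any allele
  p_any_by_len <- vapply(as.integer(win), function(L) {
    p_each <- vapply(config$alleles, function(al) {
      p_strong_background(config$motifs[[al]], L, config$background_n,
                          strong_cutoff)
    }, numeric(1))
    1 - prod(1 - p_each)
  }, numeric(1))
  w <- ld[win] / p_len
  p_bg <- sum(w * p_any_by_len)
  f <- config$planted_strong_frac
  pass_binding <- p_len * (f + (1 - f) * p_bg)
  list(
    pass_length = unname(p_len),
    pass_binding = unname(pass_binding),
    pass_selected = unname(pass_binding * config$planted_immunogenic_frac),
    p_background_strong = unname(p_bg)
  )
}

#' Exact m/z of a peptide from its raw sequence and charge
#'
#' Monoisotopic mass of the bare sequence plus any parenthesized mass
#' deltas in the raw sequence (e.g. `"M(+15.99)"`), protonated to the given
#' charge. Used to verify m/z consistency of generated and imported tables.
#'
#' @param raw_sequence Character vector, possibly with inline modification
#'   annotations carrying numeric mass deltas.
#' @param charge Integer vector of charges.
#' @return Numeric vector of m/z values (Th).
#' @export
peptide_mz <- function(raw_sequence, charge) {
  bare <- strip_modifications(raw_sequence)
  vapply(seq_along(raw_sequence), function(i) {
    res <- strsplit(bare[i], "")[[1]]
    mods <- regmatches(raw_sequence[i],
                       gregexpr("\\(([^)]*)\\)", raw_sequence[i]))[[1]]
    delta <- sum(as.numeric(gsub("[()]", "", mods)))
    if (is.na(delta)) delta <- 0
    mass <- sum(AA_MONO_MASS[res]) + MASS_WATER + delta
    (mass + charge[i] * MASS_PROTON) / charge[i]
  }, numeric(1))
}
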