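# Builders for in-code fixtures: peptide record tibbles, random prediction
# bundles, and temporary CSV files in the PEAKS export shape.

make_records <- function(bare_sequence,
                         sample_id = "S1",
                         charge = 2L,
                         mz = NA_real_,
                         ion_mobility = NA_real_,
                         accessions = NULL,
                         is_de_novo = FALSE,
                         alc = NA_real_,
                         raw_sequence = bare_sequence) {
  n <- length(bare_sequence)
  if (is.null(accessions)) accessions <- rep(list(character()), n)
  tibble::tibble(
    sample_id = rep_len(sample_id, n),
    raw_sequence = raw_sequence,
    bare_sequence = bare_sequence,
    length = nchar(bare_sequence),
    charge = as.integer(rep_len(charge, n)),
    mz = rep_len(mz, n),
    ion_mobility = rep_len(ion_mobility, n),
    accessions = accessions,
    is_de_novo = rep_len(is_de_novo, n),
    alc = rep_len(alc, n),
    fdr_level = 5,
    scorable = grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", bare_sequence)
  )
}

random_peptides <- function(n, lengths = 8:12) {
  len <- lengths[sample.int(length(lengths), n, replace = TRUE)]
  vapply(len, function(L) {
    paste(sample(amino_acids(), L, replace = TRUE), collapse = "")
  }, character(1))
}

# A random prediction bundle table in the shape join_predictions() emits,
# with independent per-peptide length, per-allele ranks, and an
# immunogenicity score; used for brute-force oracle comparisons.
random_bundles <- function(n, n_alleles = 3) {
  alleles <- sprintf("HLA-A*%02d:01", seq_len(n_alleles))
  len <- sample(6:15, n, replace = TRUE)
  seqs <- sprintf("PEP%06d", seq_len(n))  # synthetic keys, uniqueness only
  ranks <- matrix(stats::runif(n * n_alleles, 0.01, 100), nrow = n)
  imm <- stats::runif(n, -1, 1)
  bundles <- tibble::tibble(
    bare_sequence = seqs,
    length = len,
    binding_calls = lapply(seq_len(n), function(i) {
      tibble::tibble(
        bare_sequence = seqs[i], allele = alleles,
        percent_rank = ranks[i, ],
        binder_class = classify_binding(ranks[i, ])
      )
    }),
    has_strong = apply(ranks <= 0.5, 1, any),
    best_allele = alleles[apply(ranks, 1, which.min)],
    best_rank = apply(ranks, 1, min),
    missing_binding = FALSE,
    imm_score = imm,
    is_immunogenic = imm > 0,
    missing_immunogenicity = FALSE
  )
  records <- make_records(seqs)
  records$length <- len
  records$scorable <- TRUE
  list(records = records, bundles = bundles, ranks = ranks, imm = imm)
}

write_peaks_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path)
  path
}

extdata <- function(name) {
  system.file("extdata", name, package = "immunopepscore", mustWork = TRUE)
}
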