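# Synthetic identification table generator: determinism, planted
# structure, physical consistency, and the closed-form expected funnel.

test_that("generation is deterministic given the seed", {
  cfg <- synth_config(n_peptides = 500, seed = 7, background_n = 5000)
  g1 <- generate_sample(cfg)
  g2 <- generate_sample(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth$per_record, g2$truth$per_record)
  # a different seed changes the table
  g3 <- generate_sample(synth_config(n_peptides = 500, seed = 8,
                                     background_n = 5000))
  expect_false(identical(g1$records$bare_sequence, g3$records$bare_sequence))
})

test_that("planted fractions land within 3 binomial sigma", {
  cfg <- synth_config(n_peptides = 1000, seed = 13, frac_de_novo = 0,
                      frac_contaminant = 0.1, frac_duplicate = 0,
                      background_n = 5000)
  g <- generate_sample(cfg)
  n_ct <- g$truth$summary$n_contaminant_rows
  expect_lt(abs(n_ct - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  # every contaminant row carries a bundled contaminant accession
  ct_rows <- g$truth$per_record$is_contaminant
  expect_true(all(unlist(g$records$accessions[ct_rows]) %in%
                    bundled_contaminants()))
  # planted strong fraction among window-length peptides
  win <- g$records$length >= 8 & g$records$length <= 12
  p_hat <- mean(g$truth$per_record$is_planted_strong[win])
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / sum(win)))
})

test_that("m/z is consistent with monoisotopic mass and charge", {
  cfg <- synth_config(n_peptides = 300, seed = 5, frac_duplicate = 0.1,
                      background_n = 5000)
  g <- generate_sample(cfg)
  # includes oxidation-variant duplicates whose raw sequence carries a delta
  expect_true(any(grepl("\\(\\+15.99\\)", g$records$raw_sequence)))
  mz_ref <- peptide_mz(g$records$raw_sequence, g$records$charge)
  expect_lt(max(abs(mz_ref - g$records$mz)), 1e-4)
})

test_that("generated tables reproduce the expected marginal structure", {
  cfg <- synth_config(n_peptides = 3000, seed = 19, background_n = 5000)
  g <- generate_sample(cfg)
  d <- compute_distributions(g$records)
  # length mode inside the HLA-I window
  mode_len <- d$length_histogram$value[which.max(d$length_histogram$count)]
  expect_true(mode_len >= 8 && mode_len <= 12)
  expect_gte(sum(d$length_histogram$count[d$length_histogram$value %in% 8:12]) /
               sum(d$length_histogram$count), 0.7)
  # charges 1..6 overall, 1..4 inside the window
  expect_true(all(d$charge_histogram$value %in% 1:6))
  expect_true(all(d$charge_histogram_8_12$value %in% 1:4))
  # ALC bounded in [50, 100], present iff de novo
  dn <- g$records$is_de_novo
  expect_true(all(g$records$alc[dn] >= 50 & g$records$alc[dn] <= 100))
  expect_true(all(is.na(g$records$alc[!dn])))
  # some ALC values fall below the 80 filter so the filter is exercised
  expect_gt(sum(g$records$alc[dn] < 80), 0)
})

test_that("expected_funnel closed form behaves at its boundaries", {
  cfg9 <- synth_config(n_peptides = 10, seed = 1,
                       length_dist = stats::setNames(1, 9),
                       background_n = 1000)
  ef <- expected_funnel(cfg9)
  expect_equal(ef$pass_length, 1)
  # full planting: selection approaches the planted product
  cfg_full <- synth_config(n_peptides = 10, seed = 1,
                           length_dist = stats::setNames(1, 9),
                           planted_strong_frac = 1,
                           planted_immunogenic_frac = 1,
                           background_n = 1000)
  ef2 <- expected_funnel(cfg_full)
  expect_equal(ef2$pass_binding, 1)
  expect_equal(ef2$pass_selected, 1)
  # background strong rate is a small probability near the rank threshold
  expect_gt(ef$p_background_strong, 0)
  expect_lt(ef$p_background_strong, 0.1)
})

test_that("infeasible configurations raise configuration errors", {
  expect_error(synth_config(frac_de_novo = 1.2), "configuration")
  expect_error(synth_config(length_dist = c("9" = 0.5)), "sum to 1")
  expect_error(synth_config(planted_strong_frac = 0.5, alleles = character()),
               "allele")
})

test_that("planted strong binders really are strong under the stand-in", {
  cfg <- synth_config(n_peptides = 800, seed = 29, frac_de_novo = 0,
                      frac_duplicate = 0, background_n = 20000)
  g <- generate_sample(cfg)
  pl <- which(g$truth$per_record$is_planted_strong)
  # calibration: planted peptides classify strong for their planted allele
  # with probability >= 0.95 under an independent prediction background
  hits <- vapply(cfg$alleles, function(al) {
    rows <- pl[g$truth$per_record$planted_allele[pl] == al]
    if (length(rows) == 0) return(c(0, 0))
    calls <- predict_binding_standin(g$records$bare_sequence[rows],
                                     cfg$motifs[[al]],
                                     background_n = 20000, seed = 1234)
    c(sum(calls$binder_class == "strong"), length(rows))
  }, numeric(2))
  expect_gte(sum(hits[1, ]) / sum(hits[2, ]), 0.95)
  # immunogenicity planting is exact by construction
  imm <- predict_immunogenicity_standin(g$records$bare_sequence)
  expect_equal(imm$is_immunogenic,
               g$truth$per_record$is_planted_immunogenic)
})
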