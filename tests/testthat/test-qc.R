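# QC: sequence normalization, dedup/decontamination, ALC filter,
# distributions, mobility grouping, CRAPome expected fraction.

test_that("strip_modifications removes annotation groups and is idempotent", {
  expect_equal(strip_modifications("M(+15.99)LLSVPLLLG"), "MLLSVPLLLG")
  expect_equal(strip_modifications("KLDETGNSLK"), "KLDETGNSLK")
  expect_equal(strip_modifications("C(+57.02)AM(+15.99)K"), "CAMK")
  # idempotence over randomly annotated sequences, vs a regex oracle
  set.seed(3)
  for (i in 1:50) {
    pep <- paste(sample(amino_acids(), 9, replace = TRUE), collapse = "")
    pos <- sample(1:9, 1)
    raw <- paste0(substr(pep, 1, pos), "(+", round(runif(1, 1, 80), 2), ")",
                  substr(pep, pos + 1, 9))
    oracle <- gsub("\\([^)]*\\)", "", raw)
    expect_equal(strip_modifications(raw), oracle)
    expect_equal(strip_modifications(strip_modifications(raw)),
                 strip_modifications(raw))
  }
})

test_that("dedup collapses charge/mod variants; contaminant-only rows removed", {
  rec <- make_records(c("KLDETGNSLK", "KLDETGNSLK", "AAAA"),
                      charge = c(2L, 3L, 2L),
                      accessions = list("P1", "P1", "P04264"))
  out <- deduplicate_and_decontaminate(rec, c("P04264"))
  expect_equal(out$records$bare_sequence, "KLDETGNSLK")
  expect_equal(out$report,
               list(n_input = 3L, n_unique = 1L, n_contaminant_removed = 1L))

  # a peptide with one non-contaminant accession is kept
  rec2 <- make_records("CCCC", accessions = list(c("P04264", "P1")))
  expect_equal(nrow(deduplicate_and_decontaminate(rec2, "P04264")$records), 1)

  # planted-count oracle: 85 distinct + 10 duplicates + 5 contaminant-only
  set.seed(5)
  base <- unique(random_peptides(200))[1:90]
  seqs <- c(base[1:85], base[1:10], base[86:90])
  acc <- c(rep(list("SYN1"), 95), rep(list("P04264"), 5))
  rec3 <- make_records(seqs, accessions = acc)
  out3 <- deduplicate_and_decontaminate(rec3, "P04264")
  expect_equal(out3$report$n_input, 100L)
  expect_equal(out3$report$n_contaminant_removed, 5L)
  expect_equal(out3$report$n_unique, 85L)

  # idempotence
  again <- deduplicate_and_decontaminate(out3$records, "P04264")
  expect_identical(again$records, out3$records)
  expect_equal(again$report$n_contaminant_removed, 0L)
})

test_that("ALC filter keeps the 80 boundary and counts drops", {
  rec <- make_records(c("AAAA", "CCCC", "DDDD"), is_de_novo = TRUE,
                      alc = c(80, 79.9, NA))
  out <- filter_de_novo_alc(rec)
  expect_equal(out$bare_sequence, "AAAA")
  rep <- attr(out, "alc_report")
  expect_equal(rep$n_below_threshold, 1)
  expect_equal(rep$n_missing_alc, 1)

  # counting oracle over the inclusive threshold: 0..100 step 1 -> 21 kept
  sweep <- make_records(rep("AAAA", 101), is_de_novo = TRUE, alc = 0:100)
  expect_equal(nrow(filter_de_novo_alc(sweep, 80)), 21)
  # boundary behavior of the threshold parameter itself
  expect_equal(nrow(filter_de_novo_alc(sweep, 0)), 101)
  expect_equal(nrow(filter_de_novo_alc(sweep, 100 + 1e-9)), 0)
  # order preserved
  ord <- make_records(c("CCCC", "AAAA"), is_de_novo = TRUE, alc = c(90, 85))
  expect_equal(filter_de_novo_alc(ord)$bare_sequence, c("CCCC", "AAAA"))
})

test_that("length/charge histograms are exact and conserve mass", {
  rec <- make_records(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD",
                        "EEEEEEEEEEEEEEE"),
                      charge = c(1L, 2L, 2L, 3L))
  d <- compute_distributions(rec)
  expect_equal(d$length_histogram,
               tibble::tibble(value = c(9L, 15L), count = c(3L, 1L)))
  expect_equal(d$charge_histogram,
               tibble::tibble(value = 1:3, count = c(1L, 2L, 1L)))
  # conditional charge histogram restricted to the 8-12 window
  expect_equal(sum(d$charge_histogram_8_12$count), 3)
  # mass conservation on random data
  set.seed(9)
  rec2 <- make_records(random_peptides(300, 7:20),
                       charge = sample(1:6, 300, replace = TRUE))
  d2 <- compute_distributions(rec2)
  expect_equal(sum(d2$length_histogram$count), 300)
  expect_equal(sum(d2$charge_histogram$count), 300)
})

test_that("mobility grouping recovers two planted clusters deterministically", {
  cfg <- synth_config(n_peptides = 1500, seed = 21,
                      length_dist = stats::setNames(
                        c(0.2, 0.4, 0.2, 0.1, 0.1), 8:12),
                      frac_de_novo = 0)
  g <- generate_sample(cfg)
  grp <- mobility_groups(g$records)
  truth_grp <- ifelse(g$records$charge == 1,
                      "high_mz_single_charge", "low_mz_multi_charge")
  expect_gte(mean(grp$labels == truth_grp), 0.99)
  # labeling rule: the high-m/z group has the larger mean m/z
  m <- tapply(g$records$mz, grp$labels, mean)
  expect_gt(m[["high_mz_single_charge"]], m[["low_mz_multi_charge"]])
  # deterministic: same input, same output
  expect_identical(grp, mobility_groups(g$records))
  # independent cross-check against stats::kmeans on the scaled coordinates
  X <- scale(cbind(g$records$mz, g$records$ion_mobility))
  km <- stats::kmeans(X, centers = 2, nstart = 5)
  agree <- max(mean((km$cluster == 1) == (grp$labels == "high_mz_single_charge")),
               mean((km$cluster == 2) == (grp$labels == "high_mz_single_charge")))
  expect_gte(agree, 0.99)
})

test_that("mobility grouping handles degenerate inputs", {
  rec <- make_records(rep("AAAA", 5), mz = 500, ion_mobility = 0.8)
  expect_warning(grp <- mobility_groups(rec), "one group")
  expect_equal(unique(grp$labels), "low_mz_multi_charge")
  one <- make_records("AAAA", mz = 500, ion_mobility = 0.8)
  expect_warning(mobility_groups(one), "one group")
})

test_that("CRAPome expected-protein flags use the inclusive Ave SC rule", {
  crap <- tibble::tibble(accession = paste0("P", 1:4), ave_sc = c(1, 5, 6, 40))
  obs <- tibble::tibble(accession = paste0("P", 1:4))
  out <- crapome_filter(obs, crap)
  expect_equal(out$flags$expected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$expected_fraction, 0.5)
  # absence from the CRAPome table counts as expected (Ave SC treated as 0)
  out2 <- crapome_filter(tibble::tibble(accession = "NOVEL1"), crap)
  expect_true(out2$flags$expected)
  # all heavily observed -> fraction 0
  out3 <- crapome_filter(obs, dplyr::mutate(crap, ave_sc = 100))
  expect_equal(out3$expected_fraction, 0)
  # empty observed list -> fraction undefined
  out4 <- crapome_filter(obs[0, ], crap)
  expect_true(is.na(out4$expected_fraction))
  expect_match(out4$note, "undefined")
})
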