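# The decision tree: stage rules, short-circuit dismissal, funnel reports.

make_bundle_row <- function(seq, len, strong, imm_score,
                            missing_binding = FALSE, missing_imm = FALSE) {
  tibble::tibble(
    bare_sequence = seq, length = len,
    binding_calls = list(tibble::tibble()),
    has_strong = strong, best_allele = ifelse(strong, "HLA-A*03:01", NA),
    best_rank = ifelse(strong, 0.2, NA_real_),
    missing_binding = missing_binding,
    imm_score = imm_score, is_immunogenic = imm_score > 0,
    missing_immunogenicity = missing_imm
  )
}

test_that("stage 1 passes exactly lengths 8-12", {
  expect_equal(stage1_length(9), 1L)
  expect_equal(stage1_length(c(7, 13)), c(0L, 0L))
  expect_equal(sum(stage1_length(5:20)), 5L)
})

test_that("stage 2 requires a strong binder on at least one allele", {
  rec <- make_records(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"))
  binding <- tibble::tibble(
    bare_sequence = rep(rec$bare_sequence, each = 2),
    allele = rep(c("HLA-A*03:01", "HLA-B*07:02"), 3),
    percent_rank = c(1.2, 0.4, 1.0, 1.9, 50, 99),
    binder_class = classify_binding(c(1.2, 0.4, 1.0, 1.9, 50, 99))
  )
  immuno <- tibble::tibble(bare_sequence = rec$bare_sequence,
                           score = 0.5, is_immunogenic = TRUE)
  b <- join_predictions(rec, binding, immuno)
  expect_equal(stage2_binding(b), c(1L, 0L, 0L))  # (weak,strong) / (weak,weak) / (non,non)
  expect_equal(b$best_allele[1], "HLA-B*07:02")
})

test_that("the full decision tree matches its truth table with short-circuit", {
  # exhaustive 2x2x2 enumeration of (length pass, strong, positive imm)
  grid <- expand.grid(len_pass = c(TRUE, FALSE), strong = c(TRUE, FALSE),
                      imm = c(TRUE, FALSE))
  bundles <- purrr::list_rbind(lapply(seq_len(nrow(grid)), function(i) {
    make_bundle_row(sprintf("PEP%02d", i),
                    ifelse(grid$len_pass[i], 9L, 14L),
                    grid$strong[i],
                    ifelse(grid$imm[i], 0.2, -0.2))
  }))
  rec <- make_records(bundles$bare_sequence)
  rec$length <- bundles$length
  res <- score_peptides(rec, bundles)
  expect_equal(res$final_score == 3, grid$len_pass & grid$strong & grid$imm)
  # dismissal semantics: stages after a failure contribute 0
  out_of_window <- !grid$len_pass
  expect_true(all(res$dismissed_at[out_of_window] == "length"))
  expect_true(all(res$final_score[out_of_window] == 0))
  expect_true(all(res$stage2_binding[out_of_window] == 0))
  sel <- res$final_score == 3
  expect_true(all(res$dismissed_at[sel] == "none"))
  expect_equal(res$final_score, res$stage1_length + res$stage2_binding +
                 res$stage3_immunogenicity)
})

test_that("scoring equals the brute-force conjunction filter on random bundles", {
  set.seed(17)
  rb <- random_bundles(2000)
  res <- score_peptides(rb$records, rb$bundles)
  brute <- rb$records$length >= 8 & rb$records$length <= 12 &
    apply(rb$ranks, 1, min) <= 0.5 & rb$imm > 0
  expect_equal(res$final_score == 3, brute)
  # determinism and record-order independence of the selected set
  perm <- sample(nrow(rb$records))
  res2 <- score_peptides(rb$records[perm, ], rb$bundles)
  expect_setequal(res2$bare_sequence[res2$final_score == 3],
                  res$bare_sequence[res$final_score == 3])
})

test_that("missing predictions score 0 at their stage", {
  b <- make_bundle_row("AAAAAAAAA", 9L, FALSE, NA_real_,
                       missing_binding = TRUE, missing_imm = TRUE)
  rec <- make_records("AAAAAAAAA")
  res <- score_peptides(rec, b)
  expect_equal(res$final_score, 1L)
  expect_equal(res$dismissed_at, "binding")
})

test_that("funnel counts, percentages and bottleneck stage", {
  bundles <- purrr::list_rbind(lapply(1:10, function(i) {
    make_bundle_row(sprintf("P%02d", i), ifelse(i <= 6, 9L, 13L),
                    i <= 3, ifelse(i <= 2, 0.5, -0.5))
  }))
  rec <- make_records(bundles$bare_sequence)
  rec$length <- bundles$length
  f <- funnel(score_peptides(rec, bundles), "S1")
  expect_equal(f$n_input_unique, 10L)
  expect_equal(f$n_pass_length, 6L)
  expect_equal(f$n_pass_binding, 3L)
  expect_equal(f$n_pass_immunogenicity, 2L)
  expect_equal(f$pct_selected, 20)
  # monotone funnel on arbitrary random inputs
  set.seed(23)
  for (i in 1:20) {
    rb <- random_bundles(100)
    fi <- funnel(score_peptides(rb$records, rb$bundles))
    expect_true(fi$n_input_unique >= fi$n_pass_length &&
                  fi$n_pass_length >= fi$n_pass_binding &&
                  fi$n_pass_binding >= fi$n_pass_immunogenicity)
  }
})

test_that("funnel edge cases: empty input and bottleneck tie-breaking", {
  empty <- funnel(score_peptides(make_records(character()),
                                 make_bundle_row("X", 9L, TRUE, 1)[0, ]))
  expect_equal(empty$n_input_unique, 0L)
  expect_true(is.na(empty$pct_selected))
  expect_true(empty$percentages_undefined)
  # all selected: equalities hold and ties resolve to the earliest stage
  bundles <- purrr::list_rbind(lapply(1:4, function(i) {
    make_bundle_row(sprintf("P%d", i), 9L, TRUE, 1)
  }))
  rec <- make_records(bundles$bare_sequence)
  rec$length <- bundles$length
  f <- funnel(score_peptides(rec, bundles))
  expect_equal(f$n_pass_immunogenicity, 4L)
  expect_equal(f$most_restrictive_stage, "length")  # zero loss everywhere
})
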