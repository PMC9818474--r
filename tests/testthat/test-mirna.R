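test_that("fold change reproduces the clinical panel to one decimal", {
  expect_equal(fold_change(28294, 202238)$fold_reported, 7.1)
  expect_equal(fold_change(104809, 324654)$fold_reported, 3.1)
  expect_equal(fold_change(159928, 88908)$fold_reported, 0.6)
  expect_equal(fold_change(13327568, 2665531)$fold_reported, 0.2)
  expect_equal(fold_change(22209402, 111047010)$fold_reported, 5.0)
  expect_equal(fold_change(555235050, 111047010)$fold_reported, 0.2)
  expect_equal(fold_change(123, 123)$fold_reported, 1.0)
  expect_error(fold_change(0, 10), "> 0")
  expect_error(fold_change(10, -1), "> 0")
})

test_that("reported folds round half up on a grid", {
  for (f in c(0.25, 1.05, 1.15, 2.35, 4.45)) {
    n <- 1e6
    expect_equal(fold_change(n, n * f)$fold_reported,
                 floor(f * 10 + 0.5) / 10)
  }
  # fold_change(n, n*f) round-trips the fold to one decimal
  for (f in seq(0.1, 8, by = 0.1)) {
    expect_equal(fold_change(1e5, 1e5 * f)$fold_reported, round(f, 1))
  }
})

test_that("effective change measures magnitude along the risk direction", {
  expect_equal(effective_change(0.2, "down_is_risk"), 5.0)
  expect_equal(effective_change(7.1, "up_is_risk"), 7.1)
  expect_equal(effective_change(0.6, "up_is_risk"), 1)   # protective move
  expect_equal(effective_change(3.0, "down_is_risk"), 1) # protective move
  expect_equal(effective_change(1.0, "up_is_risk"), 1)
})

test_that("the 0-3 risk bands are half-open with upward boundaries", {
  expect_identical(score_marker(1.2), 0L)
  expect_identical(score_marker(1.5), 1L)
  expect_identical(score_marker(1.99), 1L)
  expect_identical(score_marker(2.0), 2L)
  expect_identical(score_marker(4.99), 2L)
  expect_identical(score_marker(5.0), 3L)
  expect_identical(score_marker(7.1), 3L)
})

test_that("expression labels map to ordinal scores", {
  expect_identical(label_to_score("Norm"), 0L)
  expect_identical(label_to_score("Slight increase"), 1L)
  expect_identical(label_to_score("Moderate increase"), 2L)
  expect_identical(label_to_score("Pronounced increase"), 3L)
  expect_identical(label_to_score("Significant increase"), 3L)
  # suffixed dialect carries its own score digit
  expect_identical(label_to_score("Pronounced increase—3"), 3L)
  expect_identical(label_to_score("Slight increase—1"), 1L)
  expect_identical(label_to_score(c("Norm", "Slight increase")), c(0L, 1L))
  expect_error(label_to_score("elevated"), "unknown expression label")
})

test_that("marker names canonicalize across spelling variants", {
  expect_identical(normalize_marker("Hsa-miR-21-5p"), "miR-21-5p")
  expect_identical(normalize_marker("Has-miR-21-5p"), "miR-21-5p")
  expect_identical(normalize_marker("Micro-196a-2"), "miR-196a-2")
  expect_identical(normalize_marker("Micro-RNA-196a-2"), "miR-196a-2")
  expect_identical(normalize_marker("hsa-let-7a-5p"), "let-7a-5p")
  expect_identical(normalize_marker("Hsa-miR-196a-3p"), "miR-199a-3p")
  expect_error(normalize_marker("miR-999"), "unknown miRNA marker")
})

test_that("the clinical example panels score 3 (low) and 7 (high)", {
  initial <- panel_risk(patientP_panel("initial_labels"))
  expect_identical(initial$risk_sum, 3L)
  expect_identical(initial$category, "low")
  expect_identical(sort(unname(initial$scores), decreasing = TRUE)[1:3],
                   c(1L, 1L, 1L))

  followup <- panel_risk(patientP_panel("followup_labels"))
  expect_identical(followup$risk_sum, 7L)
  expect_identical(followup$category, "high")
  expect_identical(sort(unname(followup$scores), decreasing = TRUE)[1:3],
                   c(3L, 3L, 1L))
})

test_that("an all-norm panel scores zero and the panel must be complete", {
  defs <- mirna_panel_markers()
  allnorm <- data.frame(marker = defs$marker, label = "Norm")
  res <- panel_risk(allnorm)
  expect_identical(res$risk_sum, 0L)
  expect_identical(res$category, "low")

  expect_error(panel_risk(allnorm[-3, ]), "missing marker")
  expect_error(panel_risk(rbind(allnorm, allnorm[1, ])), "duplicate")
  expect_error(panel_risk(data.frame(marker = defs$marker)),
               "needs either")
})

test_that("concentration and label paths agree on caption-consistent panels", {
  defs <- mirna_panel_markers()
  lab_for <- c("Norm", "Slight increase", "Moderate increase",
               "Pronounced increase")
  mags <- c(1.1, 1.7, 3.0, 6.5)  # one magnitude inside each band
  for (k in seq_along(mags)) {
    up <- defs$risk_direction == "up_is_risk"
    norm <- rep(1e5, 8)
    path <- ifelse(up, norm * mags[k], norm / mags[k])
    conc <- data.frame(marker = defs$marker, norm_conc = norm,
                       path_conc = path)
    labl <- data.frame(marker = defs$marker, label = lab_for[k])
    expect_identical(panel_risk(conc)$scores, panel_risk(labl)$scores)
  }
})

test_that("the risk sum is monotone in a single marker's magnitude", {
  defs <- mirna_panel_markers()
  base <- data.frame(marker = defs$marker, norm_conc = 1e5,
                     path_conc = 1e5)
  prev <- -1L
  for (mag in c(1, 1.4, 1.6, 2.5, 4, 5, 9)) {
    p <- base
    p$path_conc[p$marker == "miR-21-5p"] <- 1e5 * mag
    s <- panel_risk(p)$risk_sum
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("the low/high cutoff is configurable", {
  res <- panel_risk(patientP_panel("initial_labels"), low_high_cutoff = 3)
  expect_identical(res$category, "high")  # sum 3 meets a cutoff of 3
})
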