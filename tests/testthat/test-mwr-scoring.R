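test_that("Qmax is zero on a uniform field and matches hand arithmetic", {
  g <- group_temperatures(make_constant_tg(skin = 33, int = 33))
  expect_identical(compute_qmax(g)$q_max, 0)

  # one internal point at 36 over a 34 background, cool skin:
  # Qmax = 36 - mean(19 x 34, 36) = 36 - 34.1 = 1.9
  tg <- make_constant_tg(skin = 31, int = 34)
  tg$t_int_left[[5]] <- 36
  qc <- compute_qmax(group_temperatures(tg))
  expect_equal(qc$q_max, 1.9)
  expect_equal(qc$t_max_mw, 36)
  expect_equal(qc$t_mean_mw, 34.1)
})

test_that("Qmax agrees with a brute-force oracle on random exams", {
  for (seed in 1:50) {
    tg <- make_random_tg(seed)
    expect_equal(compute_qmax(group_temperatures(tg))$q_max,
                 oracle_qmax(tg))
  }
})

test_that("asymmetry coefficients find the largest symmetric-point gap", {
  sym <- group_temperatures(make_constant_tg())
  a <- compute_asymmetry(sym)
  expect_equal(a$k_int, 0)
  expect_equal(a$k_skin, 0)
  expect_identical(a$n_int, 0L)
  expect_identical(a$n_skin, 0L)

  tg <- make_constant_tg()
  tg$t_int_left[[5]] <- tg$t_int_left[[5]] + 1.8  # point 4, left hotter
  a2 <- compute_asymmetry(group_temperatures(tg))
  expect_equal(a2$k_int, 1.8)
  expect_identical(a2$n_int, 4L)

  for (seed in 51:80) {
    tg <- make_random_tg(seed)
    got <- compute_asymmetry(group_temperatures(tg))
    want <- oracle_asymmetry(tg)
    expect_equal(got[c("k_int", "n_int", "k_skin", "n_skin")],
                 want, ignore_attr = TRUE)
  }
})

test_that("the signed convention keeps the left-minus-right maximum", {
  tg <- make_constant_tg()
  tg$t_int_right[[3]] <- tg$t_int_right[[3]] + 2.0  # right hotter at point 2
  g <- group_temperatures(tg)
  expect_equal(compute_asymmetry(g)$k_int, 2.0)
  signed <- compute_asymmetry(g, sign_convention = "signed")
  expect_equal(signed$k_int, 0)  # all left-minus-right diffs are <= 0
})

test_that("R uses the same-point sum or the cross-channel construction", {
  sym <- group_temperatures(make_constant_tg())
  rr <- compute_r(sym)
  expect_equal(rr$r, 0)
  expect_identical(rr$branch, "same_point")

  # both channels peak at point 4: R = 1.8 + 1.1
  tg <- make_constant_tg()
  tg$t_int_left[[5]] <- tg$t_int_left[[5]] + 1.8
  tg$t_skin_left[[5]] <- tg$t_skin_left[[5]] + 1.1
  rr2 <- compute_r(group_temperatures(tg))
  expect_equal(rr2$r, 2.9)
  expect_identical(rr2$branch, "same_point")

  # skin peaks at point 7 (2.0), internal at point 4 (1.8); the internal
  # difference at point 7 (0.9) is the cross-channel addend
  tg3 <- make_constant_tg()
  tg3$t_int_left[[5]] <- tg3$t_int_left[[5]] + 1.8
  tg3$t_skin_left[[8]] <- tg3$t_skin_left[[8]] + 2.0
  tg3$t_int_left[[8]] <- tg3$t_int_left[[8]] + 0.9
  rr3 <- compute_r(group_temperatures(tg3))
  expect_equal(rr3$r, 2.9)
  expect_identical(rr3$branch, "cross_channel")
})

test_that("a k_int/k_skin tie at distinct points resolves to internal", {
  tg <- make_constant_tg()
  tg$t_int_left[[2]] <- tg$t_int_left[[2]] + 1.5   # k_int 1.5 at point 1
  tg$t_skin_left[[9]] <- tg$t_skin_left[[9]] + 1.5 # k_skin 1.5 at point 8
  tg$t_skin_left[[2]] <- tg$t_skin_left[[2]] + 0.4 # skin diff at point 1
  rr <- compute_r(group_temperatures(tg))
  # internal channel wins the tie; addend is the skin difference at point 1
  expect_equal(rr$r, 1.9)
  expect_identical(rr$branch, "cross_channel")
})

test_that("MWR classification matches the published decision regimes", {
  expect_identical(classify_mwr(2.45, 3.2), "malignant_suspected")
  expect_identical(classify_mwr(1.7, 1.9), "benign")
  expect_identical(classify_mwr(0, 0), "benign")
  expect_identical(classify_mwr(2.5, 1.0), "ambiguous")
  expect_identical(classify_mwr(1.0, 3.0), "ambiguous")
  # boundary equality leaves both possibilities open
  expect_identical(classify_mwr(2.0, 3.0), "ambiguous")
  expect_identical(classify_mwr(2.2, 2.5), "ambiguous")
  expect_error(classify_mwr(NaN, 1), "non-finite")
  expect_error(classify_mwr(1, NA_real_), "non-finite")
})

test_that("scoring is invariant under global shifts and breast swap", {
  for (seed in 1:20) {
    tg <- make_random_tg(seed)
    s <- score_mwr(tg)

    shifted <- tg
    for (f in c("t_skin_right", "t_skin_left", "t_int_right", "t_int_left"))
      shifted[[f]] <- shifted[[f]] + 1.7
    s2 <- score_mwr(shifted)
    expect_equal(s2$q_max, s$q_max)
    expect_equal(s2$k_int, s$k_int)
    expect_equal(s2$k_skin, s$k_skin)
    expect_equal(s2$r, s$r)

    swapped <- thermogram(tg$patient_id,
                          t_skin_right = tg$t_skin_left,
                          t_skin_left = tg$t_skin_right,
                          t_int_right = tg$t_int_left,
                          t_int_left = tg$t_int_right,
                          t_skin_ref = tg$t_skin_ref,
                          t_int_ref = tg$t_int_ref)
    s3 <- score_mwr(swapped)
    expect_equal(s3$q_max, s$q_max)
    expect_equal(s3$k_int, s$k_int)
    expect_equal(s3$k_skin, s$k_skin)
    expect_equal(s3$r, s$r)
  }
})

test_that("heating a single left internal point never decreases k_int", {
  for (seed in 1:10) {
    tg <- make_random_tg(seed)
    k0 <- compute_asymmetry(group_temperatures(tg))$k_int
    i <- (seed %% 10L) + 1L
    for (delta in c(0.5, 1.5, 3.0)) {
      hot <- tg
      hot$t_int_left[[i]] <- hot$t_int_left[[i]] + delta
      expect_gte(compute_asymmetry(group_temperatures(hot))$k_int, k0)
    }
  }
})

test_that("score_mwr never yields negative statistics", {
  for (seed in 1:20) {
    s <- score_mwr(make_random_tg(seed + 300))
    expect_gte(s$q_max, 0)
    expect_gte(s$k_int, 0)
    expect_gte(s$k_skin, 0)
    expect_gte(s$r, 0)
    if (s$branch == "same_point") expect_equal(s$r, s$k_int + s$k_skin)
  }
})
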