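test_that("angle reflection folds [0,180) onto [0,90] and is idempotent", {
  expect_equal(reflect_angles(170), 10)
  expect_equal(reflect_angles(90), 90)
  expect_equal(reflect_angles(c(60, 120)), c(60, 60))
  expect_equal(reflect_angles(0), 0)
  set.seed(1)
  a <- runif(500, 0, 180 - 1e-9)
  r <- reflect_angles(a)
  expect_true(all(r >= 0 & r <= 90))
  expect_equal(reflect_angles(r), r)
  expect_error(reflect_angles(c(10, 181)), class = "ps_validation_error")
  expect_error(reflect_angles(-1), class = "ps_validation_error")
})

test_that("co-alignment proportion counts inclusively at the threshold", {
  expect_equal(coalignment_proportion(c(90, 90, 90)), 1)
  expect_equal(coalignment_proportion(c(0, 45, 61, 90)), 0.5)
  expect_equal(coalignment_proportion(c(60)), 1) # inclusive at 60
  expect_error(coalignment_proportion(numeric(0)),
               class = "ps_validation_error")
  # membership is the same whether computed on raw [60,120] or reflected
  set.seed(2)
  raw <- runif(2000, 0, 180 - 1e-9)
  expect_equal(coalignment_proportion(reflect_angles(raw)),
               mean(raw >= 60 & raw <= 120))
})

test_that("uniform raw angles give co-alignment 1/3", {
  set.seed(3)
  raw <- runif(1e5, 0, 180)
  raw[raw >= 180] <- 0
  p <- coalignment_proportion(reflect_angles(raw))
  se <- sqrt((1 / 3) * (2 / 3) / 1e5)
  expect_lt(abs(p - 1 / 3), 3 * se)
})

test_that("LOESS smoothing reproduces constants and straight lines and matches an independent local regression", {
  tc <- tibble::tibble(condition = "PSB", time_min = 0:20,
                       n_interfaces = 40, proportion = 0.6)
  sm <- timecourse_with_loess(tc)
  expect_equal(sm$loess_fit, rep(0.6, 21), tolerance = 1e-9)
  expect_true(all(sm$ci_lo <= sm$loess_fit & sm$loess_fit <= sm$ci_hi))

  lin <- tibble::tibble(condition = "PSB", time_min = 0:20,
                        n_interfaces = 40, proportion = 0.2 + 0.01 * (0:20))
  sml <- timecourse_with_loess(lin, span = 1)
  expect_equal(sml$loess_fit, lin$proportion, tolerance = 1e-8)

  set.seed(4)
  noisy <- tibble::tibble(condition = "PSB", time_min = 0:30,
                          n_interfaces = 40,
                          proportion = 0.5 + 0.2 * sin((0:30) / 5) +
                            rnorm(31, 0, 0.03))
  smn <- timecourse_with_loess(noisy, span = 0.75)
  oracle <- local_quad_tricube(noisy$time_min, noisy$proportion,
                               noisy$time_min, span = 0.75)
  expect_equal(smn$loess_fit, oracle, tolerance = 0.02)

  expect_error(timecourse_with_loess(tc, span = 0), class = "ps_config_error")
  expect_error(timecourse_with_loess(tc[1:2, ]), class = "ps_validation_error")
})

test_that("KS statistic matches brute-force ECDF evaluation", {
  a <- c(1, 2, 3); b <- c(1.5, 2.5, 3.5)
  r <- ks_compare(a, b)
  expect_equal(r$D, 1 / 3, tolerance = 1e-12)
  expect_equal(r$D, brute_ks_D(a, b))

  expect_equal(ks_compare(0:10, 0:10 + 1e-12)$D, brute_ks_D(0:10, 0:10 + 1e-12))
  expect_equal(ks_compare(0:10, 80:90)$D, 1)
  set.seed(5)
  for (i in 1:20) {
    x <- runif(sample(5:40, 1)); y <- rnorm(sample(5:40, 1))
    expect_equal(ks_compare(x, y)$D, brute_ks_D(x, y), tolerance = 1e-12)
  }
  expect_error(ks_compare(numeric(0), 1:3), class = "ps_validation_error")
})

test_that("KS type-I error is calibrated at the 5% level", {
  set.seed(6)
  rej <- vapply(1:1000, function(i) {
    ks_compare(runif(100, 0, 90), runif(100, 0, 90))$p_value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("condition comparison separates a tense boundary from controls and annotates significance", {
  t <- small_tissue(beta = 0.9, t_min = 25, t_max = 35, seed = 21)
  ifc <- classify_interfaces(t, expressing_truth(t))
  cmp <- compare_conditions(ifc, t_test = 30, window = c(25, 35))
  ks <- cmp$ks
  psb_rows <- ks$condition_a == "PSB"
  expect_true(all(ks$p_value[psb_rows] < 0.01))
  expect_true(all(ks$significance[psb_rows] == "***"))
  ctrl <- ks[ks$condition_a == "minus1" & ks$condition_b == "plus1", ]
  expect_gt(ctrl$p_value, 0.05)
  expect_equal(ctrl$significance, "ns")
})

test_that("a missing condition at the test time yields a partial report with warning", {
  t <- small_tissue(t_min = 25, t_max = 35, seed = 22)
  ifc <- classify_interfaces(t, expressing_truth(t))
  ifc <- ifc[ifc$class != "plus1", ]
  expect_warning(cmp <- compare_conditions(ifc, t_test = 30,
                                           window = c(25, 35)),
                 "plus1")
  expect_equal(nrow(cmp$ks), 1)
})

test_that("before extension onset all interface columns are equally aligned", {
  t <- small_tissue(beta = 0.9, initial_alignment = TRUE,
                    t_min = -10, t_max = -1, seed = 23)
  ifc <- classify_interfaces(t, expressing_truth(t))
  tc <- coalignment_timecourse(ifc, window = c(-10, -1))
  props <- tapply(tc$proportion, tc$condition, mean)
  expect_lt(max(props) - min(props), 0.05)
})

test_that("permuting interface class labels destroys the boundary-control difference", {
  set.seed(30)
  t <- small_tissue(beta = 0.9, t_min = 30, t_max = 30, seed = 24)
  ifc <- classify_interfaces(t, expressing_truth(t))
  ab <- ifc[ifc$class %in% c("PSB", "plus1"), ]
  ref <- reflect_angles(ab$theta_deg)
  n_rep <- 200
  p_perm <- vapply(seq_len(n_rep), function(i) {
    lab <- sample(ab$class)
    ks_compare(ref[lab == "PSB"], ref[lab == "plus1"])$p_value
  }, 0)
  expect_gte(mean(p_perm > 0.05), 0.93)
})
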