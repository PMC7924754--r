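test_that("calibration fits through the origin and matches the closed form", {
  cal <- fit_calibration(tibble::tibble(concentration = c(1, 2),
                                        uv_area = c(10, 20)))
  expect_equal(cal$slope, 10)
  # area 15 from 1 g tissue in 1 mL: 1.5 ug/mL extract -> 1.5 ug/g FW
  expect_equal(quantify(cal, 15, tissue_mass_mg = 1000), 1.5)

  set.seed(1)
  std <- tibble::tibble(concentration = rep(c(1, 5, 20, 50), each = 2))
  std$uv_area <- 12 * std$concentration * exp(rnorm(8, 0, 0.1))
  cal2 <- fit_calibration(std)
  expect_equal(cal2$slope,
               sum(std$concentration * std$uv_area) / sum(std$concentration^2),
               tolerance = 1e-12)
  expect_error(fit_calibration(std[0, ]), ">= 2")
  expect_error(fit_calibration(tibble::tibble(concentration = c(1, 1),
                                              uv_area = c(5, 6))), "degenerate")
  expect_error(fit_calibration(tibble::tibble(concentration = c(1, 2),
                                              uv_area = c(-10, -20))), "positive")
  expect_s3_class(tidy(cal), "tbl_df")
  expect_equal(glance(cal2)$n, 8)
})

test_that("quantification is linear: doubling all areas doubles concentrations", {
  std <- tibble::tibble(concentration = c(1, 2, 5), uv_area = c(10, 20, 50))
  cal <- fit_calibration(std)
  areas <- c(5, 15, 80)
  expect_equal(quantify(cal, 2 * areas), 2 * quantify(cal, areas))
})

test_that("MS-to-UV factor equals its closed form and respects the floor", {
  p <- tibble::tibble(ms_area = c(100, 200, 300), uv_area = c(5, 10, 15))
  fct <- estimate_ms_uv_factor(p)
  expect_equal(fct, 0.05)
  expect_equal(fct * 40, 2) # predicted UV for ms = 40

  set.seed(2)
  noisy <- tibble::tibble(ms_area = runif(20, 50, 500))
  noisy$uv_area <- 0.07 * noisy$ms_area * exp(rnorm(20, 0, 0.1))
  expect_equal(estimate_ms_uv_factor(noisy),
               sum(noisy$uv_area * noisy$ms_area) / sum(noisy$ms_area^2),
               tolerance = 1e-10)
  expect_error(estimate_ms_uv_factor(p, uv_floor = 100), "reliable")
})

test_that("panel quantification only predicts UV below the reliability floor", {
  tp <- simulate_targeted_panel(seed = 3)
  q_all <- quantify_panel(tp$panel, tp$standards, uv_floor = 0)
  expect_true(all(q_all$uv_source == "measured"))
  q_fl <- quantify_panel(tp$panel, tp$standards,
                         uv_floor = tp$truth$uv_floor_suggest)
  expect_true(any(q_fl$uv_source == "predicted"))
  # predictions are confined to the knockout genotype (low-signal samples)
  expect_true(all(q_fl$genotype[q_fl$uv_source == "predicted"] == "bx1"))
})

test_that("percent reduction covers totals, root types and edge cases", {
  quant <- tibble::tibble(
    compound = rep(c("DIMBOA", "MBOA"), each = 2),
    genotype = rep(c("WT", "bx1"), 2),
    root_type = "postembryonic",
    concentration = c(80, 1.6, 20, 0.4)
  )
  red <- percent_reduction(quant)
  expect_equal(red$overall, 98)
  expect_equal(red$by_compound$percent_reduction, c(98, 98))

  same <- dplyr::mutate(quant, concentration = rep(c(10, 10), 2))
  expect_equal(percent_reduction(same)$overall, 0)

  zero_wt <- dplyr::mutate(quant, concentration = ifelse(genotype == "WT", 0, 1))
  w <- capture_warnings(und <- percent_reduction(zero_wt))
  expect_match(w, "undefined", all = FALSE)
  expect_true(is.na(und$overall))

  # bounded above by 100, attained only at a zero mutant total
  full <- dplyr::mutate(quant, concentration = ifelse(genotype == "bx1", 0, 50))
  expect_equal(percent_reduction(full)$overall, 100)
})

test_that("ddct reproduces powers of two and its shift invariance", {
  rec <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    group = c("control", "treatment", "treatment", "treatment"),
    ct_reference = c(18, 18, 18, 18),
    ct_target = c(23, 23, 24, 21) # ddCt = 0, 0, 1, -2
  )
  out <- ddct(rec)
  expect_equal(out$rel_expression, c(1, 1, 0.5, 4))

  shifted <- dplyr::mutate(rec, ct_reference = ct_reference + 3,
                           ct_target = ct_target + 3)
  expect_equal(ddct(shifted)$rel_expression, out$rel_expression)

  # constructed 4x knockdown: treatment mean expression 0.25 vs control 1
  kd <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    group = rep(c("control", "treatment"), each = 2),
    ct_reference = 18,
    ct_target = c(23, 23, 25, 25)
  )
  expect_equal(knockdown_percent(ddct(kd)), 75)

  bad <- rec; bad$ct_reference[2] <- NA
  expect_warning(dropped <- ddct(bad), "dropped")
  expect_equal(nrow(dropped), 3)
})
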