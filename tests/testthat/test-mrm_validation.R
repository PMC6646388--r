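test_that("trace integration recovers areas and apexes", {
  # unit-height rectangle of width 1 min -> 60 intensity*s
  t <- seq(0, 2, by = 1 / 60)
  rect <- as.numeric(t >= 0.5 & t <= 1.5)
  tri <- pmax(0, 1 - abs(t - 1))
  pg <- peak_group("r", "AAAAAAK",
                   traces = list(y3 = data.frame(time_min = t,
                                                 intensity = rect),
                                 y4 = data.frame(time_min = t,
                                                 intensity = tri)))
  s <- integrate_traces(pg)
  expect_equal(s$area[s$fragment_label == "y3"], 60, tolerance = 0.02)
  # symmetric triangle apexes at its center
  expect_equal(s$apex_rt_min[s$fragment_label == "y4"], 1, tolerance = 0.02)

  # Gaussian area matches the closed form A*sigma*sqrt(2*pi) within 2%
  A <- 1000; sigma <- 0.1
  g <- A * exp(-(t - 1)^2 / (2 * sigma^2))
  pg2 <- peak_group("r", "AAAAAAK",
                    traces = list(y3 = data.frame(time_min = t, intensity = g),
                                  y4 = data.frame(time_min = t,
                                                  intensity = g / 2)))
  s2 <- integrate_traces(pg2)
  expect_equal(s2$area[1], A * (sigma * 60) * sqrt(2 * pi), tolerance = 0.02)

  short <- peak_group("r", "AAAAAAK",
                      traces = list(y3 = data.frame(time_min = c(0, 1),
                                                    intensity = c(0, 1)),
                                    y4 = data.frame(time_min = t,
                                                    intensity = tri)))
  expect_error(integrate_traces(short), "shorter than 3")
})

test_that("co-elution passes within tolerance and fails on missing signal", {
  expect_true(check_coelution(c(y3 = 10, y4 = 10, y5 = 10))$pass)
  expect_equal(check_coelution(c(y3 = 10, y4 = 10))$spread_min, 0)
  shifted <- check_coelution(c(y3 = 10, y4 = 15, y5 = 10))
  expect_false(shifted$pass)
  expect_equal(shifted$spread_min, 5)
  missing <- check_coelution(c(y3 = 10, y4 = NA))
  expect_false(missing$pass)
  expect_equal(missing$reason, "missing_transition")
  expect_error(check_coelution(c(y3 = 10)), ">= 2")

  # seeded jitter: pass decisions match direct spread recomputation
  set.seed(701)
  for (i in 1:50) {
    apex <- 30 + rnorm(5, 0, 0.03)
    names(apex) <- paste0("y", 3:7)
    got <- check_coelution(apex, 0.2)
    expect_equal(got$pass, (max(apex) - min(apex)) <= 0.2)
  }
})

test_that("dotp is the normalized dot product with its invariances", {
  expect_equal(dotp(c(2, 4, 6), c(1, 2, 3)), 1.0)
  expect_equal(dotp(c(1, 0), c(0, 1)), 0.0)
  expect_equal(dotp(c(3, 4), c(4, 3)), 0.96)
  expect_warning(z <- dotp(c(0, 0), c(1, 2)), "zero observed")
  expect_equal(z, 0)
  expect_error(dotp(c(-1, 2), c(1, 2)), "nonnegative")
  expect_error(dotp(c(y3 = 1, y4 = 2), c(y3 = 1, y5 = 2)), "differ")
  # named vectors are aligned by fragment label, not position
  expect_equal(dotp(c(y4 = 4, y3 = 3), c(y3 = 3, y4 = 4)), 1.0)
  # sqrt transform equals dotp of sqrt vectors
  expect_equal(dotp(c(9, 16), c(16, 9), sqrt_transform = TRUE),
               dotp(c(3, 4), c(4, 3)))
})

test_that("detection requires all of criteria A, B and C", {
  ref <- reference_pattern("AAAAAAK", c(y3 = 0.5, y4 = 0.3, y5 = 0.2), 30)
  good <- lapply(1:3, function(r) {
    summary_group("AAAAAAK", areas = c(y3 = 500, y4 = 300, y5 = 200),
                  apex = c(y3 = 30, y4 = 30.05, y5 = 30.02), replicate = r)
  })
  v <- validate_detection(good, ref)
  expect_true(v$detected)
  expect_equal(v$dotp, 1.0, tolerance = 1e-12)

  # criterion A: one replicate with an outlying apex spoils the group
  bad_apex <- good
  bad_apex[[2]] <- summary_group("AAAAAAK",
                                 areas = c(y3 = 500, y4 = 300, y5 = 200),
                                 apex = c(y3 = 30, y4 = 35, y5 = 30))
  va <- validate_detection(bad_apex, ref)
  expect_false(va$coelution_pass)
  expect_false(va$detected)

  # criterion C: signal in only 2 of 3 replicates
  two_of_three <- good
  two_of_three[[3]] <- summary_group("AAAAAAK",
                                     areas = c(y3 = 0, y4 = 0, y5 = 0),
                                     apex = c(y3 = NA, y4 = NA, y5 = NA))
  vc <- validate_detection(two_of_three, ref)
  expect_false(vc$replicate_pass)
  expect_false(vc$detected)

  # a transition expected by the reference but absent from the group
  missing_tr <- lapply(1:3, function(r) {
    summary_group("AAAAAAK", areas = c(y3 = 500, y4 = 300),
                  apex = c(y3 = 30, y4 = 30))
  })
  vm <- validate_detection(missing_tr, ref)
  expect_false(vm$detected)

  expect_error(validate_detection(good, NULL), "reference")
  expect_error(validate_detection(list(), ref), "no replicates")
})

test_that("the dotp threshold is strict at 0.80", {
  # observed (4,3) against reference (1,0): dotp = 4/5 = 0.80 exactly
  ref <- reference_pattern("AAAAAAK", c(y3 = 1, y4 = 1e-12), 30)
  ref$ratios <- c(y3 = 1, y4 = 0)
  groups <- lapply(1:3, function(r) {
    summary_group("AAAAAAK", areas = c(y3 = 4, y4 = 3),
                  apex = c(y3 = 30, y4 = 30))
  })
  v <- validate_detection(groups, ref)
  expect_equal(v$dotp, 0.80, tolerance = 1e-12)
  expect_false(v$dotp_pass)
  expect_false(v$detected)
  # raising the threshold never adds detections (monotonicity)
  th <- default_config()$validation
  th$dotp_threshold <- 0.75
  expect_true(validate_detection(groups, ref, th)$detected)
})

test_that("spike-in agreement is inclusive at 3.0 min and needs added area", {
  ref <- reference_pattern("AAAAAAK", c(y3 = 0.6, y4 = 0.4), 30)
  endo <- summary_group("AAAAAAK", areas = c(y3 = 600, y4 = 400),
                        apex = c(y3 = 30, y4 = 30))
  spiked <- summary_group("AAAAAAK", areas = c(y3 = 1800, y4 = 1200),
                          apex = c(y3 = 33, y4 = 33))
  s <- spikein_check(endo, spiked, ref)
  expect_true(s$pass)
  expect_equal(s$rt_diff_min, 3.0)  # inclusive boundary
  expect_equal(s$area_ratio, 3)

  late <- summary_group("AAAAAAK", areas = c(y3 = 1800, y4 = 1200),
                        apex = c(y3 = 33.1, y4 = 33.1))
  expect_false(spikein_check(endo, late, ref)$pass)

  flat <- summary_group("AAAAAAK", areas = c(y3 = 500, y4 = 300),
                        apex = c(y3 = 30, y4 = 30))
  sf <- spikein_check(endo, flat, ref)
  expect_false(sf$pass)
  expect_equal(sf$reason, "no_area_increase")

  # area arithmetic matches the analytic amplitude addition
  cfg <- sim_config(seed = 77)
  rp <- simulate_reference_pattern("GTELLSVDAR", cfg, reference_rt = 40)
  e <- simulate_peak_group(rp, cfg, seed = 78, noise_scale = 0,
                           rt_jitter_sd_min = 0)
  se <- integrate_traces(e)
  sp_areas <- setNames(se$area * 3, se$fragment_label)
  sp <- summary_group("GTELLSVDAR", areas = sp_areas,
                      apex = setNames(se$apex_rt_min, se$fragment_label))
  got <- spikein_check(e, sp, rp)
  expect_equal(got$area_ratio, 3, tolerance = 1e-9)
  expect_true(got$area_increase_pass)
})
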