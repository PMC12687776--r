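test_that("preload trimming re-zeroes the curve at the 0.2 N crossing", {
  # curve starting exactly at 0.2 N is unchanged apart from the zero shift
  d0 <- data.frame(displacement_um = seq(10, 100, by = 10),
                   force_n = seq(0.2, 2, length.out = 10))
  p0 <- preprocess_curve(d0)
  expect_equal(p0$displacement_um[1], 0)
  expect_equal(p0$force_n, d0$force_n)
  expect_equal(attr(p0, "zero_um"), 10)

  # a toe of 10 samples below 0.2 N is removed; the next sample becomes zero
  toe <- data.frame(displacement_um = 1:20,
                    force_n = c(seq(0.0, 0.18, by = 0.02), 0.2 + 0.1 * (0:9)))
  pt <- preprocess_curve(toe)
  expect_equal(nrow(pt), 10)
  expect_equal(pt$displacement_um[1], 0)
  expect_equal(pt$force_n[1], 0.2)
  expect_equal(pt$force_n[2], 0.3)

  # crossing between 0.15 and 0.25 N interpolates the zero halfway
  mid <- data.frame(displacement_um = c(0, 10, 20, 30),
                    force_n = c(0.05, 0.15, 0.25, 0.35))
  pm <- preprocess_curve(mid)
  expect_equal(attr(pm, "zero_um"), 15)
  expect_equal(pm$displacement_um, c(0, 5, 15), tolerance = 1e-12)
  expect_equal(pm$force_n[1], 0.2)

  expect_error(preprocess_curve(data.frame(displacement_um = 1:25,
                                           force_n = rep(0.1, 25))),
               "never reaches")
})

test_that("beam stress and strain transforms match the closed forms", {
  cur <- data.frame(displacement_um = c(0, 100), force_n = c(0, 10))
  ss <- to_stress_strain(cur, span_mm = 6, c_mm = 1, i_mm4 = 0.7363)
  expect_equal(ss$stress_mpa[2], 10 * 6 * 1 / (4 * 0.7363), tolerance = 1e-12)
  expect_equal(ss$strain_ue[2], 6 * 1 * 0.1 / 36 * 1e6, tolerance = 1e-9)
  # doubling I halves stress, leaves strain unchanged
  ss2 <- to_stress_strain(cur, span_mm = 6, c_mm = 1, i_mm4 = 2 * 0.7363)
  expect_equal(ss2$stress_mpa, ss$stress_mpa / 2, tolerance = 1e-12)
  expect_equal(ss2$strain_ue, ss$strain_ue)
  expect_error(to_stress_strain(cur, -6, 1, 1), "positive")
})

test_that("stiffness fitting recovers exact slopes and the beam modulus", {
  d <- seq(0, 500, by = 5)
  lin <- data.frame(displacement_um = d, force_n = 0.2 + 100 * d / 1000)
  st <- fit_stiffness(lin)
  expect_equal(st$stiffness_n_mm, 100, tolerance = 1e-9)
  expect_equal(st$r2, 1, tolerance = 1e-12)
  expect_equal(beam_modulus(100, 6, 0.7363), 100 * 216 / (48 * 0.7363) / 1000,
               tolerance = 1e-12)
  expect_equal(beam_modulus(100, 6, 0.7363), 0.6112, tolerance = 1e-4)
})

test_that("the selected window matches a brute-force enumeration oracle", {
  cv <- generate_bend_curve(120, 10, postyield_slope = 25,
                            failure_displacement = 400, step_um = 5)
  cur <- preprocess_curve(cv)
  st <- fit_stiffness(cur)
  oracle <- oracle_stiffness(cur)
  expect_equal(st$window, oracle$window)
  expect_equal(st$stiffness_n_mm, oracle$slope, tolerance = 1e-9)
  # the window lies wholly in the elastic segment
  d_yield_um <- (10 - 0.2) / 120 * 1000
  expect_true(all(cur$displacement_um[st$window[1]:st$window[2]] <=
                    d_yield_um + 1e-9))
  expect_equal(st$stiffness_n_mm, 120, tolerance = 1e-9)

  # noisy curve: agreement with the oracle under identical tie rules
  cvn <- generate_bend_curve(120, 10, postyield_slope = 25,
                             failure_displacement = 400, step_um = 5,
                             noise_sd = 0.05, seed = 12)
  curn <- preprocess_curve(cvn)
  stn <- fit_stiffness(curn)
  orn <- oracle_stiffness(curn)
  expect_equal(stn$window, orn$window)
  expect_equal(stn$stiffness_n_mm, orn$slope, tolerance = 1e-8)
})

test_that("offset yield matches the analytic bilinear intersection", {
  # E = 1000 MPa then a plateau at 50 MPa: the 0.2% offset line meets the
  # plateau at 52,000 microstrain
  ss <- bilinear_ss(1000, 50, max_strain_ue = 80000, step_ue = 50)
  y <- find_yield(ss, 1000)
  expect_false(y$no_yield)
  expect_equal(y$stress_mpa, 50, tolerance = 1e-9)
  expect_equal(y$strain_ue, 52000, tolerance = 1e-6)

  # brute-force oracle agreement within 0.1% on a work-hardening curve
  ss2 <- bilinear_ss(1000, 50, post_slope_mpa = 120, max_strain_ue = 80000)
  y2 <- find_yield(ss2, 1000)
  o2 <- oracle_offset_yield(ss2, 1000)
  expect_equal(y2$strain_ue, o2$strain_ue, tolerance = 1e-3)
  expect_equal(y2$stress_mpa, o2$stress_mpa, tolerance = 1e-3)

  # purely linear curve never crosses the offset line
  lin <- data.frame(strain_ue = seq(0, 50000, by = 100),
                    stress_mpa = seq(0, 50000, by = 100) * 1e-3)
  yl <- find_yield(lin, 1000)
  expect_true(yl$no_yield)
  expect_equal(yl$strain_ue, 50000)

  # refinement invariance: yield moves < 0.1% when the grid is 10x finer
  fine <- bilinear_ss(1000, 50, post_slope_mpa = 120, step_ue = 5)
  yf <- find_yield(fine, 1000)
  expect_lt(abs(yf$strain_ue - y2$strain_ue) / yf$strain_ue, 1e-3)
})

test_that("ultimate and failure landmarks follow the documented rules", {
  cliff <- data.frame(displacement_um = seq(5, 150, by = 5),
                      force_n = c(seq(0.5, 14, length.out = 28), 14.5, 0.4))
  lf <- find_ultimate_failure(cliff)
  expect_equal(lf$ultimate_index, 29)
  expect_equal(lf$failure_index, 30)
  expect_false(lf$no_failure)

  rising <- data.frame(displacement_um = seq(5, 150, by = 5),
                       force_n = seq(0.5, 15, length.out = 30))
  lr <- find_ultimate_failure(rising)
  expect_true(lr$no_failure)
  expect_equal(lr$failure_index, 30)

  # two equal maxima: first one wins
  twin <- data.frame(displacement_um = 1:30,
                     force_n = c(seq(0.5, 10, length.out = 26), 12, 11, 12, 1))
  expect_equal(find_ultimate_failure(twin)$ultimate_index, 27)
})

test_that("works and displacements partition exactly at yield", {
  cv <- generate_bend_curve(100, 12, postyield_slope = 5,
                            failure_displacement = 700, step_um = 2)
  ms <- summarize_mechanics(cv, span_mm = 6, c_mm = 1, i_mm4 = 0.7363)
  expect_equal(ms$total_displacement_um,
               ms$displacement_to_yield_um + ms$postyield_displacement_um,
               tolerance = 1e-6)
  expect_equal(ms$total_work_mj, ms$work_to_yield_mj + ms$postyield_work_mj,
               tolerance = 1e-9)
  expect_gte(ms$ultimate_force_n, ms$yield_force_n)
  expect_gte(ms$ultimate_stress_mpa, ms$yield_stress_mpa)
  nums <- unlist(ms[, !names(ms) %in% c("no_yield", "no_failure", "excluded")])
  expect_true(all(nums >= 0))
})

test_that("a linear ramp reproduces the triangle work and exclusion flag", {
  d <- seq(0, 500, by = 2.5)
  ramp <- data.frame(displacement_um = d, force_n = 20 * d / 1000)
  ms <- summarize_mechanics(ramp, span_mm = 6, c_mm = 1, i_mm4 = 0.7363)
  expect_true(ms$no_yield)
  expect_true(ms$no_failure)
  expect_true(ms$excluded)
  # half base times height, less the sliver trimmed below the preload
  expect_equal(ms$total_work_mj, 2.5, tolerance = 0.01)
  expect_equal(ms$total_work_mj, 0.2 * 0.49 + 0.5 * 9.8 * 0.49,
               tolerance = 1e-9)
  expect_equal(ms$stiffness_n_mm, 20, tolerance = 1e-9)
})

test_that("noiseless curves reproduce generator parameters to machine precision", {
  cv <- generate_bend_curve(100, 12, postyield_slope = 0,
                            failure_displacement = 600, step_um = 2)
  truth <- attr(cv, "truth")
  ms <- summarize_mechanics(cv, span_mm = 6, c_mm = 1, i_mm4 = 0.7363)
  expect_equal(ms$stiffness_n_mm, truth$stiffness, tolerance = 1e-12)
  expect_equal(ms$ultimate_force_n, truth$ultimate_force, tolerance = 1e-12)
  # flat plateau: the offset line crosses at the plateau level
  expect_equal(ms$yield_force_n, truth$yield_force, tolerance = 1e-9)
  expect_equal(ms$modulus_gpa, beam_modulus(100, 6, 0.7363), tolerance = 1e-12)
  # analytic yield displacement: elastic rise to the plateau, plus the
  # 2000-microstrain offset (12 um at c = 1 mm, L = 6 mm), plus the
  # preload-equivalent displacement (the offset line is anchored at the
  # re-zeroed origin while the curve starts at the 0.2 N preload)
  d_elastic <- (12 - 0.2) / 100 * 1000
  d_offset <- 2000 * 6^2 / (6 * 1 * 1000)
  d_preload <- 0.2 / 100 * 1000
  expect_equal(ms$displacement_to_yield_um,
               d_elastic + d_offset + d_preload, tolerance = 1e-9)
  # analytic work to yield: preload strip + elastic triangle + plateau strip
  w_yield <- (0.2 * d_elastic + 0.5 * 11.8 * d_elastic +
                12 * (d_offset + d_preload)) / 1000
  expect_equal(ms$work_to_yield_mj, w_yield, tolerance = 1e-9)
})

test_that("summary is invariant to uniform resampling within 0.5%", {
  a <- generate_bend_curve(100, 12, postyield_slope = 5,
                           failure_displacement = 600, step_um = 2)
  b <- generate_bend_curve(100, 12, postyield_slope = 5,
                           failure_displacement = 600, step_um = 1)
  ma <- summarize_mechanics(a, 6, 1, 0.7363)
  mb <- summarize_mechanics(b, 6, 1, 0.7363)
  for (v in c("yield_force_n", "ultimate_force_n", "stiffness_n_mm",
              "total_work_mj", "resilience_mpa", "toughness_mpa")) {
    expect_equal(ma[[v]], mb[[v]], tolerance = 5e-3)
  }
})

test_that("yield-force estimates are unbiased on noisy replicate curves", {
  est <- numeric(50)
  for (i in 1:50) {
    cv <- generate_bend_curve(100, 12, postyield_slope = 0,
                              failure_displacement = 600, step_um = 5,
                              noise_sd = 0.1, seed = 900 + i)
    ms <- summarize_mechanics(cv, 6, 1, 0.7363)
    est[i] <- ms$yield_force_n
  }
  sem <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 12), 2 * sem + 1e-9)
})

test_that("batch analysis reads per-specimen CSVs with a geometry sidecar", {
  tmp <- withr::local_tempdir()
  ids <- c("s1", "s2")
  for (k in 1:2) {
    cv <- generate_bend_curve(100 + 10 * k, 12, postyield_slope = 0,
                              failure_displacement = 500, step_um = 5)
    write.csv(data.frame(displacement_um = cv$displacement_um,
                         force_n = cv$force_n),
              file.path(tmp, paste0(ids[k], ".csv")), row.names = FALSE)
  }
  geom <- data.frame(specimen_id = ids, span_mm = 6, c_mm = 1, i_mm4 = 0.7363)
  write.csv(geom, file.path(tmp, "geometry.csv"), row.names = FALSE)
  res <- analyze_bend_curves(file.path(tmp, paste0(ids, ".csv")),
                             file.path(tmp, "geometry.csv"))
  expect_equal(nrow(res), 2)
  expect_equal(res$stiffness_n_mm, c(110, 120), tolerance = 1e-9)
  expect_error(analyze_bend_curves(file.path(tmp, "s3.csv"),
                                   file.path(tmp, "geometry.csv")),
               "not found")
})
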