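test_that("fit_calibration recovers exact and collinear lines", {
  cal <- fit_calibration(data.frame(known_mass_kda = c(100, 200),
                                    mean_contrast = c(1, 2)))
  expect_equal(cal$slope, 100)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1)
  cal3 <- fit_calibration(data.frame(known_mass_kda = c(66, 146, 480),
                                     mean_contrast = (c(66, 146, 480) - 3) / 90))
  expect_equal(cal3$slope, 90)
  expect_equal(cal3$intercept, 3)
  expect_equal(cal3$r_squared, 1)
  expect_error(fit_calibration(data.frame(known_mass_kda = c(100, 200),
                                          mean_contrast = c(1, 1))),
               "singular")
  expect_error(fit_calibration(data.frame(known_mass_kda = 100,
                                          mean_contrast = 1)))
})

test_that("noisy calibration recovers the true slope within 3 s.e.", {
  set.seed(21)
  true_slope <- 520
  true_int <- -4
  contrast <- seq(0.1, 1, length.out = 10)
  std <- data.frame(known_mass_kda = true_slope * contrast + true_int +
                      rnorm(10, sd = 5),
                    mean_contrast = contrast)
  cal <- fit_calibration(std)
  se <- summary(lm(known_mass_kda ~ mean_contrast, std))$coefficients[2, 2]
  expect_lt(abs(cal$slope - true_slope), 3 * se)
})

test_that("calibration is affine-equivariant in the contrast scale", {
  set.seed(22)
  std <- data.frame(known_mass_kda = c(66, 146, 330, 480),
                    mean_contrast = c(0.13, 0.30, 0.67, 0.95) +
                      rnorm(4, sd = 0.01))
  cal <- fit_calibration(std)
  for (c_scale in c(0.1, 2, 50)) {
    scaled <- std
    scaled$mean_contrast <- std$mean_contrast * c_scale
    cal_s <- fit_calibration(scaled)
    expect_equal(cal_s$slope, cal$slope / c_scale)
    # predicted masses unchanged
    ev <- data.frame(event_index = 1:4, contrast = scaled$mean_contrast)
    ev0 <- data.frame(event_index = 1:4, contrast = std$mean_contrast)
    expect_equal(apply_calibration(ev, cal_s)$mass_kda,
                 apply_calibration(ev0, cal)$mass_kda)
  }
})

test_that("apply_calibration converts, round-trips and rejects bad input", {
  cal <- fit_calibration(data.frame(known_mass_kda = c(100, 200),
                                    mean_contrast = c(1, 2)))
  ev <- data.frame(event_index = 1L, contrast = 1.5)
  expect_equal(apply_calibration(ev, cal)$mass_kda, 150)
  # synthetic contrasts invert exactly to the simulated masses
  inst <- instrument_model(mass_sigma = 12, contrast_slope = 2.5e-4,
                           contrast_intercept = 0.003)
  tab <- simulate_sample(species_spec("x", 208), inst, n_events = 500,
                         seed = 10)
  inv <- fit_calibration(data.frame(
    known_mass_kda = c(100, 400),
    mean_contrast = inst$contrast_slope * c(100, 400) +
      inst$contrast_intercept))
  tab2 <- tab
  tab2$mass_kda <- NULL
  expect_equal(apply_calibration(tab2, inv)$mass_kda, tab$mass_kda,
               tolerance = 1e-9)
  # empty stays empty; missing contrasts are reported by row
  empty <- data.frame(event_index = integer(0), contrast = numeric(0))
  expect_equal(nrow(apply_calibration(empty, cal)), 0)
  bad <- data.frame(event_index = 1:3, contrast = c(1, NA, 2))
  expect_error(apply_calibration(bad, cal), "rows: 2")
})

test_that("calibration_drift reports per-run slopes", {
  std <- data.frame(known_mass_kda = rep(c(100, 200, 400), 2),
                    mean_contrast = c(1, 2, 4, 1.02, 2.04, 4.08),
                    run = rep(c("before", "after"), each = 3))
  d <- calibration_drift(std)
  expect_length(d$slopes, 2)
  expect_gt(d$drift, 0)
  expect_error(calibration_drift(std[, 1:2]), "run")
})

test_that("kde_spectrum has unit integral, correct argmax and scale invariance", {
  set.seed(23)
  for (masses in list(130, rnorm(100, 250, 20), runif(500, 50, 800))) {
    sp <- kde_spectrum(masses)
    expect_equal(trapz_test(sp$grid, sp$density), 1, tolerance = 1e-6)
    expect_true(all(sp$density >= 0))
    expect_lte(diff(sp$grid)[1], sp$kernel_sigma / 2)
  }
  one <- kde_spectrum(130)
  expect_lt(abs(one$grid[which.max(one$density)] - 130), 0.5 + 1e-12)
  many <- kde_spectrum(rep(130, 50))
  expect_equal(many$density, one$density)
  expect_equal(many$n_events, 50)
  expect_error(kde_spectrum(numeric(0)))
  expect_error(kde_spectrum(130, kernel_sigma = 5, grid_spacing = 3),
               "grid_spacing")
})

test_that("kde_spectrum matches the analytic convolution oracle", {
  tab <- sim_mixture(0.3, n = 1e5, seed = 24)
  sp <- kde_spectrum(tab$mass_kda, kernel_sigma = 5)
  expected <- oracle_mixture_density(sp$grid, c(208, 237.4), c(0.7, 0.3),
                                     sigma = 12, kernel_sigma = 5)
  expect_lt(max(abs(sp$density - expected)), 0.02 * max(expected))
})

test_that("find_peaks resolves a disc/stacked-disc doublet", {
  inst <- instrument_model(mass_sigma = 12, detection_limit = 40)
  tab <- simulate_sample(species_spec(c("disc", "stacked"), c(185, 370),
                                      c(0.5, 0.5)),
                         inst, n_events = 20000, seed = 25)
  sp <- kde_spectrum(tab$mass_kda)
  pk <- find_peaks(sp)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$peak_mass[1] - 185), 2)
  expect_lt(abs(pk$peak_mass[2] - 370), 2)
  # unimodal density: exactly one peak at its mean
  uni <- kde_spectrum(simulate_sample(species_spec("x", 440), inst,
                                      n_events = 20000, seed = 26)$mass_kda)
  pku <- find_peaks(uni)
  expect_equal(nrow(pku), 1)
  expect_lt(abs(pku$peak_mass - 440), 2)
  expect_lte(nrow(find_peaks(sp, min_prominence_fraction = 0)),
             length(sp$grid))
})

test_that("peak_fwhm matches the Gaussian closed form", {
  # analytic Gaussian spectra: fwhm = 2 sqrt(2 log 2) sigma
  for (s in c(5, 10, 17, 30)) {
    grid <- seq(200 - 6 * s, 200 + 6 * s, by = 1)
    spec <- structure(list(grid = grid, density = dnorm(grid, 200, s),
                           kernel_sigma = 1, n_events = 1L),
                      class = "mass_spectrum")
    expect_lt(abs(peak_fwhm(spec, 200) - 2 * sqrt(2 * log(2)) * s), 1)
  }
  grid <- seq(100, 300, by = 1)
  spec10 <- structure(list(grid = grid, density = dnorm(grid, 200, 10),
                           kernel_sigma = 1, n_events = 1L),
                      class = "mass_spectrum")
  expect_equal(peak_fwhm(spec10, 200), 23.55, tolerance = 0.1 / 23.55)
  # strictly wider for larger sigma
  widths <- vapply(c(6, 9, 14, 22), function(s) {
    g <- seq(0, 400, by = 1)
    peak_fwhm(structure(list(grid = g, density = dnorm(g, 200, s),
                             kernel_sigma = 1, n_events = 1L),
                        class = "mass_spectrum"), 200)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  # half height never reached on a truncated grid
  half_open <- structure(list(grid = seq(190, 210, 1),
                              density = dnorm(seq(190, 210, 1), 200, 10),
                              kernel_sigma = 1, n_events = 1L),
                         class = "mass_spectrum")
  expect_error(peak_fwhm(half_open, 200), "not crossed")
})

test_that("a realistic pentamer-disc spectrum stays under the 25 kDa width bound", {
  inst <- instrument_model(mass_sigma = 8.5, detection_limit = 40)
  tab <- simulate_sample(species_spec("pentamer disc", 130), inst,
                         n_events = 20000, seed = 27)
  sp <- kde_spectrum(tab$mass_kda, kernel_sigma = 5)
  pk <- find_peaks(sp)
  w <- peak_fwhm(sp, pk$peak_mass[which.max(pk$height)])
  expect_lt(w, 25)
  # consistent with sigma_total = sqrt(8.5^2 + 5^2) ~ 9.86
  expect_equal(w, 2 * sqrt(2 * log(2)) * sqrt(8.5^2 + 5^2),
               tolerance = 0.05)
})

test_that("spectra and calibrant tables survive CSV round trips", {
  dir <- withr::local_tempdir()
  sp <- kde_spectrum(c(100, 120, 125), kernel_sigma = 5)
  write_spectrum(sp, file.path(dir, "spec.csv"))
  back <- read.csv(file.path(dir, "spec.csv"))
  expect_equal(back$grid_kda, sp$grid)
  expect_equal(back$density, sp$density)
  std <- data.frame(name = "cal", known_mass_kda = 100, mean_contrast = 1)
  write.csv(rbind(std, data.frame(name = "cal2", known_mass_kda = 200,
                                  mean_contrast = 2)),
            file.path(dir, "std.csv"), row.names = FALSE)
  expect_equal(fit_calibration(read_calibrants(
    file.path(dir, "std.csv")))$slope, 100)
})
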