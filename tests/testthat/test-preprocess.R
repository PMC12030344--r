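test_that("acquisition-time normalization divides by total seconds and is guarded", {
  m <- matrix(900, 2, 5)
  s <- toy_spectra(m, normalized = FALSE)
  s$integration_time_s <- 90
  s$n_scans <- 10L
  out <- normalize_by_integration_time(s)
  expect_equal(unname(toy_matrix(out)), matrix(1, 2, 5))
  expect_true(all(out$normalized))
  expect_error(normalize_by_integration_time(out), "already")

  z <- toy_spectra(matrix(0, 1, 5), normalized = FALSE)
  expect_equal(unname(toy_matrix(normalize_by_integration_time(z))),
               matrix(0, 1, 5))
})

test_that("normalization equalizes noise-free spectra acquired at different settings", {
  st <- kinetics_at_state <- ramanpls:::kinetics_at(
    simulate_batch_kinetics(kinetics_params(duration_days = 4)), 50)
  a1 <- acquisition_settings(integration_time_s = 45, n_scans = 16,
                             noise_sd = 0)
  a2 <- acquisition_settings(integration_time_s = 90, n_scans = 10,
                             noise_sd = 0)
  s1 <- normalize_by_integration_time(
    generate_spectrum(st, acq = a1, noise = FALSE))
  s2 <- normalize_by_integration_time(
    generate_spectrum(st, acq = a2, noise = FALSE))
  expect_equal(toy_matrix(s1), toy_matrix(s2), tolerance = 1e-12)
})

test_that("block averaging: counts, identity, constants and variance reduction", {
  set.seed(1)
  s <- toy_spectra(matrix(rnorm(9 * 4), 9, 4))
  out <- average_consecutive(s, 3)
  expect_equal(nrow(out), 3L)
  expect_equal(out$timestamp_h, c(2, 5, 8))  # mean of member timestamps
  expect_identical(average_consecutive(s, 1), s)

  const <- toy_spectra(matrix(7, 7, 3))
  avg <- average_consecutive(const, 3)
  expect_equal(nrow(avg), 2L)  # trailing partial block dropped
  expect_true(all(toy_matrix(avg) == 7))

  ## white noise variance shrinks ~3x when averaging blocks of 3
  set.seed(42)
  noise <- toy_spectra(matrix(rnorm(3000), 3000, 1))
  v <- var(toy_matrix(average_consecutive(noise, 3))[, 1])
  expect_gt(v, 1 / 3 * 0.85)
  expect_lt(v, 1 / 3 * 1.15)
})

test_that("pairing picks the nearest spectrum with the earlier-on-tie rule", {
  m <- matrix(rnorm(12), 3, 4)
  s <- toy_spectra(m)
  s$timestamp_h <- c(49.8, 50.1, 50.4)
  off <- tibble::tibble(batch_id = "B1", timestamp_h = 50.0,
                        analyte = "glc", value = 5)
  p <- pair_with_reference(s, off, "glc")
  expect_equal(p$timestamp_h, 50.1)
  expect_equal(p$lag_h, 0.1, tolerance = 1e-9)

  s$timestamp_h <- c(49.9, 50.1, 50.4)  # exact tie: earlier wins
  p <- pair_with_reference(s, off, "glc")
  expect_equal(p$timestamp_h, 49.9)

  off$timestamp_h <- 60
  expect_warning(p <- pair_with_reference(s, off, "glc", max_lag_h = 1),
                 "skipped")
  expect_equal(nrow(p), 0L)
})

test_that("a full simulated batch pairs every off-line sample within the lag budget", {
  b <- generate_batch(kinetics_params(), seed = 5)
  sp <- average_consecutive(normalize_by_integration_time(b$spectra), 3)
  p <- pair_with_reference(sp, b$offline, "glc", max_lag_h = 1)
  expect_equal(nrow(p), 27L)  # day 0 + twice daily on days 2..14
  expect_true(all(p$lag_h <= 20 / 60 + 1e-9 + 2 / 3))
})

test_that("Savitzky-Golay reproduces polynomials and matches a brute-force fit", {
  wn <- 1000:1040
  s <- toy_spectra(matrix(5, 2, 41), wavenumbers = wn)
  expect_true(all(abs(toy_matrix(savitzky_golay(s, 7, 2, deriv = 1))) < 1e-10))

  ramp <- toy_spectra(matrix(rep(3 * wn + 11, 2), 2, byrow = TRUE),
                      wavenumbers = wn)
  d1 <- toy_matrix(savitzky_golay(ramp, 9, 2, deriv = 1))
  expect_equal(unname(d1), matrix(3, 2, 41), tolerance = 1e-10)
  sm <- toy_matrix(savitzky_golay(ramp, 9, 2, deriv = 0))
  expect_equal(unname(sm[1, ]), unname(3 * wn + 11), tolerance = 1e-10)

  ## brute-force windowed least-squares oracle at interior points
  set.seed(7)
  x <- rnorm(41)
  rand <- toy_spectra(matrix(x, 1), wavenumbers = wn)
  brute <- function(x, w, ord, m, i) {
    h <- (w - 1) / 2
    z <- (-h):h
    basis <- outer(z, 0:ord, "^")
    co <- qr.solve(basis, x[(i - h):(i + h)])
    factorial(m) * co[m + 1]
  }
  for (case in list(c(7, 3, 2), c(11, 2, 1), c(9, 4, 0))) {
    w <- case[1]; ord <- case[2]; m <- case[3]
    got <- toy_matrix(savitzky_golay(rand, w, ord, m))[1, ]
    h <- (w - 1) / 2
    interior <- (h + 1):(41 - h)
    want <- vapply(interior, function(i) brute(x, w, ord, m, i), numeric(1))
    expect_lt(max(abs(got[interior] - want)) / max(abs(want)), 1e-9)
  }

  expect_error(savitzky_golay(rand, 6, 2), "odd")
  expect_error(savitzky_golay(rand, 7, 9), "smaller")
  expect_error(savitzky_golay(rand, 43, 2), "exceeds")
})

test_that("SNV standardizes rows, is affine-invariant and idempotent", {
  s <- toy_spectra(matrix(c(1, 2, 3), 1))
  expect_equal(unname(toy_matrix(snv(s))), matrix(c(-1, 0, 1), 1))

  set.seed(3)
  r <- toy_spectra(matrix(rnorm(5 * 20, sd = 4), 5, 20))
  out <- toy_matrix(snv(r))
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_true(all(abs(apply(out, 1, sd) - 1) < 1e-12))

  shifted <- toy_spectra(7 * toy_matrix(r) + 3)
  expect_equal(toy_matrix(snv(shifted)), out, tolerance = 1e-12)
  expect_equal(toy_matrix(snv(snv(r))), out, tolerance = 1e-12)

  expect_error(snv(toy_spectra(matrix(2, 1, 4))), "constant")
})

test_that("linear detrending leaves residuals orthogonal to the line basis", {
  wn <- 800:850
  line <- toy_spectra(matrix(rep(2 * wn - 5, 3), 3, byrow = TRUE),
                      wavenumbers = wn)
  expect_true(all(abs(toy_matrix(detrend_linear(line))) < 1e-9))

  set.seed(8)
  r <- toy_spectra(matrix(rnorm(2 * 51), 2, 51), wavenumbers = wn)
  out <- toy_matrix(detrend_linear(r))
  for (i in 1:2) {
    co <- coef(lm(out[i, ] ~ wn))
    expect_lt(abs(co[1]), 1e-8)
    expect_lt(abs(co[2]), 1e-10)
  }

  ## quadratic: residual equals the closed-form quadratic minus its line fit
  quad <- 0.01 * (wn - 825)^2
  qs <- toy_spectra(matrix(quad, 1), wavenumbers = wn)
  basis <- cbind(1, wn)
  proj <- basis %*% qr.solve(basis, quad)
  expect_equal(unname(toy_matrix(detrend_linear(qs))[1, ]),
               unname(quad - as.vector(proj)), tolerance = 1e-10)
})

test_that("area normalization gives unit 1-norm and respects sign symmetry", {
  s <- toy_spectra(matrix(c(1, 1, 2), 1))
  expect_equal(unname(toy_matrix(area_normalize(s))),
               matrix(c(0.25, 0.25, 0.5), 1))
  set.seed(9)
  r <- toy_spectra(matrix(rnorm(4 * 30), 4, 30))
  out <- toy_matrix(area_normalize(r))
  expect_true(all(abs(rowSums(abs(out)) - 1) < 1e-12))
  neg <- toy_spectra(-toy_matrix(r))
  expect_equal(toy_matrix(area_normalize(neg)), -out, tolerance = 1e-12)
  expect_error(area_normalize(toy_spectra(matrix(0, 1, 3))), "all-zero")
})

test_that("range selection is inclusive on the integer grid", {
  full <- toy_spectra(matrix(rnorm(2 * 2951), 2),
                      wavenumbers = 250:3200)
  expect_equal(length(wn_cols(select_range(full, 1000, 1500))), 501L)
  expect_equal(length(wn_cols(select_range(full, 800, 950))), 151L)
  expect_identical(select_range(full, 250, 3200), full)
  expect_error(select_range(full, 4000, 4100), "smaller|no wavenumbers")
  expect_error(select_range(full, 3500, 3600), "no wavenumbers")
})

test_that("preprocessing spec parsing round-trips the table notation", {
  sp <- preprocess_spec("D1(23,2)+SNV", range = c(1000, 1500))
  expect_equal(length(sp$steps), 2L)
  expect_equal(sp$steps[[1]], list(op = "D1", width = 23L, order = 2L))
  expect_match(format(sp), "D1\\(23,2\\)\\+SNV \\| 1000:1500")
  expect_error(preprocess_spec("D3(9,2)"), "Unknown")
  expect_error(preprocess_spec("D1(8,2)"), "odd")
  expect_error(preprocess_spec("D2(9,1)"), "Derivative")
})

test_that("apply_spec centers with calibration statistics only", {
  set.seed(10)
  wn <- 700:1700
  cal <- toy_spectra(matrix(rnorm(20 * 1001, mean = 5), 20),
                     wavenumbers = wn)
  test <- toy_spectra(matrix(rnorm(8 * 1001, mean = 9), 8),
                      wavenumbers = wn)
  out <- apply_spec(cal, test, preprocess_spec("", range = c(900, 1100)))
  expect_true(all(abs(colMeans(toy_matrix(out$cal))) < 1e-12))
  expect_gt(mean(abs(colMeans(toy_matrix(out$test)))), 1)

  ## mutating test rows must not change the fitted center (no leakage)
  test2 <- test
  test2[wn_cols(test2)] <- test2[wn_cols(test2)] + 100
  out2 <- apply_spec(cal, test2, preprocess_spec("", range = c(900, 1100)))
  expect_identical(out$center, out2$center)

  ## re-application with the stored center reproduces the transformation
  out3 <- apply_spec(cal, test, preprocess_spec("", range = c(900, 1100)),
                     center = out$center)
  expect_equal(out3$test, out$test, tolerance = 1e-12)
})

test_that("the tuned glucose recipe yields 501 centered columns", {
  set.seed(11)
  cal <- toy_spectra(matrix(rnorm(15 * 2951, mean = 3), 15),
                     wavenumbers = 250:3200)
  sp <- preprocess_spec("D1(23,2)+SNV", range = c(1000, 1500))
  out <- apply_spec(cal, spec = sp)
  expect_equal(length(wn_cols(out$cal)), 501L)
  expect_true(all(abs(colMeans(toy_matrix(out$cal))) < 1e-12))
})

test_that("operators are row-wise: permuting samples permutes outputs", {
  set.seed(12)
  s <- toy_spectra(matrix(rnorm(6 * 40), 6, 40), wavenumbers = 901:940)
  perm <- c(4, 1, 6, 2, 5, 3)
  for (f in list(snv, detrend_linear, area_normalize,
                 function(d) savitzky_golay(d, 7, 2, 1))) {
    out <- toy_matrix(f(s))
    out_perm <- toy_matrix(f(toy_spectra(toy_matrix(s)[perm, ],
                                         wavenumbers = 901:940)))
    expect_equal(out_perm, out[perm, ], tolerance = 1e-12)
  }
})
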