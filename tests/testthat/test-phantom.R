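# Phantom construction, attenuation physics, and the paired-study simulator.

uniform_spec <- function(a = 1, mu = 0.0096, grid = 32, px = 6) {
  phantom_spec(grid, px, body = list(center = c(0, 0), semi = c(70, 55),
                                     activity = a),
               background_mu = mu)
}

test_that("degenerate phantoms rasterise to their closed forms", {
  maps <- build_phantom(uniform_spec(a = 2.5))
  inside <- maps$activity_map > 0
  expect_true(all(maps$activity_map[inside] == 2.5))
  expect_true(all(maps$activity_map[!inside] == 0))
  expect_true(all(maps$attenuation_map[!inside] == 0))
  # background_mu = 0 -> attenuation identically zero
  maps0 <- build_phantom(uniform_spec(mu = 0))
  expect_true(all(maps0$attenuation_map == 0))
  # grid too small rejected
  expect_error(phantom_spec(8, 6, body = list(center = c(0, 0), semi = c(10, 10))),
               "grid_size")
})

test_that("a lesion adds exactly (a_lesion - a_bg) * bg * pixel count of activity", {
  base <- uniform_spec(a = 1)
  les <- phantom_spec(32, 6, body = base$body,
                      lesions = list(list(center = c(10, -5), radius_mm = 15,
                                          activity = 3)))
  m0 <- build_phantom(base)$activity_map
  m1 <- build_phantom(les)$activity_map
  npix <- sum(m1 != m0)
  expect_gt(npix, 0)
  expect_equal(sum(m1) - sum(m0), (3 - 1) * 1 * npix)
})

test_that("structures outside the body are rejected", {
  expect_error(
    phantom_spec(32, 6, body = list(center = c(0, 0), semi = c(40, 30)),
                 organs = list(list(center = c(35, 0), semi = c(10, 8),
                                    mu = 0.005))),
    "outside the body")
})

test_that("survival factors are 1 for zero attenuation and lie in (0, 1]", {
  fm <- attenuation_factors(matrix(0, 24, 24), 4, n_angles = 8)
  expect_true(all(fm$values == 1))
  mu <- disc_mu(32, 6, 60, 0.008)
  fm2 <- attenuation_factors(mu, 6, n_angles = 16)
  expect_true(all(fm2$values > 0 & fm2$values <= 1))
})

test_that("uniform-disc centre factor matches the closed-form chord integral", {
  # every chord through the centre of a uniform disc has length 2r, so the
  # factor is exp(-2 mu r) independent of angle
  n <- 128; px <- 2
  mu <- disc_mu(n, px, 100, 0.0096)
  fm <- attenuation_factors(mu, px, n_angles = 32)
  co <- (seq_len(n) - (n + 1) / 2) * px
  i0 <- which.min(abs(co))
  expect_equal(fm$values[i0, i0], exp(-2 * 0.0096 * 100), tolerance = 0.01)
})

test_that("doubling mu squares the per-angle factors", {
  # exp(-2 I) = exp(-I)^2 holds along each chord; after angular averaging
  # Jensen's inequality gives f(2 mu) >= f(mu)^2, with equality where all
  # chords carry the same integral (the centre of a uniform disc)
  set.seed(4)
  mu <- disc_mu(32, 6, 70, 0.006) * matrix(runif(32 * 32, 0.5, 1.5), 32)
  f1 <- attenuation_factors(mu, 6, n_angles = 8)$values
  f2 <- attenuation_factors(2 * mu, 6, n_angles = 8)$values
  expect_true(all(f2 >= f1^2 - 1e-12))
  mu_u <- disc_mu(32, 6, 70, 0.006)
  g1 <- attenuation_factors(mu_u, 6, n_angles = 8)$values
  g2 <- attenuation_factors(2 * mu_u, 6, n_angles = 8)$values
  co <- (seq_len(32) - 16.5) * 6
  i0 <- which.min(abs(co))
  expect_equal(g2[i0, i0], g1[i0, i0]^2, tolerance = 1e-3)
})

test_that("larger bodies attenuate the centre pixel more", {
  fac_of <- function(r) {
    mu <- disc_mu(48, 5, r, 0.0096)
    co <- (seq_len(48) - 24.5) * 5
    i0 <- which.min(abs(co))
    attenuation_factors(mu, 5, n_angles = 8)$values[i0, i0]
  }
  f <- vapply(c(50, 80, 110), fac_of, 0)
  expect_true(all(diff(f) < 0))
})

test_that("with every corruption off the NAC image equals the ASC image", {
  prof <- center_profile("T", psf_fwhm_mm = 0, noise_scale = 0,
                         scatter_fraction = 0, matrix_size = 32,
                         pixel_size_mm = 6)
  maps <- build_phantom(uniform_spec(mu = 0))
  st <- simulate_pair(maps$activity_map, matrix(0, 32, 32), prof,
                      list(injected_activity_MBq = 300, body_weight_kg = 70),
                      seed = 1)
  expect_equal(st$nac_image, st$asc_image)
})

test_that("scatter fraction is recovered exactly from component sums", {
  prof <- center_profile("T", psf_fwhm_mm = 5, noise_scale = 0,
                         scatter_fraction = 0.35, matrix_size = 32,
                         pixel_size_mm = 6)
  maps <- build_phantom(uniform_spec())
  st <- simulate_pair(maps$activity_map, maps$attenuation_map, prof,
                      list(injected_activity_MBq = 300, body_weight_kg = 70),
                      seed = 2)
  s <- sum(st$components$scatter)
  p <- sum(st$components$primary)
  expect_equal(s / (s + p), 0.35, tolerance = 1e-9)
  expect_equal(sum(st$components$scatter) / sum(st$nac_image), 0.35,
               tolerance = 1e-9)
})

test_that("without scatter, attenuation only removes signal", {
  prof <- center_profile("T", psf_fwhm_mm = 4, noise_scale = 0,
                         scatter_fraction = 0, matrix_size = 32,
                         pixel_size_mm = 6)
  maps <- build_phantom(uniform_spec())
  st <- simulate_pair(maps$activity_map, maps$attenuation_map, prof,
                      list(injected_activity_MBq = 300, body_weight_kg = 70),
                      seed = 3)
  expect_true(all(st$nac_image <= st$asc_image + 1e-12))
})

test_that("dataset generation is a pure function of (profile, master seed)", {
  prof <- center_profile("C9", matrix_size = 32, pixel_size_mm = 6,
                         n_studies = 3)
  d1 <- generate_center_dataset(prof, master_seed = 77)
  d2 <- generate_center_dataset(prof, master_seed = 77)
  expect_identical(d1$studies[[2]]$nac_image, d2$studies[[2]]$nac_image)
  expect_identical(d1$studies[[3]]$asc_image, d2$studies[[3]]$asc_image)
  d3 <- generate_center_dataset(prof, master_seed = 78)
  expect_false(identical(d1$studies[[1]]$nac_image, d3$studies[[1]]$nac_image))
})

test_that("profiles differing only in blur share anatomy and attenuation", {
  p1 <- center_profile("C9", psf_fwhm_mm = 3, noise_scale = 0,
                       matrix_size = 32, pixel_size_mm = 6, n_studies = 3)
  p2 <- center_profile("C9", psf_fwhm_mm = 8, noise_scale = 0,
                       matrix_size = 32, pixel_size_mm = 6, n_studies = 3)
  d1 <- generate_center_dataset(p1, 5)
  d2 <- generate_center_dataset(p2, 5)
  for (i in 1:3) {
    # identical phantom -> identical survival factors, different blur
    expect_identical(d1$studies[[i]]$components$factors$values,
                     d2$studies[[i]]$components$factors$values)
    expect_false(identical(d1$studies[[i]]$asc_image, d2$studies[[i]]$asc_image))
  }
})
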