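# Dataset splitting and the end-to-end orchestration.

test_that("the study-default split yields 30/10/10 per 50-study centre", {
  sp <- split_dataset(50, seed = 1)
  expect_length(sp$train, 30)
  expect_length(sp$validation, 10)
  expect_length(sp$test, 10)
  expect_equal(sort(unname(unlist(sp))), 1:50)   # disjoint and exhaustive
  # pooled across six centres: 180/60 train/validation and 60 test studies
  splits <- lapply(1:6, function(k) split_dataset(50, seed = k))
  expect_equal(sum(vapply(splits, function(s) length(s$train), 0L)), 180)
  expect_equal(sum(vapply(splits, function(s) length(s$validation), 0L)), 60)
  expect_equal(sum(vapply(splits, function(s) length(s$test), 0L)), 60)
})

test_that("splits are deterministic and reject empty partitions", {
  expect_identical(split_dataset(16, seed = 9), split_dataset(16, seed = 9))
  expect_false(identical(split_dataset(16, seed = 9),
                         split_dataset(16, seed = 10)))
  sp <- split_dataset(16, seed = 3)    # 10/3/3 at the default fractions
  expect_equal(lengths(unclass(sp)), c(train = 10L, validation = 3L, test = 3L))
  expect_error(split_dataset(4, fractions = c(0.9, 0.05, 0.05)), "empty")
})

desk_mini_config <- function(seed = 5, strategies = c("CB", "CZ", "FL_PL",
                                                      "FL_SQ")) {
  profiles <- lapply(1:2, function(k)
    center_profile(paste0("M", k), psf_fwhm_mm = 4 + k, noise_scale = 0.05,
                   scatter_fraction = 0.3 + 0.1 * k, matrix_size = 32,
                   pixel_size_mm = 6, n_studies = 10))
  experiment_config(profiles = profiles, master_seed = seed,
                    strategies = strategies, rounds = 2, batch_size = 3,
                    target_size = 32, target_spacing_mm = 6,
                    fractions = c(0.4, 0.3, 0.3))
}

test_that("run_experiment produces the expected per-strategy bookkeeping", {
  res <- run_experiment(desk_mini_config())
  m <- res$metrics
  n_test_pool <- 2 * 3
  for (s in c("CZ", "FL_PL", "FL_SQ"))
    expect_equal(sum(m$strategy == s), n_test_pool)
  # CB: per centre, own tests once; cross evaluation over the pooled tests
  expect_equal(sum(m$strategy == "CB"), 2 * 3)
  expect_equal(sum(m$strategy == "CB_cross"), 2 * n_test_pool)
  expect_setequal(names(res$mean_are),
                  c("CB", "CB_cross", "CZ", "FL_PL", "FL_SQ"))
  expect_true(all(is.finite(m$ARE_pct)))
  expect_true(all(m$SSIM >= -1 & m$SSIM <= 1))
  expect_true(all(m$MAE >= abs(m$ME) - 1e-12))
  expect_true(all(m$ARE_pct >= abs(m$RE_pct) - 1e-12))
})

test_that("a CZ-only experiment produces no federated artifacts", {
  res <- run_experiment(desk_mini_config(strategies = "CZ"))
  expect_setequal(unique(res$metrics$strategy), "CZ")
  expect_null(res$stats_overall)
  expect_named(res$r2, "CZ")
})

test_that("experiments are bit-reproducible from the config", {
  r1 <- run_experiment(desk_mini_config(seed = 8, strategies = c("CZ", "FL_SQ")))
  r2 <- run_experiment(desk_mini_config(seed = 8, strategies = c("CZ", "FL_SQ")))
  expect_identical(r1$metrics, r2$metrics)
})

test_that("no test study appears in any training set", {
  cfg <- desk_mini_config()
  centers <- fedpet:::prepare_centers(cfg)
  for (ce in centers) {
    expect_length(intersect(ce$split$train, ce$split$test), 0)
    expect_length(intersect(ce$split$validation, ce$split$test), 0)
  }
})

test_that("experiment artifacts round-trip through the output directory", {
  dir <- file.path(tempdir(), "fedpet_exp")
  cfg <- desk_mini_config(strategies = c("CZ", "FL_SQ"))
  cfg$out_dir <- dir
  res <- run_experiment(cfg)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(unlist(js$mean_are_pct["CZ"]), res$mean_are[["CZ"]],
               tolerance = 1e-9, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("YAML configs round-trip into experiment configs", {
  y <- file.path(tempdir(), "cfg.yaml")
  writeLines(c(
    "master_seed: 4",
    "rounds: 3",
    "target_size: 32",
    "profiles:",
    "  - center_id: A",
    "    matrix_size: 32",
    "    pixel_size_mm: 6",
    "    n_studies: 6",
    "  - center_id: B",
    "    matrix_size: 48",
    "    pixel_size_mm: 4",
    "    n_studies: 6"), y)
  cfg <- read_experiment_config(y)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$master_seed, 4L)
  expect_equal(cfg$rounds, 3L)
  expect_length(cfg$profiles, 2)
  expect_equal(cfg$profiles[[2]]$center_id, "B")
  unlink(y)
})

test_that("the command-line front end simulates centre datasets", {
  cli <- system.file("cli", "fedpet", package = "fedpet")
  expect_true(nzchar(cli))
  y <- file.path(tempdir(), "cli.yaml")
  out <- file.path(tempdir(), "cli_out")
  writeLines(c("master_seed: 2",
               "profiles:",
               "  - center_id: Z",
               "    matrix_size: 32",
               "    pixel_size_mm: 6",
               "    n_studies: 3"), y)
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(cli, "simulate", "--config", shQuote(y),
                               "--out", shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "Z", "Z_001_nac.nii.gz")))
  expect_true(file.exists(file.path(out, "Z", "Z_003.json")))
  unlink(c(y, out), recursive = TRUE)
})

test_that("paired studies round-trip through NIfTI with sidecars", {
  prof <- center_profile("IO", matrix_size = 32, pixel_size_mm = 6,
                         n_studies = 3)
  ds <- generate_center_dataset(prof, 6)
  stem <- file.path(tempdir(), "io_study")
  write_study(ds$studies[[1]], stem)
  back <- read_study(stem)
  expect_equal(back$nac_image, ds$studies[[1]]$nac_image, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$asc_image, ds$studies[[1]]$asc_image, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$injected_activity_MBq,
               ds$studies[[1]]$injected_activity_MBq, tolerance = 1e-9)
  expect_equal(back$grid$spacing[1], 6)
  unlink(paste0(stem, c("_nac.nii.gz", "_asc.nii.gz", ".json")))
})
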