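# Federated engine: local updates, aggregation algebra, strategy degeneracies.

make_linear_centers <- function(sizes, p = 4, seed = 1) {
  set.seed(seed)
  lapply(seq_along(sizes), function(k) {
    X <- lapply(seq_len(sizes[k]), function(i) matrix(rnorm(p), 1))
    theta_true <- seq_len(p) / p
    Y <- lapply(X, function(x) sum(x * theta_true) + rnorm(1, sd = 0.1))
    local_dataset(paste0("K", k), X, Y)
  })
}

test_that("zero learning rate leaves parameters untouched", {
  centers <- make_linear_centers(c(5, 7))
  m <- linear_model(4)
  cfg <- strategy_config("FL_SQ", rounds = 3, local_epochs = 2,
                         batch_size = 2, optimizer = "sgd", lr = 0,
                         weight_decay = 0)
  st <- run_fl_sequential(centers, m, cfg, seed = 5)
  expect_equal(st$theta, m$init(fedpet:::derive_seed(5, "init")))
})

test_that("full-batch local gradients equal the closed form", {
  centers <- make_linear_centers(c(6))
  m <- linear_model(4)
  cfg <- strategy_config("FL_PL", rounds = 1, local_epochs = 1,
                         batch_size = Inf, optimizer = "sgd",
                         weight_decay = 0, aggregation_mode = "gradient")
  theta <- m$init(2)
  up <- local_update(theta, centers[[1]], cfg, m, seed = 1)
  X <- do.call(rbind, centers[[1]]$X)
  y <- unlist(centers[[1]]$Y)
  expect_equal(up$payload, linear_grad(theta, X, y), tolerance = 1e-12)
  # identical inputs give identical payloads
  up2 <- local_update(theta, centers[[1]], cfg, m, seed = 1)
  expect_identical(up$payload, up2$payload)
})

test_that("gradient mode refuses multi-step local schedules", {
  centers <- make_linear_centers(c(6))
  m <- linear_model(4)
  cfg <- strategy_config("FL_PL", local_epochs = 2, batch_size = Inf,
                         aggregation_mode = "gradient")
  expect_error(local_update(m$init(1), centers[[1]], cfg, m, 1), "full batch")
  cfg2 <- strategy_config("FL_PL", local_epochs = 1, batch_size = 2,
                          aggregation_mode = "gradient")
  expect_error(local_update(m$init(1), centers[[1]], cfg2, m, 1), "full batch")
})

test_that("weighted-gradient aggregation reproduces the hand-computed step", {
  mk <- function(n, g) structure(list(center_id = "x", n = n,
                                      mode = "gradient", payload = g),
                                 class = "local_update")
  theta <- c(0, 0)
  out <- aggregate_updates(list(mk(25, c(1, 0)), mk(75, c(0, 1))), theta,
                           lr = 0.1)
  expect_equal(out, c(-0.025, -0.075))
  # parameter averaging of identical vectors returns that vector
  mkp <- function(n, v) structure(list(center_id = "x", n = n,
                                       mode = "parameter", payload = v),
                                  class = "local_update")
  common <- c(0.3, -0.2)
  expect_equal(aggregate_updates(list(mkp(10, common), mkp(40, common)),
                                 theta, 0.1), common)
  expect_error(aggregate_updates(list(mk(5, c(1, 0)), mk(5, c(1, 2, 3))),
                                 theta, 0.1), "conformable")
})

test_that("parameter averaging with single full-batch SGD steps equals gradient mode", {
  centers <- make_linear_centers(c(4, 9, 5), seed = 3)
  m <- linear_model(4)
  base <- list(rounds = 6L, local_epochs = 1L, batch_size = Inf,
               optimizer = "sgd", lr = 0.05, weight_decay = 0)
  cfg_g <- do.call(strategy_config, c(list("FL_PL",
                                           aggregation_mode = "gradient"), base))
  cfg_p <- do.call(strategy_config,
                   c(list("FL_PL", aggregation_mode = "parameter_average"),
                     base))
  st_g <- run_fl_parallel(centers, m, cfg_g, seed = 7)
  st_p <- run_fl_parallel(centers, m, cfg_p, seed = 7)
  expect_equal(st_g$theta, st_p$theta, tolerance = 1e-12)
})

test_that("one round of gradient-mode FL equals a pooled full-batch SGD step", {
  centers <- make_linear_centers(c(5, 12, 8), seed = 9)
  m <- linear_model(4)
  cfg <- strategy_config("FL_PL", rounds = 1, local_epochs = 1,
                         batch_size = Inf, optimizer = "sgd", lr = 0.1,
                         weight_decay = 0, aggregation_mode = "gradient")
  st <- run_fl_parallel(centers, m, cfg, seed = 4)
  theta0 <- m$init(fedpet:::derive_seed(4, "init"))
  X <- do.call(rbind, do.call(c, lapply(centers, `[[`, "X")))
  y <- unlist(lapply(centers, `[[`, "Y"))
  expect_equal(st$theta, theta0 - 0.1 * linear_grad(theta0, X, y),
               tolerance = 1e-9)
})

test_that("identical data at every centre makes FL-PL follow the CZ trajectory", {
  cfgnet <- tiny_cfg()
  m <- u2net_model(cfgnet)
  X <- rand_slices(3, 8, seed = 31)
  Y <- rand_slices(3, 8, seed = 32)
  centers <- lapply(1:3, function(k) local_dataset(paste0("K", k), X, Y))
  cfg <- strategy_config("FL_PL", rounds = 4, local_epochs = 2,
                         batch_size = Inf, optimizer = "adam", lr = 1e-3,
                         weight_decay = 1e-4)
  st_fl <- run_fl_parallel(centers, m, cfg, seed = 6)
  st_cz <- run_centralized(centers, m, cfg, seed = 6)
  expect_equal(st_fl$theta, st_cz$theta, tolerance = 1e-9)
})

test_that("single-centre FL-SQ degenerates to centre-based training", {
  cfgnet <- tiny_cfg()
  m <- u2net_model(cfgnet)
  center <- local_dataset("solo", rand_slices(4, 8, seed = 41),
                          rand_slices(4, 8, seed = 42))
  cfg_sq <- strategy_config("FL_SQ", rounds = 3, local_epochs = 2,
                            batch_size = 2)
  cfg_cb <- strategy_config("CB", rounds = 3, local_epochs = 2,
                            batch_size = 2)
  st_sq <- run_fl_sequential(list(center), m, cfg_sq, seed = 8)
  st_cb <- run_center_based(center, m, cfg_cb, seed = 8)
  expect_equal(st_sq$theta, st_cb$theta, tolerance = 1e-12)
})

test_that("CZ over a single centre equals CB on that centre", {
  m <- linear_model(3)
  center <- make_linear_centers(c(7), p = 3, seed = 13)[[1]]
  cfg <- strategy_config("CZ", rounds = 4, local_epochs = 1, batch_size = 3)
  st_cz <- run_centralized(list(center), m, cfg, seed = 2)
  st_cb <- run_center_based(center, m, cfg, seed = 2)
  # the pooled dataset carries a different centre id, so shuffling differs;
  # compare through the deterministic full-batch path instead
  cfg_fb <- strategy_config("CZ", rounds = 4, local_epochs = 1,
                            batch_size = Inf)
  expect_equal(run_centralized(list(center), m, cfg_fb, seed = 2)$theta,
               run_center_based(center, m, cfg_fb, seed = 2)$theta,
               tolerance = 1e-12)
  expect_equal(st_cz$history$loss[1], st_cb$history$loss[1], tolerance = 0.5)
})

test_that("training is deterministic given (datasets, config, seed)", {
  centers <- make_linear_centers(c(6, 4), seed = 21)
  m <- linear_model(4)
  cfg <- strategy_config("FL_PL", rounds = 3, local_epochs = 2, batch_size = 2,
                         optimizer = "adam")
  s1 <- run_fl_parallel(centers, m, cfg, seed = 3)
  s2 <- run_fl_parallel(centers, m, cfg, seed = 3)
  expect_identical(s1$theta, s2$theta)
  expect_identical(s1$history, s2$history)
  s3 <- run_fl_parallel(centers, m, cfg, seed = 4)
  expect_false(identical(s1$theta, s3$theta))
})

test_that("full-batch SGD on a convex problem decreases the loss monotonically", {
  center <- make_linear_centers(c(20), p = 3, seed = 17)[[1]]
  m <- linear_model(3)
  cfg <- strategy_config("CB", rounds = 30, local_epochs = 1,
                         batch_size = Inf, optimizer = "sgd", lr = 0.02,
                         weight_decay = 0)
  st <- run_center_based(center, m, cfg, seed = 1)
  losses <- st$history$loss
  expect_true(all(diff(losses) <= 1e-12))
})
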