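# Federated training engine: the four strategies of the study design.
#
#   CB    centre-based     - each silo trains alone on its own data.
#   CZ    centralized      - all data pooled on one server.
#   FL-PL parallel FL      - per round, broadcast the global parameters, train
#                            locally at every centre, then aggregate with
#                            FedAvg weights N_k / N (either averaging the
#                            returned parameters, or applying one exact
#                            weighted-gradient step).
#   FL-SQ sequential FL    - the parameters travel centre-after-centre, each
#                            centre training locally before passing them on;
#                            no aggregation step.
#
# All strategies share one optimizer recipe (default Adam, lr 1e-3, weight
# decay 1e-4 as an L2 penalty, L2 loss) and operate on flat parameter vectors,
# so they are model-agnostic (see u2net_model(), linear_model()).

#' Construct a local (single-centre) training dataset
#'
#' @param center_id label of the silo.
#' @param X,Y lists of paired inputs/targets (normalized NAC / ASC slices for
#'   the imaging model; numeric rows for toy models).
#' @return a `local_dataset`.
#' @export
local_dataset <- function(center_id, X, Y) {
  stopifnot(length(X) == length(Y), length(X) > 0)
  structure(list(center_id = as.character(center_id), X = X, Y = Y,
                 n = length(X)), class = "local_dataset")
}

#' Training-strategy configuration
#'
#' @param strategy one of `"CB"`, `"CZ"`, `"FL_PL"`, `"FL_SQ"`.
#' @param rounds number of communication rounds R (for CB/CZ: the schedule is
#'   `rounds * local_epochs` plain epochs, evaluated every `local_epochs`).
#' @param local_epochs local epochs E per round.
#' @param batch_size mini-batch size; `Inf` for full batch.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lr learning rate (default 0.001).
#' @param weight_decay L2 penalty coefficient (default 0.0001).
#' @param aggregation_mode `"parameter_average"` (FedAvg) or `"gradient"`
#'   (exact weighted-gradient server step; requires `local_epochs = 1` and
#'   full-batch local gradients so the aggregation identity is exact).
#' @param shuffle_centers logical; reshuffle the FL-SQ centre order each round.
#' @param sq_carry_optimizer logical (FL-SQ only): hand the optimizer state to
#'   the next centre together with the parameters (default), making the chain
#'   one continuous optimisation run; `FALSE` keeps moments centre-local, in
#'   which case each centre's stale moments meet a parameter vector that has
#'   since travelled through every other silo, which destabilises short
#'   schedules.
#' @return a `strategy_config`.
#' @export
strategy_config <- function(strategy = c("FL_PL", "FL_SQ", "CB", "CZ"),
                            rounds = 10L, local_epochs = 1L, batch_size = 8L,
                            optimizer = c("adam", "sgd"), lr = 0.001,
                            weight_decay = 0.0001,
                            aggregation_mode = c("parameter_average", "gradient"),
                            shuffle_centers = FALSE,
                            sq_carry_optimizer = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(rounds >= 1, local_epochs >= 1, lr >= 0, weight_decay >= 0)
  structure(list(strategy = strategy, rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 batch_size = batch_size, optimizer = match.arg(optimizer),
                 lr = lr, weight_decay = weight_decay,
                 aggregation_mode = match.arg(aggregation_mode),
                 shuffle_centers = isTRUE(shuffle_centers),
                 sq_carry_optimizer = isTRUE(sq_carry_optimizer)),
            class = "strategy_config")
}

# Mini-batch training for `epochs` epochs starting at `epoch_offset` (used to
# derive per-epoch shuffling seeds, so schedules that split the same total
# number of epochs differently stay sample-for-sample aligned).
train_epochs <- function(theta, dataset, cfg, model, seed, opt_state,
                         epoch_offset, epochs) {
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    set.seed(derive_seed(seed, dataset$center_id, epoch_offset + e))
    ord <- if (is.finite(cfg$batch_size) && cfg$batch_size < dataset$n)
      sample(dataset$n) else seq_len(dataset$n)
    bs <- if (is.finite(cfg$batch_size)) min(cfg$batch_size, dataset$n)
    else dataset$n
    starts <- seq(1, dataset$n, by = bs)
    eloss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1, dataset$n)]
      lg <- model$loss_grad(theta, dataset$X[idx], dataset$Y[idx])
      g <- lg$grad + cfg$weight_decay * theta
      st <- opt_step(theta, g, opt_state, cfg$lr)
      theta <- st$theta; opt_state <- st$state
      eloss <- eloss + lg$loss * length(idx)
    }
    losses[e] <- eloss / dataset$n
  }
  list(theta = theta, opt_state = opt_state, losses = losses)
}

#' Run one local update for a centre
#'
#' In `"gradient"` aggregation mode (requiring `local_epochs = 1` and a full
#' batch, so that the exact weighted-gradient aggregation identity holds) the
#' payload is the local full-batch gradient of
#' `F_k(theta) = mean_i L(theta; (X_i, Y_i))` (plus the L2 penalty term)
#' evaluated at the broadcast parameters. Otherwise the centre runs
#' `local_epochs` epochs of mini-batch optimisation from the broadcast
#' parameters and the payload is the updated parameter vector.
#'
#' @param theta flat parameter vector broadcast by the server.
#' @param dataset a [local_dataset()].
#' @param cfg a [strategy_config()].
#' @param model a `fed_model`.
#' @param seed integer; all shuffling derives from it deterministically.
#' @param opt_state optimizer state kept at the centre between rounds
#'   (`NULL` to initialise).
#' @param epoch_offset cumulative local epochs already run at this centre.
#' @return a `local_update` with fields `center_id`, `n`, `mode`, `payload`,
#'   `local_loss_history`, `opt_state`.
#' @export
local_update <- function(theta, dataset, cfg, model, seed,
                         opt_state = NULL, epoch_offset = 0L) {
  if (cfg$aggregation_mode == "gradient") {
    if (cfg$local_epochs != 1L ||
        (is.finite(cfg$batch_size) && cfg$batch_size < dataset$n))
      stop("gradient aggregation mode requires local_epochs = 1 and a full ",
           "batch: the exact weighted-gradient identity does not hold for ",
           "multi-step local updates")
    lg <- model$loss_grad(theta, dataset$X, dataset$Y)
    return(structure(list(center_id = dataset$center_id, n = dataset$n,
                          mode = "gradient",
                          payload = lg$grad + cfg$weight_decay * theta,
                          local_loss_history = lg$loss, opt_state = opt_state),
                     class = "local_update"))
  }
  if (is.null(opt_state)) opt_state <- opt_init(cfg$optimizer, length(theta))
  tr <- train_epochs(theta, dataset, cfg, model, seed, opt_state,
                     epoch_offset, cfg$local_epochs)
  structure(list(center_id = dataset$center_id, n = dataset$n,
                 mode = "parameter", payload = tr$theta,
                 local_loss_history = tr$losses, opt_state = tr$opt_state),
            class = "local_update")
}

#' Server-side aggregation
#'
#' Gradient mode applies one exact weighted-gradient step
#' `theta - lr * sum_k (N_k / N) grad F_k(theta)`; parameter-average mode
#' returns the FedAvg weighted mean `sum_k (N_k / N) theta_k`. The two
#' coincide (to floating point) when every centre took a single full-batch
#' SGD step at learning rate `lr`.
#'
#' @param updates list of `local_update`s (conformable payloads).
#' @param theta current global parameter vector.
#' @param lr server learning rate (gradient mode only).
#' @return aggregated flat parameter vector.
#' @export
aggregate_updates <- function(updates, theta, lr) {
  stopifnot(length(updates) >= 1)
  N <- sum(vapply(updates, function(u) u$n, 0))
  stopifnot(N > 0)
  w <- vapply(updates, function(u) u$n / N, 0)
  stopifnot(abs(sum(w) - 1) < 1e-12)
  lens <- vapply(updates, function(u) length(u$payload), 0L)
  if (any(lens != length(theta)))
    stop("non-conformable parameter vectors in aggregation")
  modes <- unique(vapply(updates, function(u) u$mode, ""))
  stopifnot(length(modes) == 1)
  acc <- numeric(length(theta))
  for (k in seq_along(updates)) acc <- acc + w[k] * updates[[k]]$payload
  if (modes == "gradient") theta - lr * acc else acc
}

new_train_state <- function(strategy) {
  list(strategy = strategy, theta = NULL, best_theta = NULL,
       best_round = NA_integer_, best_val = Inf,
       history = data.frame(round = integer(), center = character(),
                            loss = double(), val_loss = double(),
                            stringsAsFactors = FALSE))
}

record_round <- function(state, round, updates, val_loss) {
  for (u in updates) {
    state$history <- rbind(state$history, data.frame(
      round = round, center = u$center_id,
      loss = mean(u$local_loss_history), val_loss = val_loss,
      stringsAsFactors = FALSE))
  }
  if (!is.na(val_loss) && val_loss < state$best_val) {
    state$best_val <- val_loss
    state$best_theta <- state$theta
    state$best_round <- round
  }
  state
}

val_loss_of <- function(model, theta, validation) {
  if (is.null(validation)) return(NA_real_)
  model$loss_grad(theta, validation$X, validation$Y)$loss
}

#' Parallel federated training (FL-PL)
#'
#' Per round: broadcast the global parameters to every centre, run a
#' [local_update()] at each, then aggregate with FedAvg weights N_k / N.
#' Optimizer moments stay at the centres; only parameter vectors (or exact
#' gradients) are exchanged.
#'
#' @param centers list of [local_dataset()] (>= 2).
#' @param model a `fed_model`.
#' @param cfg a [strategy_config()].
#' @param seed master seed; the whole run is a pure function of
#'   `(centers, cfg, seed)`.
#' @param validation optional list `(X, Y)` used to track the best round.
#' @return a train-state list: final `theta`, `best_theta` (lowest validation
#'   loss, when validation data are given), and a per-round/per-centre
#'   `history` data frame.
#' @export
run_fl_parallel <- function(centers, model, cfg, seed = 1L, validation = NULL) {
  stopifnot(length(centers) >= 2)
  check_centers(centers)
  theta <- model$init(derive_seed(seed, "init"))
  opt <- rep(list(NULL), length(centers))
  st <- new_train_state("FL_PL")
  for (t in seq_len(cfg$rounds)) {
    updates <- vector("list", length(centers))
    for (k in seq_along(centers)) {
      updates[[k]] <- local_update(theta, centers[[k]], cfg, model, seed,
                                   opt_state = opt[[k]],
                                   epoch_offset = (t - 1L) * cfg$local_epochs)
      opt[k] <- list(updates[[k]]$opt_state)   # may be NULL in gradient mode
    }
    theta <- aggregate_updates(updates, theta, cfg$lr)
    st$theta <- theta
    st <- record_round(st, t, updates, val_loss_of(model, theta, validation))
  }
  if (is.null(st$best_theta)) st$best_theta <- st$theta
  st
}

#' Sequential federated training (FL-SQ)
#'
#' The parameters visit the centres serially: each centre trains for
#' `local_epochs` epochs and hands the result to the next centre; a round is
#' one full pass, and there is no aggregation step. With a single centre this
#' degenerates exactly to centre-based training for `rounds * local_epochs`
#' epochs.
#'
#' @inheritParams run_fl_parallel
#' @return a train-state list (see [run_fl_parallel()]).
#' @export
run_fl_sequential <- function(centers, model, cfg, seed = 1L, validation = NULL) {
  check_centers(centers)
  theta <- model$init(derive_seed(seed, "init"))
  carry <- isTRUE(cfg$sq_carry_optimizer)
  opt <- rep(list(NULL), length(centers))
  opt_chain <- NULL
  st <- new_train_state("FL_SQ")
  order0 <- seq_along(centers)
  for (t in seq_len(cfg$rounds)) {
    ord <- order0
    if (cfg$shuffle_centers) {
      set.seed(derive_seed(seed, "order", t))
      ord <- sample(order0)
    }
    updates <- list()
    for (k in ord) {
      u <- local_update(theta, centers[[k]], cfg, model, seed,
                        opt_state = if (carry) opt_chain else opt[[k]],
                        epoch_offset = (t - 1L) * cfg$local_epochs)
      if (u$mode == "gradient")
        stop("FL_SQ has no aggregation step; use parameter mode")
      theta <- u$payload
      if (carry) opt_chain <- u$opt_state else opt[[k]] <- u$opt_state
      updates[[length(updates) + 1L]] <- u
    }
    st$theta <- theta
    st <- record_round(st, t, updates, val_loss_of(model, theta, validation))
  }
  if (is.null(st$best_theta)) st$best_theta <- st$theta
  st
}

#' Centralized (CZ) and centre-based (CB) baselines
#'
#' `run_centralized()` pools all samples onto one server and trains with the
#' shared optimizer recipe; `run_center_based()` trains on a single centre's
#' data only. Both run `rounds * local_epochs` epochs, logging every
#' `local_epochs` epochs so their histories line up with the federated runs.
#'
#' @inheritParams run_fl_parallel
#' @return a train-state list (see [run_fl_parallel()]).
#' @export
run_centralized <- function(centers, model, cfg, seed = 1L, validation = NULL) {
  check_centers(centers)
  pooled <- local_dataset("pooled",
                          do.call(c, lapply(centers, function(d) d$X)),
                          do.call(c, lapply(centers, function(d) d$Y)))
  run_single_site(pooled, model, cfg, seed, validation, strategy = "CZ")
}

#' @rdname run_centralized
#' @param center a single [local_dataset()].
#' @export
run_center_based <- function(center, model, cfg, seed = 1L, validation = NULL) {
  run_single_site(center, model, cfg, seed, validation, strategy = "CB")
}

run_single_site <- function(dataset, model, cfg, seed, validation, strategy) {
  stopifnot(inherits(dataset, "local_dataset"), dataset$n > 0)
  theta <- model$init(derive_seed(seed, "init"))
  opt <- opt_init(cfg$optimizer, length(theta))
  st <- new_train_state(strategy)
  for (t in seq_len(cfg$rounds)) {
    tr <- train_epochs(theta, dataset, cfg, model, seed, opt,
                       epoch_offset = (t - 1L) * cfg$local_epochs,
                       epochs = cfg$local_epochs)
    theta <- tr$theta; opt <- tr$opt_state
    st$theta <- theta
    u <- list(center_id = dataset$center_id, n = dataset$n,
              local_loss_history = tr$losses)
    st <- record_round(st, t, list(u), val_loss_of(model, theta, validation))
  }
  if (is.null(st$best_theta)) st$best_theta <- st$theta
  st
}

check_centers <- function(centers) {
  for (d in centers) {
    stopifnot(inherits(d, "local_dataset"))
    if (d$n < 1) stop("centre ", d$center_id, " has no training samples")
  }
  invisible(TRUE)
}

#' Dispatch a training strategy by name
#'
#' @param strategy `"CB"`, `"CZ"`, `"FL_PL"` or `"FL_SQ"`.
#' @param centers list of [local_dataset()]; CB uses only the first.
#' @inheritParams run_fl_parallel
#' @return a train-state list.
#' @export
run_strategy <- function(strategy, centers, model, cfg, seed = 1L,
                         validation = NULL) {
  switch(strategy,
         CB = run_center_based(centers[[1]], model, cfg, seed, validation),
         CZ = run_centralized(centers, model, cfg, seed, validation),
         FL_PL = run_fl_parallel(centers, model, cfg, seed, validation),
         FL_SQ = run_fl_sequential(centers, model, cfg, seed, validation),
         stop("unknown strategy: ", strategy))
}
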