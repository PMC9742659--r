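# Optimisers over flat parameter vectors. Adam follows Kingma & Ba with
# bias-corrected moments; weight decay is implemented as an L2 penalty added
# to the loss gradient (lambda * theta), not as decoupled decay.

opt_init <- function(optimizer = c("adam", "sgd"), n) {
  optimizer <- match.arg(optimizer)
  if (optimizer == "adam")
    list(kind = "adam", m = numeric(n), v = numeric(n), t = 0L)
  else
    list(kind = "sgd")
}

# One update from gradient g; returns list(theta, state).
opt_step <- function(theta, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  if (state$kind == "adam") {
    state$t <- state$t + 1L
    state$m <- beta1 * state$m + (1 - beta1) * g
    state$v <- beta2 * state$v + (1 - beta2) * g^2
    mhat <- state$m / (1 - beta1^state$t)
    vhat <- state$v / (1 - beta2^state$t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  } else {
    theta <- theta - lr * g
  }
  list(theta = theta, state = state)
}
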