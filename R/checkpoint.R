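# Checkpoints: a text (JSON) parameter store keyed by the stable parameter
# names, stamped with a config signature so that parameters are only ever
# loaded into the architecture they came from.

# Order-sensitive polynomial rolling signature of the config schema.
config_signature <- function(cfg) {
  desc <- paste(vapply(names(cfg$schema), function(nmi) {
    p <- cfg$schema[[nmi]]
    paste(nmi, p$kh, p$kw, p$cin, p$cout, p$dil, sep = ":")
  }, ""), collapse = "|")
  h <- 17
  for (b in utf8ToInt(desc)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Save / load network checkpoints
#'
#' `save_checkpoint()` writes the flat parameter vector together with the
#' per-block names and shapes and a signature of the network config;
#' `load_checkpoint()` refuses to load a checkpoint whose signature does not
#' match the supplied config, so parameters trained under one strategy can be
#' exchanged or re-evaluated under another only when the architectures are
#' identical.
#'
#' @param theta_v flat parameter vector (see [flatten_params()]).
#' @param cfg the matching [u2net_config()].
#' @param path output JSON file.
#' @return `save_checkpoint()`: the path, invisibly. `load_checkpoint()`: the
#'   flat parameter vector.
#' @export
save_checkpoint <- function(theta_v, cfg, path) {
  stopifnot(length(theta_v) == u2net_n_params(cfg))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(signature = config_signature(cfg),
         n_params = length(theta_v),
         blocks = names(cfg$schema),
         theta = theta_v),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, cfg) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ck$signature, config_signature(cfg)))
    stop("checkpoint was written for a different network config (signature ",
         ck$signature, " != ", config_signature(cfg), ")")
  stopifnot(ck$n_params == u2net_n_params(cfg))
  as.numeric(ck$theta)
}
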