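#' Training configuration
#'
#' Validated container for every knob of the training harness. Weight decay
#' follows a two-phase schedule: `wd_initial` for the first
#' `wd_switch_epoch` epochs, `wd_main` afterwards (a large initial decay
#' washes out the influence of the weight initializations, which is what
#' lets the forward weights align with the feedback pathway). Decay is
#' applied multiplicatively per minibatch step.
#'
#' @param algorithm One of `"bp"`, `"fa"`, `"dfa"`, `"sf"`, `"kp"`, `"pfa"`,
#'   `"pfa_o"`.
#' @param epochs,batch_size Training length and minibatch size.
#' @param lr Learning rate for `W`/`b` (> 0).
#' @param lr_r Learning rate for the plastic feedback `R`; defaults to `lr`
#'   (the update rules use a single rate).
#' @param wd_initial,wd_main,wd_switch_epoch Two-phase weight-decay schedule
#'   (coefficients in `[0, 1)`), shared by `W` and `R`.
#' @param expansion_ratio Intermediate-population expansion `1/lambda`
#'   (default 10).
#' @param sparsity Fraction of feedback entries fixed to zero.
#' @param r_init `"random"` or `"matched"` (see [init_feedback()]).
#' @param seed Master seed; spawns named substreams for initialization, data
#'   order and masks so runs are bit-reproducible.
#' @param hidden Hidden-layer sizes used when the harness builds an MLP
#'   itself.
#' @param activation Hidden activation for harness-built networks.
#' @return A validated list of class `train_config`.
#' @export
train_config <- function(algorithm = "bp", epochs = 10, batch_size = 32,
                         lr = 0.1, lr_r = NULL, wd_initial = 1e-3,
                         wd_main = 1e-4, wd_switch_epoch = 5,
                         expansion_ratio = 10, sparsity = 0,
                         r_init = "random", seed = 1,
                         hidden = c(64, 64), activation = "relu") {
  algorithm <- match.arg(algorithm, .algorithms)
  lr_r <- lr_r %||% lr
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, lr_r >= 0,
            wd_initial >= 0, wd_initial < 1, wd_main >= 0, wd_main < 1,
            wd_switch_epoch >= 0, expansion_ratio >= 1,
            sparsity >= 0, sparsity < 1)
  r_init <- match.arg(r_init, c("random", "matched"))
  check_activation(activation)
  structure(list(algorithm = algorithm, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, lr_r = lr_r,
                 wd_initial = wd_initial, wd_main = wd_main,
                 wd_switch_epoch = as.integer(wd_switch_epoch),
                 expansion_ratio = expansion_ratio, sparsity = sparsity,
                 r_init = r_init, seed = as.integer(seed),
                 hidden = as.integer(hidden), activation = activation),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat("<train_config ", x$algorithm, ": ", x$epochs, " epochs, batch ",
      x$batch_size, ", lr ", x$lr, ", wd ", x$wd_initial, "/", x$wd_main,
      " (switch ", x$wd_switch_epoch, "), ratio ", x$expansion_ratio,
      ", sparsity ", x$sparsity, ", seed ", x$seed, ">\n", sep = "")
  invisible(x)
}

#' Read a training configuration from a YAML file
#'
#' Flat key-value schema with the same names and defaults as
#' [train_config()]; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `train_config`.
#' @export
read_train_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(train_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(train_config, vals)
}

# Named substream seeds derived from the master seed, kept below 2^31 so
# they are valid R integer seeds.
substream_seed <- function(seed, stream) {
  offs <- c(init = 1L, feedback = 2L, data = 3L, mask = 4L, eval = 5L)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 48271 + offs[[stream]] * 7919) %% 2147483647)
}
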