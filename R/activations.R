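# Activation functions and their derivatives, evaluated at the cached
# preactivation. The ReLU subgradient at exactly 0 is fixed to 0 so that
# exact-reduction tests are well defined.

.activations <- c("relu", "identity", "tanh")

act_fun <- function(name) {
  switch(name,
    relu     = function(z) pmax(z, 0),
    identity = function(z) z,
    tanh     = function(z) tanh(z),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

act_deriv <- function(name) {
  switch(name,
    relu     = function(z) (z > 0) * 1,
    identity = function(z) array(1, dim = dim(z) %||% length(z)),
    tanh     = function(z) 1 - tanh(z)^2,
    stop("unknown activation: ", name, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_activation <- function(activation) {
  if (!activation %in% .activations) {
    stop("activation must be one of ", paste(.activations, collapse = ", "),
         ", got '", activation, "'", call. = FALSE)
  }
  activation
}
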