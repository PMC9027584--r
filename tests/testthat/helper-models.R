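# Toy models implementing the minimal model interface (params + loss_grad),
# used to exercise the optimizer and range test without CNN overhead.

# d-dimensional quadratic bowl J(theta) = 0.5 * sum(theta^2); gradient theta.
quad_model <- function(theta0) {
  m <- list(kind = "quad", params = list(layer = list(W = theta0)))
  m$loss_grad <- function(params, batch)
    list(loss = 0.5 * sum(params$layer$W^2),
         grads = list(layer = list(W = params$layer$W)))
  m
}

# Loss independent of parameters: flat sweep curve, zero gradients.
const_model <- function(theta0 = 1, value = 1) {
  m <- list(kind = "const", params = list(layer = list(W = theta0)))
  m$loss_grad <- function(params, batch)
    list(loss = value, grads = list(layer = list(W = params$layer$W * 0)))
  m
}

# Gradients of fixed huge magnitude, to trip the loss-scaling overflow guard.
exploding_model <- function(theta0 = 1, magnitude = 1e6) {
  m <- list(kind = "boom", params = list(layer = list(W = theta0)))
  m$loss_grad <- function(params, batch)
    list(loss = 1, grads = list(layer = list(W = rep(magnitude, length(params$layer$W)))))
  m
}

# Small class-separable dataset used by trainer tests (cheap: 32x32).
tiny_dataset <- function(n = 150, K = 3, side = 32, seed = 42)
  generate_synthetic(synthetic_spec(K, n, side = side,
                                    signal_strength = 0.95, seed = seed))
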