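# Discriminative fine-tuning schedule: per-layer, per-iteration learning
# rates and momenta following a triangular law, plus the momentum-velocity
# parameter update they drive.

#' Learning-rate and momentum bounds
#'
#' Container for the selected learning-rate range \eqn{[\alpha_{min},
#' \alpha_{max}]} and momentum range \eqn{[m_{min}, m_{max}]} that feed the
#' discriminative fine-tuning schedule. The rate bounds typically come from
#' [select_bounds()] after a range-test sweep; the momentum bounds default to
#' the conventional 0.85--0.95 band.
#'
#' @param alpha_min minimum learning rate, > 0.
#' @param alpha_max maximum learning rate, > `alpha_min`.
#' @param m_min minimum momentum, in \[0, 1).
#' @param m_max maximum momentum, in \[`m_min`, 1).
#' @return an object of class `lr_bounds`.
#' @examples
#' lr_bounds(1e-4, 1e-2)
#' @export
lr_bounds <- function(alpha_min, alpha_max, m_min = 0.85, m_max = 0.95) {
  check_scalar_num(alpha_min, "alpha_min")
  check_scalar_num(alpha_max, "alpha_max")
  check_scalar_num(m_min, "m_min")
  check_scalar_num(m_max, "m_max")
  if (alpha_min <= 0) abort_param("`alpha_min` must be > 0")
  if (alpha_max <= alpha_min) abort_param("`alpha_max` must exceed `alpha_min`")
  if (m_min < 0 || m_max < m_min || m_max >= 1)
    abort_param("momentum bounds must satisfy 0 <= m_min <= m_max < 1")
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max,
                 m_min = m_min, m_max = m_max), class = "lr_bounds")
}

#' @export
print.lr_bounds <- function(x, ...) {
  cat(sprintf("<lr_bounds> alpha: [%g, %g]  momentum: [%g, %g]\n",
              x$alpha_min, x$alpha_max, x$m_min, x$m_max))
  invisible(x)
}

#' Iteration budget and phase split of a triangular schedule
#'
#' @param t_max total number of optimizer iterations in the run
#'   (dataset size / batch size x epochs), >= 2.
#' @param l_max number of layer groups, >= 1.
#' @param kappa phase-split fraction in (0, 1): the learning-rate factor rises
#'   for the first `kappa` fraction of iterations and falls for the rest.
#' @return an object of class `phase_plan`.
#' @export
phase_plan <- function(t_max, l_max, kappa = 0.5) {
  check_scalar_num(t_max, "t_max")
  check_scalar_num(l_max, "l_max")
  check_scalar_num(kappa, "kappa")
  if (t_max < 2 || t_max != round(t_max)) abort_param("`t_max` must be an integer >= 2")
  if (l_max < 1 || l_max != round(l_max)) abort_param("`l_max` must be an integer >= 1")
  if (kappa <= 0 || kappa >= 1) abort_param("`kappa` must lie strictly in (0, 1)")
  structure(list(t_max = as.integer(t_max), l_max = as.integer(l_max),
                 kappa = kappa), class = "phase_plan")
}

#' Base learning rate of a layer group
#'
#' Distributes the selected learning-rate range across layer groups by linear
#' interpolation: the earliest group (index 0), which holds the most generic
#' pretrained features, gets `alpha_min`; the latest group (the classifier
#' head) gets `alpha_max`.
#'
#' @param l layer-group index, 0-based, in \[0, `l_max`).
#' @param l_max number of layer groups.
#' @param bounds an [lr_bounds()] object.
#' @return the base learning rate of group `l`.
#' @examples
#' b <- lr_bounds(1e-4, 1e-2)
#' layer_base_rate(0, 10, b)  # 1e-4
#' layer_base_rate(9, 10, b)  # 1e-2
#' @export
layer_base_rate <- function(l, l_max, bounds) {
  stopifnot(inherits(bounds, "lr_bounds"))
  if (any(l < 0 | l >= l_max)) abort_input("layer index `l` out of [0, l_max)")
  if (l_max == 1L) return(rep(bounds$alpha_max, length(l)))
  bounds$alpha_min + (bounds$alpha_max - bounds$alpha_min) * l / (l_max - 1)
}

#' Base momentum of a layer group
#'
#' In the rising phase momentum interpolates `m_min` to `m_max` across layer
#' groups; in the falling phase the direction is mirrored (`m_max` down to
#' `m_min`), matching the sign flip between the two phases of the underlying
#' algorithm. Set `invert_momentum = TRUE` on [build_schedule()] for the
#' common practice of cycling momentum opposite to the learning rate.
#'
#' @inheritParams layer_base_rate
#' @param phase `"rising"` or `"falling"`.
#' @return the momentum of group `l` during `phase`.
#' @export
layer_base_momentum <- function(l, l_max, bounds, phase = c("rising", "falling")) {
  stopifnot(inherits(bounds, "lr_bounds"))
  phase <- match.arg(phase)
  if (any(l < 0 | l >= l_max)) abort_input("layer index `l` out of [0, l_max)")
  frac <- if (l_max == 1L) rep(1, length(l)) else l / (l_max - 1)
  span <- bounds$m_max - bounds$m_min
  if (phase == "rising") bounds$m_min + span * frac
  else bounds$m_max - span * frac
}

#' Triangular iteration factor
#'
#' Piecewise-linear factor in \[0, 1\]: rises 0 to 1 over iterations
#' \[0, `kappa * t_max`), falls back towards 0 over the remainder. The
#' effective rate of layer `l` at iteration `t` is
#' `alpha_min + iteration_factor(t, plan) * (layer_base_rate(l) - alpha_min)`,
#' so the factor scales the spread above `alpha_min` and no layer is ever
#' frozen mid-run.
#'
#' @param t iteration index, 0-based, in \[0, `t_max`).
#' @param plan a [phase_plan()].
#' @return scale factor(s) in \[0, 1\].
#' @export
iteration_factor <- function(t, plan) {
  stopifnot(inherits(plan, "phase_plan"))
  if (any(t < 0 | t >= plan$t_max)) abort_input("iteration `t` out of [0, t_max)")
  peak <- plan$kappa * plan$t_max
  ifelse(t < peak, t / peak, (plan$t_max - t) / (plan$t_max - peak))
}

#' One discriminative fine-tuning parameter update
#'
#' Classical momentum ("heavy-ball") update applied to one layer group with
#' that group's current learning rate and momentum:
#' \deqn{v' = m v - \alpha g, \qquad \theta' = \theta + v'.}
#' With `momentum = 0` this reduces to plain stochastic gradient descent
#' \eqn{\theta' = \theta - \alpha g}. The function is pure: it returns an
#' updated copy of `state` and touches no hidden state.
#'
#' @param state a [layer_optim_state()].
#' @param gradient numeric array, same shape as `state$parameters`.
#' @return the updated `layer_optim_state`.
#' @export
dft_update <- function(state, gradient) {
  stopifnot(inherits(state, "layer_optim_state"))
  if (length(gradient) != length(state$parameters) ||
      !identical(dim(gradient), dim(state$parameters)))
    abort_contract("gradient shape must equal parameter shape")
  v <- state$momentum * state$velocity - state$alpha * gradient
  state$velocity <- v
  state$parameters <- state$parameters + v
  state
}

#' Per-layer optimizer state
#'
#' @param parameters numeric array of the layer group's weights.
#' @param velocity numeric array, same shape; defaults to zeros.
#' @param alpha current learning rate of the group.
#' @param momentum current momentum of the group.
#' @param layer_index 0-based group index (bookkeeping only).
#' @return an object of class `layer_optim_state`.
#' @export
layer_optim_state <- function(parameters, velocity = NULL, alpha, momentum,
                              layer_index = 0L) {
  if (is.null(velocity)) {
    velocity <- parameters * 0
  }
  if (length(velocity) != length(parameters) ||
      !identical(dim(velocity), dim(parameters)))
    abort_contract("velocity shape must equal parameter shape")
  check_scalar_num(alpha, "alpha")
  check_scalar_num(momentum, "momentum")
  structure(list(layer_index = as.integer(layer_index), parameters = parameters,
                 velocity = velocity, alpha = alpha, momentum = momentum),
            class = "layer_optim_state")
}

#' Build the full (iteration x layer) schedule table
#'
#' Expands a [phase_plan()] and [lr_bounds()] into the complete schedule: one
#' row per (iteration, layer-group) pair carrying that pair's learning rate
#' and momentum. Rates follow a triangular law over iterations (peak at the
#' phase boundary `kappa * t_max`) and increase linearly with layer index at
#' any fixed iteration; momenta interpolate across layers with the direction
#' flipping between the rising and falling phase.
#'
#' @param plan a [phase_plan()].
#' @param bounds an [lr_bounds()].
#' @param invert_momentum if `TRUE`, swap the rising/falling momentum
#'   directions (momentum cycles opposite to the learning rate).
#' @return a `data.frame` with columns `t`, `layer`, `alpha`, `momentum`
#'   (`t_max * l_max` rows, iteration-major).
#' @examples
#' s <- build_schedule(phase_plan(10, 3), lr_bounds(1e-3, 1e-2))
#' head(s)
#' @export
build_schedule <- function(plan, bounds, invert_momentum = FALSE) {
  stopifnot(inherits(plan, "phase_plan"), inherits(bounds, "lr_bounds"))
  t <- rep(seq_len(plan$t_max) - 1L, each = plan$l_max)
  l <- rep(seq_len(plan$l_max) - 1L, times = plan$t_max)
  base <- layer_base_rate(l, plan$l_max, bounds)
  fac <- iteration_factor(t, plan)
  alpha <- bounds$alpha_min + fac * (base - bounds$alpha_min)
  rising <- t < plan$kappa * plan$t_max
  if (invert_momentum) rising <- !rising
  momentum <- ifelse(rising,
                     layer_base_momentum(l, plan$l_max, bounds, "rising"),
                     layer_base_momentum(l, plan$l_max, bounds, "falling"))
  data.frame(t = t, layer = l, alpha = alpha, momentum = momentum)
}

#' Write a schedule table to a plain-text file
#'
#' Tab-separated dump of the (t, layer, alpha, momentum) table for
#' inspection or plotting.
#'
#' @param schedule a table from [build_schedule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
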