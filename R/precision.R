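# Software-emulated mixed-precision training. The contract: forward/backward
# run at reduced (IEEE binary16) precision on rounded weights, the loss is
# multiplied by a scale factor before backpropagation so small gradients
# survive fp16 quantization, gradients are unscaled in full precision before
# the update, and a full-precision master copy of the weights receives all
# updates. Non-finite scaled gradients trigger a skip-step with scale
# back-off instead of corrupting the weights.

#' Round to IEEE binary16 (half) precision
#'
#' Emulates fp16 storage: 10 significand bits with round-to-nearest-even,
#' subnormals below 2^-14 with a 2^-24 quantum, overflow beyond 65504 to
#' infinity. Vectorized; NA/NaN/Inf propagate.
#'
#' @param x numeric vector/array.
#' @return `x` rounded to the nearest representable half-precision value.
#' @export
fp16_round <- function(x) {
  out <- x
  fin <- is.finite(x) & x != 0
  if (any(fin)) {
    a <- abs(x[fin])
    e <- pmin(pmax(floor(log2(a)), -14), 15)
    q <- 2^(e - 10)
    r <- round(a / q) * q          # round() is round-half-to-even
    r[r > 65504] <- Inf
    out[fin] <- sign(x[fin]) * r
  }
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

round_params_fp16 <- function(params)
  lapply(params, function(g) lapply(g, fp16_round))

#' One mixed-precision gradient computation
#'
#' Computes the loss and gradients with fp16-rounded weights, scales the
#' loss (hence the gradients) by `loss_scale`, quantizes the scaled
#' gradients to fp16, and unscales them in full precision — the gradients a
#' DFT update would consume. If any scaled gradient is non-finite the step
#' is skipped (`skipped = TRUE`, no gradients returned) and a halved
#' back-off scale is suggested. With `emulate_fp16 = FALSE` and
#' `loss_scale = 1` the result is bit-identical to the plain full-precision
#' gradient.
#'
#' @param model a model object (see [small_cnn()]).
#' @param params full-precision master parameters.
#' @param batch a batch accepted by `model$loss_grad`.
#' @param loss_scale positive scale factor (default 1024).
#' @param emulate_fp16 if `TRUE` (default), round weights and scaled
#'   gradients to binary16.
#' @return list with `loss`, `grads` (unscaled, full precision; `NULL` when
#'   skipped), `skipped`, and `next_scale` (halved after a skip, unchanged
#'   otherwise).
#' @export
mixed_precision_step <- function(model, params, batch, loss_scale = 1024,
                                 emulate_fp16 = TRUE) {
  check_scalar_num(loss_scale, "loss_scale")
  if (loss_scale <= 0) abort_param("`loss_scale` must be > 0")
  p16 <- if (emulate_fp16) round_params_fp16(params) else params
  lg <- model$loss_grad(p16, batch)
  scaled <- lapply(lg$grads, function(g) lapply(g, function(a) {
    s <- a * loss_scale
    if (emulate_fp16) fp16_round(s) else s
  }))
  finite <- all(vapply(unlist(scaled, recursive = FALSE),
                       function(a) all(is.finite(a)), logical(1)))
  if (!finite)
    return(list(loss = lg$loss, grads = NULL, skipped = TRUE,
                next_scale = loss_scale / 2))
  grads <- lapply(scaled, function(g) lapply(g, function(a) a / loss_scale))
  list(loss = lg$loss, grads = grads, skipped = FALSE, next_scale = loss_scale,
       preds = lg$preds)
}
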