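# Learning-rate range test: a single-epoch sweep in which the learning rate
# grows at every iteration while the (smoothed) loss is recorded; the bounds
# fed to the DFT schedule are then taken where the loss falls fastest.

#' Specification of a range-test sweep
#'
#' @param lr_start first learning rate, > 0.
#' @param lr_end last learning rate, > `lr_start`.
#' @param num_steps number of optimizer steps (= rates tried), >= 10.
#' @param spacing `"geometric"` (default; equal ratios) or `"linear"`.
#' @param smoothing exponential-moving-average weight in \[0, 1) applied to
#'   the recorded losses; single-batch losses are too noisy for slope
#'   estimation, so smoothed values drive both the divergence guard and
#'   [select_bounds()]. Default 0.98.
#' @param momentum momentum used for the sweep's optimizer steps, in
#'   \[0, 1). The sweep must probe the dynamics the selected rates will be
#'   used under: momentum inflates the effective step by roughly
#'   `1 / (1 - m)`, so a momentum-free sweep would select rates that
#'   destabilize momentum training. Default 0.9, the midpoint of the default
#'   momentum band.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(lr_start, lr_end, num_steps = 100L,
                       spacing = c("geometric", "linear"), smoothing = 0.98,
                       momentum = 0.9) {
  check_scalar_num(lr_start, "lr_start"); check_scalar_num(lr_end, "lr_end")
  check_scalar_num(num_steps, "num_steps"); check_scalar_num(smoothing, "smoothing")
  check_scalar_num(momentum, "momentum")
  spacing <- match.arg(spacing)
  if (lr_start <= 0 || lr_end <= lr_start)
    abort_param("need 0 < lr_start < lr_end")
  if (num_steps < 10) abort_param("`num_steps` must be >= 10")
  if (smoothing < 0 || smoothing >= 1) abort_param("`smoothing` must lie in [0, 1)")
  if (momentum < 0 || momentum >= 1) abort_param("`momentum` must lie in [0, 1)")
  structure(list(lr_start = lr_start, lr_end = lr_end,
                 num_steps = as.integer(num_steps), spacing = spacing,
                 smoothing = smoothing, momentum = momentum),
            class = "sweep_spec")
}

sweep_rates <- function(spec) {
  if (spec$spacing == "geometric")
    exp(seq(log(spec$lr_start), log(spec$lr_end), length.out = spec$num_steps))
  else seq(spec$lr_start, spec$lr_end, length.out = spec$num_steps)
}

#' Run the single-epoch learning-rate sweep
#'
#' Performs one momentum-SGD step per learning rate (momentum from the
#' spec, default 0.9) on consecutive batches (cycling through `batches` as
#' needed), recording the raw loss observed at each rate and its
#' bias-corrected exponential moving average. The sweep
#' aborts early — recording `diverged_at` — once the smoothed loss exceeds
#' 4x its running minimum, so the exploding tail cannot pollute slope
#' estimates. Model weights are restored to their pre-sweep values before
#' returning.
#'
#' @param model a model object (see [small_cnn()] for the interface).
#' @param batches non-empty list of batches accepted by `model$loss_grad`.
#' @param spec a [sweep_spec()].
#' @param seed integer seed (shuffles the batch order).
#' @return an object of class `sweep_curve`: list with `rates`, `losses`
#'   (raw), `smoothed`, and `diverged_at` (index of the aborting step, or
#'   `NULL`).
#' @export
run_sweep <- function(model, batches, spec, seed = 1) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.list(batches) || length(batches) == 0L)
    abort_input("`batches` must be a non-empty list")
  rates <- sweep_rates(spec)
  params <- model$params
  velocity <- lapply(params, function(g) lapply(g, function(a) a * 0))
  order_ <- with_seed(seed, sample.int(length(batches)))
  batches <- batches[order_]
  n_b <- length(batches)
  losses <- smoothed <- numeric(0)
  avg <- 0; best <- Inf; diverged_at <- NULL
  for (i in seq_along(rates)) {
    b <- batches[[((i - 1L) %% n_b) + 1L]]
    lg <- model$loss_grad(params, b)
    losses[i] <- lg$loss
    avg <- spec$smoothing * avg + (1 - spec$smoothing) * lg$loss
    smoothed[i] <- avg / (1 - spec$smoothing^i)  # bias-corrected
    best <- min(best, smoothed[i])
    if (!is.finite(smoothed[i]) || smoothed[i] > 4 * best) {
      diverged_at <- i
      break
    }
    for (g in names(params)) for (a in names(params[[g]])) {
      v <- spec$momentum * velocity[[g]][[a]] - rates[i] * lg$grads[[g]][[a]]
      velocity[[g]][[a]] <- v
      params[[g]][[a]] <- params[[g]][[a]] + v
    }
  }
  k <- length(losses)
  structure(list(rates = rates[seq_len(k)], losses = losses,
                 smoothed = smoothed, diverged_at = diverged_at, spec = spec),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("<sweep_curve> %d points, rates [%g, %g]%s\n",
              length(x$rates), min(x$rates), max(x$rates),
              if (is.null(x$diverged_at)) "" else
                sprintf(", diverged at step %d", x$diverged_at)))
  invisible(x)
}

#' Select learning-rate bounds from a sweep curve
#'
#' Automates the visual "steepest descent" reading of a range-test plot:
#' finds the most negative finite-difference slope of the smoothed loss with
#' respect to log learning rate, takes the rate at that point as
#' `alpha_max` (capped strictly below any divergence point), and sets
#' `alpha_min = alpha_max / 10`.
#'
#' Two robustness guards shape which finite differences are scanned: the
#' first `warmup_frac` of the recorded points (at least 2) are excluded,
#' because the exponential average is still converging there and its ramp-in
#' transient would masquerade as a steep drop; and on longer curves the
#' finite difference spans `window` points (default 5\% of the curve, i.e.
#' consecutive pairs for curves under 20 points) so that one noisy batch
#' cannot dictate the selection. The scan itself is an exhaustive O(n) pass
#' over all candidate pairs.
#'
#' @param curve a [run_sweep()] result with at least 3 finite points.
#' @param m_min,m_max momentum bounds to attach to the result.
#' @param warmup_frac fraction of leading points excluded from the scan.
#' @param window finite-difference span in points; `NULL` for the default.
#' @return an [lr_bounds()] object.
#' @export
select_bounds <- function(curve, m_min = 0.85, m_max = 0.95,
                          warmup_frac = 0.1, window = NULL) {
  stopifnot(inherits(curve, "sweep_curve"))
  keep <- if (is.null(curve$diverged_at)) length(curve$rates)
    else curve$diverged_at - 1L
  r <- curve$rates[seq_len(keep)]
  s <- curve$smoothed[seq_len(keep)]
  if (sum(is.finite(s)) < 3L)
    abort_input("sweep curve needs at least 3 finite points")
  n <- length(s)
  if (is.null(window)) window <- max(1L, ceiling(0.05 * n))
  skip <- min(max(2L, ceiling(warmup_frac * n)), n - window - 1L)
  first <- skip + 1L
  if (first + window > n)
    abort_input("sweep curve too short after the warmup region")
  i_cand <- first:(n - window)
  slopes <- (s[i_cand + window] - s[i_cand]) /
    (log(r[i_cand + window]) - log(r[i_cand]))
  slopes[!is.finite(slopes)] <- Inf
  # a slope must be negative beyond floating-point noise in the EMA to count
  # as descent; otherwise a numerically flat curve would yield random bounds
  noise_floor <- -1e-9 * max(1, max(abs(s[is.finite(s)])))
  if (all(slopes >= noise_floor))
    stop(structure(class = c("dftune_no_descent", "dftune_input_error",
                             "error", "condition"),
                   list(message = paste("no descending region in the sweep curve;",
                                        "widen the sweep range"), call = NULL)))
  alpha_max <- r[i_cand[which.min(slopes)]]
  lr_bounds(alpha_max / 10, alpha_max, m_min, m_max)
}

#' Write a sweep curve as CSV
#'
#' Columns `rate,loss,smoothed_loss`; the machine-readable summary of the
#' selected bounds is written separately by the CLI.
#'
#' @param curve a [run_sweep()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_curve <- function(curve, path) {
  utils::write.csv(data.frame(rate = curve$rates, loss = curve$losses,
                              smoothed_loss = curve$smoothed),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
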