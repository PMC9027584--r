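# Fine-tuning orchestration: stratified 80:15:5 splitting, the regularized
# objective, the DFT training loop driven by the schedule table, and
# evaluation through the metrics module.

#' Training configuration
#'
#' Conventions default to the reference setup — batch size 64, at most 50
#' epochs, 80:15:5 split — except for the image side, which defaults to 64
#' pixels because desk-scale CPU budgets forbid 400x400 training (pass
#' `image_side = 400` to reproduce the original geometry).
#'
#' @param epochs number of training epochs, 1..`epochs_cap` (0 allowed: no-op).
#' @param batch_size minibatch size.
#' @param image_side expected image side in pixels.
#' @param split_ratio train/validation/test percentages summing to 100.
#' @param weight_decay regularization weight `lambda` on the squared norm of
#'   the weight matrices (biases excluded), >= 0.
#' @param seed integer seed controlling shuffling and initialization.
#' @param mixed_precision run updates through the emulated fp16 path.
#' @param loss_scale loss scale for mixed precision, > 0.
#' @param kappa phase split of the triangular schedule, in (0, 1).
#' @param invert_momentum cycle momentum opposite to the learning rate.
#' @param cycle `"run"` (default): one triangular cycle over the whole run;
#'   `"epoch"`: one cycle per epoch.
#' @param epochs_cap upper bound on `epochs` (default 50).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 64, image_side = 64,
                         split_ratio = c(80, 15, 5), weight_decay = 1e-4,
                         seed = 1, mixed_precision = FALSE, loss_scale = 1024,
                         kappa = 0.5, invert_momentum = FALSE,
                         cycle = c("run", "epoch"), epochs_cap = 50) {
  check_scalar_num(epochs, "epochs"); check_scalar_num(batch_size, "batch_size")
  check_scalar_num(weight_decay, "weight_decay")
  cycle <- match.arg(cycle)
  if (epochs < 0 || epochs > epochs_cap)
    abort_param(sprintf("`epochs` must lie in [0, %d]", epochs_cap))
  if (length(split_ratio) != 3 || any(split_ratio <= 0) ||
      abs(sum(split_ratio) - 100) > 1e-8)
    abort_param("`split_ratio` must be three positive parts summing to 100")
  if (weight_decay < 0) abort_param("`weight_decay` must be >= 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 image_side = as.integer(image_side), split_ratio = split_ratio,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 mixed_precision = isTRUE(mixed_precision),
                 loss_scale = loss_scale, kappa = kappa,
                 invert_momentum = isTRUE(invert_momentum), cycle = cycle,
                 epochs_cap = as.integer(epochs_cap)), class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Global subset sizes are `floor(n * val%)` and `floor(n * test%)` with the
#' remainder assigned to train (so 80:15:5 on n = 1000 gives exactly
#' 800/150/50). Within those totals, items are apportioned across classes by
#' largest remainder, so each subset mirrors the class distribution as far
#' as counts permit. Partitions are disjoint, exhaustive, and a pure
#' function of `(labels, ratio, seed)`.
#'
#' @param x an [image_dataset()] or a plain label vector.
#' @param ratio three positive percentages summing to 100 (default 80:15:5).
#' @param seed integer seed for the within-class shuffle.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(x, ratio = c(80, 15, 5), seed = 1) {
  labels <- if (inherits(x, "image_dataset")) x$labels else as.integer(x)
  n <- length(labels)
  if (n < 3L) abort_input("need at least as many items as partitions")
  if (length(ratio) != 3 || any(ratio <= 0) || abs(sum(ratio) - 100) > 1e-8)
    abort_input("`ratio` must be three positive parts summing to 100")
  n_val <- floor(n * ratio[2] / 100)
  n_test <- floor(n * ratio[3] / 100)
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  by_class <- with_seed(seed, lapply(classes, function(cl) {
    idx <- which(labels == cl)
    idx[sample.int(length(idx))]
  }))
  apportion <- function(total, avail) {
    if (total == 0) return(integer(length(avail)))
    q <- total * avail / sum(avail)
    take <- pmin(floor(q), avail)
    rem <- total - sum(take)
    if (rem > 0) {
      ord <- order(-(q - floor(q)), -avail, seq_along(avail))
      for (j in ord) {
        if (rem == 0) break
        if (take[j] < avail[j]) { take[j] <- take[j] + 1L; rem <- rem - 1L }
      }
    }
    as.integer(take)
  }
  take_val <- apportion(n_val, counts)
  take_test <- apportion(n_test, counts - take_val)
  val <- integer(0); test <- integer(0); train <- integer(0)
  for (i in seq_along(classes)) {
    idx <- by_class[[i]]
    v <- seq_len(take_val[i])
    t2 <- seq_len(take_test[i]) + take_val[i]
    val <- c(val, idx[v])
    test <- c(test, idx[t2])
    train <- c(train, idx[setdiff(seq_along(idx), c(v, t2))])
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Regularized training objective
#'
#' `J = mean(batch_losses) + lambda * Omega(theta)` where `Omega` is the
#' squared norm of the trainable weight matrices (biases excluded). Either
#' pass `params` to have `Omega` computed, or supply a precomputed `omega`.
#'
#' @param batch_losses numeric vector of per-sample (or per-batch) losses.
#' @param params optional model parameter list.
#' @param lambda regularization weight, >= 0.
#' @param omega optional precomputed regularizer value.
#' @return list with `data_loss`, `omega`, `lambda`, `J`.
#' @export
compute_objective <- function(batch_losses, params = NULL, lambda = 0,
                              omega = NULL) {
  check_scalar_num(lambda, "lambda")
  if (lambda < 0) abort_param("`lambda` must be >= 0")
  if (is.null(omega)) omega <- if (is.null(params)) 0 else weight_sq_norm(params)
  data_loss <- mean(batch_losses)
  list(data_loss = data_loss, omega = omega, lambda = lambda,
       J = data_loss + lambda * omega)
}

weight_sq_norm <- function(params)
  sum(vapply(params, function(g) sum(g$W^2), numeric(1)))

# Add the regularizer gradient 2*lambda*W to the data-loss gradients.
add_decay <- function(grads, params, lambda) {
  if (lambda == 0) return(grads)
  for (g in names(grads)) grads[[g]]$W <- grads[[g]]$W + 2 * lambda * params[[g]]$W
  grads
}

make_batches <- function(n, batch_size, order_) {
  split(order_, ceiling(seq_len(n) / batch_size))
}

model_eval <- function(model, params, ds, batch_size = 256L) {
  n <- length(ds$images)
  preds <- integer(n); loss_sum <- 0
  for (b in make_batches(n, batch_size, seq_len(n))) {
    x <- stack_images(ds$images[b])
    scores <- model$predict(params, x)
    preds[b] <- argmax0(scores)
    z <- sweep(scores, 2L, apply(scores, 2L, max), `-`)
    p <- sweep(exp(z), 2L, colSums(exp(z)), `/`)
    loss_sum <- loss_sum - sum(log(pmax(p[cbind(ds$labels[b] + 1L, seq_along(b))], 1e-12)))
  }
  list(loss = loss_sum / n, acc = mean(preds == ds$labels), preds = preds)
}

# argmax over columns, ties resolved to the lowest class index; 0-based ids.
argmax0 <- function(scores) {
  k <- nrow(scores)
  best <- scores[1L, ]
  idx <- rep(0L, ncol(scores))
  if (k > 1L) for (j in 2:k) {
    better <- scores[j, ] > best
    best[better] <- scores[j, better]
    idx[better] <- j - 1L
  }
  idx
}

#' Train a model with discriminative fine-tuning
#'
#' Runs `config$epochs` epochs of the momentum-velocity update, with each
#' layer group's learning rate and momentum taken from the triangular
#' schedule table ([build_schedule()]) built over the run's iteration
#' budget. The best-validation-accuracy parameters (ties to the earlier
#' epoch) are retained as the fitted model. Fully deterministic under
#' `config$seed`.
#'
#' @param model a model object (e.g. [small_cnn()]).
#' @param train,val [image_dataset()] partitions from [split_dataset()].
#' @param config a [train_config()].
#' @param bounds an [lr_bounds()], typically from [select_bounds()].
#' @return an object of class `dft_fit`: list with `params` (best
#'   checkpoint), `final_params`, `history` (per-epoch data frame with
#'   train/val loss and accuracy; the train-side numbers are running averages
#'   over the epoch's minibatches, each evaluated before its update, while
#'   the validation numbers come from a full pass at epoch end),
#'   `best_epoch`, `schedule`, `model`, `config`, `bounds`.
#' @export
train_dft <- function(model, train, val, config, bounds) {
  stopifnot(inherits(config, "train_config"), inherits(bounds, "lr_bounds"),
            inherits(train, "image_dataset"), inherits(val, "image_dataset"))
  params <- model$params
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  if (config$epochs == 0L)
    return(structure(list(params = params, final_params = params,
                          history = history, best_epoch = NA_integer_,
                          schedule = NULL, model = model, config = config,
                          bounds = bounds), class = "dft_fit"))
  n <- length(train$images)
  steps_per_epoch <- ceiling(n / config$batch_size)
  t_cycle <- if (config$cycle == "run") config$epochs * steps_per_epoch
    else steps_per_epoch
  plan <- phase_plan(max(t_cycle, 2L), length(params), config$kappa)
  schedule <- build_schedule(plan, bounds, config$invert_momentum)
  l_max <- length(params)
  velocity <- lapply(params, function(g) lapply(g, function(a) a * 0))
  loss_scale <- config$loss_scale
  best_acc <- -Inf; best_epoch <- NA_integer_; best_params <- params
  t_global <- 0L
  for (epoch in seq_len(config$epochs)) {
    order_ <- with_seed(derive_seed(config$seed, paste0("epoch", epoch)),
                        sample.int(n))
    loss_sum <- 0; n_seen <- 0L; n_correct <- 0L
    for (b in make_batches(n, config$batch_size, order_)) {
      t <- if (config$cycle == "run") t_global else t_global %% plan$t_max
      batch <- list(x = stack_images(train$images[b]), y = train$labels[b])
      if (config$mixed_precision) {
        st <- mixed_precision_step(model, params, batch, loss_scale)
        loss_scale <- st$next_scale
        t_global <- t_global + 1L
        if (st$skipped) next
        grads <- st$grads
        lg <- st
      } else {
        lg <- model$loss_grad(params, batch)
        if (!is.finite(lg$loss))
          abort_contract(sprintf("non-finite loss at iteration %d", t_global))
        grads <- lg$grads
        t_global <- t_global + 1L
      }
      loss_sum <- loss_sum + lg$loss * length(b)
      n_seen <- n_seen + length(b)
      if (!is.null(lg$preds)) n_correct <- n_correct + sum(lg$preds == batch$y)
      grads <- add_decay(grads, params, config$weight_decay)
      row0 <- t * l_max
      for (li in seq_len(l_max)) {
        g <- names(params)[li]
        if (any(!vapply(grads[[g]], function(a) all(is.finite(a)), logical(1))))
          abort_contract(sprintf(
            "non-finite gradient at iteration %d in layer group '%s'", t_global - 1L, g))
        alpha <- schedule$alpha[row0 + li]
        mom <- schedule$momentum[row0 + li]
        for (a in names(params[[g]])) {
          st <- dft_update(layer_optim_state(params[[g]][[a]], velocity[[g]][[a]],
                                             alpha, mom, li - 1L),
                           grads[[g]][[a]])
          params[[g]][[a]] <- st$parameters
          velocity[[g]][[a]] <- st$velocity
        }
      }
    }
    vl <- model_eval(model, params, val)
    history[epoch, ] <- list(epoch, loss_sum / max(n_seen, 1L),
                             n_correct / max(n_seen, 1L), vl$loss, vl$acc)
    if (vl$acc > best_acc) {  # strict: ties keep the earlier epoch
      best_acc <- vl$acc; best_epoch <- epoch; best_params <- params
    }
  }
  structure(list(params = best_params, final_params = params,
                 history = history, best_epoch = best_epoch,
                 schedule = schedule, model = model, config = config,
                 bounds = bounds), class = "dft_fit")
}

#' @export
print.dft_fit <- function(x, ...) {
  cat(sprintf("<dft_fit> %d epochs trained", nrow(x$history)))
  if (nrow(x$history))
    cat(sprintf("; best val acc %.3f at epoch %d",
                max(x$history$val_acc), x$best_epoch))
  cat("\n")
  invisible(x)
}

#' Evaluate a model on a labeled subset
#'
#' Argmax predictions (ties to the lowest class index) are scored through
#' the metrics module.
#'
#' @param object a `dft_fit` or a model object.
#' @param ds a non-empty [image_dataset()].
#' @param K number of classes; defaults to the model's `K`.
#' @return list with `confusion` (K x K matrix), `per_class`
#'   (sensitivity/specificity data frame), `summary` (accuracy, macro
#'   precision/recall), `loss`, and `predictions`.
#' @export
evaluate <- function(object, ds, K = NULL) {
  if (inherits(object, "dft_fit")) {
    model <- object$model; params <- object$params
  } else {
    model <- object; params <- object$params
  }
  stopifnot(inherits(ds, "image_dataset"))
  if (length(ds$images) == 0L) abort_input("cannot evaluate on an empty subset")
  if (is.null(K)) K <- model$K
  ev <- model_eval(model, params, ds)
  C <- confusion_matrix(ds$labels, ev$preds, K)
  list(confusion = C, per_class = sensitivity_specificity(C),
       summary = summary_metrics(C), loss = ev$loss, predictions = ev$preds)
}
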