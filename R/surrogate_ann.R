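#' Training configuration for the neural surrogates
#'
#' Defaults follow the study schedule: learning rate 0.5, momentum
#' coefficient 0.5, initial weights and biases uniform on (-1, 1), 100
#' restarts, and an iteration budget of 10000 for the bending target and
#' 5000 for the pullout target.
#'
#' @param target `"bending"` (maximum tensile stress, MPa) or `"pullout"`
#'   (total reaction force, N).
#' @param learning_rate Gradient-descent step size.
#' @param momentum Coefficient of the momentum term.
#' @param max_iterations Batch iterations; default depends on `target`.
#' @param init_range Interval for the uniform weight/bias initialization.
#' @param n_restarts Number of random restarts; the restart with the lowest
#'   testing error wins.
#' @param update_mode `"online"` (one weight update per learning record per
#'   iteration, fixed record order) or `"batch"` (one accumulated update per
#'   iteration).
#' @param stopping `"final"` (default): train for the full iteration budget
#'   and keep the final iterate, reading the budget as the point where the
#'   testing error bottomed out; `"best_test"`: keep the intermediate weight
#'   snapshot with the minimal testing error. See the methods vignette for
#'   why the final iterate is the default.
#' @param seed Integer seed; restart `i` initializes from `seed + i - 1`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(target = c("bending", "pullout"),
                         learning_rate = 0.5, momentum = 0.5,
                         max_iterations = NULL, init_range = c(-1, 1),
                         n_restarts = 100L,
                         update_mode = c("batch", "online"),
                         stopping = c("final", "best_test"), seed = 1L) {
  target <- match.arg(target)
  update_mode <- match.arg(update_mode)
  stopping <- match.arg(stopping)
  if (is.null(max_iterations)) {
    max_iterations <- if (target == "bending") 10000L else 5000L
  }
  structure(list(target = target, learning_rate = learning_rate,
                 momentum = momentum, max_iterations = as.integer(max_iterations),
                 init_range = init_range, n_restarts = as.integer(n_restarts),
                 update_mode = update_mode, stopping = stopping,
                 seed = as.integer(seed)),
            class = "train_config")
}

response_column <- function(target) {
  switch(target, bending = "mts_fe", pullout = "trf_fe",
         stop("unknown target: ", target))
}

#' Initialize a 6-3-1 sigmoid network
#'
#' One hidden layer of three sigmoid neurons and a sigmoid output neuron;
#' all weights and biases drawn i.i.d. uniform on `init_range`.
#'
#' @param seed Integer seed for the draw.
#' @param init_range Initialization interval, default `c(-1, 1)`.
#' @param target Response label carried by the network.
#' @param output_scale Length-2 `c(min, max)` mapping the network's (0, 1)
#'   output back to physical units; filled in by training.
#' @return An object of class `surrogate_net`: list with `w1` (6 x 3), `b1`
#'   (3), `w2` (3), `b2` (scalar), `output_scale`, `target`.
#' @export
init_network <- function(seed, init_range = c(-1, 1),
                         target = "bending", output_scale = c(0, 1)) {
  set.seed(as.integer(seed))
  runif2 <- function(n) stats::runif(n, init_range[1], init_range[2])
  structure(list(
    w1 = matrix(runif2(18L), nrow = 6L, ncol = 3L,
                dimnames = list(SCREW_VARS, NULL)),
    b1 = runif2(3L),
    w2 = runif2(3L),
    b2 = runif2(1L),
    output_scale = as.numeric(output_scale),
    target = target
  ), class = "surrogate_net")
}

#' Forward pass of a surrogate network
#'
#' `h = sigmoid(W1' x + b1)`, `y = sigmoid(w2' h + b2)`; the output is
#' strictly inside (0, 1) before denormalization.
#'
#' @param net A `surrogate_net`.
#' @param x A normalized 6-vector or an n x 6 matrix of normalized inputs.
#' @return Numeric vector of outputs in (0, 1), one per input row.
#' @export
ann_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 6L) stop("input must have 6 columns")
  sigm <- function(z) 1 / (1 + exp(-z))
  h <- sigm(x %*% net$w1 + rep(1, nrow(x)) %o% net$b1)
  drop(sigm(h %*% net$w2 + net$b2))
}

# Output normalization: learning-set response range widened by a 10% margin
# on each side, so extrapolated optimizer queries stay inside the sigmoid's
# responsive range.
output_scale_from <- function(y_learning, margin = 0.1) {
  r <- range(y_learning)
  m <- margin * diff(r)
  c(r[1] - m, r[2] + m)
}

scale_response <- function(y, scale) (y - scale[1]) / (scale[2] - scale[1])
unscale_response <- function(y01, scale) y01 * (scale[2] - scale[1]) + scale[1]

#' Train a surrogate network on a learning/testing split
#'
#' Gradient descent with momentum on the summed squared error of the scaled
#' response. The testing-set error is tracked every iteration; depending on
#' `cfg$stopping` the returned weights are either the final iterate of the
#' budgeted run or the intermediate snapshot with the minimal testing error.
#'
#' @param net An initialized `surrogate_net` (see [init_network()]).
#' @param learning,testing Data frames with the six structural variables and
#'   the response column for `cfg$target` (`mts_fe` or `trf_fe`).
#' @param cfg A [train_config()].
#' @param space Design space used for input normalization.
#' @return The trained `surrogate_net` with attributes: `learn_trace` and
#'   `test_trace` (per-iteration mean squared error on the scaled response),
#'   `test_mse` (testing error of the returned weights, the restart-selection
#'   criterion), `best_iter` (iteration the weights come from), `diverged`.
#' @export
train_network <- function(net, learning, testing, cfg, space = design_space()) {
  stopifnot(nrow(learning) >= 1L)
  col <- response_column(cfg$target)
  yl <- learning[[col]]
  scale <- output_scale_from(yl)
  Xl <- normalize_inputs(learning[, SCREW_VARS], space)
  Xt <- normalize_inputs(testing[, SCREW_VARS], space)
  fit <- cpp_ann_train(Xl, scale_response(yl, scale),
                       Xt, scale_response(testing[[col]], scale),
                       net$w1, net$b1, net$w2, net$b2,
                       cfg$learning_rate, cfg$momentum, cfg$max_iterations,
                       identical(cfg$update_mode, "online"))
  use_final <- identical(cfg$stopping, "final") && !fit$diverged
  w <- if (use_final) fit$final else fit
  out <- structure(list(
    w1 = matrix(w$w1, 6L, 3L, dimnames = list(SCREW_VARS, NULL)),
    b1 = drop(w$b1), w2 = drop(w$w2), b2 = drop(w$b2),
    output_scale = scale, target = cfg$target
  ), class = "surrogate_net")
  n_it <- length(fit$test_trace)
  attr(out, "learn_trace") <- drop(fit$learn_trace)
  attr(out, "test_trace") <- drop(fit$test_trace)
  attr(out, "test_mse") <- if (use_final) fit$test_trace[n_it] else fit$best_test_mse
  attr(out, "best_iter") <- if (use_final) n_it else fit$best_iter
  attr(out, "diverged") <- fit$diverged
  out
}

#' Multi-restart surrogate training
#'
#' Runs [train_network()] from `cfg$n_restarts` independent random
#' initializations and returns the restart with the least testing error.
#' Restarts that diverge (non-finite error) are discarded.
#'
#' @inheritParams train_network
#' @return The best trained `surrogate_net`; attribute `restart_test_mse`
#'   records every restart's best testing error.
#' @export
multi_restart_train <- function(learning, testing, cfg, space = design_space()) {
  stopifnot(cfg$n_restarts >= 1L)
  best <- NULL
  best_err <- Inf
  errs <- rep(NA_real_, cfg$n_restarts)
  for (i in seq_len(cfg$n_restarts)) {
    net0 <- init_network(cfg$seed + i - 1L, cfg$init_range, cfg$target)
    fit <- train_network(net0, learning, testing, cfg, space)
    if (attr(fit, "diverged")) next
    errs[i] <- attr(fit, "test_mse")
    if (errs[i] < best_err) {
      best_err <- errs[i]
      best <- fit
    }
  }
  if (is.null(best)) stop("all ", cfg$n_restarts, " training restarts diverged")
  attr(best, "restart_test_mse") <- errs
  best
}

#' Predict a physical response for screw designs
#'
#' Composes input normalization, the network forward pass, and output
#' denormalization.
#'
#' @param net A trained `surrogate_net`.
#' @param d A design or matrix of designs in physical units.
#' @param space Design space for input normalization.
#' @param check Bound-check inputs (disable to extrapolate for out-of-box
#'   reference screws).
#' @return Numeric vector of responses in physical units (MPa or N).
#' @export
predict_physical <- function(net, d, space = design_space(), check = TRUE) {
  unscale_response(ann_forward(net, normalize_inputs(d, space, check)),
                   net$output_scale)
}

#' Mean absolute percentage error
#'
#' @param predicted,actual Numeric vectors; `actual` must be nonzero.
#' @return `mean(|predicted - actual| / actual) * 100`.
#' @export
mape <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 1L)
  if (any(actual == 0)) stop("actual responses must be nonzero")
  mean(abs(predicted - actual) / abs(actual)) * 100
}

#' Surrogate prediction error on labeled designs
#'
#' @param net A trained `surrogate_net`.
#' @param data Data frame with the six structural variables and the
#'   response column for `net$target`.
#' @param space Design space for input normalization.
#' @return Mean absolute percentage error between the surrogate's physical
#'   predictions and the recorded responses.
#' @export
mae_percent <- function(net, data, space = design_space()) {
  col <- response_column(net$target)
  mape(predict_physical(net, data[, SCREW_VARS], space), data[[col]])
}

#' Serialize a surrogate network to JSON
#'
#' Weights are written with full precision (17 significant digits), so
#' [read_surrogate()] reproduces the network exactly.
#'
#' @param net A `surrogate_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(net, path) {
  full <- function(x) sprintf("%.17g", x)
  doc <- list(
    target = net$target,
    w1 = apply(unclass(net$w1), c(1, 2), full),
    b1 = full(net$b1), w2 = full(net$w2), b2 = full(net$b2),
    output_scale = full(net$output_scale)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}

#' Deserialize a surrogate network written by [write_surrogate()]
#'
#' @param path JSON file path.
#' @return A `surrogate_net`.
#' @export
read_surrogate <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    w1 = matrix(as.numeric(doc$w1), 6L, 3L, dimnames = list(SCREW_VARS, NULL)),
    b1 = as.numeric(doc$b1), w2 = as.numeric(doc$w2), b2 = as.numeric(doc$b2),
    output_scale = as.numeric(doc$output_scale), target = doc$target
  ), class = "surrogate_net")
}
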