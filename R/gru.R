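# A from-scratch gated recurrent unit (GRU) binary classifier whose whole
# weight set is a flat real vector, the decision variable of the
# derivative-free optimizer. The cell is the four-gate variant used here:
# besides the usual update and reset gates it carries an input gate that
# multiplicatively scales x before the candidate state,
#   i_t = sigmoid(Wi [h_{t-1}, x_t] + bi)
#   z_t = sigmoid(Wz [h_{t-1}, x_t] + bz)
#   r_t = sigmoid(Wr [h_{t-1}, x_t] + br)
#   htilde_t = tanh(Wh (r_t * h_{t-1}) + i_t * (Wx x_t) + b)
#   h_t = z_t * h_{t-1} + (1 - z_t) * htilde_t,
# where the candidate matrix W = [Wh | Wx] is hidden x (hidden + input).
# All four gates are hidden-sized, so the input gate scales the
# candidate's projected input contribution elementwise (the only
# dimension-consistent placement of an "i * x" gate when hidden and
# input sizes differ). h_t is a convex combination of h_{t-1} and a tanh
# value, so it stays in [-1, 1] for all inputs. A single affine + sigmoid
# head on the final hidden state yields the class probability.

#' GRU architecture specification
#'
#' @param input_size Features per timestep (for row-encoded images, the
#'   image width).
#' @param hidden_size Hidden state size (default 8, keeping the weight
#'   vector small enough for derivative-free search).
#' @return A list of class `gru_spec` with sizes and `n_weights`, the
#'   length of the flat weight vector: four hidden x (hidden + input)
#'   matrices with hidden-length biases (input, update, reset gates and
#'   candidate) plus the output layer (hidden weights + 1 bias).
#' @export
#' @examples
#' gru_spec(16, 8)$n_weights # 809
gru_spec <- function(input_size, hidden_size = 8L) {
  stopifnot(input_size >= 1, hidden_size >= 1)
  h <- as.integer(hidden_size); d <- as.integer(input_size)
  structure(
    list(input_size = d, hidden_size = h, output_size = 1L,
         n_weights = 4L * (h * (h + d) + h) + h + 1L),
    class = "gru_spec"
  )
}

#' Decode a flat weight vector into GRU weight matrices
#'
#' The fixed ordering is Wi, bi, Wz, bz, Wr, br, W, b, w_out, b_out, with
#' matrices filled column-major. `gru_encode()` is the exact inverse.
#'
#' @param spec A [gru_spec()].
#' @param v Numeric vector of length `spec$n_weights`.
#' @return A list of class `gru_weights` with the gate matrices/biases,
#'   the output layer, and the spec.
#' @export
gru_decode <- function(spec, v) {
  stopifnot(inherits(spec, "gru_spec"))
  if (length(v) != spec$n_weights) {
    rlang::abort(sprintf("Weight vector has length %d; spec requires %d.",
                         length(v), spec$n_weights))
  }
  h <- spec$hidden_size; d <- spec$input_size
  pos <- 0L
  take_mat <- function() {
    k <- h * (h + d)
    m <- matrix(v[pos + seq_len(k)], nrow = h)
    pos <<- pos + k
    m
  }
  take_vec <- function(k) { x <- v[pos + seq_len(k)]; pos <<- pos + k; x }
  w <- list(
    Wi = take_mat(), bi = take_vec(h),
    Wz = take_mat(), bz = take_vec(h),
    Wr = take_mat(), br = take_vec(h),
    W  = take_mat(), b  = take_vec(h),
    w_out = take_vec(h), b_out = take_vec(1L),
    spec = spec
  )
  structure(w, class = "gru_weights")
}

#' @rdname gru_decode
#' @param weights A `gru_weights` list.
#' @export
gru_encode <- function(weights) {
  stopifnot(inherits(weights, "gru_weights"))
  c(as.vector(weights$Wi), weights$bi,
    as.vector(weights$Wz), weights$bz,
    as.vector(weights$Wr), weights$br,
    as.vector(weights$W),  weights$b,
    weights$w_out, weights$b_out)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One GRU cell step
#'
#' Advances the hidden state by one timestep; batched, so `h_prev` and
#' `x` may be matrices with one row per sequence.
#'
#' @param weights A `gru_weights` (see [gru_decode()]).
#' @param h_prev Hidden state: length-`hidden` vector or B x hidden
#'   matrix, entries in [-1, 1].
#' @param x Input: length-`input` vector or B x input matrix.
#' @return New hidden state, same shape as `h_prev`, entries in [-1, 1].
#' @export
gru_cell_step <- function(weights, h_prev, x) {
  spec <- weights$spec
  vec_in <- !is.matrix(h_prev)
  if (vec_in) { h_prev <- rbind(h_prev); x <- rbind(x) }
  if (ncol(h_prev) != spec$hidden_size || ncol(x) != spec$input_size) {
    rlang::abort("Hidden/input sizes do not match the weight spec.")
  }
  hx <- cbind(h_prev, x)
  i <- sigmoid(hx %*% t(weights$Wi) + rep(weights$bi, each = nrow(hx)))
  z <- sigmoid(hx %*% t(weights$Wz) + rep(weights$bz, each = nrow(hx)))
  r <- sigmoid(hx %*% t(weights$Wr) + rep(weights$br, each = nrow(hx)))
  H <- spec$hidden_size
  Wh <- weights$W[, seq_len(H), drop = FALSE]
  Wx <- weights$W[, -seq_len(H), drop = FALSE]
  htilde <- tanh((r * h_prev) %*% t(Wh) + i * (x %*% t(Wx)) +
                   rep(weights$b, each = nrow(hx)))
  h <- z * h_prev + (1 - z) * htilde
  if (vec_in) h[1L, ] else h
}

#' GRU forward pass to class probabilities
#'
#' Runs the cell over each sequence from an all-zero initial hidden state
#' and applies the affine + sigmoid output head to the final hidden
#' state.
#'
#' @param weights A `gru_weights`.
#' @param x Sequences: a B x T x D array, or a single T x D matrix.
#' @return Probabilities in (0, 1): length-B vector (or scalar for a
#'   single matrix input).
#' @export
gru_forward <- function(weights, x) {
  single <- is.matrix(x)
  if (single) x <- array(x, c(1L, nrow(x), ncol(x)))
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[2L] < 1L) rlang::abort("Sequences must have at least one timestep.")
  B <- dim(x)[1L]
  h <- matrix(0, B, weights$spec$hidden_size)
  for (t in seq_len(dim(x)[2L])) {
    h <- gru_cell_step(weights, h, matrix(x[, t, ], nrow = B))
  }
  p <- drop(sigmoid(h %*% weights$w_out + weights$b_out))
  if (single) p[1L] else as.numeric(p)
}

#' MSE fitness of a flat weight vector
#'
#' Mean squared error between the forward-pass probabilities and the 0/1
#' labels, `(1/n) * sum((d - y)^2)` — the objective the optimizer
#' minimizes when training the classifier.
#'
#' @param v Flat weight vector of length `spec$n_weights`.
#' @param spec A [gru_spec()].
#' @param x B x T x D sequence array.
#' @param y Length-B 0/1 label vector.
#' @return Non-negative scalar.
#' @export
gru_fitness <- function(v, spec, x, y) {
  if (length(y) == 0L || is.null(dim(x)) || dim(x)[1L] == 0L) {
    rlang::abort("Fitness needs a nonempty data set.")
  }
  stopifnot(dim(x)[1L] == length(y))
  p <- gru_forward(gru_decode(spec, v), x)
  mean((y - p)^2)
}

#' Encode standardized images as GRU input sequences
#'
#' Converts each raster to grayscale (Rec. 709 luma for color rasters)
#' and reads its rows as timesteps: a height x width image becomes a
#' sequence of `height` timesteps with `width` features, values in
#' [0, 1]. All images must share one size (see [standardize_images()]).
#'
#' @param data An image-set tibble (see [image_set()]).
#' @return A list with `x` (B x T x D array), `y` (0/1; cancerous = 1)
#'   and `labels`.
#' @export
encode_image_sequences <- function(data) {
  stopifnot(nrow(data) > 0L)
  gray <- purrr::map(data$image, to_gray)
  dims <- purrr::map(gray, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1L) {
    rlang::abort("Images must share one size; run standardize_images() first.")
  }
  h <- dims[[1L]][1L]; w <- dims[[1L]][2L]
  x <- array(0, c(nrow(data), h, w))
  for (i in seq_len(nrow(data))) x[i, , ] <- gray[[i]]
  list(x = x, y = as.integer(data$label == "cancerous"), labels = data$label)
}

#' Train the GRU classifier by NGO/NGO-LC
#'
#' Runs the optimizer over the flat weight vector inside the box
#' `[-weight_bound, weight_bound]` per coordinate, minimizing
#' [gru_fitness()] on the training data.
#'
#' @param x B x T x D training sequence array (see
#'   [encode_image_sequences()]).
#' @param y Length-B 0/1 labels.
#' @param spec A [gru_spec()]; its input size must equal `dim(x)[3]`.
#' @param config An [ngo_config()].
#' @param weight_bound Half-width of the search box (default 2; the
#'   sigmoid/tanh nonlinearities saturate beyond it).
#' @return An object of class `gru_fit`: `weights`, `weight_vector`,
#'   `spec`, `result` (the [ngo_optimize()] run), `threshold` (0.5) and
#'   training-set fitness/accuracy.
#' @export
gru_train <- function(x, y, spec = NULL, config = ngo_config(),
                      weight_bound = 2) {
  if (is.null(dim(x)) || length(dim(x)) != 3L) {
    rlang::abort("`x` must be a B x T x D array.")
  }
  if (dim(x)[1L] == 0L) rlang::abort("Training data is empty.")
  if (is.null(spec)) spec <- gru_spec(dim(x)[3L])
  stopifnot(spec$input_size == dim(x)[3L])
  obj <- function(Z) {
    apply(Z, 1L, gru_fitness, spec = spec, x = x, y = y)
  }
  m <- spec$n_weights
  res <- ngo_optimize(obj, config,
                      lower = rep(-weight_bound, m),
                      upper = rep(weight_bound, m))
  w <- gru_decode(spec, res$best_position)
  p <- gru_forward(w, x)
  structure(
    list(weights = w, weight_vector = res$best_position, spec = spec,
         result = res, threshold = 0.5,
         train_fitness = res$best_value,
         train_accuracy = mean(as.integer(p >= 0.5) == y),
         n_train = length(y)),
    class = "gru_fit"
  )
}

#' Predict with a trained GRU classifier
#'
#' @param object A `gru_fit`.
#' @param x Sequences (B x T x D array or single T x D matrix) or an
#'   image-set tibble of standardized images.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 at the 0.5
#'   threshold, `"label"` for cancerous/non-cancerous strings.
#' @param ... Unused.
#' @return Vector of predictions.
#' @export
predict.gru_fit <- function(object, x, type = c("prob", "class", "label"),
                            ...) {
  type <- match.arg(type)
  if (is.data.frame(x)) x <- encode_image_sequences(x)$x
  p <- gru_forward(object$weights, x)
  switch(type,
    prob = p,
    class = as.integer(p >= object$threshold),
    label = ifelse(p >= object$threshold, "cancerous", "non-cancerous")
  )
}

#' @export
print.gru_fit <- function(x, ...) {
  cat(sprintf(
    "<gru_fit> input %d x hidden %d (%d weights)  train MSE %.4f  train acc %.3f\n",
    x$spec$input_size, x$spec$hidden_size, x$spec$n_weights,
    x$train_fitness, x$train_accuracy))
  invisible(x)
}

#' Tidy a trained classifier into its fitness history
#'
#' @param x A `gru_fit`.
#' @param ... Unused.
#' @return A tibble with `iteration` and `fitness` (best-so-far MSE).
#' @method tidy gru_fit
#' @export
tidy.gru_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$result$history),
                 fitness = x$result$history)
}

#' One-row summary of a trained classifier
#'
#' @param x A `gru_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance gru_fit
#' @export
glance.gru_fit <- function(x, ...) {
  tibble::tibble(
    n_weights = x$spec$n_weights, hidden_size = x$spec$hidden_size,
    train_fitness = x$train_fitness, train_accuracy = x$train_accuracy,
    n_train = x$n_train, iterations = length(x$result$history),
    variant = x$result$variant
  )
}

#' Save / load a trained classifier as JSON
#'
#' The file stores the architecture sizes, the flat weight vector at full
#' double precision, and the decision threshold.
#'
#' @param fit A `gru_fit`.
#' @param path File path.
#' @return `save_gru_fit` returns `path` invisibly; `load_gru_fit`
#'   returns a `gru_fit` (without the optimizer trace).
#' @export
save_gru_fit <- function(fit, path) {
  obj <- list(
    input_size = fit$spec$input_size, hidden_size = fit$spec$hidden_size,
    threshold = fit$threshold, train_fitness = fit$train_fitness,
    train_accuracy = fit$train_accuracy,
    weights = fit$weight_vector
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gru_fit
#' @export
load_gru_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- gru_spec(obj$input_size, obj$hidden_size)
  structure(
    list(weights = gru_decode(spec, obj$weights),
         weight_vector = obj$weights, spec = spec, result = NULL,
         threshold = obj$threshold, train_fitness = obj$train_fitness,
         train_accuracy = obj$train_accuracy, n_train = NA_integer_),
    class = "gru_fit"
  )
}
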