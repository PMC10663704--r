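# Atrous-pyramid random-feature classifier. A frozen, randomly
# initialized convolution/pooling stack turns an image into a feature
# vector: 9x9 convolution -> 7x7 random pooling -> 9x9 convolution ->
# 5x5 max pooling -> an atrous pyramid that applies seven dilation
# rates of a shared 9x9 filter bank, concatenated, followed by global
# per-channel pooling. Only the output weights are learned, in closed
# form, by the Moore-Penrose pseudoinverse of the hidden-layer design
# matrix (extreme-learning-machine training: a single linear solve, no
# weight updates). A three-way decision reports "suspicious" whenever
# neither class clears the confidence threshold.

#' Classifier configuration
#'
#' Window sizes follow the stack description (9x9 convolutions, 7x7
#' random pooling, 5x5 max pooling); there are exactly seven atrous
#' rates. `hidden_units` are the sizes of the dense random layer(s)
#' between the image/tabular features and the solved output weights; the
#' default is a single wide random layer, the standard
#' extreme-learning-machine form, whose width gives the closed-form
#' least-squares solve its capacity. A vector (e.g. `c(10, 2)`) stacks
#' several frozen random layers, but note that a narrow final layer
#' caps the rank of the solved design matrix.
#'
#' @param conv_window convolution kernel side (odd).
#' @param random_pool_window random-pooling window side (odd).
#' @param max_pool_window max-pooling window side (odd).
#' @param atrous_rates exactly seven positive dilation rates.
#' @param n_filters filters per convolution layer.
#' @param hidden_units integer vector of dense random-layer sizes.
#' @param activation `"sigmoid"`, `"sine"` or `"relu"`.
#' @param input_size side to which images are resized before the stack.
#' @param tau decision threshold: a case is `suspicious` when no class
#'   probability reaches `tau`.
#' @param seed seed for the frozen random weights.
#' @return object of class `apcnn_config`.
#' @export
apcnn_config <- function(conv_window = 9, random_pool_window = 7,
                         max_pool_window = 5,
                         atrous_rates = c(1, 2, 3, 4, 6, 9, 12),
                         n_filters = 4, hidden_units = 256,
                         activation = c("sigmoid", "sine", "relu"),
                         input_size = 64, tau = 0.6, seed = 1) {
  activation <- match.arg(activation)
  if (length(atrous_rates) != 7) stop("exactly seven atrous rates are required")
  if (any(atrous_rates < 1)) stop("atrous rates must be positive")
  for (wn in c(conv_window, random_pool_window, max_pool_window))
    if (wn %% 2 != 1 || wn < 1) stop("windows must be odd and positive")
  structure(list(conv_window = conv_window,
                 random_pool_window = random_pool_window,
                 max_pool_window = max_pool_window,
                 atrous_rates = atrous_rates, n_filters = n_filters,
                 hidden_units = hidden_units, activation = activation,
                 input_size = input_size, tau = tau, seed = seed),
            class = "apcnn_config")
}

act_fun <- function(name) {
  switch(name,
         sigmoid = function(x) 1 / (1 + exp(-x)),
         sine = sin,
         relu = function(x) pmax(x, 0))
}

# Zero-mean random kernels, frozen at init.
random_kernels <- function(k, n_in, n_out) {
  a <- array(stats::rnorm(k * k * n_in * n_out, 0, 1 / sqrt(k * k * n_in)),
             dim = c(k, k, n_in, n_out))
  for (j in seq_len(n_out)) a[, , , j] <- a[, , , j] - mean(a[, , , j])
  a
}

# Frozen random weights of the whole stack (convolution banks + dense
# layers), drawn once from the config seed.
apcnn_init_weights <- function(config, n_features) {
  with_local_seed(config$seed, {
    F <- config$n_filters; k <- config$conv_window
    conv1 <- random_kernels(k, 1, F)
    conv2 <- random_kernels(k, F, F)
    atrous <- random_kernels(k, F, F)
    dims <- c(n_features, config$hidden_units)
    dense <- lapply(seq_along(config$hidden_units), function(i) {
      list(W = matrix(stats::rnorm(dims[i] * dims[i + 1], 0, 1 / sqrt(dims[i])),
                      dims[i], dims[i + 1]),
           b = stats::rnorm(dims[i + 1], 0, 0.1))
    })
    list(conv1 = conv1, conv2 = conv2, atrous = atrous, dense = dense)
  })
}

#' Run the frozen feature stack on one image
#'
#' @param image gray image matrix, at least 64x64.
#' @param config an [apcnn_config()].
#' @param weights frozen weights from the same config; rebuilt from the
#'   config seed when omitted.
#' @param stochastic use stochastic random pooling (training-time
#'   behaviour, consumes the RNG stream) instead of its
#'   magnitude-weighted expectation.
#' @return list with `features` (numeric vector: per-channel mean and
#'   standard deviation of the atrous stack) and `maps` (list of
#'   per-pixel atrous channel maps at `input_size` resolution).
#' @export
build_features <- function(image, config = apcnn_config(), weights = NULL,
                           stochastic = FALSE) {
  check_gray(image)
  if (nrow(image) < 64 || ncol(image) < 64)
    stop("image must be at least 64x64")
  if (is.null(weights)) weights <- apcnn_init_weights(config, 0)
  g <- act_fun(config$activation)
  x <- resize_matrix(image * 1.0, config$input_size, config$input_size) / 255

  c1 <- lapply(conv2d(x, weights$conv1), g)
  p1 <- lapply(c1, random_pool, k = config$random_pool_window,
               stochastic = stochastic)
  c2 <- lapply(conv2d(p1, weights$conv2), g)
  p2 <- lapply(c2, max_pool, k = config$max_pool_window)
  maps <- list()
  for (r in config$atrous_rates)
    maps <- c(maps, lapply(conv2d(p2, weights$atrous, dilation = r), g))
  feats <- unlist(lapply(maps, function(m) c(mean(m), stats::sd(m))))
  names(feats) <- paste0(rep(paste0("ch", seq_along(maps)), each = 2),
                         c("_mean", "_sd"))
  list(features = feats, maps = maps)
}

#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse; singular values below
#' `tol * max(singular value)` are treated as zero.
#'
#' @param A numeric matrix.
#' @param tol relative cutoff.
#' @return the pseudoinverse of `A`.
#' @export
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Hidden design matrix: standardized features through the frozen dense
# layers, plus an intercept column.
apcnn_hidden <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  g <- act_fun(model$config$activation)
  H <- Xs
  for (layer in model$weights$dense)
    H <- g(sweep(H %*% layer$W, 2, layer$b, "+"))
  cbind(1, H)
}

#' Train the classifier output weights in closed form
#'
#' Features are standardized (training statistics are stored on the
#' model), pushed through the frozen dense layers into the hidden design
#' matrix `G`, and the output weights are `beta = pinv(G) %*% targets`
#' -- the minimum-norm least-squares solution. There is no iterative
#' weight update; refitting the same data reproduces `beta` exactly.
#' A degenerate `G` (constant column) triggers a warning and a
#' ridge-regularized solve.
#'
#' @param config an [apcnn_config()].
#' @param X numeric feature matrix, one row per training case (image
#'   stack features, optionally with tabular attributes appended).
#' @param y class labels (factor or character with levels benign /
#'   malignant), or an already one-hot numeric target matrix.
#' @return object of class `apcnn_model`.
#' @export
apcnn_fit <- function(config, X, y) {
  X <- as.matrix(X)
  if (is.matrix(y)) {
    Y <- y
    classes <- colnames(y)
    if (is.null(classes)) classes <- c("benign", "malignant")
  } else {
    classes <- c("benign", "malignant")
    y <- as.character(y)
    if (!all(y %in% classes)) stop("labels must be benign or malignant")
    Y <- cbind(benign = as.numeric(y == "benign"),
               malignant = as.numeric(y == "malignant"))
  }
  if (nrow(X) != nrow(Y)) stop("features and targets disagree in rows")
  center <- colMeans(X)
  # population (1/n) scale: invariant under duplication of the
  # training set, so refits on replicated data reproduce beta
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  scale[scale == 0] <- 1
  model <- structure(list(config = config, center = center, scale = scale,
                          weights = apcnn_init_weights(config, ncol(X)),
                          classes = classes, tau = config$tau),
                     class = "apcnn_model")
  G <- apcnn_hidden(model, X)
  degenerate <- any(apply(G, 2, stats::sd) == 0 & colMeans(G) == 0)
  if (degenerate) {
    warning("degenerate hidden matrix; using ridge-regularized solve")
    lambda <- 1e-6
    model$beta <- solve(crossprod(G) + lambda * diag(ncol(G)), crossprod(G, Y))
  } else {
    model$beta <- pinv(G) %*% Y
  }
  model$hidden_matrix_shape <- dim(G)
  model$training_residual <- norm(G %*% model$beta - Y, "F")
  model
}

#' Predict class decisions from feature rows
#'
#' Scores are the hidden-matrix projection times the solved output
#' weights, mapped through a softmax over benign/malignant. A case whose
#' top softmax probability is below the model threshold `tau` is labeled
#' `suspicious`.
#'
#' @param model an [apcnn_model()] from [apcnn_fit()].
#' @param X feature matrix (rows as in training).
#' @param tau optional threshold override.
#' @return data.frame with columns `label`, `p_benign`, `p_malignant`.
#' @export
apcnn_predict <- function(model, X, tau = NULL) {
  if (!inherits(model, "apcnn_model") || is.null(model$beta))
    stop("model is not trained")
  if (is.null(tau)) tau <- model$tau
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  Z <- apcnn_hidden(model, X) %*% model$beta
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z) / rowSums(exp(Z))
  top <- max.col(P, ties.method = "first")
  lab <- model$classes[top]
  lab[P[cbind(seq_len(nrow(P)), top)] < tau] <- "suspicious"
  data.frame(label = lab, p_benign = P[, 1], p_malignant = P[, 2],
             stringsAsFactors = FALSE)
}

#' Save / load a trained classifier as JSON
#'
#' The frozen random weights are reproducible from the config seed, so
#' the archive stores only the config, the feature standardization, the
#' solved output weights and the class order (plain text, portable).
#'
#' @param model an `apcnn_model`.
#' @param path file path.
#' @return `path` (save) or the restored `apcnn_model` (load).
#' @export
save_apcnn <- function(model, path) {
  stopifnot(inherits(model, "apcnn_model"))
  obj <- list(config = unclass(model$config), center = model$center,
              scale = model$scale, beta = model$beta,
              classes = model$classes, tau = model$tau)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_apcnn
#' @export
load_apcnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(apcnn_config, obj$config[names(obj$config) %in%
                                            names(formals(apcnn_config))])
  model <- structure(list(config = cfg, center = obj$center,
                          scale = obj$scale,
                          weights = apcnn_init_weights(cfg, length(obj$center)),
                          beta = matrix(obj$beta, ncol = length(obj$classes)),
                          classes = obj$classes, tau = obj$tau),
                     class = "apcnn_model")
  model
}

#' Bayes posterior utility
#'
#' `posterior = likelihood * prior / evidence`; used by the
#' particle-filter weighting.
#'
#' @param likelihood,prior,evidence probabilities in `(0, 1]`.
#' @return posterior probability.
#' @export
bayes_posterior <- function(likelihood, prior, evidence) {
  if (any(evidence <= 0)) stop("evidence must be > 0")
  if (any(c(likelihood, prior) <= 0) || any(c(likelihood, prior) > 1))
    stop("likelihood and prior must lie in (0, 1]")
  likelihood * prior / evidence
}
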