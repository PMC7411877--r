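#' Fit a PCA-based multivariate SPC model on interictal HRV vectors
#'
#' Each index is autoscaled (z-scored with the training mean and standard
#' deviation; the eight indices have incommensurate units), then the
#' leading principal components of the training correlation matrix are
#' retained: the orthonormal loading matrix `V_R` and the score standard
#' deviations `sigma_R`. Control limits are unset until
#' [tune_control_limits()] is called. Loadings follow a deterministic sign
#' convention (the largest-magnitude element of each column is positive)
#' so that model files are reproducible.
#'
#' @param x numeric matrix or data frame of training vectors, one row per
#'   observation (columns in [extract_hrv_matrix()] order for the standard
#'   eight-index model).
#' @param n_components number of retained components (default 6).
#' @return an object of class `mspc_model` with fields `center`, `scale`,
#'   `loadings` (p x R, orthonormal columns), `sigma` (score SDs,
#'   non-increasing), `cl_Q`, `cl_T2`, `alpha`, `n_components`,
#'   `var_explained`.
#' @export
fit_mspc <- function(x, n_components = 6) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n_components < 1 || n_components > p)
    stop("n_components must be between 1 and ", p)
  if (n < 10 * n_components)
    stop("need at least ", 10 * n_components, " training vectors, got ", n)
  if (anyNA(x)) stop("training data contain missing values")
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (any(scl < 1e-12)) {
    stop("cannot autoscale: zero variance in component(s) ",
         paste(nms[scl < 1e-12], collapse = ", "))
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  e <- eigen(crossprod(xs) / (n - 1L), symmetric = TRUE)
  v <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {           # reproducible sign
    k <- which.max(abs(v[, j]))
    if (v[k, j] < 0) v[, j] <- -v[, j]
  }
  sigma <- sqrt(pmax(e$values[seq_len(n_components)], 0))
  if (any(sigma <= 0))
    stop("degenerate component: zero score variance among the retained PCs")
  structure(list(center = center, scale = scl, loadings = v, sigma = sigma,
                 cl_Q = NA_real_, cl_T2 = NA_real_, alpha = NA_real_,
                 n_components = n_components,
                 var_explained = sum(e$values[seq_len(n_components)]) /
                   sum(e$values),
                 index_names = nms, n_train = n),
            class = "mspc_model")
}

#' @export
print.mspc_model <- function(x, ...) {
  cat(sprintf("MSPC model: %d of %d components (%.1f%% variance), n = %d\n",
              x$n_components, length(x$center), 100 * x$var_explained,
              x$n_train))
  if (is.na(x$cl_Q)) {
    cat("  control limits: not tuned\n")
  } else {
    cat(sprintf("  control limits (alpha = %g%%): Q %.3f, T2 %.3f\n",
                x$alpha, x$cl_Q, x$cl_T2))
  }
  invisible(x)
}

scale_input <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("expected ", length(model$center), " components, got ", ncol(x))
  sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
}

#' Q statistic (squared prediction error)
#'
#' Squared distance between the autoscaled sample and its projection onto
#' the retained principal-component subspace,
#' `Q = x' (I - V_R V_R') x`: sensitive to broken correlations among the
#' indices.
#'
#' @param model a fitted [fit_mspc()] model.
#' @param x a vector, or a matrix with one observation per row.
#' @return numeric vector of Q values.
#' @export
q_statistic <- function(model, x) {
  stopifnot(inherits(model, "mspc_model"))
  xs <- scale_input(model, x)
  scores <- xs %*% model$loadings
  resid <- xs - scores %*% t(model$loadings)
  rowSums(resid^2)
}

#' Hotelling T-squared statistic
#'
#' Mahalanobis distance from the origin within the retained subspace,
#' `T2 = x' V_R Sigma_R^-2 V_R' x = sum_r (score_r / sigma_r)^2`:
#' sensitive to shifts along the modelled directions.
#'
#' @inheritParams q_statistic
#' @return numeric vector of T-squared values.
#' @export
t2_statistic <- function(model, x) {
  stopifnot(inherits(model, "mspc_model"))
  if (any(model$sigma <= 0)) stop("degenerate component: sigma_r = 0")
  xs <- scale_input(model, x)
  scores <- xs %*% model$loadings
  rowSums(sweep(scores, 2L, model$sigma, "/")^2)
}

#' Both monitoring statistics for a block of samples
#'
#' @inheritParams q_statistic
#' @return data.frame with columns `Q` and `T2`.
#' @export
monitoring_statistics <- function(model, x) {
  data.frame(Q = q_statistic(model, x), T2 = t2_statistic(model, x))
}

#' Set empirical control limits from normal-condition statistics
#'
#' The control limit of each statistic is the one-sided upper
#' `alpha`-percentile of its normal-condition (interictal) sample,
#' computed with linear interpolation between order statistics.
#'
#' @param model a fitted [fit_mspc()] model.
#' @param q_values,t2_values normal-condition monitoring statistics,
#'   at least 100 of each.
#' @param alpha confidence level in percent (default 99).
#' @return the model with `cl_Q`, `cl_T2`, `alpha` set.
#' @export
tune_control_limits <- function(model, q_values, t2_values, alpha = 99) {
  stopifnot(inherits(model, "mspc_model"))
  if (alpha <= 0 || alpha >= 100) stop("alpha must be in (0, 100)")
  if (length(q_values) < 100L || length(t2_values) < 100L)
    stop("need at least 100 normal-condition statistics to tune limits")
  model$cl_Q <- unname(stats::quantile(q_values, alpha / 100, type = 7))
  model$cl_T2 <- unname(stats::quantile(t2_values, alpha / 100, type = 7))
  model$alpha <- alpha
  model
}

#' Read / write an MSPC model as JSON
#'
#' Models round-trip bit-exactly (doubles are serialized at 17 significant
#' digits). Loadings are stored row-major.
#'
#' @param model a [fit_mspc()] model.
#' @param path file path.
#' @param metadata optional list stored verbatim in the file.
#' @return `read_mspc_model` returns the model.
#' @export
write_mspc_model <- function(model, path, metadata = list()) {
  stopifnot(inherits(model, "mspc_model"))
  payload <- list(
    center = unname(model$center),
    scale = unname(model$scale),
    loadings = as.vector(t(model$loadings)),
    sigma = model$sigma,
    cl_Q = model$cl_Q,
    cl_T2 = model$cl_T2,
    alpha = model$alpha,
    n_components = model$n_components,
    n_features = length(model$center),
    var_explained = model$var_explained,
    index_names = model$index_names,
    n_train = model$n_train,
    metadata = metadata
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           na = "null", null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_mspc_model
#' @export
read_mspc_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  v <- matrix(p$loadings, nrow = p$n_features, ncol = p$n_components,
              byrow = TRUE)
  center <- as.numeric(p$center)
  scl <- as.numeric(p$scale)
  names(center) <- names(scl) <- p$index_names
  structure(list(center = center, scale = scl, loadings = v,
                 sigma = as.numeric(p$sigma),
                 cl_Q = num_or_na(p$cl_Q), cl_T2 = num_or_na(p$cl_T2),
                 alpha = num_or_na(p$alpha),
                 n_components = as.integer(p$n_components),
                 var_explained = num_or_na(p$var_explained),
                 index_names = p$index_names,
                 n_train = if (is.null(p$n_train)) NA_integer_
                           else as.integer(p$n_train)),
            class = "mspc_model")
}
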