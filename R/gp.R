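# Matern-5/2 Gaussian-process regression with automatic relevance
# determination, used as the surrogate mapping (light intensity, copy number)
# to each kinetic parameter.
#
# Conventions: features are scaled to comparable magnitudes (I by 70, the
# highest design intensity; n by 8, the highest design copy number) and
# labels are standardized to zero mean / unit variance before fitting, so
# the zero prior mean does not drag strictly-positive parameters toward zero
# off-data. Predictions are mapped back to parameter units. A raw-label mode
# (no standardization) is kept behind a flag.

DEFAULT_FEATURE_SCALE <- c(I = 70, n = 8)

#' GP training set for one kinetic parameter
#'
#' @param V 2 x nd feature matrix, rows `I` (umol m^-2 s^-1) and `n`
#'   (copy number), one column per condition.
#' @param L Numeric label vector of length nd (fitted value of one
#'   parameter per condition).
#' @param label_name Name of the parameter the labels belong to.
#' @param feature_scale Positive length-2 divisor applied to the feature
#'   rows before fitting.
#' @param standardize Standardize labels to zero mean / unit variance
#'   (default). With `FALSE`, raw labels are fitted against the zero prior
#'   mean.
#' @param log_labels Fit the GP to `log10(L)` and exponentiate predictions
#'   back (requires strictly positive labels). Used by the kinetic-parameter
#'   surrogates, whose labels are positivity-constrained rate constants
#'   spanning decades.
#' @return A list of class `gp_training_set` with the raw and scaled data
#'   and the scaling records needed to invert predictions.
#' @export
gp_training_set <- function(V, L, label_name = "theta",
                            feature_scale = DEFAULT_FEATURE_SCALE,
                            standardize = TRUE, log_labels = FALSE) {
  V <- rbind(V)
  if (nrow(V) != 2L) stop("V must have 2 rows (I, n)")
  nd <- ncol(V)
  if (length(L) != nd) stop("L must have one label per column of V")
  if (anyNA(V) || anyNA(L) || !all(is.finite(V)) || !all(is.finite(L))) {
    stop("training data must be finite with no NA")
  }
  if (nd < 1L) stop("need at least one training point")
  if (any(feature_scale <= 0)) stop("feature_scale must be positive")
  if (log_labels && any(L <= 0)) {
    stop("log_labels requires strictly positive labels")
  }
  Lw <- if (log_labels) log10(L) else L
  mu_L <- if (standardize) mean(Lw) else 0
  sd_L <- if (standardize) stats::sd(Lw) else 1
  if (!is.finite(sd_L) || sd_L <= 0) sd_L <- max(abs(mu_L), 1) * 1e-8 + 1e-12
  structure(list(V = V, L = L, nd = nd, label_name = label_name,
                 feature_scale = as.numeric(feature_scale),
                 log_labels = log_labels,
                 label_center = mu_L, label_scale = sd_L,
                 Vs = V / feature_scale, ys = (Lw - mu_L) / sd_L),
            class = "gp_training_set")
}

#' GP hyperparameters
#'
#' @param signal_variance Kernel signal variance sigma_f^2 (scaled label
#'   units squared).
#' @param length_scales Length-2 ARD length scales, one per feature
#'   (scaled feature units).
#' @param noise_variance Observation noise variance sigma_n^2.
#' @return A list of class `gp_hyperparams`; all entries strictly positive.
#' @export
gp_hyperparams <- function(signal_variance, length_scales, noise_variance) {
  if (length(length_scales) != 2L) stop("length_scales must have length 2")
  v <- c(signal_variance, length_scales, noise_variance)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("all GP hyperparameters must be strictly positive and finite")
  }
  structure(list(signal_variance = signal_variance,
                 length_scales = as.numeric(length_scales),
                 noise_variance = noise_variance),
            class = "gp_hyperparams")
}

#' Matern-5/2 covariance between two feature vectors
#'
#' k(v_i, v_j) = sigma_f^2 (1 + sqrt(5) r + 5/3 r^2) exp(-sqrt(5) r), with
#' r^2 = sum_d ((v_i,d - v_j,d) / l_d)^2 (one length scale per feature:
#' automatic relevance determination). Symmetric, bounded by sigma_f^2.
#'
#' @param v_i,v_j Feature 2-vectors (already on the scaled feature axes).
#' @param hyper A [gp_hyperparams()] object.
#' @return Covariance value.
#' @export
matern52 <- function(v_i, v_j, hyper) {
  r <- sqrt(sum(((v_i - v_j) / hyper$length_scales)^2))
  s5r <- sqrt(5) * r
  hyper$signal_variance * (1 + s5r + (5 / 3) * r^2) * exp(-s5r)
}

# Vectorized cross-covariance between column sets A (2 x na) and B (2 x nb).
matern52_cross <- function(A, B, hyper) {
  l <- hyper$length_scales
  As <- A / l; Bs <- B / l
  d2 <- outer(colSums(As^2), colSums(Bs^2), "+") - 2 * crossprod(As, Bs)
  r <- sqrt(pmax(d2, 0))
  s5r <- sqrt(5) * r
  hyper$signal_variance * (1 + s5r + (5 / 3) * r^2) * exp(-s5r)
}

#' Kernel matrix of a training set
#'
#' @param train A [gp_training_set()].
#' @param hyper A [gp_hyperparams()].
#' @return nd x nd symmetric covariance matrix (noise-free; the noise
#'   variance is added on the diagonal where the GP equations require it).
#' @export
kernel_matrix <- function(train, hyper) {
  matern52_cross(train$Vs, train$Vs, hyper)
}

# Cholesky of K + sigma_n^2 I with a jitter ladder 1e-10 -> 1e-6.
chol_with_jitter <- function(K, noise_variance) {
  nd <- nrow(K)
  for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
    R <- tryCatch(chol(K + (noise_variance + jit) * diag(nd)),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("Cholesky factorization failed even with maximum jitter")
}

#' Log marginal likelihood of a training set under given hyperparameters
#'
#' log p(y | V, rho) = -1/2 y' (K + sigma_n^2 I)^-1 y
#' - 1/2 log det(K + sigma_n^2 I) - nd/2 log(2 pi), computed via Cholesky.
#' `y` are the scaled labels (zero prior mean).
#'
#' @param train A [gp_training_set()].
#' @param hyper A [gp_hyperparams()].
#' @return Log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(train, hyper) {
  K <- kernel_matrix(train, hyper)
  R <- chol_with_jitter(K, hyper$noise_variance)
  y <- train$ys
  a <- backsolve(R, forwardsolve(t(R), y))
  -0.5 * sum(y * a) - sum(log(diag(R))) - 0.5 * train$nd * log(2 * pi)
}

#' Train GP hyperparameters by maximizing the log marginal likelihood
#'
#' Multi-start local optimization (L-BFGS-B on the log10 of the three
#' hyperparameter groups) inside the box `[1e-4, 1e4]` per hyperparameter in
#' scaled units. The returned hyperparameters achieve a likelihood at least
#' as high as every restart's.
#'
#' @param train A [gp_training_set()].
#' @param restarts Number of random restarts (a central start is always
#'   included in addition).
#' @param seed Integer seed controlling the restart draws.
#' @return A [gp_hyperparams()] object with attribute `log_marginal`.
#' @export
train_gp <- function(train, restarts = 8, seed = 1L) {
  if (train$nd < 2L) stop("need nd >= 2 to train")
  negll <- function(z) {
    h <- gp_hyperparams(10^z[1], 10^z[2:3], 10^z[4])
    val <- tryCatch(-log_marginal_likelihood(train, h),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  lo <- rep(-4, 4); hi <- rep(4, 4)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  starts <- rbind(c(0, 0, 0, -2),
                  matrix(stats::runif(4 * restarts, -2, 2), restarts, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all hyperparameter restarts failed")
  z <- best$par
  h <- gp_hyperparams(10^z[1], 10^z[2:3], 10^z[4])
  attr(h, "log_marginal") <- -best$value
  h
}

#' GP posterior at a test condition
#'
#' Posterior mean and variance of one kinetic parameter at a test input,
#' mapped back to parameter units. The predictive variance is the latent
#' (noise-free) function variance by default; set `include_noise = TRUE` to
#' add the observation noise variance.
#'
#' @param train A [gp_training_set()].
#' @param hyper A [gp_hyperparams()].
#' @param v_star Feature 2-vector `(I, n)` in raw units.
#' @param include_noise Add sigma_n^2 to the predictive variance.
#' @return A list of class `gp_posterior`: `mean` (parameter units),
#'   `variance` (parameter units squared, clamped to >= 0), and the
#'   scaled-space `mean_scaled`, `variance_scaled`.
#' @export
gp_posterior <- function(train, hyper, v_star, include_noise = FALSE) {
  vs <- matrix(as.numeric(v_star) / train$feature_scale, nrow = 2)
  K <- kernel_matrix(train, hyper)
  R <- chol_with_jitter(K, hyper$noise_variance)
  y <- train$ys
  alpha <- backsolve(R, forwardsolve(t(R), y))
  ks <- matern52_cross(train$Vs, vs, hyper)   # nd x 1
  mean_s <- drop(crossprod(ks, alpha))
  w <- forwardsolve(t(R), ks)
  var_s <- hyper$signal_variance - drop(crossprod(w))
  if (include_noise) var_s <- var_s + hyper$noise_variance
  if (var_s < -1e-12) var_s <- 0
  var_s <- max(var_s, 0)
  m_lab <- mean_s * train$label_scale + train$label_center
  v_lab <- var_s * train$label_scale^2
  if (isTRUE(train$log_labels)) {
    # invert the log10 transform: the reported mean is the posterior median
    # of the parameter; the variance follows by the delta method
    m_orig <- 10^m_lab
    v_orig <- (log(10) * m_orig)^2 * v_lab
  } else {
    m_orig <- m_lab
    v_orig <- v_lab
  }
  structure(list(mean = m_orig, variance = v_orig,
                 mean_scaled = mean_s, variance_scaled = var_s),
            class = "gp_posterior")
}

#' Train the six parameter surrogates
#'
#' One independent multi-input single-output GP per kinetic parameter, all
#' sharing the feature matrix.
#'
#' @param training_sets Named list of six [gp_training_set()] objects (as
#'   produced by [build_training_set()]).
#' @param restarts,seed Passed to [train_gp()]; per-parameter seeds are
#'   derived deterministically from `seed`.
#' @return A list of class `param_surrogate`: per parameter, the training
#'   set and its trained hyperparameters.
#' @export
train_surrogate <- function(training_sets, restarts = 8, seed = 1L) {
  if (!all(param_names() %in% names(training_sets))) {
    stop("training_sets must be named by the six kinetic parameters")
  }
  V0 <- training_sets[[1]]$V
  models <- lapply(seq_along(param_names()), function(i) {
    pn <- param_names()[i]
    ts <- training_sets[[pn]]
    if (!identical(dim(ts$V), dim(V0)) || !all(ts$V == V0)) {
      stop("all six GPs must be trained on the same feature matrix V")
    }
    hy <- train_gp(ts, restarts = restarts,
                   seed = as.integer((seed * 100L + i) %% .Machine$integer.max))
    list(train = ts, hyper = hy)
  })
  names(models) <- param_names()
  structure(models, class = "param_surrogate")
}

#' @export
print.param_surrogate <- function(x, ...) {
  cat(sprintf("GP parameter surrogate: 6 Matern-5/2 ARD GPs on %d conditions\n",
              x[[1]]$train$nd))
  for (pn in names(x)) {
    h <- x[[pn]]$hyper
    cat(sprintf("  %-7s sf2 = %8.3g  l = (%.3g, %.3g)  sn2 = %8.3g\n",
                pn, h$signal_variance, h$length_scales[1],
                h$length_scales[2], h$noise_variance))
  }
  invisible(x)
}

#' Predict the kinetic parameter set at a condition
#'
#' Assembles a [kinetic_params()] vector from the six GP posterior means at
#' `(I, n)`. Any non-positive predicted mean is floored at the parameter's
#' lower default bound with a warning (the zero-mean GP can undershoot off
#' data). Non-integer copy numbers are allowed (the surrogate is a smooth
#' map on R^2) but flagged with a warning.
#'
#' @param models A `param_surrogate` from [train_surrogate()].
#' @param condition A [condition()], or a list with `light_intensity` and
#'   `copy_number` (possibly non-integer).
#' @param include_noise Passed to [gp_posterior()].
#' @return A [kinetic_params()] object with attribute `variances`
#'   (named per-parameter posterior variances).
#' @export
predict_params <- function(models, condition, include_noise = FALSE) {
  if (!inherits(models, "param_surrogate")) stop("models must be a trained param_surrogate")
  I <- condition$light_intensity; n <- condition$copy_number
  if (n != round(n)) warning("non-integer copy number: surrogate evaluated off the strain lattice")
  v <- c(I, n)
  lbound <- default_param_bounds()[1, ]
  means <- numeric(6); vars <- numeric(6)
  for (i in seq_along(param_names())) {
    pn <- param_names()[i]
    post <- gp_posterior(models[[pn]]$train, models[[pn]]$hyper, v,
                         include_noise = include_noise)
    m <- post$mean
    if (m <= 0) {
      warning(sprintf("non-positive GP mean for %s at (I=%g, n=%g); floored at %g",
                      pn, I, n, lbound[[pn]]))
      m <- lbound[[pn]]
    }
    means[i] <- m; vars[i] <- post$variance
  }
  names(means) <- names(vars) <- param_names()
  out <- do.call(kinetic_params, as.list(means))
  attr(out, "variances") <- vars
  out
}

#' Persist / restore a trained surrogate as structured text
#'
#' Writes V, L, scaling records and hyperparameters for each parameter to a
#' plain-text file using full double precision (hex float encoding), so the
#' round trip is bit-exact.
#'
#' @param models A `param_surrogate`.
#' @param path File path.
#' @return `read_surrogate` returns the `param_surrogate`.
#' @export
write_surrogate <- function(models, path) {
  num <- function(x) paste(sprintf("%a", x), collapse = " ")
  lines <- c("optodose_surrogate_v1")
  for (pn in names(models)) {
    ts <- models[[pn]]$train; h <- models[[pn]]$hyper
    lines <- c(lines,
               paste0("param ", pn),
               paste0("V_I ", num(ts$V[1, ])),
               paste0("V_n ", num(ts$V[2, ])),
               paste0("L ", num(ts$L)),
               paste0("feature_scale ", num(ts$feature_scale)),
               paste0("log_labels ", as.integer(isTRUE(ts$log_labels))),
               paste0("label_center ", num(ts$label_center)),
               paste0("label_scale ", num(ts$label_scale)),
               paste0("hyper ", num(c(h$signal_variance, h$length_scales,
                                      h$noise_variance))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (lines[1] != "optodose_surrogate_v1") stop("not a surrogate file: ", path)
  fields <- strsplit(lines[-1], " ")
  num <- function(v) as.numeric(v)
  models <- list()
  i <- 1
  while (i <= length(fields)) {
    stopifnot(fields[[i]][1] == "param")
    pn <- fields[[i]][2]
    grab <- function(k, name) {
      stopifnot(fields[[k]][1] == name)
      num(fields[[k]][-1])
    }
    V <- rbind(I = grab(i + 1, "V_I"), n = grab(i + 2, "V_n"))
    L <- grab(i + 3, "L")
    fs <- grab(i + 4, "feature_scale")
    lg <- grab(i + 5, "log_labels") == 1
    lc <- grab(i + 6, "label_center")
    ls <- grab(i + 7, "label_scale")
    hv <- grab(i + 8, "hyper")
    ts <- gp_training_set(V, L, label_name = pn, feature_scale = fs,
                          log_labels = lg)
    ts$label_center <- lc; ts$label_scale <- ls
    ts$ys <- ((if (lg) log10(L) else L) - lc) / ls
    models[[pn]] <- list(train = ts,
                         hyper = gp_hyperparams(hv[1], hv[2:3], hv[4]))
    i <- i + 9
  }
  structure(models, class = "param_surrogate")
}
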