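# NIR spectra travel either as single `nmr_spectrum` objects (domain
# "nir") or, for multivariate work, as a plain matrix with one row per
# sample and a `wavenumbers` vector describing the columns.

as_nir_matrix <- function(X, wavenumbers = NULL) {
  if (is_spectrum(X)) {
    wavenumbers <- X$axis
    X <- matrix(X$intensity, nrow = 1L)
  } else {
    X <- as.matrix(X)
    if (is.null(wavenumbers)) wavenumbers <- attr(X, "wavenumbers")
    if (is.null(wavenumbers))
      stop("`wavenumbers` required for matrix input", call. = FALSE)
  }
  list(X = X, wn = as.numeric(wavenumbers))
}

#' Standard normal variate (SNV) transform
#'
#' Per-spectrum standardization: subtract the spectrum mean and divide by
#' its standard deviation (sample convention, n-1 divisor).  Removes
#' multiplicative scatter gain and additive offsets.
#'
#' @param x an `nmr_spectrum` or a samples-by-wavenumbers matrix.
#' @return same shape as the input, each spectrum with mean 0 and SD 1.
#' @export
snv <- function(x) {
  if (is_spectrum(x)) {
    s <- stats::sd(x$intensity)
    if (!is.finite(s) || s == 0)
      stop("zero-variance spectrum: SNV undefined", call. = FALSE)
    x$intensity <- (x$intensity - mean(x$intensity)) / s
    return(x)
  }
  X <- as.matrix(x)
  s <- apply(X, 1L, stats::sd)
  if (any(!is.finite(s) | s == 0))
    stop("zero-variance spectrum: SNV undefined", call. = FALSE)
  out <- (X - rowMeans(X)) / s
  attr(out, "wavenumbers") <- attr(x, "wavenumbers")
  out
}

#' Restrict spectra to a wavenumber range
#'
#' @param x spectrum or matrix (see [snv()]).
#' @param lo,hi range bounds in cm-1 (order-insensitive).
#' @param wavenumbers column wavenumbers when `x` is a matrix.
#' @return restricted spectrum, or a list `(X, wn)` for matrix input.
#' @export
select_range <- function(x, lo, hi, wavenumbers = NULL) {
  b <- sort(c(lo, hi))
  if (is_spectrum(x)) {
    keep <- x$axis >= b[1] & x$axis <= b[2]
    if (sum(keep) < 2L) stop("range selects fewer than 2 points", call. = FALSE)
    return(new_spectrum(x$axis[keep], x$intensity[keep], domain = x$domain,
                        meta = x$meta))
  }
  m <- as_nir_matrix(x, wavenumbers)
  keep <- m$wn >= b[1] & m$wn <= b[2]
  if (sum(keep) < 2L) stop("range selects fewer than 2 points", call. = FALSE)
  list(X = m$X[, keep, drop = FALSE], wn = m$wn[keep])
}

#' Polynomial baseline correction within a wavenumber window
#'
#' Restricts the spectrum to `range`, fits a polynomial of the given
#' order to the support regions at the two window ends (default: the
#' outer 15\% of points on each side, where the analyte band is assumed
#' absent) and subtracts it across the window.  Order 0 with full support
#' reduces to mean subtraction.
#'
#' @param spec an NIR `nmr_spectrum`.
#' @param range `c(lo, hi)` window in cm-1.
#' @param order polynomial order (0, 2 or 3 in the delivered pipelines).
#' @param support_frac fraction of window points at each end used as
#'   baseline support; `1` uses the whole window.
#' @return the baseline-corrected window as an `nmr_spectrum`.
#' @export
poly_baseline <- function(spec, range, order = 3L, support_frac = 0.15) {
  stopifnot(is_spectrum(spec), order >= 0)
  w <- select_range(spec, range[1], range[2])
  n <- length(w$axis)
  if (n < order + 2L)
    stop("window has too few points for order ", order, call. = FALSE)
  k <- max(order + 1L, ceiling(support_frac * n))
  support <- if (2L * k >= n) seq_len(n) else c(seq_len(k), (n - k + 1L):n)
  xn <- (w$axis - mean(w$axis)) / (diff(range(w$axis)) / 2)
  B <- vapply(0:order, function(d) xn^d, numeric(n))
  fit <- stats::lm.fit(B[support, , drop = FALSE], w$intensity[support])
  w$intensity <- w$intensity - drop(B %*% fit$coefficients)
  w
}

#' Preprocessing pipeline specification
#'
#' Ordered list of steps applied to NIR spectra before PLSR.  Supported
#' steps: `list("select_range", lo, hi)`, `list("snv")`,
#' `list("poly_baseline", lo, hi, order)`,
#' `list("offset_baseline", lo, hi)` (order-0 polynomial).
#'
#' @param ... step descriptors.
#' @return a list of class `preprocess_spec`.
#' @export
preprocess_spec <- function(...) {
  structure(list(...), class = "preprocess_spec")
}

#' Apply a preprocessing pipeline to a spectra matrix
#'
#' @param X samples-by-wavenumbers matrix.
#' @param wn column wavenumbers, cm-1.
#' @param steps a [preprocess_spec()] (or `NULL` for a no-op).
#' @return list with the transformed `X` and its (possibly restricted)
#'   wavenumber vector `wn`.
#' @export
apply_preprocess <- function(X, wn, steps) {
  if (is.null(steps)) return(list(X = X, wn = wn))
  for (st in steps) {
    op <- st[[1L]]
    if (op == "select_range") {
      r <- select_range(X, st[[2L]], st[[3L]], wavenumbers = wn)
      X <- r$X; wn <- r$wn
    } else if (op == "snv") {
      attr(X, "wavenumbers") <- wn
      X <- snv(X)
    } else if (op %in% c("poly_baseline", "offset_baseline")) {
      ord <- if (op == "offset_baseline") 0L else st[[4L]]
      rows <- lapply(seq_len(nrow(X)), function(i) {
        s <- new_spectrum(wn, X[i, ], domain = "nir")
        poly_baseline(s, c(st[[2L]], st[[3L]]), order = ord)
      })
      wn <- rows[[1L]]$axis
      X <- do.call(rbind, lapply(rows, function(s) s$intensity))
    } else stop("unknown preprocessing step: ", op, call. = FALSE)
  }
  list(X = X, wn = wn)
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Latent-factor regression with mean centering and NIPALS deflation;
#' prediction is linear in a new (preprocessed) spectrum.  Requested
#' factors beyond the effective rank are truncated with a warning.
#'
#' @param X samples-by-variables predictor matrix (already preprocessed).
#' @param y reference concentrations, mol L-1.
#' @param n_factors number of latent factors.
#' @param preprocess optional [preprocess_spec()] recorded in (and applied
#'   by) [predict.plsr_model()]; when supplied, `X` is raw and
#'   `wavenumbers` must be given.
#' @param wavenumbers column wavenumbers of raw `X`.
#' @param analyte label stored with the model.
#' @return object of class `plsr_model`.
#' @export
fit_plsr <- function(X, y, n_factors, preprocess = NULL,
                     wavenumbers = NULL, analyte = "analyte") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows(X) != length(y)", call. = FALSE)
  if (length(y) < n_factors + 1L)
    stop("need at least n_factors + 1 samples", call. = FALSE)
  if (!is.null(preprocess)) {
    pp <- apply_preprocess(X, wavenumbers, preprocess)
    X <- pp$X; wavenumbers <- pp$wn
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean)
  f <- y - y_mean
  nv <- ncol(X)
  A <- min(n_factors, nrow(X) - 1L, nv)
  W <- P <- matrix(0, nv, A)
  q <- numeric(A)
  tol <- 1e-12 * (sum(E^2) + 1e-300)
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw^2 < tol) break
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < tol) break
    p <- drop(crossprod(E, tt)) / tt2
    qa <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, p)
    f <- f - tt * qa
    W[, a] <- w; P[, a] <- p; q[a] <- qa
    a_eff <- a
  }
  if (a_eff < n_factors)
    warning("rank-deficient predictors: factors truncated to ", a_eff)
  if (a_eff == 0L && stats::sd(y) > 1e-12 * (abs(y_mean) + 1))
    stop("no usable latent factor (constant X?)", call. = FALSE)
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  q <- q[seq_len(a_eff)]
  # constant response degenerates to the intercept-only model
  coefs <- if (a_eff > 0L) drop(W %*% solve(crossprod(P, W), q)) else
    numeric(nv)
  structure(list(n_factors = a_eff, x_mean = x_mean, y_mean = y_mean,
                 weights = W, loadings = P, y_loadings = q, coefs = coefs,
                 preprocess = preprocess, wavenumbers = wavenumbers,
                 analyte = analyte),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<PLSR model> %s: %d factor(s), %d variables\n",
              x$analyte, x$n_factors, length(x$x_mean)))
  invisible(x)
}

#' Predict concentrations from a fitted PLSR model
#'
#' @param object a `plsr_model`.
#' @param newdata samples-by-variables matrix (raw when the model stores a
#'   preprocessing pipeline).
#' @param wavenumbers column wavenumbers of raw `newdata`.
#' @param ... unused.
#' @return predicted concentrations, mol L-1.
#' @export
predict.plsr_model <- function(object, newdata, wavenumbers = NULL, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$preprocess)) {
    if (is.null(wavenumbers)) wavenumbers <- attr(newdata, "wavenumbers")
    pp <- apply_preprocess(X, wavenumbers, object$preprocess)
    X <- pp$X
  }
  drop(sweep(X, 2L, object$x_mean) %*% object$coefs) + object$y_mean
}

#' Cross-validated RMSE over a factor grid
#'
#' Random scheme: samples are partitioned into `segments` near-equal
#' segments by a seeded shuffle.  Systematic scheme: one run (production
#' day) is left out per fold.
#'
#' @param X raw predictor matrix.
#' @param y references, mol L-1.
#' @param scheme `list(type = "random", segments = 20, seed = 20171017)`
#'   or `list(type = "systematic", runs = <label per row>)`.
#' @param n_factors_grid factor counts to evaluate.
#' @param preprocess optional [preprocess_spec()] refitted inside each
#'   fold.
#' @param wavenumbers column wavenumbers of `X`.
#' @return object of class `validation_report`: `rmse_cv` (mmol L-1, one
#'   entry per grid value), `best_factors`, the folds used.
#' @export
cross_validate <- function(X, y, scheme, n_factors_grid,
                           preprocess = NULL, wavenumbers = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (identical(scheme$type, "random")) {
    k <- scheme$segments %||% 20L
    if (k > n) stop("more segments than samples", call. = FALSE)
    seed <- scheme$seed %||% 20171017L
    perm <- local({
      rng <- seed
      ord <- seq_len(n)    # Fisher-Yates with a small LCG, self-contained
      for (i in n:2) {
        rng <- (1103515245 * rng + 12345) %% 2147483648
        j <- (rng %% i) + 1
        tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
      }
      ord
    })
    folds <- split(perm, rep_len(seq_len(k), n))
  } else if (identical(scheme$type, "systematic")) {
    runs <- scheme$runs
    if (length(unique(runs)) < 2L)
      stop("systematic CV needs >= 2 distinct run labels", call. = FALSE)
    folds <- split(seq_len(n), runs)
  } else stop("unknown CV scheme", call. = FALSE)
  rmse <- sapply(n_factors_grid, function(a) {
    sq <- 0
    for (fold in folds) {
      m <- suppressWarnings(
        fit_plsr(X[-fold, , drop = FALSE], y[-fold], a,
                 preprocess = preprocess, wavenumbers = wavenumbers))
      yhat <- predict(m, X[fold, , drop = FALSE], wavenumbers = wavenumbers)
      sq <- sq + sum((yhat - y[fold])^2)
    }
    sqrt(sq / n) * 1000
  })
  structure(list(rmse_cv = stats::setNames(rmse, n_factors_grid),
                 best_factors = n_factors_grid[which.min(rmse)],
                 scheme = scheme$type, n_folds = length(folds)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation report> %s CV, %d fold(s)\n", x$scheme, x$n_folds))
  cat("RMSECV (mmol/L) by factor count:\n")
  print(round(x$rmse_cv, 2))
  invisible(x)
}

#' Test-set RMSE of a PLSR model
#'
#' @param model fitted `plsr_model`.
#' @param X_test,y_test held-out spectra and references (mol L-1).
#' @param wavenumbers column wavenumbers of raw `X_test`.
#' @return RMSE in mmol L-1; the parity data (`reference`, `predicted`,
#'   mol L-1) in `attr(, "parity")`.
#' @export
evaluate_test <- function(model, X_test, y_test, wavenumbers = NULL) {
  if (NROW(X_test) == 0L || !length(y_test))
    stop("empty test set", call. = FALSE)
  yhat <- predict(model, X_test, wavenumbers = wavenumbers)
  rmse <- sqrt(mean((yhat - y_test)^2)) * 1000
  attr(rmse, "parity") <- data.frame(reference = y_test, predicted = yhat)
  rmse
}

#' Default per-analyte NIR pipelines
#'
#' Factor counts and preprocessing mirroring the delivered calibration
#' configuration: aniline 1 factor, o-FNB 3, Li-NDPA 5, Li-aniline 4.
#' All pipelines start by restricting to the quantitatively usable
#' 4611-8957 cm-1 region (the flanks are noise/absorption dominated),
#' then SNV; o-FNB instead uses a third-order polynomial baseline over
#' its 5995-6307 cm-1 band.  Aniline and Li-aniline add a feature window
#' with a secondary baseline (window bounds are configuration, see the
#' package vignette).
#'
#' @return named list per analyte: `preprocess` ([preprocess_spec()]) and
#'   `n_factors`.
#' @export
analyte_pipelines <- function() {
  list(
    aniline = list(
      preprocess = preprocess_spec(list("select_range", 4611, 8957),
                                   list("snv"),
                                   list("poly_baseline", 5500, 6100, 2L)),
      n_factors = 1L),
    oFNB = list(
      preprocess = preprocess_spec(list("poly_baseline", 5995, 6307, 3L)),
      n_factors = 3L),
    LiNDPA = list(
      preprocess = preprocess_spec(list("select_range", 4611, 8957),
                                   list("snv")),
      n_factors = 5L),
    LiAniline = list(
      preprocess = preprocess_spec(list("select_range", 4611, 8957),
                                   list("snv"),
                                   list("offset_baseline", 6400, 7100)),
      n_factors = 4L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
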