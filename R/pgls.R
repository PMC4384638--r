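## Phylogenetic generalized least squares with fixed or ML-estimated
## Pagel's lambda.

new_gls_fit <- function(coefficients, standard_errors, t_values, df, p_values,
                        lambda, lambda_mode, sigma2, log_likelihood,
                        residuals, r2, n, method, df_convention,
                        lambda_profile = NULL, lambda_flat = FALSE) {
  structure(list(coefficients = coefficients,
                 standard_errors = standard_errors,
                 t_values = t_values, df = df, p_values = p_values,
                 lambda = lambda, lambda_mode = lambda_mode,
                 sigma2 = sigma2, log_likelihood = log_likelihood,
                 residuals = residuals, r2 = r2, n = n, method = method,
                 df_convention = df_convention,
                 lambda_profile = lambda_profile,
                 lambda_flat = lambda_flat),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d, df = %d, df convention: %s)\n",
              x$method, x$n, x$df, x$df_convention))
  if (!is.na(x$lambda))
    cat(sprintf("lambda = %.6g (%s)\n", x$lambda, x$lambda_mode))
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    t = x$t_values, p = x$p_values)
  print(tab, ...)
  if (!is.na(x$r2)) cat(sprintf("r2 = %.4f\n", x$r2))
  if (!is.na(x$log_likelihood))
    cat(sprintf("log-likelihood = %.4f\n", x$log_likelihood))
  invisible(x)
}

# shared design/response extraction; data rows must match V$taxa exactly
pgls_design <- function(formula, data, V) {
  stopifnot(inherits(V, "phylo_vcv"))
  if (is.null(rownames(data)))
    stop("'data' must have species as row names")
  if (!identical(rownames(data), V$taxa))
    stop("taxa mismatch between data rows and covariance: expected ",
         paste(utils::head(V$taxa, 3), collapse = ", "), ", ...")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  list(y = as.numeric(y), X = X)
}

fit_gls_fixed <- function(y, X, M) {
  # M: covariance matrix (already lambda-transformed)
  R <- tryCatch(chol(M), error = function(e)
    chol(M + diag(1e-10 * mean(diag(M)), nrow(M))))
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(Xw))]]
    stop("singular whitened design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  XtX_inv <- chol2inv(qr.R(qrX))
  logdet <- 2 * sum(log(diag(R)))
  list(beta = beta, rss = rss, XtX_inv = XtX_inv, logdet = logdet,
       resid_raw = as.numeric(y - X %*% beta), Xw = Xw, resid_w = as.numeric(resid_w))
}

#' Phylogenetic generalized least squares
#'
#' Linear regression whose error covariance is the (lambda-transformed)
#' phylogenetic covariance matrix: `y = X b + e`, `e ~ N(0, sigma2 * V_lambda)`.
#' An intercept is included via the formula interface. With `lambda = 0` on
#' an ultrametric tree, or with a covariance proportional to the identity,
#' the fit reduces exactly to ordinary least squares.
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data Data frame with species as row names, ordered exactly as
#'   `V$taxa` (see [align_table_and_tree()]).
#' @param V An untransformed `"phylo_vcv"`.
#' @param lambda A number in `[0, 1]`, or `"ml"` to maximize the profile
#'   likelihood via [estimate_lambda_ml()].
#' @param df_convention `"paper"` fixes the t-test degrees of freedom at
#'   `n - 3` (the convention of the study reproduced here, for both the
#'   single- and the two-covariate model); `"standard"` uses
#'   `n - ncol(model matrix)`.
#' @param reml Use REML rather than ML for the lambda estimate when
#'   `lambda = "ml"`.
#' @return A `"gls_fit"`: coefficients, standard errors, t values, two-tailed
#'   p values, lambda used, `sigma2` (= RSS/df on the whitened scale),
#'   ML log-likelihood, raw-scale residuals, and r2 (squared correlation of
#'   observed and fitted values).
#' @export
pgls_fit <- function(formula, data, V, lambda = 1,
                     df_convention = c("paper", "standard"), reml = FALSE) {
  df_convention <- match.arg(df_convention)
  d <- pgls_design(formula, data, V)
  y <- d$y; X <- d$X
  n <- length(y)

  lambda_mode <- "fixed"
  lambda_profile <- NULL
  lambda_flat <- FALSE
  if (identical(lambda, "ml")) {
    est <- estimate_lambda_ml(formula, data, V, reml = reml)
    lambda <- est$lambda_hat
    lambda_mode <- if (reml) "reml" else "ml"
    lambda_profile <- est$profile
    lambda_flat <- est$flat
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("'lambda' must be a number in [0, 1] or \"ml\"")

  M <- lambda_transform(V, lambda)$V
  f <- fit_gls_fixed(y, X, M)

  k <- ncol(X)
  df <- if (df_convention == "paper") n - 3L else n - k
  if (df < 1L) stop("non-positive residual degrees of freedom")
  s2 <- f$rss / df
  se <- sqrt(s2 * diag(f$XtX_inv))
  names(se) <- colnames(X)
  tval <- as.numeric(f$beta) / se
  names(tval) <- colnames(X)
  p <- student_t_two_tailed_p(tval, df)
  names(p) <- colnames(X)

  sig2_ml <- f$rss / n
  ll <- -0.5 * (n * log(2 * pi * sig2_ml) + f$logdet + n)
  fitted <- y - f$resid_raw
  r2 <- if (stats::sd(fitted) > 0 && stats::sd(y) > 0)
    stats::cor(y, fitted)^2 else NA_real_

  beta <- as.numeric(f$beta)
  names(beta) <- colnames(X)
  res <- f$resid_raw
  names(res) <- V$taxa
  new_gls_fit(coefficients = beta, standard_errors = se, t_values = tval,
              df = df, p_values = p, lambda = lambda,
              lambda_mode = lambda_mode, sigma2 = s2, log_likelihood = ll,
              residuals = res, r2 = r2, n = n, method = "PGLS",
              df_convention = df_convention,
              lambda_profile = lambda_profile, lambda_flat = lambda_flat)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles the Gaussian (ML, or optionally REML) log-likelihood of the
#' regression over `lambda` in `[0, 1]`: a 41-point grid locates the basin,
#' then golden-section search refines the maximum to a tolerance of `1e-6`.
#' Boundary maxima are reported exactly as 0 or 1.
#'
#' Internally `V_lambda = lambda * V + (1 - lambda) * diag(V)` is
#' diagonalized once via the eigendecomposition of
#' `D^{-1/2} V D^{-1/2}` (`D` = diagonal of `V`), after which each
#' likelihood evaluation is a weighted least-squares solve.
#'
#' @inheritParams pgls_fit
#' @param reml Profile the REML rather than the ML criterion.
#' @return A list: `lambda_hat`, `profile` (data frame of the grid
#'   `lambda`/`log_likelihood`), `flat` (`TRUE` when the likelihood is flat
#'   in lambda, e.g. on a star tree, in which case `lambda_hat` is `NA`),
#'   `boundary` (`"none"`, `"lower"` or `"upper"`).
#' @export
estimate_lambda_ml <- function(formula, data, V, reml = FALSE) {
  d <- pgls_design(formula, data, V)
  y <- d$y; X <- d$X
  n <- length(y)
  k <- ncol(X)

  Dh <- sqrt(diag(V$V))
  if (any(Dh <= 0))
    stop("zero-depth leaf: covariance diagonal must be positive for lambda estimation")
  W <- V$V / tcrossprod(Dh)          # unit diagonal
  eig <- eigen(W, symmetric = TRUE)
  Q <- eig$vectors
  ev <- pmax(eig$values, 0)
  ys <- crossprod(Q, y / Dh)         # rotated, scaled response
  Xs <- crossprod(Q, X / Dh)
  logdetD <- 2 * sum(log(Dh))

  loglik <- function(lam) {
    w <- pmax(lam * ev + (1 - lam), 1e-12)
    sw <- sqrt(w)
    yw <- ys / sw
    Xw <- Xs / sw
    qrX <- qr(Xw)
    if (qrX$rank < k) return(-Inf)
    rss <- sum(qr.resid(qrX, yw)^2)
    logdet <- logdetD + sum(log(w))
    if (reml) {
      XtX <- crossprod(Xw)
      -0.5 * ((n - k) * log(2 * pi * rss / (n - k)) + logdet +
                determinant(XtX, logarithm = TRUE)$modulus + (n - k))
    } else {
      -0.5 * (n * log(2 * pi * rss / n) + logdet + n)
    }
  }

  grid <- seq(0, 1, length.out = 41L)
  ll <- vapply(grid, loglik, numeric(1L))
  profile <- data.frame(lambda = grid, log_likelihood = ll)

  if (max(ll) - min(ll) < 1e-9) {
    return(list(lambda_hat = NA_real_, profile = profile, flat = TRUE,
                boundary = "none"))
  }

  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(loglik, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-6)
  lambda_hat <- opt$maximum
  boundary <- "none"
  # snap to a boundary when the boundary value is at least as good
  if (loglik(0) >= opt$objective) { lambda_hat <- 0; boundary <- "lower" }
  if (loglik(1) >= opt$objective) { lambda_hat <- 1; boundary <- "upper" }
  if (lambda_hat < 1e-6) { lambda_hat <- 0; boundary <- "lower" }
  if (lambda_hat > 1 - 1e-6) { lambda_hat <- 1; boundary <- "upper" }

  list(lambda_hat = lambda_hat, profile = profile, flat = FALSE,
       boundary = boundary)
}

#' Phylogenetic residuals of a trait on a covariate
#'
#' Residuals (on the raw scale) of `trait ~ covariate` fitted by PGLS at the
#' given lambda. Used pairwise to draw residual-residual scatter plots: the
#' association of two traits after removing a common covariate and the
#' phylogenetic structure.
#'
#' @param trait,covariate Named numeric vectors over the same taxa as `V`.
#' @param V An untransformed `"phylo_vcv"`.
#' @param lambda A number in `[0, 1]`.
#' @return Named numeric vector of residuals, one per taxon.
#' @export
pgls_residualize <- function(trait, covariate, V, lambda = 1) {
  stopifnot(inherits(V, "phylo_vcv"))
  dat <- data.frame(.y = as.numeric(trait[V$taxa]),
                    .x = as.numeric(covariate[V$taxa]),
                    row.names = V$taxa)
  if (anyNA(dat)) stop("trait or covariate missing for some taxa")
  fit <- pgls_fit(.y ~ .x, dat, V, lambda = lambda,
                  df_convention = "standard")
  fit$residuals
}
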