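#' Specify a two-level random-intercept linear model
#'
#' @param outcome name of the outcome column.
#' @param fixed character vector of fixed-effect columns (continuous or
#'   categorical). Categorical columns are dummy-coded against the reference
#'   level given in `ref_levels` (first observed level otherwise).
#' @param group name of the grouping (cluster) column.
#' @param ref_levels named list mapping categorical columns to their
#'   reference level.
#' @param method `"REML"` (default) or `"ML"`.
#' @param transform outcome transform applied before fitting: `"identity"`
#'   or `"log1p"`.
#' @return a `ppa_model_spec` object.
#' @export
model_spec <- function(outcome, fixed, group, ref_levels = list(),
                       method = c("REML", "ML"),
                       transform = c("identity", "log1p")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  structure(list(outcome = outcome, fixed = fixed, group = group,
                 ref_levels = ref_levels, method = method,
                 transform = transform),
            class = "ppa_model_spec")
}

# Build the fixed-effect design matrix with declared reference levels.
build_design <- function(data, spec) {
  if (length(spec$fixed) == 0L)
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  df <- data[, spec$fixed, drop = FALSE]
  dropped <- character(0)
  for (v in spec$fixed) {
    if (is.character(df[[v]]) || is.factor(df[[v]]) || is.logical(df[[v]])) {
      f <- factor(df[[v]])
      if (nlevels(f) < 2L) {  # e.g. a filter removed all contrast
        df[[v]] <- NULL
        dropped <- c(dropped, v)
        next
      }
      ref <- spec$ref_levels[[v]]
      if (!is.null(ref) && ref %in% levels(f))
        f <- stats::relevel(f, ref = ref)
      else if (!is.null(ref) && !ref %in% levels(f))
        stop(sprintf("reference level '%s' not present in column '%s'",
                     ref, v))
      df[[v]] <- f
    }
  }
  X <- if (ncol(df) == 0L)
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(~ ., data = df)
  attr(X, "dropped_terms") <- dropped
  X
}

apply_transform <- function(y, transform) {
  switch(transform, identity = y, log1p = log1p(y),
         stop("unknown transform: ", transform))
}

# Profiled (restricted) log-likelihood machinery. For the random-intercept
# model V = sigma2_e * (I + lambda Z Z'), the inverse is block diagonal with
# W_j = I - c_j 1 1', c_j = lambda / (1 + lambda n_j), so all quantities
# reduce to per-group cross products.
profile_parts <- function(lambda, Xg, yg, XtX, Xty, yty, Xt1, yt1, nj) {
  cj <- lambda / (1 + lambda * nj)
  p <- ncol(XtX[[1]])
  Sxx <- matrix(0, p, p)
  Sxy <- numeric(p)
  Syy <- 0
  for (j in seq_along(nj)) {
    Sxx <- Sxx + XtX[[j]] - cj[j] * tcrossprod(Xt1[[j]])
    Sxy <- Sxy + Xty[[j]] - cj[j] * Xt1[[j]] * yt1[j]
    Syy <- Syy + yty[j] - cj[j] * yt1[j]^2
  }
  beta <- solve(Sxx, Sxy)
  q <- max(Syy - sum(Sxy * beta), 1e-300)  # residual quadratic form
  list(Sxx = Sxx, beta = beta, q = q, logdet_A = sum(log1p(lambda * nj)))
}

# Profiled log-likelihood at a given variance ratio lambda = s2u/s2e.
profile_loglik <- function(lambda, parts_fn, n, p, method) {
  pp <- parts_fn(lambda)
  if (method == "ML") {
    s2e <- pp$q / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2e) + pp$logdet_A + n)
  } else {
    s2e <- pp$q / (n - p)
    ld_sxx <- as.numeric(determinant(pp$Sxx, logarithm = TRUE)$modulus)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2e) +
                    pp$logdet_A + ld_sxx + (n - p))
  }
  list(loglik = ll, s2e = s2e, parts = pp)
}

#' Fit a two-level random-intercept linear model
#'
#' Fits `y_ij = x_ij' beta + u_j + e_ij` with `u_j ~ N(0, sigma2_u)` and
#' `e_ij ~ N(0, sigma2_e)` by profiling the (restricted) log-likelihood over
#' the variance ratio `lambda = sigma2_u / sigma2_e`: one-dimensional bounded
#' optimisation on `log(lambda)` plus an explicit check of the `lambda = 0`
#' boundary, generalised least squares for `beta` at the optimum, and
#' standard errors from the inverse weighted cross-product of the design.
#' Rows with missing values in modelled columns are dropped listwise (the
#' count is recorded in the fit).
#'
#' @param data a data.frame with outcome, fixed-effect and group columns.
#' @param spec a [model_spec()].
#' @return an `mlm_fit` object: coefficient table (with Wald z, p and
#'   significance stars), `sigma2_u`, `sigma2_e`, `icc`, `loglik`,
#'   `aic = -2 loglik + 2 (p_fixed + 2)`, sample sizes, method and
#'   convergence flag.
#' @export
fit_random_intercept <- function(data, spec) {
  stopifnot(inherits(spec, "ppa_model_spec"))
  data <- as.data.frame(data)
  used <- c(spec$outcome, spec$fixed, spec$group)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(data[, used, drop = FALSE])
  n_dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]

  g <- factor(data[[spec$group]])
  if (nlevels(g) < 2L) stop("grouping variable must have at least 2 groups")
  y <- apply_transform(as.numeric(data[[spec$outcome]]), spec$transform)
  X <- build_design(data, spec)
  p <- ncol(X)
  n <- nrow(X)

  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }

  # per-group sufficient statistics
  idx <- split(seq_len(n), g)
  nj <- lengths(idx)
  XtX <- lapply(idx, function(i) crossprod(X[i, , drop = FALSE]))
  Xty <- lapply(idx, function(i) crossprod(X[i, , drop = FALSE], y[i]))
  Xt1 <- lapply(idx, function(i) colSums(X[i, , drop = FALSE]))
  yty <- vapply(idx, function(i) sum(y[i]^2), 0)
  yt1 <- vapply(idx, function(i) sum(y[i]), 0)
  parts_fn <- function(lambda)
    profile_parts(lambda, NULL, NULL, XtX, Xty, yty, Xt1, yt1, nj)

  obj <- function(loglam)
    profile_loglik(exp(loglam), parts_fn, n, p, spec$method)$loglik
  opt <- stats::optimize(obj, interval = c(log(1e-10), log(1e8)),
                         maximum = TRUE, tol = 1e-10)
  at_boundary <- profile_loglik(0, parts_fn, n, p, spec$method)
  if (at_boundary$loglik >= opt$objective) {
    lambda <- 0
    sol <- at_boundary
  } else {
    lambda <- exp(opt$maximum)
    sol <- profile_loglik(lambda, parts_fn, n, p, spec$method)
  }
  converged <- is.finite(sol$loglik)

  s2e <- sol$s2e
  s2u <- lambda * s2e
  beta <- as.numeric(sol$parts$beta)
  vcov_beta <- s2e * solve(sol$parts$Sxx)
  se <- sqrt(diag(vcov_beta))
  names(beta) <- names(se) <- colnames(X)

  fit <- structure(list(
    beta = beta, se = se, vcov = vcov_beta,
    sigma2_u = s2u, sigma2_e = s2e,
    icc = icc(s2u, s2e),
    loglik = sol$loglik,
    aic = -2 * sol$loglik + 2 * (p + 2),
    n_individuals = n, n_groups = nlevels(g), n_dropped = n_dropped,
    lambda = lambda, method = spec$method, converged = converged,
    dropped_terms = attr(X, "dropped_terms"),
    spec = spec, design_colnames = colnames(X), X = X, group = g
  ), class = "mlm_fit")
  fit$coefficients <- wald_table(fit)
  if (!converged)
    warning("fit did not converge; profiled log-likelihood non-finite")
  fit
}

#' Intraclass correlation coefficient
#'
#' Share of total outcome variance attributable to the grouping level:
#' `sigma2_u / (sigma2_u + sigma2_e)`.
#'
#' @param sigma2_u between-group variance (>= 0).
#' @param sigma2_e within-group residual variance.
#' @return the ICC, in `[0, 1)`.
#' @examples
#' icc(0.022, 0.141) # 0.135
#' @export
icc <- function(sigma2_u, sigma2_e) {
  if (sigma2_u < 0 || sigma2_e < 0) stop("variances must be non-negative")
  tot <- sigma2_u + sigma2_e
  if (tot == 0) stop("ICC undefined: both variance components are zero")
  sigma2_u / tot
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from regressing design column `k` on all other
#' columns (with an intercept). A perfectly collinear column is reported as
#' `Inf` and flagged rather than raising an error.
#'
#' @param design numeric design matrix; an intercept/constant column is
#'   detected and excluded from the per-predictor set.
#' @return list with `table` (predictor, vif, flag), `max` and `mean`
#'   (computed over finite entries; `max` is `Inf` if any column is flagged).
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  keep <- apply(design, 2, function(col) stats::var(col) > 0)
  X <- design[, keep, drop = FALSE]
  if (ncol(X) < 2L) stop("need at least 2 non-constant predictor columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  k <- ncol(X)
  out <- data.frame(predictor = colnames(X), vif = NA_real_,
                    collinear = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    xi <- X[, i]
    others <- cbind(1, X[, -i, drop = FALSE])
    fit <- stats::lm.fit(others, xi)
    rss <- sum(fit$residuals^2)
    tss <- sum((xi - mean(xi))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) {
      out$vif[i] <- Inf
      out$collinear[i] <- TRUE
    } else {
      out$vif[i] <- 1 / (1 - r2)
    }
  }
  list(table = out,
       max = if (any(out$collinear)) Inf else max(out$vif),
       mean = mean(out$vif[is.finite(out$vif)]))
}

#' Wald coefficient table with significance stars
#'
#' Computes `z = beta / SE`, two-sided normal p-values, and stars at the
#' conventional reporting thresholds: `***` p < 0.010, `**` p < 0.050,
#' `*` p < 0.100 (strict inequalities).
#'
#' @param fit an `mlm_fit`, or a numeric vector of estimates (then `se`
#'   must be given).
#' @param se standard errors when `fit` is a plain numeric vector.
#' @return data.frame with term, estimate, se, z, p and stars.
#' @export
wald_table <- function(fit, se = NULL) {
  if (inherits(fit, "mlm_fit")) {
    beta <- fit$beta
    se <- fit$se
  } else {
    beta <- fit
    if (is.null(se)) stop("se required when fit is a numeric vector")
  }
  z <- ifelse(se > 0, beta / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  stars <- ifelse(p < 0.010, "***", ifelse(p < 0.050, "**",
                  ifelse(p < 0.100, "*", "")))
  data.frame(term = if (is.null(names(beta))) seq_along(beta) else names(beta),
             estimate = as.numeric(beta), se = as.numeric(se),
             z = as.numeric(z), p = as.numeric(p), stars = stars,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.mlm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Random-intercept linear model (%s)\n", x$method))
  ct <- x$coefficients
  ct$estimate <- round(ct$estimate, digits)
  ct$se <- round(ct$se, digits)
  ct$z <- round(ct$z, digits)
  ct$p <- signif(ct$p, digits)
  print(ct, row.names = FALSE)
  cat(sprintf("Var (groups) %.4f | Var (residual) %.4f | ICC %.4f\n",
              x$sigma2_u, x$sigma2_e, x$icc))
  cat(sprintf("logLik %.3f | AIC %.3f | n = %d in %d groups\n",
              x$loglik, x$aic, x$n_individuals, x$n_groups))
  invisible(x)
}
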