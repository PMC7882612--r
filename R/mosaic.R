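#' Site-level fly density
#'
#' A site's density of one fly species (individuals per square metre) is
#' reconstructed from per-plant-species survey records: the number of
#' flies per flowerhead on each plant species times that plant's
#' flowerhead density per m^2, summed over the plant species surveyed at
#' the site.
#'
#' @param records Data frame with columns `site_id`, `fly_species`,
#'   `plant_species`, `flies_per_flowerhead`, `flowerheads_per_m2`.
#' @param site_id Site to evaluate.
#' @param fly_species Fly species to evaluate.
#' @return Density (individuals per m^2).
#' @export
fly_density_per_m2 <- function(records, site_id, fly_species) {
  need <- c("site_id", "fly_species", "plant_species",
            "flies_per_flowerhead", "flowerheads_per_m2")
  stopifnot(all(need %in% names(records)))
  r <- records[records$site_id == site_id & records$fly_species == fly_species, ]
  if (nrow(r) == 0) {
    stop(sprintf("fly_density_per_m2: no survey records for site '%s', fly '%s'",
                 site_id, fly_species))
  }
  if (any(r$flies_per_flowerhead < 0) || any(r$flowerheads_per_m2 < 0)) {
    stop("fly_density_per_m2: densities must be nonnegative")
  }
  sum(r$flies_per_flowerhead * r$flowerheads_per_m2)
}

#' Binary site flower-colour code
#'
#' Codes a site 1 when only the orange focal species are present, 0 when
#' only white ones are; sites with neither get `NA`. Because the analysis
#' assumes colours never co-occur, a site listing both colours is an
#' error, not silently recoded.
#'
#' @param colors Character vector of focal-species flower colours observed
#'   at the site (`"orange"` / `"white"`).
#' @return `1`, `0`, or `NA_real_`.
#' @export
site_color_code <- function(colors) {
  colors <- unique(colors[!is.na(colors)])
  bad <- setdiff(colors, c("orange", "white"))
  if (length(bad)) stop(sprintf("site_color_code: unknown colour '%s'", bad[1]))
  has_o <- "orange" %in% colors
  has_w <- "white" %in% colors
  if (has_o && has_w) {
    stop("site_color_code: data-consistency error, both colours present at one site")
  }
  if (has_o) 1 else if (has_w) 0 else NA_real_
}

# shared: log-likelihood and info pieces for a logit model
.logit_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

.logit_pieces <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pi * (1 - pi)
  XtW <- t(X * w)
  I <- XtW %*% X
  list(pi = pi, w = w, I = I)
}

#' Ordinary maximum-likelihood logistic regression
#'
#' Fits a logit model by iteratively reweighted least squares
#' (`stats::glm`) and flags (rather than reports) divergent estimates:
#' a fit is marked `separated` when IRLS fails to converge within
#' `maxit` steps, any coefficient magnitude exceeds `guard`, or fitted
#' probabilities are numerically pinned at 0/1 -- the signatures of
#' complete or quasi-complete separation.
#'
#' @param y Binary response vector (0/1).
#' @param x Numeric predictor matrix or vector (an intercept column is
#'   added automatically).
#' @param guard Coefficient-magnitude guard (default 50).
#' @param maxit Maximum IRLS iterations (default 100).
#' @return Object of class `logistic_fit`: `coefficients`, `se`, `z`,
#'   `p`, `loglik`, `converged`, `separated`, `method = "mle"`, `n`,
#'   `df_residual`.
#' @export
logistic_fit_mle <- function(y, x = NULL, guard = 50, maxit = 100) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("logistic_fit_mle: response must be 0/1")
  if (all(y == 0) || all(y == 1)) {
    stop("logistic_fit_mle: degenerate response (all 0 or all 1)")
  }
  X <- .design_with_intercept(x, length(y))
  if (nrow(X) < ncol(X) + 1) stop("logistic_fit_mle: need n >= p + 1")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = maxit))
  )
  beta <- fit$coefficients
  pieces <- .logit_pieces(beta, X, y)
  # separation leaves fitted probabilities pinned at 0/1 (IRLS may still
  # report convergence there), or sends coefficients past the guard
  pinned <- any(pieces$pi < 1e-8 | pieces$pi > 1 - 1e-8)
  separated <- !fit$converged || any(abs(beta) > guard) || pinned
  cov <- tryCatch(solve(pieces$I), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(cov))
  z <- beta / se
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(z, colnames(X)),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    loglik = .logit_loglik(beta, X, y),
    converged = fit$converged, separated = separated,
    method = "mle", n = length(y), df_residual = length(y) - 1
  ), class = "logistic_fit")
}

.design_with_intercept <- function(x, n) {
  if (is.null(x)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    stopifnot(nrow(x) == n)
    X <- cbind("(Intercept)" = 1, x)
  }
  storage.mode(X) <- "double"
  X
}

# Firth-penalized log-likelihood: l(beta) + 0.5 log det I(beta).
.firth_loglik <- function(beta, X, y) {
  pieces <- .logit_pieces(beta, X, y)
  d <- determinant(pieces$I, logarithm = TRUE)
  .logit_loglik(beta, X, y) + 0.5 * as.numeric(d$modulus)
}

# Newton iterations on the modified score, with step-halving on the
# penalized likelihood. `free` marks the coefficients being maximized over
# (others stay fixed), which gives the profile fits for LR tests.
.firth_newton <- function(X, y, beta0 = NULL, free = NULL,
                          tol = 1e-8, maxit = 100) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  if (is.null(free)) free <- rep(TRUE, p)
  ll <- .firth_loglik(beta, X, y)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    pieces <- .logit_pieces(beta, X, y)
    Ifull <- pieces$I
    # hat values of the weighted design
    sw <- sqrt(pieces$w)
    Xs <- X * sw
    Iinv <- tryCatch(solve(Ifull), error = function(e) {
      stop("logistic_fit_firth: rank error, singular information matrix")
    })
    h <- rowSums((Xs %*% Iinv) * Xs)
    ustar <- drop(t(X) %*% (y - pieces$pi + h * (0.5 - pieces$pi)))
    uf <- ustar[free]
    if (sqrt(sum(uf^2)) < tol) { converged <- TRUE; break }
    If <- Ifull[free, free, drop = FALSE]
    step <- drop(solve(If, uf))
    # step-halving on the penalized likelihood
    lambda <- 1
    repeat {
      cand <- beta
      cand[free] <- beta[free] + lambda * step
      llc <- .firth_loglik(cand, X, y)
      if (llc >= ll - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- beta
    beta[free] <- beta[free] + lambda * step
    ll <- .firth_loglik(beta, X, y)
  }
  list(beta = beta, loglik = ll, converged = converged, iter = it)
}

#' Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' `l*(beta) = l(beta) + 0.5 log det I(beta)` by Newton iterations on the
#' modified score `U*_j = sum_i (y_i - pi_i + h_i (1/2 - pi_i)) x_ij`
#' (with `h_i` the hat values of the weighted design), yielding finite
#' coefficient estimates even under complete separation. Inference
#' defaults to penalized likelihood-ratio tests per slope (profile fit
#' with that slope fixed at 0), with Wald statistics as secondary output.
#'
#' @inheritParams logistic_fit_mle
#' @param tol Convergence tolerance on the modified-score norm.
#' @param maxit Maximum Newton iterations.
#' @return Object of class `logistic_fit` with `method = "firth"`, plus
#'   `loglik` (penalized, at optimum), and for each slope `lr` and
#'   `p_lr` (penalized LR chi-square with 1 df).
#' @export
logistic_fit_firth <- function(y, x = NULL, tol = 1e-8, maxit = 100) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("logistic_fit_firth: response must be 0/1")
  X <- .design_with_intercept(x, length(y))
  if (nrow(X) < ncol(X) + 1) stop("logistic_fit_firth: need n >= p + 1")
  full <- .firth_newton(X, y, tol = tol, maxit = maxit)
  beta <- full$beta
  pieces <- .logit_pieces(beta, X, y)
  cov <- solve(pieces$I)
  se <- sqrt(diag(cov))
  z <- beta / se
  k <- ncol(X)
  lr <- p_lr <- rep(NA_real_, k)
  if (k > 1) {
    for (j in 2:k) {
      free <- rep(TRUE, k); free[j] <- FALSE
      restr <- .firth_newton(X, y, beta0 = replace(beta, j, 0), free = free,
                             tol = tol, maxit = maxit)
      lr[j] <- max(0, 2 * (full$loglik - restr$loglik))
      p_lr[j] <- stats::pchisq(lr[j], df = 1, lower.tail = FALSE)
    }
  }
  nm <- colnames(X)
  structure(list(
    coefficients = stats::setNames(beta, nm),
    se = stats::setNames(se, nm),
    z = stats::setNames(z, nm),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), nm),
    lr = stats::setNames(lr, nm),
    p_lr = stats::setNames(p_lr, nm),
    loglik = full$loglik,
    converged = full$converged, separated = FALSE,
    method = "firth", n = length(y), df_residual = length(y) - 1
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> method=%s, n=%d, %s\n", x$method, x$n,
              if (isTRUE(x$separated)) "SEPARATED (estimates unreliable)"
              else if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p)
  if (!is.null(x$lr)) { tab$LR <- x$lr; tab$p_LR <- x$p_lr }
  print(round(tab, 4))
  invisible(x)
}
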