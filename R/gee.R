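#' Build a GEE design from choice trials
#'
#' Expands choice-trial records (one row per recorded flower visit) into
#' the response / cluster / design triple the GEE fitter consumes. The
#' response is 1 when the orange flower was chosen. Treatment coding with
#' fixed, documented reference levels keeps coefficient signs
#' reproducible: `C_nigripes` (fly species), `pale` (soil), `pre`
#' (conditioning phase).
#'
#' @param trials Data frame with columns `fly_id`, `fly_species`,
#'   `genus_pair`, `phase`, `choice_order`, `flower_color`, `soil`.
#' @param formula Character vector of predictors from
#'   `c("species", "soil", "species:soil", "phase")`; may be empty for an
#'   intercept-only model.
#' @param require_both_soils If `TRUE`, flies that never visited flowers
#'   on both soil types are excluded (with a message listing them), as in
#'   the experimental protocol.
#' @return List with `y` (0/1 vector), `x` (model matrix without
#'   intercept; `NULL` for intercept-only), `cluster` (factor),
#'   `data` (the retained rows), `excluded` (fly ids dropped), and
#'   `xlevels` (reference-level bookkeeping for marginal means).
#' @export
build_design <- function(trials,
                         formula = c("species", "soil", "species:soil"),
                         require_both_soils = FALSE) {
  need <- c("fly_id", "fly_species", "flower_color", "soil")
  stopifnot(all(need %in% names(trials)))
  known <- c("species", "soil", "species:soil", "phase")
  if (!all(formula %in% known)) {
    stop(sprintf("build_design: unknown predictor '%s'",
                 setdiff(formula, known)[1]))
  }
  ok_col <- c("orange", "white"); ok_soil <- c("red", "pale")
  ok_sp <- c("M_capensis", "C_nigripes")
  if (!all(trials$flower_color %in% ok_col)) {
    stop("build_design: input error, flower_color must be orange/white")
  }
  if (!all(trials$soil %in% ok_soil)) {
    stop("build_design: input error, soil must be red/pale")
  }
  if (!all(trials$fly_species %in% ok_sp)) {
    stop("build_design: input error, fly_species must be M_capensis/C_nigripes")
  }
  excluded <- character(0)
  if (require_both_soils) {
    soils_seen <- tapply(trials$soil, trials$fly_id,
                         function(s) length(unique(s)))
    excluded <- names(soils_seen)[soils_seen < 2]
    if (length(excluded)) {
      message(sprintf("build_design: excluded %d fly(ies) not visiting both soils: %s",
                      length(excluded), paste(excluded, collapse = ", ")))
      trials <- trials[!trials$fly_id %in% excluded, ]
    }
  }
  if (length(unique(trials$fly_id)) < 2) {
    stop("build_design: input error, need >= 2 flies (clusters)")
  }
  d <- trials
  d$species <- factor(d$fly_species, levels = ok_sp[c(2, 1)])  # ref C_nigripes
  d$soil <- factor(d$soil, levels = c("pale", "red"))
  if ("phase" %in% names(d)) {
    d$phase <- factor(d$phase, levels = intersect(c("pre", "post_1h", "post_1d"),
                                                  unique(d$phase)))
  }
  terms <- unique(formula)
  if ("species:soil" %in% terms) {
    terms <- union(terms, c("species", "soil"))  # hierarchy
    terms <- c(setdiff(terms, "species:soil"), "species:soil")
  }
  if (length(terms) == 0) {
    X <- NULL
  } else {
    fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    mm <- stats::model.matrix(fml, d)
    X <- mm[, -1, drop = FALSE]
  }
  list(y = as.numeric(d$flower_color == "orange"),
       x = X,
       cluster = factor(d$fly_id, levels = unique(d$fly_id)),
       data = d,
       excluded = excluded,
       terms = terms,
       xlevels = list(species = levels(d$species), soil = levels(d$soil),
                      phase = if ("phase" %in% names(d)) levels(d$phase)))
}

#' Generalized estimating equations for clustered binary choices
#'
#' Liang-Zeger GEE for a binary response with logit link and exchangeable
#' working correlation. Coefficients start at the independence GLM and are
#' updated by Fisher scoring on the estimating equations
#' `sum_i D_i' V_i^{-1} (y_i - mu_i) = 0`; between updates the working
#' correlation `alpha` is re-estimated by moment matching on Pearson
#' residual cross-products (dispersion `phi` is fixed at 1 for binary data
#' unless `estimate_phi = TRUE`). The reported covariance is a
#' leave-one-cluster-out jackknife: by default the one-step (influence
#' function) approximation, with the full-refit jackknife available for
#' cross-checking.
#'
#' @param y Binary response (0/1).
#' @param x Predictor matrix (or `NULL` for intercept-only); an intercept
#'   column is added automatically.
#' @param cluster Cluster identifier (one level per fly).
#' @param jackknife `"one_step"` (default) or `"full"` refit.
#' @param estimate_phi Estimate the dispersion from Pearson residuals
#'   instead of fixing it at 1.
#' @param alpha Optional fixed working correlation (skips moment
#'   estimation); `alpha = 0` reproduces the independence model.
#' @param tol,maxit Fisher-scoring convergence controls.
#' @return Object of class `gee_fit`: `coefficients`, `vcov` (jackknife),
#'   `vcov_naive`, `alpha`, `phi`, `n_clusters`, `converged`, plus the
#'   design bookkeeping needed by [gee_emmeans()].
#' @export
gee_fit <- function(y, x = NULL, cluster, jackknife = c("one_step", "full"),
                    estimate_phi = FALSE, alpha = NULL,
                    tol = 1e-10, maxit = 200) {
  jackknife <- match.arg(jackknife)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  X <- .design_with_intercept(x, length(y))
  cluster <- as.factor(cluster)
  stopifnot(length(cluster) == length(y))
  K <- nlevels(droplevels(cluster))
  if (K < 2) stop("gee_fit: need >= 2 clusters")
  idx <- split(seq_along(y), droplevels(cluster))
  p <- ncol(X)
  nmax <- max(lengths(idx))

  # independence GLM start
  beta <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients
  )
  fixed_alpha <- !is.null(alpha)
  a <- if (fixed_alpha) alpha else 0
  phi <- 1
  converged <- FALSE
  alpha_clipped <- FALSE

  est_moments <- function(beta) {
    mu <- stats::plogis(drop(X %*% beta))
    r <- (y - mu) / sqrt(mu * (1 - mu))
    ph <- if (estimate_phi) sum(r^2) / (length(y) - p) else 1
    num <- 0; den <- 0
    for (ii in idx) {
      ni <- length(ii)
      if (ni > 1) {
        ri <- r[ii]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    al <- if (den > p) num / (ph * (den - p)) else 0
    list(phi = ph, alpha = al)
  }

  for (it in seq_len(maxit)) {
    if (!fixed_alpha) {
      m <- est_moments(beta)
      phi <- m$phi
      a <- m$alpha
      lo <- -1 / (nmax - 1) + 1e-6
      if (nmax > 1 && (a <= lo || a >= 1)) {
        a_new <- min(max(a, lo), 1 - 1e-6)
        warning(sprintf("gee_fit: working correlation %.3f outside admissible range, clipped to %.3f",
                        a, a_new))
        a <- a_new
        alpha_clipped <- TRUE
      }
    }
    mu <- stats::plogis(drop(X %*% beta))
    w <- mu * (1 - mu)
    H <- matrix(0, p, p)
    U <- rep(0, p)
    for (ii in idx) {
      ni <- length(ii)
      Ai <- w[ii]
      Di <- X[ii, , drop = FALSE] * Ai
      Ri <- matrix(a, ni, ni); diag(Ri) <- 1
      Vi <- phi * (sqrt(Ai) %o% sqrt(Ai)) * Ri
      Vinv <- solve(Vi)
      DtV <- t(Di) %*% Vinv
      H <- H + DtV %*% Di
      U <- U + drop(DtV %*% (y[ii] - mu[ii]))
    }
    step <- drop(solve(H, U))
    beta <- beta + step
    if (sqrt(sum(step^2)) < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("gee_fit: convergence error, no convergence in maxit iterations")

  # cluster-level pieces at the solution
  mu <- stats::plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  H <- matrix(0, p, p)
  Ui <- matrix(0, K, p)
  Hi <- vector("list", K)
  for (k in seq_len(K)) {
    ii <- idx[[k]]
    ni <- length(ii)
    Ai <- w[ii]
    Di <- X[ii, , drop = FALSE] * Ai
    Ri <- matrix(a, ni, ni); diag(Ri) <- 1
    Vinv <- solve(phi * (sqrt(Ai) %o% sqrt(Ai)) * Ri)
    DtV <- t(Di) %*% Vinv
    Hi[[k]] <- DtV %*% Di
    H <- H + Hi[[k]]
    Ui[k, ] <- drop(DtV %*% (y[ii] - mu[ii]))
  }

  if (jackknife == "one_step") {
    # one Newton step from beta after deleting cluster k
    B <- vapply(seq_len(K), function(k) {
      drop(solve(H - Hi[[k]], -Ui[k, ]))
    }, numeric(p))
  } else {
    B <- vapply(seq_len(K), function(k) {
      keep <- unlist(idx[-k], use.names = FALSE)
      sub <- gee_fit(y[keep], if (p > 1) X[keep, -1, drop = FALSE] else NULL,
                     droplevels(cluster[keep]), jackknife = "one_step",
                     estimate_phi = estimate_phi,
                     alpha = if (fixed_alpha) alpha else NULL,
                     tol = tol, maxit = maxit)
      sub$coefficients - beta
    }, numeric(p))
  }
  B <- if (p == 1) matrix(B, ncol = 1) else t(B)
  Bc <- sweep(B, 2, colMeans(B))
  Vj <- ((K - p) / K) * crossprod(Bc)
  Vj <- (Vj + t(Vj)) / 2

  nm <- colnames(X)
  dimnames(Vj) <- list(nm, nm)
  Vn <- solve(H); dimnames(Vn) <- list(nm, nm)
  structure(list(
    coefficients = stats::setNames(beta, nm),
    vcov = Vj, vcov_naive = Vn,
    alpha = a, phi = phi, alpha_clipped = alpha_clipped,
    n_clusters = K, n_obs = length(y),
    converged = converged, jackknife = jackknife
  ), class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  cat(sprintf("<gee_fit> %d obs in %d clusters, alpha=%.3f, phi=%.3f (%s jackknife)\n",
              x$n_obs, x$n_clusters, x$alpha, x$phi, x$jackknife))
  print(round(data.frame(estimate = x$coefficients, se = se,
                         wald = (x$coefficients / se)^2,
                         p = stats::pchisq((x$coefficients / se)^2, 1,
                                           lower.tail = FALSE)), 4))
  invisible(x)
}

#' Wald test of GEE terms
#'
#' Tests `L beta = 0` with the fit's jackknife covariance:
#' `W = (L b)' (L V L')^{-1} (L b)`, chi-square with `rank(L)` df. `term`
#' may be a coefficient name (1-df test), a regular expression matching
#' several coefficients (joint test), or a contrast matrix `L`.
#'
#' @param fit A [gee_fit()].
#' @param term Coefficient name, regex, or numeric contrast matrix.
#' @return List with `wald`, `df`, `p`.
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "gee_fit"))
  b <- fit$coefficients
  V <- fit$vcov
  if (is.character(term)) {
    hit <- if (term %in% names(b)) term
           else names(b)[grepl(term, names(b))]
    if (length(hit) == 0) stop(sprintf("wald_test: no coefficient matches '%s'", term))
    L <- diag(length(b))[match(hit, names(b)), , drop = FALSE]
  } else {
    L <- as.matrix(term)
    if (ncol(L) != length(b)) stop("wald_test: contrast has wrong width")
  }
  Lb <- drop(L %*% b)
  M <- L %*% V %*% t(L)
  df <- qr(L)$rank
  Minv <- tryCatch(solve(M), error = function(e) {
    stop("wald_test: rank error, singular L V L'")
  })
  W <- drop(t(Lb) %*% Minv %*% Lb)
  list(wald = W, df = df, p = stats::pchisq(W, df, lower.tail = FALSE))
}

#' Estimated marginal means on the probability scale
#'
#' Model-predicted probability of choosing orange at a factor combination,
#' averaging the linear predictor over any factors not fixed in `at`
#' (equally weighted reference grid), then back-transforming. The 95% CI
#' is built on the link scale with the jackknife SE, so endpoints always
#' lie in (0, 1).
#'
#' @param fit A [gee_fit()].
#' @param design The [build_design()] result the fit was computed from.
#' @param at Named list fixing some factors, e.g.
#'   `list(species = "M_capensis")`.
#' @param level Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper` (probabilities), and
#'   `eta`, `se_eta` on the link scale.
#' @export
gee_emmeans <- function(fit, design, at = list(), level = 0.95) {
  stopifnot(inherits(fit, "gee_fit"))
  facs <- design$xlevels[!vapply(design$xlevels, is.null, logical(1))]
  facs <- facs[names(facs) %in% c(design$terms,
                                  unlist(strsplit(design$terms, ":", fixed = TRUE)))]
  for (nmf in names(at)) {
    if (!nmf %in% names(facs)) stop(sprintf("gee_emmeans: unknown factor '%s'", nmf))
    if (!at[[nmf]] %in% facs[[nmf]]) {
      stop(sprintf("gee_emmeans: input error, level '%s' not in factor '%s'",
                   at[[nmf]], nmf))
    }
    facs[[nmf]] <- at[[nmf]]
  }
  grid <- if (length(facs)) expand.grid(facs, stringsAsFactors = FALSE)
          else data.frame(row.names = 1)
  for (nmf in names(design$xlevels)) {
    if (!is.null(design$xlevels[[nmf]]) && nmf %in% names(grid)) {
      grid[[nmf]] <- factor(grid[[nmf]], levels = design$xlevels[[nmf]])
    }
  }
  if (length(design$terms) == 0) {
    crow <- c("(Intercept)" = 1)
  } else {
    fml <- stats::as.formula(paste("~", paste(design$terms, collapse = " + ")))
    mm <- stats::model.matrix(fml, grid)
    crow <- colMeans(mm)
  }
  b <- fit$coefficients
  stopifnot(all(names(b) == names(crow)))
  eta <- sum(crow * b)
  se <- sqrt(drop(t(crow) %*% fit$vcov %*% crow))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = stats::plogis(eta),
       lower = stats::plogis(eta - zq * se),
       upper = stats::plogis(eta + zq * se),
       eta = eta, se_eta = se)
}

#' First-choice chi-square test between soil backgrounds
#'
#' Goodness-of-fit chi-square for first choices split between two soil
#' types under the null of no differentiation (expected counts equal):
#' reduces to `(a - b)^2 / (a + b)` with 1 df.
#'
#' @param n_a,n_b Nonnegative first-choice counts on the two soils.
#' @return List with `chisq`, `df = 1`, `p`.
#' @export
first_choice_chisq <- function(n_a, n_b) {
  if (n_a < 0 || n_b < 0) stop("first_choice_chisq: input error, negative count")
  n <- n_a + n_b
  if (n < 1) stop("first_choice_chisq: input error, need >= 1 choice")
  chisq <- (n_a - n_b)^2 / n
  list(chisq = chisq, df = 1,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Conditioning contrast: did preferences change after forced feeding?
#'
#' Fits a GEE with conditioning phase as the predictor (for one fly
#' species) and returns the Wald test of the phase term(s). A
#' non-significant phase term means choices after conditioning on the
#' non-preferred colour match the spontaneous choices.
#'
#' @param trials Choice trials containing a `phase` column with `pre` and
#'   at least one `post_*` level, for >= 2 flies per phase.
#' @param jackknife Passed to [gee_fit()].
#' @return List with the `fit`, the `design`, and `phase_test` (Wald).
#' @export
conditioning_contrast <- function(trials, jackknife = "one_step") {
  if (!"phase" %in% names(trials)) {
    stop("conditioning_contrast: input error, no phase column")
  }
  phases <- unique(trials$phase)
  if (length(phases) < 2 || !"pre" %in% phases) {
    stop("conditioning_contrast: input error, need pre and post phases")
  }
  for (ph in phases) {
    if (length(unique(trials$fly_id[trials$phase == ph])) < 2) {
      stop(sprintf("conditioning_contrast: input error, < 2 flies in phase '%s'", ph))
    }
  }
  des <- build_design(trials, formula = "phase")
  fit <- gee_fit(des$y, des$x, des$cluster, jackknife = jackknife)
  list(fit = fit, design = des, phase_test = wald_test(fit, "^phase"))
}
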