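#' Centre and scale a numeric matrix
#'
#' Columns are centred to mean zero and scaled to unit variance using the
#' sample standard deviation (n - 1 denominator). The scaling record is kept
#' in attributes so the transform can be inverted exactly with
#' [uncenter_scale()].
#'
#' @param x Numeric matrix or data frame (coerced with `as.matrix`).
#' @return Scaled matrix with attributes `cs_center` and `cs_scale`.
#' @examples
#' xs <- center_scale(cbind(a = 1:3, b = c(2, 4, 9)))
#' uncenter_scale(xs)
#' @export
center_scale <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- !is.finite(sdv) | sdv <= 0
  if (any(bad)) {
    nm <- colnames(x)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
    stop("constant or non-finite column(s): ", paste(nm[bad], collapse = ", "))
  }
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  attr(xs, "cs_center") <- mu
  attr(xs, "cs_scale") <- sdv
  xs
}

#' @rdname center_scale
#' @param xs A matrix produced by [center_scale()].
#' @export
uncenter_scale <- function(xs) {
  mu <- attr(xs, "cs_center")
  sdv <- attr(xs, "cs_scale")
  if (is.null(mu) || is.null(sdv)) stop("xs carries no scaling record")
  out <- sweep(sweep(xs, 2, sdv, "*"), 2, mu, "+")
  attr(out, "cs_center") <- NULL
  attr(out, "cs_scale") <- NULL
  out
}

fill_names <- function(nm, prefix, k) {
  if (is.null(nm)) return(paste0(prefix, seq_len(k)))
  blank <- is.na(nm) | nm == ""
  nm[blank] <- paste0(prefix, which(blank))
  nm
}

#' Fit a PLS regression model by NIPALS
#'
#' Partial least squares regression (PLS1 for a single response, PLS2 for a
#' multivariate response) by the NIPALS algorithm with X-deflation only.
#' Predictors and responses are centred and scaled to unit variance (sample
#' SD) internally; all coefficients are therefore standardized, and
#' predictions are returned on the raw response scale.
#'
#' Per component `a`, NIPALS iterates `w = X'u / |X'u|`, `t = X w`,
#' `c = Y't / t't`, `u = Y c / c'c`; its fixed point `w` is the dominant
#' left singular vector of the cross-covariance `X'Y`, which this
#' implementation computes exactly (via the small `m x m` eigenproblem of
#' `Y'XX'Y`) instead of iterating, so the result is deterministic and does
#' not depend on a convergence tolerance. `X` is then deflated by
#' `t p'` with loadings `p = X't / t't` (no Y-deflation). The coefficient
#' matrix is `B = W (P'W)^{-1} C'`. Scores are mutually orthogonal and
#' weights have unit norm by construction.
#'
#' @param X Site-by-predictor matrix or data frame (no missing values).
#' @param Y Response vector, matrix or data frame.
#' @param ncomp Number of latent components, at most `min(n - 1, p)`.
#' @return An object of class `"pls_model"`: a list with weights `W`, scores
#'   `TT`, X-loadings `P`, Y-loadings `C`, per-ncomp standardized coefficient
#'   matrices `B` (list), scaling records, per-component explained Y variance
#'   on the scaled basis (`ssy`), cumulative R2Y on the raw pooled scale
#'   (`r2y_cum`), and bookkeeping fields.
#' @seealso [pls_vip()], [pls_q2_loo()], [pls_select_ncomp()],
#'   [predict.pls_model()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -1, 0) + rnorm(20, sd = 0.1)
#' fit <- pls_fit(X, y, ncomp = 2)
#' fit$r2y_cum
#' @export
pls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (anyNA(X) || anyNA(Y)) stop("missing values are not supported")
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must lie in 1..min(n-1, p) = ", min(n - 1, p))
  colnames(X) <- fill_names(colnames(X), "X", p)
  colnames(Y) <- fill_names(colnames(Y), "Y", m)

  Xs <- center_scale(X)
  Ys <- center_scale(Y)
  E <- Xs
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp); C <- matrix(0, m, ncomp)
  ssy <- numeric(ncomp)

  for (a in seq_len(ncomp)) {
    # exact NIPALS fixed point: w is the dominant left singular vector of
    # the cross-covariance Z = E'Y (for m = 1 simply Z normalised); solved
    # through the m x m eigenproblem of Z'Z, so no power iteration is needed
    Z <- crossprod(E, Ys)
    if (m == 1L) {
      w <- drop(Z)
    } else {
      q <- eigen(crossprod(Z), symmetric = TRUE)$vectors[, 1]
      w <- drop(Z %*% q)
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14)
      stop("component ", a, ": X residual carries no covariance with Y")
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w  # deterministic sign
    tt <- drop(E %*% w)
    cc <- drop(crossprod(Ys, tt)) / sum(tt^2)
    pp <- drop(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pp)
    W[, a] <- w; P[, a] <- pp; TT[, a] <- tt; C[, a] <- cc
    # Y variance captured on the scaled basis; valid because scores are
    # orthogonal and Y is regressed (not deflated) on them
    ssy[a] <- sum(tt^2) * sum(cc^2)
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(C) <- colnames(Y)

  # standardized coefficients for every sub-model 1..ncomp
  B <- vector("list", ncomp)
  for (a in seq_len(ncomp)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Ca <- C[, seq_len(a), drop = FALSE]
    Ba <- Wa %*% solve(crossprod(Pa, Wa), t(Ca))
    dimnames(Ba) <- list(colnames(X), colnames(Y))
    B[[a]] <- Ba
  }

  model <- structure(list(
    n = n, p = p, m = m, ncomp = ncomp,
    W = W, P = P, TT = TT, C = C, B = B,
    x_center = attr(Xs, "cs_center"), x_scale = attr(Xs, "cs_scale"),
    y_center = attr(Ys, "cs_center"), y_scale = attr(Ys, "cs_scale"),
    ssy = ssy,
    ss_tot_scaled = sum(Ys^2),
    sd_convention = "sample (n-1)"
  ), class = "pls_model")

  # cumulative R2Y on the raw pooled scale
  ss_tot <- sum(sweep(Y, 2, colMeans(Y), "-")^2)
  r2 <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    res <- Y - predict(model, X, ncomp = a)
    r2[a] <- 1 - sum(res^2) / ss_tot
  }
  model$ss_tot <- ss_tot
  model$r2y_cum <- r2
  model
}

#' Predict from a fitted PLS model
#'
#' @param object A `"pls_model"` from [pls_fit()].
#' @param newdata Matrix or data frame with the model's predictor columns.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Predictions on the raw response scale (n x m matrix).
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && all(rownames(object$W) %in% colnames(newdata)))
    newdata <- newdata[, rownames(object$W), drop = FALSE]
  if (ncol(newdata) != object$p) stop("newdata has wrong number of columns")
  if (ncomp < 1 || ncomp > object$ncomp) stop("invalid ncomp")
  Xs <- sweep(sweep(newdata, 2, object$x_center, "-"), 2, object$x_scale, "/")
  Yhat_s <- Xs %*% object$B[[ncomp]]
  sweep(sweep(Yhat_s, 2, object$y_scale, "*"), 2, object$y_center, "+")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS model (NIPALS):", x$n, "sites,", x$p, "predictors,",
      x$m, "response(s),", x$ncomp, "component(s)\n")
  cat("Cumulative R2(Y):", paste(sprintf("%.3f", x$r2y_cum), collapse = " "), "\n")
  invisible(x)
}

#' Standardized PLS coefficients
#'
#' Coefficients on the centred/unit-variance scale of both predictors and
#' responses, `B = W (P'W)^{-1} C'` truncated to `ncomp` components.
#'
#' @param object A `"pls_model"`.
#' @param ncomp Components to use (default all fitted).
#' @param ... Unused.
#' @return A p x m matrix.
#' @export
coef.pls_model <- function(object, ncomp = object$ncomp, ...) {
  object$B[[ncomp]]
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a w_aj^2) / sum_a(SSY_a))` where `SSY_a` is
#' the response variance captured by component `a` (scaled basis) and `w_a`
#' the unit-norm X-weights. The mean of `VIP^2` over predictors is exactly 1,
#' so VIP > 1 marks predictors of above-average importance.
#'
#' @param model A `"pls_model"` with at least one component.
#' @param ncomp Components to use (default all fitted).
#' @return Named numeric vector of length p.
#' @export
pls_vip <- function(model, ncomp = model$ncomp) {
  if (!inherits(model, "pls_model")) stop("model must be a pls_model")
  if (ncomp < 1) stop("VIP requires at least one fitted component")
  a <- seq_len(ncomp)
  ssy <- model$ssy[a]
  W2 <- model$W[, a, drop = FALSE]^2
  vip <- sqrt(model$p * drop(W2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(model$W)
  vip
}

#' Leave-one-out cross-validated Q2 and PRESS
#'
#' For each component count `a`, every site is held out in turn, the model
#' (including the centring/scaling of X and Y) is refit on the remaining
#' sites, and the held-out site is predicted. `PRESS_a` is the pooled squared
#' prediction error on the raw response scale. Following the chemometrics
#' convention, the per-component `Q2_a = 1 - PRESS_a / RESS_{a-1}` uses the
#' full-data residual sum of squares with `a - 1` components (`RESS_0` =
#' total SS about the mean) and governs the component-entry rule, while the
#' cumulative `Q2cum_a = 1 - PRESS_a / SS_tot` is the reported predictive
#' power.
#'
#' @param X,Y As in [pls_fit()]; `n >= 5` required.
#' @param ncomp Maximum number of components to evaluate (capped at
#'   `min(n - 2, p)`).
#' @return List with `press` (PRESS_a), `press0` (PRESS of the null,
#'   mean-only model), `ress` (RESS_a, a = 0..ncomp), `q2_comp`, `q2_cum`,
#'   and `ncomp`.
#' @export
pls_q2_loo <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 5) stop("leave-one-out Q2 requires n >= 5")
  ncomp <- min(ncomp, n - 2, ncol(X))
  if (ncomp < 1) stop("no components can be fitted")

  press <- numeric(ncomp)
  press0 <- 0
  for (i in seq_len(n)) {
    fit_i <- pls_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], ncomp = ncomp)
    for (a in seq_len(ncomp)) {
      e <- Y[i, ] - predict(fit_i, X[i, , drop = FALSE], ncomp = a)
      press[a] <- press[a] + sum(e^2)
    }
    press0 <- press0 + sum((Y[i, ] - colMeans(Y[-i, , drop = FALSE]))^2)
  }

  full <- pls_fit(X, Y, ncomp = ncomp)
  ss_tot <- full$ss_tot
  ress <- numeric(ncomp + 1)
  ress[1] <- ss_tot
  for (a in seq_len(ncomp)) {
    res <- Y - predict(full, X, ncomp = a)
    ress[a + 1] <- sum(res^2)
  }
  q2_comp <- 1 - press / ress[seq_len(ncomp)]
  q2_cum <- 1 - press / ss_tot
  list(press = press, press0 = press0, ress = ress,
       q2_comp = q2_comp, q2_cum = q2_cum, ncomp = ncomp)
}

#' Component-count rule on a Q2 sequence
#'
#' Components are admitted while their per-component Q2 exceeds `threshold`
#' (the 5% significance limit 0.097 by default); among the admissible counts
#' the one maximising the cumulative Q2 is returned. Zero means no
#' significant model.
#'
#' @param q2_comp Per-component Q2 sequence.
#' @param q2_cum Cumulative Q2 sequence (same length).
#' @param threshold Entry threshold (default 0.097).
#' @return Integer `A*` in `0..length(q2_comp)`.
#' @examples
#' choose_ncomp(c(0.30, 0.12, 0.05), c(0.30, 0.38, 0.36))
#' @export
choose_ncomp <- function(q2_comp, q2_cum, threshold = 0.097) {
  stopifnot(length(q2_comp) == length(q2_cum))
  fail <- which(!(q2_comp > threshold))
  k <- if (length(fail) == 0) length(q2_comp) else fail[1] - 1L
  if (k == 0L) return(0L)
  as.integer(unname(which.max(q2_cum[seq_len(k)])))
}

#' Select the number of significant PLS components
#'
#' Runs leave-one-out cross-validation ([pls_q2_loo()]) and applies the
#' maximum-Q2 entry rule ([choose_ncomp()]): components enter while their
#' per-component Q2 exceeds `threshold`, and among admissible counts the one
#' with maximal cumulative Q2 is kept.
#'
#' @inheritParams pls_q2_loo
#' @param threshold Q2 entry threshold (default 0.097, the 5% limit).
#' @param ncomp_max Maximum component count examined.
#' @return List with `ncomp` (`A*`, 0 if no significant model), `q2_comp`,
#'   `q2_cum`, and `significant`.
#' @export
pls_select_ncomp <- function(X, Y, threshold = 0.097,
                             ncomp_max = min(nrow(as.matrix(X)) - 2,
                                             ncol(as.matrix(X)), 10L)) {
  cv <- pls_q2_loo(X, Y, ncomp = ncomp_max)
  a <- choose_ncomp(cv$q2_comp, cv$q2_cum, threshold = threshold)
  list(ncomp = a, q2_comp = cv$q2_comp, q2_cum = cv$q2_cum,
       significant = a >= 1L, threshold = threshold)
}
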