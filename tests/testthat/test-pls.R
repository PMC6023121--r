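test_that("center_scale uses the sample-SD convention and inverts exactly", {
  xs <- center_scale(matrix(c(1, 2, 3), 3, 1))
  expect_equal(as.numeric(xs), c(-1, 0, 1))
  X <- matrix(rnorm(40), 10, 4)
  s1 <- center_scale(X)
  expect_equal(unname(colMeans(s1)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(s1, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # idempotence and exact inverse
  expect_equal(unclass(center_scale(s1))[, ], s1[, ], tolerance = 1e-12)
  expect_equal(uncenter_scale(s1), X, tolerance = 1e-12)
  expect_error(center_scale(cbind(a = 1:3, b = rep(2, 3))), "b")
})

test_that("full-component PLS1 predictions equal the OLS oracle", {
  for (seed in 1:5) {
    fx <- random_xy(20, 3, seed = seed)
    fit <- pls_fit(fx$X, fx$Y, ncomp = 3)
    ols <- lm(fx$Y ~ fx$X)
    expect_equal(drop(predict(fit, fx$X)), unname(fitted(ols)),
                 tolerance = 1e-6)
  }
})

test_that("first PLS1 weight vector is proportional to X'y", {
  fx <- random_xy(25, 6, seed = 3)
  fit <- pls_fit(fx$X, fx$Y, ncomp = 1)
  w_closed <- crossprod(center_scale(fx$X), center_scale(fx$Y))
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  expect_equal(abs(drop(fit$W)), abs(drop(w_closed)), tolerance = 1e-10)
})

test_that("NIPALS scores are orthogonal and weights unit-norm", {
  for (m in c(1, 4)) {
    fx <- random_xy(30, 8, m = m, seed = m)
    fit <- pls_fit(fx$X, fx$Y, ncomp = 5)
    G <- crossprod(fit$TT)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
    expect_equal(unname(colSums(fit$W^2)), rep(1, 5), tolerance = 1e-12)
  }
})

test_that("noiseless structured responses are fully explained at rank", {
  fx <- random_xy(20, 4, m = 2, noise = 0, seed = 9)
  fit <- pls_fit(fx$X, fx$Y, ncomp = 4)
  expect_equal(fit$r2y_cum[4], 1, tolerance = 1e-8)
  expect_true(all(diff(fit$r2y_cum) >= -1e-12))
  expect_true(all(fit$r2y_cum >= 0 & fit$r2y_cum <= 1 + 1e-12))
})

test_that("predictions and R2 agree with the reference implementation", {
  skip_if_not_installed("mixOmics")
  for (m in c(1, 3)) {
    fx <- random_xy(22, 5, m = m, seed = 10 + m)
    fit <- pls_fit(fx$X, fx$Y, ncomp = 3)
    ref <- mixOmics::pls(fx$X, fx$Y, ncomp = 3, mode = "regression",
                         scale = TRUE)
    pref <- predict(ref, fx$X)$predict
    for (a in 1:3) {
      expect_equal(unname(predict(fit, fx$X, ncomp = a)),
                   unname(pref[, , a, drop = TRUE], force = TRUE),
                   ignore_attr = TRUE, tolerance = 1e-6)
    }
  }
})

test_that("VIP is normalised (mean VIP^2 = 1) across random fixtures", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(10:30, 1); p <- sample(2:8, 1)
    m <- sample(1:3, 1); a <- sample(seq_len(min(n - 1, p)), 1)
    fx <- random_xy(n, p, m = m, seed = 1000 + i)
    v <- pls_vip(pls_fit(fx$X, fx$Y, ncomp = a))
    expect_equal(mean(v^2), 1, tolerance = 1e-9)
    expect_equal(sum(v^2), p, tolerance = 1e-7)
  }
})

test_that("VIP matches the hand-evaluated formula on a small fixture", {
  fx <- random_xy(6, 3, seed = 21)
  fit <- pls_fit(fx$X, fx$Y, ncomp = 2)
  # independent spreadsheet-style evaluation of the VIP formula
  ssy <- sapply(1:2, function(a) {
    sum(fit$TT[, a]^2) * sum(fit$C[, a]^2)
  })
  vip_hand <- sqrt(3 * (fit$W[, 1]^2 * ssy[1] + fit$W[, 2]^2 * ssy[2]) /
                     sum(ssy))
  expect_equal(pls_vip(fit), vip_hand, tolerance = 1e-10)
  # A = 1 with equal |w| means every VIP is 1
  Xeq <- matrix(rnorm(40), 20, 2)
  Xeq[, 2] <- Xeq[, 1] + rnorm(20, sd = 1e-8)
  yeq <- Xeq[, 1] + Xeq[, 2]
  veq <- pls_vip(pls_fit(Xeq, matrix(yeq), ncomp = 1))
  expect_equal(unname(veq), c(1, 1), tolerance = 1e-3)
})

test_that("single-predictor standardized coefficient equals Pearson r", {
  set.seed(31)
  x <- matrix(rnorm(40), dimnames = list(NULL, "x"))
  y <- 2 * x + rnorm(40)
  fit <- pls_fit(x, y, ncomp = 1)
  expect_equal(drop(coef(fit)), drop(cor(x, y)), tolerance = 1e-12)
})

test_that("duplicated predictors receive equal standardized coefficients", {
  set.seed(32)
  x <- rnorm(25)
  X <- cbind(a = x, b = x + rnorm(25, sd = 1e-9), c = rnorm(25))
  y <- x + rnorm(25, sd = 0.2)
  B <- coef(pls_fit(X, matrix(y), ncomp = 2))
  expect_equal(B["a", 1], B["b", 1], tolerance = 1e-6)
})

test_that("coefficients equal the explicit W(P'W)^-1 C' matrix algebra", {
  fx <- random_xy(18, 5, m = 2, seed = 41)
  fit <- pls_fit(fx$X, fx$Y, ncomp = 3)
  B_hand <- fit$W[, 1:3] %*%
    solve(t(fit$P[, 1:3]) %*% fit$W[, 1:3]) %*% t(fit$C[, 1:3])
  expect_equal(unname(coef(fit)), unname(B_hand), tolerance = 1e-10)
})

test_that("leave-one-out PRESS equals an explicit double-loop refit oracle", {
  fx <- random_xy(12, 4, seed = 51)
  A <- 3
  cv <- pls_q2_loo(fx$X, fx$Y, ncomp = A)
  press_oracle <- numeric(A)
  for (i in 1:12) {
    f <- pls_fit(fx$X[-i, ], fx$Y[-i, , drop = FALSE], ncomp = A)
    for (a in 1:A) {
      press_oracle[a] <- press_oracle[a] +
        sum((fx$Y[i, ] - predict(f, fx$X[i, , drop = FALSE], ncomp = a))^2)
    }
  }
  expect_equal(cv$press, press_oracle, tolerance = 1e-10)
})

test_that("Q2 conventions behave at the noiseless and null extremes", {
  fx <- random_xy(15, 3, noise = 0, seed = 61)
  cv <- pls_q2_loo(fx$X, fx$Y, ncomp = 3)
  expect_equal(cv$q2_cum[3], 1, tolerance = 1e-6)
  # pure-noise responses: mean cumulative Q2 over simulations is not positive
  q2s <- sapply(1:40, function(s) {
    set.seed(7000 + s)
    X <- matrix(rnorm(34 * 8), 34, 8)
    y <- matrix(rnorm(34))
    pls_q2_loo(X, y, ncomp = 2)$q2_cum[1]
  })
  expect_lte(mean(q2s), 0)
})

test_that("component-entry rule reproduces the max-Q2 selection on sequences", {
  expect_identical(choose_ncomp(c(0.30, 0.12, 0.05), c(0.30, 0.38, 0.36)), 2L)
  expect_identical(choose_ncomp(c(0.05, 0.30), c(0.05, 0.35)), 0L)
  expect_identical(choose_ncomp(c(0.3, 0.2, 0.15), c(0.3, 0.45, 0.50)), 3L)
  # maximum-Q2 rule can stop before the last admissible component
  expect_identical(choose_ncomp(c(0.3, 0.2), c(0.4, 0.35)), 1L)
  # exhaustive scan over constructed sequences against a direct evaluation
  vals <- c(-0.1, 0.05, 0.097, 0.1, 0.3)
  for (a1 in vals) for (a2 in vals) for (a3 in vals) {
    q2c <- c(a1, a2, a3)
    q2cum <- cumsum(pmax(q2c, 0)) # any monotone-ish stand-in is fine here
    k <- 0
    for (j in 1:3) { if (q2c[j] > 0.097) k <- j else break }
    expected <- if (k == 0) 0L else which.max(q2cum[1:k])
    expect_identical(choose_ncomp(q2c, q2cum), as.integer(expected))
  }
})

test_that("planted two-component structure is recovered by the selector", {
  hits <- 0
  for (s in 1:20) {
    set.seed(8000 + s)
    n <- 34
    t1 <- rnorm(n); t2 <- rnorm(n)
    # two planted latent X-directions as tight collinear blocks of unequal
    # size: the first covariance direction then differs from the regression
    # direction, so the fit needs exactly two components (a second latent
    # factor), after which only noise remains
    X <- cbind(t1 + rnorm(n, sd = .005), t1 + rnorm(n, sd = .005),
               t1 + rnorm(n, sd = .005), t2 + rnorm(n, sd = .005))
    y <- matrix(2 * t1 + t2 + rnorm(n, sd = 0.05))
    sel <- pls_select_ncomp(X, y, ncomp_max = 3)
    hits <- hits + (sel$ncomp == 2)
  }
  expect_gte(hits, 19)
})

test_that("scaling equivariance: rescaling an X column changes nothing", {
  fx <- random_xy(20, 5, seed = 71)
  X2 <- fx$X; X2[, 3] <- X2[, 3] * 1000
  f1 <- pls_fit(fx$X, fx$Y, ncomp = 3)
  f2 <- pls_fit(X2, fx$Y, ncomp = 3)
  expect_equal(pls_vip(f1), pls_vip(f2), tolerance = 1e-8)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$r2y_cum, f2$r2y_cum, tolerance = 1e-8)
  cv1 <- pls_q2_loo(fx$X, fx$Y, 2); cv2 <- pls_q2_loo(X2, fx$Y, 2)
  expect_equal(cv1$q2_cum, cv2$q2_cum, tolerance = 1e-8)
})

test_that("permutation of site order leaves all outputs unchanged", {
  fx <- random_xy(16, 4, seed = 81)
  set.seed(82); perm <- sample(16)
  f1 <- pls_fit(fx$X, fx$Y, ncomp = 2)
  f2 <- pls_fit(fx$X[perm, ], fx$Y[perm, , drop = FALSE], ncomp = 2)
  expect_equal(pls_vip(f1), pls_vip(f2), tolerance = 1e-10)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  cv1 <- pls_q2_loo(fx$X, fx$Y, 2)
  cv2 <- pls_q2_loo(fx$X[perm, ], fx$Y[perm, , drop = FALSE], 2)
  expect_equal(cv1$press, cv2$press, tolerance = 1e-10)
})

test_that("degenerate inputs raise informative errors", {
  fx <- random_xy(10, 3, seed = 91)
  expect_error(pls_fit(fx$X, fx$Y, ncomp = 0), "ncomp")
  expect_error(pls_fit(fx$X, fx$Y, ncomp = 4), "ncomp")
  expect_error(pls_vip(structure(list(), class = "lm")), "pls_model")
  Xna <- fx$X; Xna[1, 1] <- NA
  expect_error(pls_fit(Xna, fx$Y, 1), "missing")
  expect_error(pls_q2_loo(fx$X[1:4, ], fx$Y[1:4, , drop = FALSE], 1), "n >= 5")
})
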