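# The RDA chain is checked two ways: against a hand-rolled least-squares +
# eigendecomposition oracle, and against vegan's independent implementation.

rda_oracle <- function(y, x) {
  # brute force: center y, standardize x, project, eigen of fitted covariance
  y <- scale(y, center = TRUE, scale = FALSE)
  x <- scale(x)
  b <- solve(t(x) %*% x) %*% t(x) %*% y
  fitted <- x %*% b
  ev <- eigen(t(fitted) %*% fitted / (nrow(y) - 1), symmetric = TRUE)$values
  list(eig = ev[ev > 1e-12], r2 = sum(fitted^2) / sum(y^2))
}

test_that("rda_fit equals the least-squares + eigen oracle on random instances", {
  withr::with_seed(61, {
    for (i in 1:8) {
      y <- matrix(rnorm(10 * 8), 10, 8)
      x <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
      fit <- rda_fit(y, x, transform = "none")
      orc <- rda_oracle(y, as.matrix(x))
      expect_equal(fit$r_squared, orc$r2, tolerance = 1e-9)
      expect_equal(fit$eigenvalues, orc$eig[seq_along(fit$eigenvalues)],
                   tolerance = 1e-9)
      # independent cross-check: vegan
      vfit <- vegan::rda(y ~ ., data = as.data.frame(scale(x)))
      expect_equal(fit$r_squared, vegan::RsquareAdj(vfit)$r.squared,
                   tolerance = 1e-9)
      expect_equal(fit$adj_r_squared, vegan::RsquareAdj(vfit)$adj.r.squared,
                   tolerance = 1e-9)
      expect_equal(fit$eigenvalues, unname(vfit$CCA$eig), tolerance = 1e-9)
    }
  })
})

test_that("a single binary predictor reduces RDA to the ANOVA decomposition", {
  withr::with_seed(62, {
    g <- rep(0:1, each = 6)
    y <- matrix(rnorm(12 * 4), 12, 4)
    fit <- rda_fit(y, data.frame(g = g), transform = "none")
    yc <- scale(y, center = TRUE, scale = FALSE)
    between <- 0; total <- sum(yc^2)
    for (j in 1:4) {
      means <- tapply(yc[, j], g, mean)
      between <- between + sum(6 * means^2)
    }
    expect_equal(fit$r_squared, between / total, tolerance = 1e-9)
    # the single canonical axis separates the groups along the mean difference
    expect_equal(length(fit$eigenvalues), 1)
  })
})

test_that("R2 hits its boundary cases", {
  withr::with_seed(63, {
    n <- 8
    y <- matrix(rnorm(n * 3), n)
    # env spanning the sample space: R2 = 1
    x_full <- data.frame(matrix(rnorm(n * (n - 1)), n))
    fit <- rda_fit(y, x_full, transform = "none")
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)

    # env orthogonal to species by construction: R2 ~ 0
    yc <- scale(matrix(rnorm(n * 2), n), center = TRUE, scale = FALSE)
    x1 <- rnorm(n)
    x_orth <- residuals(lm(x1 ~ yc))  # orthogonal to both centred species
    fit0 <- rda_fit(yc, data.frame(x = x_orth), transform = "none")
    expect_lt(fit0$r_squared, 1e-12)
  })
  expect_error(
    rda_fit(matrix(rnorm(12), 6), data.frame(a = 1:6, b = 2 * (1:6)),
            transform = "none"),
    "Collinear")
  expect_error(
    rda_fit(matrix(rnorm(12), 6), data.frame(a = rep(1, 6)), transform = "none"),
    "Constant")
})

test_that("permutation test is deterministic under seed and exact at the floor", {
  withr::with_seed(64, {
    y <- matrix(rnorm(10 * 4), 10)
    x <- data.frame(v = rnorm(10))
    p1 <- permutation_test(y, x, n_perm = 99, seed = 7, transform = "none")
    p2 <- permutation_test(y, x, n_perm = 99, seed = 7, transform = "none")
    expect_identical(p1$p_value, p2$p_value)
    expect_identical(p1$statistic, p2$statistic)

    # env perfectly determining species: minimal attainable p
    x2 <- data.frame(v = seq_len(10))
    y2 <- cbind(2 * scale(x2$v), -1 * scale(x2$v)) + 0
    pt <- permutation_test(y2, x2, n_perm = 49, seed = 1, transform = "none")
    expect_equal(pt$p_value, 1 / 50)
    expect_true(pt$p_value > 0 && pt$p_value <= 1)
  })
})

test_that("permutation p-values are near-uniform under a null", {
  # 600 null datasets at alpha = 0.1: rejection rate within binomial noise
  withr::with_seed(65, {
    nsim <- 600
    pvals <- replicate(nsim, {
      y <- matrix(rnorm(10 * 4), 10)
      x <- data.frame(v = rnorm(10))
      permutation_test(y, x, n_perm = 49, transform = "none")$p_value
    })
    rate <- mean(pvals <= 0.1)
    expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / nsim) + 0.01)
    expect_gt(min(pvals), 0)
  })
})

test_that("forward selection admits a lone informative candidate and stops on noise", {
  withr::with_seed(66, {
    n <- 20
    x <- data.frame(sig = rnorm(n))
    y <- cbind(1.5 * x$sig + rnorm(n, sd = 0.4),
               -x$sig + rnorm(n, sd = 0.4),
               rnorm(n))
    sel <- forward_select(y, x, n_perm = 99, seed = 2, transform = "none")
    expect_equal(sel$variable, "sig")
    expect_lte(sel$p_value, 0.05)

    # all-noise candidates: usually empty at alpha = 0.05
    empties <- vapply(1:20, function(i) {
      y0 <- matrix(rnorm(n * 3), n)
      x0 <- data.frame(a = rnorm(n), b = rnorm(n))
      nrow(forward_select(y0, x0, n_perm = 99, transform = "none")) == 0
    }, logical(1))
    expect_gte(mean(empties), 0.7)
  })
})

test_that("VPA fractions obey inclusion-exclusion exactly", {
  withr::with_seed(67, {
    n <- 24
    x <- as.data.frame(qr.Q(qr(matrix(rnorm(n * 4), n))))
    names(x) <- c("a1", "a2", "b1", "b2")
    y <- matrix(rnorm(n * 5), n)
    part <- vpa(y, x, list(A = c("a1", "a2"), B = c("b1", "b2")),
                transform = "none")
    fr <- tidy(part)
    expect_equal(sum(fr$adj_r2), 1, tolerance = 1e-9)

    # orthogonal groups: shared ~ 0, uniques equal each group's own adj R2
    shared <- fr$adj_r2[fr$fraction == "shared_A_B"]
    fa <- rda_fit(y, x[c("a1", "a2")], transform = "none")$adj_r_squared
    fb <- rda_fit(y, x[c("b1", "b2")], transform = "none")$adj_r_squared
    expect_lt(abs(shared), 0.05)
    expect_equal(fr$adj_r2[fr$fraction == "unique_A"] + shared, fa,
                 tolerance = 1e-9)
    expect_equal(fr$adj_r2[fr$fraction == "unique_B"] + shared, fb,
                 tolerance = 1e-9)

    # independent cross-check of the two-group fractions against vegan::varpart
    # (varpart rows: [a] = X1|X2, [b] = X2|X1, [c] = shared, [d] = residual)
    vp <- vegan::varpart(y, x[c("a1", "a2")], x[c("b1", "b2")])
    indfract <- vp$part$indfract$Adj.R.square
    expect_equal(fr$adj_r2[fr$fraction == "unique_A"], indfract[1], tolerance = 1e-6)
    expect_equal(fr$adj_r2[fr$fraction == "unique_B"], indfract[2], tolerance = 1e-6)
    expect_equal(shared, indfract[3], tolerance = 1e-6)
    expect_equal(fr$adj_r2[fr$fraction == "residual"], indfract[4], tolerance = 1e-6)

    expect_error(vpa(y, x, list(A = c("a1"), B = c("a1", "b1")),
                     transform = "none"), "Overlapping")
  })
})

test_that("three-group VPA keeps the identity and names every cell", {
  withr::with_seed(68, {
    n <- 18
    x <- data.frame(matrix(rnorm(n * 3), n)); names(x) <- c("p", "q", "r")
    y <- matrix(rnorm(n * 4), n)
    part <- vpa(y, x, list(P = "p", Q = "q", R = "r"), transform = "none")
    fr <- tidy(part)
    expect_equal(nrow(fr), 8)  # 7 atoms + residual
    expect_equal(sum(fr$adj_r2), 1, tolerance = 1e-9)
  })
})
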