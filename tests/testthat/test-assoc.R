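test_that("abundance filter retains exactly the taxa above the mean threshold", {
  ra <- rbind(common = c(0.6, 0.4, 0.5),
              rare = c(0.004, 0.006, 0.005),
              mid = c(0.02, 0.005, 0.008))
  kept <- abundance_filter(ra, 0.01)
  expect_setequal(rownames(kept), c("common", "mid"))
  expect_false("rare" %in% rownames(abundance_filter(ra, 0.01)))
  # threshold 0 keeps every non-zero taxon
  ra0 <- rbind(a = c(0.5, 0), b = c(0.5, 1), z = c(0, 0))
  expect_setequal(rownames(abundance_filter(ra0, 0)), c("a", "b"))
  expect_error(abundance_filter(ra, 1), "proportion")

  withr::with_seed(71, {
    m <- matrix(runif(60, 0, 0.1), 10,
                dimnames = list(paste0("t", 1:10), NULL))
    thr <- 0.05
    expect_setequal(rownames(abundance_filter(m, thr)),
                    rownames(m)[rowMeans(m) > thr])
    expect_lte(nrow(abundance_filter(m, thr)), nrow(m))
  })
})

test_that("Spearman table matches rank arithmetic and is monotone-invariant", {
  taxa <- rbind(t1 = c(1, 2, 3), t2 = c(3, 1, 2))
  env <- data.frame(e = c(1, 2, 3))
  res <- spearman_matrix(taxa, env)
  expect_equal(res$rho[res$taxon == "t1"], 1)
  expect_equal(res$rho[res$taxon == "t2"], -0.5)  # ranks (3,1,2) vs (1,2,3)

  withr::with_seed(72, {
    x <- matrix(rnorm(40), 4, dimnames = list(c("a", "b", "c", "d"), NULL))
    env <- data.frame(v = rnorm(10), w = runif(10))
    r1 <- spearman_matrix(x, env)
    # strictly monotone transforms change nothing
    r2 <- spearman_matrix(exp(x), data.frame(v = env$v^3, w = log(env$w)))
    expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    expect_true(all(abs(r1$rho) <= 1))
    expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  })
})

test_that("Spearman t-approximation p tracks the exact permutation null", {
  withr::with_seed(73, {
    n <- 7
    for (i in 1:5) {
      x <- rnorm(n); y <- rnorm(n)
      res <- spearman_matrix(matrix(x, 1, dimnames = list("t", NULL)),
                             data.frame(e = y))
      rho_obs <- res$rho
      # exact permutation distribution over 2000 sampled permutations
      rhos <- replicate(2000, cor(rank(x), rank(sample(y))))
      p_perm <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
      expect_lt(abs(res$p_value - p_perm), 0.06)
    }
  })
})

test_that("Pearson table equals the product-moment formula and cor.test", {
  withr::with_seed(74, {
    env <- as.data.frame(matrix(rnorm(20), 5, dimnames = list(NULL, c("a", "b", "c", "d"))))
    res <- pearson_matrix(env)
    for (i in seq_len(nrow(res))) {
      v1 <- env[[res$variable[i]]]; v2 <- env[[res$variable2[i]]]
      num <- sum((v1 - mean(v1)) * (v2 - mean(v2)))
      den <- sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
      expect_equal(res$rho[i], num / den, tolerance = 1e-12)
      if (res$variable[i] != res$variable2[i]) {
        ct <- cor.test(v1, v2)
        expect_equal(res$p_value[i], ct$p.value, tolerance = 1e-9)
      } else {
        expect_equal(res$rho[i], 1)
      }
    }
    # exact negative affine relation
    env2 <- data.frame(x = 1:5, y = -2 * (1:5) + 3)
    res2 <- pearson_matrix(env2)
    expect_equal(res2$rho[res2$variable == "x" & res2$variable2 == "y"], -1)
  })
})

test_that("stars are a deterministic function of p and constants warn", {
  expect_equal(star_labels(c(0.2, 0.04, 0.004, NA)), c("", "*", "**", ""))
  taxa <- rbind(t1 = c(1, 2, 3, 4), t2 = c(2, 2, 2, 2))
  env <- data.frame(e = c(4, 3, 2, 1))
  expect_warning(res <- spearman_matrix(taxa, env), "Constant")
  expect_true(is.na(res$rho[res$taxon == "t2"]))
  expect_equal(res$stars[res$taxon == "t2"], "")
  resadj <- suppressWarnings(spearman_matrix(taxa, env, adjust = "BH"))
  expect_true("p_adj" %in% names(resadj))
})

test_that("cluster_order places identical correlation rows adjacently", {
  res <- tibble::tibble(
    taxon = rep(c("a", "b", "c"), each = 2),
    variable = rep(c("x", "y"), 3),
    rho = c(0.9, -0.8, 0.1, 0.2, 0.9, -0.8),
    p_value = rep(0.5, 6), stars = rep("", 6))
  class(res) <- c("cor_result", class(res))
  ord <- cluster_order(res)
  expect_setequal(ord$row_order, c("a", "b", "c"))
  expect_setequal(ord$col_order, c("x", "y"))
  pos <- match(c("a", "c"), ord$row_order)  # duplicated rows cluster first
  expect_equal(abs(diff(pos)), 1)
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  # between MS = 54/2, within MS = 6/6 -> F = 27
  out <- group_difference(1:9, rep(letters[1:3], each = 3))
  expect_equal(out$statistic, 27)
  expect_equal(out$df_between, 2)
  expect_equal(out$df_within, 6)

  # identical group means: F = 0
  flat <- group_difference(c(1, 2, 1, 2), c("g1", "g1", "g2", "g2"))
  expect_equal(flat$statistic, 0)

  expect_error(group_difference(1:4, c("a", "a", "a", "b")), "fewer than 2")

  # under a true null the p-values are roughly uniform
  withr::with_seed(75, {
    p <- replicate(400, group_difference(rnorm(12), rep(1:3, each = 4))$p_value)
    expect_lt(abs(mean(p < 0.3) - 0.3), 3 * sqrt(0.3 * 0.7 / 400) + 0.01)
    expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
  })
})

test_that("composition arithmetic helpers are exact", {
  expect_equal(total_community_share(0.5, 0.1), 0.05)
  expect_error(total_community_share(1.2, 0.5), "0, 1")
  expect_equal(dominance_share(c(0.4, 0.06, 0.04), threshold = 0.05), 0.46)
  expect_equal(dominance_share(c(0.02, 0.01)), 0)
})
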