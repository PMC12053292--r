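test_that("covariate residualisation has the textbook OLS properties", {
  set.seed(1)
  y <- rnorm(40)
  covs <- data.frame(age = rnorm(40, 60, 8), education = rnorm(40, 14, 3),
                     LEDD = rnorm(40, 450, 150))

  # constant covariates are absorbed by the intercept: centred originals
  adj0 <- adjust_covariates(y, data.frame(age = rep(55, 40)))
  expect_equal(adj0, y - mean(y), tolerance = 1e-12)

  # a response exactly linear in a covariate residualises to ~0
  lin <- 3 + 0.5 * covs$age
  expect_lt(max(abs(adjust_covariates(lin, covs))), 1e-10)

  # residuals are mean-zero and orthogonal to every covariate
  adj <- adjust_covariates(y, covs)
  expect_lt(abs(mean(adj)), 1e-10)
  for (j in seq_len(ncol(covs)))
    expect_lt(abs(sum(adj * (covs[[j]] - mean(covs[[j]])))), 1e-8)

  # matrix input residualises each column
  Y <- cbind(y, lin)
  adjM <- adjust_covariates(Y, covs)
  expect_equal(adjM[, 1], adj, tolerance = 1e-12)

  # collinear designs are refused with the offending column named
  bad <- data.frame(age = covs$age, age2 = 2 * covs$age)
  expect_error(adjust_covariates(y, bad), "age2")
  expect_error(adjust_covariates(y, data.frame(age = c(covs$age[-1], NA))),
               "finite")
})

test_that("permutation test is valid, deterministic and affine-invariant", {
  a <- c(1, 2, 3, 4)
  b <- c(4, 2, 1, 3)  # identical multisets
  r <- permutation_test(a, b, n_perm = 500, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)

  # separation by 5 pooled SDs forces an extreme rank
  set.seed(2)
  x <- rnorm(30)
  y <- rnorm(30) + 5
  r2 <- permutation_test(x, y, n_perm = 1000, seed = 3)
  expect_lte(r2$p, 0.001)

  # fixed seed reproduces p exactly; p has resolution 1/(n_perm + 1)
  r3 <- permutation_test(x, y, n_perm = 1000, seed = 3)
  expect_identical(r2$p, r3$p)
  expect_equal(r2$p * 1001, round(r2$p * 1001))

  # common affine transform of both cells leaves p unchanged
  r4 <- permutation_test(2 * x + 7, 2 * y + 7, n_perm = 1000, seed = 3)
  expect_identical(r2$p, r4$p)

  expect_error(permutation_test(1, c(1, 2), 100), ">= 2")
  expect_error(permutation_test(a, b, n_perm = 0), "n_perm")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(9)
  ps <- replicate(400, {
    x <- rnorm(12)
    permutation_test(x[1:6], x[7:12], n_perm = 200)$p
  })
  for (alpha in c(0.01, 0.05, 0.1)) {
    mc <- 2 * sqrt(alpha * (1 - alpha) / 400)
    expect_lte(mean(ps <= alpha), alpha + 2 * mc + 1 / 201)
  }
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.037), 0.037)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.04, 0.2, 0.9)
  q <- fdr_bh(p)
  expect_equal(q, c(0.02, 0.08, 0.8 / 3, 0.9))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(fdr_bh(c(0.5, 0)), "p-values")
})

test_that("Pearson correlation p-values match the t-distribution", {
  x <- 1:20
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)

  # printed-statistic consistency: r and n reproduce reported significance
  expect_lt(abs(pearson_p_from_r(0.408, 60) - 0.0012), 2e-4)
  expect_lt(abs(pearson_p_from_r(-0.381, 60) - 0.003), 5e-4)

  # cross-check against cor.test on random data
  set.seed(4)
  a <- rnorm(25)
  b <- 0.4 * a + rnorm(25)
  mine <- pearson_with_p(a, b)
  ref <- cor.test(a, b)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  expect_error(pearson_with_p(rep(1, 10), rnorm(10)), "variance")
  expect_error(pearson_with_p(1:2, 1:2), "n >= 3")
})

test_that("cell contrasts report signed differences, shared shuffles and FDR", {
  co <- generate_cohort(tiny_spec(seed = 11, n_per_cell = 6))
  fit <- imn_cohort(co, sparsity = sparsity_grid(0.2, 0.45, 0.05),
                    n_null = 0, grid_size = 128)
  ab <- imn_compare(fit, group = "PD-pRBD", a = "M", b = "F",
                    n_perm = 300, seed = 5)
  ba <- imn_compare(fit, group = "PD-pRBD", a = "F", b = "M",
                    n_perm = 300, seed = 5)
  expect_equal(ab$results$observed, -ba$results$observed, tolerance = 1e-12)

  r <- ab$results
  expect_true(all(is.na(r$q[is.na(r$node)])))      # global: raw p only
  nodal <- r[!is.na(r$node), ]
  expect_equal(nrow(nodal), 3 * 8)                  # Ne, Dc, Bc per region
  for (att in unique(nodal$attribute)) {
    fam <- nodal[nodal$attribute == att, ]
    expect_equal(fam$q, fdr_bh(fam$p), tolerance = 1e-12)
  }
  expect_true(all(r$p > 0 & r$p <= 1))

  # determinism
  ab2 <- imn_compare(fit, group = "PD-pRBD", a = "M", b = "F",
                     n_perm = 300, seed = 5)
  expect_identical(ab$results, ab2$results)
  expect_error(imn_compare(fit, group = "HC"), "fewer than 2")
})
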