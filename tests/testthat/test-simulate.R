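test_that("fixed seed gives bit-identical cohorts; null equals zero-effect", {
  sp <- tiny_spec(seed = 7)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)

  eff <- list(region_effect("PD-pRBD", "M", 1:3, "FD", shift = 1.2))
  sp_eff <- tiny_spec(seed = 7, effects = eff)
  expect_identical(null_cohort(sp_eff)$vertex, a$vertex)

  # generation is keyed per (seed, subject, region): changing the seed
  # changes the draws
  expect_false(identical(generate_cohort(tiny_spec(seed = 8))$vertex$value,
                         a$vertex$value))
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(n_per_cell = 1), "n_per_cell")
  expect_error(cohort_spec(n_regions = 2), "n_regions")
  expect_error(cohort_spec(vertices_per_region = c(5, 8)), ">= 10")
  expect_error(tiny_spec(1, effects = list(
    region_effect("PD-pRBD", "M", c(1, 99), "FD", 1))), "region ids")
  expect_error(tiny_spec(1, effects = list(
    region_effect("HC", "M", 1, "FD", 1))), "not in the cohort")
  expect_error(tiny_spec(1, effects = list(
    region_effect("PD-pRBD", "M", 1, "CT", 1))), "not simulated")
  expect_error(tiny_spec(1, effects = list(
    region_effect("PD-pRBD", "M", 1, "FD", 1, scale = 0))), "scale")
})

test_that("zero-shift cells differ only by sampling noise", {
  # two-sample t on per-subject region means between cells, alpha = 0.01;
  # across seeds x regions the rejection rate should stay near 1%
  n_rej <- 0
  n_tot <- 0
  for (seed in 1:12) {
    co <- generate_cohort(tiny_spec(seed = seed, n_per_cell = 6))
    v <- co$vertex
    rm <- aggregate(value ~ subject + sex + region_id, v, mean)
    for (r in unique(rm$region_id)) {
      x <- rm$value[rm$region_id == r & rm$sex == "M"]
      y <- rm$value[rm$region_id == r & rm$sex == "F"]
      n_rej <- n_rej + (t.test(x, y)$p.value < 0.01)
      n_tot <- n_tot + 1
    }
  }
  expect_lte(n_rej / n_tot, 0.05)   # 96 tests; binomial slack above 1%
})

test_that("injected mean shifts are recovered at the designed magnitude", {
  eff <- list(region_effect("PD-pRBD", "M", 1:5, "FD", shift = 1.5))
  sp <- cohort_spec(n_per_cell = 30, groups = "PD-pRBD",
                    sexes = c("M", "F"), n_regions = 6,
                    vertices_per_region = c(300, 300), metrics = "FD",
                    effects = eff, seed = 21)
  co <- generate_cohort(sp)
  v <- co$vertex
  for (r in 1:5) {
    m_mean <- mean(v$value[v$sex == "M" & v$region_id == r])
    f_mean <- mean(v$value[v$sex == "F" & v$region_id == r])
    sd_r <- sd(v$value[v$sex == "F" & v$region_id == r])
    expect_lt(abs((m_mean - f_mean) / sd_r - 1.5), 0.2)
  }
  # untouched region stays put
  r6 <- abs(mean(v$value[v$sex == "M" & v$region_id == 6]) -
              mean(v$value[v$sex == "F" & v$region_id == 6]))
  expect_lt(r6 / sd(v$value[v$region_id == 6]), 0.15)
})

test_that("larger distribution shifts strictly depress the pair's KLS", {
  # compare the shifted region's distribution (male cell) against the same
  # region's unshifted distribution (female cell): same base draws, so
  # expected similarity must fall strictly as the shift grows
  sims <- sapply(c(0, 0.5, 1.5, 3), function(shift) {
    mean(sapply(1:5, function(seed) {
      eff <- if (shift > 0)
        list(region_effect("PD-pRBD", "M", 1, "FD", shift)) else list()
      co <- generate_cohort(tiny_spec(seed = seed, n_per_cell = 2,
                                      n_regions = 4, effects = eff))
      v <- co$vertex[co$vertex$region_id == 1, ]
      m <- v$value[v$subject == v$subject[v$sex == "M"][1]]
      f <- v$value[v$subject == v$subject[v$sex == "F"][1]]
      h <- max(bw.nrd0(m), bw.nrd0(f))
      g <- seq(min(m, f) - 3 * h, max(m, f) + 3 * h, length.out = 256)
      kls(symmetric_kld(estimate_density(m, grid = g),
                        estimate_density(f, grid = g)))
    }))
  })
  expect_true(all(diff(sims) < 0))
})

test_that("score coupling ties scores to each subject's own network AUC", {
  sc <- score_coupling("mem", "FD", "Eg", slope = 10, intercept = 2,
                       noise_sd = 0, grid = sparsity_grid(0.2, 0.45, 0.05),
                       grid_size = 128)
  sp <- tiny_spec(seed = 5, n_per_cell = 3, score_coupling = sc)
  co <- generate_cohort(sp)
  fit <- imn_cohort(co, sparsity = sparsity_grid(0.2, 0.45, 0.05),
                    n_null = 0, grid_size = 128)
  eg <- auc_values(fit, "FD", "Eg", co$clinical$subject)
  expect_equal(unname(co$clinical$mem), unname(2 + 10 * eg),
               tolerance = 1e-12)

  # slope 0 decouples the score: correlation centred on 0 across seeds
  r0 <- sapply(1:6, function(seed) {
    sp0 <- tiny_spec(seed = seed, n_per_cell = 5, score_coupling =
                       score_coupling("mem", "FD", "Eg", slope = 0,
                                      noise_sd = 1,
                                      grid = sparsity_grid(0.2, 0.45, 0.05),
                                      grid_size = 128))
    co0 <- generate_cohort(sp0)
    f0 <- imn_cohort(co0, sparsity = sparsity_grid(0.2, 0.45, 0.05),
                     n_null = 0, grid_size = 128)
    cor(auc_values(f0, "FD", "Eg", co0$clinical$subject), co0$clinical$mem)
  })
  expect_lt(abs(mean(r0)), 0.35)
})

test_that("cohort round-trips through CSV", {
  co <- generate_cohort(tiny_spec(seed = 3, n_per_cell = 2, n_regions = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_vertex_table(file.path(dir, "vertex.csv"))
  expect_equal(back$value, co$vertex$value, tolerance = 1e-12)
  expect_identical(back$region_label, co$vertex$region_label)
  clin <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  expect_identical(clin$subject, co$clinical$subject)
})
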