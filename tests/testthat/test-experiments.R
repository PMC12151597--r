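test_that("a beetle-free release coexists with zero damage", {
  out <- run_release(P0 = 100, B0 = 0, species = "leaf", horizon = 300)
  expect_equal(out$classification, "coexist")
  expect_equal(out$damage, 0)
  expect_true(is.na(out$time_of_consumption))
})

test_that("a release far above threshold consumes the stand", {
  out <- run_release(P0 = 100, B0 = 100, species = "leaf")
  expect_equal(out$classification, "consumed")
  expect_equal(out$damage, 1)
  expect_lt(out$time_of_consumption, 1000)
})

test_that("damage is nondecreasing in release size and the outcome is monotone", {
  scan <- purrr::map_dfr(c(0, 2, 5, 9, 12, 20), function(B0) {
    run_release(P0 = 100, B0 = B0, species = "leaf")
  })
  expect_true(all(diff(scan$damage) >= -1e-8))
  consumed <- scan$classification == "consumed"
  # once consumed, always consumed at larger releases
  expect_true(all(diff(as.integer(consumed)) >= 0))
})

test_that("the critical release size is a sharp threshold", {
  b_star <- critical_release_size(P0 = 100, species = "leaf")
  below <- run_release(P0 = 100, B0 = b_star - 1, species = "leaf")
  at <- run_release(P0 = 100, B0 = b_star, species = "leaf")
  expect_equal(below$classification, "coexist")
  expect_equal(at$classification, "consumed")
  # continuous refinement lands inside the integer bracket
  b_cont <- critical_release_size(P0 = 100, species = "leaf",
                                  integer = FALSE, tol = 0.05)
  expect_gte(b_cont, b_star - 1)
  expect_lte(b_cont, b_star)
})

test_that("well below threshold both plant and beetles grow", {
  pr <- species_preset("leaf")
  sol <- integrate_model("coupled", release_init(100, 2), t_end = 1000,
                         plant = pr$plant, beetle = pr$beetle,
                         inter = pr$inter, times = c(0, 1000))
  expect_gt(sol$L[2], 100)
  expect_gt(sol$J[2] + sol$A[2], 2)
})

test_that("the threshold scales near-linearly with stand size on large stands", {
  per100 <- sapply(c(500, 1000, 2000, 5000), function(P0) {
    100 * critical_release_size(P0 = P0, species = "stem") / P0
  })
  expect_lt((max(per100) - min(per100)) / min(per100), 0.2)
})

test_that("the damage map is monotone per column and zero without beetles", {
  dm <- damage_map(P0_grid = c(50, 100), B0_grid = c(0, 5, 15, 40),
                   species = "leaf")
  expect_equal(nrow(dm), 8)
  for (p0 in unique(dm$P0)) {
    col <- dm[dm$P0 == p0, ]
    expect_true(all(diff(col$damage) >= -1e-8))
  }
  expect_true(all(dm$damage[dm$B0 == 0] == 0))
  thr <- attr(dm, "threshold")
  expect_equal(nrow(thr), 2)
  # cells at or above the threshold curve are all consumed
  for (i in seq_len(nrow(dm))) {
    b_star <- thr$B0_star[thr$P0 == dm$P0[i]]
    if (dm$B0[i] >= b_star) expect_equal(dm$classification[i], "consumed")
    else expect_equal(dm$classification[i], "coexist")
  }
})

test_that("a degenerate scaling sampler reproduces the unscaled threshold in every row", {
  tbl <- sensitivity_mc("leaf", n_sims = 4, P0 = 100, seed = 1,
                        scaled = c("lambda_G", "b"), range = c(1, 1))
  b0 <- critical_release_size(P0 = 100, species = "leaf")
  expect_equal(tbl$b0_per_100, rep(b0, 4))
  expect_true(all(!tbl$censored))
})

test_that("the sensitivity table is reproducible and row-stable under a fixed seed", {
  t1 <- sensitivity_mc("leaf", n_sims = 4, P0 = 100, seed = 99,
                       scaled = c("lambda_G", "b"))
  t2 <- sensitivity_mc("leaf", n_sims = 4, P0 = 100, seed = 99,
                       scaled = c("lambda_G", "b"))
  expect_identical(t1, t2)
  # growing the table does not reshuffle earlier rows
  t3 <- sensitivity_mc("leaf", n_sims = 6, P0 = 100, seed = 99,
                       scaled = c("lambda_G", "b"))
  expect_equal(as.data.frame(t3[1:4, ]), as.data.frame(t1),
               ignore_attr = TRUE)
})

test_that("OLS effect sizes recover a synthetic linear response", {
  set.seed(1)
  n <- 200
  tbl <- tibble::tibble(
    X1 = runif(n, 0.5, 2), X2 = runif(n, 0.5, 2), X3 = runif(n, 0.5, 2),
    b0_per_100 = 3 * X1 + 1e-8 * rnorm(n), censored = FALSE
  )
  class(tbl) <- c("sensitivity_table", class(tbl))
  fit <- sensitivity_regression(tbl)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "X1"], 3, tolerance = 1e-4)
  expect_equal(td$estimate[td$term == "X2"], 0, tolerance = 1e-4)
  expect_equal(glance(fit)$nobs, n)
})

test_that("aliased predictors are rejected as rank deficient", {
  set.seed(2)
  n <- 50
  x <- runif(n, 0.5, 2)
  tbl <- tibble::tibble(X1 = x, X2 = x, b0_per_100 = x + rnorm(n, 0, 0.1),
                        censored = FALSE)
  class(tbl) <- c("sensitivity_table", class(tbl))
  expect_error(sensitivity_regression(tbl), "rank-deficient")
})

test_that("fully censored tables are rejected", {
  tbl <- tibble::tibble(X1 = c(1, 1.2), b0_per_100 = NA_real_,
                        censored = TRUE)
  class(tbl) <- c("sensitivity_table", class(tbl))
  expect_error(sensitivity_regression(tbl), "censored")
})

test_that("plot builders return ggplot objects", {
  pr <- species_preset("leaf")
  traj <- integrate_model("coupled", release_init(50, 5), t_end = 50,
                          plant = pr$plant, beetle = pr$beetle,
                          inter = pr$inter)
  expect_s3_class(plot_trajectory(traj), "ggplot")
  dm <- damage_map(P0_grid = 50, B0_grid = c(0, 10), species = "leaf",
                   horizon = 300, threshold = FALSE)
  expect_s3_class(plot_damage_map(dm), "ggplot")
})
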