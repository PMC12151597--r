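test_that("plant right-hand side matches direct substitution", {
  pp <- plant_params()
  expect_equal(plant_rhs(c(T = 0, N = 10, L = 10), pp),
               c(T = 0.027, N = 0, L = 0))
  expect_equal(plant_rhs(c(T = 10, N = 0, L = 0), pp),
               c(T = 0, N = 0.934, L = 0.934))
  expect_equal(plant_rhs(c(T = 0, N = 0, L = 0), pp),
               c(T = 0, N = 0, L = 0))
})

test_that("plant growth rate is the dominant eigenvalue sqrt(lambda_B (lambda_G - lambda_D))", {
  pp <- plant_params()
  lam <- plant_growth_rate(pp)
  expect_equal(lam, 0.0159, tolerance = 2e-3)
  expect_equal(lam, plant_lambda_closed(0.0027, 0.0948, 0.0014),
               tolerance = 1e-12)
  # square-root homogeneity: scaling (lambda_G - lambda_D) by 4 doubles it
  pp4 <- plant_params(0.0027, 0.0014 + 4 * (0.0948 - 0.0014), 0.0014)
  expect_equal(plant_growth_rate(pp4), 2 * lam, tolerance = 1e-12)
  expect_error(plant_growth_rate(plant_params(0.01, 0.001, 0.002)),
               "no positive growth")
})

test_that("beetle right-hand side and growth rate match the two-stage linear model", {
  bp <- beetle_params(r = 0.0238, b = 2.6786, mu_A = 0.0089, mu_J = 3.561)
  expect_equal(beetle_rhs(c(J = 0, A = 10), bp),
               c(J = 26.786, A = -0.089))
  expect_equal(beetle_rhs(c(J = 0, A = 0), bp), c(J = 0, A = 0))
  # general eigen routine agrees with the quadratic closed form
  expect_equal(beetle_growth_rate(bp),
               beetle_lambda_closed(0.0238, 2.6786, 0.0089, 3.561),
               tolerance = 1e-12)
  # the leaf-beetle calibration implies a 4.4-fold increase in 24 weeks
  expect_equal(beetle_growth_rate(bp), log(4.4) / 168, tolerance = 0.01)
  # decoupled stages when r = 0
  expect_equal(beetle_growth_rate(beetle_params(0, 5, 0.2, 0.7)), -0.2)
  # b = 0: juveniles strictly decline
  expect_lt(beetle_rhs(c(J = 3, A = 5), beetle_params(0.1, 0, 0.1, 0.1))[["J"]], 0)
})

test_that("without beetles the coupled model reduces to the plant model", {
  pr <- species_preset("leaf")
  st <- c(T = 7, N = 50, L = 50, LX = 0, TX = 0, J = 0, A = 0)
  d <- coupled_rhs(st, pr$plant, pr$beetle, pr$inter)
  pl <- plant_rhs(c(T = 7, N = 50, L = 50), pr$plant)
  expect_equal(d[["T"]], pl[["T"]])
  expect_equal(d[["N"]], pl[["N"]])
  expect_equal(d[["L"]], pl[["L"]])
  expect_equal(d[["LX"]], pr$plant$lambda_D * 7)
  expect_equal(d[["TX"]], 0)
  # with constant G the reduction holds even when leaves were thinned
  st2 <- c(T = 7, N = 50, L = 20, LX = 30, TX = 0, J = 0, A = 0)
  d2 <- coupled_rhs(st2, pr$plant, pr$beetle, pr$inter, g_form = "constant")
  expect_equal(d2[["N"]], pl[["N"]])
})

test_that("leaf-abundance limits of the beetle equations behave as designed", {
  pr <- species_preset("leaf")
  # plentiful leaves: transition always succeeds, no starvation mortality
  hi <- coupled_rhs(c(T = 10, N = 100, L = 1e9, LX = 0, TX = 0, J = 20, A = 5),
                    pr$plant, pr$beetle, pr$inter)
  expect_equal(hi[["A"]], pr$beetle$r * 20 - pr$beetle$mu_A * 5,
               tolerance = 1e-6)
  # no leaves: no recruitment, adult mortality doubles (mu_A2 = mu_A)
  lo <- coupled_rhs(c(T = 10, N = 100, L = 0, LX = 100, TX = 0, J = 20, A = 5),
                    pr$plant, pr$beetle, pr$inter)
  expect_equal(lo[["A"]], -(pr$beetle$mu_A + pr$inter$mu_A2) * 5)
})

test_that("grazing terms are monotone in beetle numbers", {
  pr <- species_preset("tip")
  st <- function(J, A) c(T = 30, N = 200, L = 150, LX = 5, TX = 2,
                         J = J, A = A)
  dL_A <- sapply(c(0, 5, 20, 80), function(A)
    coupled_rhs(st(10, A), pr$plant, pr$beetle, pr$inter)[["L"]])
  expect_true(all(diff(dL_A) <= 0))
  dL_J <- sapply(c(0, 5, 20, 80), function(J)
    coupled_rhs(st(J, 10), pr$plant, pr$beetle, pr$inter)[["L"]])
  expect_true(all(diff(dL_J) <= 0))
  dT_J <- sapply(c(0, 5, 20, 80), function(J)
    coupled_rhs(st(J, 10), pr$plant, pr$beetle, pr$inter)[["T"]])
  expect_true(all(diff(dT_J) <= 0))
})

test_that("the logistic variant caps tip creation at the node carrying capacity", {
  pr <- species_preset("tip")
  st <- c(T = 30, N = 500, L = 400, LX = 0, TX = 0, J = 10, A = 5)
  at_K <- coupled_rhs(st, pr$plant, pr$beetle, pr$inter, K = 500)
  expect_equal(at_K[["T"]],
               -pr$inter$gamma_JT * 10 * 30 / (pr$inter$alpha + 30))
  # K -> infinity reduces to the unbounded model
  no_K <- coupled_rhs(st, pr$plant, pr$beetle, pr$inter)
  big_K <- coupled_rhs(st, pr$plant, pr$beetle, pr$inter, K = 1e12)
  expect_equal(big_K, no_K, tolerance = 1e-9)
})

test_that("with a carrying capacity and no beetles growth is capped (two integrators agree)", {
  pr <- species_preset("leaf")
  init <- release_init(100, 0)
  times <- seq(0, 2000, by = 10)
  sol <- integrate_model("coupled", init, t_end = 2000, plant = pr$plant,
                         beetle = pr$beetle, inter = pr$inter, K = 500,
                         times = times)
  # an independent stiff integrator at tight tolerance
  fn <- function(t, y, p) {
    list(unname(coupled_rhs(y, pr$plant, pr$beetle, pr$inter, K = 500)))
  }
  ref <- deSolve::ode(init, c(0, 2000), fn, NULL, method = "radau",
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(sol$N[nrow(sol)], unname(ref[2, "N"]), tolerance = 0.01)
  # exponential escape is gone: N stays within a small multiple of K,
  # while the unbounded model would have grown ~ e^(0.0159 * 2000)
  expect_lt(max(sol$N), 2 * 500)
})

test_that("plant-only integration reproduces closed-form exponential growth", {
  pp <- plant_params()
  lam <- plant_growth_rate(pp)
  s <- sqrt((pp$lambda_G - pp$lambda_D) / pp$lambda_B)  # eigenvector slope
  init <- c(T = 10, N = 10 * s, L = 10 * s)
  sol <- integrate_model("plant", init, t_end = 200, plant = pp,
                         times = c(0, 200))
  expect_equal(sol$L[2] / sol$L[1], exp(lam * 200), tolerance = 0.01)
  # linearity: doubling the initial condition doubles the solution
  sol2 <- integrate_model("plant", 2 * init, t_end = 200, plant = pp,
                          times = c(0, 200))
  expect_equal(sol2$L, 2 * sol$L, tolerance = 1e-8)
  expect_equal(sol2$T, 2 * sol$T, tolerance = 1e-8)
})

test_that("beetle-only integration from the dominant eigenvector multiplies by 4.4 in 24 weeks", {
  bp <- beetle_params(r = 0.0238, b = 2.6786, mu_A = 0.0089, mu_J = 3.561)
  m <- rbind(c(-bp$r - bp$mu_J, bp$b), c(bp$r, -bp$mu_A))
  ev <- eigen(m)
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v <- abs(v) / sum(abs(v)) * 100
  sol <- integrate_model("beetle", c(J = v[1], A = v[2]), t_end = 168,
                         beetle = bp, times = c(0, 168))
  ratio <- (sol$J[2] + sol$A[2]) / (sol$J[1] + sol$A[1])
  expect_equal(ratio, 4.4, tolerance = 0.02)
})

test_that("cumulative leaf and tip production are conserved along coupled trajectories", {
  pr <- species_preset("stem")
  init <- release_init(100, 10)
  times <- seq(0, 300, by = 0.5)
  sol <- integrate_model("coupled", init, t_end = 300, plant = pr$plant,
                         beetle = pr$beetle, inter = pr$inter,
                         times = times, g_form = "constant")
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  # d(L + LX)/dt = lambda_G T  and  d(T + TX)/dt = lambda_B N
  lhs_L <- (sol$L + sol$LX) - (init[["L"]] + init[["LX"]])
  expect_equal(lhs_L[length(times)],
               trapz(times, pr$plant$lambda_G * sol$T), tolerance = 1e-3)
  lhs_T <- (sol$T + sol$TX) - (init[["T"]] + init[["TX"]])
  expect_equal(lhs_T[length(times)],
               trapz(times, pr$plant$lambda_B * sol$N), tolerance = 1e-3)
  # no state dips below -10 * absolute tolerance
  expect_true(all(as.matrix(sol[-1]) > -1e-9))
})
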