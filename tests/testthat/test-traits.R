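test_that("growth rate, damping ratio and stable structure on hand oracles", {
  m <- population_metrics(toy$diag_A)
  expect_equal(m$lam, 0.9, tolerance = 1e-10)
  expect_equal(m$lam2_mod, 0.3, tolerance = 1e-10)
  expect_equal(m$xi, 3, tolerance = 1e-10)

  m <- population_metrics(toy$leslie_A)          # cyclic Leslie: both roots 1
  expect_equal(m$lam, 1, tolerance = 1e-10)
  expect_equal(m$xi, 1, tolerance = 1e-10)
  expect_equal(sum(m$w), 1, tolerance = 1e-9)
  expect_true(all(m$w >= 0))

  m <- population_metrics(toy$two_by_two)        # roots 0.6 and 0.1 by hand
  expect_equal(m$lam, 0.6, tolerance = 1e-10)
  expect_equal(m$lam2_mod, 0.1, tolerance = 1e-10)
  expect_equal(m$xi, 6, tolerance = 1e-10)
})

test_that("fundamental and next-generation matrices from hand inversions", {
  one <- list(U = matrix(0.5), V = matrix(0))
  expect_equal(fundamental_and_nextgen(one)$N, matrix(2))
  zero <- list(U = matrix(0, 2, 2), V = diag(2))
  expect_equal(fundamental_and_nextgen(zero)$N, diag(2))

  kl <- leslie_kernel(toy$leslie_A, toy$leslie_U, toy$leslie_V)
  der <- fundamental_and_nextgen(kl)
  expect_equal(der$N, matrix(c(1, 0.5, 0, 1), 2, 2), tolerance = 1e-12)
  expect_equal(der$F, matrix(c(1, 0, 2, 0), 2, 2), tolerance = 1e-12)
  expect_equal(net_reproductive_rate(der), 1, tolerance = 1e-10)
  expect_equal(net_reproductive_rate(matrix(0, 2, 2)), 0)

  imm <- list(U = diag(2), V = diag(2))
  expect_error(fundamental_and_nextgen(imm), "spectral radius")
})

test_that("generation time and its degenerate replacement point", {
  expect_equal(generation_time(1.1, 2), log(2) / log(1.1), tolerance = 1e-12)
  expect_equal(generation_time(1.3, 1.3), 1, tolerance = 1e-12)
  expect_true(is.na(generation_time(1, 1)))
  expect_true(is.na(generation_time(1 + 1e-12, 2)))
})

test_that("life expectancy decomposes exactly into juvenile and adult years", {
  # single-bin chain: geometric residence 1 / (1 - 0.5) = 2 juvenile years
  mesh1 <- structure(list(n_bins = 1L, lower = 0.5, upper = 1.5,
                          midpoints = 1, width = 1, edges = c(0.5, 1.5)),
                     class = "length_mesh")
  p1 <- deb_params(1, 2, 3, 0.3, 1, 0.2, 0.1)
  led <- life_expectancy_decomposition(matrix(2), mesh1, p1)
  expect_equal(led$eta_e, 2)
  expect_equal(led$L_alpha, 2)
  expect_equal(led$L_omega, 0)

  # 2-bin chain: N = (I - U)^(-1) inverted by hand
  U <- matrix(c(0.3, 0.5, 0, 0.8), 2, 2)
  N <- solve(diag(2) - U)
  led <- life_expectancy_decomposition(N, mesh2, params2)
  expect_equal(led$L_alpha, 1 / 0.7, tolerance = 1e-12)
  expect_equal(led$L_omega, 0.5 / (0.7 * 0.2), tolerance = 1e-12)
  expect_equal(led$eta_e, led$L_alpha + led$L_omega, tolerance = 1e-12)

  expect_error(life_expectancy_decomposition(N, mesh2,
                                             deb_params(10, 20, 30, .3, 1,
                                                        .2, .1)),
               "outside the mesh")
})

test_that("age schedules reproduce the two-step Leslie computation", {
  kl <- leslie_kernel(toy$leslie_A, toy$leslie_U, toy$leslie_V)
  s <- age_schedules(kl)
  expect_equal(s$l_x[1], 1)
  expect_equal(s$l_x[2], 0.5)
  expect_equal(s$m_x[2], 2)
  expect_equal(sum(s$l_x * s$m_x), 1)

  dead <- leslie_kernel(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  s <- age_schedules(dead)
  expect_equal(s$l_x[-1], numeric(0))   # no survival past birth
  expect_true(all(s$m_x == 0))
})

test_that("iteroparity implements the printed mean/sd fertility ratio", {
  expect_equal(iteroparity(list(m_x = c(0, 4)), eta_e = 1), 1)  # pop sd = 2
  expect_true(is.infinite(iteroparity(list(m_x = rep(2, 5)), eta_e = 4)))
  s1 <- iteroparity(list(m_x = c(0, 1, 3, 2)), eta_e = 3)
  s2 <- iteroparity(list(m_x = 5 * c(0, 1, 3, 2)), eta_e = 3)
  expect_equal(s1, s2)   # scale invariance
})

test_that("stable-stage weighting of progressive/retrogressive growth", {
  Kid <- list(G = diag(3), V = matrix(0, 3, 3))
  wv <- weighted_vital_rates(Kid, rep(1 / 3, 3))
  expect_equal(wv$gamma, 0)
  expect_equal(wv$rho, 0)

  Kup <- list(G = matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 1), 3, 3),
              V = matrix(0, 3, 3))  # everything moves up (last col absorbs)
  wv <- weighted_vital_rates(Kup, c(0.5, 0.5, 0))
  expect_equal(wv$gamma, 1)
  expect_equal(wv$rho, 0)

  G <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  wv <- weighted_vital_rates(list(G = G, V = matrix(1, 2, 2)), c(0.5, 0.5))
  expect_equal(wv$gamma, 0.05)
  expect_equal(wv$rho, 0.10)
  expect_equal(wv$phi, 2)
})

test_that("trait vector flags non-persistent and degenerate records", {
  # maturation unreachable at the low feeding level
  p <- deb_params(20, 85, 100, 0.3, 40, 0.2, 0.15)
  tv <- trait_vector(p, 0.6)
  expect_false(tv$persistent)

  pdead <- deb_params(20, 50, 100, 0.3, 40, mu_j = 1e9, mu_a = 1e9)
  tv <- trait_vector(pdead, 0.9)
  expect_false(tv$persistent)
  expect_equal(tv$lambda, 0)

  tv <- trait_vector(toy$params, 0.9)
  expect_true(tv$persistent)
  # construction identity T log(lambda) = log(R0)
  expect_equal(tv$T * log(tv$lambda), log(tv$R0), tolerance = 1e-8)
  expect_equal(tv$eta_e, tv$L_alpha + tv$L_omega, tolerance = 1e-8)
})

test_that("three-bin Leslie oracle: lambda from the characteristic polynomial", {
  A <- matrix(c(0, 0.5, 0,  1, 0, 0.4,  5, 0, 0), 3, 3)
  U <- matrix(c(0, 0.5, 0,  0, 0, 0.4,  0, 0, 0), 3, 3)
  V <- A - U
  # lambda^3 - 0.5 lambda - 1 = 0, solved independently via polyroot
  roots <- polyroot(c(-1, -0.5, 0, 1))
  lam_oracle <- max(Re(roots[abs(Im(roots)) < 1e-9]))
  m <- population_metrics(A)
  expect_equal(m$lam, lam_oracle, tolerance = 1e-10)
  der <- fundamental_and_nextgen(list(U = U, V = V))
  expect_equal(net_reproductive_rate(der), 1.5, tolerance = 1e-10)  # by hand
  expect_equal(sum(der$N[, 1]), 1.7, tolerance = 1e-12)             # eta_e
})
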