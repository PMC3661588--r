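test_that("sclerostin gate is the clamped osteocyte-deficit ramp", {
  expect_identical(sclerostin_gate(200, 200), 0)
  expect_identical(sclerostin_gate(0, 200), 1)
  expect_equal(sclerostin_gate(180, 200), 0.1)
  expect_identical(sclerostin_gate(220, 200), 0)   # Heaviside clamps overshoot

  # property: agrees with the literal (1 - S/K) * H(1 - S/K) definition
  set.seed(7)
  S <- runif(200, 0, 500)
  K <- runif(200, 1, 400)
  for (i in seq_along(S)) {
    x <- 1 - S[i] / K[i]
    expect_identical(sclerostin_gate(S[i], K[i]), x * as.numeric(x > 0))
  }
  expect_error(sclerostin_gate(100, 0), class = "bmusim_validation_error")
  expect_error(sclerostin_gate(100, -5), class = "bmusim_validation_error")
})

test_that("power-law conventions let exponents switch regulators off", {
  expect_identical(powerlaw(0, 1), 0)
  expect_identical(powerlaw(5, 0), 1)
  expect_identical(powerlaw(0, 0), 1)   # regulator removed, term survives
  expect_error(powerlaw(0, -1), class = "bmusim_domain_error")
  expect_error(powerlaw(-2, 2), class = "bmusim_domain_error")
  set.seed(11)
  b <- runif(100, 0.01, 50); e <- runif(100, -2, 3)
  expect_equal(powerlaw(b, e), exp(e * log(b)))
})

test_that("the intact-network state is an equilibrium, exactly", {
  expect_identical(equilibrium_residual(remodeling_params()), 0)
  for (p in random_params(20))
    expect_identical(equilibrium_residual(p), 0)
  # one lost osteocyte opens the gate and the residual turns positive
  p <- remodeling_params()
  d <- remodeling_rhs(0, c(S = p[["K_S"]] - 1, P = 0, B = 0, C = 0, z = 100), p)
  expect_gt(max(abs(d)), 0)
})

test_that("derivative at the post-apoptosis state matches hand evaluation", {
  # S = 180 opens the gate to s = 0.1; only stromal differentiation fires:
  # dP = alpha2 * 180^2 * 0.1 = 324 cells/day, everything else zero.
  d <- remodeling_rhs(0, c(S = 180, P = 0, B = 0, C = 0, z = 100),
                      remodeling_params())
  expect_equal(d, c(S = 0, P = 324, B = 0, C = 0, z = 0))
})

test_that("cell derivatives do not involve the bone turnover rates", {
  p1 <- remodeling_params()
  p2 <- remodeling_params(k1 = 1.4, k2 = 0.03089)
  set.seed(13)
  for (i in 1:25) {
    st <- c(S = runif(1, 0, 250), P = runif(1, 0, 400),
            B = runif(1, 0, 500), C = runif(1, 0, 30), z = runif(1, 60, 140))
    d1 <- remodeling_rhs(0, st, p1)
    d2 <- remodeling_rhs(0, st, p2)
    expect_identical(d1[c("S", "P", "B", "C")], d2[c("S", "P", "B", "C")])
    # dz scales linearly with its two rates
    expect_equal(d2[["z"]], -1.4 * st[["C"]] + 0.03089 * st[["B"]])
  }
})

test_that("osteocytes never die inside the model equations", {
  # no osteocyte death term: dS/dt >= 0 across the admissible region
  set.seed(17)
  for (p in random_params(5, seed = 29)) {
    for (i in 1:20) {
      st <- c(S = runif(1, 0, 1.5 * p[["K_S"]]), P = runif(1, 0, 400),
              B = runif(1, 0, 500), C = runif(1, 0, 30), z = 100)
      expect_gte(remodeling_rhs(0, st, p)[["S"]], 0)
    }
  }
})

test_that("parameter validation guards the singular exponent placements", {
  expect_error(remodeling_params(g42 = -1), class = "bmusim_validation_error")
  expect_error(remodeling_params(g22 = -0.5), class = "bmusim_validation_error")
  expect_silent(remodeling_params(g43 = -1.5))  # epsilon-guarded base
  expect_error(remodeling_params(K_S = 0), class = "bmusim_validation_error")
  expect_error(remodeling_params(epsilon = 0), class = "bmusim_validation_error")
  expect_error(remodeling_params(alpha1 = -0.1), class = "bmusim_validation_error")
  expect_error(remodeling_params(gXX = 1), class = "bmusim_validation_error")
  expect_error(remodeling_params(alpha1 = Inf), class = "bmusim_validation_error")
})

test_that("the right-hand side rejects invalid states", {
  p <- remodeling_params()
  expect_error(remodeling_rhs(0, c(S = NaN, P = 0, B = 0, C = 0, z = 100), p),
               class = "bmusim_domain_error")
  expect_error(remodeling_rhs(0, c(S = 180, P = -3, B = 0, C = 0, z = 100), p),
               class = "bmusim_domain_error")
  expect_error(remodeling_rhs(0, c(1, 2, 3), p),
               class = "bmusim_validation_error")
})

test_that("initial state derives from the osteocyte deficit", {
  p <- remodeling_params()
  expect_identical(initial_state(p, initial_condition(sigma = 20)),
                   c(S = 180, P = 0, B = 0, C = 0, z = 100))
  expect_error(initial_state(p, initial_condition(sigma = 250)),
               class = "bmusim_validation_error")
  expect_error(initial_condition(sigma = -1), class = "bmusim_validation_error")
})
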