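test_that("homogeneous populations give A(t) identical to the incidence curve", {
  cv <- fixture_incidence("cancer_like")
  A <- discover_aging_coefficient(cv, uniform_pop())
  expect_identical(A$A, A$incidence)
})

test_that("two-group hand recursion is reproduced to 1e-9", {
  pop <- new_population(c(1.5, 0.5), normalize = FALSE)
  A <- discover_aging_coefficient(flat_curve(0.1, 2), pop, max_age = 1)
  expect_equal(A$A[1], 0.1, tolerance = 1e-12)
  # after year 0 the unaffected masses are {0.425, 0.475}; mean score
  # 0.875/0.9, so A(1) = 0.1 * 0.9 / 0.875
  expect_equal(A$A[2], 0.09 / 0.875, tolerance = 1e-9)
  ap <- apply_aging_coefficient(A, pop)
  expect_equal(attr(ap, "final_weights"),
               c(0.425 * (1 - A$A[2] * 1.5), 0.475 * (1 - A$A[2] * 0.5)),
               tolerance = 1e-12)
})

test_that("discovery matches an independent uniroot-based solver on random discrete populations", {
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(2:6, 1)
    G <- exp(rnorm(k, sd = 0.8))
    w <- runif(k)
    pop <- new_population(G, weights = w)
    I <- c(0, runif(8, 0.01, 0.2))
    cv <- incidence_curve("tabulated", list(values = I), max_age = 8)
    A <- discover_aging_coefficient(cv, pop, max_age = 8)
    expect_equal(A$A, oracle_aging(I, pop$values, pop$weights),
                 tolerance = 1e-9)
  }
})

test_that("expectation-mode round trip reproduces the incidence curve to numerical precision", {
  arch <- build_architecture("common_low", 400)
  pop <- bin_population(arch, 2001)
  for (kind in c("cancer_like", "t2d_like")) {
    cv <- fixture_incidence(kind)
    A <- discover_aging_coefficient(cv, pop)
    ap <- apply_aging_coefficient(A, pop)
    idx <- A$incidence > 0
    expect_lt(max(abs(ap$incidence[idx] - A$incidence[idx]) /
                    A$incidence[idx]), 1e-10)
  }
})

test_that("the exponential hazard transform also round-trips", {
  arch <- build_architecture("common_low", 400)
  pop <- bin_population(arch, 2001)
  cv <- fixture_incidence("cancer_like")
  A <- discover_aging_coefficient(cv, pop, transform = "exponential")
  ap <- apply_aging_coefficient(A, pop)
  idx <- A$incidence > 0
  expect_lt(max(abs(ap$incidence[idx] - A$incidence[idx]) /
                  A$incidence[idx]), 1e-10)
  # exponential transform needs a larger A for the same incidence
  Ac <- discover_aging_coefficient(cv, pop)
  expect_true(all(A$A[idx] > Ac$A[idx]))
})

test_that("frailty depletion lowers the mean unaffected score and lifts A above I", {
  arch <- build_architecture("common_low", 400)
  pop <- bin_population(arch, 2001)
  cv <- fixture_incidence("t2d_like")
  A <- discover_aging_coefficient(cv, pop)
  # evolve the weights alongside and track the mean unaffected score
  w <- pop$weights
  meanG <- numeric(length(A$age))
  for (i in seq_along(A$age)) {
    meanG[i] <- sum(w * pop$values) / sum(w)
    w <- w * (1 - pmin(A$A[i] * pop$values, 1))
  }
  active <- A$incidence > 0
  expect_true(all(diff(meanG[active]) < 0))
  ratio <- A$A[active] / A$incidence[active]
  expect_true(all(ratio >= 1))
  expect_true(all(diff(ratio) > 0))
})

test_that("stochastic application recovers the curve within binomial error", {
  arch <- build_architecture("common_low", 400)
  pop <- bin_population(arch, 2001)
  cv <- fixture_incidence("cancer_like")
  A <- discover_aging_coefficient(cv, pop)
  popS <- sample_population(arch, 50000, seed = 9)
  st <- apply_aging_coefficient(A, popS, mode = "stochastic", seed = 10)
  idx <- which(A$incidence > 0 & st$unaffected > 0.1)
  se <- sqrt(A$incidence[idx] * (1 - A$incidence[idx]) /
               (50000 * st$unaffected[idx]))
  expect_true(all(abs(st$incidence[idx] - A$incidence[idx]) < 4 * se))
})

test_that("risk-lowered populations fall strictly below the curve at every age", {
  arch <- build_architecture("common_low", 400)
  pop <- bin_population(arch, 2001)
  cv <- fixture_incidence("cancer_like")
  A <- discover_aging_coefficient(cv, pop)
  lowered <- apply_therapy(pop, therapy_spec(or_multiplier = 0.5))
  ap <- apply_aging_coefficient(A, lowered)
  idx <- A$incidence > 0
  expect_true(all(ap$incidence[idx] < A$incidence[idx]))
})

test_that("degenerate inputs are rejected or truncated with a warning", {
  # I(t) = 1 cannot be reproduced with bounded scores under the clamp
  pop <- new_population(c(1.5, 0.5), normalize = FALSE)
  cv1 <- incidence_curve("tabulated", list(values = c(0.5, 1)), max_age = 1)
  expect_error(discover_aging_coefficient(cv1, pop, max_age = 1),
               "unbounded")
  # sustained extreme incidence exhausts the unaffected pool
  cv2 <- flat_curve(0.9, 30)
  expect_warning(
    A <- discover_aging_coefficient(cv2, uniform_pop(), max_age = 29),
    "exhausted")
  expect_true(any(is.na(A$A)))
  # off-scale population: neither mean-1 nor sharing the reference
  off <- new_population(c(3, 1), normalize = FALSE)
  Aok <- discover_aging_coefficient(flat_curve(0.05, 5),
                                    new_population(c(2, 1)), max_age = 4)
  expect_error(apply_aging_coefficient(Aok, off), "risk scale")
})

test_that("aging coefficients survive the CSV + sidecar round trip", {
  cv <- fixture_incidence("cancer_like")
  pop <- new_population(exp(c(-0.5, 0, 0.5)))
  A <- discover_aging_coefficient(cv, pop)
  path <- withr::local_tempfile(fileext = ".csv")
  write_aging_coefficient(A, path)
  back <- read_aging_coefficient(path)
  expect_equal(back$A, A$A, tolerance = 1e-12)
  expect_identical(back$transform, A$transform)
  expect_equal(back$normalization_reference, A$normalization_reference,
               tolerance = 1e-12)
  # the re-loaded coefficient still pairs with the population
  ap <- apply_aging_coefficient(back, pop)
  idx <- A$incidence > 0
  expect_equal(ap$incidence[idx], A$incidence[idx], tolerance = 1e-8)
})
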