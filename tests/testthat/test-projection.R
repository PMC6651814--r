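test_that("population projection reproduces the two-step hand computation", {
  # immortal cohort, homogeneous scores, I = 0.1 for two years:
  # D = (0.1, 0.9 * 0.1), lifetime risk 0.19
  pop <- uniform_pop()
  A <- discover_aging_coefficient(flat_curve(0.1, 2), pop, max_age = 1)
  proj <- project_population(A, pop, immortal_table())
  expect_equal(proj$density, c(0.1, 0.09), tolerance = 1e-12)
  expect_equal(lifetime_risk(proj), 0.19, tolerance = 1e-12)

  # no incidence, no risk
  A0 <- discover_aging_coefficient(flat_curve(0, 5), pop, max_age = 4)
  expect_equal(lifetime_risk(project_population(A0, pop, immortal_table())),
               0)
})

test_that("projection bookkeeping: C is the running sum of D and respects survival", {
  fx <- generate_fixtures("t2d_like")
  pop <- bin_population(fx$arch, 2001)
  A <- discover_aging_coefficient(fx$curve, pop)
  proj <- project_population(A, pop, fx$life_table)
  expect_equal(proj$cumulative, cumsum(proj$density), tolerance = 1e-15)
  expect_lte(lifetime_risk(proj), 1)
  expect_true(all(diff(proj$cumulative) >= 0))

  # conditional incidence equals the discovery curve; density carries the
  # disease-free and survivor fractions
  idx <- A$incidence > 0
  expect_lt(max(abs(proj$incidence[idx] - A$incidence[idx]) /
                  A$incidence[idx]), 1e-10)
  ap <- apply_aging_coefficient(A, pop)
  S <- fx$life_table$S[match(A$age, fx$life_table$age)]
  expect_equal(proj$density, proj$incidence * ap$unaffected * S,
               tolerance = 1e-12)

  # a dead cohort contributes nothing
  dead <- life_table(c(rep(0.01, 60), rep(1, 60)))
  proj2 <- project_population(A, pop, dead)
  expect_true(all(proj2$density[proj2$age > 61] == 0))
})

test_that("fixed-HR lifetime risk follows the individual-hazard closed form", {
  pop <- uniform_pop()
  A <- discover_aging_coefficient(flat_curve(0.1, 2), pop, max_age = 1)
  expect_equal(lifetime_risk(project_fixed_hr(A, 1, immortal_table())),
               0.19, tolerance = 1e-12)
  expect_equal(lifetime_risk(project_fixed_hr(A, 0, immortal_table())), 0)
})

test_that("lifetime risk halves with the hazard ratio in the low-risk regime", {
  fx <- generate_fixtures("cancer_like")
  pop <- bin_population(fx$arch, 5001)
  A <- discover_aging_coefficient(fx$curve, pop)
  lt <- fx$life_table
  r1 <- lifetime_risk(project_fixed_hr(A, 1, lt))
  r05 <- lifetime_risk(project_fixed_hr(A, 0.5, lt))
  expect_lt(r1, 0.10)
  expect_equal(r05 / r1, 0.5, tolerance = 0.02)
})

test_that("the proportionality approximation degrades as risk saturates", {
  fx <- generate_fixtures("ad_like")
  pop <- bin_population(fx$arch, 2001)
  A <- discover_aging_coefficient(fx$curve, pop)
  lt <- fx$life_table
  risks <- vapply(c(1, 2, 4, 8), function(h)
    lifetime_risk(project_fixed_hr(A, h, lt)), numeric(1))
  # deviation of each doubling from exact proportionality grows with risk
  dev <- abs(risks[-1] / risks[-4] / 2 - 1)
  expect_true(all(diff(dev) > 0))
})

test_that("the HR grid is monotone in both directions and anchored at its corner", {
  fx <- generate_fixtures("cancer_like")
  pop <- bin_population(fx$arch, 2001)
  A <- discover_aging_coefficient(fx$curve, pop)
  lt <- fx$life_table

  single <- hr_grid(A, lt, hrs = 1, deltas = 0)
  expect_equal(single$lifetime_risk,
               lifetime_risk(project_fixed_hr(A, 1, lt)))

  grid <- hr_grid(A, lt, hrs = 2^seq(-2, 2), deltas = c(0, 5, 10, 15))
  # expand.grid order: hr varies fastest within each delta
  wide <- matrix(grid$lifetime_risk, nrow = 5,
                 dimnames = list(hr = 2^seq(-2, 2), delta = c(0, 5, 10, 15)))
  expect_true(all(apply(wide, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(wide, 1, function(row) all(diff(row) > 0))))
})

test_that("onset delays interpolate, add up, and vanish for identical scenarios", {
  fx <- generate_fixtures("cancer_like")
  pop <- bin_population(fx$arch, 2001)
  A <- discover_aging_coefficient(fx$curve, pop)
  lt <- fx$life_table
  p1 <- project_fixed_hr(A, 1, lt)
  expect_identical(onset_delay_slope(p1, p1), 0)

  # closed-form check on a constant-hazard immortal cohort: the age at
  # which C reaches a fraction f of the lifetime risk solves
  # 1 - (1-p)^t = f * (1 - (1-p)^T)
  horizon <- 120
  pc <- 0.02
  Ac <- discover_aging_coefficient(flat_curve(pc, horizon), uniform_pop(),
                                   max_age = horizon - 1)
  base <- project_fixed_hr(Ac, 1, immortal_table(horizon))
  half <- project_fixed_hr(Ac, 0.5, immortal_table(horizon))
  t_at <- function(p, f) {
    lr <- 1 - (1 - p)^horizon
    log(1 - f * lr) / log(1 - p)
  }
  expected <- round(t_at(pc / 2, 0.3) - t_at(pc, 0.3))
  expect_equal(onset_delay_slope(base, half), expected, tolerance = 1)

  # chained HR reductions are additive within rounding
  p16 <- project_fixed_hr(A, 16, lt)
  p4 <- project_fixed_hr(A, 4, lt)
  d_a <- onset_delay_slope(p16, p4)
  d_b <- onset_delay_slope(p4, p1)
  d_all <- onset_delay_slope(p16, p1)
  expect_lte(abs(d_a + d_b - d_all), 1)
})

test_that("regaining the baseline after treatment takes the documented scan form", {
  fx <- generate_fixtures("cancer_like")
  pop <- bin_population(fx$arch, 2001)
  A <- discover_aging_coefficient(fx$curve, pop)
  lt <- fx$life_table
  expect_identical(years_to_regain_baseline(A, pop, pop, lt), 0L)
  expect_identical(years_to_regain_baseline(A, 1, 1, lt), 0L)
  # mild reduction regains quickly; beyond-scan cases report Inf
  mild <- apply_therapy(pop, therapy_spec(or_multiplier = 0.9))
  expect_lt(years_to_regain_baseline(A, pop, mild, lt), 10)
  strong <- apply_therapy(pop, therapy_spec(or_multiplier = 0.05))
  expect_identical(years_to_regain_baseline(A, pop, strong, lt,
                                            scan_max = 10L), Inf)
})
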