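# Shared tiny objects for the unit tests.  Everything is built in code;
# nothing is read from disk.

immortal_table <- function(n_ages = 120L) life_table(rep(0, n_ages))

# constant-incidence tabulated curve over `n_years` ages
flat_curve <- function(p, n_years) {
  incidence_curve("tabulated", list(values = rep(p, n_years)),
                  max_age = n_years - 1L)
}

# homogeneous population: every score exactly 1
uniform_pop <- function(n = 1L) new_population(rep(1, n), normalize = FALSE)

# independent reference solver for the aging-coefficient recursion:
# same model equations, but solved per age with stats::uniroot at high
# precision instead of the package's closed-form/bisection path
oracle_aging <- function(I, G, w) {
  w <- w / sum(w)
  A <- numeric(length(I))
  for (i in seq_along(I)) {
    if (I[i] == 0) { A[i] <- 0; next }
    f <- function(a) sum(w * pmin(a * G, 1)) / sum(w) - I[i]
    hi <- 1 / min(G)
    while (f(hi) < 0) hi <- hi * 2
    A[i] <- stats::uniroot(f, c(0, hi), tol = 1e-15)$root
    w <- w * (1 - pmin(A[i] * G, 1))
  }
  A
}
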