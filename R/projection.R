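#' Project a population through an aging coefficient and a life table
#'
#' Evolves the unaffected-mass recursion of the aging model jointly with
#' all-cause survival.  At age t the first-diagnosis mass is
#' m(t) = sum_u w_u(t) h(A(t) G_u) (w starts at the population weights and
#' is depleted each year), the incidence density is D(t) = m(t) S(t), and
#' the cumulative incidence C(t) is the running sum of D; its final value is
#' the lifetime risk.  Mortality is independent of the risk score, so it
#' enters only through the survivor fraction S.
#'
#' @param A an \code{lod_aging_coefficient}.
#' @param pop an \code{lod_population} sharing the discovery normalization
#'   reference.
#' @param lt an \code{lod_life_table} covering the coefficient's age range.
#' @return object of class \code{lod_projection}: data frame with columns
#'   \code{age}, \code{incidence} (conditional yearly rate among unaffected
#'   survivors), \code{density} D(t), \code{cumulative} C(t), plus
#'   attributes \code{lifetime_risk} and \code{scenario}.
#' @export
project_population <- function(A, pop, lt) {
  stopifnot(inherits(A, "lod_aging_coefficient"),
            inherits(pop, "lod_population"),
            inherits(lt, "lod_life_table"))
  .check_pairing(A, pop)
  ages <- A$age
  if (max(ages) > max(lt$age))
    stop("life table does not cover the coefficient's age range")
  S <- lt$S[match(ages, lt$age)]
  G <- pop$values
  w <- pop$weights
  inc <- dens <- numeric(length(ages))
  for (i in seq_along(ages)) {
    if (is.na(A$A[i])) { inc[i] <- dens[i] <- NA_real_; next }
    p <- .hazard_prob(A$A[i], G, A$transform)
    m <- sum(w * p)
    wsum <- sum(w)
    inc[i] <- if (wsum > 0) m / wsum else 0
    dens[i] <- m * S[i]
    w <- w * (1 - p)
  }
  .new_projection(ages, inc, dens, scenario = list(kind = "population"))
}

#' Lifetime risk and incidence density for a fixed hazard ratio
#'
#' Treats a single individual whose score is pinned at \code{hr} relative to
#' the population mean (HR 1 = average risk).  The yearly diagnosis
#' probability is p(t) = h(A(t) hr); the incidence density composes the
#' individual's own disease-free survival with all-cause survival,
#' D(t) = p(t) prod_{s<t}(1 - p(s)) S(t), and the lifetime risk is the sum
#' of D.  While the cumulative risk stays low this is proportional to hr,
#' which is the regime where halving the hazard ratio halves the lifetime
#' risk.
#'
#' @param A an \code{lod_aging_coefficient}.
#' @param hr non-negative hazard ratio.
#' @param lt an \code{lod_life_table}.
#' @return an \code{lod_projection}.
#' @export
project_fixed_hr <- function(A, hr, lt) {
  stopifnot(inherits(A, "lod_aging_coefficient"),
            inherits(lt, "lod_life_table"))
  if (!is.numeric(hr) || length(hr) != 1L || hr < 0)
    stop("'hr' must be a single non-negative number")
  ages <- A$age
  if (max(ages) > max(lt$age))
    stop("life table does not cover the coefficient's age range")
  S <- lt$S[match(ages, lt$age)]
  Avals <- ifelse(is.na(A$A), 0, A$A)
  p <- if (A$transform == "clamp") pmin(Avals * hr, 1) else
    1 - exp(-Avals * hr)
  free <- c(1, cumprod(1 - p))[seq_along(p)]  # disease-free before age t
  dens <- p * free * S
  .new_projection(ages, p, dens, scenario = list(kind = "fixed_hr", hr = hr))
}

.new_projection <- function(ages, incidence, density, scenario) {
  cum <- cumsum(ifelse(is.na(density), 0, density))
  out <- data.frame(age = ages, incidence = incidence, density = density,
                    cumulative = cum)
  structure(out, class = c("lod_projection", "data.frame"),
            lifetime_risk = cum[length(cum)], scenario = scenario)
}

#' Lifetime risk of a projection
#' @param x an \code{lod_projection}.
#' @return the final cumulative incidence, in [0, 1].
#' @export
lifetime_risk <- function(x) attr(x, "lifetime_risk")

#' @export
print.lod_projection <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Projection (%s%s): lifetime risk %.4f over ages %d..%d\n",
              sc$kind, if (!is.null(sc$hr)) sprintf(", HR %.4g", sc$hr)
              else "",
              lifetime_risk(x), min(x$age), max(x$age)))
  invisible(x)
}

#' Lifetime-risk grid over hazard ratios and life-expectancy extensions
#'
#' Cross-tabulates \code{project_fixed_hr} over a hazard-ratio list and a
#' list of mortality-curve shifts.  The default grid spans HR 16 down to
#' 1/16 in powers of two and extensions of 0, 5, 10 and 15 years.
#'
#' @param A an \code{lod_aging_coefficient}.
#' @param lt baseline \code{lod_life_table}.
#' @param hrs hazard ratios (rows).
#' @param deltas life-expectancy shifts in years (columns).
#' @return data frame with columns \code{hr}, \code{delta},
#'   \code{lifetime_risk} (long format).
#' @export
hr_grid <- function(A, lt, hrs = 2^seq(4, -4), deltas = c(0, 5, 10, 15)) {
  tables <- lapply(deltas, function(d) shift_life_expectancy(lt, d))
  out <- expand.grid(hr = hrs, delta = deltas, KEEP.OUT.ATTRS = FALSE)
  out$lifetime_risk <- mapply(function(h, d) {
    lifetime_risk(project_fixed_hr(A, h, tables[[match(d, deltas)]]))
  }, out$hr, out$delta)
  out
}

## Age at which the cumulative incidence reaches `target`, linearly
## interpolated between integer ages; NA when never reached.
.age_at_cumulative <- function(proj, target) {
  C <- proj$cumulative
  ages <- proj$age
  if (target <= 0) return(ages[1])
  i <- which(C >= target)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(ages[1])
  c0 <- C[i - 1]
  ages[i - 1] + (target - c0) / (C[i] - c0) * (ages[i] - ages[i - 1])
}

#' Onset delay measured on the cumulative-incidence slope
#'
#' Compares the ages at which two scenarios reach the same fraction
#' (default 30\%) of their own lifetime risks, interpolating linearly
#' between integer ages, and reports the difference in whole years.  A
#' positive value means scenario \code{result_b} reaches the threshold
#' later -- its onset is delayed relative to \code{result_a}.
#'
#' @param result_a baseline \code{lod_projection}.
#' @param result_b comparison \code{lod_projection}.
#' @param fraction fraction of each scenario's lifetime risk (default 0.30).
#' @return delay in whole years (integer-valued numeric).
#' @export
onset_delay_slope <- function(result_a, result_b, fraction = 0.30) {
  lr_a <- lifetime_risk(result_a)
  lr_b <- lifetime_risk(result_b)
  if (lr_a <= 0 || lr_b <= 0)
    stop("both scenarios need positive lifetime risk")
  age_a <- .age_at_cumulative(result_a, fraction * lr_a)
  age_b <- .age_at_cumulative(result_b, fraction * lr_b)
  if (is.na(age_a) || is.na(age_b))
    stop("cumulative incidence never reaches the requested fraction ",
         "within the projection horizon")
  round(age_b - age_a)
}

#' Years of life-expectancy gain needed to regain a baseline lifetime risk
#'
#' After an intervention lowers risk, longer life expectancy pushes lifetime
#' risk back up.  This scans mortality-curve shifts delta = 0, 1, 2, ... and
#' returns the smallest delta at which the treated scenario's lifetime risk
#' reaches or exceeds the untreated baseline under the unshifted table.
#' Scenarios may be given as populations (projected with
#' \code{project_population}) or as fixed hazard ratios.
#'
#' @param A an \code{lod_aging_coefficient}.
#' @param baseline untreated scenario: an \code{lod_population} or a single
#'   hazard ratio.
#' @param treated treated scenario, same forms.
#' @param lt baseline \code{lod_life_table}.
#' @param scan_max largest shift scanned (default 40).
#' @return integer years, or \code{Inf} when the baseline is not regained
#'   within \code{scan_max} years (printed as ">scan_max").
#' @export
years_to_regain_baseline <- function(A, baseline, treated, lt,
                                     scan_max = 40L) {
  proj <- function(scen, table) {
    if (inherits(scen, "lod_population")) project_population(A, scen, table)
    else project_fixed_hr(A, scen, table)
  }
  target <- lifetime_risk(proj(baseline, lt))
  for (delta in 0:scan_max) {
    if (lifetime_risk(proj(treated, shift_life_expectancy(lt, delta))) >=
        target)
      return(delta)
  }
  Inf
}

#' Write an HR-grid or scenario table to CSV
#' @param x a data frame (e.g. from \code{hr_grid} or
#'   \code{therapy_scenarios}).
#' @param path output file.
#' @export
write_grid_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
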