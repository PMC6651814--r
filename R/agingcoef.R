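#' Discover the aging coefficient from an incidence curve
#'
#' The central inverse problem of the simulator.  Under the proportional
#' model an unaffected individual with polygenic score G has yearly
#' diagnosis probability p = h(A(t) G), where the aging coefficient A(t)
#' aggregates aging and environmental effects and h is the
#' hazard-to-probability transform (\code{"clamp"}: min(A G, 1), the
#' default; \code{"exponential"}: 1 - exp(-A G)).  For each age from the
#' onset age to \code{max_age} the routine solves
#' \deqn{\sum_u w_u(t) h(A G_u) / \sum_u w_u(t) = I(t)}
#' for A -- the left side is non-decreasing in A, so a closed form is used
#' while no score saturates and bisection (run to bracket collapse, i.e.
#' machine precision) otherwise -- and then removes the newly diagnosed
#' mass: w_u(t+1) = w_u(t) (1 - h(A G_u)).  Mortality never enters this
#' recursion: the incidence rate is conditional on being alive and
#' disease-free, and mortality is independent of the risk score.
#'
#' Because high-G individuals leave the unaffected pool faster, the mean
#' score among susceptibles falls with age and A(t) must rise above I(t) to
#' keep reproducing the clinical curve (frailty depletion).  For a
#' homogeneous population (all G = 1), A(t) = I(t) exactly.
#'
#' @param curve an \code{lod_incidence}.
#' @param pop an \code{lod_population} (normalized to mean score 1).
#' @param max_age last age solved (default 119).
#' @param transform hazard-to-probability transform.
#' @return object of class \code{lod_aging_coefficient}: list with
#'   \code{age} (0:max_age), \code{A} (0 where incidence is 0, NA beyond an
#'   exhausted-pool truncation), the transform, the incidence values
#'   reproduced, and the population's normalization reference for pairing
#'   checks.
#' @export
discover_aging_coefficient <- function(curve, pop, max_age = 119L,
                                       transform = c("clamp",
                                                     "exponential")) {
  transform <- match.arg(transform)
  stopifnot(inherits(curve, "lod_incidence"), inherits(pop, "lod_population"))
  ages <- 0:max_age
  I <- evaluate_incidence(curve, ages)
  if (any(I > 1)) stop("incidence exceeds 1")
  G <- pop$values
  w <- pop$weights
  maxG <- max(G)
  A <- numeric(length(ages))
  truncated_at <- NA_integer_
  for (i in seq_along(ages)) {
    It <- I[i]
    if (It == 0) { A[i] <- 0; next }
    wsum <- sum(w)
    if (wsum <= 1e-12) {
      warning(sprintf(
        "unaffected pool exhausted at age %d; aging coefficient truncated",
        ages[i]))
      truncated_at <- ages[i]
      A[i:length(ages)] <- NA_real_
      break
    }
    if (transform == "clamp" && It >= 1)
      stop(sprintf("I(t) = 1 at age %d: aging coefficient unbounded under ",
                   ages[i]), "bounded scores")
    if (transform == "clamp") {
      ## closed form while no score saturates: A = I / mean_w(G); the
      ## mean is formed first so a homogeneous population (mean exactly 1)
      ## gives A = I to the last bit
      a_lin <- It / (sum(w * G) / wsum)
      if (a_lin * maxG <= 1) {
        A[i] <- a_lin
      } else {
        A[i] <- .bisect_clamp(G, w, It)
      }
      p <- pmin(A[i] * G, 1)
    } else {
      A[i] <- .bisect_exp(G, w, It)
      p <- 1 - exp(-A[i] * G)
    }
    w <- w * (1 - p)
  }
  structure(
    list(age = ages, A = A, transform = transform, incidence = I,
         onset_age = curve$onset_age,
         normalization_reference = pop$normalization_reference,
         truncated_at = truncated_at),
    class = "lod_aging_coefficient")
}

## Bisection to bracket collapse; mean_w pmin(A G, 1) is piecewise linear and
## non-decreasing in A, so the fixed point is unique below full saturation.
.bisect_clamp <- function(G, w, target) {
  wsum <- sum(w)
  f <- function(a) sum(w * pmin(a * G, 1)) / wsum
  hi <- target / max(G)
  while (f(hi) < target) {
    hi <- hi * 2
    if (hi > 1e12) stop("incidence not attainable: score support too small")
  }
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

.bisect_exp <- function(G, w, target) {
  wsum <- sum(w)
  f <- function(a) sum(w * (1 - exp(-a * G))) / wsum
  hi <- 1
  while (f(hi) < target) {
    hi <- hi * 2
    if (hi > 1e15) stop("incidence not attainable under exponential transform")
  }
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

## A coefficient can be applied to any population expressed on the same
## relative-risk scale as the discovery population: either freshly
## normalized (weighted mean 1, anchored at its own mean) or derived from
## such a population with the reference kept (therapy rescaling).
.check_pairing <- function(A, pop) {
  mean_ok <- abs(sum(pop$weights * pop$values) - 1) < 1e-6
  ref_ok <- isTRUE(all.equal(A$normalization_reference,
                             pop$normalization_reference,
                             tolerance = 1e-6))
  if (!mean_ok && !ref_ok)
    stop("population is not on the risk scale used at discovery: ",
         "normalize it to mean 1 or keep the discovery population's ",
         "normalization reference")
  invisible(TRUE)
}

.hazard_prob <- function(A, G, transform) {
  if (is.na(A)) return(rep.int(NA_real_, length(G)))
  if (transform == "clamp") pmin(pmax(A * G, 0), 1) else 1 - exp(-A * G)
}

#' Apply an aging coefficient to a population
#'
#' Forward simulation of yearly aging: each still-unaffected individual is
#' diagnosed with probability h(A(t) G).  In expectation mode the weighted
#' recursion is evolved deterministically and the conditional incidence per
#' age is returned; this reproduces the discovery curve to numerical
#' precision when applied to the discovery population (the model's own
#' validation).  In stochastic mode individual Bernoulli outcomes are drawn
#' under the given seed.
#'
#' @param A an \code{lod_aging_coefficient}.
#' @param pop an \code{lod_population} normalized against the same reference
#'   as at discovery (therapy-scaled populations keep that reference).
#' @param mode \code{"expectation"} or \code{"stochastic"}.
#' @param seed RNG seed (stochastic mode).
#' @return data frame with columns \code{age}, \code{incidence}
#'   (conditional yearly rate among the unaffected), and
#'   \code{unaffected} (remaining disease-free fraction at the start of the
#'   year); the final weights are attached as attribute
#'   \code{"final_weights"} (expectation mode).
#' @export
apply_aging_coefficient <- function(A, pop,
                                    mode = c("expectation", "stochastic"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(A, "lod_aging_coefficient"),
            inherits(pop, "lod_population"))
  .check_pairing(A, pop)
  ages <- A$age
  G <- pop$values
  if (mode == "expectation") {
    w <- pop$weights
    inc <- numeric(length(ages))
    unaff <- numeric(length(ages))
    for (i in seq_along(ages)) {
      unaff[i] <- sum(w)
      if (is.na(A$A[i])) { inc[i] <- NA_real_; next }
      p <- .hazard_prob(A$A[i], G, A$transform)
      inc[i] <- if (unaff[i] > 0) sum(w * p) / unaff[i] else NA_real_
      w <- w * (1 - p)
    }
    out <- data.frame(age = ages, incidence = inc, unaffected = unaff)
    attr(out, "final_weights") <- w
    out
  } else {
    set.seed(as.integer(seed))
    ## resample individuals by weight if the population is binned
    n <- length(G)
    active <- rep.int(TRUE, n)
    prob_weights <- pop$weights * n  # uniform for stochastic populations
    inc <- numeric(length(ages))
    unaff <- numeric(length(ages))
    for (i in seq_along(ages)) {
      unaff[i] <- sum(prob_weights[active]) / n
      if (is.na(A$A[i])) { inc[i] <- NA_real_; next }
      idx <- which(active)
      if (!length(idx)) { inc[i] <- NA_real_; next }
      p <- .hazard_prob(A$A[i], G[idx], A$transform)
      hit <- stats::runif(length(idx)) < p
      inc[i] <- sum(prob_weights[idx][hit]) / sum(prob_weights[idx])
      active[idx[hit]] <- FALSE
    }
    data.frame(age = ages, incidence = inc, unaffected = unaff)
  }
}

#' @export
print.lod_aging_coefficient <- function(x, ...) {
  ok <- !is.na(x$A) & x$A > 0
  cat(sprintf("Aging coefficient on ages %d..%d (%s transform)\n",
              min(x$age), max(x$age), x$transform))
  if (any(ok))
    cat(sprintf("  nonzero from age %d; A range %.3g .. %.3g\n",
                min(x$age[ok]), min(x$A[ok]), max(x$A[ok])))
  if (!is.na(x$truncated_at))
    cat(sprintf("  truncated at age %d (unaffected pool exhausted)\n",
                x$truncated_at))
  invisible(x)
}

#' Export an aging coefficient as CSV plus a JSON metadata sidecar
#'
#' The CSV holds columns \code{age}, \code{A}; the sidecar
#' (\code{<path>.json}) records the transform, onset age and the
#' population's normalization reference so a re-loaded coefficient can be
#' paired with the right population.
#'
#' @param A an \code{lod_aging_coefficient}.
#' @param path CSV output path.
#' @export
write_aging_coefficient <- function(A, path) {
  .write_csv_exact(data.frame(age = A$age, A = A$A), path)
  meta <- list(transform = A$transform, onset_age = A$onset_age,
               normalization_reference = A$normalization_reference,
               truncated_at = A$truncated_at)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_aging_coefficient
#' @return \code{read_aging_coefficient} returns the reconstructed
#'   \code{lod_aging_coefficient}.
#' @export
read_aging_coefficient <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(age = df$age, A = df$A, transform = meta$transform,
         incidence = NULL, onset_age = meta$onset_age,
         normalization_reference = meta$normalization_reference,
         truncated_at = meta$truncated_at %||% NA_integer_),
    class = "lod_aging_coefficient")
}
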