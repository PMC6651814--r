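#' Construct a life table from one-year death probabilities
#'
#' Ages are integer years on half-open intervals [t, t+1); \code{q[t]} is the
#' conditional probability of dying within the year at age t and \code{S[t]}
#' the fraction of the birth cohort surviving to exact age t.  S is always
#' recomputed from q via S(0) = 1, S(t+1) = S(t) (1 - q(t)), so the recursion
#' invariant holds by construction.
#'
#' @param q numeric vector of one-year death probabilities for ages
#'   \code{0:(length(q)-1)}, each in [0, 1].
#' @return object of class \code{lod_life_table}: data frame with columns
#'   \code{age}, \code{q}, \code{S}.
#' @export
life_table <- function(q) {
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q < 0 | q > 1))
    stop("death probabilities must lie in [0, 1]")
  n <- length(q)
  S <- c(1, cumprod(1 - q))[seq_len(n)]
  structure(data.frame(age = 0:(n - 1L), q = q, S = S),
            class = c("lod_life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Accepts either a two-column dialect \code{age,q} or a period-table dialect
#' \code{age,q_male,q_female} (select with \code{sex}; \code{"both"} averages
#' the two columns).  Ages must be contiguous from 0.  The survivor column is
#' recomputed from q, so files that also carry S round-trip exactly.
#'
#' @param path CSV file.
#' @param sex \code{"both"}, \code{"male"} or \code{"female"} for the
#'   three-column dialect.
#' @return an \code{lod_life_table}.
#' @export
load_life_table <- function(path, sex = c("both", "male", "female")) {
  sex <- match.arg(sex)
  df <- utils::read.csv(path)
  if (!"age" %in% names(df)) stop("life table CSV needs an 'age' column")
  if ("q" %in% names(df)) {
    q <- df$q
  } else if (all(c("q_male", "q_female") %in% names(df))) {
    q <- switch(sex,
                male = df$q_male,
                female = df$q_female,
                both = (df$q_male + df$q_female) / 2)
  } else {
    stop("life table CSV needs 'q' or 'q_male'/'q_female' columns")
  }
  if (!identical(as.integer(df$age), seq_len(nrow(df)) - 1L)) {
    bad <- which(as.integer(df$age) != seq_len(nrow(df)) - 1L)[1]
    stop(sprintf("ages must be contiguous from 0; first gap at row %d", bad))
  }
  bad <- which(!is.finite(q) | q < 0 | q > 1)
  if (length(bad))
    stop(sprintf("death probability outside [0, 1] at row %d", bad[1]))
  life_table(q)
}

#' Write a life table to CSV (columns age, q, S)
#' @param lt an \code{lod_life_table}.
#' @param path output file.
#' @export
write_life_table <- function(lt, path) {
  .write_csv_exact(as.data.frame(lt)[, c("age", "q", "S")], path)
  invisible(path)
}

## CSV writer preserving doubles bit-exactly (17 significant digits survive
## the decimal round trip)
.write_csv_exact <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Synthesize a Gompertz-Makeham life table
#'
#' One-year death probability q(t) = min(1, a + b exp(c t)): an
#' age-independent Makeham term plus exponentially accelerating Gompertz
#' mortality.  The defaults give a life expectancy (sum of the survivor
#' curve) of about 80 years with S(119) still positive, mimicking a modern
#' national period table.
#'
#' @param makeham_a age-independent yearly death rate (default 5e-4).
#' @param gompertz_b Gompertz level at age 0 (default 2.5e-5).
#' @param gompertz_c exponential growth rate per year of age (default 0.095).
#' @param max_age last tabulated age (default 119).
#' @return an \code{lod_life_table}.
#' @export
synthesize_life_table <- function(makeham_a = 5e-4, gompertz_b = 2.5e-5,
                                  gompertz_c = 0.095, max_age = 119L) {
  if (makeham_a < 0 || gompertz_b < 0 || gompertz_c < 0)
    stop("mortality parameters must be >= 0")
  t <- 0:max_age
  life_table(pmin(1, makeham_a + gompertz_b * exp(gompertz_c * t)))
}

#' Life expectancy of a table, as the sum of the survivor curve
#' @param lt an \code{lod_life_table}.
#' @return expected years lived (sum over ages of S).
#' @export
life_expectancy <- function(lt) sum(lt$S)

#' Emulate a longer life expectancy by shifting the mortality curve
#'
#' Translates the one-year death probabilities along the age axis:
#' q'(t) = q(t - delta) for t >= delta, and q'(t) = q(0) for younger ages.
#' The survivor curve is recomputed, is pointwise >= the original, and the
#' life expectancy grows by approximately \code{delta} years for tables
#' dominated by adult mortality.
#'
#' @param lt an \code{lod_life_table}.
#' @param delta non-negative integer years of postponement.
#' @return an \code{lod_life_table} on the same age range.
#' @export
shift_life_expectancy <- function(lt, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 ||
      delta != round(delta))
    stop("'delta' must be a single non-negative integer")
  delta <- as.integer(delta)
  if (delta == 0L) return(lt)
  q <- lt$q
  n <- length(q)
  life_table(c(rep.int(q[1], min(delta, n)), q)[seq_len(n)])
}

#' Define a yearly incidence curve
#'
#' Supported functional forms for the yearly (conditional) incidence rate
#' I(t):
#' \describe{
#'   \item{logistic}{\code{a / (1 + exp(-k (t - t50)))} -- sigmoidal rise to
#'     a plateau \code{a}, the shape used for most late-onset diseases.}
#'   \item{exp_then_linear}{\code{c0 exp(r (t - t0))} up to
#'     \code{switch_age}, continued linearly beyond it with matching value
#'     and slope (the breast-cancer pattern of early exponential growth that
#'     flattens to linear).}
#'   \item{tabulated}{explicit per-age values starting at age 0.}
#' }
#' Incidence is 0 below \code{onset_age} and clamped to [0, 1]; parameters
#' whose raw curve exceeds 1 anywhere on the age range are rejected.
#'
#' @param form one of \code{"logistic"}, \code{"exp_then_linear"},
#'   \code{"tabulated"}.
#' @param parameters named list: logistic needs \code{a}, \code{k},
#'   \code{t50}; exp_then_linear needs \code{c0}, \code{r}, \code{t0},
#'   \code{switch_age}; tabulated needs \code{values}.
#' @param onset_age first age with non-zero incidence (default 0).
#' @param max_age age range over which the curve is validated (default 119).
#' @return object of class \code{lod_incidence}.
#' @export
incidence_curve <- function(form = c("logistic", "exp_then_linear",
                                     "tabulated"),
                            parameters, onset_age = 0L, max_age = 119L) {
  form <- match.arg(form)
  needed <- switch(form,
                   logistic = c("a", "k", "t50"),
                   exp_then_linear = c("c0", "r", "t0", "switch_age"),
                   tabulated = "values")
  missing <- setdiff(needed, names(parameters))
  if (length(missing))
    stop(sprintf("incidence form '%s' needs parameter(s): %s", form,
                 paste(missing, collapse = ", ")))
  curve <- structure(
    list(form = form, parameters = parameters,
         onset_age = as.integer(onset_age), max_age = as.integer(max_age)),
    class = "lod_incidence")
  raw <- .incidence_raw(curve, 0:max_age)
  if (any(raw > 1))
    stop(sprintf("incidence parameters give I(t) > 1 (first at age %d)",
                 (0:max_age)[which(raw > 1)[1]]))
  curve
}

## Unclamped functional form, before the onset-age mask.
.incidence_raw <- function(curve, t) {
  p <- curve$parameters
  switch(curve$form,
    logistic = p$a / (1 + exp(-p$k * (t - p$t50))),
    exp_then_linear = {
      sw <- p$switch_age
      val_sw <- p$c0 * exp(p$r * (sw - p$t0))
      slope_sw <- p$r * val_sw
      ifelse(t <= sw, p$c0 * exp(p$r * (t - p$t0)),
             val_sw + slope_sw * (t - sw))
    },
    tabulated = {
      v <- p$values
      ifelse(t >= 0 & t < length(v), v[pmin(pmax(t, 0), length(v) - 1) + 1], 0)
    })
}

#' Evaluate a yearly incidence curve
#' @param curve an \code{lod_incidence}.
#' @param t integer age(s) in years.
#' @return yearly incidence probability in [0, 1]; 0 below the onset age.
#' @export
evaluate_incidence <- function(curve, t) {
  out <- pmin(pmax(.incidence_raw(curve, t), 0), 1)
  out[t < curve$onset_age] <- 0
  out
}

#' @export
print.lod_incidence <- function(x, ...) {
  cat(sprintf("Yearly incidence curve: %s form, onset age %d\n",
              x$form, x$onset_age))
  cat("  parameters:",
      paste(names(x$parameters),
            vapply(x$parameters, function(p) paste(signif(p, 4),
                                                   collapse = ","),
                   ""), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic incidence fixtures
#'
#' Three logistic families spanning the incidence magnitudes of the modelled
#' diseases, for self-contained simulation studies:
#' \describe{
#'   \item{cancer_like}{plateau 0.4\% from midlife (lifetime risk a few
#'     percent under the default mortality fixture).}
#'   \item{t2d_like}{plateau 2.5\% rising from early adulthood (high
#'     lifetime risk).}
#'   \item{ad_like}{steep rise after 60 toward a plateau above 20\% at very
#'     old age (lifetime risk above 30\%).}
#' }
#'
#' @param kind fixture family.
#' @return an \code{lod_incidence}.
#' @export
fixture_incidence <- function(kind = c("cancer_like", "t2d_like",
                                       "ad_like")) {
  kind <- match.arg(kind)
  switch(kind,
    cancer_like = incidence_curve("logistic",
      list(a = 0.004, k = 0.12, t50 = 80), onset_age = 40L),
    t2d_like = incidence_curve("logistic",
      list(a = 0.025, k = 0.10, t50 = 55), onset_age = 25L),
    ad_like = incidence_curve("logistic",
      list(a = 0.30, k = 0.20, t50 = 90), onset_age = 60L))
}

#' Read/write an incidence-curve configuration (YAML or JSON)
#'
#' The on-disk form mirrors the constructor: fields \code{form},
#' \code{parameters}, \code{onset_age}.
#' @param path file ending in .yaml/.yml or .json.
#' @return an \code{lod_incidence}.
#' @export
load_incidence_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(cfg$parameters$values))
    cfg$parameters$values <- unlist(cfg$parameters$values)
  incidence_curve(cfg$form, as.list(cfg$parameters),
                  onset_age = cfg$onset_age %||% 0L)
}

#' @rdname load_incidence_config
#' @param curve an \code{lod_incidence} to serialize.
#' @export
write_incidence_config <- function(curve, path) {
  cfg <- list(form = curve$form, parameters = curve$parameters,
              onset_age = curve$onset_age)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
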