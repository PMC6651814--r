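#' Specify a prophylactic gene-therapy intervention
#'
#' A therapy is parameterized either by an odds-ratio multiplier in (0, 1]
#' applied to every individual's risk score, or by an average number of
#' single-allele corrective edits; given an architecture each determines the
#' other through the mean log odds ratio of the allele classes
#' (\code{\link{n_edits_for_multiplier}}).
#'
#' @param or_multiplier multiplicative score reduction in (0, 1].
#' @param n_edits average single-allele edits per individual (alternative
#'   parameterization; exactly one of the two must be given).
#' @param mode \code{"uniform_multiplier"} scales every score by the
#'   multiplier; \code{"allele_editing"} reverts detrimental alleles
#'   individual by individual, largest effect first, until each individual's
#'   score reduction reaches the multiplier (requires genotype-level
#'   sampling).
#' @param arch architecture used to convert between the parameterizations
#'   (required when \code{n_edits} is given).
#' @return object of class \code{lod_therapy}.
#' @export
therapy_spec <- function(or_multiplier = NULL, n_edits = NULL,
                         mode = c("uniform_multiplier", "allele_editing"),
                         arch = NULL) {
  mode <- match.arg(mode)
  if (is.null(or_multiplier) == is.null(n_edits))
    stop("give exactly one of 'or_multiplier' or 'n_edits'")
  if (is.null(or_multiplier)) {
    if (is.null(arch))
      stop("'arch' is required to convert an edit count to a multiplier")
    if (n_edits < 0) stop("'n_edits' must be >= 0")
    or_multiplier <- exp(-n_edits * mean(arch$beta))
    derived <- "or_multiplier"
  } else {
    if (or_multiplier <= 0 || or_multiplier > 1)
      stop("'or_multiplier' must be in (0, 1]")
    n_edits <- if (!is.null(arch))
      n_edits_for_multiplier(arch, or_multiplier) else NA_integer_
    derived <- "n_edits"
  }
  structure(list(or_multiplier = or_multiplier, n_edits = n_edits,
                 mode = mode, derived = derived),
            class = "lod_therapy")
}

#' Apply a therapy to a population of risk scores
#'
#' In \code{uniform_multiplier} mode every score is scaled by the
#' multiplier and the normalization reference is left unchanged, so the
#' treated population is expressed relative to the pre-therapy mean (a
#' multiplier of 0.25 lowers the population mean risk fourfold).  In
#' \code{allele_editing} mode each individual's detrimental alleles are
#' reverted one at a time, largest odds ratio first, until the cumulative
#' reduction reaches the multiplier or no detrimental alleles remain;
#' individuals with few detrimental alleles may fall short of the target
#' reduction and low-dosage individuals stop early.
#'
#' @param pop an \code{lod_population}; allele editing requires one sampled
#'   with \code{keep_genotypes = TRUE}.
#' @param spec an \code{lod_therapy}.
#' @param arch architecture (defaults to the one stored in \code{pop}).
#' @return the treated \code{lod_population}; for allele editing the mean
#'   number of edits actually performed is attached as attribute
#'   \code{"mean_edits"}.
#' @export
apply_therapy <- function(pop, spec, arch = NULL) {
  stopifnot(inherits(pop, "lod_population"), inherits(spec, "lod_therapy"))
  m <- spec$or_multiplier
  if (spec$mode == "uniform_multiplier") {
    out <- pop
    out$values <- pop$values * m
    return(out)
  }
  ## allele editing
  if (is.null(pop$dosages))
    stop("allele_editing needs genotype-level sampling ",
         "(sample_population(..., keep_genotypes = TRUE)); ",
         "expectation-mode populations should use uniform_multiplier")
  if (is.null(arch)) arch <- pop$architecture
  if (is.null(arch)) stop("'arch' is required for allele editing")
  target <- log(1 / m)           # log reduction wanted per individual
  ord <- order(arch$beta, decreasing = TRUE)
  dos <- pop$dosages
  n <- nrow(dos)
  remaining <- rep.int(target, n)
  edits <- integer(n)
  removed_log <- numeric(n)
  for (k in ord) {
    b <- arch$beta[k]
    if (b <= 0) next
    need <- ceiling(pmax(remaining, 0) / b)
    take <- pmin(need, dos[, k])
    dos[, k] <- dos[, k] - take
    edits <- edits + take
    removed_log <- removed_log + take * b
    remaining <- remaining - take * b
    if (all(remaining <= 0)) break
  }
  out <- pop
  out$values <- pop$values * exp(-removed_log)
  out$dosages <- dos
  attr(out, "mean_edits") <- mean(edits)
  out
}

#' Therapy scenarios across life-expectancy extensions
#'
#' Applies a therapy to the population, then projects lifetime risk with
#' \code{\link{project_population}} under the baseline life table and each
#' requested mortality shift.  Risks are reported both absolutely and as a
#' percentage of the untreated, unshifted baseline (baseline = 100\%).
#'
#' @param A an \code{lod_aging_coefficient} discovered on the untreated
#'   population.
#' @param pop the untreated \code{lod_population}.
#' @param spec an \code{lod_therapy}.
#' @param lt baseline \code{lod_life_table}.
#' @param deltas life-expectancy shifts in years (default 0, 5, 10, 15).
#' @param arch architecture passed to \code{\link{apply_therapy}}.
#' @return data frame with columns \code{delta}, \code{lifetime_risk},
#'   \code{pct_of_baseline}; the untreated baseline risk is attached as
#'   attribute \code{"baseline_risk"}.
#' @export
therapy_scenarios <- function(A, pop, spec, lt, deltas = c(0, 5, 10, 15),
                              arch = NULL) {
  baseline <- lifetime_risk(project_population(A, pop, lt))
  treated <- apply_therapy(pop, spec, arch)
  risks <- vapply(deltas, function(d) {
    lifetime_risk(project_population(A, treated,
                                     shift_life_expectancy(lt, d)))
  }, numeric(1))
  out <- data.frame(delta = deltas, lifetime_risk = risks,
                    pct_of_baseline = 100 * risks / baseline)
  attr(out, "baseline_risk") <- baseline
  out
}
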