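## Model allele grids: five minor-allele frequencies crossed with five
## per-allele odds ratios, giving 25 allele classes per scenario.
.allele_grids <- list(
  common_low = list(
    maf = c(0.073, 0.18, 0.286, 0.393, 0.5),
    or  = c(1.05, 1.075, 1.1, 1.125, 1.15)
  ),
  rare_medium = list(
    maf = c(0.0146, 0.036, 0.0572, 0.0785, 0.0998),
    or  = c(1.28, 1.463, 1.645, 1.828, 2.01)
  )
)

#' Build a model genetic architecture
#'
#' Constructs an architecture of SNP allele classes on a 5 x 5 grid of minor
#' allele frequencies (MAF) and per-allele odds ratios (OR).  Two scenarios are
#' provided: \code{"common_low"} (common alleles, small effects; MAF
#' 0.073--0.5, OR 1.05--1.15) and \code{"rare_medium"} (rare alleles, medium
#' effects; MAF 0.0146--0.0998, OR 1.28--2.01).  The requested number of SNPs
#' is spread as evenly as possible over the 25 classes; any remainder is
#' assigned one SNP at a time in class order (MAF varying fastest), so the
#' allocation is deterministic.
#'
#' @param scenario_name one of \code{"common_low"}, \code{"rare_medium"}.
#' @param n_snps total number of causal SNPs (>= 1).
#' @return an object of class \code{lod_architecture}: a data frame with one
#'   row per allele class and columns \code{maf}, \code{or_per_allele},
#'   \code{beta} (log OR) and \code{n_snps}.
#' @examples
#' arch <- build_architecture("common_low", 3575)  # 143 SNPs in each class
#' sum(arch$n_snps)
#' @export
build_architecture <- function(scenario_name = c("common_low", "rare_medium"),
                               n_snps) {
  scenario_name <- match.arg(scenario_name)
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 1 ||
      n_snps != round(n_snps))
    stop("'n_snps' must be a single integer >= 1")
  grid <- .allele_grids[[scenario_name]]
  classes <- expand.grid(maf = grid$maf, or_per_allele = grid$or,
                         KEEP.OUT.ATTRS = FALSE)
  n_class <- nrow(classes)  # 25
  base <- n_snps %/% n_class
  rem <- n_snps %% n_class
  counts <- rep.int(base, n_class)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  out <- data.frame(
    maf = classes$maf,
    or_per_allele = classes$or_per_allele,
    beta = log(classes$or_per_allele),
    n_snps = as.integer(counts)
  )
  structure(out, class = c("lod_architecture", "data.frame"),
            scenario = scenario_name)
}

#' Build an architecture from an explicit class list
#'
#' Escape hatch for architectures that are not on the two built-in grids:
#' give per-class minor allele frequencies, per-allele odds ratios and SNP
#' counts directly.  Odds ratios of exactly 1 are allowed here (null
#' classes), which is useful for degenerate test populations.
#'
#' @param maf per-class minor allele frequencies in (0, 0.5].
#' @param or_per_allele per-class odds ratios (>= 1).
#' @param n_snps per-class SNP counts.
#' @return an \code{lod_architecture}.
#' @export
architecture_from_classes <- function(maf, or_per_allele, n_snps) {
  stopifnot(length(maf) == length(or_per_allele),
            length(maf) == length(n_snps))
  out <- data.frame(maf = as.numeric(maf),
                    or_per_allele = as.numeric(or_per_allele),
                    beta = log(as.numeric(or_per_allele)),
                    n_snps = as.integer(n_snps))
  arch <- structure(out, class = c("lod_architecture", "data.frame"),
                    scenario = "custom")
  validate_architecture(arch)
  arch
}

validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "lod_architecture"))
  if (any(arch$maf <= 0) || any(arch$maf > 0.5))
    stop("allele MAF must satisfy 0 < maf <= 0.5")
  if (any(arch$or_per_allele < 1))
    stop("per-allele odds ratios must be >= 1")
  if (any(arch$n_snps < 0)) stop("SNP counts must be non-negative")
  invisible(arch)
}

#' Moments of the log risk-score distribution implied by an architecture
#'
#' Under Hardy-Weinberg sampling the log score ln G is a sum of independent
#' scaled binomials: per class with allele frequency p, effect b = ln OR and
#' n SNPs the contribution has mean 2npb and variance 2np(1-p)b^2.
#'
#' @param arch an \code{lod_architecture}.
#' @return list with \code{mean} and \code{var} of ln G (raw scale, before
#'   normalization to population mean 1).
#' @export
architecture_log_moments <- function(arch) {
  validate_architecture(arch)
  list(
    mean = sum(2 * arch$n_snps * arch$maf * arch$beta),
    var = sum(2 * arch$n_snps * arch$maf * (1 - arch$maf) * arch$beta^2)
  )
}

#' Match one scenario's SNP count to another architecture's log-score variance
#'
#' Returns the SNP count for \code{scenario_name} whose evenly-allocated
#' architecture has log risk-score variance closest to that of \code{target}.
#' Used to compare the common-allele and rare-allele scenarios at matched
#' polygenic variance.
#'
#' @param target an \code{lod_architecture} whose variance is matched.
#' @param scenario_name scenario to calibrate.
#' @return integer SNP count (>= 1).
#' @export
calibrate_snp_count <- function(target,
                                scenario_name = c("common_low", "rare_medium")) {
  scenario_name <- match.arg(scenario_name)
  v_target <- architecture_log_moments(target)$var
  per_snp <- architecture_log_moments(
    build_architecture(scenario_name, 25L))$var / 25
  guess <- max(1L, as.integer(round(v_target / per_snp)))
  ## the deterministic remainder allocation makes the realized variance a
  ## step function of n; scan a window around the ratio estimate
  cand <- max(1L, guess - 30L):(guess + 30L)
  vr <- vapply(cand, function(n)
    architecture_log_moments(build_architecture(scenario_name, n))$var,
    numeric(1))
  cand[which.min(abs(vr - v_target))]
}

#' Construct a population of multiplicative polygenic risk scores
#'
#' Low-level constructor for the weighted risk-score distribution shared by
#' all downstream modules.  Scores are normalized so the weighted mean is
#' exactly 1; the divisor used is recorded as the normalization reference so
#' that hazard-ratio scenarios (HR 1 = population-average risk) and therapy
#' rescalings stay anchored to the pre-treatment population.
#'
#' @param values positive multiplicative risk scores, one per individual or
#'   per bin.
#' @param weights non-negative masses; default uniform.  Rescaled to sum to 1.
#' @param normalize divide values by their weighted mean (default TRUE).
#' @param mode \code{"expectation"} (weighted bins) or \code{"stochastic"}
#'   (explicit individuals).
#' @param dosages optional integer matrix (individuals x allele classes) of
#'   detrimental-allele counts, retained for allele-level therapy editing.
#' @param arch optional \code{lod_architecture} the population was drawn from.
#' @return an object of class \code{lod_population}.
#' @export
new_population <- function(values, weights = NULL, normalize = TRUE,
                           mode = c("expectation", "stochastic"),
                           dosages = NULL, arch = NULL) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("risk scores must be finite and > 0")
  n <- length(values)
  if (is.null(weights)) weights <- rep.int(1 / n, n)
  weights <- as.numeric(weights)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be non-negative and match 'values' in length")
  weights <- weights / sum(weights)
  norm_ref <- 1
  if (normalize) {
    norm_ref <- sum(weights * values)
    values <- values / norm_ref
  }
  structure(
    list(values = values, weights = weights,
         normalization_reference = norm_ref, mode = mode,
         dosages = dosages, architecture = arch),
    class = "lod_population")
}

#' @export
print.lod_population <- function(x, ...) {
  v <- population_log_moments(x)
  cat(sprintf("Polygenic risk-score population (%s mode)\n", x$mode))
  cat(sprintf("  %d %s, weighted mean G = %.6f\n", length(x$values),
              if (x$mode == "expectation") "bins" else "individuals",
              sum(x$weights * x$values)))
  cat(sprintf("  ln G: mean %.4f, variance %.4f\n", v$mean, v$var))
  invisible(x)
}

#' Weighted moments of ln G for a population
#' @param pop an \code{lod_population}.
#' @return list with \code{mean} and \code{var} of ln G.
#' @export
population_log_moments <- function(pop) {
  lg <- log(pop$values)
  m <- sum(pop$weights * lg)
  list(mean = m, var = sum(pop$weights * (lg - m)^2))
}

#' Sample individual polygenic risk scores under Hardy-Weinberg equilibrium
#'
#' Each individual's detrimental-allele dosage for the SNPs of an allele
#' class with frequency p is drawn from the class-aggregated binomial
#' Binom(2 * n_snps_in_class, p) -- equivalent to summing independent
#' per-SNP genotypes with frequencies p^2, 2p(1-p), (1-p)^2.  The raw
#' multiplicative score is the product over classes of OR^dosage; scores are
#' then divided by their population mean so the normalized mean is 1.
#'
#' @param arch an \code{lod_architecture}.
#' @param n_individuals number of individuals (>= 1).
#' @param seed RNG seed; the draw is reproducible given (arch, n, seed).
#' @param keep_genotypes retain the per-class dosage matrix (needed for
#'   allele-editing therapy).
#' @return an \code{lod_population} in stochastic mode.
#' @export
sample_population <- function(arch, n_individuals, seed = 1L,
                              keep_genotypes = FALSE) {
  validate_architecture(arch)
  if (!is.numeric(n_individuals) || n_individuals < 1)
    stop("'n_individuals' must be >= 1")
  n_individuals <- as.integer(n_individuals)
  set.seed(as.integer(seed))
  n_class <- nrow(arch)
  dos <- matrix(0L, n_individuals, n_class)
  for (k in seq_len(n_class)) {
    if (arch$n_snps[k] > 0L)
      dos[, k] <- stats::rbinom(n_individuals, 2L * arch$n_snps[k],
                                arch$maf[k])
  }
  lng <- drop(dos %*% arch$beta)
  new_population(exp(lng), mode = "stochastic",
                 dosages = if (keep_genotypes) dos else NULL, arch = arch)
}

#' Deterministic quantile-binned risk-score population
#'
#' Expectation-mode representation of the population: ln G, a sum of
#' thousands of independent small contributions, is approximated by its
#' matching normal distribution and discretized into \code{n_bins} equal-mass
#' quantile bins (midpoint rule).  This removes Monte Carlo noise from the
#' aging-coefficient inversion and all downstream projections.
#'
#' @param arch an \code{lod_architecture}.
#' @param n_bins number of quantile bins (default 10001).
#' @return an \code{lod_population} in expectation mode.
#' @export
bin_population <- function(arch, n_bins = 10001L) {
  validate_architecture(arch)
  if (n_bins < 1) stop("'n_bins' must be >= 1")
  mom <- architecture_log_moments(arch)
  z <- stats::qnorm((seq_len(n_bins) - 0.5) / n_bins)
  new_population(exp(mom$mean + sqrt(mom$var) * z), mode = "expectation",
                 arch = arch)
}

#' Average number of single-allele edits matching an odds-ratio multiplier
#'
#' A corrective edit of one detrimental allele divides an individual's score
#' by that allele's OR.  The average number of edits equivalent to scaling
#' the score by \code{or_multiplier} is ln(1/multiplier) divided by the mean
#' log OR over the architecture's allele classes, rounded to the nearest
#' integer.  For the common-allele scenario a fourfold reduction
#' (multiplier 0.25) corresponds to 15 edits.
#'
#' @param arch an \code{lod_architecture}.
#' @param or_multiplier multiplier in (0, 1].
#' @return non-negative integer count of edits.
#' @export
n_edits_for_multiplier <- function(arch, or_multiplier) {
  validate_architecture(arch)
  if (!is.numeric(or_multiplier) || or_multiplier <= 0 || or_multiplier > 1)
    stop("'or_multiplier' must be in (0, 1]")
  if (or_multiplier == 1) return(0L)
  mean_beta <- mean(arch$beta)
  if (mean_beta <= 0)
    stop("architecture has no effect sizes (all OR = 1): edits undefined")
  as.integer(round(log(1 / or_multiplier) / mean_beta))
}

#' Write a population to CSV
#'
#' Emits one row per individual or bin with columns
#' \code{index}, \code{G}, \code{weight}.
#' @param pop an \code{lod_population}.
#' @param path output file.
#' @export
write_population_csv <- function(pop, path) {
  .write_csv_exact(
    data.frame(index = seq_along(pop$values), G = pop$values,
               weight = pop$weights), path)
  invisible(path)
}

#' Disease presets
#'
#' Reference table of the eight late-onset diseases modelled by the package:
#' familial heritability, the SNP count of the common-allele architecture
#' that reaches it, and the synthetic incidence-fixture family whose yearly
#' incidence magnitude matches each disease.  SNP counts and heritabilities
#' are shipped as fixed presets; the mapping from heritability to SNP count
#' is not recomputed here.
#'
#' @return data frame with one row per disease.
#' @export
lod_presets <- function() {
  data.frame(
    disease = c("alzheimers", "t2d", "stroke", "cad",
                "breast_cancer", "prostate_cancer", "colorectal_cancer",
                "lung_cancer"),
    heritability = c(0.795, 0.69, 0.55, 0.41, 0.57, 0.40, 0.31, 0.10),
    snp_count = c(3575L, 2125L, 1175L, 625L, 1250L, 600L, 400L, 100L),
    incidence_kind = c("ad_like", "t2d_like", "t2d_like", "t2d_like",
                       "cancer_like", "cancer_like", "cancer_like",
                       "cancer_like"),
    sex = c("both", "both", "both", "both",
            "female", "male", "both", "both"),
    stringsAsFactors = FALSE
  )
}
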