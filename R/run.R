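#' Generate a self-contained set of synthetic simulation inputs
#'
#' Writes (or returns) a matched incidence curve, Gompertz-Makeham life
#' table and genetic architecture so that a full discovery-and-projection
#' run needs no external data.  The three incidence families are documented
#' in \code{\link{fixture_incidence}}; the architecture is the common-allele
#' scenario with a SNP count loosely matched to each family's heritability
#' tier (AD-like diseases carry the most variants).
#'
#' @param kind fixture family.
#' @param dir optional directory; when given, \code{incidence.yaml},
#'   \code{life_table.csv} and \code{architecture.csv} are written there.
#' @return list with elements \code{curve}, \code{life_table}, \code{arch}.
#' @export
generate_fixtures <- function(kind = c("cancer_like", "t2d_like", "ad_like"),
                              dir = NULL) {
  kind <- match.arg(kind)
  curve <- fixture_incidence(kind)
  lt <- synthesize_life_table()
  n_snps <- switch(kind, cancer_like = 400L, t2d_like = 2125L,
                   ad_like = 3575L)
  arch <- build_architecture("common_low", n_snps)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_incidence_config(curve, file.path(dir, "incidence.yaml"))
    write_life_table(lt, file.path(dir, "life_table.csv"))
    utils::write.csv(as.data.frame(arch),
                     file.path(dir, "architecture.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(curve = curve, life_table = lt, arch = arch)
}

.validate_run_config <- function(cfg) {
  if (is.null(cfg$fixture) && is.null(cfg$incidence))
    stop("run config: give 'fixture' (cancer_like/t2d_like/ad_like) or an ",
         "'incidence' block")
  pop <- cfg$population %||% list()
  mode <- pop$mode %||% "expectation"
  if (!mode %in% c("expectation", "stochastic"))
    stop("run config: population$mode must be 'expectation' or 'stochastic'")
  cfg$population <- list(
    mode = mode,
    n_bins = as.integer(pop$n_bins %||% 10001L),
    n_individuals = as.integer(pop$n_individuals %||% 100000L),
    scenario = pop$scenario %||% "common_low",
    n_snps = if (!is.null(pop$n_snps)) as.integer(pop$n_snps) else NULL)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$deltas <- as.numeric(unlist(cfg$deltas %||% c(0, 5, 10, 15)))
  cfg$hrs <- as.numeric(unlist(cfg$hrs %||% 2^seq(4, -4)))
  cfg
}

#' Run a full discovery / projection / scenario pipeline from a config
#'
#' Orchestrates the package end to end: build inputs (a named fixture
#' family, or an explicit incidence block plus optional life-table path),
#' construct the population, discover the aging coefficient, project the
#' baseline, and evaluate the hazard-ratio grid and an optional therapy
#' block.  All outputs are written to \code{out_dir} together with a JSON
#' run manifest from which the run can be reproduced exactly (expectation
#' mode is fully deterministic; stochastic mode is deterministic under the
#' recorded seed).
#'
#' @param config path to a YAML/JSON file, or an equivalent named list, with
#'   fields \code{fixture} or \code{incidence}, optional \code{life_table}
#'   (CSV path), \code{population} (mode, n_bins/n_individuals, scenario,
#'   n_snps), \code{hrs}, \code{deltas}, \code{therapy}
#'   (or_multiplier/n_edits, mode), \code{seed}.
#' @param out_dir output directory (created if needed).
#' @param verbose print per-stage progress.
#' @return (invisibly) a list with the constructed objects and result
#'   tables.
#' @export
lod_run <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) {
    cfg <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
           else jsonlite::read_json(config, simplifyVector = TRUE)
  } else cfg <- config
  cfg <- .validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  if (!is.null(cfg$fixture)) {
    fx <- generate_fixtures(cfg$fixture)
    curve <- fx$curve
    lt <- fx$life_table
    default_snps <- sum(fx$arch$n_snps)
  } else {
    curve <- incidence_curve(cfg$incidence$form,
                             as.list(cfg$incidence$parameters),
                             onset_age = cfg$incidence$onset_age %||% 0L)
    lt <- synthesize_life_table()
    default_snps <- 400L
  }
  if (!is.null(cfg$life_table)) lt <- load_life_table(cfg$life_table)

  pc <- cfg$population
  arch <- build_architecture(pc$scenario, pc$n_snps %||% default_snps)
  say("architecture: %s, %d SNPs", pc$scenario, sum(arch$n_snps))
  pop <- if (pc$mode == "expectation") bin_population(arch, pc$n_bins)
         else sample_population(arch, pc$n_individuals, seed = cfg$seed,
                                keep_genotypes = TRUE)
  say("population: %s mode, %d values", pc$mode, length(pop$values))

  A <- discover_aging_coefficient(curve, pop)
  write_aging_coefficient(A, file.path(out_dir, "aging_coefficient.csv"))
  say("aging coefficient discovered (max A = %.4g)", max(A$A, na.rm = TRUE))

  baseline <- project_population(A, pop, lt)
  write_grid_csv(as.data.frame(baseline),
                 file.path(out_dir, "baseline_projection.csv"))
  grid <- hr_grid(A, lt, hrs = cfg$hrs, deltas = cfg$deltas)
  write_grid_csv(grid, file.path(out_dir, "hr_grid.csv"))
  say("baseline lifetime risk %.4f; HR grid %d cells",
      lifetime_risk(baseline), nrow(grid))

  therapy_tab <- NULL
  if (!is.null(cfg$therapy)) {
    spec <- therapy_spec(
      or_multiplier = cfg$therapy$or_multiplier,
      n_edits = cfg$therapy$n_edits,
      mode = cfg$therapy$mode %||% "uniform_multiplier",
      arch = arch)
    therapy_tab <- therapy_scenarios(A, pop, spec, lt, deltas = cfg$deltas,
                                     arch = arch)
    write_grid_csv(therapy_tab, file.path(out_dir, "therapy_scenarios.csv"))
    say("therapy multiplier %.4g: risk at delta 0 is %.1f%% of baseline",
        spec$or_multiplier, therapy_tab$pct_of_baseline[1])
  }

  manifest <- list(
    config = cfg,
    architecture = list(scenario = pc$scenario,
                        n_snps = sum(arch$n_snps)),
    population = list(mode = pc$mode, size = length(pop$values),
                      normalization_reference = pop$normalization_reference),
    incidence = list(form = curve$form, parameters = curve$parameters,
                     onset_age = curve$onset_age),
    life_expectancy = life_expectancy(lt),
    baseline_lifetime_risk = lifetime_risk(baseline))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(curve = curve, life_table = lt, arch = arch, pop = pop,
                 aging = A, baseline = baseline, hr_grid = grid,
                 therapy = therapy_tab, manifest = manifest))
}
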