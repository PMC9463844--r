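VARIANTS <- c("frequency", "weighted_frequency", "aggregate")

#' Simulation configuration
#'
#' Bundles every knob of one simulation scenario: the synthetic region,
#' the true-cluster model, the sampling-proportion scenario, the data
#' variants to run, and the scan-engine settings. Defaults reproduce
#' the study conditions: 250 districts, prevalence 0.3/0.2, district
#' samples of 900--920, 100 iterations, MSWS = MRCS = 50%, 999 Monte
#' Carlo replicates, alpha = 0.05.
#'
#' Seeding: the region and true clusters use `region_seed`, the (single,
#' fixed) hypothetical population uses `master_seed`, iteration `i`
#' draws its sample with seed `master_seed + i`, and each variant's
#' scan uses `master_seed + i + 100000 * v` (`v` = 1, 2, 3 for
#' frequency, weighted frequency, aggregate), so results per variant do
#' not depend on which other variants are run.
#'
#' @param truth_model `"A"` (one 18-district cluster) or `"B"`
#'   (18 + 12).
#' @param scenario sampling-proportion scenario (1 = SRS, 2 = KCHS,
#'   3 = dispersed).
#' @param variants subset of `"frequency"`, `"weighted_frequency"`,
#'   `"aggregate"`.
#' @param n_iterations number of sample-scan-score iterations.
#' @param n_districts number of districts in the synthetic region.
#' @param msws,mrcs maximum scanning / reported window size fractions
#'   (`mrcs` may be `"gini"`).
#' @param replicates Monte Carlo replicates per scan.
#' @param alpha significance level.
#' @param master_seed master seed; all other seeds derive from it.
#' @param region_seed seed for the geography and true clusters.
#' @param weight_spec aggregate-variant precision weight (see
#'   [make_scan_input()]).
#' @param size_range district sample-size range.
#' @param regenerate_population regenerate the hypothetical population
#'   each iteration instead of fixing it per scenario.
#' @param out_dir optional directory for summary/score CSV output.
#' @param verbose print a per-iteration progress line.
#' @return a `sim_config` list.
#' @export
sim_config <- function(truth_model = "A", scenario = 1,
                       variants = VARIANTS,
                       n_iterations = 100, n_districts = 250,
                       msws = 0.5, mrcs = msws, replicates = 999,
                       alpha = 0.05, master_seed = 1,
                       region_seed = master_seed,
                       weight_spec = "inverse_variance",
                       size_range = c(900L, 920L),
                       regenerate_population = FALSE,
                       out_dir = NULL, verbose = FALSE) {
  variants <- match.arg(variants, VARIANTS, several.ok = TRUE)
  if (n_iterations < 1) stop("`n_iterations` must be >= 1", call. = FALSE)
  structure(list(truth_model = truth_model, scenario = scenario,
                 variants = variants, n_iterations = n_iterations,
                 n_districts = n_districts, msws = msws, mrcs = mrcs,
                 replicates = replicates, alpha = alpha,
                 master_seed = master_seed, region_seed = region_seed,
                 weight_spec = weight_spec, size_range = size_range,
                 regenerate_population = regenerate_population,
                 out_dir = out_dir, verbose = verbose),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Keys match the arguments of [sim_config()].
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs",
         call. = FALSE)
  do.call(sim_config, yaml::read_yaml(path))
}

#' Run one simulation scenario
#'
#' Generates the geography, true clusters and one fixed hypothetical
#' population, then repeats for each iteration: draw a complex-survey
#' sample, build the requested scan inputs, run the matching scan model
#' per variant (Bernoulli for the two individual-level variants,
#' weighted normal for the aggregate variant), and score sensitivity
#' and PPV of the significant clusters against the truth.
#'
#' @param config a [sim_config()].
#' @return list with `summary` (one row per variant), `scores` (one row
#'   per iteration x variant), `region`, `truth`.
#' @examples
#' cfg <- sim_config(n_districts = 30, n_iterations = 2,
#'                   replicates = 99, master_seed = 7)
#' res <- run_scenario(cfg)
#' res$summary
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  region <- generate_region(config$n_districts,
                            seed = config$region_seed)
  sizes <- if (config$truth_model == "A") {
    pmin(18L, max(2L, config$n_districts %/% 4L))
  } else {
    c(pmin(18L, max(2L, config$n_districts %/% 4L)),
      pmin(12L, max(1L, config$n_districts %/% 6L)))
  }
  truth <- define_true_clusters(region, config$truth_model,
                                sizes = sizes,
                                seed = config$region_seed)
  pop <- generate_population(region, truth, seed = config$master_seed)
  scores <- vector("list", length(config$variants))
  names(scores) <- config$variants
  score_rows <- list()
  for (i in seq_len(config$n_iterations)) {
    if (config$regenerate_population)
      pop <- generate_population(region, truth,
                                 seed = config$master_seed + 500000 + i)
    smp <- draw_survey_sample(region, pop, config$scenario,
                              seed = config$master_seed + i,
                              size_range = config$size_range)
    for (v in config$variants) {
      vi <- match(v, VARIANTS)
      input <- make_scan_input(smp, v, config$weight_spec)
      fit <- scan_cluster(input, region, msws = config$msws,
                          mrcs = config$mrcs,
                          replicates = config$replicates,
                          alpha = config$alpha,
                          seed = config$master_seed + i + 100000L * vi)
      sc <- score_iteration(truth, fit, region)
      scores[[v]] <- c(scores[[v]], list(sc))
      score_rows[[length(score_rows) + 1L]] <-
        data.frame(iteration = i, variant = v,
                   sensitivity = sc$sensitivity, ppv = sc$ppv,
                   n_significant = sc$n_significant,
                   max_llr = fit$max_llr,
                   min_p = if (nrow(fit$clusters))
                     min(fit$clusters$p_value) else NA_real_)
      if (config$verbose)
        message(sprintf(
          "iter %d %-18s maxLLR %8.2f  sig clusters %3d  sens %.3f",
          i, v, fit$max_llr, sc$n_significant, sc$sensitivity))
    }
  }
  summ <- do.call(rbind, lapply(config$variants, function(v) {
    cbind(data.frame(truth_model = config$truth_model,
                     scenario = config$scenario, variant = v),
          summarize_scores(scores[[v]]))
  }))
  rownames(summ) <- NULL
  out <- list(summary = summ, scores = do.call(rbind, score_rows),
              region = region, truth = truth)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tag <- paste0(config$truth_model, config$scenario)
    write.csv(summ, file.path(config$out_dir,
                              paste0("summary_", tag, ".csv")),
              row.names = FALSE)
    write.csv(out$scores, file.path(config$out_dir,
                                    paste0("scores_", tag, ".csv")),
              row.names = FALSE)
  }
  out
}

#' Run the six-scenario simulation grid
#'
#' The grid crosses the two true-cluster models with the three
#' sampling-proportion scenarios: grid scenarios 1--3 use truth model A
#' with proportions 1--3, scenarios 4--6 truth model B with proportions
#' 1--3. Each cell runs [run_scenario()] with the same engine settings
#' and master seed.
#'
#' @param config base [sim_config()]; its `truth_model` and `scenario`
#'   are overridden per grid cell.
#' @param scenarios subset of 1:6 to run.
#' @return data frame with one row per scenario x variant
#'   (`grid_scenario`, `truth_model`, `scenario`, `variant`, mean/sd of
#'   sensitivity and PPV, undefined-PPV count); written to
#'   `grid_summary.csv` under `config$out_dir` when set.
#' @export
run_grid <- function(config = sim_config(), scenarios = 1:6) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(scenarios %in% 1:6))
    stop("`scenarios` must be a subset of 1:6", call. = FALSE)
  rows <- lapply(scenarios, function(s) {
    cfg <- config
    cfg$truth_model <- if (s <= 3) "A" else "B"
    cfg$scenario <- ((s - 1L) %% 3L) + 1L
    res <- run_scenario(cfg)
    cbind(data.frame(grid_scenario = s), res$summary)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(config$out_dir, "grid_summary.csv"),
              row.names = FALSE)
  }
  out
}
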