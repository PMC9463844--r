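#' Sampling-proportion scenarios
#'
#' The three stratum sampling-proportion schemes used in the simulation
#' study. Scenario 1 ("srs") is simple random sampling within each
#' district, so the proportions equal the census stratum shares
#' `q_kj = N_kj / N_k`. Scenario 2 ("kchs") uses the age-by-sex
#' proportions observed in the 2018 Korea Community Health Survey.
#' Scenario 3 ("dispersed") over-samples the middle age groups and
#' under-samples the youngest and oldest, a deliberately more dispersed
#' scheme emulating stronger sampling bias.
#'
#' @param scenario `1`, `2`, `3`, or one of `"srs"`, `"kchs"`,
#'   `"dispersed"`.
#' @return A `sampling_scenario` object with elements `id`, `name`, and
#'   `proportions` (a length-8 vector, or `NULL` for SRS where the
#'   proportions are region-dependent).
#' @examples
#' sampling_scenario(2)$proportions
#' @export
sampling_scenario <- function(scenario) {
  if (inherits(scenario, "sampling_scenario")) return(scenario)
  names3 <- c("srs", "kchs", "dispersed")
  if (is.character(scenario)) scenario <- match(match.arg(scenario, names3),
                                                names3)
  if (!scenario %in% 1:3)
    stop("`scenario` must be 1, 2, 3 or one of \"srs\", \"kchs\", ",
         "\"dispersed\"", call. = FALSE)
  props <- switch(scenario,
    NULL,                                                  # 1: SRS
    c(0.07, 0.11, 0.14, 0.13, 0.08, 0.12, 0.16, 0.19),     # 2: KCHS 2018
    c(0.03, 0.15, 0.18, 0.09, 0.04, 0.16, 0.20, 0.15))     # 3: dispersed
  structure(list(id = scenario,
                 name = paste0(scenario, "-", names3[scenario]),
                 proportions = props),
            class = "sampling_scenario")
}

#' Stratum sampling-proportion matrix
#'
#' Expands a [sampling_scenario()] into the district-by-stratum matrix
#' of proportions `q_kj`; every row sums to 1.
#'
#' @param scenario scenario id/name or `sampling_scenario`.
#' @param region a `study_region`.
#' @return numeric matrix, districts x 8 strata.
#' @export
sampling_proportions <- function(scenario, region) {
  sc <- sampling_scenario(scenario)
  N <- stratum_populations(region)
  if (is.null(sc$proportions)) {
    q <- N / rowSums(N)
  } else {
    q <- matrix(sc$proportions, nrow = nrow(N), ncol = 8, byrow = TRUE)
  }
  dimnames(q) <- dimnames(N)
  q
}

#' Draw district sample sizes
#'
#' Draws each district's survey sample size `n_k` independently and
#' uniformly from the integers in `size_range` (default 900--920,
#' emulating an average of roughly 900 respondents per community health
#' centre).
#'
#' @param region a `study_region`; every district total must be at least
#'   `max(size_range)`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param size_range integer range for `n_k`.
#' @return integer vector of sample sizes, one per district.
#' @export
draw_district_sample_sizes <- function(region, seed = NULL,
                                       size_range = c(900L, 920L)) {
  validate_region(region)
  N_k <- rowSums(stratum_populations(region))
  if (any(N_k < max(size_range)))
    stop("invalid region: some district populations are below the ",
         "maximum sample size ", max(size_range), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  size_range <- as.integer(size_range)
  n <- nrow(region)
  size_range[1] + sample.int(size_range[2] - size_range[1] + 1L, n,
                             replace = TRUE) - 1L
}

#' Allocate district samples to strata
#'
#' Draws the stratum sample sizes `n_kj ~ Multinomial(n_k, q_k.)` for
#' every district. In the (practically negligible) event that a drawn
#' `n_kj` exceeds the stratum population `N_kj`, the district's
#' allocation is redrawn and a warning is issued.
#'
#' @param n_k integer vector of district sample sizes.
#' @param q districts x 8 matrix of sampling proportions (rows sum to 1
#'   within `1e-9`).
#' @param N districts x 8 matrix of stratum populations (for the
#'   truncation safeguard).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return integer matrix `n_kj`, districts x 8, with rows summing to
#'   `n_k`.
#' @export
allocate_strata <- function(n_k, q, N = NULL, seed = NULL) {
  if (any(abs(rowSums(q) - 1) > 1e-9))
    stop("invalid scenario: sampling proportions must sum to 1 per ",
         "district", call. = FALSE)
  if (any(n_k <= 0)) stop("`n_k` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  K <- length(n_k)
  out <- matrix(0L, K, ncol(q), dimnames = dimnames(q))
  for (k in seq_len(K)) {
    repeat {
      draw <- as.integer(rmultinom(1L, n_k[k], q[k, ]))
      if (is.null(N) || all(draw <= N[k, ])) break
      warning("stratum allocation exceeded population in district ",
              k - 1L, "; redrawing", call. = FALSE)
    }
    out[k, ] <- draw
  }
  out
}

#' Sample case counts from the population
#'
#' Samples `n_kj` individuals without replacement from each district x
#' stratum cell of the hypothetical population; the number of sampled
#' positives is `c_kj ~ Hypergeometric(N_kj, Y_kj, n_kj)`.
#'
#' @param pop a `population_outcomes` object.
#' @param n_kj integer matrix of stratum sample sizes.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return integer matrix `c_kj` of sampled positives.
#' @export
draw_cases <- function(pop, n_kj, seed = NULL) {
  stopifnot(inherits(pop, "population_outcomes"))
  if (any(n_kj > pop$N))
    stop("invalid sample: n_kj exceeds the stratum population",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cc <- rhyper(length(n_kj), m = as.vector(pop$Y),
               n = as.vector(pop$N - pop$Y), k = as.vector(n_kj))
  matrix(as.integer(cc), nrow = nrow(n_kj), dimnames = dimnames(n_kj))
}

#' Design, post-stratification and final survey weights
#'
#' The design weight of a sampled individual in district `k`, stratum
#' `j` is the inverse of its selection probability,
#' `w_kj = N_kj / (n_k q_kj)`. Post-stratification calibrates the
#' weighted stratum totals back to the census:
#' `w_kj^post = N_kj / (n_kj w_kj)`, and the final weight is the
#' product, which simplifies algebraically to `w_kj^final = N_kj /
#' n_kj`. Strata with no sampled individuals carry `NA` weights and are
#' excluded from all downstream sums.
#'
#' @param region a `study_region`.
#' @param n_k district sample sizes.
#' @param n_kj stratum sample-size matrix.
#' @param q stratum sampling-proportion matrix.
#' @return list of matrices `design`, `post`, `final` (NA where
#'   `n_kj == 0`).
#' @examples
#' # N_kj = 4500, n_k = 900, q_kj = 0.1: design weight 50,
#' # n_kj = 85: post-stratification weight 90/85, final weight 4500/85
#' @export
compute_weights <- function(region, n_k, n_kj, q) {
  N <- stratum_populations(region)
  if (any(q == 0 & N > 0))
    stop("undefined weight: q_kj = 0 for a populated stratum",
         call. = FALSE)
  design <- N / (n_k * q)
  post <- N / (n_kj * design)
  final <- design * post
  post[n_kj == 0] <- NA_real_
  final[n_kj == 0] <- NA_real_
  list(design = design, post = post, final = final)
}

#' Draw one complex-survey sample
#'
#' Runs the full sampling pipeline for one iteration: district sample
#' sizes, multinomial stratum allocation under the scenario's sampling
#' proportions, hypergeometric case sampling from the population, and
#' the three weights.
#'
#' @param region a `study_region`.
#' @param pop a `population_outcomes` for the same region.
#' @param scenario scenario id/name or [sampling_scenario()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param size_range integer range for `n_k`.
#' @return A `survey_sample`: list with `n_k`, matrices `n` (`n_kj`),
#'   `c` (`c_kj`), `w_design`, `w_post`, `w_final`, the proportion
#'   matrix `q`, `N`, and `district_id`.
#' @examples
#' region <- generate_region(25, seed = 1)
#' truth <- define_true_clusters(region, "A", sizes = 4, seed = 1)
#' pop <- generate_population(region, truth, seed = 2)
#' smp <- draw_survey_sample(region, pop, scenario = 1, seed = 3)
#' all(rowSums(smp$n) == smp$n_k)
#' @export
draw_survey_sample <- function(region, pop, scenario = 1, seed = NULL,
                               size_range = c(900L, 920L)) {
  if (!is.null(seed)) set.seed(seed)
  q <- sampling_proportions(scenario, region)
  n_k <- draw_district_sample_sizes(region, seed = NULL,
                                    size_range = size_range)
  n_kj <- allocate_strata(n_k, q, N = pop$N, seed = NULL)
  c_kj <- draw_cases(pop, n_kj, seed = NULL)
  w <- compute_weights(region, n_k, n_kj, q)
  structure(list(n_k = n_k, n = n_kj, c = c_kj,
                 w_design = w$design, w_post = w$post, w_final = w$final,
                 q = q, N = stratum_populations(region),
                 district_id = region$district_id),
            class = "survey_sample")
}

#' @export
print.survey_sample <- function(x, ...) {
  cat("Survey sample:", length(x$n_k), "districts, total n =",
      sum(x$n_k), "\n")
  cat("  crude prevalence (unweighted)", signif(sum(x$c) / sum(x$n), 4),
      "\n")
  invisible(x)
}

#' Write a survey sample as CSV
#'
#' Long layout
#' `iteration,district_id,stratum,n,c,w_design,w_post,w_final`, one row
#' per district x stratum cell.
#'
#' @param sample a `survey_sample`.
#' @param path file path.
#' @param iteration iteration label recorded in the first column.
#' @export
write_survey_sample_csv <- function(sample, path, iteration = 1L) {
  K <- length(sample$district_id)
  J <- ncol(sample$n)
  df <- data.frame(iteration = iteration,
                   district_id = rep(sample$district_id, times = J),
                   stratum = rep(seq_len(J), each = K),
                   n = as.vector(sample$n), c = as.vector(sample$c),
                   w_design = as.vector(sample$w_design),
                   w_post = as.vector(sample$w_post),
                   w_final = as.vector(sample$w_final))
  df <- df[order(df$district_id, df$stratum), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a scan input from a survey sample
#'
#' Converts a `survey_sample` into one of the three per-district data
#' types compared by the simulation study:
#' \describe{
#'   \item{`"frequency"`}{observed counts: `cases = sum_j c_kj`,
#'     `total = n_k`; analysed with the Bernoulli scan.}
#'   \item{`"weighted_frequency"`}{final-weight-inflated counts, rounded
#'     (half to even) at the district level:
#'     `cases = round(sum_j w_kj^final c_kj)`,
#'     `total = round(sum_j w_kj^final n_kj)` (approximately the census
#'     total `N_k`); analysed with the Bernoulli scan.}
#'   \item{`"aggregate"`}{the survey-weighted crude prevalence
#'     `rate_k = sum_j w c / sum_j w n` with a precision weight per
#'     `weight_spec`; analysed with the weighted normal scan.}
#' }
#'
#' For the aggregate type, `weight_spec = "inverse_variance"` (default)
#' uses the stratified estimator variance
#' `V_k = sum_j (N_kj/N_k)^2 p_kj (1 - p_kj) / n_kj` with the continuity
#' floor `p(1-p) >= 1/(4 n_kj^2)` (so the weight stays finite when a
#' district has no observed cases), and sets `weight_k = 1 / V_k`;
#' `weight_spec = "sample_size"` uses `weight_k = n_k`.
#'
#' @param sample a `survey_sample`.
#' @param variant `"frequency"`, `"weighted_frequency"` or
#'   `"aggregate"`.
#' @param weight_spec aggregate-variant precision weight:
#'   `"inverse_variance"` or `"sample_size"`.
#' @return A `scan_input` data frame: columns `district_id` plus either
#'   `cases`, `total` (Bernoulli variants) or `rate`, `weight`
#'   (aggregate); the variant is stored in `attr(, "variant")`.
#' @export
make_scan_input <- function(sample, variant = c("frequency",
                                                "weighted_frequency",
                                                "aggregate"),
                            weight_spec = c("inverse_variance",
                                            "sample_size")) {
  stopifnot(inherits(sample, "survey_sample"))
  variant <- match.arg(variant)
  obs <- sample$n > 0  # strata with no sampled units contribute nothing

  if (variant == "frequency") {
    out <- data.frame(district_id = sample$district_id,
                      cases = as.integer(rowSums(sample$c)),
                      total = as.integer(sample$n_k))
  } else if (variant == "weighted_frequency") {
    wf <- ifelse(obs, sample$w_final, 0)
    cases <- round(rowSums(wf * sample$c))
    total <- round(rowSums(wf * sample$n))
    out <- data.frame(district_id = sample$district_id,
                      cases = pmin(cases, total), total = total)
  } else {
    weight_spec <- match.arg(weight_spec)
    wf <- ifelse(obs, sample$w_final, 0)
    rate <- rowSums(wf * sample$c) / rowSums(wf * sample$n)
    if (weight_spec == "inverse_variance") {
      N_k <- rowSums(sample$N)
      p_hat <- ifelse(obs, sample$c / ifelse(obs, sample$n, 1L), 0)
      pq <- pmax(p_hat * (1 - p_hat),
                 1 / (4 * ifelse(obs, sample$n, 1L)^2))
      v_terms <- ifelse(obs,
                        (sample$N / N_k)^2 * pq / ifelse(obs, sample$n, 1L),
                        0)
      weight <- 1 / rowSums(v_terms)
    } else {
      weight <- as.numeric(sample$n_k)
    }
    out <- data.frame(district_id = sample$district_id,
                      rate = rate, weight = weight)
  }
  rownames(out) <- NULL
  structure(out, variant = variant,
            class = c("scan_input", "data.frame"))
}

#' Read / write scan inputs as CSV
#'
#' Bernoulli variants use columns `district_id,cases,total`; the
#' aggregate variant uses `district_id,rate,weight` (mirroring the
#' case/control and normal-model input layouts of standard scan
#' software).
#'
#' @param path file path.
#' @param x a `scan_input` (for writing).
#' @param variant variant label to attach when reading; inferred from
#'   the columns when `NULL`.
#' @export
read_scan_input_csv <- function(path, variant = NULL) {
  df <- read.csv(path)
  if (all(c("cases", "total") %in% names(df))) {
    if (is.null(variant)) variant <- "frequency"
  } else if (all(c("rate", "weight") %in% names(df))) {
    variant <- "aggregate"
  } else {
    stop("scan input CSV must have columns cases,total or rate,weight",
         call. = FALSE)
  }
  structure(df, variant = variant, class = c("scan_input", "data.frame"))
}

#' @rdname read_scan_input_csv
#' @export
write_scan_input_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
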