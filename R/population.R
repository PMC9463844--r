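#' Generate binary outcomes for the hypothetical population
#'
#' Draws the census-level outcome counts: for every district `k` and
#' stratum `j`, the number of positives `Y_kj` is binomial
#' `B(N_kj, p_kj)`, where `p_kj` equals the true-cluster model's inside
#' prevalence when district `k` belongs to any true cluster and the
#' outside prevalence otherwise (prevalence does not vary with stratum).
#' Individuals are never materialised; downstream sampling without
#' replacement uses hypergeometric draws against these counts, which is
#' distributionally identical to subsampling labelled individuals.
#'
#' @param region a `study_region`.
#' @param truth a `true_cluster_model`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A `population_outcomes` object: list with integer matrices
#'   `N` and `Y` (districts x 8 strata) and the per-district prevalence
#'   vector `p`.
#' @examples
#' region <- generate_region(25, seed = 1)
#' truth <- define_true_clusters(region, "A", sizes = 4, seed = 1)
#' pop <- generate_population(region, truth, seed = 2)
#' range(pop$Y / pop$N)
#' @export
generate_population <- function(region, truth, seed = NULL) {
  validate_region(region)
  stopifnot(inherits(truth, "true_cluster_model"))
  if (!is.null(seed)) set.seed(seed)
  N <- stratum_populations(region)
  inside <- region$district_id %in% unlist(truth$clusters)
  p <- ifelse(inside, truth$prevalence_inside, truth$prevalence_outside)
  Y <- matrix(rbinom(length(N), as.vector(N), rep(p, times = ncol(N))),
              nrow = nrow(N), ncol = ncol(N), dimnames = dimnames(N))
  structure(list(N = N, Y = Y, p = p, district_id = region$district_id),
            class = "population_outcomes")
}

#' @export
print.population_outcomes <- function(x, ...) {
  cat("Population outcomes:", nrow(x$N), "districts x", ncol(x$N),
      "strata\n")
  cat("  overall prevalence", signif(sum(x$Y) / sum(x$N), 4), "\n")
  invisible(x)
}

#' Write population outcome counts as CSV
#'
#' Long layout `district_id,stratum,N,Y`.
#'
#' @param pop a `population_outcomes` object.
#' @param path file path.
#' @export
write_population_csv <- function(pop, path) {
  df <- data.frame(district_id = rep(pop$district_id, times = ncol(pop$N)),
                   stratum = rep(seq_len(ncol(pop$N)),
                                 each = nrow(pop$N)),
                   N = as.vector(pop$N), Y = as.vector(pop$Y))
  df <- df[order(df$district_id, df$stratum), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
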