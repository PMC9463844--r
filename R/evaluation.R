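#' Score one scan result against the true clusters
#'
#' Let `T` be the union of true-cluster districts and `D` the union of
#' districts in significant reported clusters. Sensitivity is
#' `|T intersect D| / |T|`; positive predictive value (PPV) is
#' `|T intersect D| / |D|`, undefined (`NA`) when no significant
#' cluster was found.
#'
#' @param truth a `true_cluster_model` with at least one cluster.
#' @param result a `scan_cluster` fit, or any data frame with a
#'   `members` list column and `significant` flags (e.g. a parsed
#'   cluster report).
#' @param region optional `study_region` used to validate member ids.
#' @return An `iteration_score`: list with `sensitivity`, `ppv` (`NA`
#'   when undefined) and `n_significant`.
#' @examples
#' truth <- true_cluster_model(list(0:17))
#' fake <- data.frame(significant = TRUE)
#' fake$members <- list(0:19)
#' score_iteration(truth, fake)  # sensitivity 1, ppv 18/20
#' @export
score_iteration <- function(truth, result, region = NULL) {
  stopifnot(inherits(truth, "true_cluster_model"))
  cl <- if (inherits(result, "scan_cluster")) result$clusters else result
  stopifnot(is.data.frame(cl))
  T_set <- unique(unlist(truth$clusters))
  if (!length(T_set))
    stop("truth model has no clusters; sensitivity is undefined",
         call. = FALSE)
  D_set <- unique(unlist(cl$members[cl$significant]))
  if (!is.null(region)) {
    bad <- setdiff(c(T_set, D_set), region$district_id)
    if (length(bad))
      stop("district id(s) outside the region: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  hit <- length(intersect(T_set, D_set))
  structure(list(sensitivity = hit / length(T_set),
                 ppv = if (length(D_set)) hit / length(D_set)
                       else NA_real_,
                 n_significant = sum(cl$significant)),
            class = "iteration_score")
}

#' Summarise iteration scores
#'
#' Mean and sample standard deviation (denominator `n - 1`) of
#' sensitivity over all iterations and of PPV over the iterations where
#' it is defined; iterations with no significant cluster (undefined
#' PPV) are counted separately rather than imputed, unless
#' `impute_zero_ppv = TRUE`.
#'
#' @param scores list of `iteration_score` objects.
#' @param impute_zero_ppv treat undefined PPV as 0 instead of
#'   excluding it.
#' @return one-row data frame with `n_iterations`, `mean_sensitivity`,
#'   `sd_sensitivity`, `mean_ppv`, `sd_ppv`, `n_undefined_ppv`.
#' @export
summarize_scores <- function(scores, impute_zero_ppv = FALSE) {
  if (!length(scores)) stop("empty score list", call. = FALSE)
  sens <- vapply(scores, `[[`, 0, "sensitivity")
  ppv <- vapply(scores, `[[`, 0, "ppv")
  und <- sum(is.na(ppv))
  if (impute_zero_ppv) ppv[is.na(ppv)] <- 0
  pd <- ppv[!is.na(ppv)]
  data.frame(n_iterations = length(scores),
             mean_sensitivity = mean(sens),
             sd_sensitivity = if (length(sens) > 1) sd(sens) else 0,
             mean_ppv = if (length(pd)) mean(pd) else NA_real_,
             sd_ppv = if (length(pd) > 1) sd(pd) else 0,
             n_undefined_ppv = und)
}
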