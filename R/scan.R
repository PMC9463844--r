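`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bernoulli scan log-likelihood ratio
#'
#' High-rate Bernoulli likelihood-ratio statistic for a scanning window
#' holding `cases` of the window's `total` observations, against `C`
#' total cases among `N` observations overall. The statistic is the
#' log-ratio of the binomial likelihood maximised with separate
#' case probabilities inside and outside the window (constrained to
#' inside > outside) to the likelihood under a common probability:
#' \deqn{LLR = c \log\frac{c}{n} + (n-c) \log\frac{n-c}{n}
#'   + c_o \log\frac{c_o}{n_o} + (n_o-c_o) \log\frac{n_o-c_o}{n_o}
#'   - C \log\frac{C}{N} - (N-C) \log\frac{N-C}{N}}
#' with \eqn{c_o = C - c}, \eqn{n_o = N - n}, the convention
#' \eqn{0 \log 0 = 0}, and value 0 whenever the inside rate does not
#' exceed the outside rate (high-rate scan).
#'
#' @param cases cases inside the window (vectorised).
#' @param total observations inside the window.
#' @param C total cases.
#' @param N total observations.
#' @return non-negative numeric vector of log-likelihood ratios.
#' @examples
#' bernoulli_llr(8, 10, 10, 20)  # 16*log(0.8) + 4*log(0.2) - 20*log(0.5)
#' @export
bernoulli_llr <- function(cases, total, C, N) {
  k <- max(length(cases), length(total), length(C), length(N))
  cases <- rep_len(cases, k); total <- rep_len(total, k)
  C <- rep_len(C, k); N <- rep_len(N, k)
  if (any(cases < 0 | cases > total | total > N | cases > C | C > N))
    stop("invalid arguments: require 0 <= cases <= total <= N and ",
         "cases <= C <= N", call. = FALSE)
  .bern_llr(cases, total, C, N)
}

# unvalidated vectorised core; also applied to whole prefix matrices
.bern_llr <- function(c_in, n_in, C, N) {
  xlx <- function(a) ifelse(a > 0, a * log(a), 0)
  c_out <- C - c_in
  n_out <- N - n_in
  ll <- xlx(c_in) + xlx(n_in - c_in) - xlx(n_in) +
    xlx(c_out) + xlx(n_out - c_out) - xlx(n_out) -
    (xlx(C) + xlx(N - C) - xlx(N))
  out <- ifelse(c_in * n_out > c_out * n_in, ll, 0)
  out[n_out <= 0] <- 0
  pmax(out, 0)
}

#' Weighted normal scan log-likelihood ratio
#'
#' High-rate weighted normal statistic for region-level rates with
#' per-region precision weights (rates modelled as
#' \eqn{y_i \sim N(\mu, \sigma^2 / w_i)}). With weighted means
#' \eqn{\hat\mu_{in}}, \eqn{\hat\mu_{out}}, \eqn{\hat\mu_0} inside the
#' window, outside it, and overall, and
#' \deqn{\hat\sigma_1^2 = \frac{1}{n}\left[\sum_{i \in Z} w_i (y_i -
#'   \hat\mu_{in})^2 + \sum_{i \notin Z} w_i (y_i -
#'   \hat\mu_{out})^2\right], \quad
#'   \hat\sigma_0^2 = \frac{1}{n} \sum_i w_i (y_i - \hat\mu_0)^2,}
#' the statistic is \eqn{(n/2) \log(\hat\sigma_0^2 / \hat\sigma_1^2)}
#' when \eqn{\hat\mu_{in} > \hat\mu_{out}} and 0 otherwise.
#' \eqn{\hat\sigma_1^2} is floored at `1e-12`; constant data (zero
#' total variance) gives 0. The statistic is invariant to rescaling all
#' weights by a common factor.
#'
#' @param Z integer indices (into `y`) of the window members; a
#'   non-empty proper subset.
#' @param y region-level rates.
#' @param w positive precision weights.
#' @return non-negative log-likelihood ratio.
#' @export
weighted_normal_llr <- function(Z, y, w) {
  n <- length(y)
  Z <- as.integer(Z)
  if (length(w) != n)
    stop("`y` and `w` must have equal length", call. = FALSE)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (!length(Z) || length(Z) >= n || any(Z < 1 | Z > n) ||
      anyDuplicated(Z))
    stop("invalid window: Z must be a non-empty proper subset of 1..n",
         call. = FALSE)
  inz <- logical(n); inz[Z] <- TRUE
  mu_in <- sum(w[inz] * y[inz]) / sum(w[inz])
  mu_out <- sum(w[!inz] * y[!inz]) / sum(w[!inz])
  if (mu_in <= mu_out) return(0)
  mu0 <- sum(w * y) / sum(w)
  s0 <- sum(w * (y - mu0)^2) / n
  if (s0 <= 1e-12) return(0)
  s1 <- (sum(w[inz] * (y[inz] - mu_in)^2) +
           sum(w[!inz] * (y[!inz] - mu_out)^2)) / n
  s1 <- max(s1, 1e-12)
  max(0, n / 2 * log(s0 / s1))
}

#' Build circular scanning windows
#'
#' For every district taken as a window centre, the candidate windows
#' are the nested prefixes of the other districts ordered by ascending
#' Euclidean centroid distance (ties broken by ascending district id),
#' truncated where the cumulative window size exceeds `msws` times the
#' total size. The size basis is supplied through `size_values`: the
#' per-district observation totals for the Bernoulli model, or one unit
#' per district for the weighted normal model (where the cap is on the
#' number of districts). Every single-district window is always
#' retained.
#'
#' @param region a `study_region`.
#' @param size_values positive per-district sizes.
#' @param msws maximum scanning window size as a fraction of the total
#'   size, in (0, 1].
#' @return A `window_set`: list with the distance-order matrix `ord`
#'   (row `i`, column `c`: position of the `i`-th nearest district to
#'   centre `c`), per-centre admissible prefix counts `wlen`, the
#'   cumulative-size matrix `cum_size`, `size_values`, `total_size` and
#'   `msws`.
#' @export
build_windows <- function(region, size_values, msws = 0.5) {
  validate_region(region)
  n <- nrow(region)
  size_values <- rep_len(as.numeric(size_values), n)
  if (any(size_values <= 0))
    stop("`size_values` must be positive", call. = FALSE)
  if (msws <= 0 || msws > 1)
    stop("`msws` must lie in (0, 1]", call. = FALSE)
  d <- as.matrix(dist(cbind(region$x, region$y)))
  ord <- matrix(0L, n, n)
  for (cc in seq_len(n)) ord[, cc] <- order(d[, cc], region$district_id)
  cum_size <- apply(matrix(size_values[ord], n, n), 2, cumsum)
  total <- sum(size_values)
  wlen <- pmax(1L, colSums(cum_size <= msws * total))
  structure(list(ord = ord, wlen = wlen, cum_size = cum_size,
                 size_values = size_values, total_size = total,
                 msws = msws, district_id = region$district_id),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("Window set:", length(x$wlen), "centres,", sum(x$wlen),
      "windows (MSWS", x$msws, ")\n")
  invisible(x)
}

#' Members of one scanning window
#'
#' @param ws a `window_set`.
#' @param center district id of the window centre.
#' @param size number of member districts.
#' @return district ids of the window members.
#' @export
window_members <- function(ws, center, size) {
  cc <- match(center, ws$district_id)
  ws$district_id[ws$ord[seq_len(size), cc]]
}

# Null case counts for the Bernoulli scan: C cases re-allocated over
# districts conditional on the district totals (multivariate
# hypergeometric; equivalent to permuting case labels over all N units).
r_null_bernoulli <- function(totals, C, R) {
  n <- length(totals)
  N <- sum(totals)
  out <- matrix(0, n, R)
  remC <- rep.int(C, R)
  remN <- N
  for (k in seq_len(n - 1L)) {
    draw <- rhyper(R, m = remC, n = remN - remC, k = totals[k])
    out[k, ] <- draw
    remC <- remC - draw
    remN <- remN - totals[k]
  }
  out[n, ] <- remC
  out
}

# prefix-matrix weighted normal LLR (observed data path)
.wnorm_llr_prefix <- function(sw, swy, swyy, Tw, Twy, Twyy, n) {
  ow <- Tw - sw
  owy <- Twy - swy
  s0 <- (Twyy - Twy^2 / Tw) / n
  if (s0 <= 1e-12) return(array(0, dim = dim(sw)))
  s1 <- pmax((Twyy - swy^2 / sw - ifelse(ow > 0, owy^2 / ow, 0)) / n,
             1e-12)
  out <- ifelse(ow > 0 & swy * ow > owy * sw, n / 2 * log(s0 / s1), 0)
  pmax(out, 0)
}

#' Fit a circular spatial scan statistic
#'
#' Scans a study region for high-rate clusters with the circular
#' spatial scan statistic, using the Bernoulli model for case/control
#' counts (`frequency` and `weighted_frequency` inputs) or the weighted
#' normal model for rate/weight pairs (`aggregate` inputs), and
#' assesses significance by Monte Carlo testing: the observed maximum
#' log-likelihood ratio is ranked among the maxima of `replicates` null
#' datasets (Bernoulli: total cases re-allocated conditional on
#' district totals; weighted normal: the (rate, weight) pairs permuted
#' jointly across districts). Reported clusters are the greedily
#' selected, mutually non-overlapping windows in decreasing LLR order
#' (ties broken by smaller window, then lower centre id), truncated at
#' the maximum reported cluster size; reporting stops at the first
#' non-significant cluster, except that the most likely cluster is
#' always reported. Each reported cluster's p-value is the rank of its
#' LLR in the replicate max-LLR distribution,
#' `(1 + #\{replicate max >= LLR\}) / (replicates + 1)`.
#'
#' @param x a `scan_input` (see [make_scan_input()]), or a data frame
#'   with columns `district_id` plus `cases`/`total` or `rate`/`weight`.
#' @param region the `study_region` the input refers to.
#' @param model `"bernoulli"` or `"weighted_normal"`; by default
#'   inferred from the input columns.
#' @param msws maximum scanning window size (fraction; counts basis for
#'   Bernoulli, district basis for weighted normal).
#' @param mrcs maximum reported cluster size: a fraction not exceeding
#'   `msws`, or `"gini"` for Gini-coefficient selection over
#'   `gini_candidates`.
#' @param replicates number of Monte Carlo replicates (at least 19).
#' @param alpha significance level.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param gini_candidates candidate MRCS fractions for `mrcs = "gini"`.
#' @return An object of class `scan_cluster` with, in particular, a
#'   `clusters` data frame (rank, centre id, member count, LLR,
#'   p-value, significance flag, member ids) and the replicate maxima.
#' @examples
#' region <- generate_region(50, seed = 1)
#' truth <- define_true_clusters(region, "A", sizes = 6, seed = 1)
#' pop <- generate_population(region, truth, seed = 2)
#' smp <- draw_survey_sample(region, pop, scenario = 1, seed = 3)
#' fit <- scan_cluster(make_scan_input(smp, "frequency"), region,
#'                     replicates = 99, seed = 4)
#' fit
#' @export
scan_cluster <- function(x, region, model = NULL, msws = 0.5, mrcs = msws,
                         replicates = 999, alpha = 0.05, seed = NULL,
                         gini_candidates = c(0.01, 0.02, 0.03, 0.04, 0.05,
                                             0.06, 0.08, 0.10, 0.12, 0.15,
                                             0.20, 0.25, 0.30, 0.35, 0.40,
                                             0.45, 0.50)) {
  validate_region(region)
  n <- nrow(region)
  if (replicates < 19)
    stop("`replicates` must be at least 19 to resolve alpha = 0.05",
         call. = FALSE)
  variant <- attr(x, "variant") %||%
    (if ("cases" %in% names(x)) "frequency" else "aggregate")
  if (is.null(model))
    model <- if (variant == "aggregate") "weighted_normal" else "bernoulli"
  model <- match.arg(model, c("bernoulli", "weighted_normal"))
  x <- as.data.frame(x)[match(region$district_id, x$district_id), ]
  if (anyNA(x$district_id))
    stop("scan input does not cover every region district", call. = FALSE)
  use_gini <- identical(mrcs, "gini")
  if (!use_gini && mrcs > msws)
    stop("`mrcs` must not exceed `msws`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (model == "bernoulli") {
    cases <- as.numeric(x$cases)
    totals <- as.numeric(x$total)
    if (any(cases < 0 | cases > totals))
      stop("require 0 <= cases <= total per district", call. = FALSE)
    C <- sum(cases)
    N <- sum(totals)
    ws <- build_windows(region, totals, msws)
    cumc <- apply(matrix(cases[ws$ord], n, n), 2, cumsum)
    llr_mat <- .bern_llr(cumc, ws$cum_size, C, N)
    if (C > 0 && C < N) {
      null_cases <- r_null_bernoulli(totals, C, replicates)
      repmax <- scan_max_bernoulli(ws$ord, ws$wlen, totals, null_cases,
                                   C, N)
    } else {
      repmax <- numeric(replicates)
    }
    shares <- list(o = cumc / max(C, 1), e = ws$cum_size / N)
  } else {
    y <- as.numeric(x$rate)
    w <- as.numeric(x$weight)
    if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
    ws <- build_windows(region, rep(1, n), msws)
    ws$wlen <- pmin(ws$wlen, n - 1L)  # window must be a proper subset
    sw <- apply(matrix(w[ws$ord], n, n), 2, cumsum)
    swy <- apply(matrix((w * y)[ws$ord], n, n), 2, cumsum)
    swyy <- apply(matrix((w * y^2)[ws$ord], n, n), 2, cumsum)
    llr_mat <- .wnorm_llr_prefix(sw, swy, swyy, sum(w), sum(w * y),
                                 sum(w * y^2), n)
    perm <- vapply(seq_len(replicates), function(i) sample.int(n),
                   integer(n))
    repmax <- scan_max_wnormal(ws$ord, ws$wlen,
                               matrix(y[perm], n), matrix(w[perm], n))
    shares <- list(o = swy / sum(w * y), e = sw / sum(w))
  }
  # zero out inadmissible prefixes (beyond the MSWS cap)
  admissible <- row(llr_mat) <= ws$wlen[col(llr_mat)]
  llr_mat[!admissible] <- 0

  if (use_gini) {
    mrcs <- .gini_pick_mrcs(llr_mat, ws, repmax, alpha, replicates,
                            gini_candidates, shares)
  }
  mlen <- pmin(ws$wlen,
               pmax(1L, colSums(ws$cum_size <= mrcs * ws$total_size)))
  clusters <- .select_clusters(llr_mat, ws, mlen, repmax, alpha,
                               replicates)
  structure(list(clusters = clusters, model = model, variant = variant,
                 msws = msws, mrcs = mrcs,
                 mrcs_mode = if (use_gini) "gini" else "fixed",
                 replicates = replicates, alpha = alpha,
                 replicate_maxima = repmax,
                 max_llr = max(llr_mat),
                 n_districts = n, region = region),
            class = "scan_cluster")
}

# Greedy non-overlapping cluster selection over the admissible windows.
.select_clusters <- function(llr_mat, ws, mlen, repmax, alpha, R) {
  n <- nrow(llr_mat)
  empty <- data.frame(rank = integer(), center_id = integer(),
                      n_members = integer(), llr = numeric(),
                      p_value = numeric(), significant = logical())
  empty$members <- list()
  cand <- which(llr_mat > 0)
  if (!length(cand)) return(empty)
  pre <- (cand - 1L) %% n + 1L
  cen <- (cand - 1L) %/% n + 1L
  keep <- pre <= mlen[cen]
  if (!any(keep)) return(empty)
  pre <- pre[keep]; cen <- cen[keep]; lv <- llr_mat[cand][keep]
  # only windows that can reach significance matter, plus the best one
  m_star <- floor(alpha * (R + 1)) - 1
  lam_crit <- if (m_star < 0) Inf else
    sort(repmax, decreasing = TRUE)[m_star + 1]
  pass <- lv > lam_crit | lv >= max(lv)
  pre <- pre[pass]; cen <- cen[pass]; lv <- lv[pass]
  o <- order(-lv, pre, cen)
  covered <- logical(n)
  rows <- list()
  for (t in o) {
    mem <- ws$ord[seq_len(pre[t]), cen[t]]
    if (any(covered[mem])) next
    p <- (1 + sum(repmax >= lv[t])) / (R + 1)
    sig <- p <= alpha
    if (!sig && length(rows)) break
    covered[mem] <- TRUE
    rows[[length(rows) + 1L]] <-
      list(center = cen[t], size = pre[t], llr = lv[t], p = p, sig = sig,
           members = ws$district_id[mem])
    if (!sig) break
  }
  out <- data.frame(rank = seq_along(rows),
                    center_id = ws$district_id[vapply(rows, `[[`, 0L,
                                                      "center")],
                    n_members = vapply(rows, `[[`, 0L, "size"),
                    llr = vapply(rows, `[[`, 0, "llr"),
                    p_value = vapply(rows, `[[`, 0, "p"),
                    significant = vapply(rows, `[[`, TRUE, "sig"))
  out$members <- lapply(rows, `[[`, "members")
  out
}

#' Gini coefficient of a reported cluster collection
#'
#' Given the observed and expected shares of a set of reported
#' clusters, appends the remainder of the map as a final segment, sorts
#' segments by decreasing observed/expected ratio, draws the Lorenz
#' curve through the cumulative (expected, observed) points, and
#' returns twice the area between the curve and the diagonal.
#'
#' @param observed observed shares of the clusters (e.g. case shares).
#' @param expected expected shares (e.g. population shares).
#' @return the Gini coefficient.
#' @examples
#' gini_coefficient(observed = 0.5, expected = 0.2)  # 0.3
#' @export
gini_coefficient <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  o <- c(observed, max(0, 1 - sum(observed)))
  e <- c(expected, max(0, 1 - sum(expected)))
  keep <- e > 0 | o > 0
  o <- o[keep]; e <- e[keep]
  ord <- order(o / pmax(e, .Machine$double.xmin), decreasing = TRUE)
  co <- cumsum(o[ord]); ce <- cumsum(e[ord])
  area <- sum(diff(c(0, ce)) * (c(0, utils::head(co, -1)) + co) / 2)
  2 * (area - 0.5)
}

# Gini-optimal MRCS over the candidate fractions; falls back to msws
# when no candidate yields a significant cluster.
.gini_pick_mrcs <- function(llr_mat, ws, repmax, alpha, R, candidates,
                            shares) {
  if (!length(candidates))
    stop("empty MRCS candidate set", call. = FALSE)
  best <- NULL
  best_g <- -Inf
  for (cm in sort(candidates)) {
    mlen <- pmin(ws$wlen,
                 pmax(1L, colSums(ws$cum_size <= cm * ws$total_size)))
    cl <- .select_clusters(llr_mat, ws, mlen, repmax, alpha, R)
    cl <- cl[cl$significant, , drop = FALSE]
    if (!nrow(cl)) next
    idx <- cbind(cl$n_members, match(cl$center_id, ws$district_id))
    g <- gini_coefficient(shares$o[idx], shares$e[idx])
    if (g > best_g + 1e-12) {
      best_g <- g
      best <- cm
    }
  }
  best %||% ws$msws
}

#' Report non-overlapping clusters from scored windows
#'
#' Standalone cluster-reporting rule, applied to a pre-computed table
#' of candidate windows: greedy selection in decreasing LLR order (ties
#' broken by smaller window, then lower centre id), keeping a window
#' only when it shares no member with any previously kept window;
#' significance is flagged by `p_value <= alpha`.
#'
#' @param candidates data frame with columns `center_id`, `llr`,
#'   `p_value`, and a list column `members` of district-id vectors.
#' @param alpha significance level.
#' @return the kept rows, ranked, with a `significant` column.
#' @export
report_clusters <- function(candidates, alpha = 0.05) {
  stopifnot(is.data.frame(candidates),
            all(c("center_id", "llr", "p_value", "members") %in%
                  names(candidates)))
  nm <- lengths(candidates$members)
  o <- order(-candidates$llr, nm, candidates$center_id)
  covered <- integer()
  keep <- integer()
  for (t in o) {
    mem <- candidates$members[[t]]
    if (length(intersect(mem, covered))) next
    covered <- c(covered, mem)
    keep <- c(keep, t)
  }
  out <- candidates[keep, , drop = FALSE]
  out$significant <- out$p_value <= alpha
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.scan_cluster <- function(x, digits = 4, ...) {
  cat("Circular spatial scan (", x$model, " model, ", x$variant,
      " input)\n", sep = "")
  cat("  MSWS ", x$msws, ", MRCS ", signif(x$mrcs, 3),
      if (x$mrcs_mode == "gini") " (Gini-selected)", ", ",
      x$replicates, " Monte Carlo replicates, alpha = ", x$alpha,
      "\n", sep = "")
  cl <- x$clusters
  if (!nrow(cl)) {
    cat("  No clusters with positive LLR.\n")
  } else {
    cat("  ", sum(cl$significant), "significant cluster(s) reported:\n")
    show <- cl[, c("rank", "center_id", "n_members", "llr", "p_value",
                   "significant")]
    show$llr <- signif(show$llr, digits)
    print(utils::head(show, 10), row.names = FALSE)
    if (nrow(show) > 10) cat("  ... and", nrow(show) - 10, "more\n")
  }
  invisible(x)
}

#' @export
summary.scan_cluster <- function(object, ...) {
  cl <- object$clusters
  structure(list(model = object$model, variant = object$variant,
                 n_reported = nrow(cl),
                 n_significant = sum(cl$significant),
                 n_districts_flagged =
                   length(unique(unlist(cl$members[cl$significant]))),
                 max_llr = object$max_llr,
                 min_p = if (nrow(cl)) min(cl$p_value) else NA_real_,
                 mrcs = object$mrcs, alpha = object$alpha),
            class = "summary.scan_cluster")
}

#' @export
print.summary.scan_cluster <- function(x, ...) {
  cat("Scan summary (", x$model, "): ", x$n_significant,
      " significant of ", x$n_reported, " reported cluster(s); ",
      x$n_districts_flagged, " district(s) flagged\n", sep = "")
  cat("  max LLR ", signif(x$max_llr, 4), ", min p ",
      signif(x$min_p, 4), ", MRCS ", signif(x$mrcs, 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.scan_cluster <- function(x, ...) {
  cl <- x$clusters
  plot(x$region, clusters = cl$members[cl$significant], ...)
  invisible(x)
}

#' Write a cluster report CSV
#'
#' One row per reported cluster:
#' `cluster_rank,center_id,n_members,member_ids,llr,p_value,significant`
#' with member ids semicolon-joined.
#'
#' @param fit a `scan_cluster` object.
#' @param path file path.
#' @export
write_cluster_report <- function(fit, path) {
  cl <- fit$clusters
  df <- data.frame(cluster_rank = cl$rank, center_id = cl$center_id,
                   n_members = cl$n_members,
                   member_ids = vapply(cl$members, paste, "",
                                       collapse = ";"),
                   llr = cl$llr, p_value = cl$p_value,
                   significant = cl$significant)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cluster report CSV
#'
#' @param path file path.
#' @return data frame with a parsed `members` list column.
#' @export
read_cluster_report <- function(path) {
  df <- read.csv(path)
  df$members <- lapply(strsplit(as.character(df$member_ids), ";"),
                       as.integer)
  df
}
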