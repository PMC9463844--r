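#' Generate a synthetic study region
#'
#' Builds a study geography of `n_districts` districts on a jittered
#' rectangular lattice, each carrying a census population stratified into
#' the eight age-by-sex strata used throughout the package (strata 1--4:
#' men aged 20--34, 35--49, 50--64, 65+; strata 5--8: the same age groups
#' for women). District totals are log-normally distributed (median
#' `median_population`) and clipped to `population_range`, then split over
#' the strata by `stratum_shares` using the largest-remainder method so
#' the stratum counts sum exactly to the district total.
#'
#' The lattice jitter is kept below half the lattice spacing so that the
#' nearest-neighbour ordering used by the circular scanning windows is
#' free of distance ties (up to floating tolerance).
#'
#' @param n_districts number of districts (at least 2).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param median_population median district census total.
#' @param sdlog log-scale standard deviation of the district totals.
#' @param population_range length-2 clip range for district totals.
#' @param stratum_shares length-8 positive shares (normalised to sum 1)
#'   splitting each district total over the strata.
#' @param jitter uniform jitter half-width as a fraction of the lattice
#'   spacing; must be below 0.5.
#' @return A `study_region`: a data frame with columns `district_id`
#'   (0-based, contiguous), planar centroid coordinates `x`, `y`, and
#'   stratum populations `N_1` ... `N_8`.
#' @examples
#' region <- generate_region(25, seed = 1)
#' head(region)
#' @export
generate_region <- function(n_districts, seed = NULL,
                            median_population = 200000,
                            sdlog = 0.6,
                            population_range = c(20000, 1000000),
                            stratum_shares = c(0.10, 0.13, 0.13, 0.09,
                                               0.10, 0.13, 0.14, 0.18),
                            jitter = 0.25) {
  if (length(n_districts) != 1L || !is.finite(n_districts) || n_districts < 2)
    stop("`n_districts` must be a single integer >= 2", call. = FALSE)
  n_districts <- as.integer(n_districts)
  if (length(stratum_shares) != 8L || any(stratum_shares <= 0))
    stop("`stratum_shares` must be 8 positive values", call. = FALSE)
  if (jitter < 0 || jitter >= 0.5)
    stop("`jitter` must lie in [0, 0.5)", call. = FALSE)
  stratum_shares <- stratum_shares / sum(stratum_shares)
  if (!is.null(seed)) set.seed(seed)

  ncol_lat <- ceiling(sqrt(n_districts))
  idx <- seq_len(n_districts) - 1L
  gx <- idx %% ncol_lat
  gy <- idx %/% ncol_lat
  x <- gx + runif(n_districts, -jitter, jitter)
  y <- gy + runif(n_districts, -jitter, jitter)

  N_k <- rlnorm(n_districts, meanlog = log(median_population), sdlog = sdlog)
  N_k <- as.integer(round(pmin(pmax(N_k, population_range[1]),
                               population_range[2])))
  N_kj <- t(vapply(N_k, apportion_integer, integer(8), shares = stratum_shares))
  colnames(N_kj) <- paste0("N_", 1:8)

  region <- data.frame(district_id = idx, x = x, y = y, N_kj)
  class(region) <- c("study_region", "data.frame")
  validate_region(region)
  region
}

# Largest-remainder apportionment of `total` into integer parts ~ shares.
apportion_integer <- function(total, shares) {
  raw <- total * shares
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Validate a study region
#'
#' Checks the `study_region` invariants: unique contiguous 0-based
#' district ids, pairwise-distinct centroids, and positive stratum
#' populations.
#'
#' @param region a `study_region` data frame.
#' @return `region`, invisibly, if valid; otherwise an error.
#' @export
validate_region <- function(region) {
  cols <- c("district_id", "x", "y", paste0("N_", 1:8))
  miss <- setdiff(cols, names(region))
  if (length(miss))
    stop("region is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- region$district_id
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicated district_id ", dup, call. = FALSE)
  }
  if (!identical(as.integer(sort(ids)), seq_along(ids) - 1L))
    stop("district_id must be contiguous integers starting at 0",
         call. = FALSE)
  if (anyDuplicated(region[, c("x", "y")]))
    stop("centroids must be pairwise distinct", call. = FALSE)
  N <- as.matrix(region[, paste0("N_", 1:8)])
  if (any(N < 1))
    stop("every stratum population N_kj must be >= 1", call. = FALSE)
  invisible(region)
}

#' Stratum population matrix of a region
#'
#' @param region a `study_region`.
#' @return integer matrix, one row per district, columns `N_1` ... `N_8`.
#' @export
stratum_populations <- function(region) {
  m <- as.matrix(region[, paste0("N_", 1:8)])
  storage.mode(m) <- "integer"
  rownames(m) <- region$district_id
  m
}

#' @export
print.study_region <- function(x, ...) {
  N <- rowSums(stratum_populations(x))
  cat("Study region:", nrow(x), "districts\n")
  cat("  district totals: median", format(stats::median(N), big.mark = ","),
      " range", format(min(N), big.mark = ","), "-",
      format(max(N), big.mark = ","), "\n")
  invisible(x)
}

#' Plot a study region
#'
#' Simple centroid scatter; optionally highlights district sets (true or
#' detected clusters).
#'
#' @param x a `study_region`.
#' @param clusters optional list of district-id vectors to highlight.
#' @param ... passed to [plot()].
#' @export
plot.study_region <- function(x, clusters = NULL, ...) {
  plot(x$x, x$y, pch = 16, col = "grey60", asp = 1,
       xlab = "x", ylab = "y", ...)
  if (length(clusters)) {
    cols <- hcl.colors(max(2L, length(clusters)), "Dark 3")
    for (i in seq_along(clusters)) {
      m <- match(clusters[[i]], x$district_id)
      points(x$x[m], x$y[m], pch = 16, col = cols[i], cex = 1.3)
    }
    legend("topleft", legend = paste("cluster", seq_along(clusters)),
           col = cols[seq_along(clusters)], pch = 16, bty = "n")
  }
  invisible(x)
}

#' Define compact true clusters on a region
#'
#' Places the true clusters used by the simulation study: model `"A"` has
#' a single compact cluster (default 18 districts) anchored in the
#' upper-right quadrant of the map; model `"B"` adds a second, disjoint
#' compact cluster (default 12 districts) anchored near the map centre.
#' Each cluster is the anchor district together with its `size - 1`
#' nearest districts by Euclidean centroid distance (ties broken by
#' ascending district id). If the central cluster overlaps the first one,
#' its anchor is redrawn.
#'
#' @param region a `study_region`.
#' @param model `"A"` (one cluster) or `"B"` (two clusters).
#' @param sizes cluster sizes; defaults `c(18)` for A and `c(18, 12)`
#'   for B.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param prevalence_inside,prevalence_outside outcome prevalence for
#'   districts inside / outside the true clusters.
#' @return A `true_cluster_model` (see [true_cluster_model()]).
#' @examples
#' region <- generate_region(100, seed = 1)
#' truth <- define_true_clusters(region, "B", seed = 1)
#' lengths(truth$clusters)
#' @export
define_true_clusters <- function(region, model = c("A", "B"), sizes = NULL,
                                 seed = NULL,
                                 prevalence_inside = 0.3,
                                 prevalence_outside = 0.2) {
  model <- match.arg(model)
  validate_region(region)
  if (is.null(sizes)) sizes <- if (model == "A") 18L else c(18L, 12L)
  if (any(sizes < 1) || sum(sizes) >= nrow(region))
    stop("cluster sizes must be positive and sum to fewer districts ",
         "than the region has", call. = FALSE)
  if (model == "A" && length(sizes) != 1L)
    stop("model \"A\" takes a single cluster size", call. = FALSE)
  if (model == "B" && length(sizes) != 2L)
    stop("model \"B\" takes two cluster sizes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  xmid <- mean(range(region$x)); ymid <- mean(range(region$y))
  xr <- diff(range(region$x));   yr <- diff(range(region$y))

  # anchor 1: upper-right quadrant
  in_quadrant <- region$district_id[region$x > xmid & region$y > ymid]
  if (!length(in_quadrant))
    stop("no districts in the upper-right quadrant", call. = FALSE)
  anchor1 <- sample_one(in_quadrant)
  cl1 <- nearest_districts(region, anchor1, sizes[1])
  clusters <- list(cl1)

  if (model == "B") {
    central <- region$district_id[abs(region$x - xmid) <= xr / 4 &
                                  abs(region$y - ymid) <= yr / 4]
    central <- setdiff(central, cl1)
    # fall back to anchors outside the central box (by increasing
    # distance from the map centre) if no central anchor works
    d_mid <- sqrt((region$x - xmid)^2 + (region$y - ymid)^2)
    fallback <- setdiff(region$district_id[order(d_mid,
                                                 region$district_id)],
                        c(cl1, central))
    cl2 <- NULL
    repeat {
      if (!length(central) && !length(fallback))
        stop("cannot place a central cluster disjoint from the first",
             call. = FALSE)
      if (length(central)) {
        anchor2 <- sample_one(central)
        central <- setdiff(central, anchor2)
      } else {
        anchor2 <- fallback[1]
        fallback <- fallback[-1]
      }
      cl2 <- nearest_districts(region, anchor2, sizes[2])
      if (!length(intersect(cl1, cl2))) break
    }
    clusters <- c(clusters, list(cl2))
  }
  true_cluster_model(clusters, prevalence_inside, prevalence_outside)
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# The `k` districts nearest to `anchor` (inclusive), Euclidean distance,
# ties broken by ascending district id.
nearest_districts <- function(region, anchor, k) {
  a <- match(anchor, region$district_id)
  d <- sqrt((region$x - region$x[a])^2 + (region$y - region$y[a])^2)
  region$district_id[order(d, region$district_id)][seq_len(k)]
}

#' Construct a true-cluster model
#'
#' @param clusters list of disjoint, non-empty district-id vectors (the
#'   list itself may be empty, encoding a global null with no elevated
#'   districts).
#' @param prevalence_inside,prevalence_outside prevalences inside and
#'   outside the true clusters; must satisfy
#'   `0 < prevalence_outside < prevalence_inside < 1` unless no cluster
#'   is given.
#' @return An object of class `true_cluster_model`.
#' @export
true_cluster_model <- function(clusters, prevalence_inside = 0.3,
                               prevalence_outside = 0.2) {
  stopifnot(is.list(clusters))
  if (length(clusters)) {
    if (any(lengths(clusters) == 0))
      stop("cluster sets must be non-empty", call. = FALSE)
    all_ids <- unlist(clusters)
    if (anyDuplicated(all_ids))
      stop("true clusters must be mutually disjoint", call. = FALSE)
    if (!(prevalence_outside < prevalence_inside))
      stop("prevalence_inside must exceed prevalence_outside", call. = FALSE)
  }
  if (prevalence_outside < 0 || prevalence_inside > 1)
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  structure(list(clusters = lapply(clusters, as.integer),
                 prevalence_inside = prevalence_inside,
                 prevalence_outside = prevalence_outside),
            class = "true_cluster_model")
}

#' @export
print.true_cluster_model <- function(x, ...) {
  cat("True cluster model:", length(x$clusters), "cluster(s)",
      if (length(x$clusters))
        paste0("of size ", paste(lengths(x$clusters), collapse = ", ")),
      "\n")
  cat("  prevalence inside", x$prevalence_inside,
      "/ outside", x$prevalence_outside, "\n")
  invisible(x)
}

#' Read / write a study region as CSV
#'
#' The CSV layout is `district_id,x,y,N_1,...,N_8` with a header row;
#' populations must be non-negative integers and ids unique. A
#' write-then-read round trip reproduces the region exactly.
#'
#' @param path file path.
#' @return `read_region_csv()` returns a `study_region`;
#'   `write_region_csv()` returns `path` invisibly.
#' @export
read_region_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  cols <- c("district_id", "x", "y", paste0("N_", 1:8))
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("region CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, cols]
  N <- as.matrix(df[, paste0("N_", 1:8)])
  bad <- which(!is.finite(N) | N != round(N), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer population in row ", bad[1, 1], call. = FALSE)
  for (j in paste0("N_", 1:8)) df[[j]] <- as.integer(df[[j]])
  df$district_id <- as.integer(df$district_id)
  class(df) <- c("study_region", "data.frame")
  validate_region(df)
  df
}

#' @rdname read_region_csv
#' @param region a `study_region`.
#' @export
write_region_csv <- function(region, path) {
  validate_region(region)
  write.csv(as.data.frame(region), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write true-cluster files
#'
#' One line per cluster, comma-separated district ids.
#'
#' @param path file path.
#' @param truth a `true_cluster_model` (for writing).
#' @param ... prevalences passed on to [true_cluster_model()] when
#'   reading.
#' @return `read_true_clusters()` returns a `true_cluster_model`.
#' @export
read_true_clusters <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  clusters <- lapply(strsplit(lines, ","), function(v) as.integer(trimws(v)))
  true_cluster_model(clusters, ...)
}

#' @rdname read_true_clusters
#' @export
write_true_clusters <- function(truth, path) {
  writeLines(vapply(truth$clusters, paste, "", collapse = ","), path)
  invisible(path)
}
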