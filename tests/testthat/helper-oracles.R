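# Independent oracles used across the test files. They deliberately
# avoid the package's closed-form LLR implementations: Bernoulli LLRs
# are built from binomial log-densities, weighted normal LLRs from
# numerically maximised normal likelihoods.

# Bernoulli window LLR via dbinom at the MLE rates (binomial
# coefficients cancel between alternative and null).
oracle_bern_llr <- function(c_in, n_in, C, N) {
  c_out <- C - c_in
  n_out <- N - n_in
  if (n_out <= 0) return(0)
  p_in <- c_in / n_in
  p_out <- c_out / n_out
  if (p_in <= p_out) return(0)
  p0 <- C / N
  (dbinom(c_in, n_in, p_in, log = TRUE) +
     dbinom(c_out, n_out, p_out, log = TRUE)) -
    (dbinom(c_in, n_in, p0, log = TRUE) +
       dbinom(c_out, n_out, p0, log = TRUE))
}

# Weighted normal window LLR via numerical maximisation of the
# two-mean vs one-mean heteroscedastic normal likelihoods
# (y_i ~ N(mu, sigma^2 / w_i)).
oracle_wnorm_llr <- function(inz, y, w) {
  loglik <- function(mu_in, mu_out, s2) {
    mu <- ifelse(inz, mu_in, mu_out)
    sum(dnorm(y, mu, sqrt(s2 / w), log = TRUE))
  }
  mu0 <- sum(w * y) / sum(w)
  nll1 <- function(par) -loglik(par[1], par[2], exp(par[3]))
  nll0 <- function(par) -loglik(par[1], par[1], exp(par[2]))
  s2_start <- max(sum(w * (y - mu0)^2) / length(y), 1e-8)
  o1 <- optim(c(mean(y[inz]), mean(y[!inz]), log(s2_start)), nll1,
              method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  o0 <- optim(c(mu0, log(s2_start)), nll0, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  if (o1$par[1] <= o1$par[2]) return(0)
  max(0, o0$value - o1$value)
}

# Exhaustive circular-window scan by direct enumeration: every centre,
# every distance-ordered prefix within the size cap.
oracle_scan_max <- function(region, model, cases = NULL, totals = NULL,
                            y = NULL, w = NULL, msws = 0.5) {
  n <- nrow(region)
  best <- 0
  best_set <- integer()
  for (cc in seq_len(n)) {
    d <- sqrt((region$x - region$x[cc])^2 + (region$y - region$y[cc])^2)
    ordr <- order(d, region$district_id)
    for (m in seq_len(n)) {
      idx <- ordr[seq_len(m)]
      if (model == "bernoulli") {
        if (m > 1 && sum(totals[idx]) > msws * sum(totals)) break
        ll <- oracle_bern_llr(sum(cases[idx]), sum(totals[idx]),
                              sum(cases), sum(totals))
      } else {
        if (m > msws * n || m >= n) break
        inz <- logical(n)
        inz[idx] <- TRUE
        ll <- oracle_wnorm_llr(inz, y, w)
      }
      if (ll > best + 1e-9) {
        best <- ll
        best_set <- sort(region$district_id[idx])
      }
    }
  }
  list(max = best, members = best_set)
}

# Small fixed-population helper: one region + truth + population.
make_world <- function(n_districts, cluster_sizes, seed,
                       model = if (length(cluster_sizes) > 1) "B" else "A") {
  region <- generate_region(n_districts, seed = seed)
  truth <- define_true_clusters(region, model, sizes = cluster_sizes,
                                seed = seed)
  pop <- generate_population(region, truth, seed = seed + 1)
  list(region = region, truth = truth, pop = pop)
}
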