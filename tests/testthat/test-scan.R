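test_that("bernoulli_llr matches its closed form and boundary rules", {
  # hand-computed: 16 log 0.8 + 4 log 0.2 - 20 log 0.5
  expect_equal(bernoulli_llr(8, 10, 10, 20),
               16 * log(0.8) + 4 * log(0.2) - 20 * log(0.5),
               tolerance = 1e-12)
  expect_equal(round(bernoulli_llr(8, 10, 10, 20), 4), 3.8549)
  # inside rate equals / is below the outside rate: statistic is 0
  expect_equal(bernoulli_llr(5, 10, 10, 20), 0)
  expect_equal(bernoulli_llr(2, 10, 10, 20), 0)
  # 0 log 0 convention at the extremes
  expect_equal(bernoulli_llr(10, 10, 10, 20),
               -20 * log(0.5), tolerance = 1e-12)
  expect_error(bernoulli_llr(11, 10, 10, 20), "invalid")
  expect_error(bernoulli_llr(3, 10, 2, 20), "invalid")
})

test_that("bernoulli_llr agrees with the binomial-likelihood oracle", {
  set.seed(50)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    n <- sample(2:(N - 1), 1)
    C <- sample(1:(N - 1), 1)
    c_in <- sample(0:min(n, C), 1)
    if (C - c_in > N - n) next
    expect_equal(bernoulli_llr(c_in, n, C, N),
                 oracle_bern_llr(c_in, n, C, N), tolerance = 1e-8)
  }
})

test_that("bernoulli_llr is monotone in window cases under the indicator", {
  n <- 40; N <- 400; C <- 60
  llr <- bernoulli_llr(0:min(n, C), n, C, N)
  active <- (0:min(n, C)) / n > (C - 0:min(n, C)) / (N - n)
  expect_true(all(diff(llr[active]) > 0))
})

test_that("weighted_normal_llr matches a numerical likelihood oracle", {
  # perfectly separated rates: the alternative likelihood is unbounded
  # and the variance floor binds, LLR = (n/2) log(sigma0^2 / 1e-12)
  y <- c(0.9, 0.1, 0.1, 0.1)
  expect_equal(weighted_normal_llr(1, y, rep(1, 4)),
               2 * log(0.12 / 1e-12), tolerance = 1e-9)
  # non-degenerate window: closed form equals numerical maximisation
  y2 <- c(0.9, 0.14, 0.1, 0.06)
  w2 <- c(1, 2, 1, 2)
  expect_equal(weighted_normal_llr(1, y2, w2),
               oracle_wnorm_llr(c(TRUE, FALSE, FALSE, FALSE), y2, w2),
               tolerance = 1e-4)
  set.seed(51)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    y <- runif(n)
    w <- runif(n, 0.5, 4)
    Z <- sample(n, sample(n - 1, 1))
    inz <- seq_len(n) %in% Z
    expect_equal(weighted_normal_llr(Z, y, w),
                 oracle_wnorm_llr(inz, y, w), tolerance = 1e-3)
  }
})

test_that("weighted_normal_llr honours scale invariance and edge rules", {
  set.seed(52)
  y <- runif(8); w <- runif(8, 1, 5); Z <- c(2, 5)
  expect_equal(weighted_normal_llr(Z, y, 10 * w),
               weighted_normal_llr(Z, y, w), tolerance = 1e-9)
  expect_equal(weighted_normal_llr(Z, rep(0.4, 8), w), 0)  # constant data
  # high-rate scan only
  ylow <- c(0.1, 0.9, 0.9, 0.9)
  expect_equal(weighted_normal_llr(1, ylow, rep(1, 4)), 0)
  expect_error(weighted_normal_llr(integer(), y, w), "invalid window")
  expect_error(weighted_normal_llr(1:8, y, w), "invalid window")
  expect_error(weighted_normal_llr(1, y, -w), "positive")
})

test_that("windows are nested distance-ordered prefixes under the cap", {
  region <- generate_region(3, seed = 53)
  ws <- build_windows(region, rep(10, 3), msws = 1)
  expect_equal(sum(ws$wlen), 9)  # 3 centres x 3 prefixes
  members <- unique(lapply(seq_len(3), function(cc)
    lapply(seq_len(3), function(m) sort(window_members(ws, cc - 1, m)))))
  expect_lte(length(unique(unlist(members, recursive = FALSE))), 7)

  # msws so small only singletons fit (all sizes equal)
  region2 <- generate_region(20, seed = 54)
  ws2 <- build_windows(region2, rep(1, 20), msws = 0.05)
  expect_equal(sum(ws2$wlen), 20)

  # every window holds the size nearest districts to its centre
  region3 <- generate_region(30, seed = 55)
  ws3 <- build_windows(region3, rep(1, 30), msws = 0.5)
  for (cc in c(1, 17)) {
    d <- sqrt((region3$x - region3$x[cc])^2 +
                (region3$y - region3$y[cc])^2)
    expect_equal(window_members(ws3, cc - 1, 7),
                 region3$district_id[order(d, region3$district_id)][1:7])
  }
  expect_error(build_windows(region3, rep(0, 30)), "positive")
})

test_that("engine max LLR equals exhaustive brute force on small maps", {
  set.seed(56)
  for (i in 1:50) {
    n <- sample(4:6, 1)
    region <- generate_region(n, seed = 5600 + i)
    totals <- sample(50:150, n, replace = TRUE)
    cases <- rbinom(n, totals, runif(1, 0.1, 0.5))
    if (sum(cases) == 0 || sum(cases) == sum(totals)) next
    x <- data.frame(district_id = region$district_id,
                    cases = cases, total = totals)
    fit <- scan_cluster(x, region, model = "bernoulli", msws = 0.5,
                        replicates = 19, seed = i)
    oracle <- oracle_scan_max(region, "bernoulli", cases = cases,
                              totals = totals, msws = 0.5)
    expect_equal(fit$max_llr, oracle$max, tolerance = 1e-9)
    if (oracle$max > 1e-9)
      expect_setequal(fit$clusters$members[[1]], oracle$members)
  }
})

test_that("weighted normal engine equals brute force on small maps", {
  set.seed(57)
  for (i in 1:50) {
    n <- sample(4:6, 1)
    region <- generate_region(n, seed = 5700 + i)
    y <- runif(n, 0.1, 0.5)
    w <- runif(n, 500, 5000)
    x <- data.frame(district_id = region$district_id, rate = y,
                    weight = w)
    fit <- scan_cluster(x, region, model = "weighted_normal", msws = 0.5,
                        replicates = 19, seed = i)
    oracle <- oracle_scan_max(region, "weighted_normal", y = y, w = w,
                              msws = 0.5)
    expect_equal(fit$max_llr, oracle$max, tolerance = 1e-3)
    if (oracle$max > 1e-3)
      expect_setequal(fit$clusters$members[[1]], oracle$members)
  }
})

test_that("compiled replicate scan agrees with the observed-data path", {
  # feed the same dataset through the C++ replicate path by treating it
  # as a one-column replicate matrix
  set.seed(58)
  region <- generate_region(40, seed = 58)
  totals <- sample(880:940, 40, replace = TRUE)
  cases <- rbinom(40, totals, 0.22)
  x <- data.frame(district_id = region$district_id, cases = cases,
                  total = totals)
  fit <- scan_cluster(x, region, model = "bernoulli", replicates = 19,
                      seed = 1)
  ws <- build_windows(region, totals, msws = 0.5)
  cmax <- svyscan:::scan_max_bernoulli(ws$ord, ws$wlen, as.numeric(totals),
                                       matrix(as.numeric(cases)),
                                       sum(cases), sum(totals))
  expect_equal(fit$max_llr, cmax[1], tolerance = 1e-9)

  y <- runif(40, 0.15, 0.3); w <- runif(40, 1000, 4000)
  xa <- data.frame(district_id = region$district_id, rate = y, weight = w)
  fita <- scan_cluster(xa, region, model = "weighted_normal",
                       replicates = 19, seed = 1)
  wsa <- build_windows(region, rep(1, 40), msws = 0.5)
  amax <- svyscan:::scan_max_wnormal(wsa$ord, pmin(wsa$wlen, 39L),
                                     matrix(y), matrix(w))
  expect_equal(fita$max_llr, amax[1], tolerance = 1e-9)
})

test_that("Monte Carlo p-values follow the rank formula", {
  w <- make_world(30, 5, seed = 59)
  smp <- draw_survey_sample(w$region, w$pop, 1, seed = 60)
  fit <- scan_cluster(make_scan_input(smp, "frequency"), w$region,
                      replicates = 99, seed = 61)
  p <- fit$clusters$p_value
  expect_true(all(abs(p * 100 - round(p * 100)) < 1e-9))
  expect_true(all(p >= 1 / 100 & p <= 1))
  # strong observed signal beats every replicate: p at the floor
  expect_equal(fit$clusters$p_value[1], 1 / 100)
  expect_error(scan_cluster(make_scan_input(smp, "frequency"), w$region,
                            replicates = 10), "replicates")
})

test_that("permutation null is exchangeable under district relabelling", {
  region <- generate_region(30, seed = 62)
  set.seed(63)
  y <- runif(30, 0.15, 0.35)
  w <- runif(30, 800, 4000)
  x1 <- data.frame(district_id = region$district_id, rate = y, weight = w)
  perm <- sample(30)
  x2 <- data.frame(district_id = region$district_id, rate = y[perm],
                   weight = w[perm])
  f1 <- scan_cluster(x1, region, replicates = 500, seed = 64)
  f2 <- scan_cluster(x2, region, replicates = 500, seed = 65)
  ks <- suppressWarnings(ks.test(f1$replicate_maxima,
                                 f2$replicate_maxima))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster reporting keeps non-overlapping windows in LLR order", {
  cand <- data.frame(center_id = c(1L, 2L, 9L), llr = c(10, 8, 6),
                     p_value = c(0.001, 0.002, 0.004))
  cand$members <- list(c(1L, 2L, 3L), c(3L, 4L), c(8L, 9L))
  rep1 <- report_clusters(cand, alpha = 0.05)
  expect_equal(rep1$llr, c(10, 6))  # overlapping LLR-8 window dropped
  expect_true(all(rep1$significant))
  cand$members <- list(c(1L, 2L, 3L), c(4L, 5L), c(8L, 9L))
  rep2 <- report_clusters(cand, alpha = 0.05)
  expect_equal(rep2$llr, c(10, 8, 6))
  expect_equal(rep2$rank, 1:3)
  # significance flag respects alpha
  cand$p_value <- c(0.001, 0.2, 0.004)
  expect_equal(report_clusters(cand, 0.05)$significant,
               c(TRUE, FALSE, TRUE))
})

test_that("the MRCS filter can displace the most likely cluster", {
  w <- make_world(40, 8, seed = 66)
  smp <- draw_survey_sample(w$region, w$pop, 1, seed = 67)
  x <- make_scan_input(smp, "frequency")
  full <- scan_cluster(x, w$region, msws = 0.5, mrcs = 0.5,
                       replicates = 99, seed = 68)
  small <- scan_cluster(x, w$region, msws = 0.5, mrcs = 0.05,
                        replicates = 99, seed = 68)
  cap <- 0.05 * sum(x$total)
  expect_true(all(vapply(small$clusters$members, function(m)
    sum(x$total[match(m, x$district_id)]), 0) <= cap))
  expect_lte(small$clusters$llr[1], full$clusters$llr[1])
  expect_error(scan_cluster(x, w$region, msws = 0.3, mrcs = 0.5),
               "mrcs")
})

test_that("Gini coefficient and MRCS selection behave as specified", {
  # two-segment Lorenz curve: e = 0.2, o = 0.5 gives 2(0.65 - 1/2)
  expect_equal(gini_coefficient(0.5, 0.2), 0.3, tolerance = 1e-12)
  expect_equal(gini_coefficient(numeric(), numeric()), 0)

  w <- make_world(60, 8, seed = 69)
  smp <- draw_survey_sample(w$region, w$pop, 1, seed = 70)
  x <- make_scan_input(smp, "frequency")
  fit <- scan_cluster(x, w$region, mrcs = "gini", replicates = 99,
                      seed = 71)
  expect_equal(fit$mrcs_mode, "gini")
  expect_lte(fit$mrcs, 0.5)
  # singleton candidate set returns that candidate
  fit1 <- scan_cluster(x, w$region, mrcs = "gini", replicates = 99,
                       seed = 71, gini_candidates = 0.5)
  expect_equal(fit1$mrcs, 0.5)
  # no significant cluster anywhere: falls back to msws
  null_truth <- true_cluster_model(list())
  pop0 <- generate_population(w$region, null_truth, seed = 72)
  smp0 <- draw_survey_sample(w$region, pop0, 1, seed = 73)
  fit0 <- scan_cluster(make_scan_input(smp0, "frequency"), w$region,
                       mrcs = "gini", replicates = 99, seed = 74)
  if (!any(fit0$clusters$significant)) expect_equal(fit0$mrcs, 0.5)
  expect_error(scan_cluster(x, w$region, mrcs = "gini", replicates = 99,
                            gini_candidates = numeric()), "candidate")
})

test_that("scan results print, summarise, and export reports", {
  w <- make_world(30, 5, seed = 75)
  smp <- draw_survey_sample(w$region, w$pop, 1, seed = 76)
  fit <- scan_cluster(make_scan_input(smp, "aggregate"), w$region,
                      replicates = 99, seed = 77)
  expect_output(print(fit), "weighted_normal")
  s <- summary(fit)
  expect_output(print(s), "significant")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_report(fit, path)
  back <- read_cluster_report(path)
  expect_equal(back$llr, fit$clusters$llr, tolerance = 1e-6)
  expect_identical(back$members, fit$clusters$members)
})
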