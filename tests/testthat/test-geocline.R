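test_that("the cline core is a tanh sigmoid in centre/width form", {
  par <- list(centre = 1000, width = 200, pmin = 0, pmax = 1)
  expect_equal(cline_value(1000, par), 0.5)
  expect_equal(cline_value(1100, par), (1 + tanh(1)) / 2)
  expect_equal(cline_value(1100, par), 0.880797, tolerance = 1e-6)
  # scaling
  par2 <- list(centre = 0, width = 100, pmin = 8, pmax = 12)
  expect_equal(cline_value(0, par2), 10)
  # decreasing cline (southern asymptote above the northern one)
  par3 <- list(centre = 0, width = 100, pmin = 12, pmax = 8)
  expect_equal(cline_value(-1e6, par3), 12)
  expect_equal(cline_value(1e6, par3), 8)
  expect_error(cline_value(0, list(centre = 0, width = -1)), "width")
})

test_that("exponential tails are continuous at the junction and stay in range", {
  par <- list(centre = 1000, width = 200, pmin = 0, pmax = 1,
              deltaL = 150, tauL = 0.5, deltaR = 100, tauR = 0.8)
  eps <- 1e-9
  expect_equal(cline_value(850 - eps, par), cline_value(850 + eps, par),
               tolerance = 1e-6)
  expect_equal(cline_value(1100 - eps, par), cline_value(1100 + eps, par),
               tolerance = 1e-6)
  x <- seq(-2000, 4000, by = 10)
  v <- cline_value(x, par)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v) >= -1e-12))  # monotone non-decreasing
  # far tails decay to the asymptotes
  expect_lt(cline_value(-5000, par), 1e-6)
  expect_gt(cline_value(7000, par), 1 - 1e-6)
})

test_that("cline_value is monotone for random models in every tail mode", {
  set.seed(5)
  x <- seq(-500, 2500, by = 25)
  for (rep in 1:40) {
    par <- list(centre = runif(1, 0, 2000), width = runif(1, 20, 800),
                pmin = 0, pmax = 1,
                deltaL = runif(1, 0, 500), tauL = runif(1),
                deltaR = runif(1, 0, 500), tauR = runif(1))
    mode <- sample(c("none", "left", "right", "both"), 1)
    if (mode %in% c("none", "right")) par$deltaL <- Inf
    if (mode %in% c("none", "left")) par$deltaR <- Inf
    v <- cline_value(x, par)
    expect_true(all(diff(v) >= -1e-10))
  }
})

test_that("binomial and Gaussian likelihoods match closed forms", {
  par <- list(centre = 0, width = 100, pmin = 0, pmax = 1)
  d <- data.frame(distance_km = 0, count = 1, total = 2)
  expect_equal(loglik_freq(par, d), log(2) + 2 * log(0.5), tolerance = 1e-12)
  expect_equal(loglik_freq(par, d), log(0.5), tolerance = 1e-12)

  # epsilon clipping keeps the likelihood finite at impossible frequencies
  far <- data.frame(distance_km = -1e5, count = 5, total = 10)
  ll <- loglik_freq(par, far)
  expect_true(is.finite(ll))
  expect_lt(ll, -50)

  # population means exactly on the cline leave only normalising constants
  x <- c(0, 50, 100)
  td <- data.frame(distance_km = x,
                   mean = cline_value(x, list(centre = 50, width = 80,
                                              pmin = 3, pmax = 7)),
                   sd = 2, n = 4)
  par_t <- list(centre = 50, width = 80, pmin = 3, pmax = 7)
  expect_equal(loglik_trait(par_t, td),
               sum(dnorm(0, 0, td$sd / sqrt(td$n), log = TRUE)))
  # one standard error off costs exactly 0.5 log-likelihood units
  td2 <- td[1, ]; td2$mean <- td2$mean + td2$sd / sqrt(td2$n)
  expect_equal(loglik_trait(par_t, td2),
               dnorm(0, 0, 1, log = TRUE) - log(td2$sd / sqrt(td2$n)) - 0.5,
               tolerance = 1e-10)
  expect_error(loglik_trait(par_t, transform(td, sd = 0)), "sd")
})

test_that("likelihoods agree with direct pmf/pdf sums on random data", {
  set.seed(14)
  for (rep in 1:10) {
    par <- list(centre = runif(1, 200, 800), width = runif(1, 50, 400),
                pmin = 0, pmax = 1)
    x <- sort(runif(8, 0, 1000))
    n <- sample(5:30, 8, replace = TRUE)
    k <- rbinom(8, n, 0.5)
    d <- data.frame(distance_km = x, count = k, total = n)
    p <- pmin(pmax(cline_value(x, par), 1e-9), 1 - 1e-9)
    direct <- sum(lchoose(n, k) + k * log(p) + (n - k) * log(1 - p))
    expect_equal(loglik_freq(par, d), direct, tolerance = 1e-10)
  }
})

test_that("AICc matches its closed form and penalises parameters", {
  expect_equal(aicc(-10, 2, 10), 20 + 4 + 12 / 7)
  expect_equal(aicc(-10, 2, 10), 25.714, tolerance = 1e-3)
  expect_equal(aicc(-3, 0, 10), 6)
  expect_lt(aicc(-10, 2, 30), aicc(-10, 3, 30))
  expect_warning(out <- aicc(-10, 9, 10), "undefined")
  expect_true(is.na(out))
})

test_that("2-LLU intervals solve the quadratic profile and flag flat ones", {
  theta <- seq(0, 10, by = 0.01)
  prof <- data.frame(value = theta, lnl = -(theta - 5)^2 / 2)
  iv <- two_llu_interval(prof, 5)
  expect_equal(iv$lower, 3, tolerance = 1e-3)
  expect_equal(iv$upper, 7, tolerance = 1e-3)
  expect_true(iv$lower_bounded && iv$upper_bounded)

  flat <- data.frame(value = theta, lnl = rep(-1, length(theta)))
  ivf <- two_llu_interval(flat, 5)
  expect_false(ivf$lower_bounded)
  expect_false(ivf$upper_bounded)
  expect_equal(c(ivf$lower, ivf$upper), range(theta))

  # MLE at the profile edge: one-sided interval flagged
  half <- prof[prof$value >= 5, ]
  ivh <- two_llu_interval(half, 5)
  expect_false(ivh$lower_bounded)
  expect_true(ivh$upper_bounded)
  expect_error(two_llu_interval(half, 4), "cover")
})

test_that("model selection prefers parsimony on ties and detects no-cline data", {
  x <- seq(0, 1000, length.out = 12)
  set.seed(3)
  d <- data.frame(distance_km = x, count = rbinom(12, 30, 0.4), total = 30)
  nul <- fit_null(d, "freq")
  expect_equal(nul$k, 1L)
  expect_equal(unname(nul$mle["p"]), sum(d$count) / sum(d$total))
  fake_fit <- structure(list(model = list(name = "none.fixed01"), type = "freq",
                             mle = c(centre = 1, width = 1), lnl = nul$lnl,
                             k = 2L, n_obs = 12L, aicc = aicc(nul$lnl, 2, 12)),
                        class = "cline_fit")
  sel <- select_model(list(fake_fit), nul)
  expect_true(sel$is_null)  # equal lnL, fewer parameters wins
  expect_error(select_model(list()), "no fitted")
})

test_that("MCMC fitting is seed-reproducible and recovers a planted cline", {
  x <- seq(0, 2000, length.out = 25)
  set.seed(8)
  p <- cline_value(x, list(centre = 900, width = 300, pmin = 0, pmax = 1))
  d <- data.frame(distance_km = x, count = rbinom(25, 30, p), total = 30)
  f1 <- fit_cline_mcmc(d, "freq", cline_model("none", "fixed01"),
                       chain_len = 3000, burnin = 600, n_chains = 2, seed = 9,
                       profile_params = "centre")
  f2 <- fit_cline_mcmc(d, "freq", cline_model("none", "fixed01"),
                       chain_len = 3000, burnin = 600, n_chains = 2, seed = 9,
                       profile_params = "centre")
  expect_identical(f1$mle, f2$mle)
  expect_identical(f1$intervals, f2$intervals)
  # identical seeds for both chains give identical best states
  f3 <- fit_cline_mcmc(d, "freq", cline_model("none", "fixed01"),
                       chain_len = 1000, burnin = 200, n_chains = 2,
                       seeds = c(4, 4), profile_params = "centre")
  expect_equal(f3$chain_best[1, ], f3$chain_best[2, ])
  # the 2-LLU interval contains the MLE and the truth here
  iv <- f1$intervals$centre
  expect_lte(iv$lower, f1$mle[["centre"]])
  expect_gte(iv$upper, f1$mle[["centre"]])
  expect_lt(abs(f1$mle[["centre"]] - 900), 150)
})

test_that("larger per-population samples tighten the centre interval", {
  x <- seq(0, 2000, length.out = 25)
  widths <- vapply(c(10, 100, 1000), function(n) {
    set.seed(33)
    p <- cline_value(x, list(centre = 1000, width = 250, pmin = 0, pmax = 1))
    d <- data.frame(distance_km = x, count = rbinom(25, n, p), total = n)
    f <- fit_cline_mcmc(d, "freq", cline_model("none", "fixed01"),
                        chain_len = 3000, burnin = 600, n_chains = 2,
                        seed = 5, profile_params = "centre")
    f$intervals$centre$upper - f$intervals$centre$lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("centre shift and width difference summarise fitted clines", {
  expect_equal(cline_centre_shift(1523, c(1054, 1100)), 446)
  expect_equal(cline_width_difference(898, 845), 53)
  expect_equal(cline_centre_shift(100, 100), 0)
})
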