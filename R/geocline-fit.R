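## Metropolis-Hastings fitting of the cline model family, AICc model
## selection against a no-cline null, and profile-based 2-LLU intervals.

# Parameter bounds for one model on one dataset. L = transect length.
# Centres beyond the transect are allowed (up to 1.25 L): fits whose centre
# MLE exceeds the transect length are what downstream classification
# excludes as off-transect.
param_bounds <- function(model, type, L, resp_range) {
  b <- list(centre = c(-0.25 * L, 1.25 * L),
            width = c(1e-3 * L, 3 * L))
  if (model$scaling_mode == "estimated") {
    if (type == "freq") {
      b$pmin <- c(0, 1); b$pmax <- c(0, 1)
    } else {
      span <- diff(resp_range)
      if (span <= 0) span <- max(abs(resp_range[1]), 1)
      b$pmin <- resp_range + c(-span, span)
      b$pmax <- resp_range + c(-span, span)
    }
  }
  tails <- intersect(c("delta", "deltaL", "deltaR"), free_params(model))
  for (d in tails) b[[d]] <- c(0, L)
  for (tpar in intersect(c("tau", "tauL", "tauR"), free_params(model))) {
    b[[tpar]] <- c(0, 1)
  }
  b[free_params(model)]
}

# Fixed floor/ceiling for a model on one dataset
fixed_scaling <- function(model, type, resp_range) {
  switch(model$scaling_mode,
    fixed01 = c(pmin = 0, pmax = 1),
    observed = c(pmin = resp_range[1], pmax = resp_range[2]),
    fixed = c(pmin = model$pmin, pmax = model$pmax),
    estimated = c(pmin = NA_real_, pmax = NA_real_))
}

# Crude data-driven starting values
init_params <- function(model, type, data, L, resp_range) {
  x <- data$distance_km
  resp <- if (type == "freq") data$count / pmax(data$total, 1) else data$mean
  mid <- mean(resp_range)
  ord <- order(x)
  above <- resp[ord] > mid
  cross <- which(diff(above) != 0)
  c0 <- if (length(cross)) mean(x[ord][cross[1] + 0:1]) else stats::median(x)
  th <- c(centre = c0, width = L / 4)
  if (model$scaling_mode == "estimated") {
    # orient the asymptotes by the transect ends so decreasing responses
    # start near their own geometry (pmin = southern, pmax = northern)
    qx <- quantile(x, c(0.25, 0.75), names = FALSE)
    th <- c(th, pmin = mean(resp[x <= qx[1]]), pmax = mean(resp[x >= qx[2]]))
  }
  fp <- free_params(model)
  for (d in intersect(c("delta", "deltaL", "deltaR"), fp)) th[d] <- L / 10
  for (tpar in intersect(c("tau", "tauL", "tauR"), fp)) th[tpar] <- 0.5
  th[fp]
}

# Log-likelihood closure for one model/data pair; -Inf outside constraints
make_loglik <- function(model, type, data, fixed) {
  if (type == "freq") {
    keep <- data$total > 0
    x <- data$distance_km[keep]; k <- data$count[keep]; n <- data$total[keep]
    function(theta) {
      par <- expand_params(as.list(theta), model, fixed)
      p <- clamp(cline_value(x, par), 1e-9, 1 - 1e-9)
      sum(dbinom(k, n, p, log = TRUE))
    }
  } else {
    x <- data$distance_km; m <- data$mean; se <- data$sd / sqrt(data$n)
    function(theta) {
      par <- expand_params(as.list(theta), model, fixed)
      sum(dnorm(m, cline_value(x, par), se, log = TRUE))
    }
  }
}

# One adaptive Metropolis-Hastings chain. Proposal: joint Gaussian
# random walk, per-parameter scales multiplicatively tuned during burn-in
# to a 20-40% acceptance window, frozen afterwards.
run_chain <- function(loglik, theta0, bounds, chain_len, burnin, seed,
                      keep_max = 20000L) {
  set.seed(seed)
  k <- length(theta0)
  lo <- vapply(bounds, `[`, 0, 1L); hi <- vapply(bounds, `[`, 0, 2L)
  scales <- 0.1 * (hi - lo)
  theta <- theta0; lcur <- loglik(theta)
  if (!is.finite(lcur)) { theta <- (lo + hi) / 2; lcur <- loglik(theta) }
  best <- theta; lbest <- lcur
  total <- burnin + chain_len
  thin <- max(1L, ceiling(chain_len / keep_max))
  kept <- matrix(NA_real_, floor(chain_len / thin), k,
                 dimnames = list(NULL, names(theta0)))
  kept_lnl <- numeric(nrow(kept))
  acc_window <- 0L; n_kept <- 0L; n_acc <- 0L
  for (s in seq_len(total)) {
    prop <- theta + rnorm(k) * scales
    if (all(prop >= lo & prop <= hi)) {
      lprop <- loglik(prop)
      if (is.finite(lprop) && log(runif(1)) < (lprop - lcur)) {
        theta <- prop; lcur <- lprop
        acc_window <- acc_window + 1L; n_acc <- n_acc + 1L
        if (lcur > lbest) { best <- theta; lbest <- lcur }
      }
    }
    if (s <= burnin && s %% 50L == 0L) {
      rate <- acc_window / 50
      if (rate < 0.20) scales <- scales * 0.8
      else if (rate > 0.40) scales <- scales * 1.25
      acc_window <- 0L
    }
    if (s > burnin && (s - burnin) %% thin == 0L && n_kept < nrow(kept)) {
      n_kept <- n_kept + 1L
      kept[n_kept, ] <- theta
      kept_lnl[n_kept] <- lcur
    }
  }
  list(samples = kept[seq_len(n_kept), , drop = FALSE],
       lnl = kept_lnl[seq_len(n_kept)],
       best = best, best_lnl = lbest,
       acceptance = n_acc / total)
}

# Profile log-likelihood for one parameter on a grid, re-optimising the
# remaining free parameters (started from the MLE) at every grid point;
# the visited-state binned maximum is used as a floor so the profile can
# only improve on the raw chain profile.
profile_param <- function(pname, grid, mle, loglik, bounds, chain, chain_lnl) {
  fp <- names(mle)
  others <- setdiff(fp, pname)
  lnl <- vapply(grid, function(v) {
    if (!length(others)) return(loglik(setNames(v, pname)))
    fn <- function(th) {
      full <- setNames(numeric(length(fp)), fp)
      full[others] <- th; full[pname] <- v
      ll <- loglik(full)
      if (!is.finite(ll)) 1e10 else -ll
    }
    lo <- vapply(bounds[others], `[`, 0, 1L)
    hi <- vapply(bounds[others], `[`, 0, 2L)
    st <- clamp(mle[others], lo + 1e-9, hi - 1e-9)
    res <- tryCatch(
      optim(st, fn, method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) list(value = fn(st)))
    -res$value
  }, 0)
  # floor with binned chain maxima
  if (!is.null(chain) && nrow(chain) > 0) {
    idx <- findInterval(chain[, pname], grid, rightmost.closed = TRUE)
    for (b in unique(idx)) {
      if (b >= 1 && b <= length(grid)) {
        m <- max(chain_lnl[idx == b])
        gi <- b
        if (m > lnl[gi]) lnl[gi] <- m
      }
    }
  }
  data.frame(value = grid, lnl = lnl)
}

#' Fit one cline model by Metropolis-Hastings sampling
#'
#' Runs `n_chains` replicate adaptive Metropolis-Hastings chains with
#' different random seeds under flat priors on the bounded parameter space,
#' takes the highest-likelihood visited state, refines it by bounded local
#' optimisation, and computes profile-likelihood 2-LLU intervals for the
#' requested parameters. Convergence is flagged (not enforced) when the
#' across-chain spread of per-chain best parameter values is below 5 percent
#' of the pooled 2-LLU interval width.
#'
#' @param data for `type = "freq"`: data frame with `distance_km`, `count`,
#'   `total`; for `type = "trait"`: `distance_km`, `mean`, `sd`, `n`.
#' @param type `"freq"` (binomial likelihood) or `"trait"` (Gaussian).
#' @param model a [cline_model()].
#' @param chain_len,burnin post-burn-in and burn-in chain lengths.
#' @param n_chains number of replicate chains.
#' @param seed base seed; chain `i` uses `seed + i - 1` unless `seeds` given.
#' @param seeds optional explicit per-chain seeds.
#' @param transect_length transect length L (km); default the largest
#'   observed distance. Bounds: centre in `[-0.25 L, 1.25 L]`, width in
#'   `(0, 3 L]`, delta in `[0, L]`, tau in `[0, 1]`.
#' @param refine logical; refine MLE and profiles by local optimisation.
#' @param profile_params parameters to profile (default centre and width).
#' @param n_grid profile grid size.
#' @return object of class `cline_fit`: model, `mle` (named vector), `lnl`,
#'   `k`, `n_obs`, `aicc`, `intervals` (per profiled parameter), `profiles`,
#'   `converged`, `acceptance`, per-chain summaries.
#' @export
fit_cline_mcmc <- function(data, type = c("freq", "trait"), model = cline_model(),
                           chain_len = 1e5, burnin = 1e4, n_chains = 6,
                           seed = 1, seeds = NULL, transect_length = NULL,
                           refine = TRUE, profile_params = c("centre", "width"),
                           n_grid = 25) {
  type <- match.arg(type)
  if (type == "freq" && any(data$total == 0)) {
    warning("excluding populations with total == 0")
    data <- data[data$total > 0, , drop = FALSE]
  }
  if (nrow(data) < 4) abort("need >= 4 populations spanning the transect")
  L <- if (is.null(transect_length)) max(data$distance_km) else transect_length
  resp <- if (type == "freq") data$count / data$total else data$mean
  resp_range <- range(resp)
  fixed <- fixed_scaling(model, type, resp_range)
  bounds <- param_bounds(model, type, L, resp_range)
  loglik <- make_loglik(model, type, data, fixed)
  theta0 <- init_params(model, type, data, L, resp_range)
  if (is.null(seeds)) seeds <- seed + seq_len(n_chains) - 1L
  stopifnot(length(seeds) == n_chains)
  chains <- lapply(seeds, function(s)
    run_chain(loglik, theta0, bounds, chain_len, burnin, s))
  lbest <- vapply(chains, `[[`, 0, "best_lnl")
  best <- chains[[which.max(lbest)]]$best
  mle <- best; lnl <- max(lbest)
  if (refine) {
    lo <- vapply(bounds, `[`, 0, 1L); hi <- vapply(bounds, `[`, 0, 2L)
    fn <- function(th) { ll <- loglik(setNames(th, names(mle))); if (is.finite(ll)) -ll else 1e10 }
    res <- tryCatch(
      optim(clamp(best, lo + 1e-9, hi - 1e-9), fn, method = "L-BFGS-B",
            lower = lo, upper = hi),
      error = function(e) NULL)
    if (!is.null(res) && -res$value >= lnl) {
      mle <- setNames(res$par, names(best)); lnl <- -res$value
    }
  }
  pooled <- do.call(rbind, lapply(chains, `[[`, "samples"))
  pooled_lnl <- unlist(lapply(chains, `[[`, "lnl"))
  profile_params <- intersect(profile_params, names(mle))
  intervals <- list(); profiles <- list()
  for (pn in profile_params) {
    vr <- range(c(pooled[, pn], mle[pn]))
    # ensure a minimum span so poorly mixing chains cannot shrink the
    # profile to a sliver around the best state
    bspan <- bounds[[pn]][2] - bounds[[pn]][1]
    min_half <- 0.05 * bspan
    lo <- min(vr[1], mle[pn] - min_half)
    hi <- max(vr[2], mle[pn] + min_half)
    lo <- max(lo, bounds[[pn]][1]); hi <- min(hi, bounds[[pn]][2])
    pad <- 0.05 * (hi - lo) + 1e-9
    grid <- sort(unique(c(seq(max(lo - pad, bounds[[pn]][1]),
                              min(hi + pad, bounds[[pn]][2]),
                              length.out = n_grid), mle[pn])))
    prof <- if (refine) {
      profile_param(pn, grid, mle, loglik, bounds, pooled, pooled_lnl)
    } else {
      profile_param(pn, grid, mle, function(th) -Inf, bounds, pooled, pooled_lnl)
    }
    prof$lnl[prof$value == mle[pn]] <- max(prof$lnl[prof$value == mle[pn]], lnl)
    profiles[[pn]] <- prof
    intervals[[pn]] <- two_llu_interval(prof, mle[pn])
  }
  # convergence: across-chain spread of per-chain best values vs 2-LLU width
  converged <- TRUE
  chain_best <- do.call(rbind, lapply(chains, `[[`, "best"))
  for (pn in profile_params) {
    width <- intervals[[pn]]$upper - intervals[[pn]]$lower
    if (width <= 0) width <- diff(range(pooled[, pn])) + 1e-12
    if (diff(range(chain_best[, pn])) > 0.05 * width) converged <- FALSE
  }
  n_obs <- nrow(data)
  k <- length(mle)
  structure(list(model = model, type = type, mle = mle, lnl = lnl, k = k,
                 n_obs = n_obs, aicc = aicc(lnl, k, n_obs),
                 intervals = intervals, profiles = profiles,
                 converged = converged,
                 acceptance = vapply(chains, `[[`, 0, "acceptance"),
                 chain_best = chain_best, fixed = fixed,
                 transect_length = L),
            class = "cline_fit")
}

#' Null (no-cline) model fit
#'
#' Constant-response model: for frequencies the pooled allele frequency
#' (1 parameter); for traits the precision-weighted constant mean
#' (counted as 2 parameters, mean plus implicit scale).
#'
#' @inheritParams fit_cline_mcmc
#' @return a `cline_fit`-like list with `mle`, `lnl`, `k`, `aicc`.
#' @export
fit_null <- function(data, type = c("freq", "trait")) {
  type <- match.arg(type)
  if (type == "freq") {
    data <- data[data$total > 0, , drop = FALSE]
    phat <- clamp(sum(data$count) / sum(data$total), 1e-9, 1 - 1e-9)
    lnl <- sum(dbinom(data$count, data$total, phat, log = TRUE))
    k <- 1L; mle <- c(p = phat)
  } else {
    w <- data$n / data$sd^2
    mu <- sum(w * data$mean) / sum(w)
    lnl <- sum(dnorm(data$mean, mu, data$sd / sqrt(data$n), log = TRUE))
    k <- 2L; mle <- c(mu = mu)
  }
  n_obs <- nrow(data)
  structure(list(model = list(name = "null"), type = type, mle = mle,
                 lnl = lnl, k = k, n_obs = n_obs,
                 aicc = aicc(lnl, k, n_obs), converged = TRUE),
            class = "cline_fit")
}

#' AICc model selection across fitted cline models
#'
#' The minimum-AICc model wins; ties go to the model with fewer parameters.
#' When the null (no-cline) model wins, the locus is flagged `is_null` and
#' should be excluded from centre-based analyses downstream.
#'
#' @param fits list of `cline_fit` objects on identical data.
#' @param null_fit optional [fit_null()] result to include in the comparison.
#' @return list with `best` (the winning fit), `is_null` (logical) and
#'   `aicc_table` (data frame: model, k, lnl, aicc).
#' @export
select_model <- function(fits, null_fit = NULL) {
  if (!length(fits) && is.null(null_fit)) abort("no fitted models supplied")
  all_fits <- fits
  if (!is.null(null_fit)) all_fits <- c(all_fits, list(null_fit))
  tab <- data.frame(
    model = vapply(all_fits, function(f) f$model$name, ""),
    k = vapply(all_fits, `[[`, 0L, "k"),
    lnl = vapply(all_fits, `[[`, 0, "lnl"),
    aicc = vapply(all_fits, `[[`, 0, "aicc"),
    stringsAsFactors = FALSE)
  ok <- which(is.finite(tab$aicc))
  if (!length(ok)) abort("no model has a defined AICc")
  best_i <- ok[order(tab$aicc[ok], tab$k[ok])][1L]
  list(best = all_fits[[best_i]],
       is_null = identical(all_fits[[best_i]]$model$name, "null"),
       aicc_table = tab)
}

#' Fit a cline to one response with model selection
#'
#' Fits every model in `models` by [fit_cline_mcmc()], optionally a no-cline
#' null, and selects by AICc.
#'
#' @inheritParams fit_cline_mcmc
#' @param models list of [cline_model()] specs (default: the full family for
#'   the response type).
#' @param include_null compare against the no-cline null model.
#' @param ... passed to [fit_cline_mcmc()].
#' @return object of class `geocline_fit` with elements `best`, `is_null`,
#'   `aicc_table`, `fits`, `null`.
#' @export
fit_geocline <- function(data, type = c("freq", "trait"), models = NULL,
                         include_null = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(models)) models <- cline_model_family(type)
  fits <- lapply(models, function(m) fit_cline_mcmc(data, type, m, ...))
  nul <- if (include_null) fit_null(data, type) else NULL
  sel <- select_model(fits, nul)
  structure(c(sel, list(fits = fits, null = nul, type = type)),
            class = "geocline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("cline_fit [%s]: lnL = %.3f, k = %d, AICc = %.3f\n",
              x$model$name, x$lnl, x$k, x$aicc))
  if (length(x$mle)) {
    cat("  MLE:", paste(sprintf("%s = %.4g", names(x$mle), x$mle), collapse = ", "), "\n")
  }
  for (pn in names(x$intervals)) {
    iv <- x$intervals[[pn]]
    cat(sprintf("  2-LLU %s: [%.4g, %.4g]%s\n", pn, iv$lower, iv$upper,
                if (!iv$lower_bounded || !iv$upper_bounded) " (unbounded side)" else ""))
  }
  invisible(x)
}

#' @export
print.geocline_fit <- function(x, ...) {
  cat(sprintf("geocline_fit: best model = %s%s\n",
              x$best$model$name, if (x$is_null) " (no cline)" else ""))
  print(x$best)
  invisible(x)
}
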