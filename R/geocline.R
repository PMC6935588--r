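## Geographic cline model family: tanh sigmoid core with optional
## exponential tails, the standard parameterisation for hybrid-zone
## transect data. centre c = inflection location (km); width w = inverse
## of the maximal slope (km); pmin/pmax = response floor/ceiling; tails
## take over delta km from the centre with a slope-ratio parameter tau.

TAIL_MODES <- c("none", "left", "right", "mirror", "independent")
SCALING_MODES <- c("fixed01", "observed", "estimated", "fixed")

#' Specify one member of the cline model family
#'
#' @param tail_mode one of `"none"`, `"left"`, `"right"`, `"mirror"`,
#'   `"independent"` (which exponential tails are estimated).
#' @param scaling_mode handling of the response floor/ceiling: `"fixed01"`
#'   (0 and 1, for frequencies and hybrid indices), `"observed"` (set to the
#'   observed response range), `"estimated"` (free parameters), or `"fixed"`
#'   (caller-supplied via `pmin`, `pmax`).
#' @param pmin,pmax fixed floor/ceiling when `scaling_mode = "fixed"`.
#' @return a `cline_model` list describing the family member.
#' @export
cline_model <- function(tail_mode = "none", scaling_mode = "fixed01",
                        pmin = NA_real_, pmax = NA_real_) {
  tail_mode <- match.arg(tail_mode, TAIL_MODES)
  scaling_mode <- match.arg(scaling_mode, SCALING_MODES)
  if (scaling_mode == "fixed" && (is.na(pmin) || is.na(pmax))) {
    abort("scaling_mode 'fixed' requires pmin and pmax")
  }
  structure(list(tail_mode = tail_mode, scaling_mode = scaling_mode,
                 pmin = pmin, pmax = pmax,
                 name = paste(tail_mode, scaling_mode, sep = ".")),
            class = "cline_model")
}

#' The cline model families for frequency and trait responses
#'
#' The frequency family crosses the five tail modes with the three scaling
#' modes (15 models); the trait family uses the five tail modes with
#' estimated asymptotes (5 models).
#'
#' @param type `"freq"` or `"trait"`.
#' @param tail_modes,scaling_modes subsets of the full family, for reduced
#'   fits.
#' @return list of [cline_model()] specs.
#' @export
cline_model_family <- function(type = c("freq", "trait"),
                               tail_modes = TAIL_MODES,
                               scaling_modes = c("fixed01", "observed", "estimated")) {
  type <- match.arg(type)
  if (type == "trait") {
    lapply(tail_modes, function(tm) cline_model(tm, "estimated"))
  } else {
    out <- list()
    for (sm in scaling_modes) for (tm in tail_modes) {
      out[[length(out) + 1L]] <- cline_model(tm, sm)
    }
    out
  }
}

# Names of the free parameters for a model spec
free_params <- function(model) {
  p <- c("centre", "width")
  if (model$scaling_mode == "estimated") p <- c(p, "pmin", "pmax")
  p <- switch(model$tail_mode,
    none = p,
    left = c(p, "deltaL", "tauL"),
    right = c(p, "deltaR", "tauR"),
    mirror = c(p, "delta", "tau"),
    independent = c(p, "deltaL", "tauL", "deltaR", "tauR"))
  p
}

# Expand a free-parameter vector into the full parameter list used by
# cline_value(); `fixed` supplies pmin/pmax when not estimated.
expand_params <- function(theta, model, fixed = c(pmin = 0, pmax = 1)) {
  par <- as.list(theta)
  if (is.null(par$pmin)) par$pmin <- unname(fixed["pmin"])
  if (is.null(par$pmax)) par$pmax <- unname(fixed["pmax"])
  if (model$tail_mode == "mirror") {
    par$deltaL <- par$deltaR <- par$delta
    par$tauL <- par$tauR <- par$tau
  }
  if (model$tail_mode == "left") { par$deltaR <- Inf; par$tauR <- 1 }
  if (model$tail_mode == "right") { par$deltaL <- Inf; par$tauL <- 1 }
  if (model$tail_mode == "none") { par$deltaL <- par$deltaR <- Inf; par$tauL <- par$tauR <- 1 }
  par$tail_mode <- model$tail_mode
  par
}

#' Evaluate a geographic cline
#'
#' Core sigmoid `p(x) = pmin + (pmax - pmin) * (1 + tanh(2 (x - c) / w)) / 2`.
#' Outside `[c - deltaL, c + deltaR]` the response follows an exponential tail
#' continuous with the core at the junction:
#' `p(x) = pmin + (p(c - deltaL) - pmin) * exp(4 tauL (x - (c - deltaL)) / w)`
#' on the left, mirrored on the right. `tau` in `[0, 1]` scales the tail decay
#' relative to the core slope.
#'
#' @param x positions (km), vectorised.
#' @param par named list or vector with `centre`, `width` (> 0), `pmin`,
#'   `pmax`, and tail parameters `deltaL`, `tauL`, `deltaR`, `tauR` as
#'   applicable (use `Inf` delta to disable a tail).
#' @return response values, always within `[pmin, pmax]`.
#' @examples
#' cline_value(1000, list(centre = 1000, width = 100, pmin = 0, pmax = 1))  # 0.5
#' @export
cline_value <- function(x, par) {
  par <- as.list(par)
  c0 <- par$centre; w <- par$width
  if (is.null(w) || !is.finite(w) || w <= 0) abort("width must be > 0")
  pmin <- if (is.null(par$pmin)) 0 else par$pmin
  pmax <- if (is.null(par$pmax)) 1 else par$pmax
  dL <- if (is.null(par$deltaL) || is.na(par$deltaL)) Inf else par$deltaL
  dR <- if (is.null(par$deltaR) || is.na(par$deltaR)) Inf else par$deltaR
  tL <- if (is.null(par$tauL) || is.na(par$tauL)) 1 else par$tauL
  tR <- if (is.null(par$tauR) || is.na(par$tauR)) 1 else par$tauR
  core <- function(z) pmin + (pmax - pmin) * (1 + tanh(2 * (z - c0) / w)) / 2
  p <- core(x)
  if (is.finite(dL)) {
    left <- x < (c0 - dL)
    if (any(left)) {
      pj <- core(c0 - dL)
      p[left] <- pmin + (pj - pmin) * exp(4 * tL * (x[left] - (c0 - dL)) / w)
    }
  }
  if (is.finite(dR)) {
    right <- x > (c0 + dR)
    if (any(right)) {
      pj <- core(c0 + dR)
      p[right] <- pmax - (pmax - pj) * exp(-4 * tR * (x[right] - (c0 + dR)) / w)
    }
  }
  clamp(p, min(pmin, pmax), max(pmin, pmax))
}

#' Binomial log-likelihood of allele-frequency cline data
#'
#' Sum over populations of the binomial log pmf of the counted-allele count
#' `k` out of `n` sampled alleles, with success probability given by the
#' cline evaluated at the population's transect position and clipped to
#' `[eps, 1 - eps]`.
#'
#' @param par full parameter list (see [cline_value()]).
#' @param data data frame with `distance_km`, `count` (k), `total` (n).
#'   Populations with `total == 0` are excluded with a warning.
#' @param eps clipping bound, default 1e-9.
#' @return log-likelihood (scalar).
#' @export
loglik_freq <- function(par, data, eps = 1e-9) {
  stopifnot(all(c("distance_km", "count", "total") %in% names(data)))
  if (any(data$total == 0)) {
    warning("excluding populations with total == 0")
    data <- data[data$total > 0, , drop = FALSE]
  }
  if (any(data$count < 0 | data$count > data$total)) abort("require 0 <= k <= n")
  p <- clamp(cline_value(data$distance_km, par), eps, 1 - eps)
  sum(dbinom(data$count, data$total, p, log = TRUE))
}

#' Gaussian log-likelihood of trait cline data
#'
#' Population trait means are modelled as
#' `mean_i ~ Normal(cline(x_i), sd_i / sqrt(n_i))`.
#'
#' @param par full parameter list (floor/ceiling act as parental asymptotes).
#' @param data data frame with `distance_km`, `mean`, `sd` (> 0), `n` (>= 1).
#' @return log-likelihood (scalar).
#' @export
loglik_trait <- function(par, data) {
  stopifnot(all(c("distance_km", "mean", "sd", "n") %in% names(data)))
  if (any(data$sd <= 0)) abort("sd must be > 0")
  if (any(data$n < 1)) abort("n must be >= 1")
  mu <- cline_value(data$distance_km, par)
  sum(dnorm(data$mean, mu, data$sd / sqrt(data$n), log = TRUE))
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`. Undefined (NA with a warning)
#' when `n <= k + 1`.
#'
#' @param lnL maximised log-likelihood.
#' @param k_params number of free parameters.
#' @param n_obs number of observations (populations).
#' @export
aicc <- function(lnL, k_params, n_obs) {
  if (n_obs <= k_params + 1) {
    warning(sprintf("AICc undefined: n_obs (%d) <= k + 1 (%d)", n_obs, k_params + 1))
    return(NA_real_)
  }
  -2 * lnL + 2 * k_params + 2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

#' 2 log-likelihood-unit interval from a profile
#'
#' The connected set of parameter values around the MLE whose profile
#' log-likelihood is within 2 units of the maximum, the standard approximate
#' 95 percent confidence interval for cline parameters. Endpoints are found by
#' linear interpolation between profile points; a side on which the profile
#' never drops 2 units is reported at the explored bound and flagged
#' unbounded.
#'
#' @param profile data frame with columns `value` (parameter) and `lnl`.
#' @param mle the MLE of the parameter (must be covered by the profile range).
#' @param drop log-likelihood drop defining the interval (default 2).
#' @return list with `lower`, `upper`, `lower_bounded`, `upper_bounded`.
#' @export
two_llu_interval <- function(profile, mle, drop = 2) {
  stopifnot(all(c("value", "lnl") %in% names(profile)), nrow(profile) >= 1)
  profile <- profile[order(profile$value), , drop = FALSE]
  if (mle < min(profile$value) - 1e-8 || mle > max(profile$value) + 1e-8) {
    abort("profile does not cover the MLE")
  }
  thr <- max(profile$lnl) - drop
  v <- profile$value; l <- profile$lnl
  i0 <- which.min(abs(v - mle))
  # walk left
  lower <- v[1]; lower_bounded <- FALSE
  for (i in seq(i0, 1)) {
    if (l[i] < thr) {
      # crossing between i and i+1
      j <- i + 1
      lower <- v[i] + (thr - l[i]) * (v[j] - v[i]) / (l[j] - l[i])
      lower_bounded <- TRUE
      break
    }
  }
  upper <- v[length(v)]; upper_bounded <- FALSE
  for (i in seq(i0, length(v))) {
    if (l[i] < thr) {
      j <- i - 1
      upper <- v[j] + (thr - l[j]) * (v[i] - v[j]) / (l[i] - l[j])
      upper_bounded <- TRUE
      break
    }
  }
  list(lower = lower, upper = upper,
       lower_bounded = lower_bounded, upper_bounded = upper_bounded)
}

#' Centre shift between a genetic and a morphological cline
#'
#' Signed difference between a hybrid-index (Q-score) cline centre and the
#' average of one or more morphological trait cline centres; positive values
#' indicate the genetic cline lies further along the transect (northward for
#' a south-to-north transect).
#'
#' @param q_centre genetic (hybrid index) cline centre, km.
#' @param morph_centres numeric vector of trait cline centres, km.
#' @export
cline_centre_shift <- function(q_centre, morph_centres) {
  q_centre - mean(morph_centres)
}

#' Absolute difference between two cline widths
#' @param w1,w2 cline widths, km.
#' @export
cline_width_difference <- function(w1, w2) abs(w1 - w2)
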