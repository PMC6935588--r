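## Supervised maximum-likelihood hybrid index and per-locus genomic clines
## (excess-ancestry parameters alpha/beta with credible-interval outlier
## classification).

#' Maximum-likelihood hybrid index
#'
#' Estimates, per individual, the proportion `h` of species-B ancestry under
#' a per-locus binomial mixture: the counted-allele dose at locus `l` is
#' `Binomial(2, h pB_l + (1 - h) pA_l)`, using parental reference allele
#' frequencies at (nearly) diagnostic loci. This is the supervised
#' two-ancestry stand-in for global admixture coefficients (Q-scores) at
#' K = 2. The MLE is found by bounded one-dimensional optimisation and the
#' support interval is the 2 log-likelihood-unit region from a grid profile.
#'
#' @param g a [genotype_matrix] or plain loci x individuals 0/1/2 matrix.
#' @param parental_freqs data frame or list with `pA`, `pB` (frequencies of
#'   the counted allele in the two parental groups) for the loci used, in
#'   the same order as `loci`.
#' @param loci locus ids (rownames of the genotype matrix) to use.
#' @param grid_step grid resolution for the support interval.
#' @return data frame: `ind_id`, `h`, `lower`, `upper`.
#' @export
hybrid_index <- function(g, parental_freqs, loci = NULL, grid_step = 0.002) {
  geno <- if (inherits(g, "genotype_matrix")) g$geno else g
  if (!is.null(loci)) geno <- geno[match(loci, rownames(geno)), , drop = FALSE]
  pA <- clamp(parental_freqs$pA, 1e-6, 1 - 1e-6)
  pB <- clamp(parental_freqs$pB, 1e-6, 1 - 1e-6)
  stopifnot(length(pA) == nrow(geno), length(pB) == nrow(geno))
  if (all(abs(pA - pB) < 1e-12)) abort("all loci uninformative (pA == pB)")
  hgrid <- seq(0, 1, by = grid_step)
  # log-likelihood matrix: individuals x grid
  lnl <- matrix(0, ncol(geno), length(hgrid))
  dose <- geno
  for (j in seq_along(hgrid)) {
    p <- clamp(hgrid[j] * pB + (1 - hgrid[j]) * pA, 1e-9, 1 - 1e-9)
    ll <- dose * log(p) + (2 - dose) * log1p(-p) +
      ifelse(dose == 1, log(2), 0)
    lnl[, j] <- colSums(ll, na.rm = TRUE)
  }
  ids <- colnames(geno)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(geno)))
  out <- data.frame(ind_id = ids, h = NA_real_, lower = NA_real_,
                    upper = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(geno))) {
    d <- dose[, i]
    f <- function(h) {
      p <- clamp(h * pB + (1 - h) * pA, 1e-9, 1 - 1e-9)
      -sum(d * log(p) + (2 - d) * log1p(-p), na.rm = TRUE)
    }
    j0 <- which.max(lnl[i, ])
    opt <- optimize(f, c(max(0, hgrid[j0] - 2 * grid_step),
                         min(1, hgrid[j0] + 2 * grid_step)))
    out$h[i] <- opt$minimum
    prof <- data.frame(value = hgrid, lnl = lnl[i, ])
    iv <- two_llu_interval(prof, hgrid[j0])
    out$lower[i] <- iv$lower; out$upper[i] <- iv$upper
  }
  out$h <- clamp(out$h, 0, 1)
  out
}

#' Orient counted alleles to the species-B allele
#'
#' Flips loci whose counted allele is more frequent in species A, so that
#' genotype doses count the species-B-enriched allele everywhere (the
#' convention genomic clines and fixed-0/1 frequency clines assume).
#'
#' @param g a [genotype_matrix].
#' @param freqA,freqB named parental frequencies of the counted allele (as
#'   from [group_allele_freqs()] columns) for (a superset of) the loci.
#' @return `g` with flipped genotypes/haplotypes and a `flipped` column on
#'   the locus table.
#' @export
orient_to_speciesB <- function(g, freqA, freqB) {
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- rownames(g$geno)
  flip <- which(freqA[ids] > freqB[ids])
  if (length(flip)) {
    g$geno[flip, ] <- 2L - g$geno[flip, ]
    if (!is.null(g$hapA)) {
      g$hapA[flip, ] <- 1L - g$hapA[flip, ]
      g$hapB[flip, ] <- 1L - g$hapB[flip, ]
    }
  }
  g$loci$flipped <- seq_len(nrow(g$geno)) %in% flip
  g
}

#' Genomic cline function
#'
#' Expected probability of species-B ancestry at a locus given hybrid index
#' `h`: `phi = h + 2 h (1 - h) (alpha + beta (2 h - 1))`, clamped to
#' `[0, 1]`. `alpha` measures excess ancestry (genomic cline centre);
#' `beta` measures rate. `phi(0) = 0` and `phi(1) = 1` for any
#' `alpha`, `beta`.
#'
#' @param h hybrid index in `[0, 1]` (vectorised).
#' @param alpha,beta genomic cline parameters.
#' @export
genomic_cline_phi <- function(h, alpha, beta = 0) {
  clamp(h + 2 * h * (1 - h) * (alpha + beta * (2 * h - 1)), 0, 1)
}

#' Estimate per-locus genomic cline parameters
#'
#' Metropolis-Hastings sampling of `(alpha, beta)` for one locus with
#' independent Gaussian priors, likelihood
#' `dose_i ~ Binomial(2, phi(h_i, alpha, beta))` over hybrid-zone
#' individuals. Reports posterior medians and the 95 percent equal-tailed
#' credible interval for `alpha`, and the outlier class (positive when the
#' interval is entirely above 0, negative when entirely below).
#'
#' @param dose integer vector (0/1/2) of species-B allele dose per individual.
#' @param h hybrid indices of the same individuals.
#' @param prior_sd Gaussian prior standard deviation for both parameters
#'   (default 0.5).
#' @param n_steps,burnin chain length after burn-in, and burn-in.
#' @param seed RNG seed.
#' @return one-row data frame: `alpha_median`, `alpha_low`, `alpha_high`,
#'   `beta_median`, `beta_low`, `beta_high`, `outlier_class`.
#' @export
estimate_alpha <- function(dose, h, prior_sd = 0.5, n_steps = 8000,
                           burnin = 2000, seed = 1) {
  ok <- !is.na(dose) & !is.na(h)
  dose <- dose[ok]; h <- h[ok]
  if (length(dose) < 10) abort("need >= 10 hybrid individuals with defined h")
  if (length(unique(dose)) == 1L && all(dose %in% c(0, 2)) &&
      all(h %in% c(0, 1))) {
    warning("locus carries no genomic-cline information")
  }
  set.seed(seed)
  logpost <- function(ab) {
    p <- clamp(genomic_cline_phi(h, ab[1], ab[2]), 1e-9, 1 - 1e-9)
    sum(dose * log(p) + (2 - dose) * log1p(-p)) +
      dnorm(ab[1], 0, prior_sd, log = TRUE) + dnorm(ab[2], 0, prior_sd, log = TRUE)
  }
  ab <- c(0, 0); lcur <- logpost(ab)
  scale <- c(0.2, 0.2)
  total <- burnin + n_steps
  keep <- matrix(NA_real_, n_steps, 2)
  accw <- 0L
  for (s in seq_len(total)) {
    prop <- ab + rnorm(2) * scale
    lprop <- logpost(prop)
    if (is.finite(lprop) && log(runif(1)) < lprop - lcur) {
      ab <- prop; lcur <- lprop; accw <- accw + 1L
    }
    if (s <= burnin && s %% 50L == 0L) {
      r <- accw / 50
      if (r < 0.2) scale <- scale * 0.8 else if (r > 0.4) scale <- scale * 1.25
      accw <- 0L
    }
    if (s > burnin) keep[s - burnin, ] <- ab
  }
  qa <- quantile(keep[, 1], c(0.025, 0.5, 0.975), names = FALSE)
  qb <- quantile(keep[, 2], c(0.025, 0.5, 0.975), names = FALSE)
  cls <- if (qa[1] > 0) "positive" else if (qa[3] < 0) "negative" else "none"
  data.frame(alpha_median = qa[2], alpha_low = qa[1], alpha_high = qa[3],
             beta_median = qb[2], beta_low = qb[1], beta_high = qb[3],
             outlier_class = cls, stringsAsFactors = FALSE)
}

#' Genomic clines for a set of loci
#'
#' Applies [estimate_alpha()] locus by locus over hybrid-zone individuals.
#' Monomorphic loci are skipped with a warning.
#'
#' @param g a [genotype_matrix] (columns restricted to hybrid-zone
#'   individuals by `individuals`).
#' @param h data frame from [hybrid_index()] (matched on `ind_id`) or a
#'   numeric vector aligned with the selected individuals.
#' @param loci locus ids to analyse.
#' @param individuals optional individual ids to restrict to.
#' @param ... passed to [estimate_alpha()]; per-locus seeds are derived from
#'   `seed`.
#' @param seed base seed.
#' @return data frame: locus plus the [estimate_alpha()] columns.
#' @export
genomic_clines <- function(g, h, loci = NULL, individuals = NULL, seed = 1, ...) {
  geno <- if (inherits(g, "genotype_matrix")) g$geno else g
  if (!is.null(individuals)) geno <- geno[, match(individuals, colnames(geno)), drop = FALSE]
  if (!is.null(loci)) geno <- geno[match(loci, rownames(geno)), , drop = FALSE]
  if (is.data.frame(h)) {
    h <- h$h[match(colnames(geno), h$ind_id)]
  }
  stopifnot(length(h) == ncol(geno))
  res <- vector("list", nrow(geno))
  for (i in seq_len(nrow(geno))) {
    d <- geno[i, ]
    if (length(unique(d[!is.na(d)])) < 2L) {
      warning(sprintf("locus %s monomorphic; skipped", rownames(geno)[i]))
      next
    }
    res[[i]] <- cbind(locus = rownames(geno)[i],
                      estimate_alpha(d, h, seed = seed + i, ...),
                      stringsAsFactors = FALSE)
  }
  do.call(rbind, res[!vapply(res, is.null, TRUE)])
}

#' Classify genomic-cline outliers from credible intervals
#'
#' @param params data frame with `alpha_low`, `alpha_high` (e.g. from
#'   [genomic_clines()]).
#' @return `params` with `outlier_class` set to `"positive"` (interval
#'   entirely above 0), `"negative"` (entirely below) or `"none"`.
#' @export
classify_outliers <- function(params) {
  params$outlier_class <- ifelse(params$alpha_low > 0, "positive",
                          ifelse(params$alpha_high < 0, "negative", "none"))
  params
}
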