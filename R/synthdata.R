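## Synthetic landscapes, genotypes and traits emulating a two-species
## conifer hybrid zone sampled along a ~2,000 km south-to-north transect:
## two parental groups flanking a hybrid-zone band, a subset of loci with
## elevated parental allele-frequency differentials, admixture-gradient
## hybrid genotypes with ancestry-block LD, and Gaussian clinal traits.

#' Default trait definitions
#'
#' Two reproductive-output traits with distinct parental means. Raw trait
#' scales are arbitrary (configurable); species A is the larger-coned
#' southern species.
#' @export
default_trait_defs <- function() {
  data.frame(trait = c("cone_length", "seed_weight"),
             mean_A = c(20, 3.2), mean_B = c(9, 1.1),
             sd = c(2.5, 0.5), stringsAsFactors = FALSE)
}

#' Specification for a synthetic hybrid-zone data set
#'
#' Defines the sampled landscape (population counts per group along the
#' transect), the genotype model (number of loci, fraction with elevated
#' parental divergence, Balding-Nichols dispersion), the ancestry cline
#' (centre, width), trait clines, and optional planted per-locus classes
#' used to emulate directional introgression:
#' `frac_introgressed` diagnostic loci get a genomic-cline ancestry boost
#' `intro_alpha` (excess species-B ancestry at a given hybrid index, i.e.
#' positive genomic-cline alpha); `frac_retained` loci get the deficit
#' `retained_alpha` (species-A alleles retained against the genome-wide
#' gradient, negative alpha); `frac_relict` loci follow a displaced
#' southern cline (centre at the trait cline, width `relict_width_km`).
#' `drift_concentration` adds per-locus, per-population ancestry jitter to
#' the unclassified divergent loci (locus-specific drift), scattering their
#' fitted geographic centres without distorting their expected genomic
#' cline; `ancestry_tail_delta_km`/`ancestry_tail_tau` put an exponential
#' northern tail on the ancestry cline (admixed individuals left behind an
#' expanding front).
#'
#' @param n_pops_speciesA,n_pops_hybrid,n_pops_speciesB population counts
#'   per group (defaults 5/16/13, i.e. 34 populations).
#' @param inds_per_pop range (min, max) of individuals per population.
#' @param n_loci number of biallelic loci (>= 10).
#' @param frac_diagnostic fraction of loci with elevated parental divergence.
#' @param transect_extent_km transect length.
#' @param trait_defs data frame: trait, mean_A, mean_B, sd.
#' @param cline_centre_km,cline_width_km ancestry cline centre and width.
#' @param trait_centre_offset_km trait cline centre minus ancestry centre
#'   (0 = concordant clines; negative values emulate a morphological cline
#'   lagging south of the genetic cline).
#' @param trait_width_km trait cline width (traits turn over more slowly
#'   than the genomic cline).
#' @param fst_noise Balding-Nichols dispersion in (0, 1) controlling
#'   parental divergence at background loci and residual polymorphism at
#'   divergent loci.
#' @param admix_concentration Beta concentration of individual admixture
#'   proportions around the cline expectation (smaller = more ancestry
#'   variance within populations, hence more admixture LD).
#' @param frac_introgressed,intro_alpha,frac_relict,relict_width_km,
#'   frac_retained,retained_alpha planted locus classes (see above), all
#'   fractions of the divergent loci; defaults 0.
#' @param drift_concentration Beta concentration of per-population ancestry
#'   jitter at unclassified divergent loci (`Inf` = none).
#' @param ancestry_tail_delta_km,ancestry_tail_tau northern exponential
#'   tail of the ancestry cline (`NULL` = pure sigmoid).
#' @param front_concentration Beta concentration of individual admixture
#'   north of the cline centre (`NULL` = same as `admix_concentration`);
#'   small values emulate the high ancestry variance of recently admixed
#'   populations behind an expanding front.
#' @param lat0,lon0 coordinates of the southern end of the transect.
#' @param seed RNG seed; fixing it fixes every emitted value.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pops_speciesA = 5, n_pops_hybrid = 16,
                           n_pops_speciesB = 13, inds_per_pop = c(3, 10),
                           n_loci = 2000, frac_diagnostic = 0.1,
                           transect_extent_km = 2000,
                           trait_defs = default_trait_defs(),
                           cline_centre_km = 1500, cline_width_km = 150,
                           trait_centre_offset_km = 0, trait_width_km = 600,
                           fst_noise = 0.2, admix_concentration = 10,
                           frac_introgressed = 0, intro_alpha = 0.5,
                           intro_beta = 0,
                           frac_relict = 0, relict_width_km = NULL,
                           frac_retained = 0, retained_alpha = -0.5,
                           retained_beta = 0,
                           drift_concentration = Inf,
                           ancestry_tail_delta_km = NULL,
                           ancestry_tail_tau = 0.3,
                           front_concentration = NULL,
                           lat0 = 23.5, lon0 = -106, seed = 1) {
  if (any(c(n_pops_speciesA, n_pops_hybrid, n_pops_speciesB) <= 0)) {
    abort("all group population counts must be > 0")
  }
  stopifnot(length(inds_per_pop) == 2, inds_per_pop[1] >= 1,
            inds_per_pop[2] >= inds_per_pop[1])
  if (frac_diagnostic <= 0 || frac_diagnostic >= 1) {
    abort("frac_diagnostic must be in (0, 1)")
  }
  if (fst_noise <= 0 || fst_noise >= 1) abort("fst_noise must be in (0, 1)")
  if (any(trait_defs$sd <= 0)) abort("trait SD must be > 0")
  if (any(trait_defs$mean_A == trait_defs$mean_B)) {
    abort("parental trait means must differ for every trait")
  }
  if (is.null(relict_width_km)) relict_width_km <- trait_width_km
  spec <- list(n_pops_speciesA = n_pops_speciesA, n_pops_hybrid = n_pops_hybrid,
               n_pops_speciesB = n_pops_speciesB, inds_per_pop = inds_per_pop,
               n_loci = n_loci, frac_diagnostic = frac_diagnostic,
               transect_extent_km = transect_extent_km, trait_defs = trait_defs,
               cline_centre_km = cline_centre_km, cline_width_km = cline_width_km,
               trait_centre_offset_km = trait_centre_offset_km,
               trait_width_km = trait_width_km, fst_noise = fst_noise,
               admix_concentration = admix_concentration,
               frac_introgressed = frac_introgressed, intro_alpha = intro_alpha,
               intro_beta = intro_beta,
               frac_relict = frac_relict, relict_width_km = relict_width_km,
               frac_retained = frac_retained, retained_alpha = retained_alpha,
               retained_beta = retained_beta,
               drift_concentration = drift_concentration,
               ancestry_tail_delta_km = ancestry_tail_delta_km,
               ancestry_tail_tau = ancestry_tail_tau,
               front_concentration = front_concentration,
               lat0 = lat0, lon0 = lon0, seed = seed)
  structure(spec, class = "synthetic_spec")
}

# ancestry-cline expectation at position x
sigmoid_cline <- function(x, centre, width) (1 + tanh(2 * (x - centre) / width)) / 2

#' Generate the sampled landscape
#'
#' Places populations at strictly increasing latitude along a
#' one-dimensional transect, group bands ordered species A (south), hybrid
#' zone (middle band, 25-75 percent of the extent), species B (north).
#'
#' @param spec a [synthetic_spec()].
#' @return population table: `pop_id`, `lat`, `lon`, `group`,
#'   `distance_km`, sorted south to north.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ext <- spec$transect_extent_km
  bands <- list(speciesA = c(0, 0.25), hybrid = c(0.25, 0.75),
                speciesB = c(0.75, 1)) # fractions of the extent
  counts <- c(speciesA = spec$n_pops_speciesA, hybrid = spec$n_pops_hybrid,
              speciesB = spec$n_pops_speciesB)
  pos <- numeric(0); grp <- character(0)
  for (gname in names(bands)) {
    b <- bands[[gname]] * ext
    k <- counts[[gname]]
    base <- seq(b[1], b[2], length.out = k + 2)[2:(k + 1)]
    jit <- runif(k, -0.25, 0.25) * diff(b) / (k + 1)
    pos <- c(pos, sort(base + jit))
    grp <- c(grp, rep(gname, k))
  }
  km_per_deg <- 6371 * pi / 180
  lat <- spec$lat0 + pos / km_per_deg
  lon <- spec$lon0 + runif(length(pos), -0.15, 0.15)
  pops <- data.frame(pop_id = sprintf("pop%02d", seq_along(pos)),
                     lat = lat, lon = lon, group = grp,
                     stringsAsFactors = FALSE)
  great_circle_distances(pops)
}

# per-locus class assignment for the divergent loci
assign_locus_classes <- function(spec, n_div) {
  n_intro <- round(spec$frac_introgressed * n_div)
  n_relict <- round(spec$frac_relict * n_div)
  n_retained <- round(spec$frac_retained * n_div)
  if (n_intro + n_relict + n_retained > n_div) {
    abort("planted locus class fractions exceed the divergent loci")
  }
  cls <- rep("main", n_div)
  idx <- seq_len(n_div)
  if (n_intro) { cls[idx[seq_len(n_intro)]] <- "introgressed"; idx <- idx[-seq_len(n_intro)] }
  if (n_relict) { cls[idx[seq_len(n_relict)]] <- "relict"; idx <- idx[-seq_len(n_relict)] }
  if (n_retained) cls[idx[seq_len(n_retained)]] <- "retained"
  cls
}

#' Generate phased genotypes along the landscape
#'
#' Parental allele frequencies follow a Balding-Nichols divergence model
#' with dispersion `fst_noise`; a `frac_diagnostic` subset of loci is
#' strongly divergent (frequencies near 0 in species A and near 1 in
#' species B, within `fst_noise / 2` of fixation, orientation randomised).
#' Each individual carries an admixture proportion drawn around the
#' ancestry-cline expectation at its population's transect position
#' (Beta, concentration `admix_concentration`); every haplotype allele is
#' drawn by first picking an ancestry (Bernoulli in the individual's
#' admixture proportion, per unlinked locus) and then an allele from the
#' corresponding parental frequency. The shared individual-level admixture
#' proportion generates within-population linkage disequilibrium between
#' divergent loci without a linkage map. Phased haplotypes are retained
#' alongside the 0/1/2 genotypes.
#'
#' @param spec a [synthetic_spec()].
#' @param pops landscape from [generate_landscape()].
#' @return object of class `genotype_matrix`: list with `geno` (loci x
#'   individuals 0/1/2), `hapA`/`hapB` (phased haplotypes, 0/1), `ind`
#'   (individual table: `ind_id`, `pop_id`, `group`, `distance_km`, `q_true`),
#'   `loci` (locus table: `locus_id`, `pA`, `pB`, `divergent` ground truth,
#'   `class`, `centre_km`, `alpha_true`).
#' @export
generate_genotypes <- function(spec, pops) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_loci < 10) abort("n_loci must be >= 10")
  set.seed(spec$seed + 1L)
  L <- spec$n_loci
  n_div <- round(spec$frac_diagnostic * L)
  divergent <- c(rep(TRUE, n_div), rep(FALSE, L - n_div))
  F <- spec$fst_noise
  p_anc <- runif(L, 0.05, 0.95)
  shp <- (1 - F) / F
  pA <- rbeta(L, p_anc * shp, (1 - p_anc) * shp)
  pB <- rbeta(L, p_anc * shp, (1 - p_anc) * shp)
  flip <- runif(n_div) < 0.5
  lowf <- runif(n_div, 0, F / 2)
  highf <- runif(n_div, 1 - F / 2, 1)
  pA[seq_len(n_div)] <- ifelse(flip, highf, lowf)
  pB[seq_len(n_div)] <- ifelse(flip, lowf, highf)
  cls <- rep("background", L)
  cls[seq_len(n_div)] <- assign_locus_classes(spec, n_div)
  alpha_true <- beta_true <- rep(0, L)
  alpha_true[cls == "introgressed"] <- spec$intro_alpha
  beta_true[cls == "introgressed"] <- spec$intro_beta
  alpha_true[cls == "retained"] <- spec$retained_alpha
  beta_true[cls == "retained"] <- spec$retained_beta
  centre_km <- rep(spec$cline_centre_km, L)
  width_km <- rep(spec$cline_width_km, L)
  centre_km[cls == "relict"] <- spec$cline_centre_km + spec$trait_centre_offset_km
  width_km[cls == "relict"] <- spec$relict_width_km
  # individuals
  n_ind_pop <- sample(spec$inds_per_pop[1]:spec$inds_per_pop[2],
                      nrow(pops), replace = TRUE)
  pop_of <- rep(seq_len(nrow(pops)), n_ind_pop)
  N <- length(pop_of)
  x_ind <- pops$distance_km[pop_of]
  # a right tail makes the ancestry cline approach full species-B ancestry
  # slowly north of the centre: admixed individuals trailing the front
  qbar_of <- function(x) {
    if (is.null(spec$ancestry_tail_delta_km)) {
      sigmoid_cline(x, spec$cline_centre_km, spec$cline_width_km)
    } else {
      par <- list(centre = spec$cline_centre_km, width = spec$cline_width_km,
                  pmin = 0, pmax = 1,
                  deltaR = spec$ancestry_tail_delta_km,
                  tauR = spec$ancestry_tail_tau)
      cline_value(x, par)
    }
  }
  qbar <- clamp(qbar_of(x_ind), 1e-4, 1 - 1e-4)
  # ancestry variance rises behind the expanding (northern) front when a
  # front concentration is set: recently admixed populations mix residents
  # and immigrants spanning the ancestry range
  nu <- rep(spec$admix_concentration, N)
  if (!is.null(spec$front_concentration)) {
    nu[x_ind > spec$cline_centre_km] <- spec$front_concentration
  }
  q <- rbeta(N, qbar * nu, (1 - qbar) * nu)
  # per-locus, per-individual expected species-B ancestry probability
  Phi <- matrix(rep(q, each = L), L, N)
  relict <- which(cls == "relict")
  for (l in relict) {
    Phi[l, ] <- clamp(sigmoid_cline(x_ind, centre_km[l], width_km[l]),
                      1e-4, 1 - 1e-4)
  }
  for (l in which(alpha_true != 0 | beta_true != 0)) {
    Phi[l, ] <- genomic_cline_phi(Phi[l, ], alpha_true[l], beta_true[l])
  }
  if (is.finite(spec$drift_concentration)) {
    main <- which(cls == "main")
    kap <- spec$drift_concentration
    qp <- clamp(qbar_of(pops$distance_km), 1e-4, 1 - 1e-4)
    for (l in main) {
      dev <- rbeta(nrow(pops), qp * kap, (1 - qp) * kap) - qp
      Phi[l, ] <- clamp(Phi[l, ] + dev[pop_of], 1e-3, 1 - 1e-3)
    }
  }
  Phi <- clamp(Phi, 1e-4, 1 - 1e-4)
  draw_hap <- function() {
    z <- matrix(rbinom(L * N, 1, Phi), L, N)
    pz <- ifelse(z == 1, pB, pA)  # recycles by column: pB/pA are length L
    matrix(rbinom(L * N, 1, pz), L, N)
  }
  hapA <- draw_hap()
  hapB <- draw_hap()
  geno <- hapA + hapB
  locus_ids <- sprintf("snp%05d", seq_len(L))
  ind_ids <- sprintf("ind%04d", seq_len(N))
  dimnames(geno) <- dimnames(hapA) <- dimnames(hapB) <- list(locus_ids, ind_ids)
  structure(list(
    geno = geno, hapA = hapA, hapB = hapB,
    ind = data.frame(ind_id = ind_ids, pop_id = pops$pop_id[pop_of],
                     group = pops$group[pop_of], distance_km = x_ind,
                     q_true = q, stringsAsFactors = FALSE),
    loci = data.frame(locus_id = locus_ids, pA = pA, pB = pB,
                      divergent = divergent, class = cls,
                      centre_km = centre_km, alpha_true = alpha_true,
                      beta_true = beta_true, stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d individuals (%d populations)%s\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$ind$pop_id)),
              if (!is.null(x$hapA)) ", phased" else ""))
  invisible(x)
}

#' Generate clinal quantitative traits
#'
#' Per-population trait means follow a sigmoid cline between the parental
#' means (centre = ancestry centre + `trait_centre_offset_km`, width =
#' `trait_width_km`); individual values are Gaussian with the stated
#' within-population SD, and per-population mean/SD/n summaries are emitted.
#'
#' @param spec a [synthetic_spec()].
#' @param pops landscape from [generate_landscape()].
#' @param n_per_pop individuals measured per population (default: a fresh
#'   draw from `inds_per_pop`).
#' @return trait table: `pop_id`, `distance_km`, `trait`, `mean`, `sd`, `n`,
#'   `true_mean`.
#' @export
generate_traits <- function(spec, pops, n_per_pop = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  if (is.null(n_per_pop)) {
    n_per_pop <- sample(spec$inds_per_pop[1]:spec$inds_per_pop[2],
                        nrow(pops), replace = TRUE)
  }
  n_per_pop <- rep_len(n_per_pop, nrow(pops))
  centre <- spec$cline_centre_km + spec$trait_centre_offset_km
  rows <- list()
  for (t in seq_len(nrow(spec$trait_defs))) {
    td <- spec$trait_defs[t, ]
    mu <- td$mean_A + (td$mean_B - td$mean_A) *
      sigmoid_cline(pops$distance_km, centre, spec$trait_width_km)
    for (i in seq_len(nrow(pops))) {
      vals <- rnorm(n_per_pop[i], mu[i], td$sd)
      rows[[length(rows) + 1L]] <- data.frame(
        pop_id = pops$pop_id[i], distance_km = pops$distance_km[i],
        trait = td$trait, mean = mean(vals),
        sd = if (n_per_pop[i] > 1) sd(vals) else td$sd,
        n = n_per_pop[i], true_mean = mu[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
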