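## Spatially explicit individual-based meta-population simulator of a
## hybrid zone on a one-dimensional column of patches grouped into
## species A (south), hybrid zone (middle) and species B (north), run
## through four phases: (I) divergence with the middle closed, (II)
## colonization of the middle from species A, (III) a scenario-specific
## among-group gene-flow regime triggered once every middle patch holds
## half its carrying capacity, (IV) bidirectional dispersal only between
## the hybrid zone and species B. Monoecious random mating, Mendelian
## transmission over unlinked biallelic loci, Poisson fecundity, density
## regulation truncating to carrying capacity, no selection, no age
## structure (non-overlapping generations).

#' Configure a hybrid-zone simulation scenario
#'
#' Model A (secondary contact) has zero among-group dispersal during
#' Phase I; model B (speciation with gene flow) keeps background
#' species A / species B exchange throughout Phase I. Phase III scenarios:
#' `i` = bidirectional dispersal between the hybrid zone and both parental
#' groups; `ii` = bidirectional dispersal only between the hybrid zone and
#' species B; `iii` (model B only) = scenario i with among-group dispersal
#' reduced by 50 percent. Phase IV is common to all scenarios
#' (hybrid zone and species B only).
#'
#' @param model `"A"` (secondary contact) or `"B"` (speciation with gene
#'   flow).
#' @param scenario `"i"`, `"ii"`, or (model B only) `"iii"`.
#' @param n_patches named counts of patches per group (south to north).
#' @param K named per-patch carrying capacities per group (hybrid-zone
#'   patches default smaller than parental ones).
#' @param phase_gens generations per phase `I`, `II`, `III`, `IV`.
#' @param m_among per-offspring probability of among-group dispersal along
#'   an enabled group pair per generation.
#' @param m_within per-offspring probability of moving to an adjacent patch
#'   within its group.
#' @param colonize_m species A to hybrid-zone dispersal probability during
#'   the colonization phase.
#' @param phaseI_bg background species A / species B exchange under model B
#'   during Phase I (and II).
#' @param trigger_frac fraction of carrying capacity every middle patch
#'   must reach before the Phase III regime starts (default 0.5).
#' @param fecundity expected offspring per adult (Poisson, capped at
#'   `K * fecundity` per patch).
#' @param n_loci,n_diagnostic unlinked biallelic loci and how many start
#'   near fixation for alternative alleles in the two parental groups.
#' @param extent_km total spatial extent of the landscape.
#' @param snapshot_every generations between F-statistic snapshots.
#' @param track_schedule generations at which per-patch hybrid-index
#'   summaries (for cline-centre tracking) are recorded.
#' @param store_genotypes_at generations at which a full phased
#'   [genotype_matrix] snapshot is kept (e.g. for LD profiling).
#' @param n_replicates replicate runs used by [simulate_scenario()].
#' @param seed RNG seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(model = c("A", "B"), scenario = c("i", "ii", "iii"),
                            n_patches = c(speciesA = 12, hybrid = 10, speciesB = 12),
                            K = c(speciesA = 100, hybrid = 50, speciesB = 100),
                            phase_gens = c(I = 200, II = 20, III = 500, IV = 300),
                            m_among = 0.02, m_within = 0.15, colonize_m = 0.1,
                            phaseI_bg = 0.001, trigger_frac = 0.5, fecundity = 2,
                            n_loci = 120, n_diagnostic = 100, extent_km = 2000,
                            snapshot_every = 50, track_schedule = integer(0),
                            store_genotypes_at = integer(0),
                            n_replicates = 12, seed = 1) {
  model <- match.arg(model)
  scenario <- match.arg(scenario)
  if (scenario == "iii" && model != "B") {
    abort("scenario iii is only defined under model B (speciation with gene flow)")
  }
  probs <- c(m_among, m_within, colonize_m, phaseI_bg)
  if (any(probs < 0 | probs > 1)) abort("dispersal probabilities must be in [0, 1]")
  stopifnot(n_diagnostic <= n_loci, all(n_patches > 0), all(K >= 0),
            trigger_frac > 0, trigger_frac <= 1)
  structure(list(model = model, scenario = scenario, n_patches = n_patches,
                 K = K, phase_gens = phase_gens, m_among = m_among,
                 m_within = m_within, colonize_m = colonize_m,
                 phaseI_bg = phaseI_bg, trigger_frac = trigger_frac,
                 fecundity = fecundity, n_loci = n_loci,
                 n_diagnostic = n_diagnostic, extent_km = extent_km,
                 snapshot_every = snapshot_every,
                 track_schedule = as.integer(track_schedule),
                 store_genotypes_at = as.integer(store_genotypes_at),
                 n_replicates = n_replicates, seed = seed),
            class = "scenario_config")
}

# patch table for a config
build_patches <- function(cfg) {
  groups <- rep(c("speciesA", "hybrid", "speciesB"),
                cfg$n_patches[c("speciesA", "hybrid", "speciesB")])
  P <- length(groups)
  data.frame(patch = seq_len(P), group = groups,
             position_km = seq(0, cfg$extent_km, length.out = P),
             K = unname(cfg$K[groups]), stringsAsFactors = FALSE)
}

# 3x3 among-group movement matrix for a phase regime
phase_matrix <- function(cfg, phase) {
  g <- c("speciesA", "hybrid", "speciesB")
  m <- matrix(0, 3, 3, dimnames = list(g, g))
  if (phase == "I") {
    if (cfg$model == "B") m["speciesA", "speciesB"] <- m["speciesB", "speciesA"] <- cfg$phaseI_bg
  } else if (phase == "II") {
    if (cfg$model == "B") m["speciesA", "speciesB"] <- m["speciesB", "speciesA"] <- cfg$phaseI_bg
    m["speciesA", "hybrid"] <- cfg$colonize_m
  } else if (phase == "III") {
    rate <- if (cfg$scenario == "iii") cfg$m_among / 2 else cfg$m_among
    if (cfg$scenario %in% c("i", "iii")) {
      m["speciesA", "hybrid"] <- m["hybrid", "speciesA"] <- rate
    }
    m["hybrid", "speciesB"] <- m["speciesB", "hybrid"] <- rate
  } else if (phase == "IV") {
    m["hybrid", "speciesB"] <- m["speciesB", "hybrid"] <- cfg$m_among
  }
  m
}

# initial state: parental patches at carrying capacity, middle empty
init_state <- function(cfg, patches) {
  L <- cfg$n_loci
  fA <- fB <- runif(L, 0.2, 0.8)
  dg <- seq_len(cfg$n_diagnostic)
  fA[dg] <- 0.05; fB[dg] <- 0.95
  rows <- patches$group != "hybrid"
  n_per <- ifelse(rows, patches$K, 0L)
  N <- sum(n_per)
  patch_of <- rep(patches$patch, n_per)
  f_ind <- ifelse(patches$group[patch_of] == "speciesA", 0, 1) # 0=A freqs,1=B
  fmat <- rbind(fA, fB)[f_ind + 1L, , drop = FALSE]
  hap1 <- matrix(rbinom(N * L, 1, fmat), N, L)
  hap2 <- matrix(rbinom(N * L, 1, fmat), N, L)
  list(hap1 = hap1, hap2 = hap2, patch = patch_of,
       founder_freqs = list(pA = fA, pB = fB),
       diagnostic = dg)
}

# reproduction within patches: random mating with Mendelian transmission
sim_reproduce <- function(state, patches, cfg) {
  counts <- tabulate(state$patch, nbins = nrow(patches))
  lambda <- pmin(counts * cfg$fecundity, patches$K * cfg$fecundity)
  n_off <- rpois(nrow(patches), lambda)
  n_off[counts == 0] <- 0L
  M <- sum(n_off)
  L <- ncol(state$hap1)
  if (M == 0) return(list(hap1 = state$hap1[0, , drop = FALSE],
                          hap2 = state$hap2[0, , drop = FALSE],
                          patch = integer(0)))
  members <- split(seq_along(state$patch), factor(state$patch, seq_len(nrow(patches))))
  mothers <- fathers <- integer(M)
  pos <- 0L
  for (p in which(n_off > 0)) {
    idx <- members[[p]]
    mothers[pos + seq_len(n_off[p])] <- idx[sample.int(length(idx), n_off[p], replace = TRUE)]
    fathers[pos + seq_len(n_off[p])] <- idx[sample.int(length(idx), n_off[p], replace = TRUE)]
    pos <- pos + n_off[p]
  }
  # unlinked loci: a gamete allele is Bernoulli(parental dose / 2), which
  # is exactly Mendelian segregation without tracking parental phase
  G <- state$hap1 + state$hap2
  gamete <- function(par_idx) {
    p <- G[par_idx, , drop = FALSE] * 0.5
    h <- (runif(length(p)) < p) + 0L
    dim(h) <- dim(p)
    h
  }
  list(hap1 = gamete(mothers), hap2 = gamete(fathers),
       patch = rep(patches$patch, n_off))
}

# dispersal: one multinomial group-destination draw per offspring, then a
# within-group adjacent-patch kernel for the ones that stayed in group
sim_disperse <- function(off, patches, mig, cfg, open) {
  if (!length(off$patch)) return(off)
  grp <- patches$group[off$patch]
  gnames <- rownames(mig)
  u <- runif(length(off$patch))
  newpatch <- off$patch
  for (gi in gnames) {
    src <- which(grp == gi)
    if (!length(src)) next
    probs <- mig[gi, ]
    cum <- cumsum(probs)
    moved_to <- rep(NA_character_, length(src))
    for (j in seq_along(gnames)) {
      gj <- gnames[j]
      lowerb <- if (j == 1) 0 else cum[j - 1]
      sel <- u[src] >= lowerb & u[src] < cum[j]
      if (any(sel)) moved_to[sel] <- gj
    }
    for (gj in unique(moved_to[!is.na(moved_to)])) {
      dest_pool <- patches$patch[patches$group == gj & open]
      if (!length(dest_pool)) next
      movers <- src[!is.na(moved_to) & moved_to == gj]
      newpatch[movers] <- dest_pool[sample.int(length(dest_pool), length(movers), replace = TRUE)]
    }
  }
  # within-group kernel for non-movers
  stayed <- which(newpatch == off$patch)
  if (length(stayed)) {
    hop <- stayed[runif(length(stayed)) < cfg$m_within]
    if (length(hop)) {
      dir <- sample(c(-1L, 1L), length(hop), replace = TRUE)
      cand <- newpatch[hop] + dir
      okc <- cand >= 1 & cand <= nrow(patches) &
        patches$group[pmin(pmax(cand, 1), nrow(patches))] == grp[hop] &
        open[pmin(pmax(cand, 1), nrow(patches))]
      newpatch[hop[okc]] <- cand[okc]
    }
  }
  off$patch <- newpatch
  off
}

# density regulation: truncate each patch to K
sim_regulate <- function(off, patches) {
  if (!length(off$patch)) return(off)
  keep <- logical(length(off$patch))
  members <- split(seq_along(off$patch), factor(off$patch, patches$patch))
  for (p in seq_len(nrow(patches))) {
    idx <- members[[p]]
    Kp <- patches$K[p]
    if (length(idx) <= Kp) keep[idx] <- TRUE
    else keep[idx[sample.int(length(idx), Kp)]] <- TRUE
  }
  list(hap1 = off$hap1[keep, , drop = FALSE],
       hap2 = off$hap2[keep, , drop = FALSE],
       patch = off$patch[keep])
}

# export the current state as a genotype_matrix (loci x individuals)
state_to_genotypes <- function(state, patches) {
  N <- length(state$patch)
  L <- ncol(state$hap1)
  locus_ids <- sprintf("snp%05d", seq_len(L))
  ind_ids <- sprintf("ind%05d", seq_len(N))
  hapA <- t(state$hap1); hapB <- t(state$hap2)
  dimnames(hapA) <- dimnames(hapB) <- list(locus_ids, ind_ids)
  structure(list(
    geno = hapA + hapB, hapA = hapA, hapB = hapB,
    ind = data.frame(ind_id = ind_ids,
                     pop_id = sprintf("patch%02d", state$patch),
                     group = patches$group[state$patch],
                     distance_km = patches$position_km[state$patch],
                     stringsAsFactors = FALSE),
    loci = data.frame(locus_id = locus_ids,
                      pA = state$founder_freqs$pA, pB = state$founder_freqs$pB,
                      divergent = seq_len(L) %in% state$diagnostic,
                      stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

# hybrid-index per-patch summaries for cline tracking
track_summary <- function(state, patches, grid_step = 0.005) {
  dg <- state$diagnostic
  geno <- t(state$hap1[, dg, drop = FALSE] + state$hap2[, dg, drop = FALSE])
  hi <- hybrid_index(geno,
                     list(pA = state$founder_freqs$pA[dg],
                          pB = state$founder_freqs$pB[dg]),
                     grid_step = grid_step)
  df <- data.frame(patch = state$patch, h = hi$h)
  agg <- aggregate(h ~ patch, df, function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(patch = agg$patch,
                    distance_km = patches$position_km[agg$patch],
                    mean = agg$h[, "mean"],
                    sd = agg$h[, "sd"],
                    n = agg$h[, "n"])
  out$sd[is.na(out$sd)] <- 0
  out
}

#' Run one simulation scenario
#'
#' Advances the meta-population through Phases I-IV (see
#' [scenario_config()]). Each generation performs reproduction, dispersal
#' under the current phase's among-group matrix, and density regulation.
#' The Phase III regime begins only once every middle patch holds at least
#' `trigger_frac` of its carrying capacity (evaluated each generation after
#' the colonization phase; the switch happens once, permanently).
#' F-statistics are recorded every `snapshot_every` generations; per-patch
#' hybrid-index summaries at `track_schedule`; full genotype snapshots at
#' `store_genotypes_at`. Extinction of any group terminates the run early
#' with `extinct = TRUE`.
#'
#' @param cfg a [scenario_config()].
#' @return object of class `hzsim_run`: `cfg`, `patches`, `snapshots`
#'   (generation, phase, census, F_ST, F_CT), `track` (named list of
#'   per-patch hybrid summaries), `genotypes` (named list of
#'   [genotype_matrix] snapshots), `extinct`, `generations_run`,
#'   `phase_switch` (generation at which each phase began).
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  patches <- build_patches(cfg)
  state <- init_state(cfg, patches)
  pg <- unname(cfg$phase_gens[c("I", "II", "III", "IV")])
  total_max <- sum(pg) + 200L  # slack for the colonization trigger wait
  snapshots <- list(); track <- list(); genotypes <- list()
  phase <- "I"; phase_switch <- c(I = 1L)
  gens_in_phase <- 0L
  extinct <- FALSE
  hybrid_idx <- patches$group == "hybrid"
  gen <- 0L
  want <- sort(unique(c(cfg$track_schedule, cfg$store_genotypes_at)))
  take_snapshot <- function(gen, phase, state) {
    census <- length(state$patch)
    fs <- tryCatch(
      hierarchical_fstats(state_to_genotypes(state, patches)),
      error = function(e) list(F_ST = NA_real_, F_CT = NA_real_))
    data.frame(generation = gen, phase = phase, census = census,
               F_ST = fs$F_ST, F_CT = fs$F_CT, stringsAsFactors = FALSE)
  }
  snapshots[[length(snapshots) + 1L]] <- take_snapshot(0L, phase, state)
  repeat {
    gen <- gen + 1L
    open <- patches$K > 0 & (phase != "I" | !hybrid_idx)
    mig <- phase_matrix(cfg, phase)
    off <- sim_reproduce(state, patches, cfg)
    off <- sim_disperse(off, patches, mig, cfg, open)
    off <- sim_regulate(off, patches)
    off$founder_freqs <- state$founder_freqs
    off$diagnostic <- state$diagnostic
    state <- off
    gens_in_phase <- gens_in_phase + 1L
    # group extinction check
    census_group <- table(factor(patches$group[state$patch],
                                 c("speciesA", "hybrid", "speciesB")))
    if (census_group[["speciesA"]] == 0L || census_group[["speciesB"]] == 0L ||
        (phase %in% c("III", "IV") && census_group[["hybrid"]] == 0L)) {
      extinct <- TRUE
      snapshots[[length(snapshots) + 1L]] <- take_snapshot(gen, phase, state)
      warning(sprintf("group extinction at generation %d; run terminated", gen))
      break
    }
    # phase transitions
    if (phase == "I" && gens_in_phase >= pg[1]) {
      phase <- "II"; gens_in_phase <- 0L; phase_switch["II"] <- gen + 1L
    } else if (phase == "II" && gens_in_phase >= pg[2]) {
      hyb_counts <- tabulate(state$patch, nbins = nrow(patches))[hybrid_idx]
      if (all(hyb_counts >= cfg$trigger_frac * patches$K[hybrid_idx])) {
        phase <- "III"; gens_in_phase <- 0L; phase_switch["III"] <- gen + 1L
      }
    } else if (phase == "III" && gens_in_phase >= pg[3]) {
      phase <- "IV"; gens_in_phase <- 0L; phase_switch["IV"] <- gen + 1L
    }
    if (gen %% cfg$snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <- take_snapshot(gen, phase, state)
    }
    if (gen %in% cfg$track_schedule) {
      track[[as.character(gen)]] <- track_summary(state, patches)
    }
    if (gen %in% cfg$store_genotypes_at) {
      genotypes[[as.character(gen)]] <- state_to_genotypes(state, patches)
    }
    done <- phase == "IV" && gens_in_phase >= pg[4]
    if (done || gen >= total_max) break
  }
  if (gen %% cfg$snapshot_every != 0L && !extinct) {
    snapshots[[length(snapshots) + 1L]] <- take_snapshot(gen, phase, state)
  }
  structure(list(cfg = cfg, patches = patches,
                 snapshots = do.call(rbind, snapshots),
                 track = track, genotypes = genotypes,
                 extinct = extinct, generations_run = gen,
                 phase_switch = phase_switch, final_state = state),
            class = "hzsim_run")
}

#' @export
print.hzsim_run <- function(x, ...) {
  cat(sprintf("hzsim_run: model %s scenario %s, %d generations%s\n",
              x$cfg$model, x$cfg$scenario, x$generations_run,
              if (x$extinct) " (terminated: extinction)" else ""))
  invisible(x)
}

#' Track the fitted cline centre through time
#'
#' For each scheduled generation, fits a geographic cline (fixed 0/1
#' scaling, mirror tails by default) to the per-patch mean hybrid indices
#' recorded by [run_scenario()] and returns the centre MLE with its 2-LLU
#' interval. Non-converged fits are kept but flagged; fit failures are
#' recorded as missing.
#'
#' @param run an `hzsim_run` with recorded `track` summaries.
#' @param schedule generations to use (default: all recorded); requesting a
#'   generation that was not tracked is an error.
#' @param model cline model for the fits.
#' @param chain_len,burnin,n_chains,seed passed to [fit_cline_mcmc()].
#' @param sd_floor lower bound on per-patch SD of the hybrid index (fixed
#'   patches otherwise carry zero variance).
#' @return data frame: `generation`, `centre`, `lower`, `upper`,
#'   `converged`.
#' @export
track_cline_centre <- function(run, schedule = NULL,
                               model = cline_model("mirror", "fixed01"),
                               chain_len = 2000, burnin = 500, n_chains = 2,
                               seed = 1, sd_floor = 0.02) {
  stopifnot(inherits(run, "hzsim_run"))
  avail <- as.integer(names(run$track))
  if (is.null(schedule)) schedule <- avail
  if (!all(schedule %in% avail)) {
    abort("schedule requests generations that were not tracked during the run")
  }
  rows <- lapply(schedule, function(gen) {
    d <- run$track[[as.character(gen)]]
    d <- d[d$n >= 2, , drop = FALSE]
    d$sd <- pmax(d$sd, sd_floor)
    fit <- tryCatch(
      fit_cline_mcmc(d, type = "trait", model = model, chain_len = chain_len,
                     burnin = burnin, n_chains = n_chains,
                     seed = seed + gen, transect_length = run$cfg$extent_km,
                     profile_params = "centre"),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(generation = gen, centre = NA_real_, lower = NA_real_,
                        upper = NA_real_, converged = FALSE))
    }
    data.frame(generation = gen, centre = unname(fit$mle["centre"]),
               lower = fit$intervals$centre$lower,
               upper = fit$intervals$centre$upper,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Relative shift of a cline centre
#'
#' Percentage change in the cline centre relative to the total spatial
#' extent of the landscape; positive values point toward species B
#' (northward).
#'
#' @param centre_t,centre_ref centre at the focal and reference time (km).
#' @param landscape_extent total extent (km), must be > 0.
#' @export
relative_shift <- function(centre_t, centre_ref, landscape_extent) {
  if (any(landscape_extent <= 0)) abort("landscape extent must be > 0")
  100 * (centre_t - centre_ref) / landscape_extent
}
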