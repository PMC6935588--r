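## Pipeline orchestration: runs the stages in the study's order
## (transect -> diagnostic selection -> hybrid index -> geographic clines
## for traits, hybrid index and per-SNP frequencies -> genomic clines ->
## contingency -> LD variance partitioning), serialises every stage's
## outputs, and records a run manifest. A companion driver runs replicate
## simulation scenarios.

default_pipeline_params <- function() {
  list(diagnostic_quantile = 0.90,
       chain_len = 3000, burnin = 800, n_chains = 2,
       trait_tail_modes = TAIL_MODES,
       snp_models = list(cline_model("none", "fixed01")),
       q_model = cline_model("mirror", "fixed01"),
       max_snps = Inf,
       genocline_steps = 3000, genocline_burnin = 800,
       ohta_set_size = 4, ohta_overlap = 1, ohta_max_pairs = 20000,
       ohta_bootstrap_sets = 0,
       alpha_classes = NULL,
       hybrid_index_loci = "all", hybrid_index_grid = 0.005,
       q_sd_floor = 0.05)
}

#' Run the full hybrid-zone movement pipeline
#'
#' Executes, on synthetic or supplied data: transect construction,
#' diagnostic-SNP selection, hybrid-index estimation, geographic cline
#' fits (two traits, the hybrid index, and each diagnostic SNP), genomic
#' clines over hybrid-zone individuals, the geographic x genomic
#' contingency analysis, and the within/among-population LD profile.
#' All stage outputs are written under `out_dir` together with a JSON
#' manifest (package version, seed, parameters, files). Rerunning with
#' the same seed and inputs reproduces every numeric output.
#'
#' @param spec a [synthetic_spec()]; when supplied, genotypes, populations
#'   and traits are generated (and `geno`/`pops`/`traits` must be NULL).
#' @param geno,pops,traits real inputs: a [genotype_matrix], population
#'   table with coordinates and `group`, and trait summary table.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @param seed seed governing every stochastic stage.
#' @param params named list overriding entries of the default stage
#'   parameters (chain lengths, model families, subsampling caps, ...).
#' @param stages character subset of
#'   `c("traits", "snps", "genomic", "contingency", "ohta")` to run after
#'   the always-on transect/diagnostic/hybrid-index stages.
#' @return list with every stage's result (`pops`, `geno`, `traits`,
#'   `diagnostic`, `hybrid_index`, `q_fit`, `trait_fits`, `snp_fits`,
#'   `genomic`, `classification`, `contingency`, `ohta`, `manifest`).
#' @export
run_pipeline <- function(spec = NULL, geno = NULL, pops = NULL, traits = NULL,
                         out_dir = NULL, seed = 1,
                         params = list(),
                         stages = c("traits", "snps", "genomic",
                                    "contingency", "ohta")) {
  prm <- utils::modifyList(default_pipeline_params(), params)
  if (is.null(spec) && (is.null(geno) || is.null(pops))) {
    abort("either a synthetic spec or genotype + population inputs are required")
  }
  if (!is.null(spec)) {
    spec$seed <- seed
    pops <- generate_landscape(spec)
    geno <- generate_genotypes(spec, pops)
    traits <- generate_traits(spec, pops)
  } else {
    if (is.null(pops$distance_km)) pops <- great_circle_distances(pops)
    if ("traits" %in% stages && is.null(traits)) {
      abort("trait stage enabled but no trait table supplied")
    }
  }
  files <- character(0)
  emit <- function(obj, name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, name)
    writer(obj, p)
    files[[length(files) + 1L]] <<- p
  }
  emit(pops, "populations.csv", write_populations_csv)
  emit(geno, "genotypes.tsv", write_genotypes_tsv)
  if (!is.null(traits)) emit(traits, "traits.csv", write_traits_csv)

  ## transect stage: parental frequencies and diagnostic SNPs
  gf <- group_allele_freqs(geno)
  diag_set <- select_diagnostic(setNames(gf[, "speciesA"], rownames(gf)),
                                setNames(gf[, "speciesB"], rownames(gf)),
                                quantile = prm$diagnostic_quantile)
  emit(diag_set, "diagnostic.tsv", write_diagnostic_tsv)

  ## orient doses to the species-B allele for cline work
  geno_or <- orient_to_speciesB(geno, gf[, "speciesA"], gf[, "speciesB"])
  gf_or <- group_allele_freqs(geno_or)

  ## hybrid index: genome-wide by default (all loci with defined parental
  ## frequencies), mirroring global admixture coefficients; diagnostic-only
  ## as an option
  dloci <- diag_set$loci
  hloci <- if (identical(prm$hybrid_index_loci, "diagnostic")) dloci else {
    rownames(gf_or)[!is.na(gf_or[, "speciesA"]) & !is.na(gf_or[, "speciesB"]) &
                      abs(gf_or[, "speciesA"] - gf_or[, "speciesB"]) > 1e-8]
  }
  pf <- list(pA = gf_or[hloci, "speciesA"], pB = gf_or[hloci, "speciesB"])
  hi <- hybrid_index(geno_or, pf, loci = hloci,
                     grid_step = prm$hybrid_index_grid)
  hi$pop_id <- geno$ind$pop_id[match(hi$ind_id, geno$ind$ind_id)]
  emit(hi, "hybrid_index.tsv",
       function(o, p) write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## hybrid-index (Q-score analogue) geographic cline
  hsum <- aggregate(h ~ pop_id, hi, function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  qdat <- data.frame(pop_id = hsum$pop_id,
                     distance_km = pops$distance_km[match(hsum$pop_id, pops$pop_id)],
                     mean = hsum$h[, "mean"],
                     sd = pmax(hsum$h[, "sd"], prm$q_sd_floor, na.rm = TRUE),
                     n = hsum$h[, "n"])
  qdat$sd[is.na(qdat$sd)] <- prm$q_sd_floor
  L_tr <- max(pops$distance_km)
  q_fit <- fit_cline_mcmc(qdat, type = "trait", model = prm$q_model,
                          chain_len = prm$chain_len, burnin = prm$burnin,
                          n_chains = prm$n_chains, seed = seed + 10L,
                          transect_length = L_tr, profile_params = "centre")

  out <- list(pops = pops, geno = geno, traits = traits,
              diagnostic = diag_set, hybrid_index = hi, q_fit = q_fit,
              transect_length = L_tr)

  ## trait clines
  if ("traits" %in% stages && !is.null(traits)) {
    trait_fits <- list()
    for (tr in unique(traits$trait)) {
      d <- traits[traits$trait == tr, ]
      trait_fits[[tr]] <- fit_geocline(
        d, type = "trait",
        models = lapply(prm$trait_tail_modes, function(tm) cline_model(tm, "estimated")),
        chain_len = prm$chain_len, burnin = prm$burnin, n_chains = prm$n_chains,
        seed = seed + 20L, transect_length = L_tr, profile_params = "centre")
    }
    out$trait_fits <- trait_fits
  }

  ## per-SNP geographic clines
  if ("snps" %in% stages) {
    snps <- head(dloci, prm$max_snps)
    rows <- vector("list", length(snps))
    for (i in seq_along(snps)) {
      d <- freq_cline_data(geno_or, pops, snps[i])
      sel <- fit_geocline(d, type = "freq", models = prm$snp_models,
                          include_null = TRUE, chain_len = prm$chain_len,
                          burnin = prm$burnin, n_chains = prm$n_chains,
                          seed = seed + 100L + i, transect_length = L_tr,
                          profile_params = "centre")
      rows[[i]] <- data.frame(
        locus = snps[i], is_null = sel$is_null,
        centre = if (sel$is_null) NA_real_ else unname(sel$best$mle["centre"]),
        lower = if (sel$is_null) NA_real_ else sel$best$intervals$centre$lower,
        upper = if (sel$is_null) NA_real_ else sel$best$intervals$centre$upper,
        converged = sel$best$converged, stringsAsFactors = FALSE)
    }
    out$snp_fits <- do.call(rbind, rows)
    emit(out$snp_fits, "snp_clines.tsv",
         function(o, p) write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## genomic clines over hybrid-zone individuals
  if ("genomic" %in% stages) {
    hz_ind <- geno$ind$ind_id[geno$ind$group == "hybrid"]
    snps <- head(dloci, prm$max_snps)
    gc <- genomic_clines(geno_or, hi, loci = snps, individuals = hz_ind,
                         seed = seed + 1000L,
                         n_steps = prm$genocline_steps,
                         burnin = prm$genocline_burnin)
    out$genomic <- gc
    emit(gc, "genomic_clines.tsv",
         function(o, p) write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## contingency analysis
  if ("contingency" %in% stages && !is.null(out$snp_fits) &&
      !is.null(out$trait_fits) &&
      (!is.null(out$genomic) || !is.null(prm$alpha_classes))) {
    q_iv <- c(q_fit$intervals$centre$lower, q_fit$intervals$centre$upper)
    m_centres <- vapply(out$trait_fits, function(f) unname(f$best$mle["centre"]), 0)
    m_ivs <- lapply(out$trait_fits, function(f)
      c(f$best$intervals$centre$lower, f$best$intervals$centre$upper))
    cl <- classify_geo(out$snp_fits, unname(q_fit$mle["centre"]), q_iv,
                       m_centres, m_ivs, L_tr)
    # outlier classes: estimated in the genomic stage, or imported calls
    # (e.g. from an earlier genomic-cline study) supplied by the caller
    cl$outlier_class <- if (!is.null(prm$alpha_classes)) {
      unname(prm$alpha_classes[cl$locus])
    } else {
      out$genomic$outlier_class[match(cl$locus, out$genomic$locus)]
    }
    out$classification <- cl
    tab <- tryCatch(build_table(cl), error = function(e) NULL)
    out$contingency <- if (!is.null(tab)) {
      list(table = tab,
           test = tryCatch(chisq_with_contributions(tab), error = function(e) NULL))
    }
    emit(cl, "snp_classification.tsv",
         function(o, p) write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## Ohta D profile along the transect
  if ("ohta" %in% stages && !is.null(geno$hapA)) {
    sets <- window_sets(pops, prm$ohta_set_size, prm$ohta_overlap)
    out$ohta <- dis_dst_profile(geno, pops, sets, dloci,
                                max_pairs = prm$ohta_max_pairs,
                                seed = seed + 2000L)
    if (prm$ohta_bootstrap_sets > 0) {
      neutral <- setdiff(rownames(geno$geno), dloci)
      out$ohta_bootstrap <- bootstrap_neutral(
        geno, pops, sets, neutral, n_sets = prm$ohta_bootstrap_sets,
        max_pairs = prm$ohta_max_pairs, seed = seed + 3000L)
    }
    emit(out$ohta, "ohta_profile.tsv",
         function(o, p) write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  out$manifest <- list(
    package = "hzmove",
    version = as.character(utils::packageVersion("hzmove")),
    r_version = R.version.string,
    seed = seed,
    params = prm[setdiff(names(prm), c("snp_models", "q_model"))],
    stages = stages,
    synthetic = !is.null(spec),
    files = unname(unlist(files)))
  if (!is.null(out_dir)) {
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  }
  out
}

VALID_SCENARIOS <- c("A.i", "A.ii", "B.i", "B.ii", "B.iii")

#' Run replicate simulation runs of one scenario
#'
#' Parses a scenario id (`"A.i"`, `"A.ii"`, `"B.i"`, `"B.ii"`, `"B.iii"`),
#' runs `n_replicates` independent runs (replicate `r` uses seed
#' `seed + r`), and aggregates the per-generation F-statistics (and, when a
#' tracking schedule is configured, the fitted cline centres) across
#' replicates as mean and standard error.
#'
#' @param scenario_id one of `"A.i"`, `"A.ii"`, `"B.i"`, `"B.ii"`,
#'   `"B.iii"`.
#' @param n_replicates replicate count (default from the config, 12).
#' @param cfg base [scenario_config()]; its model/scenario fields are set
#'   from `scenario_id`.
#' @param seed base seed.
#' @param out_dir optional directory for per-replicate and aggregate TSVs.
#' @return list with `runs` (list of `hzsim_run`), `summary` (per
#'   generation: mean and SE of F_ST and F_CT across replicates), and
#'   `centres` (per tracked generation: mean and SE of the fitted centre),
#'   or NULL when no schedule was set.
#' @export
simulate_scenario <- function(scenario_id, n_replicates = NULL, cfg = NULL,
                              seed = 1, out_dir = NULL) {
  if (!scenario_id %in% VALID_SCENARIOS) {
    abort(sprintf("unknown scenario '%s'; valid: %s", scenario_id,
                  paste(VALID_SCENARIOS, collapse = ", ")))
  }
  parts <- strsplit(scenario_id, ".", fixed = TRUE)[[1]]
  if (is.null(cfg)) cfg <- scenario_config(model = parts[1], scenario = parts[2])
  else { cfg$model <- parts[1]; cfg$scenario <- parts[2] }
  if (parts[2] == "iii" && parts[1] != "B") abort("scenario iii requires model B")
  if (is.null(n_replicates)) n_replicates <- cfg$n_replicates
  runs <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- seed + r
    runs[[r]] <- run_scenario(cfg_r)
  }
  snaps <- do.call(rbind, lapply(seq_along(runs), function(r) {
    s <- runs[[r]]$snapshots; s$replicate <- r; s
  }))
  agg <- aggregate(cbind(F_ST, F_CT) ~ generation, snaps, function(v) {
    c(mean = mean(v, na.rm = TRUE),
      se = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  })
  summary <- do.call(data.frame, agg)
  centres <- NULL
  if (length(cfg$track_schedule)) {
    ctr <- do.call(rbind, lapply(seq_along(runs), function(r) {
      d <- track_cline_centre(runs[[r]], seed = seed + 500L + r)
      d$replicate <- r; d
    }))
    cagg <- aggregate(centre ~ generation, ctr, function(v) {
      c(mean = mean(v, na.rm = TRUE),
        se = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
    })
    centres <- list(per_replicate = ctr, summary = do.call(data.frame, cagg))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(snaps, file.path(out_dir, sprintf("%s_snapshots.tsv", scenario_id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(out_dir, sprintf("%s_summary.tsv", scenario_id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(centres)) {
      write.table(centres$per_replicate,
                  file.path(out_dir, sprintf("%s_centres.tsv", scenario_id)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(scenario = scenario_id, runs = runs, summary = summary, centres = centres)
}
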