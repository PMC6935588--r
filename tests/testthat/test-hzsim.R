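# a deliberately small configuration for fast structural checks
small_cfg <- function(seed = 1, ...) {
  scenario_config(model = "B", scenario = "ii",
                  n_patches = c(speciesA = 3, hybrid = 3, speciesB = 3),
                  K = c(speciesA = 20, hybrid = 15, speciesB = 20),
                  phase_gens = c(I = 10, II = 5, III = 15, IV = 10),
                  n_loci = 30, n_diagnostic = 20, snapshot_every = 10,
                  extent_km = 400, seed = seed, ...)
}

test_that("scenario configuration is validated", {
  expect_error(scenario_config(model = "A", scenario = "iii"), "model B")
  expect_error(scenario_config(m_among = 1.5), "probabilities")
  expect_s3_class(scenario_config(model = "B", scenario = "iii"),
                  "scenario_config")
})

test_that("phase regimes wire the dispersal matrices as designed", {
  cfgA <- small_cfg(); cfgA$model <- "A"; cfgA$scenario <- "i"
  mI <- hzmove:::phase_matrix(cfgA, "I")
  expect_true(all(mI == 0))  # secondary contact: divergence in isolation
  cfgB <- small_cfg(); cfgB$scenario <- "i"
  expect_gt(hzmove:::phase_matrix(cfgB, "I")["speciesA", "speciesB"], 0)
  mIII <- hzmove:::phase_matrix(cfgB, "III")
  expect_equal(mIII["speciesA", "hybrid"], cfgB$m_among)
  expect_equal(mIII["hybrid", "speciesB"], cfgB$m_among)
  cfgB$scenario <- "ii"
  mIII2 <- hzmove:::phase_matrix(cfgB, "III")
  expect_equal(mIII2["speciesA", "hybrid"], 0)
  expect_equal(mIII2["hybrid", "speciesB"], cfgB$m_among)
  cfgB$scenario <- "iii"
  expect_equal(hzmove:::phase_matrix(cfgB, "III")["speciesA", "hybrid"],
               cfgB$m_among / 2)
  mIV <- hzmove:::phase_matrix(cfgB, "IV")
  expect_equal(mIV["speciesA", "hybrid"], 0)
  expect_equal(mIV["hybrid", "speciesB"], cfgB$m_among)
})

test_that("dispersal conserves individuals and regulation enforces K", {
  cfg <- small_cfg()
  set.seed(3)
  patches <- hzmove:::build_patches(cfg)
  state <- hzmove:::init_state(cfg, patches)
  off <- hzmove:::sim_reproduce(state, patches, cfg)
  n_before <- length(off$patch)
  moved <- hzmove:::sim_disperse(off, patches, hzmove:::phase_matrix(cfg, "III"),
                                 cfg, open = rep(TRUE, nrow(patches)))
  expect_equal(length(moved$patch), n_before)
  expect_equal(nrow(moved$hap1), n_before)
  # alleles are relocated, never created or destroyed
  expect_equal(sum(moved$hap1) + sum(moved$hap2),
               sum(off$hap1) + sum(off$hap2))
  reg <- hzmove:::sim_regulate(moved, patches)
  counts <- tabulate(reg$patch, nrow(patches))
  expect_true(all(counts <= patches$K))
})

test_that("runs are bit-identical under a fixed seed and respect capacity", {
  r1 <- run_scenario(small_cfg())
  r2 <- run_scenario(small_cfg())
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$final_state$hap1, r2$final_state$hap1)
  expect_true(all(r1$snapshots$census <= sum(hzmove:::build_patches(small_cfg())$K)))
  r3 <- run_scenario(small_cfg(seed = 2))
  expect_false(identical(r1$final_state$hap1, r3$final_state$hap1))
})

test_that("hierarchical F-statistics solve the degenerate structures", {
  pop <- rep(paste0("p", 1:4), each = 10)
  grp <- rep(c("g1", "g2"), each = 20)
  set.seed(8)
  geno <- matrix(rbinom(30 * 40, 2, 0.5), 30, 40)
  # monomorphic data: statistics undefined and flagged
  mono <- matrix(2L, 5, 40)
  expect_true(hierarchical_fstats(mono + 0, pop, grp)$undefined)
  expect_true(is.na(hierarchical_fstats(mono + 0, pop, grp)$F_CT))
  # identical allele frequencies everywhere: both statistics near zero
  het <- matrix(1L, 5, 40)  # every population at frequency 0.5 exactly
  fs0 <- hierarchical_fstats(het + 0, pop, grp)
  expect_equal(fs0$F_CT, 0, tolerance = 1e-12)
  expect_equal(fs0$F_ST, 0, tolerance = 1e-12)
  # groups fixed for alternative alleles, pops identical within groups
  fixed <- rbind(matrix(rep(c(0L, 2L), each = 20), 1, byrow = FALSE))
  fixed <- matrix(rep(c(rep(0L, 20), rep(2L, 20)), 10), 10, 40, byrow = TRUE)
  fs <- hierarchical_fstats(fixed, pop, grp)
  expect_equal(fs$F_CT, 1, tolerance = 1e-12)
  expect_error(hierarchical_fstats(geno, pop, rep("g", 40)), ">= 2 groups")
  expect_error(hierarchical_fstats(geno, rep(c("a", "b"), 20), grp),
               "more than one group")
})

test_that("variance components match the raw-allele nested ANOVA oracle", {
  set.seed(15)
  pop <- rep(paste0("p", 1:12), times = sample(4:9, 12, replace = TRUE))
  grp <- c("g1", "g2", "g3")[as.integer(factor(pop)) %% 3 + 1]
  N <- length(pop)
  geno <- matrix(rbinom(50 * N, 2, runif(50, 0.2, 0.8)), 50, N)
  fs <- hierarchical_fstats(geno, pop, grp)
  tot <- c(sa = 0, sb = 0, sw = 0)
  for (l in 1:50) {
    # expand genotypes into two 0/1 allele indicators per individual
    alleles <- unlist(lapply(seq_len(N), function(i) {
      g <- geno[l, i]
      c(as.integer(g >= 1), as.integer(g == 2))
    }))
    tot <- tot + slow_varcomp(alleles, rep(pop, each = 2), rep(grp, each = 2))
  }
  expect_equal(fs$sigma2_groups, unname(tot["sa"]), tolerance = 1e-8)
  expect_equal(fs$sigma2_pops, unname(tot["sb"]), tolerance = 1e-8)
  expect_equal(fs$sigma2_within, unname(tot["sw"]), tolerance = 1e-8)
  tt <- pmax(tot, 0)  # ratio convention: negative components truncated
  expect_equal(fs$F_CT, unname(tt["sa"] / sum(tt)), tolerance = 1e-8)
})

test_that("cline tracking errors on unscheduled generations", {
  cfg <- small_cfg(track_schedule = c(30L))
  run <- run_scenario(cfg)
  expect_error(track_cline_centre(run, schedule = 999), "not tracked")
  ctr <- track_cline_centre(run, chain_len = 500, burnin = 100, seed = 2)
  expect_equal(ctr$generation, 30L)
  expect_true(is.finite(ctr$centre) || is.na(ctr$centre))
})

test_that("relative shift is the signed percentage of the extent", {
  expect_equal(relative_shift(50, 40, 100), 10)
  expect_equal(relative_shift(40, 40, 100), 0)
  expect_equal(relative_shift(140, 40, 100), 100)
  expect_equal(relative_shift(30, 40, 100), -10)
  expect_error(relative_shift(1, 2, 0), "extent")
})
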