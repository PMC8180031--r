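# Grid metadata + table for hand-built series: one site/location, values
# supplied per timepoint (NA = missing sample). The filler species is the
# complement to a fixed total, so closure rescales the target by an exact
# constant (1/10) and its temporal pattern is preserved exactly.
series_fixture <- function(values, site = "left_palm", location = 1L) {
  present <- !is.na(values)
  tps <- which(present) - 1L
  ids <- sprintf("t%02d", tps)
  md <- data.frame(
    sample_id = ids, location = location, site = site,
    day = tps %/% 2 + 1L, period = ifelse(tps %% 2 == 0, "AM", "PM"),
    stringsAsFactors = FALSE
  )
  tv <- values[present]
  stopifnot(all(tv < 1000))
  v <- cbind(tv, 1000 - tv)
  rownames(v) <- ids
  colnames(v) <- c("k__B|p__P|f__F1|s__Target", "k__B|p__P|f__F2|s__Filler")
  list(table = abundance_table(v),
       metadata = skintrace:::validate_metadata(md))
}

test_that("presence filter, trimming and gap interpolation behave", {
  vals <- rep(0, 20); vals[c(2, 7, 12)] <- 5
  fx <- series_fixture(vals)
  expect_error(
    prepare_series(fx$table, fx$metadata, colnames(fx$table$values)[1],
                   "left_palm", 1),
    class = "skintrace_excluded"
  )

  vals2 <- rep(c(1, 3), 10)
  fx2 <- series_fixture(vals2)
  ser <- prepare_series(fx2$table, fx2$metadata,
                        colnames(fx2$table$values)[1], "left_palm", 1)
  expect_length(ser$values, 20L)
  expect_identical(ser$values, ser$observed)

  # internal gap in a perfectly alternating series is restored exactly
  vals3 <- rep(c(1, 3), 10); vals3[9] <- NA
  fx3 <- series_fixture(vals3)
  ser3 <- prepare_series(fx3$table, fx3$metadata,
                         colnames(fx3$table$values)[1], "left_palm", 1)
  scaled <- ser3$values / ser3$values[1]
  expect_equal(scaled, rep(c(1, 3), 10), tolerance = 1e-9)

  # leading missing slots are trimmed, not imputed
  vals4 <- rep(c(1, 3), 10); vals4[1:2] <- NA
  fx4 <- series_fixture(vals4)
  ser4 <- prepare_series(fx4$table, fx4$metadata,
                         colnames(fx4$table$values)[1], "left_palm", 1)
  expect_length(ser4$values, 18L)
  expect_equal(ser4$timepoints[1], 2L)
})

test_that("decomposition matches hand evaluation and stats::decompose", {
  d <- decompose_series(rep(7, 20))
  expect_equal(d$trend[2:19], rep(7, 18))
  expect_equal(d$seasonal, rep(0, 20))
  expect_equal(d$random[2:19], rep(0, 18))

  d2 <- decompose_series(rep(c(1, 3), 10))
  expect_equal(d2$trend[2:19], rep(2, 18))
  expect_equal(d2$seasonal, rep(c(-1, 1), 10))
  expect_equal(d2$random[2:19], rep(0, 18))

  set.seed(11)
  for (i in 1:20) {
    x <- exp(rnorm(20, 0, 0.5))
    mine <- decompose_series(x)
    ref <- stats::decompose(stats::ts(x, frequency = 2))
    expect_equal(mine$trend, as.numeric(ref$trend), tolerance = 1e-12)
    expect_equal(mine$seasonal, as.numeric(ref$seasonal),
                 tolerance = 1e-12)
    expect_equal(mine$random, as.numeric(ref$random), tolerance = 1e-12)
    # additivity and centering invariants
    ok <- !is.na(mine$trend)
    expect_equal(mine$trend[ok] + mine$seasonal[ok] + mine$random[ok],
                 x[ok], tolerance = 1e-9)
    expect_equal(sum(mine$figure), 0, tolerance = 1e-12)
  }
  expect_error(decompose_series(c(1, 2, 3)), "length >= 4")
})

test_that("seasonality strength follows the variance-ratio formula", {
  # S+R = (-1,1,-1,1), R = (-0.1,0.1,-0.1,0.1): 1 - Var(R)/Var(S+R) = 0.99
  dec <- list(trend = rep(0, 4), seasonal = c(-0.9, 0.9, -0.9, 0.9),
              random = c(-0.1, 0.1, -0.1, 0.1))
  expect_equal(seasonality_strength(dec), 0.99, tolerance = 1e-12)

  pure <- decompose_series(rep(c(1, 3), 10))
  expect_equal(seasonality_strength(pure), 1)

  noise_only <- list(trend = rep(0, 6), seasonal = rep(0, 6),
                     random = c(0.3, -0.2, 0.5, 0.1, -0.4, -0.3))
  expect_equal(seasonality_strength(noise_only), 0)

  zero_var <- list(trend = rep(0, 4), seasonal = rep(0, 4),
                   random = rep(0, 4))
  expect_equal(seasonality_strength(zero_var), 0)

  set.seed(12)
  for (i in 1:10) {
    x <- exp(rnorm(20, 0, 0.4))
    fs <- seasonality_strength(decompose_series(x))
    expect_gte(fs, 0); expect_lte(fs, 1)
    # invariant to adding a constant
    expect_equal(seasonality_strength(decompose_series(x + 50)), fs,
                 tolerance = 1e-9)
    expect_equal(skintrace:::fs_stat(x), fs, tolerance = 1e-14)
  }
  # a pure linear ramp has no 1-day seasonality
  expect_lt(seasonality_strength(decompose_series(seq(1, 20))), 1e-9)
})

test_that("permutation test: maximal statistic, determinism, degeneracy", {
  x <- rep(c(1, 3), 10)
  pt <- permutation_test(x, n_permutations = 199, seed = 1)
  expect_equal(pt$f_s, 1)
  expect_equal(pt$p, 0)

  y <- null_series(20, 0.3, seed = 3)
  p1 <- permutation_test(y, 199, seed = 5)
  p2 <- permutation_test(y, 199, seed = 5)
  expect_identical(p1$p, p2$p)

  const <- permutation_test(rep(4, 20), 199, seed = 1)
  expect_equal(const$p, 1)
  expect_true(const$degenerate)
  expect_error(permutation_test(x, n_permutations = 50), ">= 99")
})

test_that("planted diurnal species are recovered with their peak period", {
  sim <- full_grid_sim(diurnal_amplitude = 3, noise_sd = 0.2, seed = 11)
  tr <- sim$truth$diurnal_species
  tr1 <- tr[tr$location == 1, ]
  det <- detect_diurnal(sim$table, sim$metadata,
                        species = unique(tr1$species), locations = 1,
                        n_permutations = 199, seed = 7)
  key <- paste(det$catalog$species, det$catalog$site,
               det$catalog$location)
  hit <- match(paste(tr1$species, tr1$site, tr1$location), key)
  planted <- det$catalog[hit[!is.na(hit)], ]
  truth <- tr1[!is.na(hit), ]
  expect_gte(mean(planted$significant), 0.9)
  rec <- planted$significant
  expect_true(all(planted$peak_period[rec] == truth$peak_period[rec]))
  # summaries account for every tested series
  expect_equal(sum(det$summary$n_tested), nrow(det$catalog))
  expect_equal(sum(det$summary$n_significant),
               sum(det$catalog$significant))
})

test_that("without planted effects the detection rate is near alpha", {
  # a true null needs dispersal off too: PM public pickup and overnight
  # normalisation give skin communities a genuine 12 h rhythm
  sim <- full_grid_sim(diurnal_amplitude = 1,
                       dispersal_mix_public_to_skin = 0,
                       mix_skin_to_household = 0, seed = 13)
  set.seed(14)
  sp <- sample(colnames(sim$table$values), 30)
  det <- detect_diurnal(sim$table, sim$metadata, species = sp,
                        sites = c("left_palm", "door_knob"),
                        locations = c(1, 3), n_permutations = 199,
                        seed = 15)
  n <- nrow(det$catalog)
  rate <- mean(det$catalog$significant)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("paired signed-rank alternative is exact and flags degeneracy", {
  vals <- rep(c(3, 1), 10)  # AM always above PM, every day
  fx <- series_fixture(vals)
  ser <- prepare_series(fx$table, fx$metadata,
                        colnames(fx$table$values)[1], "left_palm", 1)
  mw <- mann_whitney_alternative(ser)
  expect_equal(mw$n_pairs, 10L)
  expect_equal(mw$p, 2 / 2^10, tolerance = 1e-12)

  flat <- series_fixture(rep(5, 20))
  serf <- prepare_series(flat$table, flat$metadata,
                         colnames(flat$table$values)[1], "left_palm", 1)
  mwf <- mann_whitney_alternative(serf)
  expect_true(mwf$degenerate)
  expect_equal(mwf$p, 1)
})

test_that("permutation and signed-rank methods mostly agree on planted species", {
  sim <- full_grid_sim(diurnal_amplitude = 3, noise_sd = 0.2, seed = 11)
  tr <- sim$truth$diurnal_species
  tr1 <- tr[tr$location %in% 1:2 & tr$site == "left_palm", ]
  both <- 0L; either <- 0L
  for (i in seq_len(nrow(tr1))) {
    ser <- tryCatch(
      prepare_series(sim$table, sim$metadata, tr1$species[i],
                     tr1$site[i], tr1$location[i]),
      error = function(e) NULL
    )
    if (is.null(ser)) next
    p_perm <- permutation_test(ser, 199, seed = 100 + i)$p
    p_mw <- mann_whitney_alternative(ser)$p
    sig <- c(p_perm < 0.05, p_mw < 0.05)
    if (any(sig)) either <- either + 1L
    if (all(sig)) both <- both + 1L
  }
  expect_gt(both / either, 0.5)
})

test_that("negative-control removal re-analysis accounts for the catalog", {
  sim <- full_grid_sim(diurnal_amplitude = 3, noise_sd = 0.2, seed = 11)
  tr <- sim$truth$diurnal_species
  tr1 <- tr[tr$location == 2 & tr$site == "door_knob", ]
  sp <- unique(tr1$species)

  unchanged <- control_species_reanalysis(
    sim$table, sim$metadata, character(0), species = sp,
    sites = "door_knob", locations = 2, n_permutations = 199, seed = 3
  )
  expect_identical(unchanged$before$catalog, unchanged$after$catalog)
  expect_equal(unchanged$delta$n_removed, 0L)

  all_removed <- control_species_reanalysis(
    sim$table, sim$metadata, sp, species = sp,
    sites = "door_knob", locations = 2, n_permutations = 199, seed = 3
  )
  expect_equal(all_removed$delta$n_removed,
               sum(all_removed$before$catalog$significant))
  expect_equal(all_removed$delta$n_retained, 0L)
  expect_equal(
    all_removed$delta$n_removed + all_removed$delta$n_lost +
      all_removed$delta$n_retained,
    sum(all_removed$before$catalog$significant)
  )
})

test_that("a single diurnal species induces antiphase that removal dispels", {
  # two-species closure scenario: A has a genuine diurnal cycle, B is
  # constant in absolute terms; closure makes B's relative abundance
  # alternate in antiphase with A
  a_abs <- rep(c(60, 20), 10)  # peaks AM
  b_abs <- rep(40, 20)
  v <- cbind(a_abs, b_abs)
  v <- 100 * v / rowSums(v)
  rownames(v) <- sprintf("t%02d", 0:19)
  colnames(v) <- c("k__B|p__P|f__F1|s__A", "k__B|p__P|f__F2|s__B")
  md <- data.frame(
    sample_id = rownames(v), location = 1L, site = "door_knob",
    day = 0:19 %/% 2 + 1L, period = rep(c("AM", "PM"), 10),
    stringsAsFactors = FALSE
  )
  tab <- abundance_table(v)
  md <- skintrace:::validate_metadata(md)

  re <- compositional_reanalysis(
    tab, md, "door_knob", 1, "k__B|p__P|f__F1|s__A",
    n_permutations = 199, seed = 9
  )
  b_before <- re$before[re$before$species == "k__B|p__P|f__F2|s__B", ]
  expect_true(b_before$significant)     # induced antiphase
  expect_equal(b_before$peak_period, "PM")
  b_after <- re$after[re$after$species == "k__B|p__P|f__F2|s__B", ]
  expect_false(b_after$significant)     # artefact gone after removal
  expect_true("k__B|p__P|f__F2|s__B" %in% re$changed)
})

test_that("removal and renormalisation round-trips algebraically", {
  sim <- full_grid_sim(seed = 2)
  vals <- sim$table$values
  sp <- colnames(vals)[7]
  reduced <- vals[, setdiff(colnames(vals), sp), drop = FALSE]
  renorm <- 100 * reduced / rowSums(reduced)
  # undo: re-add the removed column and rescale
  back <- renorm * (100 - vals[, sp]) / 100
  restored <- cbind(back, vals[, sp, drop = FALSE])
  restored <- restored[, colnames(vals)]
  expect_equal(restored, vals, tolerance = 1e-9)
})

test_that("diurnal species are detectably more abundant when planted so", {
  sim <- full_grid_sim(diurnal_amplitude = 3, noise_sd = 0.2, seed = 11)
  tr <- sim$truth$diurnal_species
  tr1 <- tr[tr$location == 1 & tr$site == "left_palm", ]
  # compare planted (diurnal) against a random non-planted background
  set.seed(21)
  background <- sample(setdiff(colnames(sim$table$values), tr$species), 20)
  det <- detect_diurnal(sim$table, sim$metadata,
                        species = c(unique(tr1$species), background),
                        sites = "left_palm", locations = 1,
                        n_permutations = 199, seed = 22)
  res <- diurnal_vs_nondiurnal_abundance(det$catalog, sim$table,
                                         sim$metadata)
  expect_true(is.finite(res$U))
  expect_true(res$p >= 0 && res$p <= 1)
  expect_true(is.finite(res$mean_diurnal))
  expect_true(is.finite(res$mean_nondiurnal))
})
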