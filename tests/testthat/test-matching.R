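test_that("reference pools follow the per-person eligibility rule", {
  sim <- full_grid_sim(seed = 2)
  pools <- build_reference_pools(sim$metadata)
  expect_length(pools, 20L)
  for (p in pools) {
    expect_setequal(names(p$members), as.character(1:4))
    expect_true(all(lengths(p$members) == 2L))
  }

  # person 2 loses both palms at timepoint 7 -> that pool is excluded
  md <- sim$metadata
  drop <- md$location == 2 & md$site_class == "skin" & md$timepoint == 7
  expect_message(pools19 <- build_reference_pools(md[!drop, ]),
                 "excluding timepoint 7")
  expect_length(pools19, 19L)

  # losing one palm only keeps the pool, with 1 sample for that person
  drop1 <- md$location == 2 & md$site == "left_palm" & md$timepoint == 7
  pools20 <- build_reference_pools(md[!drop1, ])
  expect_length(pools20, 20L)
  p7 <- pools20[[which(vapply(pools20, `[[`, 0L, "timepoint") == 7)]]
  expect_length(p7$members[["2"]], 1L)
  expect_true(all(lengths(p7$members[c("1", "3", "4")]) == 2L))
})

test_that("match_query finds an identical reference and breaks ties low", {
  sim <- full_grid_sim(seed = 2)
  pools <- build_reference_pools(sim$metadata)
  pool <- pools[[1]]
  ref_id <- pool$members[["3"]][1]
  m <- match_query(sim$table$values[ref_id, ], pool, sim$table,
                   metric = "canberra", rule = "nearest_sample")
  expect_equal(m$predicted_person, 3L)
  expect_equal(unname(m$distances[["3"]]), 0)

  # two equidistant persons: identical reference communities
  vals <- rbind(q = c(50, 50), r1 = c(60, 40), r2 = c(60, 40))
  colnames(vals) <- c("k__B|p__P|f__F|s__A", "k__B|p__P|f__F|s__B")
  tab <- abundance_table(vals)
  tie_pool <- list(timepoint = 0L, members = list(`1` = "r1", `2` = "r2"))
  expect_warning(m2 <- match_query(tab$values["q", ], tie_pool, tab),
                 "tie")
  expect_equal(m2$predicted_person, 1L)
})

test_that("match_query is invariant to reference ordering within a pool", {
  sim <- full_grid_sim(seed = 2)
  pools <- build_reference_pools(sim$metadata)
  pool <- pools[[3]]
  rev_pool <- pool
  rev_pool$members <- lapply(rev(pool$members), rev)
  q <- sim$metadata$sample_id[sim$metadata$site == "door_knob"][5]
  m1 <- match_query(sim$table$values[q, ], pool, sim$table)
  m2 <- match_query(sim$table$values[q, ], rev_pool, sim$table)
  expect_equal(m1$predicted_person, m2$predicted_person)
})

test_that("evaluate_matching enumerates every query x pool combination", {
  sim <- full_grid_sim(seed = 2)
  mt <- evaluate_matching(sim$table, sim$metadata, metric = "canberra",
                          query_sites = "door_knob")
  # 4 locations x 20 timepoints queries x 20 pools
  expect_equal(nrow(mt$results), 80L * 20L)
  one_loc <- mt$results[mt$results$query_location == 1, ]
  expect_equal(nrow(one_loc), 400L)
  expect_setequal(unique(mt$results$delay_hours), seq(-228, 228, by = 12))
  # conservation: curve counts add up to the attempt totals
  expect_equal(sum(mt$curve$n_correct), sum(mt$results$correct))
  expect_equal(sum(mt$curve$n_attempts), nrow(mt$results))
})

test_that("noise-free signatures give perfect household matching", {
  sim <- full_grid_sim(noise_sd = 0, seed = 3)
  mt <- evaluate_matching(sim$table, sim$metadata, metric = "canberra",
                          query_sites = c("bed_headboard", "door_knob"))
  expect_true(all(mt$results$correct))
  expect_true(all(mt$curve$accuracy_percent == 100))
})

test_that("Spearman delay correlation matches a rank-formula oracle", {
  curve <- data.frame(
    query_site = "door_knob",
    delay_hours = seq(-60, 60, by = 12),
    n_attempts = 10L
  )
  # monotone decreasing in |delay| (ties aligned) -> rho = -1
  curve$accuracy_percent <- 100 - abs(curve$delay_hours) / 2
  curve$n_correct <- curve$n_attempts
  expect_equal(spearman_delay_accuracy(curve, "door_knob")$rho, -1)

  set.seed(9)
  curve$accuracy_percent <- sample(c(55, 60, 65, 70, 75, 80, 85, 90,
                                     95, 100, 50))
  got <- spearman_delay_accuracy(curve, "door_knob")
  oracle <- stats::cor(rank(curve$accuracy_percent),
                       rank(abs(curve$delay_hours)))
  expect_equal(got$rho, oracle, tolerance = 1e-12)

  curve$accuracy_percent <- 80
  flat <- spearman_delay_accuracy(curve, "door_knob")
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
})

test_that("chi-squared comparison matches the hand Pearson formula", {
  mk <- function(correct_n, total) {
    data.frame(correct = rep(c(TRUE, FALSE),
                             c(correct_n, total - correct_n)))
  }
  res <- compare_accuracy_chisq(mk(90, 100), mk(50, 100))
  # hand Pearson on [[90,10],[50,50]]: sum (O-E)^2/E with E = 70/30
  hand <- 2 * (20^2 / 70 + 20^2 / 30)
  expect_equal(res$chi2, hand, tolerance = 1e-12)
  expect_equal(res$chi2, 38.0952380952, tolerance = 1e-9)

  res2 <- compare_accuracy_chisq(mk(1, 1), mk(0, 1))
  expect_equal(res2$chi2, 2, tolerance = 1e-12)

  same <- mk(30, 50)
  res3 <- compare_accuracy_chisq(same, same)
  expect_equal(res3$chi2, 0)
  expect_equal(res3$p, 1)

  expect_error(compare_accuracy_chisq(mk(5, 5), mk(5, 5)), "zero margin")
})

test_that("time-of-day stratification conserves counts and handles ceilings", {
  sim <- full_grid_sim(noise_sd = 0, seed = 3)
  mt <- evaluate_matching(sim$table, sim$metadata, metric = "canberra",
                          query_sites = "door_knob")
  tod <- time_of_day_accuracy(mt$results)
  expect_equal(sum(tod$strata$n_correct), sum(mt$results$correct))
  expect_true(all(tod$strata$accuracy_percent == 100))
  expect_true(all(tod$tests$chi2 == 0))
  expect_true(all(tod$tests$p == 1))
})

test_that("morning references beat evening references for household queries", {
  # heavy PM public pickup on skin + daily pool turnover: evening skin
  # references are perturbed away from the personal signature
  sim <- full_grid_sim(noise_sd = 0.5, dispersal_mix_public_to_skin = 0.7,
                       public_turnover = 0.3, seed = 31)
  mt <- evaluate_matching(sim$table, sim$metadata, metric = "canberra",
                          query_sites = c("bed_headboard", "door_knob"))
  tod <- time_of_day_accuracy(mt$results)
  ref <- tod$tests[tod$tests$axis == "reference_period" &
                     tod$tests$site_class == "household", ]
  expect_gt(ref$accuracy_am, ref$accuracy_pm)
  expect_lt(ref$p, 0.05)
})
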