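#!/usr/bin/env Rscript
# Stage 2: distance-based microbiota matching.
#
# Every surface sample is matched against every per-timepoint pool of skin
# references (minimum mean distance over each person's palms); accuracy is
# tabulated by query site and sampling delay, compared between the
# Canberra and Bray-Curtis kernels, stratified by time of day, and the
# delay-decay of public-surface matching is quantified with Spearman rank
# correlations.

suppressPackageStartupMessages(library(skintrace))

ds <- read_abundance_table("results/data/abundance.tsv",
                           "results/data/metadata.tsv")
out_dir <- "results/matching"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

household <- c("bed_headboard", "door_knob")
public <- c("public_handrail", "subway_handrail")

runs <- list()
for (metric in c("canberra", "bray_curtis")) {
  mt <- suppressMessages(evaluate_matching(ds$table, ds$metadata,
                                           metric = metric))
  runs[[metric]] <- mt
  write_results_table(mt$results,
                      file.path(out_dir, paste0("attempts_", metric, ".tsv")))
  write_results_table(mt$curve,
                      file.path(out_dir, paste0("curve_", metric, ".tsv")))
  for (grp in list(household = household, public = public)) {
    sub <- mt$results[mt$results$query_site %in% grp, ]
    cat(sprintf("%-11s accuracy, %-9s queries: %5.1f%% (%d attempts)\n",
                metric, site_class(grp[1]), 100 * mean(sub$correct),
                nrow(sub)))
  }
}

# method comparison (chi-squared, no continuity correction)
for (grp in list(household = household, public = public)) {
  a <- runs$canberra$results[runs$canberra$results$query_site %in% grp, ]
  b <- runs$bray_curtis$results[
    runs$bray_curtis$results$query_site %in% grp, ]
  cmp <- tryCatch(compare_accuracy_chisq(a, b), error = function(e) NULL)
  if (is.null(cmp)) {
    cat(sprintf(
      "Canberra vs Bray-Curtis (%s): both at ceiling, no test possible\n",
      site_class(grp[1])))
  } else {
    cat(sprintf("Canberra vs Bray-Curtis (%s): chi2 = %.2f, p = %.3g\n",
                site_class(grp[1]), cmp$chi2, cmp$p))
  }
}

# delay decay for public queries
decay <- do.call(rbind, lapply(public, function(s) {
  sp <- spearman_delay_accuracy(runs$canberra$curve, s)
  cat(sprintf("Spearman |delay| vs accuracy at %s: rho = %.2f, p = %.3g\n",
              s, sp$rho, sp$p))
  data.frame(site = s, rho = sp$rho, p = sp$p, n = sp$n)
}))
write_results_table(decay, file.path(out_dir, "delay_spearman.tsv"))

# time-of-day stratification
tod <- time_of_day_accuracy(runs$canberra$results)
write_results_table(tod$strata, file.path(out_dir, "time_of_day_strata.tsv"))
write_results_table(tod$tests, file.path(out_dir, "time_of_day_tests.tsv"))

# are surfaces closer to their own occupant's skin?
for (s in c(household, public)) {
  sv <- same_vs_different_location_test(ds$table, ds$metadata, s)
  cat(sprintf(
    "%s: median BC same-location %.3f vs different %.3f (U = %.0f, p = %.3g)\n",
    s, sv$median_same, sv$median_different, sv$U, sv$p))
}
cat("Outputs in", out_dir, "\n")
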