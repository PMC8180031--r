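# Detection of diurnally varying species: 20-slot abundance series per
# (species, site, location), additive moving-average decomposition with a
# 1-day (2-slot) period, the seasonality-strength statistic F_S, a
# permutation null, and the robustness re-analyses (negative-control
# removal, compositional single-species removal, abundance comparisons).

#' Build the 20-slot abundance series for one (species, site, location)
#'
#' Slots where the sample is missing are NA. Species with non-zero
#' abundance at fewer than `min_presence` timepoints raise a classed
#' condition (`skintrace_excluded`) so catalog loops can skip them.
#' Leading/trailing missing slots are trimmed; internal gaps are filled by
#' seasonal-aware interpolation: subtract per-period (AM/PM) means,
#' interpolate linearly, re-add the period means.
#'
#' @param table An [abundance_table].
#' @param metadata Sample metadata.
#' @param species Taxon lineage string (column of the table).
#' @param site Site label.
#' @param location Location id.
#' @param min_presence Minimum number of non-zero timepoints (default 4).
#' @return An `abundance_series`: list with `values` (gap-filled),
#'   `observed` (pre-interpolation, NA at gaps), `period_labels`,
#'   `timepoints`, and the series coordinates.
#' @export
prepare_series <- function(table, metadata, species, site, location,
                           min_presence = 4L) {
  if (!species %in% colnames(table$values)) {
    stop("species not in table: ", species)
  }
  sel <- metadata[metadata$site == site & metadata$location == location, ,
                  drop = FALSE]
  vals <- rep(NA_real_, 20L)
  vals[sel$timepoint + 1L] <- table$values[sel$sample_id, species]
  if (all(is.na(vals))) stop("all slots missing for this series")
  n_present <- sum(vals > 0, na.rm = TRUE)
  if (n_present < min_presence) {
    cond <- structure(
      class = c("skintrace_excluded", "error", "condition"),
      list(message = sprintf(
        "%s at %s/location %d present at %d < %d timepoints",
        species, site, location, n_present, min_presence
      ), call = sys.call())
    )
    stop(cond)
  }
  keep <- which(!is.na(vals))
  lo <- min(keep); hi <- max(keep)
  vals <- vals[lo:hi]
  tps <- (lo:hi) - 1L
  periods <- ifelse(tps %% 2L == 0L, "AM", "PM")
  filled <- seasonal_interpolate(vals, periods)
  structure(
    list(values = filled, observed = vals, period_labels = periods,
         timepoints = tps, species = species, site = site,
         location = location),
    class = "abundance_series"
  )
}

# Seasonal-aware gap interpolation: deseasonalise by per-period means,
# linearly interpolate, re-add. Exact on a noiseless alternating series.
seasonal_interpolate <- function(vals, periods) {
  if (!anyNA(vals)) return(vals)
  pm <- tapply(vals, periods, mean, na.rm = TRUE)
  de <- vals - pm[periods]
  idx <- seq_along(de)
  obs <- which(!is.na(de))
  de[-obs] <- stats::approx(idx[obs], de[obs], xout = idx[-obs])$y
  as.vector(de + pm[periods])
}

#' Additive seasonal decomposition with a 2-slot (1-day) period
#'
#' Classical moving-average decomposition at frequency 2: the trend is the
#' centred 3-term moving average with weights (0.25, 0.5, 0.25) (NA at the
#' two ends); the seasonal figure is the per-period-position mean of the
#' detrended series, centred to sum to zero and tiled; the random
#' component is the remainder. This is the same recipe as
#' `stats::decompose()` at frequency 2, implemented vectorised so the
#' permutation null is cheap.
#'
#' @param x Numeric series (an `abundance_series` or plain vector),
#'   length >= 4.
#' @return List with `trend`, `seasonal`, `random`, `figure`.
#' @export
decompose_series <- function(x) {
  if (inherits(x, "abundance_series")) x <- x$values
  n <- length(x)
  if (n < 4L) stop("series must have length >= 4 (two full periods)")
  trend <- c(NA_real_,
             0.25 * x[1:(n - 2L)] + 0.5 * x[2:(n - 1L)] + 0.25 * x[3:n],
             NA_real_)
  de <- x - trend
  i1 <- seq.int(1L, n, 2L)
  i2 <- seq.int(2L, n, 2L)
  f <- c(mean(de[i1], na.rm = TRUE), mean(de[i2], na.rm = TRUE))
  f <- f - mean(f)
  seasonal <- numeric(n)
  seasonal[i1] <- f[1L]
  seasonal[i2] <- f[2L]
  list(trend = trend, seasonal = seasonal, random = x - trend - seasonal,
       figure = f)
}

#' Seasonality strength of a decomposition
#'
#' `F_S = max(0, 1 - Var(R) / Var(S + R))`, with sample variances
#' (denominator n - 1) over the slots where both components are defined;
#' `Var(S + R) = 0` yields `F_S = 0`. Lies in `[0, 1]`: 1 for a purely
#' seasonal series, 0 when the seasonal component explains nothing.
#'
#' @param decomp Output of [decompose_series()].
#' @return Scalar F_S in `[0, 1]`.
#' @export
seasonality_strength <- function(decomp) {
  ok <- !is.na(decomp$random)
  if (sum(ok) < 2L) stop("fewer than 2 slots with all components defined")
  sr <- decomp$seasonal[ok] + decomp$random[ok]
  v <- stats::var(sr)
  if (!is.finite(v) || v <= 0) return(0)
  max(0, 1 - stats::var(decomp$random[ok]) / v)
}

# Fast path: decomposition + F_S in one call, used inside permutation
# loops. Must agree with decompose_series + seasonality_strength exactly.
fs_stat <- function(x) {
  n <- length(x)
  trend <- c(NA_real_,
             0.25 * x[1:(n - 2L)] + 0.5 * x[2:(n - 1L)] + 0.25 * x[3:n],
             NA_real_)
  de <- x - trend
  i1 <- seq.int(1L, n, 2L)
  i2 <- seq.int(2L, n, 2L)
  f <- c(mean(de[i1], na.rm = TRUE), mean(de[i2], na.rm = TRUE))
  f <- f - mean(f)
  seasonal <- numeric(n)
  seasonal[i1] <- f[1L]
  seasonal[i2] <- f[2L]
  r <- de - seasonal
  ok <- !is.na(r)
  sr <- seasonal[ok] + r[ok]
  v <- stats::var(sr)
  if (!is.finite(v) || v <= 0) return(0)
  max(0, 1 - stats::var(r[ok]) / v)
}

#' Permutation test for seasonality strength
#'
#' The observed series is permuted uniformly over slots
#' `n_permutations` times; each permutation is decomposed and its F_S
#' computed. `p = #(F_S_perm > F_S_obs) / n_permutations` (strict
#' inequality, no +1 correction by default).
#'
#' @param series An `abundance_series` or numeric vector (gap-filled).
#' @param n_permutations Number of permutations (>= 99; 999 by default).
#' @param seed RNG seed.
#' @param plus_one Use the conservative `(b + 1) / (m + 1)` convention.
#' @return List `(f_s, p, n_permutations)`.
#' @export
permutation_test <- function(series, n_permutations = 999, seed = 1L,
                             plus_one = FALSE) {
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  x <- if (inherits(series, "abundance_series")) series$values else series
  if (stats::sd(x) == 0) {
    # a constant series carries no seasonal evidence; every permutation
    # ties the observed statistic, so report the null outcome directly
    return(list(f_s = 0, p = 1, n_permutations = n_permutations,
                degenerate = TRUE))
  }
  f_obs <- fs_stat(x)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    if (fs_stat(x[sample.int(length(x))]) > f_obs) exceed <- exceed + 1L
  }
  p <- if (plus_one) (exceed + 1) / (n_permutations + 1) else
    exceed / n_permutations
  list(f_s = f_obs, p = p, n_permutations = n_permutations)
}

#' Catalog diurnally varying species
#'
#' Iterates every (species, site, location) series that passes the
#' presence filter, runs the permutation test, and reports F_S, p, the
#' peak period (the period with higher mean interpolated abundance) and
#' the AM - PM mean abundance difference. Site-class summaries mirror the
#' per-class proportions of significant series, mean F_S among them and
#' mean absolute AM/PM difference.
#'
#' @param table An [abundance_table].
#' @param metadata Sample metadata.
#' @param species Optional subset of taxa (default: all columns).
#' @param sites,locations Optional subsets of the grid.
#' @param alpha Significance level on the raw permutation p (no
#'   multiplicity correction by default, matching the method).
#' @param n_permutations Permutations per series.
#' @param seed Base RNG seed (each series gets a derived seed).
#' @param min_presence Presence filter threshold.
#' @return List with `catalog` (all tested series), `summary` (per site
#'   class, over significant series) and `n_tested` / `n_excluded`.
#' @export
detect_diurnal <- function(table, metadata, species = NULL, sites = NULL,
                           locations = NULL, alpha = 0.05,
                           n_permutations = 999, seed = 1L,
                           min_presence = 4L) {
  if (is.null(species)) species <- colnames(table$values)
  if (is.null(sites)) sites <- intersect(SITE_LEVELS, metadata$site)
  if (is.null(locations)) locations <- sort(unique(metadata$location))
  rows <- list()
  n_excluded <- 0L
  k <- 0L
  for (loc in locations) {
    for (st in sites) {
      if (!any(metadata$site == st & metadata$location == loc)) next
      for (sp in species) {
        k <- k + 1L
        ser <- tryCatch(
          prepare_series(table, metadata, sp, st, loc,
                         min_presence = min_presence),
          skintrace_excluded = function(e) NULL,
          error = function(e) NULL
        )
        if (is.null(ser) || length(ser$values) < 4L) {
          n_excluded <- n_excluded + 1L
          next
        }
        pt <- permutation_test(ser, n_permutations = n_permutations,
                               seed = seed + k)
        am <- mean(ser$values[ser$period_labels == "AM"])
        pm <- mean(ser$values[ser$period_labels == "PM"])
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, site = st, location = loc,
          f_s = pt$f_s, p = pt$p, significant = pt$p < alpha,
          peak_period = if (am >= pm) "AM" else "PM",
          am_pm_diff = am - pm,
          mean_abundance = mean(ser$values),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  catalog <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), site = character(),
               location = integer(), f_s = numeric(), p = numeric(),
               significant = logical(), peak_period = character(),
               am_pm_diff = numeric(), mean_abundance = numeric())
  summary <- NULL
  if (nrow(catalog) > 0L) {
    catalog$site_class <- site_class(catalog$site)
    summary <- do.call(rbind, lapply(split(catalog, catalog$site_class),
      function(sub) {
        sig <- sub[sub$significant, , drop = FALSE]
        data.frame(
          site_class = sub$site_class[1L],
          n_tested = nrow(sub), n_significant = nrow(sig),
          proportion_significant = nrow(sig) / nrow(sub),
          mean_f_s = if (nrow(sig)) mean(sig$f_s) else NA_real_,
          mean_abs_am_pm_diff = if (nrow(sig)) mean(abs(sig$am_pm_diff))
            else NA_real_,
          stringsAsFactors = FALSE
        )
      }))
    rownames(summary) <- NULL
  }
  list(catalog = catalog, summary = summary,
       n_tested = nrow(catalog), n_excluded = n_excluded)
}

#' Paired Wilcoxon signed-rank alternative to the permutation test
#'
#' Pairs AM and PM abundances within each day and applies the exact
#' two-sided Wilcoxon signed-rank test (exact for n <= 25 without ties).
#'
#' @param series An `abundance_series`.
#' @return List `(p, n_pairs, statistic, degenerate)`; all-zero
#'   differences give `p = 1` flagged degenerate.
#' @export
mann_whitney_alternative <- function(series) {
  stopifnot(inherits(series, "abundance_series"))
  days <- series$timepoints %/% 2L
  am <- pm <- rep(NA_real_, 10L)
  for (i in seq_along(series$timepoints)) {
    d <- days[i] + 1L
    if (series$period_labels[i] == "AM") am[d] <- series$values[i]
    else pm[d] <- series$values[i]
  }
  ok <- !is.na(am) & !is.na(pm)
  if (sum(ok) < 4L) stop("need >= 4 complete AM/PM day pairs")
  diffs <- am[ok] - pm[ok]
  if (all(diffs == 0)) {
    return(list(p = 1, n_pairs = sum(ok), statistic = NA_real_,
                degenerate = TRUE))
  }
  n <- sum(ok)
  no_ties <- !any(duplicated(abs(diffs[diffs != 0]))) && !any(diffs == 0)
  if (n <= 25L && no_ties) {
    wt <- stats::wilcox.test(am[ok], pm[ok], paired = TRUE, exact = TRUE)
    return(list(p = wt$p.value, n_pairs = n,
                statistic = unname(wt$statistic), degenerate = FALSE))
  }
  if (n <= 14L) {
    # exact sign-flip enumeration with average ranks (handles ties/zeros)
    nz <- diffs[diffs != 0]
    r <- rank(abs(nz))
    v_obs <- sum(r[nz > 0])
    m <- length(nz)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    v_null <- as.vector(signs %*% r)
    mu <- sum(r) / 2
    p <- mean(abs(v_null - mu) >= abs(v_obs - mu) - 1e-12)
    return(list(p = p, n_pairs = n, statistic = v_obs,
                degenerate = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(am[ok], pm[ok],
                                            paired = TRUE, exact = FALSE))
  list(p = wt$p.value, n_pairs = n,
       statistic = unname(wt$statistic), degenerate = FALSE)
}

# Drop columns from a table and renormalise rows to 100; samples emptied
# by the removal are dropped with a warning.
remove_species <- function(table, metadata, species) {
  keep <- setdiff(colnames(table$values), species)
  if (length(keep) == 0L) stop("removal would empty the table")
  vals <- table$values[, keep, drop = FALSE]
  empty <- rowSums(vals) <= 0
  if (any(empty)) {
    warning("dropping sample(s) emptied by removal: ",
            paste(rownames(vals)[empty], collapse = ", "))
    vals <- vals[!empty, , drop = FALSE]
    metadata <- metadata[metadata$sample_id %in% rownames(vals), ,
                         drop = FALSE]
  }
  list(table = abundance_table(vals), metadata = metadata)
}

#' Re-run diurnal detection with negative-control species removed
#'
#' Removes the listed species everywhere, renormalises each sample to
#' 100%, re-runs [detect_diurnal()] and reports, for the originally
#' significant series, how many were removed with the control set, how
#' many lost significance, and how many remained significant.
#'
#' @param table,metadata Data set.
#' @param control_species Character vector of lineages seen in negative
#'   controls (may be empty: catalog is then unchanged).
#' @param ... Passed to [detect_diurnal()] (alpha, n_permutations, seed,
#'   species, sites, locations).
#' @return List with `before`, `after` (full [detect_diurnal()] outputs)
#'   and `delta` (counts removed / lost / retained).
#' @export
control_species_reanalysis <- function(table, metadata, control_species,
                                       ...) {
  before <- detect_diurnal(table, metadata, ...)
  if (length(control_species) == 0L) {
    return(list(before = before, after = before,
                delta = list(n_removed = 0L, n_lost = 0L,
                             n_retained = sum(before$catalog$significant))))
  }
  cleaned <- remove_species(table, metadata, control_species)
  args <- list(...)
  if (!is.null(args$species)) {
    args$species <- setdiff(args$species, control_species)
  }
  after <- do.call(detect_diurnal,
                   c(list(cleaned$table, cleaned$metadata), args))
  sig_before <- before$catalog[before$catalog$significant, , drop = FALSE]
  key <- function(df) paste(df$species, df$site, df$location)
  removed <- sig_before$species %in% control_species
  still <- key(sig_before) %in%
    key(after$catalog[after$catalog$significant, , drop = FALSE])
  list(
    before = before, after = after,
    delta = list(
      n_removed = sum(removed),
      n_lost = sum(!removed & !still),
      n_retained = sum(!removed & still)
    )
  )
}

#' Single-species removal re-analysis of a compositional effect
#'
#' For one (site, location), removes one species, renormalises the
#' remaining abundances in those samples, and re-runs detection for the
#' remaining species there; reports which species changed significance.
#' This is the check that an apparent antiphase diurnal pattern in other
#' species is an artefact of closure against a single genuinely diurnal
#' species.
#'
#' @param table,metadata Data set.
#' @param site,location The site/location to re-analyse.
#' @param species_to_remove Single lineage; must be present there.
#' @param ... Passed to [detect_diurnal()].
#' @return List with `before`, `after` catalogs (that site/location only)
#'   and `changed` (species whose significance flipped).
#' @export
compositional_reanalysis <- function(table, metadata, site, location,
                                     species_to_remove, ...) {
  sel <- metadata$site == site & metadata$location == location
  if (!any(sel)) stop("no samples at that site/location")
  ids <- metadata$sample_id[sel]
  if (all(table$values[ids, species_to_remove] == 0)) {
    stop("species absent at that site/location: ", species_to_remove)
  }
  args <- list(...)
  args$sites <- site
  args$locations <- location
  before <- do.call(detect_diurnal, c(list(table, metadata), args))
  vals <- table$values
  vals[ids, species_to_remove] <- 0
  keep_rows <- rowSums(vals) > 0
  vals <- vals[keep_rows, , drop = FALSE]
  md <- metadata[metadata$sample_id %in% rownames(vals), , drop = FALSE]
  if (!is.null(args$species)) {
    args$species <- setdiff(args$species, species_to_remove)
  } else {
    args$species <- setdiff(colnames(table$values), species_to_remove)
  }
  after <- do.call(detect_diurnal, c(list(abundance_table(vals), md), args))
  b <- before$catalog[before$catalog$species != species_to_remove, ,
                      drop = FALSE]
  key <- function(df) paste(df$species, df$site, df$location)
  a_sig <- key(after$catalog[after$catalog$significant, , drop = FALSE])
  changed <- b$species[b$significant != (key(b) %in% a_sig)]
  list(before = before$catalog, after = after$catalog, changed = changed)
}

#' Are diurnal species more abundant than non-diurnal ones?
#'
#' Mann-Whitney comparison of mean relative abundance (computed over
#' samples where the species is present, i.e. non-zero) between
#' significant and non-significant catalog entries, plus the Spearman
#' correlation between abundance and F_S among the significant entries.
#'
#' @param catalog Catalog from [detect_diurnal()] (needs both significant
#'   and non-significant rows).
#' @param table,metadata Data set the catalog was computed from.
#' @return List `(U, p, mean_diurnal, mean_nondiurnal, spearman_rho,
#'   spearman_p)`.
#' @export
diurnal_vs_nondiurnal_abundance <- function(catalog, table, metadata) {
  if (nrow(catalog) == 0L) stop("catalog is empty")
  present_mean <- function(sp, st, loc) {
    ids <- metadata$sample_id[metadata$site == st &
                                metadata$location == loc]
    v <- table$values[ids, sp]
    v <- v[v > 0]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  ab <- mapply(present_mean, catalog$species, catalog$site,
               catalog$location)
  sig <- catalog$significant & !is.na(ab)
  non <- !catalog$significant & !is.na(ab)
  if (!any(sig) || !any(non)) {
    stop("need both significant and non-significant series")
  }
  wt <- suppressWarnings(stats::wilcox.test(ab[sig], ab[non],
                                            exact = FALSE))
  sp_ct <- if (sum(sig) >= 3L) {
    suppressWarnings(stats::cor.test(ab[sig], catalog$f_s[sig],
                                     method = "spearman", exact = FALSE))
  } else NULL
  list(
    U = unname(wt$statistic), p = wt$p.value,
    mean_diurnal = mean(ab[sig]), mean_nondiurnal = mean(ab[non]),
    spearman_rho = if (is.null(sp_ct)) NA_real_ else
      unname(sp_ct$estimate),
    spearman_p = if (is.null(sp_ct)) NA_real_ else sp_ct$p.value
  )
}
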