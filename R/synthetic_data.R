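# Synthetic community generator emulating a twice-daily, 10-day,
# 4-location x 6-site sampling design with person-specific signature taxa,
# planted diurnal species, public->skin->household dispersal coupling,
# multiplicative noise and missingness. The generator is first-class code:
# its planted structure is the ground truth every recovery test measures
# against.

#' Configuration for the synthetic community generator
#'
#' All fractions are in `[0, 1]`; multiplicative parameters
#' (`signature_boost`, `diurnal_amplitude`) are >= 1.
#'
#' @param n_locations Number of residences/persons (one occupant each).
#' @param n_species Number of species in the shared species pool.
#' @param n_signature_per_location Species boosted on each person's skin.
#' @param signature_boost Multiplier applied to a person's signature
#'   species baseline on their skin.
#' @param n_diurnal_per_site Diurnally varying species planted per
#'   (site, location).
#' @param diurnal_amplitude Multiplier applied in a planted species' peak
#'   period (AM or PM) relative to its off-peak expectation.
#' @param dispersal_mix_public_to_skin Fraction of the local public pool
#'   mixed into skin at every PM timepoint.
#' @param mix_skin_to_household Fraction of the previous timepoint's skin
#'   community mixed into household surfaces at every timepoint.
#' @param normalization_rate Weight with which skin is pulled back toward
#'   the personal baseline at each AM timepoint (overnight normalisation).
#' @param public_turnover Fraction of public-pool species whose baseline
#'   is resampled each day, independently per location.
#' @param noise_sd Standard deviation of multiplicative log-normal
#'   observation noise.
#' @param missing_prob Probability that any one sample is dropped
#'   (sequencing failure); missing samples have no metadata row.
#' @param seed Integer RNG seed; the same seed yields a bit-identical
#'   table.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_locations = 4L,
                             n_species = 150L,
                             n_signature_per_location = 5L,
                             signature_boost = 10,
                             n_diurnal_per_site = 8L,
                             diurnal_amplitude = 3,
                             dispersal_mix_public_to_skin = 0.3,
                             mix_skin_to_household = 0.3,
                             normalization_rate = 0.8,
                             public_turnover = 0.0,
                             noise_sd = 0.3,
                             missing_prob = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_locations = as.integer(n_locations),
    n_species = as.integer(n_species),
    n_signature_per_location = as.integer(n_signature_per_location),
    signature_boost = signature_boost,
    n_diurnal_per_site = as.integer(n_diurnal_per_site),
    diurnal_amplitude = diurnal_amplitude,
    dispersal_mix_public_to_skin = dispersal_mix_public_to_skin,
    mix_skin_to_household = mix_skin_to_household,
    normalization_rate = normalization_rate,
    public_turnover = public_turnover,
    noise_sd = noise_sd,
    missing_prob = missing_prob,
    seed = as.integer(seed)
  )
  fr <- c("dispersal_mix_public_to_skin", "mix_skin_to_household",
          "normalization_rate", "public_turnover", "missing_prob")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$n_species < 1L) stop("n_species must be positive")
  if (cfg$n_locations < 1L) stop("n_locations must be positive")
  if (cfg$diurnal_amplitude < 1) stop("diurnal_amplitude must be >= 1")
  if (cfg$signature_boost <= 0) stop("signature_boost must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$n_signature_per_location * cfg$n_locations > cfg$n_species) {
    stop("signature species demand exceeds n_species")
  }
  if (cfg$n_diurnal_per_site > cfg$n_species) {
    stop("n_diurnal_per_site exceeds n_species")
  }
  structure(cfg, class = "synthetic_config")
}

# MetaPhlAn-style lineages for a pool of n species: species grouped 5 per
# family, families grouped 5 per phylum.
synthetic_lineages <- function(n_species) {
  sp <- seq_len(n_species)
  fam_idx <- (sp - 1L) %/% 5L + 1L
  phy_idx <- (fam_idx - 1L) %/% 5L + 1L
  sprintf(
    "k__Bacteria|p__Phylum%02d|f__Family%02d|s__Species%03d",
    phy_idx, fam_idx, sp
  )
}

#' Generate a synthetic study data set
#'
#' Simulates the full spatiotemporal grid: per timepoint t = 0..19,
#' compartment expectations (skin, household, public pool per location)
#' evolve by mixing dynamics; planted diurnal species are amplified at
#' their site in their peak period; multiplicative log-normal noise is
#' applied and each sample is closed to 100%; samples are dropped at
#' random with `missing_prob`. Compartments are burned in for 10 slots so
#' household surfaces already carry their occupant's signal at t = 0.
#'
#' @param config A [synthetic_config()].
#' @return A list with `table` (an [abundance_table]), `metadata`
#'   (data frame) and `truth`, a ground-truth record with
#'   `signature_species` (list location -> lineages), `diurnal_species`
#'   (data frame species/site/location/peak_period) and `dispersal_edges`
#'   (data frame of planted site-class couplings).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  S <- config$n_species
  L <- config$n_locations
  lineages <- synthetic_lineages(S)
  norm100 <- function(v) 100 * v / sum(v)

  # --- baselines -----------------------------------------------------------
  sig <- vector("list", L)
  skin_base <- matrix(0, L, S)
  hh_base <- matrix(0, L, S)
  for (l in seq_len(L)) {
    b <- exp(stats::rnorm(S))
    idx <- ((l - 1L) * config$n_signature_per_location +
              seq_len(config$n_signature_per_location))
    b[idx] <- b[idx] * config$signature_boost
    sig[[l]] <- idx
    skin_base[l, ] <- norm100(b)
    hh_base[l, ] <- norm100(exp(stats::rnorm(S)))
  }
  pub0 <- norm100(exp(stats::rnorm(S)))
  # Public pool per (location, day); shared baseline, per-location daily
  # turnover so pools diverge over the study.
  P <- array(0, dim = c(L, 10L, S))
  for (l in seq_len(L)) P[l, 1L, ] <- pub0
  for (d in 2:10) {
    for (l in seq_len(L)) {
      prev <- P[l, d - 1L, ]
      if (config$public_turnover > 0) {
        flip <- stats::runif(S) < config$public_turnover
        prev[flip] <- exp(stats::rnorm(sum(flip)))
      }
      P[l, d, ] <- norm100(prev)
    }
  }

  # --- planted diurnal species --------------------------------------------
  diurnal <- list()
  for (l in seq_len(L)) {
    for (s in SITE_LEVELS) {
      if (config$n_diurnal_per_site > 0L) {
        sp <- sample.int(S, config$n_diurnal_per_site)
        pk <- sample(c("AM", "PM"), config$n_diurnal_per_site,
                     replace = TRUE)
        diurnal[[length(diurnal) + 1L]] <- data.frame(
          species = lineages[sp], species_index = sp, site = s,
          location = l, peak_period = pk, stringsAsFactors = FALSE
        )
      }
    }
  }
  diurnal <- if (length(diurnal)) do.call(rbind, diurnal) else
    data.frame(species = character(), species_index = integer(),
               site = character(), location = integer(),
               peak_period = character())

  # --- compartment dynamics with burn-in ----------------------------------
  mp <- config$dispersal_mix_public_to_skin
  mh <- config$mix_skin_to_household
  nr <- config$normalization_rate
  n_burn <- 10L
  skin <- skin_base
  hh <- hh_base
  skin_exp <- array(0, dim = c(L, 20L, S))
  hh_exp <- array(0, dim = c(L, 20L, S))
  for (t in seq(-n_burn, 19L)) {
    day <- if (t < 0L) 1L else t %/% 2L + 1L
    is_pm <- abs(t) %% 2L == 1L
    if (t > -n_burn) {
      skin_prev <- skin
      hh <- (1 - mh) * hh + mh * skin_prev
      if (is_pm) {
        skin <- (1 - mp) * skin + mp * matrix(P[, day, ], nrow = L)
      } else {
        skin <- (1 - nr) * skin + nr * skin_base
      }
    }
    if (t >= 0L) {
      skin_exp[, t + 1L, ] <- skin
      hh_exp[, t + 1L, ] <- hh
    }
  }

  # --- assemble samples ----------------------------------------------------
  rows <- list()
  meta <- list()
  for (l in seq_len(L)) {
    for (s in SITE_LEVELS) {
      cls <- site_class(s)
      planted <- diurnal[diurnal$site == s & diurnal$location == l, ,
                         drop = FALSE]
      for (t in 0:19) {
        day <- t %/% 2L + 1L
        period <- if (t %% 2L == 0L) "AM" else "PM"
        e <- switch(cls,
          skin = skin_exp[l, t + 1L, ],
          household = hh_exp[l, t + 1L, ],
          public = P[l, day, ]
        )
        if (nrow(planted) > 0L) {
          hit <- planted$species_index[planted$peak_period == period]
          if (length(hit) > 0L) {
            e[hit] <- e[hit] * config$diurnal_amplitude
          }
        }
        v <- e * exp(stats::rnorm(S, 0, config$noise_sd))
        drop_it <- stats::runif(1L) < config$missing_prob
        if (!drop_it) {
          id <- sprintf("L%d_%s_D%02d_%s", l, s, day, period)
          rows[[id]] <- norm100(v)
          meta[[id]] <- data.frame(
            sample_id = id, location = l, site = s, day = day,
            period = period, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) stop("all samples dropped; lower missing_prob")
  values <- do.call(rbind, rows)
  colnames(values) <- lineages
  metadata <- validate_metadata(do.call(rbind, meta))
  rownames(metadata) <- NULL

  truth <- list(
    signature_species = lapply(sig, function(ix) lineages[ix]),
    diurnal_species = diurnal,
    dispersal_edges = data.frame(
      parent_class = c("public", "skin"),
      child_class = c("skin", "household"),
      stringsAsFactors = FALSE
    ),
    public_pool = P,
    lineages = lineages
  )
  list(table = abundance_table(values), metadata = metadata, truth = truth)
}

#' Generate an i.i.d. null abundance series
#'
#' Log-normal series with no seasonal structure, for calibrating the
#' seasonality permutation test.
#'
#' @param n_timepoints Series length (>= 8).
#' @param sd Standard deviation of the log values.
#' @param seed RNG seed.
#' @return Numeric vector of positive abundances.
#' @export
null_series <- function(n_timepoints = 20L, sd = 0.3, seed = 1L) {
  if (n_timepoints < 8L) stop("n_timepoints must be >= 8")
  if (sd < 0) stop("sd must be non-negative")
  set.seed(seed)
  exp(stats::rnorm(n_timepoints, 0, sd))
}
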