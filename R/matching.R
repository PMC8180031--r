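# Distance-based microbiota matching: per-timepoint reference pools of skin
# samples, minimum-mean-distance assignment of surface queries to persons,
# and accuracy accounting across sampling delay and time of day.

#' Build per-timepoint reference pools of skin samples
#'
#' A pool at a timepoint is the set of all skin (palm) samples from every
#' person at that timepoint. Timepoints where any person lacks a skin
#' sample are excluded (with a message); a person keeping only one palm
#' is retained.
#'
#' @param metadata Sample metadata (see [read_abundance_table()]).
#' @return A list of pools, each `list(timepoint =, members =)` where
#'   `members` maps person id (as character location) to skin sample ids.
#' @export
build_reference_pools <- function(metadata) {
  skin <- metadata[metadata$site_class == "skin", , drop = FALSE]
  if (nrow(skin) == 0L) stop("metadata contains no skin samples")
  persons <- sort(unique(metadata$location))
  pools <- list()
  for (tp in sort(unique(skin$timepoint))) {
    at <- skin[skin$timepoint == tp, , drop = FALSE]
    members <- split(at$sample_id, at$location)
    if (all(as.character(persons) %in% names(members))) {
      pools[[length(pools) + 1L]] <- list(
        timepoint = tp,
        members = members[as.character(persons)]
      )
    } else {
      message("excluding timepoint ", tp,
              ": not every person has a skin sample")
    }
  }
  if (length(pools) == 0L) stop("no eligible reference pool timepoints")
  pools
}

#' Match one query sample against a reference pool
#'
#' For each person, the metric is averaged over that person's skin samples
#' in the pool; the predicted person is the argmin of these per-person
#' mean distances (`rule = "per_person_mean"`), or the owner of the single
#' nearest reference sample (`rule = "nearest_sample"`). Exact ties go to
#' the lowest person id with a warning.
#'
#' @param query_values Abundance vector of the query sample.
#' @param pool One pool from [build_reference_pools()].
#' @param table An [abundance_table] holding the reference samples.
#' @param metric `"canberra"` or `"bray_curtis"`.
#' @param rule Aggregation rule over a person's pool samples.
#' @return A list with `predicted_person` (integer) and `distances`
#'   (named per-person summary distances).
#' @export
match_query <- function(query_values, pool, table,
                        metric = c("canberra", "bray_curtis"),
                        rule = c("per_person_mean", "nearest_sample")) {
  metric <- match.arg(metric)
  rule <- match.arg(rule)
  agg <- if (rule == "per_person_mean") mean else min
  per_person <- vapply(pool$members, function(ids) {
    refs <- table$values[ids, , drop = FALSE]
    agg(dist_to_refs(query_values, refs, metric))
  }, 0)
  best <- min(per_person)
  hits <- which(abs(per_person - best) < 1e-12)
  if (length(hits) > 1L) {
    warning("tie between persons ",
            paste(names(per_person)[hits], collapse = ", "),
            "; lowest id wins")
  }
  list(
    predicted_person = as.integer(names(per_person)[hits[1L]]),
    distances = per_person
  )
}

#' Run every (query, pool) matching attempt and tabulate accuracy
#'
#' Each surface query sample is matched against every eligible reference
#' pool, including pools collected before and after it; the sampling delay
#' is `12 * (query_timepoint - reference_timepoint)` hours, negative when
#' the query precedes the references. A match is correct when the
#' predicted person's location equals the query's location.
#'
#' @param table An [abundance_table].
#' @param metadata Sample metadata.
#' @param metric `"canberra"` or `"bray_curtis"`.
#' @param query_sites Sites whose samples serve as queries (default: all
#'   non-skin sites present).
#' @param rule Passed to [match_query()].
#' @return A list with `results` (one row per attempt) and `curve`
#'   (accuracy percent per query site x delay).
#' @export
evaluate_matching <- function(table, metadata,
                              metric = c("canberra", "bray_curtis"),
                              query_sites = NULL,
                              rule = c("per_person_mean", "nearest_sample")) {
  metric <- match.arg(metric)
  rule <- match.arg(rule)
  if (is.null(query_sites)) {
    query_sites <- intersect(SITE_LEVELS,
                             metadata$site[metadata$site_class != "skin"])
  }
  pools <- build_reference_pools(metadata)
  queries <- metadata[metadata$site %in% query_sites, , drop = FALSE]
  if (nrow(queries) == 0L) stop("no query samples at the requested sites")
  out <- vector("list", nrow(queries) * length(pools))
  k <- 0L
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    qv <- table$values[q$sample_id, ]
    for (pool in pools) {
      m <- match_query(qv, pool, table, metric = metric, rule = rule)
      k <- k + 1L
      out[[k]] <- data.frame(
        query_sample = q$sample_id,
        query_site = q$site,
        query_location = q$location,
        query_timepoint = q$timepoint,
        reference_timepoint = pool$timepoint,
        delay_hours = 12 * (q$timepoint - pool$timepoint),
        metric = metric,
        predicted_person = m$predicted_person,
        correct = m$predicted_person == q$location,
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, out)
  curve <- accuracy_curve(results)
  list(results = results, curve = curve)
}

#' Aggregate matching attempts into an accuracy curve
#'
#' @param results Attempt table from [evaluate_matching()].
#' @return Data frame of (query_site, delay_hours, n_attempts, n_correct,
#'   accuracy_percent).
#' @export
accuracy_curve <- function(results) {
  agg <- stats::aggregate(
    cbind(n_correct = correct, n_attempts = rep(1L, nrow(results))) ~
      query_site + delay_hours,
    data = results, FUN = sum
  )
  agg$accuracy_percent <- 100 * agg$n_correct / agg$n_attempts
  agg[order(agg$query_site, agg$delay_hours), , drop = FALSE]
}

#' Spearman correlation of accuracy against absolute sampling delay
#'
#' Rank correlation (average ranks on ties) between accuracy and
#' `|delay|` for one query site; a decaying trace gives rho < 0.
#'
#' @param curve Accuracy curve from [evaluate_matching()].
#' @param site Query site to test.
#' @return A list `(rho, p, n, defined)`; `defined = FALSE` with rho `NA`
#'   when accuracy is constant.
#' @export
spearman_delay_accuracy <- function(curve, site) {
  cv <- curve[curve$query_site == site, , drop = FALSE]
  if (length(unique(abs(cv$delay_hours))) < 3L) {
    stop("need at least 3 distinct absolute delays")
  }
  if (stats::sd(cv$accuracy_percent) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = nrow(cv),
                defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(
    cv$accuracy_percent, abs(cv$delay_hours),
    method = "spearman", exact = FALSE
  ))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(cv),
       defined = TRUE)
}

#' Chi-squared comparison of two sets of matching attempts
#'
#' Plain Pearson chi-squared (no continuity correction by default) on the
#' 2x2 correct/incorrect x group contingency table.
#'
#' @param results_a,results_b Attempt tables (need a logical `correct`
#'   column).
#' @param correct_continuity Apply the Yates correction.
#' @return List `(chi2, p, table)`.
#' @export
compare_accuracy_chisq <- function(results_a, results_b,
                                   correct_continuity = FALSE) {
  if (nrow(results_a) == 0L || nrow(results_b) == 0L) {
    stop("both result sets must be non-empty")
  }
  tab <- rbind(
    a = c(sum(results_a$correct), sum(!results_a$correct)),
    b = c(sum(results_b$correct), sum(!results_b$correct))
  )
  colnames(tab) <- c("correct", "incorrect")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate contingency table (zero margin)")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct_continuity))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Matching accuracy stratified by time of day
#'
#' Cross-tabulates accuracy by query period x reference period within each
#' query site class, and tests (Pearson chi-squared) AM vs PM queries and
#' AM vs PM references.
#'
#' @param results Attempt table from [evaluate_matching()].
#' @return List with `strata` (accuracy per site_class x query_period x
#'   reference_period; empty strata reported as NA) and `tests` (one
#'   chi-squared row per site class and axis).
#' @export
time_of_day_accuracy <- function(results) {
  results$query_period <- ifelse(results$query_timepoint %% 2 == 0,
                                 "AM", "PM")
  results$reference_period <- ifelse(results$reference_timepoint %% 2 == 0,
                                     "AM", "PM")
  results$site_class <- site_class(results$query_site)
  grid <- expand.grid(
    site_class = unique(results$site_class),
    query_period = c("AM", "PM"), reference_period = c("AM", "PM"),
    stringsAsFactors = FALSE
  )
  strata <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- results[results$site_class == g$site_class &
                     results$query_period == g$query_period &
                     results$reference_period == g$reference_period, ]
    data.frame(
      g, n_attempts = nrow(sub), n_correct = sum(sub$correct),
      accuracy_percent = if (nrow(sub) == 0L) NA_real_ else
        100 * sum(sub$correct) / nrow(sub),
      stringsAsFactors = FALSE
    )
  }))
  tests <- list()
  for (cls in unique(results$site_class)) {
    sub <- results[results$site_class == cls, ]
    for (axis in c("query_period", "reference_period")) {
      am <- sub[sub[[axis]] == "AM", ]
      pm <- sub[sub[[axis]] == "PM", ]
      res <- if (nrow(am) == 0L || nrow(pm) == 0L ||
                 (sum(am$correct) + sum(pm$correct)) %in%
                   c(0L, nrow(am) + nrow(pm))) {
        list(chi2 = 0, p = 1)  # no variation to test
      } else {
        compare_accuracy_chisq(am, pm)
      }
      tests[[length(tests) + 1L]] <- data.frame(
        site_class = cls, axis = axis,
        accuracy_am = 100 * mean(am$correct),
        accuracy_pm = 100 * mean(pm$correct),
        chi2 = res$chi2, p = res$p, stringsAsFactors = FALSE
      )
    }
  }
  list(strata = strata, tests = do.call(rbind, tests))
}
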