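# Community-level comparisons: one-factor PERMANOVA on Bray-Curtis
# distances, indicator-family source profiling, and the same- vs
# different-location skin-surface dissimilarity test.

#' One-factor PERMANOVA on Bray-Curtis distances
#'
#' Pseudo-F from among/within sums of squared distances (Anderson's
#' distance-based formulation): `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `F = (SS_among / (a - 1)) / (SS_within / (N - a))`. Significance by
#' label permutation with the +1 convention:
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)`.
#'
#' @param x An [abundance_table], a samples x taxa matrix, or a
#'   precomputed symmetric distance matrix (`dist` or square matrix with
#'   zero diagonal).
#' @param grouping Factor-like group labels, one per sample (e.g. AM/PM).
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return List `(pseudo_F, p, n, groups)`.
#' @export
permanova <- function(x, grouping, n_permutations = 999, seed = 1L) {
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  if (inherits(x, "abundance_table")) x <- x$values
  d <- if (inherits(x, "dist")) {
    as.matrix(x)
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             all(abs(diag(x)) < 1e-12) && isTRUE(all.equal(x, t(x)))) {
    x
  } else {
    bray_curtis_matrix(as.matrix(x))
  }
  grouping <- as.factor(grouping)
  n <- nrow(d)
  if (length(grouping) != n) stop("grouping length must match sample count")
  if (any(table(grouping) < 2L)) stop("need >= 2 samples per group")
  a <- nlevels(grouping)
  d2 <- d^2
  pseudo_f <- function(g) {
    ss_t <- sum(d2[upper.tri(d2)]) / n
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      sub <- d2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- pseudo_f(grouping)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_permutations), function(i) {
    pseudo_f(grouping[sample.int(n)])
  }, 0)
  list(
    pseudo_F = f_obs,
    p = (1 + sum(f_perm >= f_obs)) / (1 + n_permutations),
    n = n, groups = a
  )
}

#' Per-sample source profile from indicator families
#'
#' Sums abundance over the families mapped to each source category
#' (e.g. human skin, soil, leaf); families not in the map accumulate
#' under `"unassigned"`. The family lists are supplied by the user.
#'
#' @param table An [abundance_table].
#' @param indicator_map Named character vector `family -> source`.
#' @return Data frame, one row per sample: one column per source,
#'   `unassigned`, and `top_source`.
#' @export
indicator_source_profile <- function(table, indicator_map) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(indicator_map) == 0L) stop("indicator_map must be non-empty")
  fam <- table$taxa$family
  src <- indicator_map[fam]
  src[is.na(src)] <- "unassigned"
  sources <- c(sort(unique(unname(indicator_map))), "unassigned")
  sums <- t(rowsum(t(table$values), group = factor(src, levels = sources)))
  sums[is.na(sums)] <- 0
  miss <- setdiff(sources, colnames(sums))
  for (m in miss) sums <- cbind(sums, `colnames<-`(matrix(0, nrow(sums)), m))
  sums <- sums[, sources, drop = FALSE]
  top <- sources[max.col(sums, ties.method = "first")]
  data.frame(sample_id = rownames(sums), sums, top_source = top,
             check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

#' Same- vs different-location skin-surface dissimilarity test
#'
#' For one surface site, computes Bray-Curtis dissimilarities between
#' every surface sample and every skin sample, split into same-location
#' and different-location pairs, and compares the two sets with a
#' two-sided Mann-Whitney U test.
#'
#' @param table An [abundance_table].
#' @param metadata Sample metadata.
#' @param surface_site One non-skin site label.
#' @return List `(U, p, median_same, median_different, n_same,
#'   n_different)`.
#' @export
same_vs_different_location_test <- function(table, metadata, surface_site) {
  if (site_class(surface_site) == "skin") {
    stop("surface_site must be a non-skin site")
  }
  surf <- metadata[metadata$site == surface_site, , drop = FALSE]
  skin <- metadata[metadata$site_class == "skin", , drop = FALSE]
  if (nrow(surf) == 0L || nrow(skin) == 0L) {
    stop("need at least one surface and one skin sample")
  }
  same <- numeric(0)
  diff <- numeric(0)
  for (i in seq_len(nrow(surf))) {
    sv <- table$values[surf$sample_id[i], ]
    dvals <- vapply(skin$sample_id, function(id) {
      bray_curtis(sv, table$values[id, ])
    }, 0)
    is_same <- skin$location == surf$location[i]
    same <- c(same, dvals[is_same])
    diff <- c(diff, dvals[!is_same])
  }
  if (length(same) == 0L || length(diff) == 0L) {
    stop("need both same-location and different-location pairs")
  }
  wt <- suppressWarnings(stats::wilcox.test(same, diff, exact = FALSE))
  list(
    U = unname(wt$statistic), p = wt$p.value,
    median_same = stats::median(same),
    median_different = stats::median(diff),
    n_same = length(same), n_different = length(diff)
  )
}
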