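# Community distance kernels. Both follow the vegdist() dialect the
# matching method is defined in terms of; Canberra in particular is scaled
# by the number of non-double-zero taxa.

#' Canberra distance between two abundance vectors
#'
#' `d = (1/NZ) * sum_{i: x_i + y_i > 0} |x_i - y_i| / (x_i + y_i)`, where
#' `NZ` counts the indices where at least one vector is non-zero. This is
#' the scaled dialect computed by `vegan::vegdist(..., "canberra")`; set
#' `scaled = FALSE` for the unscaled textbook sum.
#'
#' Sensitivity to low-abundance taxa (every non-shared rare taxon
#' contributes a full unit) is what makes this kernel effective for
#' person-level matching of grossly similar communities.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @param scaled Divide by the number of non-double-zero taxa (default).
#' @return Non-negative scalar distance.
#' @export
canberra_distance <- function(x, y, scaled = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  s <- x + y
  nz <- s > 0
  n_nz <- sum(nz)
  if (n_nz == 0L) stop("no shared support: both vectors are all zero")
  d <- sum(abs(x[nz] - y[nz]) / s[nz])
  if (scaled) d / n_nz else d
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)`; lies in `[0, 1]` for non-negative
#' input, 0 on identity and 1 for disjoint support.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all zero")
  sum(abs(x - y)) / tot
}

# Distances from one query vector to each row of a reference matrix,
# vectorised over references. Used by the matching loop.
dist_to_refs <- function(query, refs, metric = c("canberra", "bray_curtis")) {
  metric <- match.arg(metric)
  apply(refs, 1L, function(r) {
    if (metric == "canberra") canberra_distance(query, r) else
      bray_curtis(query, r)
  })
}

# Full symmetric Bray-Curtis matrix for a samples x taxa matrix.
bray_curtis_matrix <- function(values) {
  n <- nrow(values)
  d <- matrix(0, n, n, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(values[i, ], values[j, ])
    }
  }
  d
}
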