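# Lag-1 dynamic Bayesian networks over the six sites, one network per
# (location, taxonomic family): family abundances are log2-transformed,
# discretised into 5 equal-width bins, and a greedy hill-climbing search
# over single-edge moves maximises a BDeu score (equivalent sample size 1)
# computed over the 19 lag-1 transition pairs. Edges are read as dispersal
# routes parent-site -> child-site across one ~12 h step.

#' Build per-site family abundance series for one (location, family)
#'
#' Aggregates species to the family level, takes `log2(abundance +
#' epsilon)` per site and slot, and linearly interpolates internal
#' missing slots (with a message). The default epsilon is half the
#' smallest non-zero relative abundance in the table.
#'
#' @param table A species- or family-rank [abundance_table].
#' @param metadata Sample metadata.
#' @param location Location id.
#' @param family Family name (e.g. `"Family03"`).
#' @param epsilon Pseudo-count added before the log; `NULL` for the
#'   default.
#' @return List with `location`, `family`, `epsilon` and `series`, a
#'   20 x 6 matrix (slots x sites) of log2 abundances (NA where a slot is
#'   missing at the series edge).
#' @export
build_family_series <- function(table, metadata, location, family,
                                epsilon = NULL) {
  fam_table <- aggregate_to_family(table)
  hit <- which(fam_table$taxa$family == family)
  if (length(hit) == 0L) stop("family not in table: ", family)
  if (is.null(epsilon)) {
    nz <- table$values[table$values > 0]
    epsilon <- min(nz) / 2
  }
  md <- metadata[metadata$location == location, , drop = FALSE]
  if (nrow(md) == 0L) stop("no samples at location ", location)
  if (all(fam_table$values[md$sample_id, hit] == 0)) {
    cond <- structure(
      class = c("skintrace_family_absent", "error", "condition"),
      list(message = sprintf("family %s absent at location %d",
                             family, location), call = sys.call())
    )
    stop(cond)
  }
  series <- matrix(NA_real_, 20L, length(SITE_LEVELS),
                   dimnames = list(NULL, SITE_LEVELS))
  for (st in SITE_LEVELS) {
    sel <- md[md$site == st, , drop = FALSE]
    series[sel$timepoint + 1L, st] <-
      log2(fam_table$values[sel$sample_id, hit] + epsilon)
    x <- series[, st]
    obs <- which(!is.na(x))
    if (length(obs) >= 2L && length(obs) < 20L) {
      gap <- setdiff(seq.int(min(obs), max(obs)), obs)
      if (length(gap) > 0L) {
        message("interpolating ", length(gap), " slot(s) for ", st,
                " at location ", location)
        x[gap] <- stats::approx(obs, x[obs], xout = gap)$y
        series[, st] <- x
      }
    }
  }
  list(location = location, family = family, epsilon = epsilon,
       series = series)
}

#' Discretise a series into 5 equal-width bins (the i5 policy)
#'
#' Five equal-width intervals spanning `[min, max]`; the maximum falls in
#' bin 4. A constant series maps to the middle bin (2) with a message.
#'
#' @param values Numeric vector (no NA).
#' @param n_bins Number of bins (default 5).
#' @return Integer vector of bins `0 .. n_bins - 1`.
#' @export
discretize_i5 <- function(values, n_bins = 5L) {
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    message("constant series: all values assigned to the middle bin")
    return(rep(as.integer(n_bins %/% 2L), length(values)))
  }
  b <- floor((values - rng[1L]) / (rng[2L] - rng[1L]) * n_bins)
  as.integer(pmin(b, n_bins - 1L))
}

# BDeu (equivalent sample size `ess`) log marginal likelihood of one
# child's transitions given its parents' states; unobserved parent
# configurations contribute zero and are skipped.
score_child_family <- function(child_states, parent_states, ess = 1,
                               r = 5L) {
  n_par <- if (is.null(parent_states)) 0L else ncol(parent_states)
  q <- r^n_par
  conf <- if (n_par == 0L) rep(1, length(child_states)) else
    1 + as.vector(parent_states %*% r^(seq_len(n_par) - 1L))
  a_j <- ess / q
  a_jk <- ess / (q * r)
  score <- 0
  for (j in unique(conf)) {
    idx <- conf == j
    njk <- tabulate(child_states[idx] + 1L, nbins = r)
    score <- score + lgamma(a_j) - lgamma(a_j + sum(njk)) +
      sum(lgamma(a_jk + njk) - lgamma(a_jk))
  }
  score
}

# BIC alternative: log-likelihood of the transition multinomials minus
# (r - 1) * q * log(N) / 2 per child.
score_child_family_bic <- function(child_states, parent_states, r = 5L) {
  n_par <- if (is.null(parent_states)) 0L else ncol(parent_states)
  q <- r^n_par
  conf <- if (n_par == 0L) rep(1, length(child_states)) else
    1 + as.vector(parent_states %*% r^(seq_len(n_par) - 1L))
  ll <- 0
  for (j in unique(conf)) {
    njk <- tabulate(child_states[conf == j] + 1L, nbins = r)
    nj <- sum(njk)
    pos <- njk > 0
    ll <- ll + sum(njk[pos] * log(njk[pos] / nj))
  }
  ll - (r - 1) * q * log(length(child_states)) / 2
}

#' Score a lag-1 network on discretised transition data
#'
#' Decomposable score: the sum over child nodes of the per-child family
#' score given that child's parents. `"bdeu"` is the Dirichlet-multinomial
#' marginal likelihood with equivalent sample size 1; `"bic"` the
#' penalised multinomial log-likelihood.
#'
#' @param parents List (one element per node) of integer parent-node
#'   indices; each must have length <= `max_parents`.
#' @param disc Integer matrix (slots x nodes) of bins 0..4, no NA rows
#'   among used transitions.
#' @param score `"bdeu"` or `"bic"`.
#' @param max_parents Parent cap (default 5).
#' @return Scalar log score.
#' @export
score_network <- function(parents, disc, score = c("bdeu", "bic"),
                          max_parents = 5L) {
  score <- match.arg(score)
  if (nrow(disc) < 2L) stop("need at least one transition pair")
  if (any(vapply(parents, length, 0L) > max_parents)) {
    stop("a child exceeds the maximum parent count of ", max_parents)
  }
  ok <- which(stats::complete.cases(disc[-nrow(disc), , drop = FALSE]) &
                stats::complete.cases(disc[-1L, , drop = FALSE]))
  if (length(ok) == 0L) stop("no usable transition pairs")
  from <- disc[ok, , drop = FALSE]
  to <- disc[ok + 1L, , drop = FALSE]
  fun <- if (score == "bdeu") score_child_family else
    function(c_s, p_s, ...) score_child_family_bic(c_s, p_s)
  total <- 0
  for (child in seq_len(ncol(disc))) {
    ps <- if (length(parents[[child]]) == 0L) NULL else
      from[, parents[[child]], drop = FALSE]
    total <- total + fun(to[, child], ps)
  }
  total
}

#' Greedy hill-climbing structure search for one lag-1 network
#'
#' Starts from the empty network and repeatedly applies the single-edge
#' addition or deletion (over all parent/child pairs, self-edges
#' excluded) that most improves the decomposable score, until no move
#' improves it. Restarted `n_restarts` times with shuffled move
#' enumeration order (which only matters at exact ties); the best-scoring
#' network is returned. Deterministic given `seed`.
#'
#' @param disc Integer matrix (slots x 6 sites) of bins 0..4.
#' @param max_parents Parent cap per child (default 5).
#' @param n_restarts Number of restarts (default 5).
#' @param seed RNG seed.
#' @param score `"bdeu"` or `"bic"`.
#' @return List with `edges` (data frame parent/child site labels),
#'   `score`, `n_edges`, `score_trace` (accepted-move scores) and
#'   `parents`.
#' @export
greedy_search <- function(disc, max_parents = 5L, n_restarts = 5L,
                          seed = 1L, score = c("bdeu", "bic")) {
  score <- match.arg(score)
  n_nodes <- ncol(disc)
  nodes <- colnames(disc)
  if (is.null(nodes)) nodes <- paste0("node", seq_len(n_nodes))
  ok <- which(stats::complete.cases(disc[-nrow(disc), , drop = FALSE]) &
                stats::complete.cases(disc[-1L, , drop = FALSE]))
  from <- disc[ok, , drop = FALSE]
  to <- disc[ok + 1L, , drop = FALSE]
  fun <- if (score == "bdeu") score_child_family else
    function(c_s, p_s, ...) score_child_family_bic(c_s, p_s)
  child_score <- function(child, pset) {
    ps <- if (length(pset) == 0L) NULL else
      from[, pset, drop = FALSE]
    fun(to[, child], ps)
  }
  moves <- expand.grid(parent = seq_len(n_nodes), child = seq_len(n_nodes))
  moves <- moves[moves$parent != moves$child, , drop = FALSE]
  set.seed(seed)
  best <- NULL
  for (restart in seq_len(n_restarts)) {
    order_i <- sample.int(nrow(moves))
    parents <- rep(list(integer(0)), n_nodes)
    scores <- vapply(seq_len(n_nodes), function(ch) child_score(ch,
      integer(0)), 0)
    trace <- sum(scores)
    repeat {
      best_delta <- 1e-9
      best_move <- NULL
      for (mi in order_i) {
        p <- moves$parent[mi]; ch <- moves$child[mi]
        pset <- parents[[ch]]
        newset <- if (p %in% pset) setdiff(pset, p) else {
          if (length(pset) >= max_parents) next
          sort(c(pset, p))
        }
        delta <- child_score(ch, newset) - scores[ch]
        if (delta > best_delta) {
          best_delta <- delta
          best_move <- list(child = ch, pset = newset)
        }
      }
      if (is.null(best_move)) break
      parents[[best_move$child]] <- best_move$pset
      scores[best_move$child] <- child_score(best_move$child,
                                             best_move$pset)
      trace <- c(trace, sum(scores))
    }
    total <- sum(scores)
    if (is.null(best) || total > best$score + 1e-12) {
      best <- list(parents = parents, score = total, trace = trace)
    }
  }
  edges <- do.call(rbind, lapply(seq_len(n_nodes), function(ch) {
    if (length(best$parents[[ch]]) == 0L) return(NULL)
    data.frame(parent = nodes[best$parents[[ch]]], child = nodes[ch],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  }
  list(edges = edges, score = best$score, n_edges = nrow(edges),
       score_trace = best$trace, parents = best$parents)
}

#' Learn DBNs for every (location, family) combination
#'
#' For each location and each taxonomic family present there, builds the
#' per-site log2 family series, discretises each site with the i5 policy,
#' and runs [greedy_search()]. Families with fewer than `min_transitions`
#' usable lag-1 pairs are skipped.
#'
#' @param table A species-rank [abundance_table].
#' @param metadata Sample metadata.
#' @param max_parents,n_restarts,score Passed to [greedy_search()].
#' @param seed Base seed; each model derives its own.
#' @param min_transitions Minimum usable transition pairs (default 8).
#' @param locations,families Optional subsets.
#' @return List with `models` (one entry per learned network),
#'   `n_models`, and `fraction_with_edges`.
#' @export
learn_all <- function(table, metadata, max_parents = 5L, n_restarts = 5L,
                      score = "bdeu", seed = 1L, min_transitions = 8L,
                      locations = NULL, families = NULL) {
  fam_table <- aggregate_to_family(table)
  if (is.null(locations)) locations <- sort(unique(metadata$location))
  if (is.null(families)) families <- sort(unique(fam_table$taxa$family))
  models <- list()
  k <- 0L
  for (loc in locations) {
    for (fam in families) {
      k <- k + 1L
      fs <- tryCatch(
        build_family_series(table, metadata, loc, fam),
        skintrace_family_absent = function(e) NULL
      )
      if (is.null(fs)) next
      series <- fs$series
      usable <- sum(stats::complete.cases(series[-20L, ]) &
                      stats::complete.cases(series[-1L, ]))
      if (usable < min_transitions) next
      disc <- apply(series, 2L, function(x) {
        out <- rep(NA_integer_, length(x))
        obs <- !is.na(x)
        out[obs] <- suppressMessages(discretize_i5(x[obs]))
        out
      })
      colnames(disc) <- colnames(series)
      g <- greedy_search(disc, max_parents = max_parents,
                         n_restarts = n_restarts, seed = seed + k,
                         score = score)
      models[[length(models) + 1L]] <- list(
        location = loc, family = fam, edges = g$edges, score = g$score,
        n_edges = g$n_edges, score_metric = score
      )
    }
  }
  frac <- if (length(models)) {
    mean(vapply(models, function(m) m$n_edges > 0L, NA))
  } else NA_real_
  list(models = models, n_models = length(models),
       fraction_with_edges = frac)
}

#' Summarise edge roles across a set of DBNs
#'
#' Counts edges by (parent site class, child site class), tallies
#' per-node parent (out-degree) and child (in-degree) edge counts for
#' every node of every model, reports the most common class pair, and
#' runs Kruskal-Wallis tests for differences in per-node out-degree and
#' in-degree across the three site classes.
#'
#' @param models `models` element from [learn_all()] (or a list of model
#'   lists with `edges`).
#' @return List with `class_pair_counts` (3 x 3 matrix), `total_edges`,
#'   `most_common` (parent/child classes and count), `node_degrees`, and
#'   `kruskal_parent` / `kruskal_child` test results.
#' @export
summarize_edges <- function(models) {
  if (length(models) == 0L) stop("need at least one model")
  classes <- c("skin", "household", "public")
  counts <- matrix(0L, 3L, 3L, dimnames = list(parent = classes,
                                               child = classes))
  deg <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    outdeg <- stats::setNames(rep(0L, length(SITE_LEVELS)), SITE_LEVELS)
    indeg <- outdeg
    if (nrow(m$edges) > 0L) {
      pc <- site_class(m$edges$parent)
      cc <- site_class(m$edges$child)
      for (i in seq_len(nrow(m$edges))) {
        counts[pc[i], cc[i]] <- counts[pc[i], cc[i]] + 1L
      }
      t_out <- table(m$edges$parent)
      t_in <- table(m$edges$child)
      outdeg[names(t_out)] <- as.integer(t_out)
      indeg[names(t_in)] <- as.integer(t_in)
    }
    deg[[mi]] <- data.frame(
      model = mi, node = SITE_LEVELS, site_class = site_class(SITE_LEVELS),
      out_degree = unname(outdeg), in_degree = unname(indeg),
      stringsAsFactors = FALSE
    )
  }
  deg <- do.call(rbind, deg)
  kw <- function(values) {
    if (stats::sd(values) == 0) {
      return(list(statistic = 0, p.value = 1))
    }
    kt <- stats::kruskal.test(values, factor(deg$site_class, classes))
    list(statistic = unname(kt$statistic), p.value = kt$p.value)
  }
  total <- sum(counts)
  mc <- which(counts == max(counts), arr.ind = TRUE)[1L, ]
  list(
    class_pair_counts = counts,
    total_edges = total,
    most_common = list(parent_class = classes[mc[["parent"]]],
                       child_class = classes[mc[["child"]]],
                       count = max(counts)),
    node_degrees = deg,
    kruskal_parent = kw(deg$out_degree),
    kruskal_child = kw(deg$in_degree)
  )
}
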