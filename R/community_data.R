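# Data model and I/O for relative-abundance tables and sample metadata on the
# study's 4-location x 6-site x 20-timepoint grid.

#' Site labels used throughout the package
#'
#' The six sampled sites, in canonical order: two palm (skin) sites, two
#' household surface sites and two public surface sites.
#' @export
SITE_LEVELS <- c(
  "left_palm", "right_palm",
  "bed_headboard", "door_knob",
  "public_handrail", "subway_handrail"
)

.SITE_CLASS <- c(
  left_palm = "skin", right_palm = "skin",
  bed_headboard = "household", door_knob = "household",
  public_handrail = "public", subway_handrail = "public"
)

#' Map site labels to site classes
#'
#' Palms map to `"skin"`, bed headboard and door knob to `"household"`,
#' the two handrails to `"public"`.
#'
#' @param site Character vector of site labels (see [SITE_LEVELS]).
#' @return Character vector of classes among `"skin"`, `"household"`,
#'   `"public"`.
#' @export
site_class <- function(site) {
  bad <- setdiff(unique(site), names(.SITE_CLASS))
  if (length(bad) > 0L) {
    stop("unknown site label(s): ", paste(bad, collapse = ", "))
  }
  unname(.SITE_CLASS[site])
}

#' Timepoint index from day and period
#'
#' Maps (day, period) to the 0-based slot on the 20-point grid:
#' `2 * (day - 1)` for AM, plus one for PM.
#'
#' @param day Integer day 1-10.
#' @param period `"AM"` or `"PM"`.
#' @return Integer timepoint 0-19.
#' @export
timepoint_of <- function(day, period) {
  stopifnot(all(day >= 1), all(period %in% c("AM", "PM")))
  as.integer(2L * (day - 1L) + (period == "PM"))
}

# Parse MetaPhlAn-style lineage strings "k__...|p__...|f__...|s__..." into
# name/family/phylum/rank. Rank is "species" when an s__ field is present,
# otherwise "family".
parse_lineage <- function(lineage) {
  out <- data.frame(
    lineage = lineage, name = NA_character_, family = NA_character_,
    phylum = NA_character_, rank = NA_character_,
    stringsAsFactors = FALSE
  )
  parts <- strsplit(lineage, "|", fixed = TRUE)
  grab <- function(p, prefix) {
    hit <- p[startsWith(p, prefix)]
    if (length(hit) == 0L) NA_character_ else sub(prefix, "", hit[1L])
  }
  out$phylum <- vapply(parts, grab, "", prefix = "p__")
  out$family <- vapply(parts, grab, "", prefix = "f__")
  sp <- vapply(parts, grab, "", prefix = "s__")
  out$rank <- ifelse(is.na(sp), "family", "species")
  out$name <- ifelse(is.na(sp), out$family, sp)
  out
}

#' Construct an abundance table
#'
#' The central exchange object: a samples x taxa matrix of relative
#' abundances in percent, with taxa identified by full lineage strings.
#' Rows are renormalised to sum to 100.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns. Row
#'   names are sample ids, column names are lineage strings.
#' @return An object of class `abundance_table` with elements `values`
#'   (the renormalised matrix), `taxa` (data frame with `lineage`,
#'   `name`, `family`, `phylum`, `rank`) and `sample_ids`.
#' @export
abundance_table <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have sample row names and taxon column names")
  }
  if (anyDuplicated(colnames(values))) {
    stop("taxa must be unique by lineage string")
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(
      "negative abundance for sample ", rownames(values)[neg[1L, 1L]],
      ", taxon ", colnames(values)[neg[1L, 2L]]
    )
  }
  rs <- rowSums(values)
  if (any(rs <= 0)) {
    stop("sample(s) with zero total abundance: ",
         paste(rownames(values)[rs <= 0], collapse = ", "))
  }
  values <- sweep(values, 1L, rs / 100, "/")
  structure(
    list(
      values = values,
      taxa = parse_lineage(colnames(values)),
      sample_ids = rownames(values)
    ),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(
    "abundance_table:", length(x$sample_ids), "samples x",
    nrow(x$taxa), "taxa (", sum(x$taxa$rank == "species"),
    "species rank )\n"
  )
  invisible(x)
}

validate_metadata <- function(metadata) {
  required <- c("sample_id", "location", "site", "day", "period")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0L) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- !metadata$site %in% SITE_LEVELS
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(
      "sample ", metadata$sample_id[i], " has unknown site label '",
      metadata$site[i], "'"
    )
  }
  if (!all(metadata$period %in% c("AM", "PM"))) {
    stop("period must be AM or PM")
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         metadata$sample_id[anyDuplicated(metadata$sample_id)])
  }
  metadata$location <- as.integer(metadata$location)
  metadata$day <- as.integer(metadata$day)
  metadata$site_class <- site_class(metadata$site)
  metadata$timepoint <- timepoint_of(metadata$day, metadata$period)
  metadata
}

#' Read an abundance table and its sample metadata
#'
#' Reads a plain TSV abundance matrix (taxa rows, first column the lineage
#' string, one column per sample) together with a TSV metadata file (one
#' row per sample with `sample_id`, `location`, `site`, `day`, `period`).
#' Missing samples are represented by absence of a metadata row, never by
#' zero-filled columns. Rows are renormalised to sum to 100.
#'
#' @param path Path to the abundance TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A list with `table` (an [abundance_table]) and `metadata`
#'   (data frame with derived `site_class` and `timepoint` columns).
#' @export
read_abundance_table <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("abundance file must have lineage + sample columns")
  lineage <- raw[[1L]]
  mat <- t(as.matrix(raw[, -1L, drop = FALSE]))
  colnames(mat) <- lineage
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  metadata <- validate_metadata(metadata)
  unknown <- setdiff(rownames(mat), metadata$sample_id)
  if (length(unknown) > 0L) {
    stop("sample(s) in abundance table but not metadata: ",
         paste(unknown, collapse = ", "))
  }
  metadata <- metadata[match(rownames(mat), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  list(table = abundance_table(mat), metadata = metadata)
}

#' Write an abundance table (and optionally metadata) as TSV
#'
#' Inverse of [read_abundance_table()]: taxa rows, lineage first column.
#'
#' @param table An [abundance_table].
#' @param path Output TSV path.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(lineage = colnames(table$values),
                   t(table$values), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata as TSV
#' @param metadata Metadata data frame.
#' @param path Output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  keep <- intersect(
    c("sample_id", "location", "site", "site_class", "day", "period",
      "timepoint"),
    names(metadata)
  )
  utils::write.table(metadata[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate a species-rank table to family rank
#'
#' Sums member species within each taxonomic family; per-sample totals are
#' conserved exactly. A table that is already family rank is returned
#' unchanged.
#'
#' @param table An [abundance_table].
#' @return An [abundance_table] with one column per family, lineages of
#'   the form `k__...|p__...|f__Family`.
#' @export
aggregate_to_family <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (all(table$taxa$rank == "family")) return(table)
  orphan <- is.na(table$taxa$family) | table$taxa$family == ""
  if (any(orphan)) {
    stop("species lacking family annotation: ",
         paste(table$taxa$name[orphan], collapse = ", "))
  }
  fam <- table$taxa$family
  fam_lineage <- sub("\\|s__.*$", "", table$taxa$lineage)
  fam_lineage <- sub("\\|g__[^|]*$", "", fam_lineage)
  lin_of <- tapply(fam_lineage, fam, function(v) v[1L])
  groups <- factor(fam, levels = unique(fam))
  agg <- t(rowsum(t(table$values), group = groups))
  colnames(agg) <- unname(lin_of[colnames(agg)])
  abundance_table(agg)
}

#' Write a tabular result as TSV
#'
#' Generic result writer used by all stages; writes a header even when the
#' record set is empty (with a warning).
#'
#' @param records A data frame (or coercible list of records).
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    warning("writing header-only results table to ", path)
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
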