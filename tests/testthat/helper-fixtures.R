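# Small programmatic fixtures shared across test files.

# 3-taxon, 2-sample table whose rows sum to 100.
tiny_values <- function() {
  v <- rbind(
    s1 = c(50, 30, 20),
    s2 = c(10, 70, 20)
  )
  colnames(v) <- c(
    "k__Bacteria|p__P1|f__F1|s__SpA",
    "k__Bacteria|p__P1|f__F1|s__SpB",
    "k__Bacteria|p__P2|f__F2|s__SpC"
  )
  v
}

tiny_metadata <- function(sample_ids = c("s1", "s2"),
                          sites = c("left_palm", "door_knob"),
                          locations = c(1L, 1L),
                          days = c(1L, 1L),
                          periods = c("AM", "AM")) {
  data.frame(
    sample_id = sample_ids, location = locations, site = sites,
    day = days, period = periods, stringsAsFactors = FALSE
  )
}

# Write the pair of TSVs the reader expects; returns the two paths.
write_fixture <- function(values, metadata,
                          dir = local_dir(parent.frame())) {
  ab <- file.path(dir, "abundance.tsv")
  md <- file.path(dir, "metadata.tsv")
  df <- data.frame(lineage = colnames(values), t(values),
                   check.names = FALSE)
  utils::write.table(df, ab, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(metadata, md, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(abundance = ab, metadata = md)
}

# Temp directory scoped to the calling test, not to the helper itself.
local_dir <- function(envir = parent.frame()) {
  withr::local_tempdir(.local_envir = envir)
}

# Complete-grid synthetic data set (no missingness), cached per option set
# so several tests can share one generation.
full_grid_sim <- local({
  cache <- new.env()
  function(...) {
    key <- paste(deparse(list(...)), collapse = "")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_synthetic(
        synthetic_config(missing_prob = 0, ...)
      )
    }
    cache[[key]]
  }
})
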