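# On-disk artifacts. Internal coordinates are 1-based inclusive
# (array-manifest convention); BED export converts to 0-based half-open.

# numeric columns serialized at full precision so TSV round-trips exactly
format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v)
        if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
  }
  df
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format_full(as.data.frame(df)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of a run: DMR-calling parameters,
#' category-mapping thresholds, the enrichment FDR cut-off, the
#' expression-correlation significance cut-off, and the seed. All outputs
#' written by \code{\link{run_pipeline}} embed a fingerprint of these
#' values.
#'
#' @param dmr a \code{\link{dmr_params}} object.
#' @param thresholds a \code{\link{mapping_thresholds}} object.
#' @param enrichment_fdr FDR cut-off for enrichment significance.
#' @param expression_p two-sided p cut-off for candidate correlations.
#' @param seed integer seed used by the synthetic generator.
#' @return list of class \code{methmap_config}.
#' @export
pipeline_config <- function(dmr = dmr_params(),
                            thresholds = mapping_thresholds(),
                            enrichment_fdr = 0.05,
                            expression_p = 0.05,
                            seed = 1L) {
  for (v in c(enrichment_fdr, expression_p))
    if (v <= 0 || v >= 1) stopf("cut-offs must lie in (0,1)")
  structure(list(dmr = dmr, thresholds = thresholds,
                 enrichment_fdr = enrichment_fdr,
                 expression_p = expression_p, seed = as.integer(seed)),
            class = "methmap_config")
}

config_fingerprint <- function(config) {
  flat <- config_flatten(config)
  paste(sprintf("%s=%s", names(flat), flat), collapse = " ")
}

config_flatten <- function(config) {
  c(stats::setNames(vapply(config$dmr, function(v) format(v, digits = 15),
                           character(1)),
                    paste0("dmr.", names(config$dmr))),
    stats::setNames(vapply(config$thresholds,
                           function(v) format(v, digits = 15), character(1)),
                    paste0("thresholds.", names(config$thresholds))),
    enrichment_fdr = format(config$enrichment_fdr, digits = 15),
    expression_p = format(config$expression_p, digits = 15),
    seed = format(config$seed))
}

#' Write / read a pipeline configuration
#'
#' Flat key-value text file, one \code{key<TAB>value} pair per line.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param path file path.
#' @return \code{path} (write) or a \code{methmap_config} (read).
#' @export
write_config <- function(config, path) {
  flat <- config_flatten(config)
  writeLines(sprintf("%s\t%s", names(flat), flat), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  num <- function(k) as.numeric(vals[[k]])
  pipeline_config(
    dmr = dmr_params(min_cpgs = as.integer(num("dmr.min_cpgs")),
                     region_p_cutoff = num("dmr.region_p_cutoff"),
                     min_mean_abs_delta = num("dmr.min_mean_abs_delta"),
                     max_gap = as.integer(num("dmr.max_gap")),
                     per_probe_p_seed_cutoff = num("dmr.per_probe_p_seed_cutoff")),
    thresholds = mapping_thresholds(
      presence_min_abs_delta = num("thresholds.presence_min_abs_delta"),
      corroboration_min_abs_delta = num("thresholds.corroboration_min_abs_delta"),
      absence_max_abs_delta = num("thresholds.absence_max_abs_delta"),
      stringent_fold = num("thresholds.stringent_fold"),
      progenitor_arrested_disease = vals[["thresholds.progenitor_arrested_disease"]]),
    enrichment_fdr = num("enrichment_fdr"),
    expression_p = num("expression_p"),
    seed = as.integer(num("seed")))
}

#' Write DMR results to BED and TSV
#'
#' The BED file uses 0-based half-open intervals, the category as the name
#' field and \code{1000 * |mean delta-beta|} (capped at 1000) as the
#' score. The TSV keeps the full DMR table joined with the category
#' assignment and any per-comparison delta columns, at full numeric
#' precision, and is round-trippable via \code{\link{read_dmr_results}}.
#'
#' @param dmrs a \code{methmap_dmrs} table (may be empty).
#' @param path_prefix output prefix; writes \code{<prefix>.bed} and
#'   \code{<prefix>.tsv}.
#' @param assignments optional \code{methmap_assignments} to join.
#' @param profiles optional \code{methmap_profiles} to join.
#' @param header optional fingerprint line embedded in the TSV.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_dmr_results <- function(dmrs, path_prefix, assignments = NULL,
                              profiles = NULL, header = NULL) {
  full <- as.data.frame(dmrs)
  if (!is.null(assignments))
    full <- merge(full, as.data.frame(assignments), by = "dmr_id",
                  sort = FALSE)
  if (!is.null(profiles))
    full <- merge(full, as.data.frame(profiles), by = "dmr_id", sort = FALSE)
  tsv <- paste0(path_prefix, ".tsv")
  bed <- paste0(path_prefix, ".bed")
  write_tsv(full, tsv, header = header)
  name <- if (!is.null(assignments) && nrow(full))
    full$category else rep(".", nrow(full))
  name[is.na(name)] <- "."
  bed_df <- data.frame(chrom = full$chrom,
                       start = full$start - 1L,   # to 0-based half-open
                       end = full$end,
                       name = name,
                       score = pmin(round(1000 * abs(full$mean_delta_beta)),
                                    1000),
                       strand = rep(".", nrow(full)))
  con <- file(bed, "w")
  utils::write.table(bed_df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(tsv = tsv, bed = bed))
}

#' Read back a DMR results TSV
#'
#' @param path a \code{<prefix>.tsv} written by
#'   \code{\link{write_dmr_results}}.
#' @return data frame of class \code{methmap_dmrs} (plus any joined
#'   columns).
#' @export
read_dmr_results <- function(path) {
  df <- read_tsv(path)
  class(df) <- c("methmap_dmrs", "data.frame")
  df
}

# BED interval helpers (conversion tested both ways)
to_bed_interval <- function(start1, end1) {
  cbind(start = start1 - 1L, end = end1)
}
from_bed_interval <- function(start0, end0) {
  cbind(start = start0 + 1L, end = end0)
}
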