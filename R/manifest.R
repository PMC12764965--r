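#' Validate a probe manifest
#'
#' A probe manifest is a data frame with one row per array probe carrying its
#' genomic coordinates, CpG-island context, signed distance to the nearest
#' transcription start site (negative = upstream), the nearest gene symbol,
#' and semicolon-joined feature labels for the annotation namespaces
#' \code{chromHMM}, \code{histone} and \code{TFBS}.
#'
#' @param manifest data frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos}, \code{island_context}, \code{tss_distance},
#'   \code{nearest_gene} and optionally \code{chromHMM}, \code{histone},
#'   \code{TFBS}.
#' @return The manifest, sorted by chromosome then position, invisibly
#'   classed as \code{methmap_manifest}.
#' @export
validate_manifest <- function(manifest) {
  req <- c("probe_id", "chrom", "pos", "island_context", "tss_distance",
           "nearest_gene")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stopf("manifest is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stopf("duplicate probe_id in manifest: %s",
          manifest$probe_id[duplicated(manifest$probe_id)][1])
  ctx <- c("island", "shore", "shelf", "open_sea")
  bad <- setdiff(unique(manifest$island_context), ctx)
  if (length(bad))
    stopf("unknown island_context value(s): %s", paste(bad, collapse = ", "))
  if (any(is.na(manifest$pos)) || any(manifest$pos < 1))
    stopf("probe positions must be positive 1-based integers")
  manifest <- manifest[order(manifest$chrom, manifest$pos), , drop = FALSE]
  dup_pos <- ave(manifest$pos, manifest$chrom,
                 FUN = function(p) duplicated(p))
  if (any(dup_pos > 0))
    stopf("probes at identical positions on %s",
          manifest$chrom[which(dup_pos > 0)[1]])
  rownames(manifest) <- NULL
  class(manifest) <- c("methmap_manifest", "data.frame")
  invisible(manifest)
}

#' Read a probe manifest from TSV
#'
#' @param path path to a tab-delimited file with the columns described in
#'   \code{\link{validate_manifest}}.
#' @return A validated manifest data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (ns in c("chromHMM", "histone", "TFBS"))
    if (!ns %in% names(df)) df[[ns]] <- ""
  df[c("chromHMM", "histone", "TFBS")] <-
    lapply(df[c("chromHMM", "histone", "TFBS")],
           function(x) ifelse(is.na(x), "", as.character(x)))
  validate_manifest(df)
}

#' Write a probe manifest to TSV
#'
#' @param manifest a validated manifest.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' The sample sheet maps samples to populations and roles. Exactly one
#' population must carry the \code{baseline} role (the low-proliferation
#' progenitor reference); at least one population must carry the
#' \code{disease} role; the \code{normal_proliferated} role marks the
#' long-lived proliferated normal population (memory B cells in the
#' motivating study).
#'
#' @param sheet data frame with columns \code{sample_id}, \code{population},
#'   \code{role}.
#' @return The sheet, invisibly.
#' @export
validate_sheet <- function(sheet) {
  req <- c("sample_id", "population", "role")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stopf("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stopf("duplicate sample_id in sheet")
  roles <- c("baseline", "normal_proliferated", "disease")
  bad <- setdiff(unique(sheet$role), roles)
  if (length(bad))
    stopf("unknown role(s): %s", paste(bad, collapse = ", "))
  pop_role <- unique(sheet[c("population", "role")])
  if (anyDuplicated(pop_role$population))
    stopf("a population maps to more than one role")
  n_base <- length(unique(pop_role$population[pop_role$role == "baseline"]))
  if (n_base != 1L)
    stopf("exactly one baseline population required, found %d", n_base)
  if (!any(pop_role$role == "disease"))
    stopf("at least one disease population required")
  invisible(sheet)
}

# population names by role, in sheet order
populations_by_role <- function(sheet, role) {
  unique(sheet$population[sheet$role == role])
}

samples_of <- function(sheet, population) {
  sheet$sample_id[sheet$population %in% population]
}
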