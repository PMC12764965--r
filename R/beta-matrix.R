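#' Read a beta-value matrix from TSV
#'
#' Reads a probes-by-samples table of methylation fractions. The first
#' column holds probe identifiers; the remaining columns are samples.
#' Probes not present in the manifest are dropped (the count is reported via
#' a message); any value outside [0, 1] is a hard error naming the
#' offending probe and sample.
#'
#' @param path path to a tab-delimited table.
#' @param manifest a validated probe manifest; probes absent from it are
#'   dropped.
#' @return A numeric matrix (probes x samples) with probe ids as rownames,
#'   in manifest order.
#' @export
read_beta_matrix <- function(path, manifest) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stopf("duplicate probe_id in beta matrix: %s", ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stopf("beta value %.4g outside [0,1] at probe %s, sample %s",
          m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
          colnames(m)[bad[1, 2]])
  keep <- ids %in% manifest$probe_id
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("read_beta_matrix: dropped %d probe(s) absent from manifest",
                    n_drop))
  m <- m[keep, , drop = FALSE]
  # manifest order (genomic sort)
  m[manifest$probe_id[manifest$probe_id %in% rownames(m)], , drop = FALSE]
}

#' Write a beta-value matrix to TSV
#'
#' @param beta numeric matrix, probes x samples, probe ids as rownames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# group means per probe, honouring the missingness filter:
# a probe is NA'd for the comparison if more than `max_missing` of either
# group's values are missing; otherwise means ignore missing values
group_means <- function(beta, samples, max_missing = 0.2) {
  sub <- beta[, samples, drop = FALSE]
  frac_na <- rowMeans(is.na(sub))
  mu <- rowMeans(sub, na.rm = TRUE)
  mu[frac_na > max_missing] <- NA_real_
  mu
}
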