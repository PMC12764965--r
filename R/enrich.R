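#' Genomic-feature enrichment of a DMR set
#'
#' For each feature of a namespace, builds the 2x2 table of unique member
#' probes of the DMR set versus all other array probes, crossed with
#' feature membership, and tests it with a two-sided Fisher's exact test.
#' P-values are Benjamini-Hochberg adjusted within the (DMR set x
#' namespace) family. The odds ratio reported is the sample cross-product
#' ratio; features absent from both the set and the background are skipped.
#'
#' @param dmr_set a \code{methmap_dmrs} table (one group).
#' @param manifest validated probe manifest (the full-array background).
#' @param namespace one of \code{"island_context"}, \code{"chromHMM"},
#'   \code{"histone"}, \code{"TFBS"}.
#' @param group label carried into the result.
#' @return data frame of class \code{methmap_enrichment}, sorted by FDR:
#'   \code{group}, \code{namespace}, \code{feature}, the four cell counts
#'   (\code{set_with}, \code{set_without}, \code{bg_with},
#'   \code{bg_without}), \code{odds_ratio}, \code{p_value}, \code{fdr}.
#' @export
enrich <- function(dmr_set, manifest,
                   namespace = c("island_context", "chromHMM", "histone",
                                 "TFBS"),
                   group = "group") {
  namespace <- match.arg(namespace)
  if (nrow(dmr_set) == 0) stopf("empty DMR set")
  set_probes <- unique(unlist(strsplit(dmr_set$probes, ";", fixed = TRUE)))
  set_probes <- intersect(set_probes, manifest$probe_id)
  in_set <- manifest$probe_id %in% set_probes
  if (namespace == "island_context") {
    membership <- lapply(unique(manifest$island_context), function(f)
      manifest$island_context == f)
    names(membership) <- unique(manifest$island_context)
  } else {
    feats <- split_features(manifest[[namespace]])
    all_feats <- sort(unique(unlist(feats)))
    membership <- lapply(all_feats, function(f)
      vapply(feats, function(v) f %in% v, logical(1)))
    names(membership) <- all_feats
  }
  if (!length(membership)) {
    message(sprintf("enrich: no features in namespace %s", namespace))
    return(empty_enrichment())
  }
  rows <- lapply(names(membership), function(f) {
    has <- membership[[f]]
    a <- sum(in_set & has); b <- sum(in_set & !has)
    c_ <- sum(!in_set & has); d <- sum(!in_set & !has)
    if (a + c_ == 0) {
      message(sprintf("enrich: feature %s absent everywhere; skipped", f))
      return(NULL)
    }
    or <- if (a * d == 0 && b * c_ == 0) 1
          else if (b * c_ == 0) Inf
          else (a * d) / (b * c_)
    data.frame(group = group, namespace = namespace, feature = f,
               set_with = a, set_without = b, bg_with = c_, bg_without = d,
               odds_ratio = or, p_value = fisher_p(rbind(c(a, b), c(c_, d))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) return(empty_enrichment())
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$fdr, res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("methmap_enrichment", "data.frame")
  res
}

empty_enrichment <- function() {
  res <- data.frame(group = character(0), namespace = character(0),
                    feature = character(0), set_with = integer(0),
                    set_without = integer(0), bg_with = integer(0),
                    bg_without = integer(0), odds_ratio = numeric(0),
                    p_value = numeric(0), fdr = numeric(0),
                    stringsAsFactors = FALSE)
  class(res) <- c("methmap_enrichment", "data.frame")
  res
}

#' Enrichment across all namespaces
#'
#' @param dmr_set a \code{methmap_dmrs} table.
#' @param manifest validated manifest.
#' @param group label carried into the results.
#' @return row-bound \code{methmap_enrichment} across the four namespaces.
#' @export
enrich_all <- function(dmr_set, manifest, group = "group") {
  out <- lapply(c("island_context", "chromHMM", "histone", "TFBS"),
                function(ns) enrich(dmr_set, manifest, ns, group))
  res <- do.call(rbind, out)
  class(res) <- c("methmap_enrichment", "data.frame")
  res
}

#' Features enriched in every group
#'
#' Returns the features that are significantly enriched (FDR below the
#' cut-off and odds ratio above 1 — depletions are excluded) in every one
#' of the supplied per-group enrichment tables; the analogue of the shared
#' "core set" of transcription-factor binding sites.
#'
#' @param results list (length >= 2) of \code{methmap_enrichment} tables.
#' @param fdr_cutoff significance cut-off on the BH-adjusted p.
#' @return Character vector of shared feature labels (possibly empty).
#' @export
shared_features <- function(results, fdr_cutoff = 0.05) {
  if (length(results) < 2) stopf("need at least two groups")
  sig <- lapply(results, function(r)
    unique(r$feature[r$fdr < fdr_cutoff & r$odds_ratio > 1]))
  Reduce(intersect, sig)
}
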