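#' Methylation-expression correlation for one DMR/gene pair
#'
#' Because methylation and expression typically come from disjoint
#' cohorts, the correlation is computed across population-level means:
#' for each population present in both cohorts, the DMR's mean methylation
#' and the gene's mean expression are paired, and a Pearson correlation
#' with a two-sided p-value is computed over these pairs.
#'
#' @param dmr one row of a \code{methmap_dmrs} table.
#' @param gene gene label (row of the expression matrix).
#' @param beta probes x samples methylation matrix.
#' @param expression genes x samples expression matrix (log scale).
#' @param sheet methylation sample sheet.
#' @param expr_sheet expression sample sheet.
#' @return list with \code{r}, \code{p}, \code{n_populations}, or, when a
#'   variance is zero (e.g. an unlinked gene in noiseless data),
#'   \code{r = NA} with \code{degenerate = TRUE}.
#' @export
meth_expr_correlation <- function(dmr, gene, beta, expression, sheet,
                                  expr_sheet) {
  pops <- intersect(unique(sheet$population), unique(expr_sheet$population))
  if (length(pops) < 3) stopf("need at least 3 populations in both cohorts")
  if (!gene %in% rownames(expression))
    stopf("gene '%s' absent from expression matrix", gene)
  pr <- intersect(strsplit(dmr$probes, ";", fixed = TRUE)[[1]],
                  rownames(beta))
  meth <- vapply(pops, function(p)
    mean(group_means(beta[pr, , drop = FALSE], samples_of(sheet, p)),
         na.rm = TRUE), numeric(1))
  expr <- vapply(pops, function(p)
    mean(expression[gene, samples_of(expr_sheet, p)], na.rm = TRUE),
    numeric(1))
  if (stats::sd(meth) == 0 || stats::sd(expr) == 0)
    return(list(r = NA_real_, p = NA_real_, n_populations = length(pops),
                degenerate = TRUE))
  ct <- stats::cor.test(meth, expr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       n_populations = length(pops), degenerate = FALSE)
}

# nearest gene of a DMR = nearest_gene of the member probe with the
# smallest |tss_distance|; dmr-level TSS distance = that minimum
dmr_gene_tss <- function(dmrs, manifest) {
  gene_of <- stats::setNames(manifest$nearest_gene, manifest$probe_id)
  tss_of <- stats::setNames(abs(manifest$tss_distance), manifest$probe_id)
  out <- t(vapply(dmrs$probes, function(p) {
    pr <- strsplit(p, ";", fixed = TRUE)[[1]]
    i <- which.min(tss_of[pr])
    c(unname(gene_of[pr[i]]), as.character(unname(tss_of[pr[i]])))
  }, character(2), USE.NAMES = FALSE))
  colnames(out) <- c("gene", "tss")
  out
}

#' Nominate pan-cancer candidate genes
#'
#' Keeps cancer-specific and cancer-absent DMRs whose nearest gene shows a
#' significant negative methylation-expression correlation across
#' population means, annotates the promoter-proximity filter (TSS distance
#' below 1000 bp) and the effect-size filter (|delta-beta| above
#' \code{effect_min} versus baseline in every disease, and versus
#' the proliferated normal population in the same direction), and ranks by
#' (both filters passed, |r|).
#'
#' @param assignments pan-mode \code{methmap_assignments}.
#' @param dmrs the corresponding \code{methmap_dmrs} table.
#' @param profiles the corresponding \code{methmap_profiles}.
#' @param manifest validated manifest.
#' @param beta,expression,sheet,expr_sheet data for
#'   \code{\link{meth_expr_correlation}}.
#' @param p_cutoff two-sided significance cut-off on the correlation.
#' @param effect_min effect-size filter threshold (default 0.2).
#' @param tss_cut promoter cut-off in bp.
#' @return data frame of class \code{methmap_candidates}: \code{gene},
#'   \code{dmr_id}, \code{category}, \code{correlation},
#'   \code{correlation_p}, \code{tss_distance}, \code{n_cpgs},
#'   \code{passes_promoter_filter}, \code{passes_effect_filter}, ranked.
#' @export
nominate_pan <- function(assignments, dmrs, profiles, manifest, beta,
                         expression, sheet, expr_sheet,
                         p_cutoff = 0.05, effect_min = 0.2,
                         tss_cut = 1000) {
  keep <- assignments$category %in% c("cancer_specific", "cancer_absent")
  ids <- assignments$dmr_id[keep]
  cand <- list()
  memory <- attr(profiles, "memory")
  diseases <- attr(profiles, "diseases")
  for (id in ids) {
    dmr <- dmrs[dmrs$dmr_id == id, ]
    gt <- dmr_gene_tss(dmr, manifest)
    gene <- gt[1, "gene"]; tssd <- as.numeric(gt[1, "tss"])
    cc <- meth_expr_correlation(dmr, gene, beta, expression, sheet,
                                expr_sheet)
    if (isTRUE(cc$degenerate) || is.na(cc$r)) next
    if (!(cc$r < 0 && cc$p < p_cutoff)) next
    prof <- profiles[profiles$dmr_id == id, ]
    s <- sign(prof$discovery_delta)
    dis_d <- unlist(prof[, diseases, drop = FALSE])
    mem_d <- prof[[memory]]
    effect_ok <- all(sign(dis_d) == s & abs(dis_d) > effect_min)
    # cancer-absent changes sit in the normal proliferated population
    if (assignments$category[assignments$dmr_id == id] == "cancer_absent")
      effect_ok <- sign(mem_d) == s && abs(mem_d) > effect_min
    cand[[length(cand) + 1L]] <- data.frame(
      gene = gene, dmr_id = id,
      category = assignments$category[assignments$dmr_id == id],
      correlation = cc$r, correlation_p = cc$p,
      tss_distance = tssd, n_cpgs = dmr$n_cpgs,
      passes_promoter_filter = tssd < tss_cut,
      passes_effect_filter = effect_ok, stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty_candidates())
  res <- do.call(rbind, cand)
  res <- res[order(-(res$passes_promoter_filter & res$passes_effect_filter),
                   -abs(res$correlation)), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("methmap_candidates", "data.frame")
  res
}

empty_candidates <- function() {
  res <- data.frame(gene = character(0), dmr_id = character(0),
                    category = character(0), correlation = numeric(0),
                    correlation_p = numeric(0), tss_distance = numeric(0),
                    n_cpgs = integer(0),
                    passes_promoter_filter = logical(0),
                    passes_effect_filter = logical(0),
                    stringsAsFactors = FALSE)
  class(res) <- c("methmap_candidates", "data.frame")
  res
}

#' Nominate per-disease candidate genes
#'
#' Keeps disease-specific DMRs whose nearest gene shows a reciprocal
#' specific expression difference: in the examined disease, expression
#' differs from every other population in the direction opposite to the
#' methylation change (hypermethylation with disease-lowest expression, or
#' hypomethylation with disease-highest expression).
#'
#' @param assignments per-disease \code{methmap_assignments} for one
#'   disease.
#' @param disease the disease examined.
#' @param dmrs,profiles,manifest,expression,expr_sheet as in
#'   \code{\link{nominate_pan}}.
#' @return \code{methmap_candidates} table (correlation fields NA; the
#'   reciprocity rule, not a correlation, is the selection criterion).
#' @export
nominate_per_disease <- function(assignments, disease, dmrs, profiles,
                                 manifest, expression, expr_sheet) {
  keep <- !is.na(assignments$category) &
    assignments$category == "disease_specific"
  ids <- assignments$dmr_id[keep]
  pops <- unique(expr_sheet$population)
  others <- setdiff(pops, disease)
  cand <- list()
  for (id in ids) {
    dmr <- dmrs[dmrs$dmr_id == id, ]
    gt <- dmr_gene_tss(dmr, manifest)
    gene <- gt[1, "gene"]; tssd <- as.numeric(gt[1, "tss"])
    if (!gene %in% rownames(expression)) next
    ex <- vapply(pops, function(p)
      mean(expression[gene, samples_of(expr_sheet, p)], na.rm = TRUE),
      numeric(1))
    s <- sign(profiles[[disease]][profiles$dmr_id == id])
    reciprocal <- all(sign(ex[[disease]] - ex[others]) == -s)
    if (!reciprocal) next
    cand[[length(cand) + 1L]] <- data.frame(
      gene = gene, dmr_id = id, category = "disease_specific",
      correlation = NA_real_, correlation_p = NA_real_,
      tss_distance = tssd, n_cpgs = dmr$n_cpgs,
      passes_promoter_filter = tssd < 1000,
      passes_effect_filter = NA, stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty_candidates())
  res <- do.call(rbind, cand)
  rownames(res) <- NULL
  class(res) <- c("methmap_candidates", "data.frame")
  res
}
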