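#' Descriptive summary of a DMR group
#'
#' Reports, for one category of DMRs, the count, mean and range of CpG
#' sites per DMR, mean and range of DMR size, hyper/hypomethylation split,
#' and the fraction lying promoter-proximal. A DMR's distance to the
#' nearest TSS is the minimum absolute probe-level TSS distance over its
#' member probes; proximal means strictly less than \code{tss_cut} bp
#' (a DMR at exactly the cut-off counts as distal).
#'
#' @param dmrs a \code{methmap_dmrs} table restricted to one group.
#' @param manifest validated probe manifest.
#' @param label group label to carry in the output.
#' @param tss_cut promoter-proximity cut-off in bp (default 1000).
#' @return One-row data frame (class \code{methmap_group_summary}).
#' @export
summarize_group <- function(dmrs, manifest, label = "group",
                            tss_cut = 1000) {
  if (nrow(dmrs) == 0) {
    out <- data.frame(group = label, n_dmrs = 0L,
                      mean_cpgs = NA_real_, min_cpgs = NA_integer_,
                      max_cpgs = NA_integer_, mean_bp = NA_real_,
                      min_bp = NA_integer_, max_bp = NA_integer_,
                      n_hyper = 0L, n_hypo = 0L, fraction_hyper = NA_real_,
                      n_tss_proximal = 0L, n_tss_distal = 0L,
                      fraction_proximal = NA_real_, stringsAsFactors = FALSE)
    class(out) <- c("methmap_group_summary", "data.frame")
    return(out)
  }
  tssd <- stats::setNames(abs(manifest$tss_distance), manifest$probe_id)
  dmr_tss <- vapply(dmrs$probes, function(p) {
    pr <- strsplit(p, ";", fixed = TRUE)[[1]]
    min(tssd[pr], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  n_hyper <- sum(dmrs$direction == "hyper")
  n_prox <- sum(dmr_tss < tss_cut)
  out <- data.frame(group = label, n_dmrs = nrow(dmrs),
                    mean_cpgs = mean(dmrs$n_cpgs),
                    min_cpgs = min(dmrs$n_cpgs), max_cpgs = max(dmrs$n_cpgs),
                    mean_bp = mean(dmrs$size_bp),
                    min_bp = min(dmrs$size_bp), max_bp = max(dmrs$size_bp),
                    n_hyper = n_hyper, n_hypo = nrow(dmrs) - n_hyper,
                    fraction_hyper = round_half_up(100 * n_hyper / nrow(dmrs), 1),
                    n_tss_proximal = n_prox,
                    n_tss_distal = nrow(dmrs) - n_prox,
                    fraction_proximal = round_half_up(100 * n_prox / nrow(dmrs), 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("methmap_group_summary", "data.frame")
  out
}

#' Compare a proportion between two DMR groups
#'
#' Two-sided Fisher's exact test on the 2x2 table of counts
#' (hyper/hypo or TSS-proximal/distal) between two group summaries.
#'
#' @param groupA,groupB outputs of \code{\link{summarize_group}}.
#' @param which \code{"hyper"} or \code{"proximal"}.
#' @return Two-sided p-value.
#' @export
compare_fractions <- function(groupA, groupB, which = c("hyper", "proximal")) {
  which <- match.arg(which)
  tab <- if (which == "hyper")
    rbind(c(groupA$n_hyper, groupA$n_hypo),
          c(groupB$n_hyper, groupB$n_hypo))
  else
    rbind(c(groupA$n_tss_proximal, groupA$n_tss_distal),
          c(groupB$n_tss_proximal, groupB$n_tss_distal))
  if (sum(tab) == 0) stopf("zero-total table")
  fisher_p(tab)
}

#' Compare mean CpG counts between two DMR groups
#'
#' Welch's two-sided t-test on the per-DMR CpG counts of two groups
#' (counts are discrete but group sizes are typically large enough for
#' the location test; an exact test fits proportions, not means).
#'
#' @param dmrsA,dmrsB \code{methmap_dmrs} tables (>= 2 DMRs each).
#' @return Two-sided p-value.
#' @export
compare_cpg_means <- function(dmrsA, dmrsB) {
  if (nrow(dmrsA) < 2 || nrow(dmrsB) < 2)
    stopf("need at least 2 DMRs per group")
  stats::t.test(dmrsA$n_cpgs, dmrsB$n_cpgs)$p.value
}

# two-sided Fisher's exact p for a 2x2 count table
fisher_p <- function(tab) {
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Cross-comparison correlation of effect sizes
#'
#' Pearson correlation of per-DMR beta differences between two
#' comparisons (e.g. disease-versus-baseline against proliferated-normal-
#' versus-baseline), reproducing the replicated-landscape check. Also
#' counts DMRs whose y-axis change opposes the discovery direction.
#'
#' @param profiles a \code{methmap_profiles} table.
#' @param x,y column names of the two comparisons
#'   (\code{"discovery_delta"} or a population label).
#' @return list with \code{r}, \code{p}, \code{n},
#'   \code{n_opposite} (sign(y) != sign(discovery)), and the plotted
#'   \code{points} data frame.
#' @export
cross_comparison_correlation <- function(profiles, x, y) {
  if (nrow(profiles) < 3) stopf("need at least 3 profiles")
  xv <- profiles[[x]]; yv <- profiles[[y]]
  if (is.null(xv) || is.null(yv)) stopf("unknown comparison label")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stopf("zero variance in one of the comparisons; correlation undefined")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xv),
       n_opposite = sum(sign(yv) != sign(profiles$discovery_delta)),
       points = data.frame(dmr_id = profiles$dmr_id, x = xv, y = yv,
                           stringsAsFactors = FALSE))
}
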