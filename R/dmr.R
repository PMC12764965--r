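#' DMR-calling parameters
#'
#' Region criteria for the simplified DMR caller: a region must contain at
#' least \code{min_cpgs} probes, reach a combined significance below
#' \code{region_p_cutoff}, and show an average beta-value difference of at
#' least \code{min_mean_abs_delta} (0.2 by default, 0.1 as the relaxed
#' alternative). Probes enter a region as seeds when their own two-sided p
#' falls below \code{per_probe_p_seed_cutoff}; consecutive sign-consistent
#' seeds are chained while inter-probe gaps stay within \code{max_gap}.
#'
#' @param min_cpgs minimum probes per DMR (>= 2).
#' @param region_p_cutoff region-level significance cut-off.
#' @param min_mean_abs_delta minimum |mean beta difference| across the DMR.
#' @param max_gap maximum genomic gap (bp) between chained probes.
#' @param per_probe_p_seed_cutoff per-probe p below which a probe can seed
#'   or extend a region.
#' @return list of class \code{methmap_dmr_params}.
#' @export
dmr_params <- function(min_cpgs = 2L, region_p_cutoff = 1e-4,
                       min_mean_abs_delta = 0.2, max_gap = 1000L,
                       per_probe_p_seed_cutoff = 0.01) {
  if (min_cpgs < 2L) stopf("min_cpgs must be >= 2")
  for (v in c(region_p_cutoff, min_mean_abs_delta, per_probe_p_seed_cutoff))
    if (v <= 0 || v >= 1) stopf("cut-offs must lie in (0,1)")
  structure(list(min_cpgs = as.integer(min_cpgs),
                 region_p_cutoff = region_p_cutoff,
                 min_mean_abs_delta = min_mean_abs_delta,
                 max_gap = as.integer(max_gap),
                 per_probe_p_seed_cutoff = per_probe_p_seed_cutoff),
            class = "methmap_dmr_params")
}

#' Per-probe differential methylation test
#'
#' Welch's two-sided t-test per probe on logit-transformed beta values
#' (an M-value-like scale that stabilizes variance), with group variances
#' floored at \code{var_floor} so zero-variance groups remain testable.
#' The effect size \code{delta_beta} is reported on the beta scale
#' (mean of group B minus mean of group A). Probes with more than 20%
#' missing values in either group are omitted.
#'
#' @param beta probes x samples matrix.
#' @param groupA,groupB character vectors of sample ids (>= 2 each).
#' @param var_floor lower bound on the per-group variance of the logit
#'   values entering the test.
#' @return data frame with \code{probe_id}, \code{delta_beta},
#'   \code{statistic}, \code{p_value}.
#' @export
per_probe_test <- function(beta, groupA, groupB, var_floor = 1e-3) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stopf("each group needs at least 2 samples")
  missing <- setdiff(c(groupA, groupB), colnames(beta))
  if (length(missing))
    stopf("samples not in beta matrix: %s", paste(missing, collapse = ", "))
  a <- beta[, groupA, drop = FALSE]
  b <- beta[, groupB, drop = FALSE]
  ok <- rowMeans(is.na(a)) <= 0.2 & rowMeans(is.na(b)) <= 0.2
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  la <- logit(a); lb <- logit(b)
  na <- rowSums(!is.na(la)); nb <- rowSums(!is.na(lb))
  ma <- rowMeans(la, na.rm = TRUE); mb <- rowMeans(lb, na.rm = TRUE)
  va <- pmax(apply(la, 1, stats::var, na.rm = TRUE), var_floor)
  vb <- pmax(apply(lb, 1, stats::var, na.rm = TRUE), var_floor)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(probe_id = rownames(a),
             delta_beta = rowMeans(b, na.rm = TRUE) - rowMeans(a, na.rm = TRUE),
             statistic = tstat, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

# direction-aware Stouffer combination of two-sided per-probe p-values
stouffer_p <- function(p, delta) {
  z <- sign(delta) * stats::qnorm(pmin(p, 1 - 1e-16) / 2, lower.tail = FALSE)
  Z <- sum(z) / sqrt(length(z))
  max(2 * stats::pnorm(-abs(Z)), .Machine$double.xmin)
}

#' Call differentially methylated regions
#'
#' Chains consecutive seed probes (per-probe p below the seed cut-off,
#' consistent sign of \code{delta_beta}) along each chromosome while gaps
#' stay within \code{max_gap}; a non-seed probe, a sign flip or a large gap
#' terminates the chain. Chains are kept as DMRs when they contain at
#' least \code{min_cpgs} probes, their direction-aware Stouffer-combined p
#' is below \code{region_p_cutoff}, and the mean beta difference across
#' member probes exceeds \code{min_mean_abs_delta} in magnitude.
#'
#' @param diffs output of \code{\link{per_probe_test}}.
#' @param manifest validated probe manifest (genomic order).
#' @param params a \code{\link{dmr_params}} object.
#' @return data frame of class \code{methmap_dmrs}: one row per DMR with
#'   \code{dmr_id}, \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive), \code{n_cpgs}, \code{size_bp}, \code{mean_delta_beta},
#'   \code{region_p}, \code{direction}, \code{probes} (semicolon-joined).
#' @export
call_dmrs <- function(diffs, manifest, params = dmr_params()) {
  m <- as.data.frame(manifest)[, c("probe_id", "chrom", "pos")]
  d <- merge(m, diffs, by = "probe_id", sort = FALSE)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  if (nrow(d) == 0) return(empty_dmrs())
  is_seed <- d$p_value < params$per_probe_p_seed_cutoff & d$delta_beta != 0
  out <- list()
  i <- 1L
  n <- nrow(d)
  while (i <= n) {
    if (!is_seed[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && is_seed[j + 1L] &&
           d$chrom[j + 1L] == d$chrom[j] &&
           d$pos[j + 1L] - d$pos[j] <= params$max_gap &&
           sign(d$delta_beta[j + 1L]) == sign(d$delta_beta[i])) {
      j <- j + 1L
    }
    if (j - i + 1L >= params$min_cpgs) {
      idx <- i:j
      mean_delta <- mean(d$delta_beta[idx])
      rp <- stouffer_p(d$p_value[idx], d$delta_beta[idx])
      if (rp < params$region_p_cutoff &&
          abs(mean_delta) >= params$min_mean_abs_delta) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = d$chrom[i], start = d$pos[i], end = d$pos[j],
          n_cpgs = j - i + 1L, size_bp = d$pos[j] - d$pos[i] + 1L,
          mean_delta_beta = mean_delta, region_p = rp,
          direction = if (mean_delta > 0) "hyper" else "hypo",
          probes = paste(d$probe_id[idx], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    i <- j + 1L
  }
  if (!length(out)) return(empty_dmrs())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$dmr_id <- sprintf("DMR%04d", seq_len(nrow(res)))
  res <- res[c("dmr_id", setdiff(names(res), "dmr_id"))]
  rownames(res) <- NULL
  class(res) <- c("methmap_dmrs", "data.frame")
  res
}

empty_dmrs <- function() {
  res <- data.frame(dmr_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    n_cpgs = integer(0), size_bp = integer(0),
                    mean_delta_beta = numeric(0), region_p = numeric(0),
                    direction = character(0), probes = character(0),
                    stringsAsFactors = FALSE)
  class(res) <- c("methmap_dmrs", "data.frame")
  res
}

#' Mean beta-value difference of a DMR between two groups
#'
#' Averages, over the DMR's member probes, the difference of group-mean
#' beta values (group B minus group A). Reusable for any pair of groups,
#' not only the discovery pair — this is how cross-population effect
#' profiles are built.
#'
#' @param dmr one row of a \code{methmap_dmrs} table (or a list with a
#'   \code{probes} field).
#' @param beta probes x samples matrix.
#' @param groupA,groupB character vectors of sample ids.
#' @return Signed mean beta difference.
#' @export
effect_size <- function(dmr, beta, groupA, groupB) {
  pr <- strsplit(dmr$probes, ";", fixed = TRUE)[[1]]
  pr <- intersect(pr, rownames(beta))
  if (!length(pr)) stopf("no member probe of %s present in beta matrix",
                         dmr$dmr_id %||% "DMR")
  ma <- group_means(beta[pr, , drop = FALSE], groupA)
  mb <- group_means(beta[pr, , drop = FALSE], groupB)
  ok <- !is.na(ma) & !is.na(mb)
  if (!any(ok)) stopf("no member probe with sufficient data")
  mean(mb[ok] - ma[ok])
}

#' @export
print.methmap_dmrs <- function(x, ...) {
  cat(sprintf("DMR set: %d regions (%d hyper, %d hypo)\n", nrow(x),
              sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  if (nrow(x)) {
    cat(sprintf("  mean |delta-beta| %.3f, mean CpGs/DMR %.1f\n",
                mean(abs(x$mean_delta_beta)), mean(x$n_cpgs)))
    print(utils::head(as.data.frame(x)[, c("dmr_id", "chrom", "start",
                                           "end", "n_cpgs",
                                           "mean_delta_beta", "direction")],
                      6))
  }
  invisible(x)
}
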