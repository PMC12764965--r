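#' Run the full integrative methylation mapping pipeline
#'
#' Orchestrates every stage on either a synthetic dataset (generated from
#' \code{sim_spec} when \code{inputs} is \code{NULL}) or user-supplied
#' files: DMR discovery for the combined-disease, proliferated-normal and
#' per-disease comparisons against baseline; cross-population effect
#' profiling; pan-mode and per-disease category mapping; group
#' characterization and cross-comparison correlation; genomic-feature
#' enrichment per category; methylation-expression candidate nomination;
#' and, when planted truth is available, a recovery report. All stage
#' outputs are written under \code{out_dir} with the config fingerprint
#' embedded; the run is deterministic given the config seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param inputs \code{NULL} (simulate) or a named list of paths:
#'   \code{manifest}, \code{beta}, \code{sheet}, and optionally
#'   \code{expression}, \code{expr_sheet}.
#' @param sim_spec a \code{\link{simulation_spec}} used when
#'   \code{inputs} is \code{NULL}; its seed is overridden by the config
#'   seed.
#' @param out_dir output directory (created); \code{NULL} skips writing.
#' @return An object of class \code{methmap_run}.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         sim_spec = NULL, out_dir = NULL) {
  stage <- "load"
  result <- tryCatch({
    if (is.null(inputs)) {
      spec <- sim_spec %||% simulation_spec()
      spec$seed <- config$seed
      data <- simulate_methylome(spec)
    } else {
      manifest <- read_manifest(inputs$manifest)
      beta <- read_beta_matrix(inputs$beta, manifest)
      sheet <- utils::read.delim(inputs$sheet, stringsAsFactors = FALSE)
      validate_sheet(sheet)
      data <- list(manifest = manifest, beta = beta, sheet = sheet,
                   truth = NULL)
      if (!is.null(inputs$expression)) {
        expr_df <- utils::read.delim(inputs$expression,
                                     stringsAsFactors = FALSE,
                                     check.names = FALSE)
        expr <- as.matrix(expr_df[, -1, drop = FALSE])
        rownames(expr) <- expr_df[[1]]
        data$expression <- expr
        es <- utils::read.delim(inputs$expr_sheet, stringsAsFactors = FALSE)
        data$expr_sheet <- es
      }
    }
    run_pipeline_stages(config, data, out_dir)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  result
}

# stage execution on in-memory data (exported so synthetic objects built in
# tests can be run without touching disk)
#' @rdname run_pipeline
#' @param data in-memory list as produced by
#'   \code{\link{simulate_methylome}}.
#' @export
run_pipeline_stages <- function(config, data, out_dir = NULL) {
  manifest <- data$manifest
  beta <- data$beta
  sheet <- data$sheet
  t <- config$thresholds
  fp <- config_fingerprint(config)

  baseline <- populations_by_role(sheet, "baseline")
  memory <- populations_by_role(sheet, "normal_proliferated")
  diseases <- populations_by_role(sheet, "disease")
  base_s <- samples_of(sheet, baseline)
  dis_s <- samples_of(sheet, diseases)
  mem_s <- samples_of(sheet, memory)

  # --- DMR discovery -------------------------------------------------
  discoveries <- list()
  discoveries$pan <- call_dmrs(per_probe_test(beta, base_s, dis_s),
                               manifest, config$dmr)
  discoveries$memory <- call_dmrs(per_probe_test(beta, base_s, mem_s),
                                  manifest, config$dmr)
  for (d in diseases)
    discoveries[[d]] <- call_dmrs(
      per_probe_test(beta, base_s, samples_of(sheet, d)),
      manifest, config$dmr)

  # --- pan-mode universe: discovery DMRs plus non-overlapping
  #     memory-discovered DMRs (cancer-absent changes need not reach
  #     significance in the disease comparison) ------------------------
  universe <- rbind(as.data.frame(discoveries$pan),
                    as.data.frame(novel_dmrs(discoveries$memory,
                                             discoveries$pan)))
  if (nrow(universe)) {
    universe$dmr_id <- sprintf("DMR%04d", seq_len(nrow(universe)))
  }
  class(universe) <- c("methmap_dmrs", "data.frame")

  pan_profiles <- build_profiles(universe, beta, sheet)
  pan_assign <- classify_profiles(pan_profiles, t, mode = "pan")
  pan_summary <- summarize_categories(pan_assign,
                                      total_dmrs = max(nrow(discoveries$pan), 1L))

  # --- per-disease mode ----------------------------------------------
  per_disease <- list()
  for (d in diseases) {
    dmrs_d <- discoveries[[d]]
    if (nrow(dmrs_d) == 0) {
      per_disease[[d]] <- list(dmrs = dmrs_d, profiles = NULL,
                               assignments = NULL)
      next
    }
    prof_d <- build_profiles(dmrs_d, beta, sheet,
                             discovery = samples_of(sheet, d))
    asg_d <- classify_profiles(prof_d, t, mode = "per_disease", disease = d)
    per_disease[[d]] <- list(dmrs = dmrs_d, profiles = prof_d,
                             assignments = asg_d)
  }

  # --- characterization ----------------------------------------------
  categories <- c("proliferation", "differentiation", "cancer_specific",
                  "cancer_absent")
  group_summaries <- do.call(rbind, lapply(categories, function(cat) {
    ids <- pan_assign$dmr_id[pan_assign$category == cat]
    summarize_group(universe[universe$dmr_id %in% ids, ], manifest, cat)
  }))
  correlation <- if (nrow(pan_profiles) >= 3 &&
                     stats::sd(pan_profiles[[memory]]) > 0 &&
                     stats::sd(pan_profiles$discovery_delta) > 0)
    cross_comparison_correlation(pan_profiles, "discovery_delta", memory)
  else NULL

  # --- enrichment ------------------------------------------------------
  enrichment <- list()
  for (cat in categories) {
    ids <- pan_assign$dmr_id[pan_assign$category == cat]
    set <- universe[universe$dmr_id %in% ids, ]
    if (nrow(set) > 0)
      enrichment[[cat]] <- enrich_all(set, manifest, group = cat)
  }
  core_features <- if (length(enrichment) >= 2)
    shared_features(enrichment, fdr_cutoff = config$enrichment_fdr)
  else character(0)

  # --- expression integration ------------------------------------------
  candidates <- list(pan = empty_candidates(), per_disease = list())
  if (!is.null(data$expression)) {
    candidates$pan <- nominate_pan(pan_assign, universe, pan_profiles,
                                   manifest, beta, data$expression, sheet,
                                   data$expr_sheet,
                                   p_cutoff = config$expression_p)
    for (d in diseases) {
      pd <- per_disease[[d]]
      if (is.null(pd$assignments)) next
      candidates$per_disease[[d]] <-
        nominate_per_disease(pd$assignments, d, pd$dmrs, pd$profiles,
                             manifest, data$expression, data$expr_sheet)
    }
  }

  # --- recovery against planted truth ----------------------------------
  recovery <- if (!is.null(data$truth))
    recovery_report(data$truth, discoveries, universe, pan_assign,
                    pan_profiles, per_disease, sheet, t)
  else NULL

  run <- structure(list(config = config, manifest = manifest, sheet = sheet,
                        discoveries = discoveries, universe = universe,
                        profiles = pan_profiles, assignments = pan_assign,
                        summary_table = pan_summary,
                        per_disease = per_disease,
                        group_summaries = group_summaries,
                        correlation = correlation,
                        enrichment = enrichment,
                        core_features = core_features,
                        candidates = candidates,
                        recovery = recovery),
                   class = "methmap_run")
  if (!is.null(out_dir)) write_run(run, out_dir, fp, data)
  run
}

# memory-discovered DMRs that share no member probe with any pan DMR
novel_dmrs <- function(new, existing) {
  if (nrow(new) == 0 || nrow(existing) == 0) return(new)
  existing_probes <- unique(unlist(strsplit(existing$probes, ";",
                                            fixed = TRUE)))
  keep <- vapply(new$probes, function(p)
    !any(strsplit(p, ";", fixed = TRUE)[[1]] %in% existing_probes),
    logical(1), USE.NAMES = FALSE)
  new[keep, , drop = FALSE]
}

# match planted DMRs to calls by shared member probes in the comparison
# where the category is discoverable, then score category recovery:
# pan categories against the pan-mode assignment, disease-specific against
# the per-disease assignment of that disease's own calls, disease-absent
# by classifying the pan-universe region's profile from that disease's
# perspective (the region is, by definition, invisible to the disease's
# own discovery comparison)
recovery_report <- function(truth, discoveries, universe, pan_assign,
                            pan_profiles, per_disease, sheet, t) {
  memory <- attr(pan_profiles, "memory")
  diseases <- attr(pan_profiles, "diseases")
  overlap_hits <- function(calls, pr) {
    if (is.null(calls) || nrow(calls) == 0) return(integer(0))
    which(vapply(calls$probes, function(p)
      any(strsplit(p, ";", fixed = TRUE)[[1]] %in% pr), logical(1),
      USE.NAMES = FALSE))
  }
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    cat <- truth$category[i]
    d <- truth$target_disease[i]
    pr <- strsplit(truth$probes[i], ";", fixed = TRUE)[[1]]
    comp <- switch(cat, cancer_absent = "memory", disease_specific = d,
                   "pan")
    hit <- overlap_hits(discoveries[[comp]], pr)
    detected <- length(hit) > 0
    direction_ok <- detected &&
      any(discoveries[[comp]]$direction[hit] == truth$direction[i])
    assigned <- NA_character_
    if (detected) {
      if (cat == "disease_specific") {
        asg <- per_disease[[d]]$assignments
        hit_d <- overlap_hits(per_disease[[d]]$dmrs, pr)
        if (length(hit_d)) assigned <- asg$category[hit_d[1]]
      } else if (cat == "disease_absent") {
        uhit <- overlap_hits(universe, pr)
        if (length(uhit)) {
          delta <- unlist(pan_profiles[uhit[1], c(memory, diseases),
                                       drop = FALSE])
          assigned <- classify_per_disease(delta, d, memory, diseases,
                                           t)$category
        }
      } else {
        uhit <- overlap_hits(universe, pr)
        if (length(uhit))
          assigned <- pan_assign$category[match(universe$dmr_id[uhit[1]],
                                                pan_assign$dmr_id)]
      }
    }
    data.frame(truth_id = truth$truth_id[i], category = cat,
               target_disease = d, detected = detected,
               direction_ok = direction_ok, assigned = assigned,
               category_ok = identical(assigned, cat),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "detection_rate") <- mean(rep$detected)
  attr(rep, "category_accuracy") <- mean(rep$category_ok[rep$detected])
  rep
}

write_run <- function(run, out_dir, fingerprint, data) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(run$config, file.path(out_dir, "config.txt"))
  write_dmr_results(run$universe, file.path(out_dir, "pan_dmrs"),
                    assignments = run$assignments,
                    profiles = run$profiles, header = fingerprint)
  write_tsv(run$summary_table, file.path(out_dir, "pan_summary.tsv"),
            header = fingerprint)
  write_tsv(run$group_summaries, file.path(out_dir, "group_summaries.tsv"),
            header = fingerprint)
  for (d in names(run$per_disease)) {
    pd <- run$per_disease[[d]]
    if (is.null(pd$assignments)) next
    write_dmr_results(pd$dmrs, file.path(out_dir, paste0("dmrs_", d)),
                      assignments = pd$assignments, profiles = pd$profiles,
                      header = fingerprint)
  }
  if (length(run$enrichment)) {
    enr <- do.call(rbind, run$enrichment)
    enr$neg_log10_fdr <- -log10(pmax(enr$fdr, .Machine$double.xmin))
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"), header = fingerprint)
  }
  if (nrow(run$candidates$pan))
    write_tsv(run$candidates$pan, file.path(out_dir, "candidates_pan.tsv"),
              header = fingerprint)
  for (d in names(run$candidates$per_disease)) {
    cd <- run$candidates$per_disease[[d]]
    if (nrow(cd))
      write_tsv(cd, file.path(out_dir, paste0("candidates_", d, ".tsv")),
                header = fingerprint)
  }
  if (!is.null(run$recovery))
    write_tsv(run$recovery, file.path(out_dir, "recovery.tsv"),
              header = fingerprint)
  invisible(out_dir)
}

#' @export
print.methmap_run <- function(x, ...) {
  cat("Integrative methylation mapping run\n")
  cat(sprintf("  seed %d; DMR cut-off |delta-beta| >= %.2f\n",
              x$config$seed, x$config$dmr$min_mean_abs_delta))
  cat(sprintf("  discovery DMRs (combined diseases vs baseline): %d\n",
              nrow(x$discoveries$pan)))
  cat("  pan-mode categories:\n")
  s <- x$summary_table
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-16s %5d  (%.1f%%)\n", s$category[i], s$count[i],
                s$fraction_pct[i]))
  if (!is.null(x$correlation))
    cat(sprintf("  cross-comparison r = %.3f (n = %d, %d opposite-direction)\n",
                x$correlation$r, x$correlation$n, x$correlation$n_opposite))
  if (!is.null(x$recovery))
    cat(sprintf("  planted-truth recovery: detection %.1f%%, category accuracy %.1f%%\n",
                100 * attr(x$recovery, "detection_rate"),
                100 * attr(x$recovery, "category_accuracy")))
  invisible(x)
}

#' @export
summary.methmap_run <- function(object, ...) {
  print(object)
  cat("\nGroup characteristics:\n")
  print(as.data.frame(object$group_summaries))
  if (length(object$core_features)) {
    cat("\nFeatures enriched in every category: ",
        paste(object$core_features, collapse = ", "), "\n")
  }
  if (nrow(object$candidates$pan)) {
    cat("\nPan-cancer candidate genes:\n")
    print(as.data.frame(object$candidates$pan))
  }
  invisible(object)
}

#' Scatter of cross-comparison effect sizes
#'
#' Plots each DMR's beta difference in the proliferated-normal comparison
#' against the discovery comparison (the replicated-landscape view).
#'
#' @param x a \code{methmap_run}.
#' @param ... passed to \code{plot}.
#' @export
plot.methmap_run <- function(x, ...) {
  if (is.null(x$correlation)) {
    warnf("no correlation available to plot")
    return(invisible(x))
  }
  pts <- x$correlation$points
  graphics::plot(pts$y, pts$x,
                 xlab = "delta-beta (proliferated normal vs baseline)",
                 ylab = "delta-beta (diseases vs baseline)",
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.6),
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("r = %.3f", x$correlation$r))
  invisible(x)
}
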