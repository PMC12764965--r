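#' Thresholds for category mapping
#'
#' A population "shows" a methylation change when its beta-value difference
#' versus baseline has the discovery sign and magnitude of at least
#' \code{corroboration_min_abs_delta}; it "lacks" the change when the
#' magnitude is below \code{absence_max_abs_delta} or the sign is opposite
#' (the published absence rule). The discovery comparison itself must reach
#' \code{presence_min_abs_delta} (the run's DMR cut-off). The stringent
#' per-disease variant additionally demands other diseases' changes be more
#' than \code{stringent_fold} times smaller than the specific disease's.
#'
#' @param presence_min_abs_delta minimum |delta-beta| of the discovery
#'   comparison (default 0.2).
#' @param corroboration_min_abs_delta minimum same-sign |delta-beta| for a
#'   non-discovery population to count as showing the change (default 0.1).
#' @param absence_max_abs_delta |delta-beta| below which (or with opposite
#'   sign) a population counts as lacking the change (default 0.1).
#' @param stringent_fold fold-change divisor for the stringent
#'   disease-specific rule (default 4).
#' @param progenitor_arrested_disease label of the disease arrested at the
#'   progenitor stage (differentiation-driven changes are absent from it).
#' @return list of class \code{methmap_thresholds}.
#' @export
mapping_thresholds <- function(presence_min_abs_delta = 0.2,
                               corroboration_min_abs_delta = 0.1,
                               absence_max_abs_delta = 0.1,
                               stringent_fold = 4,
                               progenitor_arrested_disease = "ALL") {
  if (!(absence_max_abs_delta <= corroboration_min_abs_delta &&
        corroboration_min_abs_delta <= presence_min_abs_delta))
    stopf("need absence_max <= corroboration_min <= presence_min")
  if (stringent_fold <= 1) stopf("stringent_fold must exceed 1")
  structure(list(presence_min_abs_delta = presence_min_abs_delta,
                 corroboration_min_abs_delta = corroboration_min_abs_delta,
                 absence_max_abs_delta = absence_max_abs_delta,
                 stringent_fold = stringent_fold,
                 progenitor_arrested_disease = progenitor_arrested_disease),
            class = "methmap_thresholds")
}

#' Build cross-population effect profiles
#'
#' For every DMR, recomputes the mean beta-value difference versus the
#' baseline population for the proliferated normal population and each
#' disease (reusing \code{\link{effect_size}}), plus the discovery
#' comparison's difference. These per-DMR effect vectors are what the
#' category-mapping rules classify.
#'
#' @param dmrs a \code{methmap_dmrs} table.
#' @param beta probes x samples matrix.
#' @param sheet validated sample sheet.
#' @param discovery sample ids of the discovery group; defaults to all
#'   disease samples combined.
#' @return data frame of class \code{methmap_profiles}: \code{dmr_id},
#'   \code{discovery_delta}, and one column per non-baseline population.
#'   Attributes: \code{memory} and \code{diseases} population labels.
#' @export
build_profiles <- function(dmrs, beta, sheet, discovery = NULL) {
  validate_sheet(sheet)
  baseline <- populations_by_role(sheet, "baseline")
  memory <- populations_by_role(sheet, "normal_proliferated")
  diseases <- populations_by_role(sheet, "disease")
  base_s <- samples_of(sheet, baseline)
  if (is.null(discovery)) discovery <- samples_of(sheet, diseases)
  pops <- c(memory, diseases)
  prof <- data.frame(dmr_id = dmrs$dmr_id, stringsAsFactors = FALSE)
  prof$discovery_delta <- vapply(seq_len(nrow(dmrs)), function(i)
    effect_size(dmrs[i, ], beta, base_s, discovery), numeric(1))
  for (p in pops) {
    prof[[p]] <- vapply(seq_len(nrow(dmrs)), function(i)
      effect_size(dmrs[i, ], beta, base_s, samples_of(sheet, p)), numeric(1))
  }
  attr(prof, "memory") <- memory
  attr(prof, "diseases") <- diseases
  class(prof) <- c("methmap_profiles", "data.frame")
  prof
}

# presence / absence predicates shared by both classification modes
shows_change <- function(delta, s, t) {
  !is.na(delta) & sign(delta) == s & abs(delta) >= t$corroboration_min_abs_delta
}
lacks_change <- function(delta, s, t) {
  !is.na(delta) & (abs(delta) < t$absence_max_abs_delta | sign(delta) != s)
}

#' Classify one effect profile (pan-cancer mode)
#'
#' Applies the deconvolution rules to a single DMR's cross-population
#' effect vector: proliferation-driven if every disease and the
#' proliferated normal population show the change; differentiation-driven
#' if the proliferated normal population and every mature disease show it
#' while the progenitor-arrested disease lacks it; cancer-specific if all
#' diseases show it but the normal proliferated population lacks it;
#' cancer-absent if only the normal proliferated population shows it; else
#' unclassified.
#'
#' @param delta named vector of beta differences versus baseline (one entry
#'   per non-baseline population).
#' @param discovery_delta beta difference of the discovery comparison
#'   (its sign defines the change's direction).
#' @param memory label of the proliferated normal population.
#' @param diseases labels of the disease populations.
#' @param t a \code{\link{mapping_thresholds}} object.
#' @return One of \code{"proliferation"}, \code{"differentiation"},
#'   \code{"cancer_specific"}, \code{"cancer_absent"},
#'   \code{"unclassified"}.
#' @export
classify_pan <- function(delta, discovery_delta, memory, diseases, t) {
  mem <- delta[[memory]]
  s <- sign(discovery_delta)
  if (s == 0 || abs(discovery_delta) < t$presence_min_abs_delta) {
    # cancer-absent changes are discovered in the proliferated-normal
    # comparison and need not reach the cut-off in the disease comparison
    if (!is.na(mem) && abs(mem) >= t$presence_min_abs_delta) {
      s <- sign(mem)
    } else {
      return("unclassified")
    }
  }
  dis <- delta[diseases]
  mature <- setdiff(diseases, t$progenitor_arrested_disease)
  arrested <- t$progenitor_arrested_disease
  mem_shows <- shows_change(mem, s, t)
  mem_lacks <- lacks_change(mem, s, t)
  if (mem_shows && all(shows_change(dis, s, t)))
    return("proliferation")
  if (arrested %in% diseases &&
      mem_shows && all(shows_change(delta[mature], s, t)) &&
      lacks_change(delta[[arrested]], s, t))
    return("differentiation")
  if (all(shows_change(dis, s, t)) && mem_lacks)
    return("cancer_specific")
  if (mem_shows && all(lacks_change(dis, s, t)))
    return("cancer_absent")
  "unclassified"
}

#' Classify one effect profile for a single disease
#'
#' Disease-specific: the disease's change reaches the presence cut-off
#' while every other disease and the proliferated normal population lack
#' the change; the stringent variant additionally requires all other
#' diseases' changes to be at least \code{stringent_fold} times smaller in
#' magnitude. Disease-absent: the disease lacks a change that the
#' proliferated normal population and all other diseases show. For the
#' progenitor-arrested disease the disease-absent category is not
#' computable (it would coincide with normal differentiation-related
#' changes) and is reported as \code{NA}.
#'
#' @param delta named vector of beta differences versus baseline.
#' @param disease the disease being examined.
#' @param memory label of the proliferated normal population.
#' @param diseases all disease labels.
#' @param t a \code{\link{mapping_thresholds}} object.
#' @return list with \code{category} (\code{"disease_specific"},
#'   \code{"disease_absent"}, \code{"unclassified"}, or \code{NA} when not
#'   computable) and \code{stringent_pass} (logical, \code{NA} unless
#'   disease-specific).
#' @export
classify_per_disease <- function(delta, disease, memory, diseases, t) {
  if (!disease %in% diseases) stopf("unknown disease label '%s'", disease)
  others <- setdiff(diseases, disease)
  d_d <- delta[[disease]]
  s <- sign(d_d)
  if (s != 0 && abs(d_d) >= t$presence_min_abs_delta &&
      all(lacks_change(delta[others], s, t)) &&
      lacks_change(delta[[memory]], s, t)) {
    stringent <- all(abs(delta[others]) <= abs(d_d) / t$stringent_fold)
    return(list(category = "disease_specific", stringent_pass = stringent))
  }
  # disease-absent: direction defined by the shared change in the others
  if (disease != t$progenitor_arrested_disease) {
    for (s2 in c(1, -1)) {
      if (shows_change(delta[[memory]], s2, t) &&
          all(shows_change(delta[others], s2, t)) &&
          lacks_change(d_d, s2, t))
        return(list(category = "disease_absent", stringent_pass = NA))
    }
  } else {
    # would be indistinguishable from differentiation-driven changes
    for (s2 in c(1, -1)) {
      if (shows_change(delta[[memory]], s2, t) &&
          all(shows_change(delta[others], s2, t)) &&
          lacks_change(d_d, s2, t))
        return(list(category = NA_character_, stringent_pass = NA))
    }
  }
  list(category = "unclassified", stringent_pass = NA)
}

#' Classify all profiles
#'
#' @param profiles a \code{methmap_profiles} table.
#' @param t a \code{\link{mapping_thresholds}} object.
#' @param mode \code{"pan"} or \code{"per_disease"}.
#' @param disease disease label (per-disease mode).
#' @return data frame of class \code{methmap_assignments} with
#'   \code{dmr_id}, \code{mode}, \code{category}, \code{stringent_pass}.
#' @export
classify_profiles <- function(profiles, t = mapping_thresholds(),
                              mode = c("pan", "per_disease"),
                              disease = NULL) {
  mode <- match.arg(mode)
  memory <- attr(profiles, "memory")
  diseases <- attr(profiles, "diseases")
  pops <- c(memory, diseases)
  out <- data.frame(dmr_id = profiles$dmr_id, stringsAsFactors = FALSE)
  if (mode == "pan") {
    out$mode <- "pan"
    out$category <- vapply(seq_len(nrow(profiles)), function(i) {
      delta <- unlist(profiles[i, pops, drop = FALSE])
      classify_pan(delta, profiles$discovery_delta[i], memory, diseases, t)
    }, character(1))
    out$stringent_pass <- NA
  } else {
    if (is.null(disease)) stopf("per-disease mode needs a disease label")
    out$mode <- paste0("per_disease:", disease)
    res <- lapply(seq_len(nrow(profiles)), function(i) {
      delta <- unlist(profiles[i, pops, drop = FALSE])
      classify_per_disease(delta, disease, memory, diseases, t)
    })
    out$category <- vapply(res, function(r)
      if (is.na(r$category)) NA_character_ else r$category, character(1))
    out$stringent_pass <- vapply(res, function(r) r$stringent_pass,
                                 logical(1))
  }
  class(out) <- c("methmap_assignments", "data.frame")
  out
}

#' Category counts and fractions
#'
#' Tabulates assignments and expresses each category as a percentage of
#' the discovery-comparison total, rounded half-up to one decimal place
#' (published-table formatting).
#'
#' @param assignments a \code{methmap_assignments} table, or a named
#'   integer vector of category counts.
#' @param total_dmrs denominator (total DMRs of the discovery comparison).
#' @return data frame with \code{category}, \code{count},
#'   \code{fraction_pct}.
#' @export
summarize_categories <- function(assignments, total_dmrs) {
  if (total_dmrs <= 0) stopf("total_dmrs must be positive")
  counts <- if (is.data.frame(assignments)) {
    tab <- table(assignments$category[!is.na(assignments$category)])
    stats::setNames(as.integer(tab), names(tab))
  } else assignments
  if (total_dmrs < sum(counts[setdiff(names(counts), "unclassified")]))
    stopf("total_dmrs smaller than the sum of category counts")
  data.frame(category = names(counts),
             count = as.integer(counts),
             fraction_pct = round_half_up(100 * as.integer(counts) / total_dmrs, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
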