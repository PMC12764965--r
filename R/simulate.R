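#' Build a simulation specification
#'
#' Defines the synthetic methylome: an array-like probe layout (dense
#' island blocks separated by sparse open-sea stretches), a baseline
#' population plus a proliferated normal population plus disease
#' populations, planted DMR blocks whose cross-population sharing pattern
#' encodes a truth category, beta-distributed per-sample noise, and a
#' per-population proliferation dose that scales proliferation- and
#' differentiation-driven effect sizes (indolent diseases change about as
#' much as the proliferated normal cells; highly proliferative diseases
#' change more).
#'
#' @param n_probes total number of probes.
#' @param n_chromosomes number of chromosomes to spread probes over.
#' @param probes_per_island_block integer range (length 2) of core probes
#'   per dense block.
#' @param samples_per_population named integer vector, one entry per
#'   population (first entry is taken as written in \code{populations}).
#' @param populations data frame with columns \code{population},
#'   \code{role}; defaults to a progenitor baseline, a memory population
#'   and five B-cell-malignancy-like diseases.
#' @param progenitor_arrested which disease is arrested at the progenitor
#'   stage (its cells never executed the differentiation programme, so
#'   differentiation-driven changes are absent from it).
#' @param baseline_beta_means named beta means per island context.
#' @param noise_precision concentration of the beta-distributed per-sample
#'   noise around the target mean; \code{Inf} gives noiseless data.
#' @param proliferation_dose named non-negative multipliers applied to
#'   proliferation/differentiation effect sizes per population.
#' @param base_effect planted effect magnitude (beta-value difference).
#' @param planted_counts named integer vector of planted DMRs per category
#'   (\code{proliferation}, \code{differentiation}, \code{cancer_specific},
#'   \code{cancer_absent}, \code{disease_specific}, \code{disease_absent});
#'   per-disease categories are spread round-robin over eligible diseases.
#' @param promoter_fraction fraction of blocks whose TSS lies inside the
#'   block (promoter-proximal, minimum probe distance < 1000 bp).
#' @param feature_background per-probe background membership probability of
#'   each annotation feature.
#' @param enrichment_multiplier odds multiplier over background for the
#'   category-tagged feature inside planted blocks of that category.
#' @param expression_slope log-scale expression decrease per unit of
#'   promoter methylation at linked genes (positive value = negative
#'   methylation-expression association).
#' @param expression_noise_sd log-scale expression noise s.d.
#' @param expression_samples samples per population in the (disjoint)
#'   expression cohort.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return An object of class \code{methmap_sim_spec}.
#' @export
simulation_spec <- function(n_probes = 2000L,
                            n_chromosomes = 2L,
                            probes_per_island_block = c(4L, 8L),
                            samples_per_population = NULL,
                            populations = NULL,
                            progenitor_arrested = "ALL",
                            baseline_beta_means = c(island = 0.10,
                                                    shore = 0.35,
                                                    shelf = 0.65,
                                                    open_sea = 0.85),
                            noise_precision = 50,
                            proliferation_dose = c(memory = 1.0, CLL = 1.0,
                                                   MCL = 1.0, DLBCL = 1.2,
                                                   ALL = 1.5, PCNSL = 1.5),
                            base_effect = 0.3,
                            planted_counts = c(proliferation = 24L,
                                               differentiation = 5L,
                                               cancer_specific = 1L,
                                               cancer_absent = 1L,
                                               disease_specific = 5L,
                                               disease_absent = 4L),
                            promoter_fraction = 0.4,
                            feature_background = 0.10,
                            enrichment_multiplier = 3.0,
                            expression_slope = 4.0,
                            expression_noise_sd = 0.3,
                            expression_samples = 10L,
                            seed = 1L) {
  if (is.null(populations)) {
    populations <- data.frame(
      population = c("progenitor", "memory", "ALL", "CLL", "MCL", "DLBCL",
                     "PCNSL"),
      role = c("baseline", "normal_proliferated", rep("disease", 5)),
      stringsAsFactors = FALSE)
  }
  if (is.null(samples_per_population))
    samples_per_population <- stats::setNames(rep(10L, nrow(populations)),
                                              populations$population)
  if (!all(populations$population %in% names(samples_per_population)))
    stopf("samples_per_population must name every population")
  if (any(baseline_beta_means <= 0 | baseline_beta_means >= 1))
    stopf("baseline beta means must lie in (0,1)")
  if (any(proliferation_dose < 0)) stopf("proliferation doses must be >= 0")
  if (base_effect <= 0 || base_effect >= 1)
    stopf("base_effect must lie in (0,1)")
  diseases <- populations$population[populations$role == "disease"]
  if (!progenitor_arrested %in% diseases)
    stopf("progenitor_arrested must be one of the disease populations")
  miss_dose <- setdiff(setdiff(populations$population,
                               populations$population[populations$role == "baseline"]),
                       names(proliferation_dose))
  if (length(miss_dose))
    stopf("proliferation_dose missing for: %s", paste(miss_dose, collapse = ", "))
  spec <- list(n_probes = as.integer(n_probes),
               n_chromosomes = as.integer(n_chromosomes),
               probes_per_island_block = as.integer(probes_per_island_block),
               samples_per_population = samples_per_population,
               populations = populations,
               progenitor_arrested = progenitor_arrested,
               baseline_beta_means = baseline_beta_means,
               noise_precision = noise_precision,
               proliferation_dose = proliferation_dose,
               base_effect = base_effect,
               planted_counts = planted_counts,
               promoter_fraction = promoter_fraction,
               feature_background = feature_background,
               enrichment_multiplier = enrichment_multiplier,
               expression_slope = expression_slope,
               expression_noise_sd = expression_noise_sd,
               expression_samples = as.integer(expression_samples),
               seed = as.integer(seed))
  class(spec) <- "methmap_sim_spec"
  spec
}

# deterministic probe layout: alternating low-methylation (island-core) and
# high-methylation (shelf-core) dense blocks, flanked, separated by sparse
# open-sea probes.  Returns manifest columns minus features plus block ids.
sim_layout <- function(spec) {
  rng_low <- spec$probes_per_island_block[1]
  rng_high <- spec$probes_per_island_block[2]
  probes <- list()
  n_done <- 0L
  block_id <- 0L
  chrom_i <- 1L
  pos <- 10000L
  per_chrom <- ceiling(spec$n_probes / spec$n_chromosomes)
  n_chrom_done <- 0L
  while (n_done < spec$n_probes) {
    if (n_chrom_done >= per_chrom && chrom_i < spec$n_chromosomes) {
      chrom_i <- chrom_i + 1L
      n_chrom_done <- 0L
      pos <- 10000L
    }
    block_id <- block_id + 1L
    k <- sample.int(rng_high - rng_low + 1L, 1L) + rng_low - 1L
    flavor <- if (block_id %% 2L == 1L) "low" else "high"
    core_ctx <- if (flavor == "low") "island" else "shelf"
    flank_ctx <- if (flavor == "low") "shore" else "shelf"
    ctx <- c(flank_ctx, rep(core_ctx, k), flank_ctx)
    is_core <- c(FALSE, rep(TRUE, k), FALSE)
    gaps <- sample(50:200, length(ctx), replace = TRUE)
    p <- pos + cumsum(gaps)
    for (j in seq_along(ctx)) {
      probes[[length(probes) + 1L]] <-
        list(chrom = sprintf("chr%d", chrom_i), pos = p[j],
             island_context = ctx[j], block = block_id, core = is_core[j])
    }
    pos <- p[length(p)]
    # open-sea stretch
    n_sea <- sample(1:3, 1L)
    for (j in seq_len(n_sea)) {
      pos <- pos + sample(2000:5000, 1L)
      probes[[length(probes) + 1L]] <-
        list(chrom = sprintf("chr%d", chrom_i), pos = pos,
             island_context = "open_sea", block = block_id, core = FALSE)
    }
    pos <- pos + sample(2000:5000, 1L)
    n_done <- n_done + length(ctx) + n_sea
    n_chrom_done <- n_chrom_done + length(ctx) + n_sea
  }
  df <- do.call(rbind, lapply(probes, function(x)
    data.frame(chrom = x$chrom, pos = x$pos, island_context = x$island_context,
               block = x$block, core = x$core, stringsAsFactors = FALSE)))
  df <- df[seq_len(spec$n_probes), , drop = FALSE]
  df$probe_id <- sprintf("cg%07d", seq_len(nrow(df)))
  df
}

# choose planted blocks and build the truth table
sim_plant <- function(spec, layout) {
  diseases <- spec$populations$population[spec$populations$role == "disease"]
  mature <- setdiff(diseases, spec$progenitor_arrested)
  counts <- spec$planted_counts
  cats <- character(0)
  target <- character(0)
  for (nm in names(counts)) {
    n <- counts[[nm]]
    if (n == 0) next
    if (nm == "disease_specific") {
      tg <- rep(diseases, length.out = n)
    } else if (nm == "disease_absent") {
      tg <- rep(mature, length.out = n)  # not identifiable for the arrested disease
    } else tg <- rep(NA_character_, n)
    cats <- c(cats, rep(nm, n))
    target <- c(target, tg)
  }
  # candidate blocks: core runs with >= 2 probes
  core_blocks <- unique(layout$block[layout$core])
  sizes <- vapply(core_blocks, function(b) sum(layout$core & layout$block == b),
                  integer(1))
  core_blocks <- core_blocks[sizes >= 2]
  if (length(cats) > length(core_blocks))
    stopf("spec infeasible: %d planted DMRs but only %d eligible blocks",
          length(cats), length(core_blocks))
  if (!length(cats)) {
    return(data.frame(truth_id = character(0), block = integer(0),
                      category = character(0),
                      target_disease = character(0),
                      direction = character(0), base_effect = numeric(0),
                      linked_gene = character(0), expr_slope = numeric(0),
                      stringsAsFactors = FALSE))
  }
  picked <- sample(core_blocks, length(cats))
  truth <- data.frame(truth_id = sprintf("T%03d", seq_along(cats)),
                      block = picked, category = cats,
                      target_disease = target, stringsAsFactors = FALSE)
  # direction follows block flavor so the shifted mean stays inside (0,1)
  flavor_of <- vapply(truth$block, function(b)
    layout$island_context[layout$core & layout$block == b][1], character(1))
  truth$direction <- ifelse(flavor_of == "island", "hyper", "hypo")
  truth$base_effect <- spec$base_effect
  # promoter-linked genes for cancer-category DMRs (expression integration)
  linked <- truth$category %in% c("cancer_specific", "cancer_absent",
                                  "disease_specific")
  truth$linked_gene <- NA_character_
  truth$expr_slope <- ifelse(linked, spec$expression_slope, NA_real_)
  truth
}

#' Generate a synthetic probe manifest
#'
#' Lays out probes in dense island blocks separated by open-sea stretches,
#' assigns TSS distances so a configurable fraction of blocks is
#' promoter-proximal, and assigns annotation features (chromHMM, histone,
#' TFBS namespaces) with a planted enrichment: each truth category carries
#' one tag feature at \code{enrichment_multiplier} times the background
#' odds inside its planted blocks.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return A validated manifest with attributes \code{truth} (the planted
#'   DMR table) and \code{layout}.
#' @export
generate_manifest <- function(spec) {
  set.seed(spec$seed)
  layout <- sim_layout(spec)
  truth <- sim_plant(spec, layout)

  # TSS placement per block; planted cancer-category blocks are forced
  # promoter-proximal so their linked genes are nominable
  blocks <- unique(layout$block)
  promoter <- stats::setNames(
    stats::runif(length(blocks)) < spec$promoter_fraction, blocks)
  promoter[as.character(truth$block[!is.na(truth$expr_slope)])] <- TRUE
  gene_of <- stats::setNames(sprintf("G%04d", seq_along(blocks)), blocks)
  truth$linked_gene <- ifelse(!is.na(truth$expr_slope),
                              gene_of[as.character(truth$block)],
                              NA_character_)
  tss <- integer(0)
  tssd <- integer(nrow(layout))
  for (b in blocks) {
    idx <- which(layout$block == b)
    first_core <- idx[layout$core[idx]][1]
    anchor <- if (is.na(first_core)) layout$pos[idx[1]] else layout$pos[first_core]
    tss_pos <- if (promoter[as.character(b)]) anchor
               else anchor - sample(5000:50000, 1L)
    tssd[idx] <- layout$pos[idx] - tss_pos
  }

  # features: background rate everywhere, boosted odds in planted blocks
  bg <- spec$feature_background
  mult <- spec$enrichment_multiplier
  boosted <- (mult * bg / (1 - bg)) / (1 + mult * bg / (1 - bg))
  ns_features <- list(
    chromHMM = c("quiescent", "enhancer", "bivalent_promoter", "polycomb"),
    histone = c("H3K27me3", "H3K9me3", "H3K36me3", "H3K4me1"),
    TFBS = c("EZH2", "SUZ12", "RYBP", "CDCA2", "CTCF"))
  # tag feature per category, one per namespace cycle
  cat_levels <- unique(truth$category)
  tag_ns <- rep(c("TFBS", "chromHMM", "histone"), length.out = length(cat_levels))
  names(tag_ns) <- cat_levels
  feat <- list(chromHMM = vector("list", nrow(layout)),
               histone = vector("list", nrow(layout)),
               TFBS = vector("list", nrow(layout)))
  planted_block_cat <- stats::setNames(truth$category, truth$block)
  for (ns in names(ns_features)) {
    for (f in ns_features[[ns]]) {
      hit <- stats::runif(nrow(layout)) < bg
      feat[[ns]] <- mapply(function(cur, h) if (h) c(cur, f) else cur,
                           feat[[ns]], hit, SIMPLIFY = FALSE)
    }
  }
  for (cat in cat_levels) {
    ns <- tag_ns[[cat]]
    f <- paste0("tag_", cat)
    in_cat <- layout$core &
      layout$block %in% truth$block[truth$category == cat]
    p <- ifelse(in_cat, boosted, bg)
    hit <- stats::runif(nrow(layout)) < p
    feat[[ns]] <- mapply(function(cur, h) if (h) c(cur, f) else cur,
                         feat[[ns]], hit, SIMPLIFY = FALSE)
  }

  manifest <- data.frame(probe_id = layout$probe_id, chrom = layout$chrom,
                         pos = layout$pos,
                         island_context = layout$island_context,
                         tss_distance = tssd,
                         nearest_gene = gene_of[as.character(layout$block)],
                         chromHMM = join_features(feat$chromHMM),
                         histone = join_features(feat$histone),
                         TFBS = join_features(feat$TFBS),
                         stringsAsFactors = FALSE)
  manifest <- validate_manifest(manifest)
  # record member probes of each planted DMR (core run of its block)
  truth$probes <- vapply(truth$block, function(b)
    paste(layout$probe_id[layout$core & layout$block == b], collapse = ";"),
    character(1))
  truth$chrom <- vapply(truth$block, function(b)
    layout$chrom[layout$block == b][1], character(1))
  attr(manifest, "truth") <- truth
  attr(manifest, "layout") <- layout
  manifest
}

# which populations receive a planted effect, and with what multiplier
category_applicability <- function(category, target_disease, spec) {
  pops <- spec$populations
  memory <- pops$population[pops$role == "normal_proliferated"]
  diseases <- pops$population[pops$role == "disease"]
  mature <- setdiff(diseases, spec$progenitor_arrested)
  dose <- spec$proliferation_dose
  none <- stats::setNames(numeric(0), character(0))
  switch(category,
    proliferation = dose[c(memory, diseases)],
    differentiation = dose[c(memory, mature)],
    cancer_specific = stats::setNames(rep(1, length(diseases)), diseases),
    cancer_absent = stats::setNames(rep(1, length(memory)), memory),
    disease_specific = stats::setNames(1, target_disease),
    disease_absent = stats::setNames(rep(1, length(c(memory,
                       setdiff(diseases, target_disease)))),
                       c(memory, setdiff(diseases, target_disease))),
    null = none,
    stopf("unknown planted category '%s'", category))
}

#' Generate synthetic beta values
#'
#' Per probe and sample, draws a beta-distributed value with mean equal to
#' the island-context baseline shifted by the planted effect wherever the
#' probe belongs to a planted DMR whose category applies to the sample's
#' population (proliferation/differentiation effects are scaled by the
#' population's proliferation dose). Means are clipped to [0.01, 0.99];
#' infinite \code{noise_precision} yields the means exactly.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param manifest output of \code{\link{generate_manifest}} (carries the
#'   planted truth).
#' @return list with \code{beta} (matrix), \code{sheet} (sample sheet),
#'   \code{truth} (planted DMR table), \code{target_means} (population x
#'   probe matrix of noiseless means).
#' @export
generate_beta <- function(spec, manifest) {
  truth <- attr(manifest, "truth")
  if (is.null(truth)) stopf("manifest lacks planted truth; use generate_manifest")
  set.seed(spec$seed + 1L)
  pops <- spec$populations
  n_probe <- nrow(manifest)
  base <- spec$baseline_beta_means[manifest$island_context]
  # noiseless target mean per population
  tm <- matrix(rep(base, nrow(pops)), nrow = nrow(pops), byrow = TRUE,
               dimnames = list(pops$population, manifest$probe_id))
  for (i in seq_len(nrow(truth))) {
    pr <- strsplit(truth$probes[i], ";", fixed = TRUE)[[1]]
    appl <- category_applicability(truth$category[i],
                                   truth$target_disease[i], spec)
    sgn <- if (truth$direction[i] == "hyper") 1 else -1
    for (p in names(appl)) {
      tm[p, pr] <- tm[p, pr] + sgn * truth$base_effect[i] * appl[[p]]
    }
  }
  tm <- pmin(pmax(tm, 0.01), 0.99)

  sheet <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    n <- spec$samples_per_population[[pops$population[i]]]
    data.frame(sample_id = sprintf("%s_%02d", pops$population[i], seq_len(n)),
               population = pops$population[i], role = pops$role[i],
               stringsAsFactors = FALSE)
  }))
  validate_sheet(sheet)

  beta <- matrix(NA_real_, nrow = n_probe, ncol = nrow(sheet),
                 dimnames = list(manifest$probe_id, sheet$sample_id))
  phi <- spec$noise_precision
  for (j in seq_len(nrow(sheet))) {
    mu <- tm[sheet$population[j], ]
    if (is.infinite(phi)) {
      beta[, j] <- mu
    } else {
      beta[, j] <- stats::rbeta(n_probe, mu * phi, (1 - mu) * phi)
    }
  }
  list(beta = beta, sheet = sheet, truth = truth, target_means = tm)
}

#' Generate a synthetic expression cohort
#'
#' Builds a log-scale expression matrix on a cohort disjoint from the
#' methylation samples. Genes linked to a planted DMR follow
#' \code{baseline - slope * (population mean methylation of the DMR)} plus
#' Gaussian noise, so promoter methylation and expression are negatively
#' associated across populations; unlinked genes vary independently of
#' methylation.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param truth planted DMR table (from \code{\link{generate_beta}}).
#' @param target_means population x probe matrix of noiseless methylation
#'   means.
#' @param manifest the synthetic manifest (gene universe).
#' @return list with \code{expression} (genes x samples matrix, log scale)
#'   and \code{sheet} (expression sample sheet).
#' @export
generate_expression <- function(spec, truth, target_means, manifest) {
  linked <- truth[!is.na(truth$linked_gene), , drop = FALSE]
  if (any(!nzchar(linked$probes)))
    stopf("linked gene without DMR probes in truth table")
  set.seed(spec$seed + 2L)
  pops <- spec$populations
  genes <- unique(manifest$nearest_gene)
  sheet <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    data.frame(sample_id = sprintf("E_%s_%02d", pops$population[i],
                                   seq_len(spec$expression_samples)),
               population = pops$population[i], role = pops$role[i],
               stringsAsFactors = FALSE)
  }))
  base_expr <- stats::setNames(stats::rnorm(length(genes), 8, 1), genes)
  # per-gene, per-population mean
  mu <- matrix(rep(base_expr, each = nrow(pops)), nrow = nrow(pops),
               dimnames = list(pops$population, genes))
  for (i in seq_len(nrow(linked))) {
    g <- linked$linked_gene[i]
    pr <- strsplit(linked$probes[i], ";", fixed = TRUE)[[1]]
    meth <- rowMeans(target_means[, pr, drop = FALSE])
    mu[, g] <- base_expr[[g]] - linked$expr_slope[i] * meth
  }
  expr <- matrix(NA_real_, nrow = length(genes), ncol = nrow(sheet),
                 dimnames = list(genes, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    m <- mu[sheet$population[j], ]
    expr[, j] <- if (spec$expression_noise_sd > 0)
      stats::rnorm(length(genes), m, spec$expression_noise_sd) else m
  }
  list(expression = expr, sheet = sheet)
}

#' Simulate a full synthetic methylome study
#'
#' Convenience wrapper running \code{\link{generate_manifest}},
#' \code{\link{generate_beta}} and \code{\link{generate_expression}} for
#' one spec. Deterministic given the spec (which includes the seed).
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{manifest}, \code{beta}, \code{sheet},
#'   \code{truth}, \code{target_means}, \code{expression}, \code{expr_sheet}.
#' @export
simulate_methylome <- function(spec) {
  manifest <- generate_manifest(spec)
  gb <- generate_beta(spec, manifest)
  ge <- generate_expression(spec, gb$truth, gb$target_means, manifest)
  list(manifest = manifest, beta = gb$beta, sheet = gb$sheet,
       truth = gb$truth, target_means = gb$target_means,
       expression = ge$expression, expr_sheet = ge$sheet)
}
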