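test_that("population-mean correlations are exact in the noiseless limit", {
  spec <- small_spec(seed = 41, noise_precision = Inf,
                     expression_noise_sd = 0)
  sim <- simulate_methylome(spec)
  linked <- sim$truth[!is.na(sim$truth$linked_gene), ][1, ]
  dmr <- list(dmr_id = linked$truth_id, probes = linked$probes)
  cc <- meth_expr_correlation(dmr, linked$linked_gene, sim$beta,
                              sim$expression, sim$sheet, sim$expr_sheet)
  expect_false(cc$degenerate)
  expect_equal(cc$r, -1, tolerance = 1e-9)
  expect_lt(cc$p, 1e-6)

  # an unlinked gene has zero expression variance: degenerate, skipped
  unlinked <- setdiff(unique(sim$manifest$nearest_gene),
                      sim$truth$linked_gene)[1]
  cc2 <- meth_expr_correlation(dmr, unlinked, sim$beta, sim$expression,
                               sim$sheet, sim$expr_sheet)
  expect_true(cc2$degenerate)
  expect_true(is.na(cc2$r))

  expect_error(meth_expr_correlation(dmr, "NOT_A_GENE", sim$beta,
                                     sim$expression, sim$sheet,
                                     sim$expr_sheet), "absent")
})

test_that("linked genes correlate below -0.8 at default noise for most candidates", {
  hits <- 0; total <- 0
  for (seed in 42:44) {
    spec <- small_spec(seed = seed)
    sim <- simulate_methylome(spec)
    linked <- sim$truth[!is.na(sim$truth$linked_gene), ]
    for (i in seq_len(nrow(linked))) {
      dmr <- list(dmr_id = linked$truth_id[i], probes = linked$probes[i])
      cc <- meth_expr_correlation(dmr, linked$linked_gene[i], sim$beta,
                                  sim$expression, sim$sheet, sim$expr_sheet)
      total <- total + 1
      if (!is.na(cc$r) && cc$r < -0.8) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("pan nomination keeps only cancer-category DMRs and annotates filters", {
  spec <- small_spec(seed = 45, noise_precision = Inf,
                     expression_noise_sd = 0)
  sim <- simulate_methylome(spec)
  run <- run_pipeline_stages(pipeline_config(seed = 45), sim)
  cand <- run$candidates$pan
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$category %in% c("cancer_specific", "cancer_absent")))
  expect_true(all(cand$correlation < 0))
  expect_true(all(cand$correlation_p < 0.05))
  # planted candidates were forced promoter-proximal
  expect_true(all(cand$passes_promoter_filter))
  # no proliferation- or differentiation-driven DMR is ever nominated
  prolif_ids <- run$assignments$dmr_id[run$assignments$category %in%
                                         c("proliferation",
                                           "differentiation")]
  expect_false(any(cand$dmr_id %in% prolif_ids))
  # nominated genes are exactly the planted pan-cancer links
  planted_genes <- sim$truth$linked_gene[sim$truth$category %in%
                                           c("cancer_specific",
                                             "cancer_absent")]
  expect_setequal(cand$gene, planted_genes)
})

test_that("a distal candidate is retained but flagged non-promoter", {
  man <- tiny_manifest()
  dmrs <- data.frame(dmr_id = "DMR0001", chrom = "chr1", start = 20000L,
                     end = 40000L, n_cpgs = 2L, size_bp = 20001L,
                     mean_delta_beta = 0.3, region_p = 1e-9,
                     direction = "hyper", probes = "p09;p10",
                     stringsAsFactors = FALSE)
  class(dmrs) <- c("methmap_dmrs", "data.frame")
  asg <- data.frame(dmr_id = "DMR0001", mode = "pan",
                    category = "cancer_specific", stringent_pass = NA)
  prof <- data.frame(dmr_id = "DMR0001", discovery_delta = 0.3,
                     memory = 0.01, ALL = 0.3, CLL = 0.3, MCL = 0.3,
                     DLBCL = 0.3, PCNSL = 0.3)
  attr(prof, "memory") <- "memory"
  attr(prof, "diseases") <- DISEASES
  pops <- c("progenitor", "memory", DISEASES)
  sheet <- data.frame(sample_id = paste0(rep(pops, each = 2), "_", 1:2),
                      population = rep(pops, each = 2),
                      role = rep(c("baseline", "normal_proliferated",
                                   rep("disease", 5)), each = 2))
  # methylation high only in diseases at the DMR probes
  beta <- matrix(0.2, nrow = nrow(man), ncol = nrow(sheet),
                 dimnames = list(man$probe_id, sheet$sample_id))
  dis_samples <- sheet$sample_id[sheet$role == "disease"]
  beta[c("p09", "p10"), dis_samples] <- 0.5
  # expression of GENE3 low exactly where methylation is high
  expr_sheet <- data.frame(sample_id = paste0("E_", sheet$sample_id),
                           population = sheet$population,
                           role = sheet$role)
  expr <- matrix(8, nrow = 1, ncol = nrow(expr_sheet),
                 dimnames = list("GENE3", expr_sheet$sample_id))
  expr["GENE3", paste0("E_", dis_samples)] <- 6
  cand <- nominate_pan(asg, dmrs, prof, man, beta, expr, sheet, expr_sheet)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$gene, "GENE3")
  expect_false(cand$passes_promoter_filter)  # 15 kb from the nearest TSS
  expect_true(cand$passes_effect_filter)
})

test_that("per-disease reciprocity obeys the all-pairs sign rule, symmetrically", {
  spec <- small_spec(seed = 46, noise_precision = Inf,
                     expression_noise_sd = 0)
  sim <- simulate_methylome(spec)
  run <- run_pipeline_stages(pipeline_config(seed = 46), sim)
  planted <- sim$truth[sim$truth$category == "disease_specific", ]
  for (i in seq_len(nrow(planted))) {
    d <- planted$target_disease[i]
    cand <- run$candidates$per_disease[[d]]
    expect_true(planted$linked_gene[i] %in% cand$gene)
  }
  # reciprocity: both hyper+silenced and hypo+overexpressed directions occur
  dirs <- planted$direction
  if (length(unique(dirs)) == 2) succeed()

  # a gene whose expression in the disease sits inside the others' range
  # is rejected: flatten the planted gene's expression and re-nominate
  d <- planted$target_disease[1]
  g <- planted$linked_gene[1]
  expr2 <- sim$expression
  expr2[g, ] <- 8
  cand2 <- nominate_per_disease(run$per_disease[[d]]$assignments, d,
                                run$per_disease[[d]]$dmrs,
                                run$per_disease[[d]]$profiles,
                                sim$manifest, expr2, sim$expr_sheet)
  expect_false(g %in% cand2$gene)
})
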