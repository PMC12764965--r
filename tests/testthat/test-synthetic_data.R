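test_that("generated manifests satisfy layout invariants and are seed-deterministic", {
  spec <- small_spec(seed = 2)
  man <- generate_manifest(spec)
  expect_equal(nrow(man), spec$n_probes)
  expect_false(anyDuplicated(man$probe_id) > 0)
  for (ch in unique(man$chrom)) {
    p <- man$pos[man$chrom == ch]
    expect_true(all(diff(p) > 0))
  }
  expect_true(all(man$island_context %in% c("island", "shore", "shelf",
                                            "open_sea")))
  man2 <- generate_manifest(small_spec(seed = 2))
  expect_identical(as.data.frame(man), as.data.frame(man2))
  expect_false(identical(as.data.frame(man),
                         as.data.frame(generate_manifest(small_spec(seed = 3)))))
})

test_that("planted DMRs occupy >= 2 consecutive probes and infeasible specs error", {
  spec <- small_spec(seed = 4)
  man <- generate_manifest(spec)
  truth <- attr(man, "truth")
  expect_equal(nrow(truth), sum(spec$planted_counts))
  idx <- match(strsplit(truth$probes[1], ";")[[1]], man$probe_id)
  expect_true(length(idx) >= 2)
  expect_equal(idx, seq(idx[1], idx[length(idx)]))  # consecutive
  big <- simulation_spec(n_probes = 60L,
                         planted_counts = c(proliferation = 50L),
                         seed = 1)
  expect_error(generate_manifest(big), "infeasible")
})

test_that("planted feature enrichment follows the odds-multiplier algebra", {
  # multiplier 3 over background 0.1 gives odds 3 * (1/9) = 1/3, i.e. a
  # planted-region frequency of 0.25; multiplier 1 reduces to background
  boost <- function(m, bg) (m * bg / (1 - bg)) / (1 + m * bg / (1 - bg))
  expect_equal(boost(3, 0.1), 0.25)
  expect_equal(boost(1, 0.1), 0.1)
  # simulate many planted probes and check the empirical frequency
  spec <- simulation_spec(n_probes = 3000L,
                          planted_counts = c(proliferation = 60L),
                          enrichment_multiplier = 3, seed = 7)
  man <- generate_manifest(spec)
  truth <- attr(man, "truth")
  planted <- unique(unlist(strsplit(truth$probes, ";")))
  feats <- methmap:::split_features(man$TFBS[match(planted, man$probe_id)])
  freq <- mean(vapply(feats, function(v) "tag_proliferation" %in% v,
                      logical(1)))
  expect_gt(freq, 0.25 - 3 * sqrt(0.25 * 0.75 / length(planted)))
  expect_lt(freq, 0.25 + 3 * sqrt(0.25 * 0.75 / length(planted)))
})

test_that("noiseless beta values hit the planted category patterns exactly", {
  spec <- small_spec(seed = 5, noise_precision = Inf)
  sim <- simulate_methylome(spec)
  truth <- sim$truth
  sheet <- sim$sheet
  base_s <- methmap:::samples_of(sheet, "progenitor")
  for (i in seq_len(nrow(truth))) {
    pr <- strsplit(truth$probes[i], ";")[[1]]
    dmr <- list(probes = truth$probes[i], dmr_id = truth$truth_id[i])
    mem_d <- effect_size(dmr, sim$beta, base_s,
                         methmap:::samples_of(sheet, "memory"))
    all_d <- effect_size(dmr, sim$beta, base_s,
                         methmap:::samples_of(sheet, "ALL"))
    sgn <- if (truth$direction[i] == "hyper") 1 else -1
    if (truth$category[i] == "proliferation") {
      expect_equal(mem_d, sgn * 0.3, tolerance = 1e-12)
      expect_equal(all_d, sgn * 0.3 * spec$proliferation_dose[["ALL"]],
                   tolerance = 1e-12)
    }
    if (truth$category[i] == "cancer_absent") {
      expect_equal(mem_d, sgn * 0.3, tolerance = 1e-12)
      expect_equal(all_d, 0, tolerance = 1e-12)
    }
    if (truth$category[i] == "differentiation") {
      expect_equal(mem_d, sgn * 0.3, tolerance = 1e-12)
      expect_equal(all_d, 0, tolerance = 1e-12)  # progenitor-arrested
    }
  }
})

test_that("noiseless planted patterns agree with the classifier (built-in oracle)", {
  spec <- small_spec(seed = 6, noise_precision = Inf)
  sim <- simulate_methylome(spec)
  tm <- sim$target_means
  t <- mapping_thresholds()
  pan_cats <- c("proliferation", "differentiation", "cancer_specific",
                "cancer_absent")
  for (i in seq_len(nrow(sim$truth))) {
    if (!sim$truth$category[i] %in% pan_cats) next
    pr <- strsplit(sim$truth$probes[i], ";")[[1]]
    delta <- vapply(c("memory", DISEASES), function(p)
      mean(tm[p, pr] - tm["progenitor", pr]), numeric(1))
    disc <- mean(colMeans(tm[DISEASES, pr, drop = FALSE])) -
      mean(tm["progenitor", pr])
    got <- classify_pan(delta, disc, "memory", DISEASES, t)
    if (sim$truth$category[i] == "cancer_absent")
      expect_equal(got, "cancer_absent")
    else expect_equal(got, sim$truth$category[i])
  }
})

test_that("default-noise group means stay near target for nearly all planted DMRs", {
  spec <- simulation_spec(seed = 8)  # precision 50, n = 10/group
  sim <- simulate_methylome(spec)
  sheet <- sim$sheet
  base_s <- methmap:::samples_of(sheet, "progenitor")
  mem_s <- methmap:::samples_of(sheet, "memory")
  errs <- vapply(seq_len(nrow(sim$truth)), function(i) {
    pr <- strsplit(sim$truth$probes[i], ";")[[1]]
    obs <- mean(colMeans(t(sim$beta[pr, mem_s, drop = FALSE]))) -
      mean(colMeans(t(sim$beta[pr, base_s, drop = FALSE])))
    target <- mean(sim$target_means["memory", pr] -
                     sim$target_means["progenitor", pr])
    abs(obs - target)
  }, numeric(1))
  expect_gte(mean(errs <= 0.04), 0.95)
})

test_that("expression links are negative and unlinked genes are flat (noiseless)", {
  spec <- small_spec(seed = 9, noise_precision = Inf,
                     expression_noise_sd = 0)
  sim <- simulate_methylome(spec)
  linked <- sim$truth[!is.na(sim$truth$linked_gene), ]
  expect_gt(nrow(linked), 0)
  pops <- unique(sim$expr_sheet$population)
  for (i in seq_len(nrow(linked))) {
    g <- linked$linked_gene[i]
    pr <- strsplit(linked$probes[i], ";")[[1]]
    meth <- vapply(pops, function(p) mean(sim$target_means[p, pr]),
                   numeric(1))
    expr <- vapply(pops, function(p)
      mean(sim$expression[g, methmap:::samples_of(sim$expr_sheet, p)]),
      numeric(1))
    # slope > 0, no noise: expression decreases monotonically in methylation
    expect_true(all(diff(expr[order(meth)]) <= 1e-12))
    expect_equal(unname(cor(meth, expr)), -1, tolerance = 1e-12)
  }
  # an unlinked gene is constant across populations
  unlinked <- setdiff(unique(sim$manifest$nearest_gene),
                      linked$linked_gene)[1]
  expr_u <- vapply(pops, function(p)
    mean(sim$expression[unlinked, methmap:::samples_of(sim$expr_sheet, p)]),
    numeric(1))
  expect_equal(sd(expr_u), 0, tolerance = 1e-12)
})

test_that("default-noise linked genes correlate strongly negatively with methylation", {
  hits <- 0; total <- 0
  for (seed in 1:3) {
    spec <- small_spec(seed = seed)
    sim <- simulate_methylome(spec)
    linked <- sim$truth[!is.na(sim$truth$linked_gene), ]
    pops <- unique(sim$expr_sheet$population)
    for (i in seq_len(nrow(linked))) {
      g <- linked$linked_gene[i]
      pr <- strsplit(linked$probes[i], ";")[[1]]
      meth <- vapply(pops, function(p)
        mean(colMeans(sim$beta[pr, methmap:::samples_of(sim$sheet, p),
                               drop = FALSE])), numeric(1))
      expr <- vapply(pops, function(p)
        mean(sim$expression[g, methmap:::samples_of(sim$expr_sheet, p)]),
        numeric(1))
      total <- total + 1
      if (cor(meth, expr) < -0.8) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
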