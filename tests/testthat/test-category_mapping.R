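test_that("pan-mode classification reproduces the canonical sharing patterns", {
  t <- mapping_thresholds()
  # shared by the proliferated normal population and every disease
  expect_equal(classify_pan(profile_delta(), 0.25, "memory", DISEASES, t),
               "proliferation")
  # shared with mature diseases only, absent from the arrested disease
  expect_equal(classify_pan(profile_delta(ALL = 0.02), 0.25, "memory",
                            DISEASES, t), "differentiation")
  # present in all diseases, absent from the normal proliferated population
  expect_equal(classify_pan(profile_delta(memory = 0.05), 0.25, "memory",
                            DISEASES, t), "cancer_specific")
  # present only in the normal proliferated population
  expect_equal(classify_pan(profile_delta(ALL = 0.02, CLL = -0.12,
                                          MCL = 0.01, DLBCL = 0.05,
                                          PCNSL = 0.0), 0.25, "memory",
                            DISEASES, t), "cancer_absent")
  # mixed pattern falls to unclassified
  expect_equal(classify_pan(profile_delta(memory = 0.05, ALL = 0.02), 0.25,
                            "memory", DISEASES, t), "unclassified")
  # an opposite-direction change in the proliferated normal population
  # counts as absence, so the all-disease pattern is cancer-specific
  expect_equal(classify_pan(profile_delta(memory = -0.25), 0.25, "memory",
                            DISEASES, t), "cancer_specific")
})

test_that("classification is symmetric under direction reversal", {
  t <- mapping_thresholds()
  pats <- list(profile_delta(),
               profile_delta(ALL = 0.02),
               profile_delta(memory = 0.05),
               profile_delta(ALL = 0.01, CLL = 0.02, MCL = 0.0,
                             DLBCL = 0.05, PCNSL = 0.03),
               profile_delta(memory = 0.15, ALL = 0.3, CLL = 0.02))
  for (pat in pats) {
    a <- classify_pan(pat, 0.25, "memory", DISEASES, t)
    b <- classify_pan(-pat, -0.25, "memory", DISEASES, t)
    expect_identical(a, b)
  }
})

test_that("per-disease classification applies presence, absence and the 4x rule", {
  t <- mapping_thresholds()
  # specific with clean absence everywhere else
  delta <- profile_delta(memory = 0.05, ALL = 0.05, CLL = 0.05,
                         MCL = 0.05, DLBCL = 0.05, PCNSL = 0.4)
  r <- classify_per_disease(delta, "PCNSL", "memory", DISEASES, t)
  expect_equal(r$category, "disease_specific")
  expect_true(r$stringent_pass)  # 0.05 <= 0.4 / 4

  # another disease at 0.15 violates the absence rule
  delta2 <- replace(delta, "CLL", 0.15)
  r2 <- classify_per_disease(delta2, "PCNSL", "memory", DISEASES, t)
  expect_equal(r2$category, "unclassified")

  # stringency flips exactly at |other| = specific / 4 (0.09 for 0.36)
  delta36 <- replace(delta, "PCNSL", 0.36)
  for (other in c(0.05, 0.089, 0.09, 0.091, 0.099)) {
    d <- replace(delta36, "CLL", other)
    r3 <- classify_per_disease(d, "PCNSL", "memory", DISEASES, t)
    expect_equal(r3$category, "disease_specific")
    expect_equal(r3$stringent_pass, other <= 0.36 / 4)
  }

  # disease-absent: others and the proliferated normal population share a
  # change that the examined disease lacks
  delta4 <- profile_delta(memory = 0.3, ALL = 0.35, CLL = 0.02, MCL = 0.3,
                          DLBCL = 0.3, PCNSL = 0.3)
  r4 <- classify_per_disease(delta4, "CLL", "memory", DISEASES, t)
  expect_equal(r4$category, "disease_absent")
  # ...but is not computable for the progenitor-arrested disease
  delta5 <- profile_delta(memory = 0.3, ALL = 0.02)
  r5 <- classify_per_disease(delta5, "ALL", "memory", DISEASES, t)
  expect_true(is.na(r5$category))

  expect_error(classify_per_disease(delta, "XYZ", "memory", DISEASES, t),
               "unknown disease")
})

test_that("category fractions reproduce published-table arithmetic", {
  # 0.2 cut-off worked example
  counts <- c(cancer_specific = 156L, cancer_absent = 18L,
              differentiation = 514L, proliferation = 5004L)
  tab <- summarize_categories(counts, total_dmrs = 5692L)
  expect_equal(tab$fraction_pct[match(c("cancer_specific", "cancer_absent",
                                        "differentiation", "proliferation"),
                                      tab$category)],
               c(2.7, 0.3, 9.0, 87.9))
  # single category trivially 100%
  expect_equal(summarize_categories(c(x = 1L), 1L)$fraction_pct, 100)
  # relaxed 0.1 cut-off: the two cancer categories combined drop to 2.1%
  counts01 <- c(cancer_specific = 224L, cancer_absent = 56L,
                differentiation = 4409L, proliferation = 8628L)
  tab01 <- summarize_categories(counts01, total_dmrs = sum(counts01))
  combined <- sum(tab01$count[tab01$category %in%
                                c("cancer_specific", "cancer_absent")])
  expect_equal(methmap:::round_half_up(100 * combined / sum(counts01), 1),
               2.1)
  expect_error(summarize_categories(counts, 0), "positive")
  expect_error(summarize_categories(counts, 100L), "smaller")
})

test_that("classification is exclusive and exhaustive over profiled DMRs", {
  spec <- small_spec(seed = 14)
  sim <- simulate_methylome(spec)
  run <- run_pipeline_stages(pipeline_config(seed = 14), sim)
  asg <- run$assignments
  expect_equal(nrow(asg), nrow(run$profiles))
  expect_true(all(asg$category %in% c("proliferation", "differentiation",
                                      "cancer_specific", "cancer_absent",
                                      "unclassified")))
  tab <- table(asg$category)
  expect_equal(sum(tab), nrow(run$profiles))
})

test_that("profiles recover planted deltas within tolerance at default noise", {
  spec <- simulation_spec(seed = 15)
  sim <- simulate_methylome(spec)
  run <- run_pipeline_stages(pipeline_config(seed = 15), sim)
  prof <- run$profiles
  tm <- sim$target_means
  errs <- c()
  for (i in seq_len(nrow(prof))) {
    pr <- strsplit(run$universe$probes[i], ";")[[1]]
    for (p in c("memory", DISEASES)) {
      target <- mean(tm[p, pr] - tm["progenitor", pr])
      errs <- c(errs, abs(prof[[p]][i] - target))
    }
  }
  expect_gte(mean(errs <= 0.05), 0.9)
})
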