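# Small fixtures built in code.

# a hand-laid manifest: two dense probe clusters on chr1 plus sparse
# open-sea probes, with simple feature annotations
tiny_manifest <- function() {
  df <- data.frame(
    probe_id = sprintf("p%02d", 1:10),
    chrom = "chr1",
    pos = c(1001L, 1101L, 1201L, 5000L, 9000L, 9100L, 9200L, 9300L,
            20000L, 40000L),
    island_context = c("island", "island", "shore", "open_sea", "shelf",
                       "shelf", "shelf", "shelf", "open_sea", "open_sea"),
    tss_distance = c(-200L, -100L, 0L, 4000L, 1500L, 800L, 4000L, 4100L,
                     15000L, 35000L),
    nearest_gene = c(rep("GENE1", 4), rep("GENE2", 4), "GENE3", "GENE3"),
    chromHMM = c("bivalent_promoter", "bivalent_promoter", "", "quiescent",
                 "enhancer", "enhancer", "", "", "quiescent", "quiescent"),
    histone = c("H3K27me3", "H3K27me3;H3K9me3", "", "", "H3K36me3",
                "H3K36me3", "", "", "", ""),
    TFBS = c("EZH2", "EZH2;SUZ12", "SUZ12", "", "", "CTCF", "", "", "", ""),
    stringsAsFactors = FALSE)
  validate_manifest(df)
}

# beta matrix with two groups of n samples at given per-probe means
two_group_beta <- function(manifest, meanA, meanB, n = 5, sd = 0,
                           seed = 42) {
  set.seed(seed)
  probes <- manifest$probe_id
  mk <- function(mu, tag) {
    m <- vapply(seq_len(n), function(i)
      pmin(pmax(mu + stats::rnorm(length(mu), 0, sd), 0.001), 0.999),
      numeric(length(mu)))
    colnames(m) <- sprintf("%s%d", tag, seq_len(n))
    m
  }
  muA <- rep_len(meanA, length(probes))
  muB <- rep_len(meanB, length(probes))
  beta <- cbind(mk(muA, "A"), mk(muB, "B"))
  rownames(beta) <- probes
  beta
}

# an effect-profile row as classify_* expects it
profile_delta <- function(memory = 0.25, ALL = 0.25, CLL = 0.25,
                          MCL = 0.25, DLBCL = 0.25, PCNSL = 0.25) {
  c(memory = memory, ALL = ALL, CLL = CLL, MCL = MCL, DLBCL = DLBCL,
    PCNSL = PCNSL)
}

DISEASES <- c("ALL", "CLL", "MCL", "DLBCL", "PCNSL")

# small, fast simulation spec used where defaults would be overkill
small_spec <- function(seed = 1, ...) {
  simulation_spec(n_probes = 600L,
                  planted_counts = c(proliferation = 6L,
                                     differentiation = 2L,
                                     cancer_specific = 2L,
                                     cancer_absent = 1L,
                                     disease_specific = 2L,
                                     disease_absent = 1L),
                  samples_per_population = NULL,
                  seed = seed, ...)
}
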