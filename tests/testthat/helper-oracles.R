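# Independent oracles used by the suite; deliberately written without
# reference to the package internals they check.

# two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration
# (rows = set/background, cols = with/without feature); the (1 + 1e-7)
# factor is the conventional guard against ties lost to floating point
hypergeom_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- vapply(support, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)), numeric(1))
  obs <- dens[support == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# rule-table classifier for the pan-mode deconvolution: every population's
# state versus the discovery sign is reduced to shows/lacks, then the four
# published sharing patterns are looked up in order
oracle_pan_rule_table <- function(mem, dis, arrested, s,
                                  presence = 0.2, corro = 0.1, absent = 0.1,
                                  discovery = 0.3) {
  if (abs(discovery) < presence) {
    if (abs(mem) < presence) return("unclassified")
    s <- sign(mem)
  }
  state <- function(x) {
    if (sign(x) == s && abs(x) >= corro) "shows"
    else if (abs(x) < absent || sign(x) != s) "lacks"
    else "neither"
  }
  m <- state(mem)
  d_states <- vapply(dis, state, character(1))
  mature <- setdiff(names(dis), arrested)
  all_show <- all(d_states == "shows")
  all_lack <- all(d_states == "lacks")
  mature_show <- all(d_states[mature] == "shows")
  arrested_lacks <- d_states[[arrested]] == "lacks"
  if (m == "shows" && all_show) return("proliferation")
  if (m == "shows" && mature_show && arrested_lacks) return("differentiation")
  if (m == "lacks" && all_show) return("cancer_specific")
  if (m == "shows" && all_lack) return("cancer_absent")
  "unclassified"
}

# brute-force chain enumeration for the DMR caller: every maximal run of
# consecutive seed probes with consistent sign and small gaps, scored with
# the same region criteria
brute_force_chains <- function(pos, delta, p, params) {
  seed <- p < params$per_probe_p_seed_cutoff & delta != 0
  n <- length(pos)
  regions <- list()
  i <- 1
  while (i <= n) {
    if (!seed[i]) { i <- i + 1; next }
    j <- i
    while (j < n && seed[j + 1] && pos[j + 1] - pos[j] <= params$max_gap &&
           sign(delta[j + 1]) == sign(delta[i])) j <- j + 1
    if (j - i + 1 >= params$min_cpgs) {
      md <- mean(delta[i:j])
      z <- sign(delta[i:j]) * qnorm(pmin(p[i:j], 1 - 1e-16) / 2,
                                    lower.tail = FALSE)
      rp <- 2 * pnorm(-abs(sum(z) / sqrt(j - i + 1)))
      if (rp < params$region_p_cutoff &&
          abs(md) >= params$min_mean_abs_delta)
        regions[[length(regions) + 1]] <- c(start = i, end = j)
    }
    i <- j + 1
  }
  regions
}
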