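# Shared fixture builders. Everything is generated in code at test time.

# A minimal one-stress design: condition "S" at times 0/6 with n_rep
# replicates per time point.
tiny_design <- function(n_rep = 3L, times = c(0, 6)) {
  cfg <- tibble::tibble(acclimation = "LL", condition = "S",
                        times = list(times), n_rep = as.integer(n_rep),
                        kind = "shift", reference_time = 0)
  generate_design(cfg, share_t0 = FALSE)
}

# Truth with every planted effect switched off (pure NB noise).
null_truth <- function(design, n_genes, seed, ...) {
  simulate_truth(design, n_genes = n_genes, module_frac = 0, frac_de = 0,
                 n_cyanorons = 0, seed = seed, ...)
}

# Brute-force BH: literal definition, quadratic scan.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[o[j]] / j), numeric(1))
    padj[o[i]] <- min(vals)
  }
  padj
}

# Brute-force cyanoron enumeration: every contiguous window of length >=
# min_run, checked directly against the rule (same nonzero module
# throughout, maximal, and concordant in >= half the stress's time
# points).
brute_force_cyanorons <- function(genome_modules, lfc_matrix, min_run, lfc) {
  n <- length(genome_modules)
  times <- colnames(lfc_matrix)
  need <- ceiling(length(times) / 2)
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (e - s + 1 < min_run) next
      mods <- genome_modules[s:e]
      if (any(mods == 0) || length(unique(mods)) != 1) next
      # maximality
      if (s > 1 && genome_modules[s - 1] == mods[1]) next
      if (e < n && genome_modules[e + 1] == mods[1]) next
      block <- lfc_matrix[s:e, , drop = FALSE]
      supp <- apply(block > lfc, 2, all) | apply(block < -lfc, 2, all)
      if (sum(supp) >= need) {
        out[[length(out) + 1]] <- tibble::tibble(
          start = s, end = e, module = mods[1], n_support = sum(supp))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          module = integer(), n_support = integer()))
  }
  dplyr::bind_rows(out)
}

# Pearson correlation and Student-t p-value from first principles.
brute_force_corr <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Adjusted Rand index (mclust's implementation, used as the clustering
# agreement metric in recovery tests).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
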