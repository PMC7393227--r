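test_that("count generation is deterministic and respects the null model", {
  d <- tiny_design(n_rep = 50L)
  tr <- null_truth(d, 60, seed = 42)
  cm1 <- generate_counts(d, tr, seed = 42)
  cm2 <- generate_counts(d, tr, seed = 42)
  expect_identical(cm1$counts, cm2$counts)
  expect_false(identical(cm1$counts, generate_counts(d, tr, seed = 43)$counts))

  # near-Poisson null: per-gene means converge to baseline x size factor
  tr$nb_dispersion[] <- 1e-6
  cm <- generate_counts(d, tr, seed = 42)
  expected <- outer(tr$baseline_mean, tr$size_factors[d$sample_id])
  rel <- abs(rowMeans(cm$counts) - rowMeans(expected)) / rowMeans(expected)
  expect_lt(median(rel), 0.05)
})

test_that("a planted log2FC of 2 quadruples the mean normalised counts", {
  d <- tiny_design(n_rep = 400L)
  tr <- null_truth(d, 30, seed = 7)
  tr$de_truth <- tibble::tibble(gene_id = "g0001", condition = "S",
                                time_h = 6, log2fc = 2)
  cm <- generate_counts(d, tr, seed = 7)
  q <- sweep(cm$counts, 2, tr$size_factors[d$sample_id], `/`)
  stress <- d$time_h == 6
  ratio <- mean(q["g0001", stress]) / mean(q["g0001", !stress])
  expect_equal(ratio, 4, tolerance = 0.1)
  # a null gene stays flat
  r0 <- mean(q["g0002", stress]) / mean(q["g0002", !stress])
  expect_equal(r0, 1, tolerance = 0.1)
})

test_that("traits are linear read-outs of the latent factors", {
  d <- generate_design()
  tr <- simulate_truth(d, n_genes = 50, n_modules = 2, n_cyanorons = 0,
                       seed = 5)
  tr$trait_loadings <- matrix(c(1, -1, 0, 0), 2, 2,
                              dimnames = list(c("t_pos", "t_neg"),
                                              c("ME1", "ME2")))
  tt <- generate_traits(d, tr, noise_sd = 0, seed = 5)
  expect_equal(tt$t_pos, unname(tr$latent_factors[1, ]), tolerance = 1e-12)
  expect_equal(cor(tt$t_neg, tr$latent_factors[1, ]), -1, tolerance = 1e-12)

  # noisy recovery at the default noise level
  hits <- vapply(1:20, function(i) {
    ti <- generate_traits(d, tr, noise_sd = 0.3, seed = 100 + i)
    abs(cor(ti$t_pos, tr$latent_factors[1, ])) > 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(generate_traits(d, tr, noise_sd = -1), ">= 0")
})

test_that("latent factors are centred and planted truth is fully queryable", {
  d <- generate_design()
  tr <- simulate_truth(d, n_genes = 300, n_modules = 3, seed = 9)
  expect_equal(unname(rowMeans(tr$latent_factors)), rep(0, 3),
               tolerance = 1e-12)
  expect_true(all(tr$cyanoron_truth$end_index - tr$cyanoron_truth$start_index
                  + 1 >= 4))
  expect_true(all(tr$baseline_mean > 0 & is.finite(tr$baseline_mean)))
  # planted cyanoron members share the module label and the planted effect
  for (i in seq_len(nrow(tr$cyanoron_truth))) {
    run <- tr$cyanoron_truth[i, ]
    span <- (run$start_index + 1):(run$end_index + 1)
    expect_true(all(tr$module_labels[span] == run$module))
    lfc <- planted_lfc(tr, run$condition,
                       max(tr$de_truth$time_h[tr$de_truth$condition ==
                                                run$condition]))
    expect_true(all(abs(lfc[span]) > 1))
  }
})

test_that("annotation is genome-ordered, GFF3 round-trips, and planted runs are adjacent", {
  d <- tiny_design()
  tr <- simulate_truth(d, n_genes = 60, n_modules = 2, n_cyanorons = 2,
                       seed = 13)
  anno <- generate_annotation(60, tr, seed = 13)
  g <- anno$genes
  expect_equal(g$genome_index, 0:59)
  expect_true(all(diff(g$start) > 0))
  expect_true(all(g$end >= g$start))
  expect_true(all(g$start[-1] > g$end[-60]))  # non-overlapping

  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(anno, f)
  rt <- read_gff3(f)
  expect_identical(rt[, c("gene_id", "start", "end", "strand")],
                   g[, c("gene_id", "start", "end", "strand")])

  expect_error(generate_annotation(10, tr), "smaller")
  # default genome-scale layout emits 2,634 records
  expect_equal(nrow(generate_annotation(2634, seed = 1)$genes), 2634)
})

test_that("kinetics generator encodes repair as a decay-coefficient difference", {
  k0 <- generate_kinetics(0.2, 0, y0 = 0.5, noise_sd = 0, seed = 1)
  expect_equal(k0$control$value, k0$inhibited$value, tolerance = 1e-12)

  kin <- generate_kinetics(0.2, 0.3, y0 = 0.6, noise_sd = 0, seed = 1)
  fc <- fit_exp_decay(kin$control$time_h, kin$control$value)
  fi <- fit_exp_decay(kin$inhibited$time_h, kin$inhibited$value)
  expect_equal(fi$k - fc$k, 0.3, tolerance = 1e-6)

  expect_error(generate_kinetics(0.2, 0.3, times = numeric(0)), "non-empty")
  expect_error(generate_kinetics(0.2, 0.3, noise_sd = -0.1), ">= 0")
  noisy <- generate_kinetics(0.2, 0.3, noise_sd = 0.5, seed = 2)
  expect_true(all(noisy$control$value >= 0 & noisy$control$value <= 1))
})

test_that("spectrum generator and ratio extraction form a closed loop", {
  # well-separated peaks: ratios recovered to 1e-6
  sp <- generate_spectrum(c(2, 1, 1), widths = c(4, 4, 4))
  r <- spectrum_ratios(sp$wavelength_nm, sp$intensity)
  expect_equal(r$pe_pc, 2, tolerance = 1e-6)
  expect_equal(r$pc_ta, 1, tolerance = 1e-6)

  # default widths overlap slightly at the PC/TA shoulder
  spd <- generate_spectrum(c(2, 1, 1))
  rd <- spectrum_ratios(spd$wavelength_nm, spd$intensity)
  expect_equal(rd$pe_pc, 2, tolerance = 1e-4)
  expect_equal(rd$pc_ta, 1, tolerance = 1e-4)

  sp2 <- generate_spectrum(c(3, 1.5, 0.5))
  r2 <- spectrum_ratios(sp2$wavelength_nm, sp2$intensity)
  expect_equal(r2$pe_pc, 2, tolerance = 1e-3)
  expect_equal(r2$pc_ta, 3, tolerance = 0.02)

  # PE-only spectrum leaves PC/TA undefined
  pe_only <- generate_spectrum(c(2, 0, 0), widths = c(4, 4, 4))
  expect_error(spectrum_ratios(pe_only$wavelength_nm, pe_only$intensity))
  expect_error(generate_spectrum(grid = seq(600, 750)), "cover")
})
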