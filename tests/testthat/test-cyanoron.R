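make_lfc_table <- function(lfc_matrix, condition = "S") {
  tibble::as_tibble(lfc_matrix, rownames = "gene_id") |>
    tidyr::pivot_longer(-gene_id, names_to = "time_h",
                        values_to = "log2fc") |>
    dplyr::mutate(time_h = as.numeric(time_h), condition = condition)
}

toy_annotation <- function(n) {
  tibble::tibble(gene_id = sprintf("g%03d", 1:n), seqid = "chr",
                 start = (1:n) * 1000L, end = (1:n) * 1000L + 800L,
                 strand = "+", genome_index = 0:(n - 1))
}

test_that("a fully concordant adjacent run is called once, with all time points supporting", {
  anno <- toy_annotation(10)
  asn <- tibble::tibble(gene_id = anno$gene_id,
                        module = c(0L, rep(1L, 5), 0L, 0L, 0L, 0L),
                        submodule = "x")
  lfc <- matrix(0, 10, 4, dimnames = list(anno$gene_id, c(1, 2, 4, 6)))
  lfc[2:6, ] <- 2
  calls <- find_cyanorons(anno, asn, make_lfc_table(lfc))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$length, 5)
  expect_equal(calls$n_support, 4)
  expect_equal(calls$start_index, 1)
  expect_equal(calls$end_index, 5)
  expect_equal(calls$directions[[1]], rep("up", 4))

  # three adjacent concordant genes: below the minimum run length
  asn3 <- dplyr::mutate(asn, module = c(0L, rep(1L, 3), rep(0L, 6)))
  expect_equal(nrow(find_cyanorons(anno, asn3, make_lfc_table(lfc))), 0)

  # all log2FC zero: nothing is called even with one big module
  asn_all <- dplyr::mutate(asn, module = 1L)
  expect_equal(nrow(find_cyanorons(anno, asn_all,
                                   make_lfc_table(lfc * 0))), 0)
})

test_that("down-concordance counts and mixed directions do not", {
  anno <- toy_annotation(6)
  asn <- tibble::tibble(gene_id = anno$gene_id, module = 1L, submodule = "x")
  lfc <- matrix(-2, 6, 2, dimnames = list(anno$gene_id, c(3, 6)))
  calls <- find_cyanorons(anno, asn, make_lfc_table(lfc))
  expect_equal(calls$directions[[1]], c("down", "down"))

  mixed <- lfc; mixed[3, ] <- 2  # one member up while others down
  expect_equal(nrow(find_cyanorons(anno, asn, make_lfc_table(mixed))), 0)
})

test_that("detection agrees exactly with brute-force window enumeration", {
  for (s in 1:20) {
    withr::with_seed(3000 + s, {
      n <- 200
      anno <- toy_annotation(n)
      modules <- sample(0:4, n, replace = TRUE, prob = c(0.2, rep(0.2, 4)))
      lfc <- matrix(rnorm(n * 4, 0, 1.6), n, 4,
                    dimnames = list(anno$gene_id, c(1, 2, 4, 6)))
      asn <- tibble::tibble(gene_id = anno$gene_id, module = modules,
                            submodule = "x")
      got <- find_cyanorons(anno, asn, make_lfc_table(lfc))
      want <- brute_force_cyanorons(modules, lfc, min_run = 4, lfc = 1)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        got_s <- dplyr::arrange(tibble::tibble(
          start = got$start_index + 1, end = got$end_index + 1,
          module = got$module, n_support = got$n_support), start)
        expect_equal(got_s, dplyr::arrange(want, start))
      }
    })
  }
})

test_that("calls are monotone in the fold-change threshold and run length", {
  withr::with_seed(77, {
    n <- 300
    anno <- toy_annotation(n)
    modules <- sample(0:2, n, replace = TRUE, prob = c(0.1, 0.45, 0.45))
    lfc <- matrix(rnorm(n * 4, 0, 2), n, 4,
                  dimnames = list(anno$gene_id, c(1, 2, 4, 6)))
    asn <- tibble::tibble(gene_id = anno$gene_id, module = modules,
                          submodule = "x")
    tab <- make_lfc_table(lfc)
    n_calls <- function(min_run, thr) {
      nrow(find_cyanorons(anno, asn, tab, min_run = min_run, lfc = thr))
    }
    for (thr in c(0.5, 1, 1.5)) {
      expect_gte(n_calls(4, thr), n_calls(4, thr + 0.5))
    }
    for (mr in c(4, 5, 6)) {
      expect_gte(n_calls(mr, 1), n_calls(mr + 1, 1))
    }
  })
})

test_that("planted runs are always recovered from noiseless planted effects", {
  d <- generate_design()
  for (s in 1:5) {
    tr <- simulate_truth(d, n_genes = 300, n_modules = 3, n_cyanorons = 4,
                         seed = 400 + s)
    anno <- generate_annotation(300, tr, seed = 400 + s)
    asn <- tibble::tibble(gene_id = tr$gene_ids, module = tr$module_labels,
                          submodule = "x")
    lfc_tab <- tr$de_truth |>
      dplyr::right_join(tidyr::expand_grid(
        gene_id = tr$gene_ids,
        dplyr::distinct(design_contrasts(d), condition, time_h)),
        by = c("gene_id", "condition", "time_h")) |>
      dplyr::mutate(log2fc = ifelse(is.na(log2fc), 0, log2fc))
    calls <- find_cyanorons(anno, asn, lfc_tab)
    for (i in seq_len(nrow(tr$cyanoron_truth))) {
      run <- tr$cyanoron_truth[i, ]
      hit <- calls$condition == run$condition &
        calls$start_index == run$start_index &
        calls$end_index == run$end_index & calls$module == run$module
      expect_true(any(hit))
    }
  }
})

test_that("the null model produces almost no false calls", {
  nr <- cyanoron_null_rate(n_genes = 800, module_sizes = c(160, 160, 160),
                           n_sims = 20, seed = 5)
  expect_lt(nr$mean_calls, 0.5)
  expect_error(cyanoron_null_rate(n_sims = 0), ">= 1")
})

test_that("BED export is 0-based half-open with start < end", {
  anno <- toy_annotation(8)
  asn <- tibble::tibble(gene_id = anno$gene_id, module = 1L, submodule = "x")
  lfc <- matrix(2, 8, 2, dimnames = list(anno$gene_id, c(3, 6)))
  calls <- find_cyanorons(anno, asn, make_lfc_table(lfc))
  f <- withr::local_tempfile(fileext = ".bed")
  write_cyanoron_bed(calls, anno, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2, anno$start[1] - 1L)  # 0-based start
  expect_equal(bed$V3, anno$end[8])         # half-open end
  expect_true(all(bed$V2 < bed$V3))
  expect_equal(bed$V4, "S:1:8")
})
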