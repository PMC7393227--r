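test_that("module-trait correlation matches first-principles Pearson/Student computation", {
  me <- matrix(c(1.2, 0.5, -0.3, 2.0, -1.1, 0.4), 1,
               dimnames = list("ME1", paste0("s", 1:6)))
  traits <- tibble::tibble(sample_id = paste0("s", 1:6),
                           t1 = c(1.0, 0.7, -0.2, 1.8, -1.3, 0.6),
                           t2 = c(0.3, -0.5, 1.1, 0.2, 0.9, -0.7))
  res <- module_trait_corr(me, traits, adjust = "none")
  for (tn in c("t1", "t2")) {
    bf <- brute_force_corr(me[1, ], traits[[tn]])
    row <- res[res$trait == tn, ]
    expect_equal(row$r, bf$r, tolerance = 1e-12)
    expect_equal(row$p, bf$p, tolerance = 1e-12)
  }
  # identity trait: perfect correlation
  traits$self <- me[1, ]
  res2 <- module_trait_corr(me, traits, adjust = "none")
  row <- res2[res2$trait == "self", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_true(row$significant)
  expect_s3_class(autoplot(res2), "ggplot")
})

test_that("correlation is symmetric and affine-invariant, and short overlaps are flagged", {
  withr::with_seed(11, {
    x <- rnorm(30); y <- rnorm(30)
    me <- matrix(x, 1, dimnames = list("ME1", paste0("s", 1:30)))
    tr1 <- tibble::tibble(sample_id = paste0("s", 1:30), t = y)
    a <- module_trait_corr(me, tr1, adjust = "none")
    me_swap <- matrix(y, 1, dimnames = list("ME1", paste0("s", 1:30)))
    b <- module_trait_corr(me_swap,
                           tibble::tibble(sample_id = paste0("s", 1:30),
                                          t = x), adjust = "none")
    expect_equal(a$r, b$r, tolerance = 1e-12)
    c_ <- module_trait_corr(me, dplyr::mutate(tr1, t = 3 * t - 7),
                            adjust = "none")
    expect_equal(a$r, c_$r, tolerance = 1e-12)
  })
  me <- matrix(1:6, 1, dimnames = list("ME1", paste0("s", 1:6)))
  short <- tibble::tibble(sample_id = paste0("s", 1:6),
                          t = c(1, 2, 3, NA, NA, NA))
  res <- module_trait_corr(me, short)
  expect_false(res$testable[1])
  expect_true(is.na(res$p[1]))
})

test_that("null traits are flagged significant at close to the nominal rate", {
  withr::with_seed(13, {
    n <- 100
    me <- matrix(rnorm(5 * n), 5,
                 dimnames = list(paste0("ME", 1:5), paste0("s", 1:n)))
    hits <- vapply(1:60, function(i) {
      traits <- tibble::as_tibble(
        stats::setNames(as.data.frame(matrix(rnorm(4 * n), n)),
                        paste0("t", 1:4)))
      traits$sample_id <- paste0("s", 1:n)
      res <- module_trait_corr(me, traits, adjust = "none",
                               p_threshold = 0.05)
      mean(res$significant)
    }, numeric(1))
    # 20 tests per repetition at nominal 5%
    expect_lt(abs(mean(hits) - 0.05), 0.02)
  })
})

test_that("VIP scores satisfy their algebraic identities", {
  withr::with_seed(17, {
    # single predictor: VIP exactly 1
    x <- matrix(rnorm(30), 1, dimnames = list("g1", paste0("s", 1:30)))
    y <- 0.5 * x[1, ] + rnorm(30, 0, 0.3)
    expect_equal(pls_vip(x, y, n_components = 1)$vip, 1, tolerance = 1e-10)

    # mean(VIP^2) = 1 for arbitrary fitted models
    for (i in 1:10) {
      P <- sample(3:40, 1); n <- sample((P + 5):60, 1)
      X <- matrix(rnorm(P * n), P, dimnames = list(paste0("g", 1:P), NULL))
      y <- rnorm(n)
      v <- pls_vip(X, y, n_components = sample(1:3, 1))
      expect_equal(mean(v$vip^2), 1, tolerance = 1e-10)
    }
    expect_error(pls_vip(x, rep(1, 30)), "constant")
  })
})

test_that("the informative predictor earns the top VIP score", {
  hits <- vapply(1:100, function(i) {
    withr::with_seed(2000 + i, {
      X <- matrix(rnorm(20 * 40), 20,
                  dimnames = list(paste0("g", 1:20), NULL))
      y <- 1.5 * X[7, ] + rnorm(40, 0, 0.5)
      v <- pls_vip(X, y)
      which.max(v$vip) == 7 && v$vip[7] > 1
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("VIP agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(19, {
    X <- matrix(rnorm(10 * 30), 10, dimnames = list(paste0("g", 1:10), NULL))
    y <- X[1, ] - 2 * X[2, ] + rnorm(30, 0, 0.2)
    ours <- pls_vip(X, y, n_components = 2)
    fit <- mixOmics::pls(t(X), y, ncomp = 2, scale = TRUE, mode = "regression")
    theirs <- mixOmics::vip(fit)[, 2]
    expect_equal(unname(ours$vip), unname(theirs), tolerance = 1e-6)
  })
})

test_that("exclusive condition sets match brute-force power-set enumeration", {
  withr::with_seed(23, {
    conds <- c("A", "B", "C")
    genes <- sprintf("g%03d", 1:500)
    de <- tidyr::expand_grid(gene_id = genes, condition = conds,
                             time_h = c(1, 2)) |>
      dplyr::mutate(log2fc = rnorm(dplyr::n(), 0, 1.5),
                    padj = runif(dplyr::n())^2) |>
      call_de()
    asn <- tibble::tibble(gene_id = genes,
                          module = sample(0:3, 500, TRUE),
                          submodule = "x")
    ups <- upset_classify(de, conds, asn)

    # brute force: enumerate each gene's hit set directly
    hit_mat <- sapply(conds, function(cc) {
      vapply(genes, function(g) {
        any(de$status != "ns" & de$gene_id == g & de$condition == cc)
      }, logical(1))
    })
    expected_sets <- apply(hit_mat, 1, function(h) {
      paste(conds[h], collapse = "+")
    })
    keep <- expected_sets != ""
    bf <- tibble::tibble(gene_id = genes[keep],
                         set = unname(expected_sets[keep])) |>
      dplyr::left_join(asn[, c("gene_id", "module")], by = "gene_id") |>
      dplyr::count(set, module, name = "n") |>
      dplyr::arrange(set, module)
    expect_equal(dplyr::arrange(ups$counts, set, module), bf)

    # partition property: set counts sum to the number of ever-DE genes
    expect_equal(sum(ups$counts$n), sum(keep))
    expect_s3_class(autoplot(ups), "ggplot")
  })
})

test_that("upset rule examples and the inclusive mode behave as documented", {
  de <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g2"),
    condition = c("LLHL", "LLUV", "LLHL", "LLUV", "HLUV"),
    time_h = c(6, 6, 6, 6, 6),
    log2fc = c(2, 0.2, 2, -2, 1.4),
    status = factor(c("up", "ns", "up", "down", "up"),
                    levels = c("up", "down", "ns")))
  ups <- upset_classify(de, c("LLHL", "LLUV", "HLUV"))
  m <- ups$membership
  expect_equal(m$set[m$gene_id == "g1"], "LLHL")
  expect_equal(m$set[m$gene_id == "g2"], "HLUV+LLHL+LLUV")
  inc <- upset_classify(de, c("LLHL", "LLUV", "HLUV"), mode = "inclusive")
  # g2 supports all 7 non-empty subsets, g1 adds one to {LLHL}
  expect_equal(sum(inc$counts$n), 8)
  expect_error(upset_classify(de, character(0)), "empty")
  expect_error(upset_classify(de, c("LLHL", "ZZ")), "lack")
})
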