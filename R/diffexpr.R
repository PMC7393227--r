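#' Median-of-ratios library-size factors
#'
#' For each sample, the size factor is the median over all-sample-expressed
#' genes of the ratio of that sample's count to the gene's geometric mean
#' across samples. No post-hoc renormalisation is applied. Genes with a
#' zero in any sample contribute nothing to the factors but remain in all
#' downstream tests.
#'
#' @param counts A `count_matrix` or a gene x sample numeric matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else
    as_gene_matrix(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) abort("no gene has nonzero counts in every sample")
  lg <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, stats::median)
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments on normalised counts pooled within replicate groups
#' (same condition and time): per gene,
#' `alpha_raw = max(0, (s2 - mu) / mu^2)` with `mu` the grand mean of group
#' means and `s2` the pooled within-group variance. Raw estimates are then
#' shrunk halfway toward a smooth trend of dispersion versus mean
#' expression, and floored at 1e-8.
#'
#' @param counts A `count_matrix`, or matrix plus `design`.
#' @param design Design tibble (ignored when `counts` is a `count_matrix`).
#' @param sf Optional precomputed size factors.
#' @return Named per-gene dispersion vector (>= 1e-8).
#' @export
estimate_dispersion <- function(counts, design = NULL, sf = NULL) {
  if (inherits(counts, "count_matrix")) {
    design <- counts$design
    counts <- counts$counts
  }
  if (is.null(design)) abort("`design` is required")
  groups <- paste(design$condition, design$time_h)
  tab <- table(groups)
  if (!any(tab >= 2)) abort("no replicated group in the design")
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, `/`)

  rep_groups <- names(tab)[tab >= 2]
  gm <- vapply(rep_groups, function(g) {
    rowMeans(q[, groups == g, drop = FALSE])
  }, numeric(nrow(q)))
  gv <- vapply(rep_groups, function(g) {
    apply(q[, groups == g, drop = FALSE], 1, stats::var)
  }, numeric(nrow(q)))
  w <- tab[rep_groups] - 1
  mu <- rowMeans(gm)
  s2 <- as.vector(gv %*% w / sum(w))
  alpha_raw <- pmax(0, (s2 - mu) / mu^2)
  alpha_raw[!is.finite(alpha_raw)] <- 0

  # trend: mean dispersion against log mean expression. No robustness
  # iterations: raw moment estimates are legitimately right-skewed, and a
  # median-type trend would systematically understate the dispersion.
  ok <- mu > 0
  trend <- rep(0, length(mu))
  if (sum(ok) >= 10) {
    lo <- stats::lowess(log(mu[ok]), alpha_raw[ok], f = 0.5, iter = 0)
    trend[ok] <- stats::approx(lo$x, lo$y, xout = log(mu[ok]), rule = 2)$y
  }
  alpha <- pmax(1e-8, 0.5 * alpha_raw + 0.5 * pmax(0, trend))
  stats::setNames(alpha, rownames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: in ascending order of p,
#' `padj_(i) = min_{j >= i} min(1, m * p_(j) / j)`, mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in [0, 1]; NA passes through.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok])
  padj_sorted <- rev(cummin(rev(pmin(1, m * p[ok][o] / seq_len(m)))))
  out[ok[o]] <- padj_sorted
  out
}

#' Wald test of a stress-vs-reference contrast
#'
#' For one (condition, time) group against its reference group: the log2
#' fold change is computed from group means of normalised counts with a
#' pseudocount of 0.5; its standard error comes from the delta method under
#' the negative-binomial variance `mu + alpha * mu^2`; the p-value is the
#' two-sided normal tail of `log2fc / se`.
#'
#' @param counts A `count_matrix`.
#' @param condition,time_h Stress group coordinates.
#' @param ref_condition,ref_time Reference group coordinates.
#' @param sf Size factors (computed if missing).
#' @param dispersion Per-gene dispersions (estimated if missing).
#' @param pseudocount Added to normalised group means before the log
#'   (default 0.5).
#' @return A tibble: `gene_id`, `base_mean`, `log2fc`, `se`, `p`.
#' @export
wald_test <- function(counts, condition, time_h, ref_condition, ref_time,
                      sf = NULL, dispersion = NULL, pseudocount = 0.5) {
  design <- counts$design
  m <- counts$counts
  g1 <- design$condition == condition & design$time_h == time_h
  g0 <- design$condition == ref_condition & design$time_h == ref_time
  if (!any(g1) || !any(g0)) {
    abort(sprintf("contrast groups empty: %s t=%s vs %s t=%s",
                  condition, time_h, ref_condition, ref_time))
  }
  if (is.null(sf)) sf <- size_factors(m)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, sf = sf)
  q <- sweep(m, 2, sf, `/`)

  mean1 <- rowMeans(q[, g1, drop = FALSE])
  mean0 <- rowMeans(q[, g0, drop = FALSE])
  log2fc <- log2(mean1 + pseudocount) - log2(mean0 + pseudocount)

  # var of a group mean of normalised counts under NB(mu, alpha):
  # (1/n^2) * sum_j (mu / sf_j + alpha * mu^2)
  vmean <- function(mu, idx) {
    n <- sum(idx)
    (mu / n^2) * sum(1 / sf[idx]) + dispersion * mu^2 / n
  }
  v1 <- vmean(mean1, g1)
  v0 <- vmean(mean0, g0)
  ln2sq <- log(2)^2
  se <- sqrt(v1 / ((mean1 + pseudocount)^2 * ln2sq) +
             v0 / ((mean0 + pseudocount)^2 * ln2sq))
  se <- pmax(se, 1e-12)
  z <- log2fc / se
  tibble(gene_id = rownames(m),
         base_mean = unname((mean1 + mean0) / 2),
         log2fc = unname(log2fc), se = unname(se),
         p = unname(2 * stats::pnorm(-abs(z))))
}

#' Differential expression across all contrasts of a design
#'
#' Runs the Wald test for every stress-vs-reference contrast (shift
#' conditions against the acclimation time-0 reference, diel samples
#' against the 6 a.m. time point), adjusts p-values by Benjamini-Hochberg
#' within each contrast, and applies the DE rule: a gene is `up` if
#' `padj <= alpha` and `log2fc >= lfc_min`, `down` if `padj <= alpha` and
#' `log2fc <= -lfc_min`, otherwise `ns`.
#'
#' @param counts A `count_matrix`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param contrasts Optional contrast tibble; defaults to
#'   [design_contrasts()] of the attached design.
#' @return An object of class `de_result`: a tibble with `gene_id`,
#'   `condition`, `time_h`, `base_mean`, `log2fc`, `se`, `p`, `padj`,
#'   `status`, with the thresholds recorded as attributes.
#' @export
run_de <- function(counts, alpha = 0.05, lfc_min = 1, contrasts = NULL) {
  if (is.null(contrasts)) contrasts <- design_contrasts(counts$design)
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf = sf)
  res <- purrr::pmap(contrasts |> select("condition", "time_h",
                                         "ref_condition", "ref_time"),
                     function(condition, time_h, ref_condition, ref_time) {
    wald_test(counts, condition, time_h, ref_condition, ref_time,
              sf = sf, dispersion = disp) |>
      mutate(condition = condition, time_h = time_h, .after = "gene_id")
  }) |>
    purrr::list_rbind() |>
    group_by(.data$condition, .data$time_h) |>
    mutate(padj = bh_adjust(.data$p)) |>
    ungroup()
  res <- call_de(res, alpha = alpha, lfc_min = lfc_min)
  structure(res, class = c("de_result", class(res)),
            alpha = alpha, lfc_min = lfc_min)
}

#' Apply the differential-expression decision rule
#'
#' @param de Tibble with `padj` and `log2fc` columns.
#' @param alpha Adjusted-p threshold.
#' @param lfc_min Minimum |log2FC|.
#' @return The tibble with a `status` factor (`up`/`down`/`ns`).
#' @export
call_de <- function(de, alpha = 0.05, lfc_min = 1) {
  if (!"padj" %in% names(de)) abort("`padj` column required")
  de |>
    mutate(status = factor(case_when(
      .data$padj <= alpha & .data$log2fc >= lfc_min ~ "up",
      .data$padj <= alpha & .data$log2fc <= -lfc_min ~ "down",
      TRUE ~ "ns"
    ), levels = c("up", "down", "ns")))
}

#' Per-contrast counts of up-, down- and non-regulated genes
#'
#' @param de A `de_result` (or tibble with `condition`, `time_h`, `status`).
#' @return A tibble with one row per contrast and columns `up`, `down`,
#'   `ns`.
#' @export
de_summary <- function(de) {
  as_tibble(de) |>
    count(.data$condition, .data$time_h, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L) |>
    (\(df) {
      for (col in c("up", "down", "ns")) {
        if (!col %in% names(df)) df[[col]] <- 0L
      }
      df
    })()
}

#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = n_distinct(x$gene_id),
         n_contrasts = nrow(distinct(as_tibble(x), .data$condition,
                                     .data$time_h)),
         n_de = sum(x$status != "ns"),
         alpha = attr(x, "alpha"), lfc_min = attr(x, "lfc_min"))
}
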