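#' Module eigengene vs trait correlations
#'
#' Pairwise-complete Pearson correlation between each module eigengene and
#' each trait, with the p-value from the Student t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' P-values are BH-adjusted across the whole module x trait grid by
#' default before applying the significance threshold (1e-3).
#'
#' @param eigengenes Module x sample matrix from [module_eigengene()].
#' @param traits Tibble with `sample_id` and numeric trait columns; missing
#'   values allowed.
#' @param p_threshold Significance threshold on the (adjusted) p-value.
#' @param adjust `"BH"` (default) or `"none"`.
#' @param min_n Minimum overlapping samples per pair (default 4).
#' @return An object of class `module_trait_correlation`: tibble with
#'   `module`, `trait`, `r`, `n`, `p`, `padj`, `significant`, `testable`.
#' @export
module_trait_corr <- function(eigengenes, traits, p_threshold = 1e-3,
                              adjust = c("BH", "none"), min_n = 4) {
  adjust <- match.arg(adjust)
  trait_names <- setdiff(names(traits), "sample_id")
  samples <- intersect(colnames(eigengenes), traits$sample_id)
  tm <- as.matrix(traits[match(samples, traits$sample_id), trait_names,
                         drop = FALSE])
  res <- tidyr::expand_grid(module = rownames(eigengenes),
                            trait = trait_names) |>
    rowwise() |>
    mutate(.pair = list(.corr_pair(eigengenes[.data$module, samples],
                                   tm[, .data$trait], min_n))) |>
    ungroup() |>
    tidyr::unnest_wider(".pair")
  res$padj <- if (adjust == "BH") bh_adjust(res$p) else res$p
  res |>
    mutate(significant = !is.na(.data$padj) & .data$padj <= p_threshold) |>
    structure(class = c("module_trait_correlation", "tbl_df", "tbl",
                        "data.frame"),
              p_threshold = p_threshold, adjust = adjust)
}

.corr_pair <- function(x, y, min_n) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_n) {
    return(list(r = NA_real_, n = n, p = NA_real_, testable = FALSE))
  }
  r <- stats::cor(x[ok], y[ok])
  if (!is.finite(r)) {
    return(list(r = NA_real_, n = n, p = NA_real_, testable = FALSE))
  }
  r2 <- min(r^2, 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  list(r = r, n = n, p = 2 * stats::pt(-abs(tstat), df = n - 2),
       testable = TRUE)
}

#' PLS1 regression with VIP scores
#'
#' NIPALS partial least squares of one trait on a module's standardised
#' expression. Variable importance in projection for gene g is
#' `VIP_g = sqrt(P * sum_c w_gc^2 SS_c / sum_c SS_c)` where `P` is the
#' number of predictors, `w_c` the unit-norm weight vectors and `SS_c` the
#' trait variance explained by component c. The mean of `VIP^2` over genes
#' is exactly 1, so `VIP > 1` marks above-average contributors.
#'
#' @param module_expr Gene x sample matrix (predictors; standardised
#'   internally).
#' @param trait Numeric response, one value per sample (aligned to
#'   columns); NA samples are dropped.
#' @param n_components Number of PLS components (default 2).
#' @return An object of class `vip_result`: tibble with `gene_id`, `vip`,
#'   `vip_flag` (`vip > 1`), ordered as the input genes; attributes carry
#'   the weights, scores and explained sums of squares.
#' @export
pls_vip <- function(module_expr, trait, n_components = 2) {
  X0 <- t(as_gene_matrix(module_expr)) # samples x genes
  ok <- is.finite(trait)
  X0 <- X0[ok, , drop = FALSE]
  y <- trait[ok]
  if (stats::sd(y) == 0) abort("constant trait: PLS undefined")
  if (nrow(X0) < n_components + 2) {
    abort("need at least n_components + 2 samples with trait values")
  }
  P <- ncol(X0)
  n_components <- min(n_components, P, nrow(X0) - 1)
  X <- scale(X0)
  X[, attr(X, "scaled:scale") == 0] <- 0
  y <- as.vector(scale(y))

  W <- matrix(0, P, n_components)
  SS <- numeric(n_components)
  Tsc <- matrix(0, nrow(X), n_components)
  Xc <- X
  yc <- y
  for (c in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- c - 1L; break }
    w <- w / nw
    t_c <- drop(Xc %*% w)
    tt <- sum(t_c^2)
    p_c <- drop(crossprod(Xc, t_c)) / tt
    q_c <- sum(t_c * yc) / tt
    Xc <- Xc - tcrossprod(t_c, p_c)
    yc <- yc - q_c * t_c
    W[, c] <- w
    Tsc[, c] <- t_c
    SS[c] <- q_c^2 * tt  # trait sum of squares explained by component c
  }
  if (n_components < 1) abort("no informative PLS component")
  W <- W[, seq_len(n_components), drop = FALSE]
  SS <- SS[seq_len(n_components)]
  vip <- sqrt(P * drop(W^2 %*% SS) / sum(SS))
  structure(tibble(gene_id = colnames(X0) %||% paste0("x", seq_len(P)),
                   vip = vip, vip_flag = vip > 1),
            class = c("vip_result", "tbl_df", "tbl", "data.frame"),
            weights = W, scores = Tsc[, seq_len(n_components), drop = FALSE],
            ss = SS, n_components = n_components)
}

#' @export
glance.vip_result <- function(x, ...) {
  tibble(n_genes = nrow(x), n_components = attr(x, "n_components"),
         mean_vip_sq = mean(x$vip^2), n_vip = sum(x$vip_flag))
}

#' VIP scores for every module against every trait
#'
#' Runs [pls_vip()] per (module, trait) pair on the module's member genes.
#'
#' @param expr Gene x sample expression matrix.
#' @param assignment A `module_assignment`.
#' @param traits Trait tibble (`sample_id` + numeric columns).
#' @param n_components PLS components.
#' @return Tibble: `module`, `trait`, `gene_id`, `vip`, `vip_flag`.
#' @export
module_vip <- function(expr, assignment, traits, n_components = 2) {
  expr <- as_gene_matrix(expr)
  trait_names <- setdiff(names(traits), "sample_id")
  samples <- intersect(colnames(expr), traits$sample_id)
  tm <- traits[match(samples, traits$sample_id), ]
  mods <- sort(unique(assignment$module[assignment$module > 0]))
  tidyr::expand_grid(module = mods, trait = trait_names) |>
    purrr::pmap(function(module, trait) {
      genes <- assignment$gene_id[assignment$module == module]
      as_tibble(pls_vip(expr[genes, samples, drop = FALSE], tm[[trait]],
                        n_components)) |>
        mutate(module = module, trait = trait, .before = 1)
    }) |>
    purrr::list_rbind()
}

#' Classify DE genes into exclusive condition sets per module
#'
#' A gene "hits" a condition if it is differentially expressed (up or
#' down) at one or more time points of that condition. Its exclusive set
#' is exactly the set of conditions it hits (standard UpSet semantics), so
#' the sets partition the ever-DE genes. Counts are aggregated per
#' (exclusive set, module).
#'
#' @param de A `de_result` (or tibble with `gene_id`, `condition`,
#'   `status`).
#' @param condition_universe Conditions to consider (default: all in
#'   `de`).
#' @param assignment Optional `module_assignment` for per-module counts.
#' @param mode `"exclusive"` (default) or `"inclusive"` ("at least these
#'   conditions").
#' @return An object of class `upset_membership`: list with `membership`
#'   (tibble gene_id, set, n_conditions, module) and `counts` (tibble set,
#'   module, n).
#' @export
upset_classify <- function(de, condition_universe = NULL, assignment = NULL,
                           mode = c("exclusive", "inclusive")) {
  mode <- match.arg(mode)
  de <- as_tibble(de)
  if (is.null(condition_universe)) {
    condition_universe <- sort(unique(de$condition))
  }
  if (length(condition_universe) == 0) abort("empty condition universe")
  missing_cond <- setdiff(condition_universe, unique(de$condition))
  if (length(missing_cond) > 0) {
    abort(paste("DE results lack conditions:",
                paste(missing_cond, collapse = ", ")))
  }
  hits <- de |>
    filter(.data$condition %in% condition_universe, .data$status != "ns") |>
    distinct(.data$gene_id, .data$condition)
  membership <- hits |>
    group_by(.data$gene_id) |>
    summarise(
      set = paste(sort(unique(.data$condition)), collapse = "+"),
      n_conditions = n_distinct(.data$condition), .groups = "drop")
  if (!is.null(assignment)) {
    membership <- membership |>
      left_join(as_tibble(assignment) |> select("gene_id", "module"),
                by = "gene_id")
  } else {
    membership$module <- NA_integer_
  }
  counts <- if (mode == "exclusive") {
    membership |> count(.data$set, .data$module, name = "n")
  } else {
    # inclusive: a gene supports every subset of its hit set
    membership |>
      mutate(conds = strsplit(.data$set, "+", fixed = TRUE)) |>
      rowwise() |>
      mutate(subsets = list(.all_subsets(.data$conds))) |>
      ungroup() |>
      select("module", "subsets") |>
      tidyr::unnest("subsets") |>
      count(set = .data$subsets, .data$module, name = "n")
  }
  structure(list(membership = membership, counts = counts,
                 universe = condition_universe, mode = mode),
            class = "upset_membership")
}

.all_subsets <- function(x) {
  unlist(lapply(seq_along(x), function(k) {
    apply(utils::combn(x, k), 2, paste, collapse = "+")
  }))
}

#' @export
print.upset_membership <- function(x, ...) {
  cat(sprintf("UpSet classification (%s) over {%s}: %d ever-DE genes, %d sets\n",
              x$mode, paste(x$universe, collapse = ", "),
              nrow(x$membership), n_distinct(x$counts$set)))
  invisible(x)
}
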