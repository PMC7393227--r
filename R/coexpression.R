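#' Log-transformed normalised expression for network analysis
#'
#' `log2(count / size factor + 1)` per gene and sample; the input to the
#' co-expression network.
#'
#' @param counts A `count_matrix`.
#' @param sf Optional size factors.
#' @return Gene x sample numeric matrix.
#' @export
network_expression <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts$counts, 2, sf, `/`) + 1)
}

#' Soft-thresholded co-expression adjacency
#'
#' Pairwise Pearson correlations across samples, mapped to [0, 1] and
#' raised to the soft-threshold power `beta`. In `signed` mode (default)
#' `a_ij = ((1 + r_ij)/2)^beta`, so anti-correlated genes get near-zero
#' adjacency; in `unsigned` mode `a_ij = |r_ij|^beta`. `beta = 12` is the
#' conventional signed-network default chosen for scale-free topology fit.
#'
#' @param expr Gene x sample matrix (genes in rows).
#' @param beta Soft-threshold exponent (>= 1).
#' @param mode `"signed"` or `"unsigned"`.
#' @return An object of class `adjacency_matrix`: list with `a` (gene x
#'   gene, diagonal 1), `beta`, `mode`, `dropped` (zero-variance genes).
#' @export
soft_adjacency <- function(expr, beta = 12, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  assert_scalar_number(beta, "beta", lower = 1)
  expr <- as_gene_matrix(expr)
  if (ncol(expr) < 3) abort("need >= 3 samples")
  v <- apply(expr, 1, stats::var)
  dropped <- rownames(expr)[v == 0 | !is.finite(v)]
  if (length(dropped) > 0) {
    warn(sprintf("excluding %d zero-variance gene(s) from the network",
                 length(dropped)))
    expr <- expr[!(rownames(expr) %in% dropped), , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  a <- if (mode == "signed") ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 1
  structure(list(a = a, beta = beta, mode = mode, dropped = dropped),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("%s adjacency: %d genes, beta = %g\n", x$mode, nrow(x$a),
              x$beta))
  invisible(x)
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Computes per-gene connectivity `k_i = sum_{j != i} a_ij`, bins genes by
#' connectivity (10 bins), and regresses `log10(frequency)` on
#' `log10(mean k)` per bin. Returns the regression R-squared, negated when
#' the slope is positive (a scale-free network has a decreasing degree
#' distribution).
#'
#' @param adjacency An `adjacency_matrix`.
#' @param n_bins Number of connectivity bins (default 10).
#' @return A one-row tibble: `r_squared`, `slope`, `n_bins_used`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  a <- adjacency$a
  if (nrow(a) < 20) abort("need >= 20 genes for a degree-distribution fit")
  k <- colSums(a) - diag(a)
  if (diff(range(k)) < .Machine$double.eps^0.5) {
    abort("all connectivities identical: scale-free fit undefined")
  }
  bins <- cut(k, breaks = n_bins)
  df <- tibble(k = k, bin = bins) |>
    group_by(.data$bin) |>
    summarise(freq = n(), mean_k = mean(.data$k), .groups = "drop") |>
    filter(.data$freq > 0, .data$mean_k > 0)
  fit <- stats::lm(log10(freq) ~ log10(mean_k), data = df)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  tibble(r_squared = if (slope > 0) -r2 else r2, slope = slope,
         n_bins_used = nrow(df))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over shared neighbours; `TOM_ii = 1`.
#'
#' @param adjacency An `adjacency_matrix`.
#' @return Symmetric gene x gene matrix in [0, 1].
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency$a
  diag(a) <- 0
  L <- a %*% a
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules and submodules
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity (`1 - TOM`; plain `1 - a` available via `dist_method`),
#' with a static cut of the gene dendrogram at `tree_cut` of its maximum
#' merge height. Clusters smaller than `min_size` become the unassigned
#' "gray" module (label 0). When `expr` is supplied, modules whose
#' eigengenes are closer than `cut_height` (dissimilarity `1 - cor(ME)`,
#' the conventional 0.25 merge height) are merged iteratively. Submodules
#' come from re-clustering each module's genes at a finer cut (`sub_cut`
#' of the module subtree height). Every step is deterministic.
#'
#' @param adjacency An `adjacency_matrix`.
#' @param expr Optional gene x sample expression matrix enabling the
#'   eigengene-merge step.
#' @param min_size Minimum module size (default 30).
#' @param cut_height Eigengene-merge dissimilarity threshold (default
#'   0.25).
#' @param tree_cut Static gene-tree cut as a fraction of maximum merge
#'   height (default 0.95).
#' @param sub_cut Cut fraction for submodule detection within each module
#'   subtree (default 0.97).
#' @param min_sub Minimum submodule size (default 10); smaller subclusters
#'   collapse into submodule "m.0".
#' @param dist_method `"tom"` (default) or `"adjacency"`.
#' @return An object of class `module_assignment`: tibble with `gene_id`,
#'   `module` (integer, 0 = gray, labelled by decreasing size), and
#'   `submodule` (e.g. "1.2"; "0" for gray).
#' @export
detect_modules <- function(adjacency, expr = NULL, min_size = 30,
                           cut_height = 0.25, tree_cut = 0.95,
                           sub_cut = 0.97, min_sub = 10,
                           dist_method = c("tom", "adjacency")) {
  dist_method <- match.arg(dist_method)
  d <- if (dist_method == "tom") 1 - topological_overlap(adjacency) else
    1 - adjacency$a
  if (diff(range(d[upper.tri(d)])) < .Machine$double.eps^0.5) {
    abort("degenerate adjacency: all dissimilarities identical")
  }
  labels0 <- .static_cut(d, tree_cut)
  sizes <- table(labels0)
  keep <- names(sizes)[sizes >= min_size]
  keep <- keep[order(-sizes[keep])]
  module <- integer(length(labels0))
  for (i in seq_along(keep)) module[labels0 == keep[i]] <- i

  if (!is.null(expr) && length(keep) >= 2) {
    module <- .merge_close_modules(module, as_gene_matrix(expr), cut_height)
  }
  # relabel by decreasing size after merging
  ord <- order(-table(factor(module[module > 0])))
  mods_old <- sort(unique(module[module > 0]))[ord]
  module <- ifelse(module > 0, match(module, mods_old), 0L)

  gene_ids <- rownames(adjacency$a)
  submodule <- as.character(module)
  for (m in unique(module[module > 0])) {
    idx <- module == m
    if (sum(idx) >= 4) {
      sub <- .static_cut(d[idx, idx, drop = FALSE], sub_cut)
      tab <- table(sub)
      big <- names(tab)[tab >= min_sub]
      big <- big[order(-tab[big])]
      lab <- match(as.character(sub), big)  # NA for small subclusters
      lab[is.na(lab)] <- 0L
      submodule[idx] <- paste0(m, ".", lab)
    } else {
      submodule[idx] <- paste0(m, ".1")
    }
  }
  structure(tibble(gene_id = gene_ids, module = module,
                   submodule = submodule),
            class = c("module_assignment", "tbl_df", "tbl", "data.frame"),
            cut_height = cut_height, tree_cut = tree_cut,
            min_size = min_size, dist_method = dist_method)
}

.static_cut <- function(d, frac) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, h = frac * max(hc$height))
}

# iteratively merge the closest module pair while 1 - cor(ME) < threshold
.merge_close_modules <- function(module, expr, threshold) {
  repeat {
    mods <- sort(unique(module[module > 0]))
    if (length(mods) < 2) break
    me <- vapply(mods, function(m) {
      xs <- t(scale(t(expr[module == m, , drop = FALSE])))
      svd(xs[stats::complete.cases(xs), , drop = FALSE], nu = 0, nv = 1)$v[, 1]
    }, numeric(ncol(expr)))
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= threshold) break
    module[module == mods[top[2]]] <- mods[top[1]]
  }
  module
}

#' Module eigengenes
#'
#' The first principal component of each module's standardised member-gene
#' expression across samples, scaled to unit variance and sign-oriented so
#' that its mean correlation with the member genes is non-negative.
#'
#' @param expr Gene x sample matrix (the network input expression).
#' @param assignment A `module_assignment`.
#' @return A module x sample matrix, rownames `ME<module>`.
#' @export
module_eigengene <- function(expr, assignment) {
  expr <- as_gene_matrix(expr)
  mods <- sort(unique(assignment$module[assignment$module > 0]))
  if (length(mods) == 0) abort("no assigned modules")
  me <- vapply(mods, function(m) {
    genes <- assignment$gene_id[assignment$module == m]
    if (length(genes) < 2) abort(sprintf("module %s has < 2 genes", m))
    x <- expr[genes, , drop = FALSE]
    xs <- t(scale(t(x)))           # standardise each gene across samples
    xs <- xs[stats::complete.cases(xs), , drop = FALSE]
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    e <- e / stats::sd(e)
    if (mean(stats::cor(e, t(xs))) < 0) e <- -e
    e
  }, numeric(ncol(expr)))
  me <- t(me)
  dimnames(me) <- list(paste0("ME", mods), colnames(expr))
  me
}
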