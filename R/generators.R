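#' Simulate a read-count matrix from planted truth
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(planted log2FC) * exp(loading * latent factor) * size factor`
#' and variance `mu + alpha * mu^2`. The same seed always yields a
#' bit-identical matrix.
#'
#' @param design Design tibble from [generate_design()].
#' @param truth A `planted_truth` object whose dimensions match `design`.
#' @param seed Integer seed.
#' @return An object of class `count_matrix`: list with `counts` (integer
#'   gene x sample matrix) and `design`.
#' @export
generate_counts <- function(design, truth, seed = truth$seed) {
  if (!identical(design$sample_id, colnames(truth$latent_factors))) {
    abort("`design` samples do not match the truth's latent factor columns")
  }
  if (any(truth$nb_dispersion < 0)) abort("negative dispersion in truth")
  n_g <- length(truth$gene_ids)
  n_s <- nrow(design)

  lfc <- matrix(0, n_g, n_s,
                dimnames = list(truth$gene_ids, design$sample_id))
  if (nrow(truth$de_truth) > 0) {
    hit <- truth$de_truth |>
      inner_join(design |> select("sample_id", "condition", "time_h"),
                 by = c("condition", "time_h"), relationship = "many-to-many")
    lfc[cbind(hit$gene_id, hit$sample_id)] <- hit$log2fc
  }

  fac <- matrix(0, n_g, n_s)
  in_mod <- truth$module_labels > 0L
  fac[in_mod, ] <- truth$latent_factors[truth$module_labels[in_mod], ,
                                        drop = FALSE]
  mu <- truth$baseline_mean * 2^lfc * exp(truth$gene_loading * fac)
  mu <- sweep(mu, 2, truth$size_factors[design$sample_id], `*`)

  size <- 1 / pmax(truth$nb_dispersion, 1e-12)
  counts <- with_seed(split_seed(seed, "counts"), {
    k <- stats::rnbinom(n_g * n_s, mu = as.vector(mu), size = size)
    pois <- truth$nb_dispersion == 0
    if (any(pois)) {
      kp <- matrix(k, n_g, n_s)
      kp[pois, ] <- stats::rpois(sum(pois) * n_s,
                                 as.vector(mu[pois, , drop = FALSE]))
      k <- as.vector(kp)
    }
    matrix(as.integer(k), n_g, n_s,
           dimnames = list(truth$gene_ids, design$sample_id))
  })
  new_count_matrix(counts, design)
}

#' Construct a count matrix object
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param design Design tibble; `sample_id` must match the matrix columns.
#' @return A `count_matrix` object.
#' @export
new_count_matrix <- function(counts, design) {
  if (any(counts < 0)) abort("counts must be non-negative")
  if (!identical(colnames(counts), design$sample_id)) {
    abort("count matrix columns must match design sample_ids exactly")
  }
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  conditions:", paste(unique(x$design$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy.count_matrix
#' @export
tidy.count_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "count") |>
    left_join(x$design, by = "sample_id")
}

#' Tidy a count matrix into long form
#'
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return A long tibble with one row per (gene, sample) pair joined to the
#'   design.
#' @name tidy.count_matrix
NULL

#' Simulate per-sample phenotypic traits coupled to latent factors
#'
#' Each trait is a linear combination of the module latent factors
#' (`trait value = loadings %*% factors + noise`), so traits with a large
#' loading on a module are recoverably (anti)correlated with that module's
#' eigengene.
#'
#' @param design Design tibble.
#' @param truth A `planted_truth`.
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @return A tibble: `sample_id` plus one numeric column per trait.
#' @export
generate_traits <- function(design, truth, noise_sd = 0.3,
                            seed = truth$seed) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  L <- truth$trait_loadings
  if (ncol(L) != nrow(truth$latent_factors)) {
    abort("trait loadings do not match the number of modules")
  }
  vals <- L %*% truth$latent_factors[, design$sample_id, drop = FALSE]
  noise <- with_seed(split_seed(seed, "traits"), {
    matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals))
  })
  t(vals + noise) |>
    as_tibble(rownames = "sample_id")
}

#' Simulate a genome-ordered gene annotation
#'
#' Genes are laid out on a single circular-chromosome-style sequence in
#' genome order with non-overlapping 1-based inclusive coordinates (GFF3
#' convention) and a 0-based `genome_index`. Planted cyanoron members are
#' genomically adjacent by construction. Operons are emitted for every
#' planted run plus random short runs.
#'
#' @param n_genes Number of genes; must cover the largest planted run.
#' @param truth A `planted_truth` (for planted runs), or `NULL`.
#' @param seed Integer seed.
#' @return A list with `genes` (tibble: gene_id, seqid, start, end, strand,
#'   genome_index) and `operons` (tibble: operon_id, gene_id).
#' @export
generate_annotation <- function(n_genes = 2634, truth = NULL, seed = 1L) {
  if (!is.null(truth)) {
    if (n_genes < length(truth$gene_ids)) {
      abort("`n_genes` smaller than the truth requires")
    }
    if (nrow(truth$cyanoron_truth) > 0 &&
        n_genes < max(truth$cyanoron_truth$end_index) + 1) {
      abort("`n_genes` smaller than the largest planted run end")
    }
  }
  gene_ids <- if (!is.null(truth)) truth$gene_ids else
    sprintf("g%04d", seq_len(n_genes))
  with_seed(split_seed(seed, "annotation"), {
    len <- as.integer(round(stats::rlnorm(n_genes, log(800), 0.35)))
    gap <- as.integer(round(stats::rlnorm(n_genes, log(120), 0.8)))
    start <- as.integer(cumsum(c(1L, (len + gap)[-n_genes])))
    genes <- tibble(
      gene_id = gene_ids,
      seqid = "chr",
      start = start,
      end = start + len - 1L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      genome_index = seq_len(n_genes) - 1L
    )
    operons <- .make_operons(genes, truth)
    list(genes = genes, operons = operons)
  })
}

.make_operons <- function(genes, truth) {
  runs <- list()
  if (!is.null(truth) && nrow(truth$cyanoron_truth) > 0) {
    runs <- purrr::pmap(truth$cyanoron_truth, function(start_index, end_index,
                                                       ...) {
      genes$gene_id[(start_index + 1):(end_index + 1)]
    })
  }
  n_rand <- 20
  occupied <- unlist(runs)
  for (i in seq_len(n_rand)) {
    len <- sample(2:5, 1)
    s <- sample.int(nrow(genes) - len + 1, 1)
    ids <- genes$gene_id[s:(s + len - 1)]
    if (!any(ids %in% occupied)) {
      runs <- c(runs, list(ids))
      occupied <- c(occupied, ids)
    }
  }
  if (length(runs) == 0) {
    return(tibble(operon_id = character(), gene_id = character()))
  }
  purrr::imap(runs, function(ids, i) {
    tibble(operon_id = sprintf("op%03d", i), gene_id = ids)
  }) |> purrr::list_rbind()
}

#' Simulate paired fluorescence-decay kinetics
#'
#' Emulates a photoinhibition assay: the control culture's PSII quantum
#' yield decays with net coefficient `k_decay` (damage partly offset by
#' repair), while the translation-inhibitor-treated culture decays with
#' coefficient `k_decay + k_repair` because repair requires protein
#' synthesis. The difference of fitted decay coefficients therefore
#' estimates the repair rate. Gaussian noise is added, then values are
#' clipped to [0, 1].
#'
#' @param k_decay,k_repair Decay/repair coefficients (per hour, >= 0).
#' @param y0 Initial quantum yield in (0, 1].
#' @param times Sampling times (hours), strictly increasing.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @return A list of two tibbles, `control` and `inhibited`, each with
#'   columns `time_h`, `value`, `inhibitor`.
#' @export
generate_kinetics <- function(k_decay, k_repair, y0 = 0.6,
                              times = c(0, 0.3, 1, 2, 3, 4.5, 6),
                              noise_sd = 0, seed = 1L) {
  stopifnot(k_decay >= 0, k_repair >= 0, y0 > 0, y0 <= 1)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (length(times) == 0) abort("`times` must be non-empty")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  mk <- function(k, flag, sub) {
    mu <- y0 * exp(-k * times)
    val <- with_seed(split_seed(seed, paste0("kinetics_", sub)), {
      mu + stats::rnorm(length(times), 0, noise_sd)
    })
    tibble(time_h = times, value = pmin(1, pmax(0, val)), inhibitor = flag)
  }
  list(control = mk(k_decay, FALSE, "ctl"),
       inhibited = mk(k_decay + k_repair, TRUE, "inh"))
}

#' Simulate a phycobilisome fluorescence emission spectrum
#'
#' A sum of Gaussian peaks for phycoerythrin (570 nm), phycocyanin
#' (650 nm) and the terminal acceptor (680 nm) on a wavelength grid
#' covering 545-750 nm, the range scanned upon phycoerythrobilin
#' excitation.
#'
#' @param heights Peak heights at 570, 650 and 680 nm (length 3, >= 0).
#' @param widths Gaussian SDs in nm (length 3).
#' @param grid Wavelength grid (nm).
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return A tibble with `wavelength_nm` and `intensity`.
#' @export
generate_spectrum <- function(heights = c(2, 1, 1),
                              widths = c(8, 6, 5),
                              grid = seq(545, 750, by = 1),
                              noise_sd = 0, seed = 1L) {
  stopifnot(length(heights) == 3, length(widths) == 3)
  if (any(heights < 0)) abort("`heights` must be >= 0")
  centers <- c(570, 650, 680)
  windows <- list(c(565, 575), c(645, 655), c(675, 685))
  for (w in windows) {
    if (min(grid) > w[1] || max(grid) < w[2]) {
      abort("wavelength grid does not cover the peak windows")
    }
  }
  intensity <- rowSums(vapply(1:3, function(i) {
    heights[i] * exp(-(grid - centers[i])^2 / (2 * widths[i]^2))
  }, numeric(length(grid))))
  if (noise_sd > 0) {
    intensity <- intensity + with_seed(split_seed(seed, "spectrum"), {
      stats::rnorm(length(grid), 0, noise_sd)
    })
  }
  tibble(wavelength_nm = grid, intensity = pmax(0, intensity))
}
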