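#' Default per-sample trait loading matrix
#'
#' Rows are the phenotypic traits the trait generator emulates (PSII quantum
#' yield as percent of T0, phycobilisome emission ratios, carotenoid to
#' chlorophyll ratios, temperature, membrane-lipid chain length and
#' unsaturation, cell-density change); columns are co-expression modules.
#' Each trait loads strongly (|loading| = 1.2) on one module and weakly on
#' the others, so module-trait correlations are recoverable but not trivial.
#'
#' @param n_modules Number of latent modules.
#' @param seed Integer seed for the weak cross-loadings.
#' @return A numeric matrix traits x modules with dimnames.
#' @export
default_trait_loadings <- function(n_modules = 3, seed = 1L) {
  traits <- c("fvfm_pct", "pe_pc", "pc_ta", "zea_chl", "bcar_chl",
              "bcrypto_chl", "temperature", "chain_length", "unsaturation",
              "cell_density")
  with_seed(split_seed(seed, "trait_loadings"), {
    L <- matrix(stats::rnorm(length(traits) * n_modules, 0, 0.1),
                nrow = length(traits),
                dimnames = list(traits, paste0("ME", seq_len(n_modules))))
    for (i in seq_along(traits)) {
      m <- (i - 1L) %% n_modules + 1L
      L[i, m] <- 1.2 * sign(stats::rnorm(1))
    }
    L
  })
}

#' Plant the generative ground truth for a synthetic experiment
#'
#' Draws everything the downstream analyses are later asked to recover:
#' module labels (0 = unassigned/"gray"), per-module latent factors that are
#' smooth in time (AR(1) within each condition), planted per-(gene,
#' condition, time) log2 fold changes, trait loadings, genomically adjacent
#' co-expressed runs ("cyanorons"), per-gene negative-binomial dispersions
#' and baseline means, and per-sample library-size factors.
#'
#' @param design Design tibble from [generate_design()].
#' @param n_genes Number of genes (default 2634, a picocyanobacterial
#'   genome-scale gene count).
#' @param n_modules Number of latent co-expression modules.
#' @param module_frac Fraction of genes assigned to modules (rest gray).
#' @param frac_de Fraction of genes planted as differentially expressed per
#'   condition.
#' @param n_cyanorons Number of planted adjacent co-expressed runs.
#' @param factor_sd Standard deviation of the latent factors (natural-log
#'   expression scale).
#' @param ar_rho AR(1) autocorrelation of latent factors along time.
#' @param trait_loadings Trait x module loading matrix.
#' @param seed Integer master seed.
#' @return An object of class `planted_truth`: a list with elements
#'   `gene_ids`, `module_labels`, `gene_loading`, `latent_factors`
#'   (module x sample), `de_truth` (tibble gene_id/condition/time_h/log2fc),
#'   `trait_loadings`, `cyanoron_truth`, `nb_dispersion`, `baseline_mean`,
#'   `size_factors`, and the `design`.
#' @export
simulate_truth <- function(design,
                           n_genes = 2634,
                           n_modules = 3,
                           module_frac = 0.6,
                           frac_de = 0.12,
                           n_cyanorons = 5,
                           factor_sd = 0.7,
                           ar_rho = 0.7,
                           trait_loadings = default_trait_loadings(n_modules, seed),
                           seed = 1L) {
  stopifnot(n_genes >= 1, n_modules >= 1)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))

  module_labels <- with_seed(split_seed(seed, "modules"), {
    sample(c(rep(0L, round(n_genes * (1 - module_frac))),
             rep(seq_len(n_modules),
                 length.out = n_genes - round(n_genes * (1 - module_frac)))))
  })
  names(module_labels) <- gene_ids

  gene_loading <- with_seed(split_seed(seed, "loadings"), {
    stats::runif(n_genes, 0.8, 1.2)
  })
  gene_loading[module_labels == 0L] <- 0
  names(gene_loading) <- gene_ids

  latent_factors <- .simulate_latent_factors(design, n_modules, factor_sd,
                                             ar_rho,
                                             split_seed(seed, "factors"))

  contrasts <- design_contrasts(design)
  de_truth <- .plant_de_truth(gene_ids, contrasts, frac_de,
                              split_seed(seed, "de"))

  cy <- .plant_cyanorons(gene_ids, module_labels, contrasts, n_cyanorons,
                         split_seed(seed, "cyanorons"))
  module_labels <- cy$module_labels
  gene_loading[module_labels > 0 & gene_loading == 0] <-
    with_seed(split_seed(seed, "loadfill"),
              stats::runif(sum(module_labels > 0 & gene_loading == 0), 0.8, 1.2))
  # planted runs override any fold change planted independently
  de_truth <- bind_rows(
    anti_join(de_truth, cy$de, by = c("gene_id", "condition", "time_h")),
    cy$de
  )

  disp_base <- with_seed(split_seed(seed, "dispersion"), {
    exp(stats::runif(n_genes, log(0.01), log(0.5)))
  })
  base_mean <- with_seed(split_seed(seed, "baseline"), {
    pmax(5, stats::rlnorm(n_genes, meanlog = log(150), sdlog = 1))
  })
  sf <- with_seed(split_seed(seed, "sizefactors"), {
    stats::rlnorm(nrow(design), 0, 0.15)
  })
  names(sf) <- design$sample_id
  names(disp_base) <- names(base_mean) <- gene_ids

  structure(list(
    gene_ids = gene_ids,
    module_labels = module_labels,
    gene_loading = gene_loading,
    latent_factors = latent_factors,
    de_truth = de_truth,
    trait_loadings = trait_loadings,
    cyanoron_truth = cy$truth,
    nb_dispersion = disp_base,
    baseline_mean = base_mean,
    size_factors = sf,
    design = design,
    seed = as.integer(seed)
  ), class = "planted_truth")
}

# AR(1) latent factors per module: one value per (condition, time), shared
# by replicates (the factor is a property of the culture state, not the
# aliquot), centred to zero mean per module across samples.
.simulate_latent_factors <- function(design, n_modules, factor_sd, ar_rho,
                                     seed) {
  states <- design |>
    distinct(.data$condition, .data$time_h) |>
    arrange(.data$condition, .data$time_h)
  with_seed(seed, {
    F <- matrix(0, n_modules, nrow(states))
    for (m in seq_len(n_modules)) {
      for (cond in unique(states$condition)) {
        idx <- which(states$condition == cond)
        n_t <- length(idx)
        z <- stats::rnorm(n_t)
        x <- numeric(n_t)
        x[1] <- z[1]
        for (t in seq_len(n_t)[-1]) {
          x[t] <- ar_rho * x[t - 1] + sqrt(1 - ar_rho^2) * z[t]
        }
        F[m, idx] <- factor_sd * x
      }
    }
    key <- paste(states$condition, states$time_h)
    out <- F[, match(paste(design$condition, design$time_h), key),
             drop = FALSE]
    out <- out - rowMeans(out)
    dimnames(out) <- list(paste0("ME", seq_len(n_modules)), design$sample_id)
    out
  })
}

.plant_de_truth <- function(gene_ids, contrasts, frac_de, seed) {
  empty <- tibble(gene_id = character(), condition = character(),
                  time_h = numeric(), log2fc = numeric())
  if (frac_de <= 0 || nrow(contrasts) == 0) return(empty)
  with_seed(seed, {
    purrr::map(unique(contrasts$condition), function(cond) {
      times <- sort(unique(contrasts$time_h[contrasts$condition == cond]))
      n_de <- round(length(gene_ids) * frac_de)
      if (n_de == 0) return(NULL)
      genes <- sample(gene_ids, n_de)
      lfc <- stats::runif(n_de, 1, 3) * sample(c(-1, 1), n_de, replace = TRUE)
      # effect switches on at a random onset time and persists
      onset <- sample(seq_along(times), n_de, replace = TRUE,
                      prob = rev(seq_along(times))) # earlier onsets likelier
      purrr::map(seq_len(n_de), function(i) {
        tibble(gene_id = genes[i], condition = cond,
               time_h = times[onset[i]:length(times)], log2fc = lfc[i])
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
}

.plant_cyanorons <- function(gene_ids, module_labels, contrasts, n_cyanorons,
                             seed) {
  n_genes <- length(gene_ids)
  truth <- tibble(start_index = integer(), end_index = integer(),
                  module = integer(), condition = character(),
                  direction = character())
  de <- tibble(gene_id = character(), condition = character(),
               time_h = numeric(), log2fc = numeric())
  if (n_cyanorons == 0) {
    return(list(truth = truth, de = de, module_labels = module_labels))
  }
  conds <- unique(contrasts$condition)
  with_seed(seed, {
    occupied <- rep(FALSE, n_genes)
    for (k in seq_len(n_cyanorons)) {
      len <- sample(4:8, 1)
      for (try in 1:200) {
        s <- sample.int(n_genes - len + 1, 1)
        span <- s:(s + len - 1)
        # keep a one-gene buffer so planted runs stay maximal and separate
        lo <- max(1, s - 1); hi <- min(n_genes, s + len)
        if (!any(occupied[lo:hi])) break
        span <- NULL
      }
      if (is.null(span)) next
      occupied[span] <- TRUE
      mod <- sample(max(module_labels), 1)
      module_labels[span] <- mod
      # neighbours must not extend the run within the same module
      if (s > 1 && module_labels[s - 1] == mod) module_labels[s - 1] <- 0L
      if (s + len <= n_genes && module_labels[s + len] == mod) {
        module_labels[s + len] <- 0L
      }
      cond <- sample(conds, 1)
      dirn <- sample(c(-1, 1), 1)
      times <- sort(unique(contrasts$time_h[contrasts$condition == cond]))
      de <- bind_rows(de, tidyr::expand_grid(
        gene_id = gene_ids[span], time_h = times) |>
          mutate(condition = cond, log2fc = dirn * 2))
      truth <- bind_rows(truth, tibble(
        start_index = s - 1L, end_index = s + len - 2L, module = mod,
        condition = cond, direction = if (dirn > 0) "up" else "down"))
    }
  })
  list(truth = truth, de = de, module_labels = module_labels)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("Planted ground truth\n")
  cat("  genes:", length(x$gene_ids),
      " modules:", nrow(x$latent_factors),
      " gray genes:", sum(x$module_labels == 0L), "\n")
  cat("  planted DE entries:", nrow(x$de_truth),
      " cyanorons:", nrow(x$cyanoron_truth), "\n")
  cat("  samples:", nrow(x$design), "\n")
  invisible(x)
}

#' Query the planted log2 fold change for genes at a contrast
#'
#' @param truth A `planted_truth` object.
#' @param condition,time_h Contrast coordinates.
#' @return Named numeric vector over all genes (0 where no effect planted).
#' @export
planted_lfc <- function(truth, condition, time_h) {
  out <- stats::setNames(numeric(length(truth$gene_ids)), truth$gene_ids)
  hit <- truth$de_truth |>
    filter(.data$condition == !!condition, .data$time_h == !!time_h)
  out[hit$gene_id] <- hit$log2fc
  out
}
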