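#' Default pipeline configuration
#'
#' A complete, documented configuration for an end-to-end synthetic run.
#' Parameter defaults are the analysis defaults used throughout the
#' package: DE at BH-adjusted p <= 0.05 and |log2FC| >= 1; a signed
#' network at soft threshold 12 with a static tree cut at 0.25 and minimum
#' module size 30; 2 PLS components; cyanoron runs of >= 4 genes at
#' |log2FC| > 1.
#'
#' @param outdir Output directory.
#' @param seed Master seed; every stage draws from a stream derived from
#'   it.
#' @return A named list (class `pipeline_config`), serialisable to YAML
#'   with [write_config()].
#' @export
default_pipeline_config <- function(outdir = tempfile("stresscape_"),
                                    seed = 1L) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, de = TRUE, network = TRUE,
                  integrate = TRUE, cyanorons = TRUE, physiology = TRUE),
    simulate = list(n_genes = 2634, n_modules = 3, module_frac = 0.6,
                    frac_de = 0.12, n_cyanorons = 5, factor_sd = 0.7,
                    ar_rho = 0.7, trait_noise_sd = 0.3, share_t0 = TRUE),
    de = list(alpha = 0.05, lfc_min = 1),
    network = list(beta = 12, mode = "signed", cut_height = 0.25,
                   min_size = 30, dist_method = "tom"),
    integrate = list(n_components = 2, p_threshold = 1e-3, adjust = "BH"),
    cyanorons = list(min_run = 4, lfc = 1),
    physiology = list(k_decay = 0.2, k_repair = 0.3, y0 = 0.6,
                      noise_sd = 0.02)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config A `pipeline_config` list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, as toggled in the configuration: synthetic-data generation,
#' differential expression, co-expression network and module detection,
#' module-trait integration (correlations, PLS VIP, exclusive DE sets),
#' cyanoron detection, and the physiology calculators. All outputs are
#' written under `config$outdir`; a JSON manifest records parameters, the
#' seed, and an MD5 hash of every output so a rerun with the same
#' configuration can be verified bit-identical.
#'
#' @param config A `pipeline_config` from [default_pipeline_config()] or
#'   [read_config()].
#' @return The manifest, invisibly (list with `params`, `seed`, `files`).
#' @export
run_all <- function(config = default_pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  out <- function(f) file.path(config$outdir, f)
  st <- config$stages
  results <- list()

  if (isTRUE(st$simulate)) {
    sim <- config$simulate
    design <- generate_design(share_t0 = isTRUE(sim$share_t0))
    truth <- simulate_truth(design, n_genes = sim$n_genes,
                            n_modules = sim$n_modules,
                            module_frac = sim$module_frac,
                            frac_de = sim$frac_de,
                            n_cyanorons = sim$n_cyanorons,
                            factor_sd = sim$factor_sd, ar_rho = sim$ar_rho,
                            seed = seed)
    counts <- generate_counts(design, truth, seed = seed)
    traits <- generate_traits(design, truth, noise_sd = sim$trait_noise_sd,
                              seed = seed)
    anno <- generate_annotation(sim$n_genes, truth, seed = seed)
    write_design_csv(design, out("design.csv"), seed)
    write_counts_tsv(counts, out("counts.tsv"), seed)
    write_traits_csv(traits, out("traits.csv"), seed)
    write_gff3(anno, out("annotation.gff3"))
    write_operons_tsv(anno$operons, out("operons.tsv"))
    write_truth_json(truth, out("truth.json"))
    results <- c(results, list(design = design, truth = truth,
                               counts = counts, traits = traits,
                               annotation = anno))
  } else {
    if (is.null(config$inputs$counts) || !file.exists(config$inputs$counts)) {
      abort(sprintf("simulation disabled and counts input missing: %s",
                    config$inputs$counts %||% "<unset>"))
    }
    design <- read_design_csv(config$inputs$design)
    counts <- read_counts_tsv(config$inputs$counts, design)
    traits <- read_traits_csv(config$inputs$traits)
    anno <- list(genes = read_gff3(config$inputs$gff3),
                 operons = read_operons_tsv(config$inputs$operons))
    results <- c(results, list(design = design, counts = counts,
                               traits = traits, annotation = anno))
  }

  if (isTRUE(st$de)) {
    de <- run_de(counts, alpha = config$de$alpha,
                 lfc_min = config$de$lfc_min)
    .write_with_header(as_tibble(de), out("de_results.tsv"), "de",
                       config$de, seed)
    .write_with_header(de_summary(de), out("de_summary.tsv"), "de",
                       config$de, seed)
    results$de <- de
  }

  if (isTRUE(st$network)) {
    nw <- config$network
    expr <- network_expression(counts)
    adj <- soft_adjacency(expr, beta = nw$beta, mode = nw$mode)
    fit <- scale_free_fit(adj)
    assignment <- detect_modules(adj, expr = expr, min_size = nw$min_size,
                                 cut_height = nw$cut_height,
                                 dist_method = nw$dist_method)
    me <- module_eigengene(expr, assignment)
    .write_with_header(as_tibble(assignment), out("modules.tsv"),
                       "network", nw[c("beta", "mode", "cut_height")], seed)
    .write_with_header(as_tibble(me, rownames = "module"),
                       out("eigengenes.csv"), "network", delim = ",",
                       seed = seed)
    jsonlite::write_json(as.list(fit), out("scale_free_fit.json"),
                         digits = NA, auto_unbox = TRUE)
    results <- c(results, list(expr = expr, adjacency = adj,
                               scale_free = fit, assignment = assignment,
                               eigengenes = me))
  }

  if (isTRUE(st$integrate)) {
    ig <- config$integrate
    mtc <- module_trait_corr(results$eigengenes, traits,
                             p_threshold = ig$p_threshold,
                             adjust = ig$adjust)
    vip <- module_vip(results$expr, results$assignment, traits,
                      n_components = ig$n_components)
    ups <- upset_classify(results$de, assignment = results$assignment)
    .write_with_header(as_tibble(mtc), out("module_trait.csv"),
                       "integrate", ig, seed, delim = ",")
    .write_with_header(vip, out("vip.tsv"), "integrate", ig, seed)
    .write_with_header(ups$counts, out("upset_counts.tsv"), "integrate",
                       ig, seed)
    results <- c(results, list(module_trait = mtc, vip = vip, upset = ups))
  }

  if (isTRUE(st$cyanorons)) {
    cy <- config$cyanorons
    calls <- find_cyanorons(results$annotation, results$assignment,
                            results$de, min_run = cy$min_run, lfc = cy$lfc)
    flat <- as_tibble(calls) |>
      mutate(gene_ids = purrr::map_chr(.data$gene_ids, paste, collapse = ","),
             support_times = purrr::map_chr(.data$support_times, paste,
                                            collapse = ","),
             directions = purrr::map_chr(.data$directions, paste,
                                         collapse = ","))
    .write_with_header(flat, out("cyanorons.tsv"), "cyanorons", cy, seed)
    if (nrow(calls) > 0) {
      write_cyanoron_bed(calls, results$annotation, out("cyanorons.bed"))
    }
    results$cyanorons <- calls
  }

  if (isTRUE(st$physiology)) {
    ph <- config$physiology
    kin <- generate_kinetics(ph$k_decay, ph$k_repair, ph$y0,
                             noise_sd = ph$noise_sd,
                             seed = split_seed(seed, "physiology"))
    rr <- repair_rate_short(kin$control, kin$inhibited)
    spec <- generate_spectrum()
    ratios <- spectrum_ratios(spec$wavelength_nm, spec$intensity)
    .write_with_header(bind_rows(kin), out("kinetics.csv"), "physiology",
                       ph, seed, delim = ",")
    .write_with_header(spec, out("spectrum.csv"), "physiology", ph, seed,
                       delim = ",")
    .write_with_header(bind_cols(tidy(rr) |>
                                   tidyr::pivot_wider(names_from = "term",
                                                      values_from = "estimate"),
                                 ratios),
                       out("physiology_summary.csv"), "physiology", ph,
                       seed, delim = ",")
    results <- c(results, list(kinetics = kin, repair = rr,
                               spectrum_ratios = ratios))
  }

  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("stresscape")),
    seed = seed,
    params = unclass(config)[setdiff(names(config), c("outdir"))],
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
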