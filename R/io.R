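# File formats. Every writer prepends '#'-comment header lines recording
# the producing stage, parameters and seed; readers skip them.

.header_lines <- function(stage, params = list(), seed = NULL) {
  p <- if (length(params)) {
    paste(names(params), unlist(params), sep = "=", collapse = " ")
  } else ""
  c(sprintf("# stresscape stage=%s %s", stage, p),
    if (!is.null(seed)) sprintf("# seed=%s", seed))
}

.write_with_header <- function(df, path, stage, params = list(), seed = NULL,
                               delim = "\t") {
  writeLines(.header_lines(stage, params, seed), path)
  readr::write_delim(df, path, delim = delim, append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' Write / read a count matrix as TSV
#'
#' Genes x samples with a `gene_id` first column and a header row of
#' sample ids. The reader validates that all counts are non-negative
#' integers and reports the first offending line.
#'
#' @param counts A `count_matrix`.
#' @param path File path.
#' @param seed Seed recorded in the file header.
#' @return `write_counts_tsv`: the path, invisibly. `read_counts_tsv`: a
#'   `count_matrix` when a design is supplied, else the count matrix.
#' @export
write_counts_tsv <- function(counts, path, seed = NULL) {
  df <- as_tibble(counts$counts, rownames = "gene_id")
  .write_with_header(df, path, "simulate", list(n_genes = nrow(counts$counts)),
                     seed)
}

#' @rdname write_counts_tsv
#' @param design Optional design tibble to attach.
#' @export
read_counts_tsv <- function(path, design = NULL) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene_id
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("invalid count at data line %d (gene %s): %s",
                  bad[1, 1], rownames(m)[bad[1, 1]], m[bad[1, , drop = FALSE]]))
  }
  storage.mode(m) <- "integer"
  if (!is.null(design)) new_count_matrix(m, design) else m
}

#' Write / read the sample design as CSV
#' @param design Design tibble.
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @return The path / the design tibble.
#' @export
write_design_csv <- function(design, path, seed = NULL) {
  .write_with_header(design, path, "simulate", seed = seed, delim = ",")
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", acclimation = "c", condition = "c",
                    time_h = "d", replicate = "i", kind = "c",
                    is_reference = "l"))
}

#' Write / read the trait table as CSV
#' @param traits Trait tibble (`sample_id` + numeric columns).
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @export
write_traits_csv <- function(traits, path, seed = NULL) {
  .write_with_header(traits, path, "simulate", seed = seed, delim = ",")
}

#' @rdname write_traits_csv
#' @export
read_traits_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write / read a gene annotation as GFF3
#'
#' Coordinates are 1-based inclusive per the GFF3 convention; the 0-based
#' `genome_index` rank travels in the attributes column.
#'
#' @param annotation Annotation list (or its `genes` tibble).
#' @param path File path.
#' @return The path / an annotation `genes` tibble sorted by genome index.
#' @export
write_gff3 <- function(annotation, path) {
  genes <- if (is.data.frame(annotation)) annotation else annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seqid,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$genome_index <- genes$genome_index
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    gene_id = gr$ID,
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    genome_index = as.integer(gr$genome_index)
  ) |>
    arrange(.data$genome_index)
}

#' Write / read operon membership as TSV
#' @param operons Tibble `operon_id`, `gene_id`.
#' @param path File path.
#' @export
write_operons_tsv <- function(operons, path) {
  .write_with_header(operons, path, "simulate")
}

#' @rdname write_operons_tsv
#' @export
read_operons_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Serialise planted truth to JSON
#' @param truth A `planted_truth`.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  x <- list(
    gene_ids = truth$gene_ids,
    module_labels = unname(truth$module_labels),
    gene_loading = unname(truth$gene_loading),
    latent_factors = truth$latent_factors,
    de_truth = truth$de_truth,
    trait_loadings = truth$trait_loadings,
    cyanoron_truth = truth$cyanoron_truth,
    nb_dispersion = unname(truth$nb_dispersion),
    baseline_mean = unname(truth$baseline_mean),
    size_factors = unname(truth$size_factors),
    seed = truth$seed
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fluorescence time series from CSV
#'
#' Expected columns: `time_h`, `value`, optional `replicate` and
#' `inhibitor` (logical). Returns the control and inhibited arms split
#' apart when an `inhibitor` column is present.
#'
#' @param path CSV file; '#' comment lines are skipped.
#' @return A tibble, or a list with `control` and `inhibited` tibbles.
#' @export
read_kinetics_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  for (col in c("time_h", "value")) {
    if (!col %in% names(df)) abort(sprintf("missing column `%s`", col))
  }
  if (any(df$value < 0 | df$value > 1)) {
    abort("quantum-yield values must lie in [0, 1]")
  }
  if ("inhibitor" %in% names(df)) {
    list(control = filter(df, !.data$inhibitor),
         inhibited = filter(df, .data$inhibitor))
  } else {
    df
  }
}

#' Read an emission spectrum from CSV
#'
#' Expected columns: `wavelength_nm`, `intensity`.
#'
#' @param path CSV file; '#' comment lines are skipped.
#' @return A tibble sorted by wavelength.
#' @export
read_spectrum_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  for (col in c("wavelength_nm", "intensity")) {
    if (!col %in% names(df)) abort(sprintf("missing column `%s`", col))
  }
  arrange(df, .data$wavelength_nm)
}
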