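#' Detect cyanorons: adjacent co-expressed gene runs
#'
#' A cyanoron is a maximal run of at least `min_run` genomically adjacent
#' genes (consecutive genome indices, strand ignored) that share a
#' co-expression module label and respond concordantly to a stress: a time
#' point supports the run when every member gene has `log2FC > lfc` at
#' that time, or every member has `log2FC < -lfc`. A run is called for a
#' stress when supporting time points number at least half of the stress's
#' time points (rounded up). Unassigned ("gray", module 0) genes never
#' form runs. Maximal runs only are reported; sub-runs are not emitted
#' separately.
#'
#' @param annotation Annotation list from [generate_annotation()] (or a
#'   tibble with `gene_id`, `genome_index`, and optionally `start`, `end`,
#'   `seqid`, `strand`).
#' @param assignment A `module_assignment` (tibble `gene_id`, `module`).
#' @param lfc_table Tibble with `gene_id`, `condition`, `time_h`,
#'   `log2fc` for every stress time point (e.g. a `de_result`).
#' @param min_run Minimum run length (default 4).
#' @param lfc Concordance threshold on |log2FC| (default 1).
#' @return An object of class `cyanoron_calls`: tibble with `condition`,
#'   `module`, `start_index`, `end_index`, `length`, `gene_ids`
#'   (list-column), `n_support`, `n_timepoints`, `support_times`
#'   (list-column), `directions` (list-column, per supporting time point).
#' @export
find_cyanorons <- function(annotation, assignment, lfc_table, min_run = 4,
                           lfc = 1) {
  genes <- if (is.data.frame(annotation)) annotation else annotation$genes
  if (is.unsorted(genes$genome_index)) {
    abort("annotation must be sorted by genome_index")
  }
  lfc_table <- as_tibble(lfc_table)
  missing <- setdiff(genes$gene_id, unique(lfc_table$gene_id))
  if (length(missing) > 0) {
    abort(sprintf("log2FC missing for %d annotated gene(s), e.g. %s",
                  length(missing), missing[1]))
  }
  mod <- as_tibble(assignment)
  module <- mod$module[match(genes$gene_id, mod$gene_id)]
  module[is.na(module)] <- 0L

  # maximal same-module runs partition the genome ordering
  runs <- .module_runs(module, min_run)
  conds <- sort(unique(lfc_table$condition))
  out <- purrr::map(conds, function(cond) {
    sub <- lfc_table |> filter(.data$condition == cond)
    times <- sort(unique(sub$time_h))
    need <- ceiling(length(times) / 2)
    lfc_m <- matrix(NA_real_, nrow(genes), length(times),
                    dimnames = list(genes$gene_id, as.character(times)))
    lfc_m[cbind(sub$gene_id, as.character(sub$time_h))] <- sub$log2fc
    purrr::pmap(runs, function(s, e, m) {
      block <- lfc_m[s:e, , drop = FALSE]
      if (anyNA(block)) {
        abort("log2FC missing for a gene/time combination in a run")
      }
      up <- apply(block > lfc, 2, all)
      down <- apply(block < -lfc, 2, all)
      supp <- up | down
      if (sum(supp) < need) return(NULL)
      tibble(condition = cond, module = m,
             start_index = genes$genome_index[s],
             end_index = genes$genome_index[e],
             length = e - s + 1L,
             gene_ids = list(genes$gene_id[s:e]),
             n_support = sum(supp), n_timepoints = length(times),
             support_times = list(times[supp]),
             directions = list(unname(ifelse(up[supp], "up", "down"))))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(condition = character(), module = integer(),
                  start_index = integer(), end_index = integer(),
                  length = integer(), gene_ids = list(),
                  n_support = integer(), n_timepoints = integer(),
                  support_times = list(), directions = list())
  }
  structure(out, class = c("cyanoron_calls", class(out)),
            min_run = min_run, lfc = lfc)
}

# maximal runs of identical nonzero module label, length >= min_run
.module_runs <- function(module, min_run) {
  r <- rle(module)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0 & r$lengths >= min_run
  tibble(s = starts[keep], e = ends[keep], m = r$values[keep])
}

#' Expected cyanoron false-call rate under a null model
#'
#' Simulates genomes with permuted module labels and independent Gaussian
#' log2 fold changes (no planted runs) and counts cyanoron calls, to
#' contextualise observed counts.
#'
#' @param n_genes Genome size.
#' @param module_sizes Integer vector of module sizes to permute over the
#'   genome (rest gray).
#' @param conditions Condition labels.
#' @param times Time points per condition.
#' @param lfc_sd SD of the null log2FC draws (default 0.5).
#' @param min_run,lfc Detection parameters.
#' @param n_sims Number of simulations (>= 1).
#' @param seed Integer seed.
#' @return A one-row tibble: `mean_calls`, `sd_calls`, `n_sims`.
#' @export
cyanoron_null_rate <- function(n_genes = 2634,
                               module_sizes = c(500, 500, 500),
                               conditions = "S1",
                               times = c(1, 2, 3, 4),
                               lfc_sd = 0.5, min_run = 4, lfc = 1,
                               n_sims = 50, seed = 1L) {
  if (n_sims < 1) abort("`n_sims` must be >= 1")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  anno <- tibble(gene_id = gene_ids, genome_index = seq_len(n_genes) - 1L)
  base_labels <- c(rep(seq_along(module_sizes), module_sizes),
                   rep(0L, n_genes - sum(module_sizes)))
  calls <- with_seed(split_seed(seed, "cyanoron_null"), {
    vapply(seq_len(n_sims), function(i) {
      assignment <- tibble(gene_id = gene_ids, module = sample(base_labels))
      lfc_tab <- tidyr::expand_grid(gene_id = gene_ids,
                                    condition = conditions,
                                    time_h = times) |>
        mutate(log2fc = stats::rnorm(n(), 0, lfc_sd))
      nrow(find_cyanorons(anno, assignment, lfc_tab, min_run, lfc))
    }, numeric(1))
  })
  tibble(mean_calls = mean(calls), sd_calls = stats::sd(calls),
         n_sims = n_sims)
}

#' Write cyanoron calls as a BED track
#'
#' Intervals are 0-based half-open over the genomic coordinates of the
#' first and last run member; `name` is `condition:module:length` and
#' `score` the supporting-time-point count.
#'
#' @param calls A `cyanoron_calls` object.
#' @param annotation Annotation (for gene coordinates).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cyanoron_bed <- function(calls, annotation, path) {
  genes <- if (is.data.frame(annotation)) annotation else annotation$genes
  df <- as_tibble(calls) |>
    rowwise() |>
    mutate(
      chrom = genes$seqid[match(.data$gene_ids[[1]][1], genes$gene_id)],
      bed_start = genes$start[genes$genome_index == .data$start_index] - 1L,
      bed_end = genes$end[genes$genome_index == .data$end_index],
      name = sprintf("%s:%d:%d", .data$condition, .data$module, .data$length)
    ) |>
    ungroup()
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", df$chrom, df$bed_start,
                   df$bed_end, df$name, df$n_support)
  writeLines(lines, path)
  invisible(path)
}
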