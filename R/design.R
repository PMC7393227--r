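#' Default experiment design configuration
#'
#' The default layout mirrors a stress time-course study on *Synechococcus*
#' sp. WH7803: seven acclimation/shift combinations sampled at five time
#' points in triplicate, plus two light/dark (L/D) diel cycles at 21 and
#' 27 degrees C sampled at eight clock times in quadruplicate. Shift
#' conditions reference time 0 h within their acclimation; the diel cycles
#' reference the 6 a.m. sample.
#'
#' @return A tibble with one row per condition: `acclimation`, `condition`,
#'   `times` (list-column of sampling times, hours or clock hours),
#'   `n_rep`, `kind` (`"shift"` or `"diel"`), and `reference_time`.
#' @export
#' @examples
#' default_design_config()
default_design_config <- function() {
  tibble(
    acclimation = c("LL", "LL", "LL", "LL", "HL", "HL", "HL", "LD21", "LD27"),
    condition   = c("LLHL", "LLUV", "LLLT", "LLHT",
                    "HLUV", "HLLT", "HLHT", "LD21", "LD27"),
    times = list(
      c(0, 0.3, 1, 3, 6), c(0, 0.3, 1, 3, 6),
      c(0, 12, 24, 48, 72), c(0, 12, 24, 48, 72),
      c(0, 0.3, 1, 3, 6), c(0, 4, 8, 16, 24), c(0, 4, 8, 16, 24),
      c(6, 9, 12, 15, 18, 20, 22, 2), c(6, 9, 12, 15, 18, 20, 22, 2)
    ),
    n_rep = c(rep(3L, 7), 4L, 4L),
    kind = c(rep("shift", 7), "diel", "diel"),
    reference_time = c(rep(0, 7), 6, 6)
  )
}

#' Generate an experiment design table
#'
#' Expands a condition configuration into one row per RNA-seq sample. For
#' shift conditions the `share_t0` flag controls whether the reference
#' (time 0) samples are shared across all shift conditions of the same
#' acclimation (a single control culture split at T0) or duplicated per
#' condition. With the default configuration, sharing yields 154 distinct
#' samples; without sharing the naive expansion yields 169.
#'
#' @param config Condition table as returned by [default_design_config()].
#' @param share_t0 Share the time-0 reference samples across shift
#'   conditions within each acclimation (default `TRUE`).
#' @return A tibble with columns `sample_id`, `acclimation`, `condition`,
#'   `time_h`, `replicate`, `is_reference`. Shared reference samples carry
#'   the acclimation label as their `condition`.
#' @export
#' @examples
#' nrow(generate_design())                    # 154
#' nrow(generate_design(share_t0 = FALSE))    # 169
generate_design <- function(config = default_design_config(), share_t0 = TRUE) {
  if (!is.data.frame(config) || nrow(config) == 0) {
    abort("`config` must be a non-empty condition table")
  }
  if (any(config$n_rep < 1)) abort("replicate counts must be >= 1")
  if (anyDuplicated(config$condition)) abort("condition labels must be unique")
  if (!"kind" %in% names(config)) config$kind <- "shift"
  if (!"reference_time" %in% names(config)) {
    config$reference_time <- purrr::map_dbl(config$times, 1)
  }

  rows <- purrr::pmap(config, function(acclimation, condition, times, n_rep,
                                       kind, reference_time) {
    tidyr::expand_grid(time_h = times, replicate = seq_len(n_rep)) |>
      mutate(
        acclimation = acclimation, condition = condition, kind = kind,
        is_reference = .data$time_h == reference_time
      )
  }) |>
    purrr::list_rbind()

  if (share_t0) {
    # One reference sample set per acclimation, reused by all of that
    # acclimation's shift conditions. Diel cycles keep their own reference
    # (the 6 a.m. sample is an ordinary sample of the cycle).
    shared <- rows |>
      filter(.data$kind == "shift", .data$is_reference) |>
      distinct(.data$acclimation, .data$time_h, .data$replicate,
               .keep_all = TRUE) |>
      mutate(condition = .data$acclimation)
    rows <- bind_rows(filter(rows, !(.data$kind == "shift" & .data$is_reference)),
                      shared)
  }

  rows |>
    arrange(.data$acclimation, .data$condition, .data$time_h, .data$replicate) |>
    mutate(sample_id = sprintf("%s_t%s_r%d",
                               .data$condition,
                               sub("\\.", "p", format(.data$time_h, trim = TRUE)),
                               .data$replicate)) |>
    select("sample_id", "acclimation", "condition", "time_h",
           "replicate", "kind", "is_reference")
}

#' Enumerate the stress-vs-reference contrasts of a design
#'
#' Shift conditions are contrasted against the time-0 reference of their
#' acclimation (shared or condition-specific, whichever the design holds);
#' diel cycles against their own 6 a.m. sample set.
#'
#' @param design A design tibble from [generate_design()].
#' @return A tibble with `condition`, `time_h`, `ref_condition`, `ref_time`.
#' @export
design_contrasts <- function(design) {
  ref_of <- function(acc, cond, kind) {
    if (kind == "diel") return(cond)
    if (any(design$condition == acc)) acc else cond
  }
  design |>
    filter(!.data$is_reference) |>
    distinct(.data$acclimation, .data$condition, .data$time_h, .data$kind) |>
    rowwise() |>
    mutate(
      ref_condition = ref_of(.data$acclimation, .data$condition, .data$kind),
      ref_time = if (.data$kind == "diel") 6 else 0
    ) |>
    ungroup() |>
    arrange(.data$condition, .data$time_h) |>
    select("condition", "time_h", "ref_condition", "ref_time", "kind")
}
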