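# Figure-level summary tables across scenario runs.

one_sided_t <- function(x, y, alternative = "greater") {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  stats::t.test(x, y, alternative = alternative)$p.value
}

#' Active-region columns of a localized-source scenario
#'
#' @param config a [scenario_config()] with a localized secretion pattern.
#' @return `c(min, max)` site columns spanned by the secreting SCs.
#' @export
localized_region_columns <- function(config) {
  g <- config$geometry
  st <- build_bcr(g, config$chemo)
  secr <- st$cells$id[st$cells$kind == "SC" & st$cells$c0 > 0]
  idx <- which(st$labels %in% secr)
  xs <- ((idx - 1L) %% nrow(st$labels)) + 1L
  range(xs)
}

#' Summary tables across scenario runs
#'
#' Builds the per-figure summary tables: tissue thickness by condition,
#' Out/In intercalation fractions, expansion by condition, and (when sweep
#' runs are supplied) expansion and thickness against secretion level. Each
#' table reports mean +/- SD over replicates and one-sided Student t-test
#' p-values against the control condition.
#'
#' @param runs named list of `cpm_run` objects; the element named
#'   `"control"` is the comparison baseline when present.
#' @return named list of tibbles: `thickness`, `out_in`, `expansion`, and
#'   `sweep` (secretion-level members only, detected by their
#'   `level_multiplier`).
#' @export
figure_tables <- function(runs) {
  if (length(runs) == 0) {
    empty <- tibble::tibble(scenario = character(), mean = numeric(),
                            sd = numeric(), n = integer(),
                            p_vs_control = numeric())
    return(list(thickness = empty, out_in = empty, expansion = empty,
                sweep = tibble::tibble(level = numeric(),
                                       expansion_mean = numeric(),
                                       expansion_sd = numeric(),
                                       thickness_mean = numeric(),
                                       thickness_sd = numeric())))
  }
  ctrl <- runs[["control"]]
  tissue <- purrr::keep(runs, ~ !.x$config$geometry$explant_mode == "two-cluster")
  metric_table <- function(var, alternative) {
    purrr::imap_dfr(tissue, function(run, nm) {
      v <- run$summary[[var]]
      p <- if (!is.null(ctrl) && nm != "control")
        one_sided_t(v, ctrl$summary[[var]], alternative) else NA_real_
      tibble::tibble(scenario = nm, mean = mean(v, na.rm = TRUE),
                     sd = stats::sd(v, na.rm = TRUE), n = length(v),
                     p_vs_control = p)
    })
  }
  out_in <- purrr::imap_dfr(tissue, function(run, nm) {
    tibble::tibble(scenario = nm,
                   out_mean = mean(run$summary$out_frac, na.rm = TRUE),
                   out_sd = stats::sd(run$summary$out_frac, na.rm = TRUE),
                   in_mean = mean(run$summary$in_frac, na.rm = TRUE),
                   in_sd = stats::sd(run$summary$in_frac, na.rm = TRUE),
                   p_out_gt_in = one_sided_t(run$summary$out_frac,
                                             run$summary$in_frac, "greater"))
  })
  levels <- purrr::map_dbl(tissue, ~ .x$config$chemo$level_multiplier)
  is_sweep <- grepl("^secretion_", purrr::map_chr(tissue, ~ .x$config$name))
  sweep <- purrr::map_dfr(which(is_sweep), function(i) {
    run <- tissue[[i]]
    tibble::tibble(level = levels[i],
                   expansion_mean = mean(run$summary$expansion, na.rm = TRUE),
                   expansion_sd = stats::sd(run$summary$expansion, na.rm = TRUE),
                   thickness_mean = mean(run$summary$thickness, na.rm = TRUE),
                   thickness_sd = stats::sd(run$summary$thickness, na.rm = TRUE))
  })
  if (nrow(sweep) == 0) {
    sweep <- tibble::tibble(level = numeric(), expansion_mean = numeric(),
                            expansion_sd = numeric(),
                            thickness_mean = numeric(),
                            thickness_sd = numeric())
  }
  sweep <- dplyr::arrange(sweep, .data$level)
  list(thickness = metric_table("thickness", "greater"),
       out_in = out_in,
       expansion = metric_table("expansion", "less"),
       sweep = sweep)
}
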