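# End-to-end pipeline: simulate/read -> screen -> fit -> validate ->
# reference tables.

#' Pipeline configuration
#'
#' @param input Path to a cohort CSV, or \code{NULL} to simulate.
#' @param sim A [sim_config()] used when \code{input} is \code{NULL}.
#' @param variables Dimensions to analyze (default all six).
#' @param bw_grid Body-weight grid for the PI table (kg); default the
#'   2–75 kg grid of printed reference tables.
#' @param min_stratum_n,k Outlier-screen settings (defaults 50 and 3).
#' @param deviance_cutoff_pct Deviant-breed cutoff (default 10).
#' @param r2_gate Weight-independence gate for FS (default 0.1).
#' @param linearity_threshold Linearity verdict threshold (default 0.02).
#' @param level PI level (default 0.95).
#' @param seed Seed controlling any simulation (overrides \code{sim$seed}
#'   when given).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(input = NULL, sim = NULL,
                            variables = names(mm_variables()),
                            bw_grid = c(2, 3.5, 5, 7.5, 10, 12.5, 15, 17.5,
                                        20, 22.5, 25, 27.5, 30, 32.5, 35,
                                        40, 45, 50, 55, 60, 65, 70, 75),
                            min_stratum_n = 50, k = 3,
                            deviance_cutoff_pct = 10, r2_gate = 0.1,
                            linearity_threshold = 0.02, level = 0.95,
                            seed = NULL) {
  if (length(variables) == 0L) {
    stop("pipeline_config: 'variables' must not be empty", call. = FALSE)
  }
  variables <- vapply(variables, match_mm_variable, character(1),
                      USE.NAMES = FALSE)
  if (is.unsorted(bw_grid)) {
    stop("pipeline_config: 'bw_grid' must be sorted ascending",
         call. = FALSE)
  }
  stopifnot(min_stratum_n > 0, k > 0, deviance_cutoff_pct > 0,
            r2_gate > 0, linearity_threshold > 0, level > 0, level < 1)
  if (is.null(input) && is.null(sim)) {
    sim <- sim_config(seed = if (is.null(seed)) 1L else seed)
  }
  if (!is.null(sim) && !is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(
    input = input, sim = sim, variables = variables, bw_grid = bw_grid,
    min_stratum_n = min_stratum_n, k = k,
    deviance_cutoff_pct = deviance_cutoff_pct, r2_gate = r2_gate,
    linearity_threshold = linearity_threshold, level = level,
    seed = seed
  ), class = "pipeline_config")
}

#' Run the full reference-interval pipeline
#'
#' Executes, in order: cohort acquisition (CSV or simulation), outlier
#' screening, allometric fits per variable for the two nonsighthound
#' groups (all, and the immaculate subgroup), P-spline linearity
#' validation, group comparison of upper PI limits, percentile indexing
#' constants, the PI reference table, deviant-breed classification of all
#' breeds (sighthounds included) against the all-nonsighthound PIs, the
#' weight-independent FS cutoff, and the interobserver variance
#' decomposition on the largest breed. Deterministic given the config
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV/JSON files.
#' @return A \code{report_bundle} list: \code{cohort} (screened),
#'   \code{outlier_report}, \code{fits} / \code{fits_immaculate},
#'   \code{fit_table} (coefficients per group), \code{constants} (named
#'   list of [index_constants]), \code{constants_table}, \code{pi_grid}
#'   (per-variable [pi_table()]s), \code{linearity}, \code{group_diffs},
#'   \code{breed_table}, \code{fs_cutoff}, \code{observer}, \code{config}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input, strict = FALSE)
  } else {
    generate_cohort(config$sim)
  }

  scr <- screen_cohort(cohort, min_stratum_n = config$min_stratum_n,
                       k = config$k)
  cohort <- scr$cohort

  nonsh <- cohort[!cohort$sighthound, , drop = FALSE]
  imm <- nonsh[nonsh$health_class == "immaculate", , drop = FALSE]

  fits <- lapply(config$variables, function(v)
    fit_allometric(nonsh, v, level = config$level))
  names(fits) <- config$variables
  fits_imm <- NULL
  if (nrow(imm) >= 10L) {
    fits_imm <- lapply(config$variables, function(v)
      fit_allometric(imm, v, level = config$level))
    names(fits_imm) <- config$variables
  }

  fit_table <- do.call(rbind, lapply(config$variables, function(v) {
    f <- fits[[v]]
    row <- data.frame(variable = mm_label(v), group = "all_nonsighthound",
                      a = f$a, b = f$b, sigma = f$sigma, n = f$n,
                      r2 = f$r2, stringsAsFactors = FALSE)
    if (!is.null(fits_imm)) {
      g <- fits_imm[[v]]
      row <- rbind(row, data.frame(
        variable = mm_label(v), group = "immaculate_nonsighthound",
        a = g$a, b = g$b, sigma = g$sigma, n = g$n, r2 = g$r2,
        stringsAsFactors = FALSE))
    }
    row
  }))

  linearity <- lapply(fits, linearity_check, cohort = nonsh,
                      threshold = config$linearity_threshold)

  group_diffs <- NULL
  if (!is.null(fits_imm)) {
    group_diffs <- lapply(config$variables, function(v)
      group_upper_limit_difference(nonsh, imm, v))
    names(group_diffs) <- config$variables
  }

  constants <- lapply(fits, index_constants, cohort = nonsh)
  constants_table <- do.call(rbind, lapply(config$variables, function(v) {
    cc <- constants[[v]]
    out <- as.data.frame(as.list(rev(cc$constants)))
    names(out) <- paste0("p", rev(as.character(cc$percentiles)))
    cbind(data.frame(variable = mm_label(v), stringsAsFactors = FALSE),
          out, exponent = cc$exponent)
  }))

  pi_grid <- lapply(constants, pi_table, bw_grid = config$bw_grid)

  breed_table <- breed_deviance(cohort, fits,
                                cutoff_pct = config$deviance_cutoff_pct)

  fs_cutoff <- tryCatch(
    weight_independent_cutoff(nonsh, "fs_pct", r2_gate = config$r2_gate),
    error = function(e) NULL)

  observer <- lapply(config$variables, function(v)
    tryCatch(interobserver_rva(cohort, v), error = function(e) NULL))
  names(observer) <- config$variables

  bundle <- structure(list(
    cohort = cohort, outlier_report = scr$report,
    fits = fits, fits_immaculate = fits_imm, fit_table = fit_table,
    constants = constants, constants_table = constants_table,
    pi_grid = pi_grid, linearity = linearity, group_diffs = group_diffs,
    breed_table = breed_table, fs_cutoff = fs_cutoff, observer = observer,
    config = config
  ), class = "report_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write.csv(bundle$fit_table, fp("allometric_fits.csv"), row.names = FALSE)
  write.csv(bundle$constants_table, fp("index_constants.csv"),
            row.names = FALSE)
  for (v in names(bundle$pi_grid)) {
    write.csv(bundle$pi_grid[[v]],
              fp(paste0("pi_table_", mm_label(v), ".csv")),
              row.names = FALSE)
  }
  write.csv(breed_deviance_wide(bundle$breed_table),
            fp("breed_deviance.csv"), row.names = FALSE)
  write.csv(bundle$outlier_report$fences, fp("outlier_fences.csv"),
            row.names = FALSE)
  lin <- do.call(rbind, lapply(bundle$linearity, function(l)
    data.frame(variable = mm_label(l$variable),
               max_rel_dev = l$max_rel_dev, edf = l$edf,
               verdict = l$verdict, stringsAsFactors = FALSE)))
  write.csv(lin, fp("linearity.csv"), row.names = FALSE)
  obs <- do.call(rbind, lapply(Filter(Negate(is.null), bundle$observer),
    function(o) data.frame(variable = mm_label(o$variable),
                           breed = o$breed_used, rva_pct = o$rva_pct,
                           stringsAsFactors = FALSE)))
  if (!is.null(obs)) write.csv(obs, fp("interobserver_rva.csv"),
                               row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  cohort: ", nrow(x$cohort), " dogs (",
      sum(!x$cohort$sighthound), " nonsighthound)\n", sep = "")
  cat("  outliers removed: ", x$outlier_report$total_removed, "\n", sep = "")
  cat("  fitted variables: ",
      paste(vapply(names(x$fits), mm_label, character(1)), collapse = ", "),
      "\n", sep = "")
  lin_ok <- vapply(x$linearity, `[[`, logical(1), "verdict")
  cat("  linearity adequate: ", sum(lin_ok), "/", length(lin_ok), "\n",
      sep = "")
  dev <- x$breed_table
  n_dev <- length(unique(dev$breed[dev$deviant_above | dev$deviant_below]))
  cat("  deviant breeds: ", n_dev, "\n", sep = "")
  invisible(x)
}
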