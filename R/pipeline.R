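#' Default pipeline configuration
#'
#' Every parameter of the end-to-end analysis with its default: the bundled
#' demo simulation scenario (a drought-tolerant and a drought-sensitive
#' reference strain measured under control and PEG, plus five synthetic soil
#' samples with graded active fractions and a linked plant-revival vector),
#' preprocessing settings, threshold policy, DAPC policy and statistics
#' options.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = NULL,
    input = NULL,  # list(spectra=, format=, metadata=) to ingest real data
    simulate = list(
      n_reference_cells = 20L,
      n_soil_cells = 25L,
      soil_fractions = c(AC = 0.5, CP = 0.22, BB = 0.22, DP = 0.12, ES = 0.0),
      revival = c(AC = 40, CP = 40, BB = 20, DP = 0, ES = 0),
      noise_sd = 0.002,
      baseline_coefficients = c(0.05, 0.02),
      # reference DTB activity laws: means 0.35 (control) / 0.275 (PEG),
      # so the derived thresholds centre near 0.14 / 0.11
      dtb_activity = list(
        control = list(inactive_max = 0.05, shape1 = 1.5, shape2 = 6.5,
                       active_min = 0.2, active_max = 1.0),
        PEG = list(inactive_max = 0.05, shape1 = 1.2, shape2 = 11.6,
                   active_min = 0.2, active_max = 1.0)
      )
    ),
    preprocessing = list(lambda = 1e5, p = 0.001, n_iter = 10L,
                         align = TRUE, max_shift = 10L),
    threshold = list(policy = "dtb_reference",
                     fixed_control = 0.14, fixed_peg = 0.11),
    dapc = list(var_explained = 0.9, n_lds = 2L),
    stats = list(alpha = 0.01, alpha_normality = 0.05,
                 spearman_method = "classical_d2", linkage = "average")
  ), class = "pipeline_config")
}

merge_config <- function(default, user, path = "", violations) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(default)) {
      violations$msgs <- c(violations$msgs, paste0("unknown key: ", full))
      next
    }
    if (is.list(default[[key]]) && !is.null(names(default[[key]])) &&
        is.list(user[[key]])) {
      default[[key]] <- merge_config(default[[key]], user[[key]], full,
                                     violations)
    } else {
      default[[key]] <- user[[key]]
    }
  }
  default
}

check_config <- function(cfg) {
  v <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  pp <- cfg$preprocessing
  chk(is.numeric(pp$lambda) && pp$lambda > 0, "lambda must be > 0")
  chk(is.numeric(pp$p) && pp$p > 0 && pp$p < 1, "p must lie in (0, 1)")
  chk(pp$n_iter >= 1, "n_iter must be >= 1")
  chk(pp$max_shift >= 1, "max_shift must be >= 1")
  chk(is.logical(pp$align) || pp$align %in% c(0, 1),
      "align must be logical")
  chk(cfg$threshold$policy %in% c("dtb_reference", "fixed"),
      "threshold policy must be 'dtb_reference' or 'fixed'")
  chk(cfg$dapc$var_explained > 0 && cfg$dapc$var_explained <= 1,
      "var_explained must lie in (0, 1]")
  chk(cfg$dapc$n_lds >= 1, "n_lds must be >= 1")
  chk(cfg$stats$alpha > 0 && cfg$stats$alpha < 1,
      "alpha must lie in (0, 1)")
  chk(cfg$stats$spearman_method %in% c("classical_d2", "pearson_on_ranks"),
      "spearman_method must be 'classical_d2' or 'pearson_on_ranks'")
  sim <- cfg$simulate
  chk(sim$n_reference_cells >= 2, "n_reference_cells must be >= 2")
  chk(sim$n_soil_cells >= 1, "n_soil_cells must be >= 1")
  chk(all(sim$soil_fractions >= 0 & sim$soil_fractions <= 1),
      "soil_fractions must lie in [0, 1]")
  chk(sim$noise_sd >= 0, "noise_sd must be >= 0")
  chk(identical(sort(names(sim$soil_fractions)), sort(names(sim$revival))),
      "soil_fractions and revival must name the same samples")
  if (!is.null(cfg$input)) {
    chk(!is.null(cfg$input$spectra), "input.spectra path is required")
  }
  v
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills every omitted field
#' with its default, and checks the whole schema, reporting every violation
#' at once rather than only the first. Unknown keys are errors.
#'
#' @param path YAML file, or `NULL` when `config` is given directly.
#' @param config named list overriding defaults (used when `path` is NULL).
#' @return A fully-defaulted `pipeline_config`; errors list all violations.
#' @examples
#' cfg <- validate_config(config = list(seed = 42))
#' cfg$preprocessing$lambda
#' @export
validate_config <- function(path = NULL, config = list()) {
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    config <- yaml::read_yaml(path)
    if (is.null(config)) config <- list()
    if (!is.null(config$simulate)) {
      for (f in c("soil_fractions", "revival")) {
        if (!is.null(config$simulate[[f]])) {
          config$simulate[[f]] <- unlist(config$simulate[[f]])
        }
      }
    }
  }
  violations <- new.env()
  violations$msgs <- character()
  cfg <- merge_config(default_config(), config, "", violations)
  msgs <- c(violations$msgs, check_config(cfg))
  if (length(msgs)) {
    stop("invalid configuration:\n  - ", paste(msgs, collapse = "\n  - "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

simulate_stage <- function(cfg) {
  sim <- cfg$simulate
  seed0 <- cfg$seed
  ref <- list()
  sets <- list()
  i <- 0L
  for (cond in c("control", "PEG")) {
    for (role in c("DTB", "DSB")) {
      i <- i + 1L
      act <- if (role == "DTB") sim$dtb_activity[[cond]] else
        list(inactive_max = 0.05, shape1 = 2, shape2 = 2,
             active_min = 0.2, active_max = 1.0)
      ps <- population_spec(sim$n_reference_cells, fraction_active = 1,
                            activity_distribution = act,
                            noise_sd = sim$noise_sd,
                            baseline_coefficients = sim$baseline_coefficients,
                            seed = derive_seed(seed0, i))
      sets[[paste(role, cond, sep = "_")]] <- generate_population(
        ps, phenotype_profile(role, cond), sample = paste0(role, "_ref"))
    }
  }
  for (s in names(sim$soil_fractions)) {
    i <- i + 1L
    ps <- population_spec(sim$n_soil_cells,
                          fraction_active = sim$soil_fractions[[s]],
                          noise_sd = sim$noise_sd,
                          baseline_coefficients = sim$baseline_coefficients,
                          seed = derive_seed(seed0, i))
    sets[[paste0("soil_", s)]] <- generate_population(
      ps, phenotype_profile("DTB", "PEG"), sample = s)
  }
  # soil role label overrides the template's
  for (s in names(sim$soil_fractions)) {
    sets[[paste0("soil_", s)]]$metadata$role <- "soil"
  }
  sets
}

ingest_stage <- function(cfg) {
  inp <- cfg$input
  if (!file.exists(inp$spectra)) {
    stop("stage ingest: input file not found: ", inp$spectra)
  }
  set <- read_spectra(inp$spectra, format = inp$format %||% "long",
                      metadata = inp$metadata)
  split_sets <- split(seq_len(n_cells(set)),
                      paste(set$metadata$role, set$metadata$condition,
                            sep = "_"))
  lapply(split_sets, function(idx) set[idx])
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: simulation (or ingestion) of single-cell Raman
#' spectra; preprocessing (ALS baseline, total-intensity normalization, peak
#' alignment); C-D ratio computation and reference-threshold classification
#' of drought-tolerant cells per soil sample; DAPC on the fingerprint window
#' with centroid-distance summaries and the per-wavenumber significance
#' screen; and the association layer (Spearman correlation of
#' percent-tolerant cells against the plant-revival vector). All per-stage
#' tables are written to `output_dir` as TSV, the report as JSON and text.
#' A single master seed derives all stage seeds, so the same configuration
#' reproduces the same report.
#'
#' @param config a validated `pipeline_config` (see [validate_config()]).
#' @return A `run_report` list: `percent_tolerant` (per sample, 1 decimal),
#'   `thresholds`, `dapc_distances`, `n_significant`, `association`,
#'   `version`, `seed`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- validate_config(config = unclass(config))
  out_dir <- cfg$output_dir %||% tempfile("ramandip_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", sep = "", file = log_file, append = TRUE)
    message(msg)
  }
  logf("config: ", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))

  logf("stage simulate/ingest")
  sets <- if (is.null(cfg$input)) simulate_stage(cfg) else ingest_stage(cfg)

  logf("stage preprocess (", length(sets), " sets)")
  pp <- cfg$preprocessing
  sets <- lapply(sets, function(s) {
    preprocess_spectra(s, lambda = pp$lambda, p = pp$p, n_iter = pp$n_iter,
                       align = isTRUE(as.logical(pp$align)) && n_cells(s) >= 2,
                       max_shift = pp$max_shift)
  })
  for (nm in names(sets)) {
    write_spectra(sets[[nm]], file.path(out_dir, paste0(nm, "_processed.csv")),
                  format = "wide", seed = cfg$seed)
  }

  logf("stage cdratio")
  ratios <- lapply(sets, cd_ratios_of)
  all_ratios <- do.call(rbind, ratios)
  utils::write.table(all_ratios, file.path(out_dir, "cd_ratios.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  thresholds <- if (cfg$threshold$policy == "fixed") {
    c(control = cfg$threshold$fixed_control, PEG = cfg$threshold$fixed_peg)
  } else {
    ctrl <- ratios[["DTB_control"]]
    peg <- ratios[["DTB_PEG"]]
    if (is.null(ctrl) || is.null(peg)) {
      stop("stage cdratio: DTB reference sets required for policy ",
           "'dtb_reference'")
    }
    c(control = compute_threshold(ctrl$cd_ratio),
      PEG = compute_threshold(peg$cd_ratio))
  }
  logf(sprintf("thresholds: control %.4f, PEG %.4f",
               thresholds["control"], thresholds["PEG"]))

  soil_names <- grep("^soil_", names(sets), value = TRUE)
  summary_rows <- lapply(soil_names, function(nm) {
    cls <- classify_active(ratios[[nm]], thresholds["PEG"])
    data.frame(sample = sub("^soil_", "", nm),
               n_cells = nrow(cls$calls), n_active = cls$n_active,
               percent_active = round(cls$percent_active, 1))
  })
  soil_summary <- do.call(rbind, summary_rows)
  if (!is.null(soil_summary)) {
    utils::write.table(soil_summary, file.path(out_dir, "soil_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  logf("stage dapc + peak screen")
  fp <- default_bands()$fingerprint
  dapc_rows <- list()
  n_signif <- NA_integer_
  signif_track <- NULL
  for (role in c("DTB", "DSB")) {
    a <- sets[[paste0(role, "_control")]]
    b <- sets[[paste0(role, "_PEG")]]
    if (is.null(a) || is.null(b)) next
    ca <- crop_band(a, fp)
    cb <- crop_band(b, fp)
    m <- rbind(ca$intensities, cb$intensities)
    grp <- rep(c("control", "PEG"), c(n_cells(ca), n_cells(cb)))
    fit <- fit_dapc(m, grp, var_explained = cfg$dapc$var_explained,
                    n_lds = min(cfg$dapc$n_lds, 1L))
    dapc_rows[[role]] <- cbind(role = role,
                               centroid_distances(fit, "control", "PEG"))
    if (role == "DSB") {
      signif_track <- peakwise_significance(
        ca, cb, alpha = cfg$stats$alpha,
        alpha_normality = cfg$stats$alpha_normality)
      n_signif <- sum(signif_track$significant)
      utils::write.table(
        signif_track[c("wavenumber", "p_value", "direction")],
        file.path(out_dir, "significance_track.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  dapc_distances <- do.call(rbind, dapc_rows)
  if (!is.null(dapc_distances)) {
    utils::write.table(dapc_distances, file.path(out_dir, "dapc_distances.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  logf("stage associate")
  association <- NULL
  if (!is.null(soil_summary) && nrow(soil_summary) >= 3 &&
      !is.null(cfg$simulate$revival)) {
    revival <- cfg$simulate$revival[soil_summary$sample]
    association <- spearman_rho(soil_summary$percent_active, revival,
                                method = cfg$stats$spearman_method)
    assoc_df <- data.frame(x = "percent_tolerant", y = "percent_revived",
                           rho = association$rho, p = association$p_value,
                           method = association$method, n = association$n)
    utils::write.table(assoc_df, file.path(out_dir, "associations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  report <- structure(list(
    percent_tolerant = if (is.null(soil_summary)) NULL else
      stats::setNames(soil_summary$percent_active, soil_summary$sample),
    thresholds = thresholds,
    dapc_distances = dapc_distances,
    n_significant = n_signif,
    association = association,
    version = as.character(utils::packageVersion("ramandip")),
    seed = cfg$seed,
    output_dir = out_dir
  ), class = "run_report")
  json <- report
  json$association <- if (!is.null(association)) unclass(association)
  jsonlite::write_json(
    lapply(json[setdiff(names(json), "output_dir")],
           function(el) if (inherits(el, "data.frame")) el else
             as.list(el %||% list())),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  logf("done")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Raman-DIP drought-tolerance report ==\n")
  cat(sprintf("seed %d, version %s\n", x$seed, x$version))
  cat(sprintf("thresholds: control %.4f, PEG %.4f\n",
              x$thresholds["control"], x$thresholds["PEG"]))
  if (!is.null(x$percent_tolerant)) {
    cat("percent drought-tolerant cells per sample:\n")
    print(x$percent_tolerant)
  }
  if (!is.null(x$dapc_distances)) {
    cat("DAPC control-centroid to PEG-cell distances:\n")
    print(x$dapc_distances, row.names = FALSE)
  }
  if (!is.na(x$n_significant)) {
    cat("significant fingerprint wavenumbers (DSB control vs PEG):",
        x$n_significant, "\n")
  }
  if (!is.null(x$association)) {
    cat("phenotype vs plant revival: ")
    print(x$association)
  }
  invisible(x)
}

#' Run the bundled demonstration scenario
#'
#' Convenience wrapper around [run_pipeline()] with the default
#' configuration: two reference strains and five synthetic soil samples with
#' active fractions 0.5, 0.22, 0.22, 0.12 and 0, cross-validated against a
#' linked plant-revival vector.
#'
#' @param seed master seed.
#' @param output_dir where to write tables; a temporary directory by default.
#' @return The `run_report`.
#' @export
run_demo <- function(seed = 1L, output_dir = NULL) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$output_dir <- output_dir
  run_pipeline(cfg)
}
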