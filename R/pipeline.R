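#' Build and validate a pipeline run configuration
#'
#' The configuration is one JSON object (or an equivalent R list). Every
#' default is filled in and echoed into the run manifest so all thresholds
#' are auditable. Fields:
#'
#' * `seed` (int), `out_dir` (path), `alpha` (0-1), `ratio_mode`
#'   (`"mean_widths"`/`"per_pair"`), `var_equal` (logical).
#' * `cohort`: `parameters` (`"printed"`, `"pooled"` or a CSV path with
#'   columns genotype, age_months, region, metric, mean, sd),
#'   `n_per_group`.
#' * `images`: `enabled` (logical; when `TRUE` the pipeline synthesizes and
#'   measures images instead of drawing metric values directly),
#'   `n_longitudinal`, `n_section`, `pixel_size_um`, `section_pixel_size_um`,
#'   `image_shape`, `n_section_fibers`, `channels` (role -> slice map,
#'   required when enabled), `write_tiffs` (logical).
#' * `subset`: optional `genotypes`, `ages`, `regions` restricting the
#'   cohort grid (useful for quick runs).
#' * `report`: `enabled` (logical).
#'
#' @param config Path to a JSON file or a named list.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_dmq("dmq_config_error", "config file not found: %s", config)
    }
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- list(
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir %||% "diamorph-run",
    alpha = config$alpha %||% 0.05,
    ratio_mode = config$ratio_mode %||% "mean_widths",
    var_equal = isTRUE(config$var_equal),
    cohort = list(
      parameters = config$cohort$parameters %||% "printed",
      n_per_group = as.integer(config$cohort$n_per_group %||% 6L)
    ),
    images = list(
      enabled = isTRUE(config$images$enabled),
      n_longitudinal = as.integer(config$images$n_longitudinal %||% 1L),
      n_section = as.integer(config$images$n_section %||% 1L),
      pixel_size_um = config$images$pixel_size_um %||% 0.15,
      section_pixel_size_um = config$images$section_pixel_size_um %||% 0.5,
      image_shape = as.integer(config$images$image_shape %||% c(512L, 512L)),
      n_section_fibers = as.integer(config$images$n_section_fibers %||% 16L),
      channels = config$images$channels,
      write_tiffs = isTRUE(config$images$write_tiffs)
    ),
    subset = list(
      genotypes = config$subset$genotypes %||% .GENOTYPES,
      ages = as.integer(config$subset$ages %||% .AGES),
      regions = config$subset$regions %||% .REGIONS
    ),
    report = list(enabled = !isFALSE(config$report$enabled))
  )
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop_dmq("dmq_config_error", "field 'alpha' must lie in (0, 1)")
  }
  if (!cfg$ratio_mode %in% c("mean_widths", "per_pair")) {
    stop_dmq("dmq_config_error", "field 'ratio_mode' must be mean_widths or per_pair")
  }
  if (cfg$images$enabled) {
    ch <- cfg$images$channels
    if (is.null(ch) || !all(c("laminin", "nuclei", "cd68") %in% names(ch))) {
      stop_dmq("dmq_config_error",
               "field 'images.channels' must map laminin, nuclei and cd68 to slices")
    }
    cfg$images$channels <- vapply(ch[c("laminin", "nuclei", "cd68")],
                                  as.integer, integer(1))
  }
  pchoice <- cfg$cohort$parameters
  if (is.character(pchoice) && !pchoice %in% c("printed", "pooled") &&
      !file.exists(pchoice)) {
    stop_dmq("dmq_config_error",
             "field 'cohort.parameters' must be 'printed', 'pooled' or an existing CSV")
  }
  structure(cfg, class = "run_config")
}

resolve_parameters <- function(choice) {
  if (is.data.frame(choice)) return(tibble::as_tibble(choice))
  switch(choice,
    printed = default_group_parameters(),
    pooled = pooled_group_parameters(),
    readr::read_csv(choice, show_col_types = FALSE)
  )
}

stage_log <- function(stage, status, detail = "") {
  message(sprintf("[%s] %s %s", stage, status, detail))
}

# Synthesize + measure the images of one cohort cell; per-image generator
# parameters are drawn from the cell's metric distributions.
measure_group_images <- function(pars, gt, ag, rg, n_long, n_section, cfg,
                                 seed_base, img_dir = NULL) {
  pick <- function(metric) {
    r <- pars[pars$genotype == gt & pars$age_months == ag &
                pars$region == rg & pars$metric == metric, ]
    c(r$mean[1], r$sd[1])
  }
  rows <- list()
  for (i in seq_len(n_long)) {
    seed_i <- (seed_base + i) %% .Machine$integer.max
    draw <- withr::with_seed(seed_i, {
      sarc <- rtruncnorm0(1, pick("sarcomere_length_um")[1], pick("sarcomere_length_um")[2])
      isr <- rtruncnorm0(1, pick("interstitial_ratio")[1], pick("interstitial_ratio")[2])
      brf <- rtruncnorm0(1, pick("percent_branched")[1], pick("percent_branched")[2]) / 100
      list(sarc = max(sarc, 1.6), isr = isr, brf = min(brf, 1))
    })
    # fiber width: realistic scale but always >= 3 lanes in frame
    field_v <- cfg$images$image_shape[1] * cfg$images$pixel_size_um
    fw <- min(max(5, 0.1 * field_v), field_v / (3.5 * (1 + draw$isr)))
    spec <- striation_spec(
      period_um = draw$sarc, pixel_size_um = cfg$images$pixel_size_um,
      image_shape = cfg$images$image_shape,
      fiber_width_um = fw,
      gap_to_fiber_ratio = draw$isr, branch_fraction = draw$brf,
      orientation_deg = 0, noise_sd = 0.05, seed = seed_i)
    gen <- generate_striation_image(spec)
    img_id <- sprintf("%s_%dmo_%s_long%02d", gt, ag, substr(rg, 1, 3), i)
    if (!is.null(img_dir)) {
      write_calibrated_tiff(gen$image, file.path(img_dir, paste0(img_id, ".tif")))
    }
    est <- tryCatch(estimate_sarcomere_length(gen$image)$modal_length_um,
                    dmq_error = function(e) NA_real_)
    lm <- tryCatch(longitudinal_metrics(gen$image, ratio_mode = cfg$ratio_mode),
                   dmq_error = function(e) NULL)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      genotype = gt, age_months = ag, region = rg, image_id = img_id,
      metric = c("sarcomere_length_um", "interstitial_ratio", "percent_branched"),
      value = c(est,
                if (is.null(lm)) NA_real_ else lm$interstitial_ratio,
                if (is.null(lm)) NA_real_ else lm$percent_branched))
  }
  for (i in seq_len(n_section)) {
    seed_i <- (seed_base + 1000L + i) %% .Machine$integer.max
    draw <- withr::with_seed(seed_i, {
      csa <- rtruncnorm0(1, pick("csa_um2")[1], pick("csa_um2")[2])
      cnf <- rtruncnorm0(1, pick("percent_regenerating")[1],
                         pick("percent_regenerating")[2]) / 100
      mac <- rtruncnorm0(1, pick("macrophage_density_per_mm2")[1],
                         pick("macrophage_density_per_mm2")[2])
      list(csa = max(csa, 50), cnf = min(cnf, 1), mac = mac)
    })
    # keep the drawn mean CSA packable into the section field
    sect_field <- prod(cfg$images$image_shape) * cfg$images$section_pixel_size_um^2
    draw$csa <- min(draw$csa, 0.9 * sect_field / cfg$images$n_section_fibers)
    spec <- cross_section_spec(
      n_fibers = cfg$images$n_section_fibers, csa_mean_um2 = draw$csa,
      csa_sd_um2 = 0.3 * draw$csa, central_nucleus_fraction = draw$cnf,
      macrophage_density_per_mm2 = draw$mac,
      pixel_size_um = cfg$images$section_pixel_size_um,
      image_shape = cfg$images$image_shape, seed = seed_i)
    gen <- generate_cross_section(spec)
    img_id <- sprintf("%s_%dmo_%s_sect%02d", gt, ag, substr(rg, 1, 3), i)
    if (!is.null(img_dir)) {
      write_calibrated_tiff(gen$image, file.path(img_dir, paste0(img_id, ".tif")))
    }
    rep <- tryCatch(section_report(gen$image), dmq_error = function(e) NULL)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      genotype = gt, age_months = ag, region = rg, image_id = img_id,
      metric = c("csa_um2", "percent_regenerating", "macrophage_density_per_mm2"),
      value = if (is.null(rep)) rep(NA_real_, 3) else
        c(rep$mean_csa_um2, rep$percent_regenerating, rep$macrophage_density_per_mm2))
  }
  dplyr::bind_rows(rows)
}

#' Run the full generate -> measure -> compare pipeline
#'
#' Executes the stages in order, writing `metrics.csv`, `summary.csv`,
#' `comparisons.csv`, report figures and a `manifest.json` (config with all
#' defaults filled, per-stage file lists with MD5 checksums, package
#' version, seed) into `out_dir`. Re-running an identical config + seed
#' reproduces byte-identical CSV outputs.
#'
#' @param config A [run_config()], list, or JSON path.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  # always re-validate: a run_config edited by hand must not bypass checks
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  pars <- resolve_parameters(cfg$cohort$parameters)
  outputs <- character(0)

  stage_log("generate", "start",
            if (cfg$images$enabled) "synthesizing and measuring images"
            else "sampling cohort metric table")
  g <- grid_groups()
  g <- g[g$genotype %in% cfg$subset$genotypes &
           g$age_months %in% cfg$subset$ages &
           g$region %in% cfg$subset$regions, , drop = FALSE]
  if (!nrow(g)) stop_dmq("dmq_config_error", "field 'subset' selects no groups")
  if (cfg$images$enabled) {
    img_dir <- if (cfg$images$write_tiffs) {
      d <- file.path(cfg$out_dir, "images"); dir.create(d, showWarnings = FALSE); d
    } else NULL
    metrics <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
      measure_group_images(pars, g$genotype[i], g$age_months[i], g$region[i],
                           cfg$images$n_longitudinal, cfg$images$n_section,
                           cfg, seed_base = cfg$seed * 10000L + i * 97L,
                           img_dir = img_dir)
    }))
    metrics <- metrics[is.finite(metrics$value), ]
  } else {
    metrics <- sample_cohort(cohort_spec(pars, cfg$cohort$n_per_group, cfg$seed))
    metrics <- metrics[metrics$genotype %in% cfg$subset$genotypes &
                         metrics$age_months %in% cfg$subset$ages &
                         metrics$region %in% cfg$subset$regions, , drop = FALSE]
  }
  metrics_path <- file.path(cfg$out_dir, "metrics.csv")
  write_metric_table(metrics, metrics_path)
  outputs <- c(outputs, metrics_path)
  stage_log("generate", "done", sprintf("%d rows", nrow(metrics)))

  stage_log("stats", "start")
  summ <- group_summary(metrics)
  comps <- compare_all(metrics, alpha = cfg$alpha, var_equal = cfg$var_equal)
  summary_path <- file.path(cfg$out_dir, "summary.csv")
  comparisons_path <- file.path(cfg$out_dir, "comparisons.csv")
  readr::write_csv(summ, summary_path)
  readr::write_csv(comps, comparisons_path)
  outputs <- c(outputs, summary_path, comparisons_path)
  stage_log("stats", "done", sprintf("%d comparisons", nrow(comps)))

  report_files <- character(0)
  if (cfg$report$enabled) {
    stage_log("report", "start")
    report_files <- render_report(summ, comps, cfg$out_dir, alpha = cfg$alpha)
    outputs <- c(outputs, report_files)
    stage_log("report", "done", paste(basename(report_files), collapse = ", "))
  }

  manifest <- list(
    package = "diamorph",
    version = as.character(utils::packageVersion("diamorph")),
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render mean +/- SD bar panels with significance markers
#'
#' One panel set grouped by region and one by age, faceted per metric, with
#' an asterisk marking metrics whose pooled genotype contrast is significant
#' after Holm-Sidak adjustment.
#'
#' @param summary A [group_summary()] tibble.
#' @param comparisons A [compare_all()] tibble.
#' @param out_dir Output directory for PNG files.
#' @param alpha Significance level for markers.
#' @return Paths of the files written (invisibly `character(0)` for an
#'   empty summary, with a warning).
#' @export
render_report <- function(summary, comparisons, out_dir, alpha = 0.05) {
  if (is.null(summary) || !nrow(summary)) {
    warning("empty summary; no report rendered")
    return(invisible(character(0)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pooled <- comparisons[comparisons$group_a == "mdx:pooled" &
                          !is.na(comparisons$adjusted_p), ]
  sig <- pooled$metric[pooled$adjusted_p < alpha]
  summary$metric_lab <- ifelse(summary$metric %in% sig,
                               paste0(summary$metric, " *"), summary$metric)

  mk_panel <- function(xvar) {
    ggplot2::ggplot(summary,
      ggplot2::aes(x = factor(.data[[xvar]]), y = .data$mean, fill = .data$genotype)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
        position = ggplot2::position_dodge(0.9), width = 0.3) +
      ggplot2::facet_wrap(~metric_lab, scales = "free_y") +
      ggplot2::labs(x = xvar, y = "mean ± SD",
                    caption = "* pooled mdx vs control significant (Holm-Sidak)") +
      ggplot2::theme_minimal()
  }
  f1 <- file.path(out_dir, "panels_by_region.png")
  f2 <- file.path(out_dir, "panels_by_age.png")
  ggplot2::ggsave(f1, mk_panel("region"), width = 9, height = 6, dpi = 120)
  ggplot2::ggsave(f2, mk_panel("age_months"), width = 9, height = 6, dpi = 120)
  c(f1, f2)
}
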