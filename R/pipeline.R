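#' Run the simulate-measure-normalize-test pipeline
#'
#' Orchestrates one reproducible analysis run. The configuration (a YAML
#' file or an equivalent named list) either names per-group synthetic
#' junction-image parameters or points at a manifest CSV of real images; the
#' pipeline measures every image (junction morphometry, object statistics,
#' entropy, ROI corrected intensity), normalizes each metric to percent of
#' control, runs the gated group statistics, and writes tidy CSVs plus a
#' machine-readable provenance file to the output directory. Every random
#' operation's seed is derived deterministically from the master seed via
#' [derive_seed()], so rerunning an identical configuration reproduces all
#' outputs byte-identically. Per-image failures are recorded in
#' `errors.csv` and do not abort the run; a run in which no image survives
#' aborts with a summary.
#'
#' Configuration fields: `master_seed` (integer), `control_label`
#' (default `"control"`), `metrics` (subset of `strand_length_px`,
#' `n_branch_points`, `complexity_index`, `n_objects`, `mean_object_size`,
#' `entropy_bits`, `corrected`), `threshold` (`"otsu"` or a fixed intensity),
#' and either `groups` (list of `name`, `n_images`, plus any
#' [simulate_junction_image()] parameter overrides, with image-level
#' defaults under `image:`) or `manifest` (CSV with columns `path`, `group`,
#' and optionally `um_per_pixel`).
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory (created if missing); defaults to
#'   `config$out_dir`.
#' @return Invisibly, a list with `metrics`, `percent`, `stats`,
#'   `figure_tables`, `errors`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) tj_abort("param", "`config` must be a list or a YAML path.")
  master_seed <- config$master_seed %||% 1L
  control <- config$control_label %||% "control"
  out_dir <- out_dir %||% config$out_dir %||%
    tj_abort("param", "No output directory given.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics_wanted <- config$metrics %||%
    c("strand_length_px", "n_branch_points", "complexity_index",
      "n_objects", "mean_object_size", "entropy_bits", "corrected")
  threshold <- config$threshold %||% "otsu"
  fixed_value <- if (is.numeric(threshold)) threshold else NULL
  thr_method <- if (is.numeric(threshold)) "fixed" else threshold

  log_lines <- character(0)
  log1 <- function(...) log_lines <<- c(log_lines, sprintf(...))
  log1("run: master_seed=%d control=%s threshold=%s", master_seed, control,
       as.character(threshold))

  # assemble the image jobs: either simulated per group, or from a manifest
  jobs <- list()
  if (!is.null(config$manifest)) {
    man <- readr::read_csv(config$manifest, show_col_types = FALSE)
    for (i in seq_len(nrow(man))) {
      jobs[[length(jobs) + 1L]] <- list(
        id = sprintf("%s_%03d", man$group[i], i), group = man$group[i],
        path = man$path[i],
        um_per_pixel = if ("um_per_pixel" %in% names(man)) man$um_per_pixel[i] else 1
      )
    }
  } else if (!is.null(config$groups)) {
    # pipeline default: strands wide enough (dilation radius 4, ~9 px) to
    # carry the 7x7 intensity rectangles of the ROI procedure
    img_defaults <- utils::modifyList(list(strand_width = 4),
                                      config$image %||% list())
    for (grp in config$groups) {
      for (i in seq_len(grp$n_images %||% 10L)) {
        id <- sprintf("%s_%03d", grp$name, i)
        sim_args <- utils::modifyList(img_defaults,
                                      grp[setdiff(names(grp), c("name", "n_images"))])
        sim_args$seed <- derive_seed(master_seed, "simulate", id)
        jobs[[length(jobs) + 1L]] <- list(id = id, group = grp$name,
                                          sim_args = sim_args)
      }
    }
  } else {
    tj_abort("param", "Config must contain either `groups` or `manifest`.")
  }

  rows <- list(); errs <- list()
  for (job in jobs) {
    res <- tryCatch({
      img <- if (!is.null(job$path)) {
        read_image(job$path, um_per_pixel = job$um_per_pixel,
                   meta = list(image_id = job$id, group = job$group))
      } else {
        do.call(simulate_junction_image, job$sim_args)$image
      }
      jm <- junction_metrics(img, threshold = thr_method, fixed_value = fixed_value)
      # ROIs are placed on the thresholded staining mask: strand interiors
      # carry the 7x7 foreground rectangles, unstained area the background
      ci <- corrected_intensity(img,
                                fg_mask = threshold_image(img, thr_method, fixed_value),
                                seed = derive_seed(master_seed, "roi", job$id))
      log1("image %s: group=%s seed_sim=%s seed_roi=%d", job$id, job$group,
           if (is.null(job$sim_args)) "NA" else as.character(job$sim_args$seed),
           derive_seed(master_seed, "roi", job$id))
      dplyr::bind_cols(
        tibble::tibble(image_id = job$id, group = job$group), jm,
        ci[, c("mean_fg", "mean_bg", "corrected")]
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- tibble::tibble(
        image_id = job$id, group = job$group, error = conditionMessage(res))
      log1("image %s: ERROR %s", job$id, conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0) {
    tj_abort("validation", sprintf(
      "No image survived the run (%d failures); see errors above.", length(errs)))
  }
  metrics <- dplyr::bind_rows(rows)
  errors <- if (length(errs)) dplyr::bind_rows(errs) else
    tibble::tibble(image_id = character(0), group = character(0), error = character(0))

  metric_cols <- intersect(metrics_wanted, names(metrics))
  long <- metrics %>%
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
                        names_to = "metric", values_to = "value") %>%
    dplyr::filter(!is.na(.data$value))
  percent <- long %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::group_modify(function(d, key) {
      # a metric whose control mean is zero (e.g. no branch points in the
      # control images) cannot be normalized; keep it with NA percent
      tryCatch(percent_of_control(d, "value", "group", control_group = control),
               tjquant_error_normalization = function(e) {
                 log1("metric %s: %s", key$metric, conditionMessage(e))
                 dplyr::mutate(d, percent_of_control = NA_real_)
               })
    }) %>%
    dplyr::ungroup()

  multi_group <- length(unique(metrics$group)) >= 2
  stats_tbl <- NULL; fig_tables <- NULL
  if (multi_group) {
    comparisons <- long %>%
      dplyr::group_by(.data$metric) %>%
      dplyr::group_map(function(d, key) {
        cmp <- tryCatch(suppressWarnings(compare_groups(d, "value", "group")),
                        tjquant_error = function(e) {
                          log1("metric %s: %s", key$metric, conditionMessage(e))
                          NULL
                        })
        if (is.null(cmp)) return(NULL)
        list(metric = key$metric, cmp = cmp)
      })
    comparisons <- purrr::compact(comparisons)
    stats_tbl <- purrr::map_dfr(comparisons, function(x) {
      dplyr::bind_cols(tibble::tibble(metric = x$metric), glance(x$cmp))
    })
    pairwise_tbl <- purrr::map_dfr(comparisons, function(x) {
      dplyr::bind_cols(tibble::tibble(metric = x$metric), tidy(x$cmp))
    })
    fig_tables <- purrr::map_dfr(comparisons, function(x) {
      tbl <- tryCatch(report_figure_table(x$cmp, control_group = control),
                      tjquant_error = function(e) {
                        log1("metric %s: %s", x$metric, conditionMessage(e))
                        NULL
                      })
      if (is.null(tbl)) return(NULL)
      dplyr::bind_cols(tibble::tibble(metric = x$metric), tbl)
    })
    readr::write_csv(pairwise_tbl, file.path(out_dir, "pairwise.csv"))
    readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
    readr::write_csv(fig_tables, file.path(out_dir, "percent_of_control_report.csv"))
  }
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(percent, file.path(out_dir, "percent_of_control.csv"))
  readr::write_csv(errors, file.path(out_dir, "errors.csv"))
  provenance <- list(
    package = "tjquant",
    version = as.character(utils::packageVersion("tjquant")),
    master_seed = master_seed,
    config = config,
    n_images = nrow(metrics),
    n_errors = nrow(errors),
    seeds = purrr::map(jobs, function(j) list(
      image_id = j$id,
      seed_sim = if (is.null(j$sim_args)) NA else j$sim_args$seed,
      seed_roi = derive_seed(master_seed, "roi", j$id)))
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(metrics = metrics, percent = percent, stats = stats_tbl,
                 figure_tables = fig_tables, errors = errors, out_dir = out_dir))
}
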