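
#' Pipeline configuration
#'
#' All tunable parameters of the per-participant stages and the statistics
#' layer, with their defaults. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `fovea_config`.
#' @export
fovea_config <- function(...) {
  defaults <- list(
    roi_width_um = 300, roi_height_um = 300,
    window_side_um = 50, grid_step_um = 1, fraction = 0.8,
    cdc_weighted = TRUE,
    x_step_um = 5, central_width_um = 227, max_search_halfwidth_um = 500,
    search_halfwidth_um = 750,
    n_angles = 180, radial_step_um = 10, max_radius_um = 3000,
    prominence_um = 2, smooth_halfwidth = 2, pit_search_radius_um = 750,
    central_radius_um = 500, ratio_threshold = 0.3,
    icc_model = "agreement")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop_fovea("unknown config key(s): %s", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "fovea_config")
}

# metric pairs examined across the cohort: ONL vs cone density, pit vs cone
# density, and FAZ vs pit geometry
default_metric_pairs <- function() {
  dens <- c("pcd", "cdc_density", "areal_density")
  rbind(
    cbind("max_onl_um", dens),
    cbind("central_onl_um", dens),
    cbind("pit_diameter_mm", dens),
    cbind("pit_volume_mm3", dens),
    cbind("faz_area_mm2", c("pit_diameter_mm", "pit_volume_mm3")))
}

#' Run the full foveal morphometry pipeline over a cohort manifest
#'
#' Executes, per participant and per available modality: cone density mapping
#' (PCD, CDC), ONL profile extraction, pit morphometry and FAZ morphometry;
#' then the cohort-level areal density over the CDC-aligned common area, the
#' summary table and the Spearman correlation set. Per-participant stage
#' failures are logged and the affected metrics marked missing; the pipeline
#' continues. Outputs (`cohort.csv`, `summary.csv`, `correlations.csv`,
#' `run_log.json`) are deterministic for a fixed manifest and configuration.
#'
#' @param manifest data frame with columns `id`, `axial_length_mm` and any of
#'   the per-modality file columns `coords_csv`, `seg_csv`, `thickness_csv`,
#'   `mask_png` (`NA` = modality absent).
#' @param out_dir output directory (created if needed); `NULL` = no files
#'   written.
#' @param config a [fovea_config()].
#' @return invisibly, a list with `cohort` (data frame), `summary`,
#'   `correlations`, `common_width_um` and `log`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, config = fovea_config()) {
  stopifnot(is.data.frame(manifest), "id" %in% names(manifest))
  if (anyDuplicated(manifest$id)) stop_fovea("manifest ids must be unique")
  log <- list()
  note <- function(id, stage, msg) {
    log[[length(log) + 1]] <<- list(id = as.character(id), stage = stage,
                                    message = msg)
  }
  n <- nrow(manifest)
  cohort <- data.frame(participant_id = as.character(manifest$id),
                       pcd = NA_real_, cdc_density = NA_real_,
                       areal_density = NA_real_, max_onl_um = NA_real_,
                       central_onl_um = NA_real_, pit_diameter_mm = NA_real_,
                       pit_volume_mm3 = NA_real_, faz_area_mm2 = NA_real_,
                       fragmented = NA)
  maps <- vector("list", n)
  metrics <- vector("list", n)
  get_path <- function(i, col) {
    if (!col %in% names(manifest)) return(NA_character_)
    p <- manifest[[col]][i]
    if (is.na(p) || !nzchar(p)) NA_character_ else p
  }
  run_stage <- function(i, stage, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(manifest$id[i], stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      note(manifest$id[i], stage, paste("ERROR:", conditionMessage(e)))
      NULL
    })
  }
  for (i in seq_len(n)) {
    p <- get_path(i, "coords_csv")
    if (!is.na(p)) {
      res <- run_stage(i, "cone_density", {
        mos <- read_cone_coords(p, config$roi_width_um, config$roi_height_um,
                                as.character(manifest$id[i]))
        map <- density_map(mos, config$window_side_um, config$grid_step_um)
        met <- cdc(map, config$fraction, config$cdc_weighted)
        list(map = map, met = met)
      })
      if (!is.null(res)) {
        maps[[i]] <- res$map
        metrics[[i]] <- res$met
        cohort$pcd[i] <- res$met$pcd
        cohort$cdc_density[i] <- res$met$cdc_density
      }
    }
    p <- get_path(i, "seg_csv")
    if (!is.na(p)) {
      res <- run_stage(i, "onl_profile", {
        seg <- read_segmentation(p)
        onl_metrics(seg, config$x_step_um, config$central_width_um,
                    config$max_search_halfwidth_um,
                    config$search_halfwidth_um)
      })
      if (!is.null(res)) {
        cohort$max_onl_um[i] <- res$max_onl_um
        cohort$central_onl_um[i] <- res$central_onl_um
      }
    }
    p <- get_path(i, "thickness_csv")
    if (!is.na(p)) {
      res <- run_stage(i, "pit_morphometry", {
        map <- read_thickness_map(p, participant_id =
                                    as.character(manifest$id[i]))
        pit_metrics(map, config$n_angles, config$radial_step_um,
                    config$max_radius_um, config$smooth_halfwidth,
                    config$prominence_um, config$pit_search_radius_um)
      })
      if (!is.null(res)) {
        cohort$pit_diameter_mm[i] <- res$diameter_mm
        cohort$pit_volume_mm3[i] <- res$volume_mm3
      }
    }
    p <- get_path(i, "mask_png")
    if (!is.na(p)) {
      res <- run_stage(i, "faz_morphometry", {
        vm <- read_vessel_mask(p, participant_id =
                                 as.character(manifest$id[i]))
        faz_area(vm, config$central_radius_um, config$ratio_threshold)
      })
      if (!is.null(res)) {
        cohort$faz_area_mm2[i] <- res$faz_area_mm2
        cohort$fragmented[i] <- res$fragmented
      }
    }
  }
  # areal density over the cohort-common CDC-aligned area
  have <- which(!vapply(maps, is.null, TRUE))
  common_width <- NA_real_
  if (length(have) > 0) {
    ar <- tryCatch(
      areal_foveal_density(maps[have], metrics[have], config$fraction),
      error = function(e) {
        note("cohort", "areal_density", paste("ERROR:", conditionMessage(e)))
        NULL
      })
    if (!is.null(ar)) {
      cohort$areal_density[have] <- ar$areal$areal_density
      common_width <- ar$common_width_um
    }
  }
  summary_tab <- cohort_summary(cohort, setdiff(names(cohort),
                                                c("participant_id",
                                                  "fragmented")))
  pairs <- default_metric_pairs()
  usable <- apply(pairs, 1, function(pr)
    sum(is.finite(cohort[[pr[1]]]) & is.finite(cohort[[pr[2]]])) >= 4)
  correlations <- NULL
  if (any(usable))
    correlations <- suppressMessages(
      correlation_matrix(cohort, pairs[usable, , drop = FALSE]))
  result <- list(cohort = cohort, summary = summary_tab,
                 correlations = correlations,
                 common_width_um = common_width, log = log,
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    write.csv(summary_tab, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    if (!is.null(correlations))
      write.csv(correlations, file.path(out_dir, "correlations.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("foveamorph")),
           config = unclass(config), common_width_um = common_width,
           log = log),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(result)
}
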