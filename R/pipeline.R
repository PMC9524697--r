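# End-to-end orchestration: mesh or contour set -> per-level asymmetry
# table -> whole-torso and apex summaries, plus report IO and comparison.

#' Default analysis configuration
#'
#' @param separation backside anchor separation in degrees (default 70).
#' @param sp_offset assumed spinous-process length in mm (default 40).
#' @param sp_search posterior SP search sector, geometric degrees.
#' @param sp_smooth SP pre-filter window in degrees (0 = off).
#' @param apex_range character vector of levels forming the apex region
#'   (may be empty; the summaries then report NA). Defaults to empty:
#'   choosing the apex region is an operator decision.
#' @param masks named list (by level) of angular mask lists for
#'   [exclude_sector].
#' @param up_axis,anterior_axis mesh axis conventions for [load_mesh].
#' @return a named list of class `torso_config`.
#' @export
default_config <- function(separation = 70, sp_offset = 40,
                           sp_search = c(-150, -30), sp_smooth = 0,
                           apex_range = character(0), masks = list(),
                           up_axis = "z", anterior_axis = "y") {
  structure(list(separation = separation, sp_offset = sp_offset,
                 sp_search = sp_search, sp_smooth = sp_smooth,
                 apex_range = apex_range, masks = masks,
                 up_axis = up_axis, anterior_axis = anterior_axis),
            class = "torso_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognized keys match the arguments of [default_config], plus an optional
#' `landmarks` block (`c7`, `t8`, `l5` heights in mm) used when assessing a
#' mesh. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `torso_config`; landmarks, when present, are attached as the
#'   `landmarks` attribute.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  known <- names(formals(default_config))
  extra <- setdiff(names(y), c(known, "landmarks"))
  if (length(extra))
    validation_error(paste0("unknown config keys: ", paste(extra, collapse = ", ")))
  lm <- y$landmarks
  y$landmarks <- NULL
  if (!is.null(y$sp_search)) y$sp_search <- as.numeric(unlist(y$sp_search))
  cfg <- do.call(default_config, y)
  if (!is.null(lm)) attr(cfg, "landmarks") <- unlist(lm)
  cfg
}

#' Run a full torso assessment
#'
#' Processes every vertebral level independently: each transverse contour is
#' masked (if configured), converted to centroid-origin polar form, aligned
#' on the spinous-process dip, resampled to the 1-degree grid, and scored
#' with the per-slice asymmetry parameters. A failure at one level is
#' recorded as a warning and does not abort the run.
#'
#' @param x input torso: a named list of [raw_contour] (names = level
#'   labels), a `synthetic_torso` from [generate_torso], or a [torso_mesh]
#'   (then `landmarks` is required and contours are cut with
#'   [extract_slice]).
#' @param config a `torso_config` (default [default_config()]).
#' @param landmarks c7/t8/l5 heights (mm), required for mesh input.
#' @return object of class `assessment_report`: list with `per_level` (data
#'   frame, one row per processed level), `profiles` (named list of
#'   `slice_asymmetry`), `summary_all`, `summary_apex` (named numeric means
#'   of backside_area_asym, lr_area_asym, r_squared_full), `apex_range`,
#'   `config`, `warnings`, `version`.
#' @export
run_assessment <- function(x, config = default_config(), landmarks = NULL) {
  if (inherits(x, "synthetic_torso")) {
    contours <- x$contours
  } else if (inherits(x, "torso_mesh")) {
    if (is.null(landmarks)) landmarks <- attr(config, "landmarks")
    if (is.null(landmarks))
      validation_error("mesh input requires c7/t8/l5 landmark heights")
    lv <- interpolate_levels(landmarks)
    contours <- list()
    for (i in seq_len(nrow(lv))) {
      l <- as.character(lv$level[i])
      contours[[l]] <- tryCatch(extract_slice(x, lv$height[i], level = l),
                                error = function(e) e)
    }
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "raw_contour"))) {
    if (is.null(names(x)) || !all(names(x) %in% LEVEL_LABELS))
      validation_error("contour list must be named by vertebral level labels")
    contours <- x
  } else {
    validation_error("input must be a contour list, synthetic_torso or torso_mesh")
  }

  run_warnings <- character(0)
  profiles <- list()
  levels_present <- intersect(LEVEL_LABELS, names(contours))
  missing_levels <- setdiff(LEVEL_LABELS, levels_present)
  if (length(missing_levels))
    run_warnings <- c(run_warnings, paste0(
      "levels absent from input: ", paste(missing_levels, collapse = ", ")))
  for (l in levels_present) {
    ct <- contours[[l]]
    if (inherits(ct, "error")) {
      run_warnings <- c(run_warnings,
                        sprintf("level %s: %s", l, conditionMessage(ct)))
      next
    }
    res <- tryCatch(
      analyze_contour(ct,
                      separation = config$separation,
                      sp_offset = config$sp_offset,
                      sp_search = config$sp_search,
                      sp_smooth = config$sp_smooth,
                      masks = if (!is.null(config$masks[[l]])) config$masks[[l]] else list()),
      error = function(e) e)
    if (inherits(res, "error")) {
      run_warnings <- c(run_warnings,
                        sprintf("level %s: %s", l, conditionMessage(res)))
    } else {
      res$level <- l
      profiles[[l]] <- res
      w <- torso_warnings(res)
      if (length(w)) run_warnings <- c(run_warnings, paste0("level ", l, ": ", w))
    }
  }
  if (length(profiles) == 0) run_error("no vertebral level could be processed")

  per_level <- do.call(rbind, lapply(profiles, function(s) data.frame(
    level = s$level,
    r_squared_full = s$r_squared_full,
    r_squared_backside = s$r_squared_backside,
    slope_full = s$slope_full,
    la = s$la, ra = s$ra,
    lr_area_asym = s$lr_area_asym,
    backside_area_asym = s$backside_area_asym,
    mean_radius = s$mean_radius,
    rotation_applied = s$rotation_applied)))
  per_level <- per_level[order(level_index(per_level$level)), ]
  rownames(per_level) <- NULL

  sums <- summarize_assessment(per_level, config$apex_range)
  structure(list(per_level = per_level, profiles = profiles,
                 summary_all = sums$summary_all,
                 summary_apex = sums$summary_apex,
                 apex_range = config$apex_range,
                 config = config, warnings = run_warnings,
                 version = as.character(utils::packageVersion("torsometry"))),
            class = "assessment_report")
}

#' Whole-torso and apex-region summaries
#'
#' Arithmetic means of the backside area asymmetry, the left-right area
#' asymmetry and the full-side R-squared, over all processed levels and over
#' the configured apex region. An empty apex range yields NA apex summaries
#' (the apex region is selected from the clinical curvature, which pure
#' surface data does not determine).
#'
#' @param per_level per-level data frame from an [assessment_report].
#' @param apex_range character vector of levels (contiguous subset of
#'   C7..L5), possibly empty.
#' @return list with `summary_all` and `summary_apex`, each a named numeric
#'   vector `backside_area_asym`, `lr_area_asym`, `r_squared_full`.
#' @export
summarize_assessment <- function(per_level, apex_range = character(0)) {
  cols <- c("backside_area_asym", "lr_area_asym", "r_squared_full")
  mean_of <- function(df) {
    if (nrow(df) == 0) return(stats::setNames(rep(NA_real_, 3), cols))
    vapply(df[cols], mean, 0)
  }
  if (length(apex_range)) {
    ai <- sort(level_index(apex_range))
    if (length(ai) > 1 && !all(diff(ai) == 1))
      validation_error("apex_range must be a contiguous run of levels")
    apex_df <- per_level[per_level$level %in% apex_range, , drop = FALSE]
  } else {
    apex_df <- per_level[0, , drop = FALSE]
  }
  list(summary_all = mean_of(per_level), summary_apex = mean_of(apex_df))
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("assessment_report: %d levels processed\n", nrow(x$per_level)))
  cat(sprintf("  mean R^2 (full)        : %.4f\n", x$summary_all["r_squared_full"]))
  cat(sprintf("  mean LR area asymmetry : %.4f\n", x$summary_all["lr_area_asym"]))
  cat(sprintf("  mean backside asymmetry: %.4f\n", x$summary_all["backside_area_asym"]))
  if (length(x$apex_range))
    cat(sprintf("  apex region %s: LR asym %.4f, R^2 %.4f\n",
                paste(range(x$apex_range), collapse = ".."),
                x$summary_apex["lr_area_asym"], x$summary_apex["r_squared_full"]))
  if (length(x$warnings))
    cat(sprintf("  %d warning(s); see $warnings\n", length(x$warnings)))
  invisible(x)
}

#' Compare two assessment reports level by level
#'
#' Differences (b minus a) of the three asymmetry parameters at every level
#' covered by both reports, plus the corresponding summary differences --
#' the follow-up use case: has the torso become more or less asymmetric
#' since the previous scan?
#'
#' @param report_a,report_b two `assessment_report` objects.
#' @return list with `per_level` (data frame of deltas) and `summary_all`
#'   (named numeric deltas of the whole-torso means over shared levels).
#' @export
compare_reports <- function(report_a, report_b) {
  shared <- intersect(report_a$per_level$level, report_b$per_level$level)
  if (length(shared) == 0)
    validation_error("reports cover disjoint level sets")
  cols <- c("r_squared_full", "lr_area_asym", "backside_area_asym")
  a <- report_a$per_level[match(shared, report_a$per_level$level), ]
  b <- report_b$per_level[match(shared, report_b$per_level$level), ]
  d <- data.frame(level = shared)
  for (cc in cols) d[[paste0("d_", cc)]] <- b[[cc]] - a[[cc]]
  list(per_level = d,
       summary_all = vapply(cols, function(cc) mean(b[[cc]]) - mean(a[[cc]]), 0))
}

#' Write an assessment report to disk
#'
#' Writes `per_level.csv` (one row per level), `report.json` (per-level
#' table, summaries, configuration, warnings) and, optionally,
#' `profiles.csv` in long format (level, angle_offset, side, rr, dist_vb)
#' for the backside profiles.
#'
#' @param report an `assessment_report`.
#' @param dir output directory (created if absent).
#' @param profiles write the long-format backside profile CSV (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, profiles = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_level, file.path(dir, "per_level.csv"),
                   row.names = FALSE)
  obj <- list(per_level = report$per_level,
              summary_all = as.list(report$summary_all),
              summary_apex = as.list(report$summary_apex),
              apex_range = report$apex_range,
              config = unclass(report$config),
              warnings = report$warnings,
              version = report$version)
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  if (profiles) {
    long <- do.call(rbind, lapply(report$profiles, function(s) {
      k <- length(s$dist_vb_right)
      rbind(
        data.frame(level = s$level, angle_offset = 0:(k - 1), side = "right",
                   rr = s$rad_back_right, dist_vb = s$dist_vb_right),
        data.frame(level = s$level, angle_offset = 0:(k - 1), side = "left",
                   rr = s$rad_back_left, dist_vb = s$dist_vb_left))
    }))
    utils::write.csv(long, file.path(dir, "profiles.csv"), row.names = FALSE)
  }
  invisible(dir)
}
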