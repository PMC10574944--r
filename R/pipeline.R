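#' Run the full climbing-analysis pipeline
#'
#' Chains wall calibration (or an already-fitted wall model), wall-space
#' transform, route delimitation, key-joint motion segmentation, phase
#' classification, error detection (with the DTW-referenced hip rule when a
#' reference climb is supplied), and optionally evaluation against labelled
#' ground truth. Deterministic given the config (its seed drives RANSAC).
#'
#' @param sequence camera- or wall-space [skeleton_sequence()], or a path
#'   readable by [read_sequence()].
#' @param wall a `wall_model`, a path to a wall-model JSON, or `NULL` when
#'   `cloud` is given or the sequence is already in wall space.
#' @param cloud optional calibration point cloud (`n x 3` matrix or PLY
#'   path) used to fit the wall when no model is supplied.
#' @param reference optional reference climb (sequence or path) for the
#'   hip-close-to-the-wall rule.
#' @param labels optional ground-truth labels (data frame or JSON path);
#'   when present the report gains per-type precision-recall curves.
#' @param config a [pipeline_config()].
#' @param verbose emit per-stage progress messages to stderr.
#' @return A `pipeline_report`: `limits`, `phases`, `report`
#'   (the [detect_errors()] result), `evaluation` (per-type [pr_curve()]s
#'   or `NULL`), `config`.
#' @export
run_pipeline <- function(sequence, wall = NULL, cloud = NULL, reference = NULL,
                         labels = NULL, config = pipeline_config(),
                         verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS2"), sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      ct_stop("stage_failure", "stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (is.character(sequence)) sequence <- stage("read", read_sequence(sequence))
  if (is.character(wall)) wall <- stage("read_wall", read_wall_model(wall))
  if (is.character(cloud)) cloud <- stage("read_cloud", read_ply(cloud))
  if (is.character(reference)) reference <- stage("read_ref", read_sequence(reference))
  if (is.character(labels)) labels <- stage("read_labels", read_labels(labels))

  if (sequence$space == "camera") {
    if (is.null(wall)) {
      if (is.null(cloud))
        ct_stop("stage_failure", "stage 'calibrate' failed: camera-space input needs a wall model or a calibration cloud")
      say("calibrating wall from %d points", nrow(cloud))
      wall <- stage("calibrate",
                    build_wall_model(cloud, config$ransac_iterations,
                                     config$ransac_tol, seed = config$seed))
    }
    sequence <- stage("to_wall", to_wall_coords(sequence, wall))
  }
  if (!is.null(reference) && reference$space == "camera") {
    if (is.null(wall))
      ct_stop("stage_failure", "stage 'to_wall' failed: camera-space reference needs a wall model")
    reference <- stage("to_wall_ref", to_wall_coords(reference, wall))
  }

  say("delimiting route over %d frames", length(sequence))
  limits <- stage("delimit", delimit_route(sequence))
  say("route [%d, %d)", limits$start, limits$end)
  motion <- stage("segment", segment_key_joints(sequence, config))
  phases <- stage("phases", segment_phases(sequence, motion, limits,
                                           config$min_phase_frames))
  say("%d phase instances", nrow(phases))
  coupling <- NULL
  if (!is.null(reference))
    coupling <- stage("align", align_climbs(reference, sequence,
                                            query_limits = limits))
  report <- stage("analyze",
                  detect_errors(sequence, phases, motion, limits, config,
                                reference = reference, coupling = coupling))
  evaluation <- NULL
  if (!is.null(labels) && nrow(labels) > 0)
    evaluation <- stage("evaluate", evaluate_report(report, labels))
  structure(list(limits = limits, phases = phases, motion = motion,
                 report = report, evaluation = evaluation,
                 wall = wall, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> route [%d, %d), %d phases\n",
              x$limits$start, x$limits$end, nrow(x$phases)))
  print(x$report)
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' The JSON is deterministic: rerunning the pipeline with the same inputs,
#' config and seed writes identical bytes. Events carry absolute
#' (full-recording) frame indices.
#'
#' @param result a [run_pipeline()] report.
#' @param path output path; `NULL` returns the JSON string.
#' @export
write_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_report"))
  rep <- result$report
  doc <- list(
    route = list(start = result$limits$start, end = result$limits$end),
    phases = result$phases,
    events = rep$events,
    per_phase = rep$per_phase,
    totals = as.list(rep$totals),
    evaluated = as.list(rep$evaluated),
    hints = ERROR_HINTS[names(which(rep$totals > 0))],
    config = unclass(result$config)
  )
  if (!is.null(result$evaluation)) {
    doc$evaluation <- lapply(result$evaluation, function(pc)
      list(points = pc$points, optimal = pc$optimal))
  }
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

# Human-readable improvement hints shown with a non-zero error count.
ERROR_HINTS <- c(
  decoupling = "Keep the holding arm straight while you set your feet; hang from the skeleton, not the biceps.",
  reaching_hand_supports = "Keep the supporting hand on its hold while standing up; reach in one decisive move.",
  weight_shift = "Shift the hips over the supporting leg so the knee passes in front of that foot before standing.",
  both_feet_set = "Place or press both feet on the wall before standing up; a dangling foot wastes arm strength.",
  hip_close_to_wall = "Bring the hips closer to the wall during the reach so the weight stays over the toes.",
  shoulder_relaxing = "After the grip, stretch the new holding arm and lower the body to rest."
)

#' Frame-level phase agreement
#'
#' Fraction of frames on which a detected phase table and a ground-truth
#' table assign the same phase kind, over the intersection of their covered
#' ranges (optionally clipped to route limits).
#'
#' @param phases,phases_gt phase tables (`kind`, `start`, `end`).
#' @param limits optional route limits clipping the comparison.
#' @return Agreement fraction in `[0, 1]`.
#' @export
phase_agreement <- function(phases, phases_gt, limits = NULL) {
  lo <- max(min(phases$start), min(phases_gt$start))
  hi <- min(max(phases$end), max(phases_gt$end))
  if (!is.null(limits)) {
    lo <- max(lo, limits$start)
    hi <- min(hi, limits$end)
  }
  if (hi <= lo) return(NA_real_)
  f <- lo:(hi - 1)
  kind_at <- function(tab) {
    k <- character(length(f))
    for (i in seq_len(nrow(tab))) {
      sel <- f >= tab$start[i] & f < tab$end[i]
      k[sel] <- tab$kind[i]
    }
    k
  }
  mean(kind_at(phases) == kind_at(phases_gt))
}
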