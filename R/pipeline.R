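#' Default run configuration
#'
#' Bundles and validates every tunable of the end-to-end workflow before any
#' work starts.
#'
#' @param thresholds per-segment dilation thresholds, mm.
#' @param window,order Savitzky-Golay smoothing parameters.
#' @param step_mm centerline resampling step, mm.
#' @param plane_extent_mm CPR in-plane field of view, mm.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir optional output directory for persisted artifacts.
#' @param log_level `"info"` or `"quiet"`.
#' @return validated `run_config` list.
#' @export
run_config <- function(thresholds = c(ascending = 40, arch = 35,
                                      descending = 30),
                       window = 11, order = 2, step_mm = 1,
                       plane_extent_mm = 80, seed = 1L, out_dir = NULL,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (window %% 2 != 1 || order >= window)
    stop("invalid smoothing config: window must be odd and > order",
         call. = FALSE)
  if (step_mm <= 0 || plane_extent_mm <= 0)
    stop("step_mm and plane_extent_mm must be > 0", call. = FALSE)
  if (!all(c("ascending", "arch", "descending") %in% names(thresholds)))
    stop("thresholds must name ascending, arch and descending", call. = FALSE)
  structure(list(thresholds = thresholds, window = window, order = order,
                 step_mm = step_mm, plane_extent_mm = plane_extent_mm,
                 seed = as.integer(seed), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

aq_log <- function(config, ...) {
  if (!is.null(config$log_level) && config$log_level == "quiet") return()
  message("[aortaquant] ", ...)
}

# tiny polynomial rolling hash over the deparsed config, for provenance
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config),
                                                  "out_dir")]),
                           collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance <- function(config) {
  list(package = "aortaquant",
       version = as.character(utils::packageVersion("aortaquant")),
       config_hash = config_hash(unclass(config)))
}

stage <- function(config, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  aq_log(config, sprintf("%-12s %6.2f s", name,
                         proc.time()[["elapsed"]] - t0))
  out
}

resolve_landmarks <- function(landmarks, cl) {
  if (inherits(landmarks, "segment_spec")) return(landmarks)
  lmk <- as.list(landmarks)
  if (!is.null(lmk$s_bct) && !is.null(lmk$s_lsa))
    return(segment_spec(lmk$s_bct, lmk$s_lsa))
  if (!is.null(lmk$p_bct) && !is.null(lmk$p_lsa)) {
    # voxel/world coordinates: project onto the centerline
    proj <- function(p) {
      d <- sqrt(rowSums(sweep(cl$points, 2, as.numeric(p))^2))
      cl$arclength[which.min(d)]
    }
    return(segment_spec(proj(lmk$p_bct), proj(lmk$p_lsa)))
  }
  stop("landmarks must provide s_bct/s_lsa arc lengths or p_bct/p_lsa points",
       call. = FALSE)
}

#' Run the full quantification workflow on one mask
#'
#' Endpoint detection, first/farthest inlet-outlet selection, centerline
#' extraction, rotation-minimizing frames, curved planar reformation,
#' per-slice profiles with Savitzky-Golay smoothing, segment subdivision at
#' the supplied landmarks, summaries and dilation flags — the whole chain the
#' package exists for. Deterministic given identical inputs and config.
#'
#' @param mask binary [image_volume] or a path readable by [read_volume()].
#' @param landmarks a [segment_spec()], a `list(s_bct=, s_lsa=)` of landmark
#'   arc lengths (mm), a `list(p_bct=, p_lsa=)` of world points projected
#'   onto the centerline, or a path to a JSON file with those fields.
#' @param config a [run_config()].
#' @return list with `report` (quant_report incl. `dilated`, `thresholds`),
#'   `profile`, `centerline`, `straightened`, `provenance`. If
#'   `config$out_dir` is set, writes `report.json` and `profile.csv` there.
#' @export
run_quantify <- function(mask, landmarks, config = run_config()) {
  if (is.character(landmarks)) {
    if (!file.exists(landmarks))
      stop("landmark file does not exist: ", landmarks, call. = FALSE)
    landmarks <- jsonlite::read_json(landmarks, simplifyVector = TRUE)
  }
  if (is.character(mask)) mask <- stage(config, "read", read_volume(mask))
  stopifnot_volume(mask)
  # the workflow operates on a uniform 1 mm^3 grid; thick-slice masks are
  # resampled up front so skeleton topology does not suffer from staircase
  # terraces (label-preserving nearest interpolation)
  if (max(mask$spacing) / min(mask$spacing) > 1.01 ||
      abs(max(mask$spacing) - 1) > 0.5)
    mask <- stage(config, "resample", resample_isotropic(mask, 1, "nearest"))

  cand <- stage(config, "endpoints", detect_endpoints(mask))
  io <- stage(config, "select", select_inlet_outlet(cand))
  cl <- stage(config, "centerline",
              extract_centerline(mask, io$inlet, io$outlet,
                                 step_mm = config$step_mm))
  frames <- stage(config, "frames", compute_frames(cl))
  sv <- stage(config, "straighten",
              curved_planar_reformat(mask, cl, frames,
                                     plane_extent_mm = config$plane_extent_mm,
                                     interp = "nearest"))
  prof <- stage(config, "profile",
                profile_from_straightened(sv, window = config$window,
                                          order = config$order))
  seg <- resolve_landmarks(landmarks, cl)
  report <- stage(config, "summarize", summarize_segments(prof, seg))
  report$dilated <- detect_dilation(report, config$thresholds)
  report$thresholds <- as.list(config$thresholds)
  prov <- provenance(config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(c(unclass(report), list(provenance = prov)),
                         file.path(config$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE)
    df <- as.data.frame(prof)
    idx <- subdivide_segments(prof, seg)
    df$segment <- NA_character_
    for (nm in names(idx)) df$segment[idx[[nm]]] <- nm
    utils::write.csv(df, file.path(config$out_dir, "profile.csv"),
                     row.names = FALSE)
  }
  list(report = report, profile = prof, centerline = cl, straightened = sv,
       segments = seg, provenance = prov)
}

#' Paired-cohort experiment: quantify both arms and validate against truth
#'
#' Generates a paired contrast / non-contrast phantom cohort
#' ([make_paired_cohort()]), runs [run_quantify()] on both arms of every
#' case using the truth landmark arc lengths, then computes per-arm
#' agreement of the measured vs true max lumen diameter (Pearson, ICC,
#' Bland-Altman), per-arm ROC of the measured ascending max diameter against
#' the truth dilation labels, and Bland-Altman between the two arms. Cases
#' whose quantification fails are recorded and skipped; more than 20%
#' failures aborts.
#'
#' @param config a [run_config()]; its seed drives the cohort.
#' @param n cohort size (>= 10 for meaningful statistics).
#' @param wall_mm non-contrast wall thickness, mm.
#' @return list with `cases` (per-case data.frame), `agreement` (per arm),
#'   `roc` (per arm), `between_arms` (Bland-Altman of max diameters),
#'   `failures`, `provenance`. With `config$out_dir` set, writes
#'   `experiment.json` and `cases.csv`.
#' @export
run_paired_experiment <- function(config = run_config(), n = 20,
                                  wall_mm = 2) {
  if (n < 10) stop("'n' must be >= 10", call. = FALSE)
  cohort <- stage(config, "cohort",
                  make_paired_cohort(n, seed = config$seed,
                                     thresholds = config$thresholds,
                                     wall_mm = wall_mm))
  rows <- list()
  failures <- character(0)
  qconfig <- config
  qconfig$out_dir <- NULL
  for (i in seq_len(n)) {
    case <- cohort[[i]]
    lm <- case$truth$landmark_arclengths
    if (length(lm) < 2) {
      R <- case$truth$spec$ring_radius_mm
      lm <- case$truth$spec$asc_mm + pi * R * c(0.35, 0.65)
    }
    res <- tryCatch({
      qc <- run_quantify(case$contrast_mask,
                         list(s_bct = lm[1], s_lsa = lm[2]), qconfig)
      qn <- run_quantify(case$noncontrast_mask,
                         list(s_bct = lm[1], s_lsa = lm[2]), qconfig)
      data.frame(
        case = i,
        true_max = case$truth$max_diameter_mm[["whole"]],
        true_asc_max = case$truth$max_diameter_mm[["ascending"]],
        true_dilated_asc = isTRUE(case$truth$dilated$ascending),
        contrast_max = qc$report$whole$diameter_max,
        contrast_asc_max = qc$report$ascending$diameter_max,
        contrast_desc_max = qc$report$descending$diameter_max,
        noncontrast_max = qn$report$whole$diameter_max,
        noncontrast_asc_max = qn$report$ascending$diameter_max,
        noncontrast_desc_max = qn$report$descending$diameter_max,
        contrast_flag_asc = isTRUE(qc$report$dilated$ascending),
        noncontrast_flag_asc = isTRUE(qn$report$dilated$ascending))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("case %d: %s", i, res))
      aq_log(config, "case ", i, " FAILED: ", res)
    } else {
      rows[[length(rows) + 1]] <- res
      aq_log(config, sprintf("case %2d/%d done", i, n))
    }
  }
  if (length(failures) > 0.2 * n)
    stop("more than 20% of cases failed:\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  cases <- do.call(rbind, rows)

  arm_stats <- function(meas) {
    list(pearson = pearson_ci(meas, cases$true_max),
         icc = icc(meas, cases$true_max),
         bland_altman = bland_altman(meas, cases$true_max))
  }
  roc_arm <- function(scores) {
    r <- roc_auc(scores, cases$true_dilated_asc, ci_boot = 500,
                 seed = config$seed)
    list(auc = r$auc, ci = r$ci, operating_point = youden_optimal(r))
  }
  out <- list(
    cases = cases,
    agreement = list(contrast = arm_stats(cases$contrast_max),
                     noncontrast = arm_stats(cases$noncontrast_max)),
    roc = list(contrast = roc_arm(cases$contrast_asc_max),
               noncontrast = roc_arm(cases$noncontrast_asc_max)),
    between_arms = list(
      whole_max = bland_altman(cases$noncontrast_max, cases$contrast_max),
      descending_max = bland_altman(cases$noncontrast_desc_max,
                                    cases$contrast_desc_max)),
    failures = failures,
    provenance = provenance(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(out[setdiff(names(out), "cases")],
                         file.path(config$out_dir, "experiment.json"),
                         digits = NA, auto_unbox = TRUE)
    utils::write.csv(cases, file.path(config$out_dir, "cases.csv"),
                     row.names = FALSE)
  }
  out
}
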