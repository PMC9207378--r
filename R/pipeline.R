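#' Batch-process report pages and curve tables into an index table
#'
#' Runs the full chain — locate panel, calibrate axes, trace, compute
#' indices — on each input independently: report page images (PNG/TIFF, or
#' in-memory [ReportPage-class] objects) go through the digitizer, curve
#' CSVs (and [ExpiratoryCurve-class] objects) skip straight to the index
#' computation. A failure on one input is recorded in the manifest
#' (statuses \code{panel-not-found}, \code{trace-failed},
#' \code{calibration-failed}, \code{degenerate-curve}, \code{error}) and
#' never aborts the batch. Inputs named in \code{metadata} with
#' FEV1/FVC <= 0.7 are excluded up front (status \code{excluded}); the
#' tool never reads those values off the report itself. Output rows are
#' ordered by input position, so a batch is fully deterministic.
#'
#' @param inputs character vector of paths (images or curve CSVs), or a
#'   list mixing paths, ReportPage and ExpiratoryCurve objects.
#' @param config named list of settings: \code{hashThreshold} (default 4),
#'   \code{intensityThreshold} (128), \code{aspect} (1), \code{bFraction}
#'   (0.75), \code{margin} (panel expansion margins).
#' @param label,digit glyph templates for the digitizer (defaults:
#'   [fvlLabelTemplate()], [fvlDigitTemplate()]).
#' @param metadata optional data.frame with columns \code{source_id} and
#'   \code{fev1_fvc}: the proximal-obstruction filter (only curves with
#'   FEV1/FVC > 0.7 are indexed) applied when the values are supplied.
#' @return list with \code{indices} (data.frame, one row per successful
#'   input) and \code{manifest} (list: tool version, config hash, per-input
#'   status data.frame, status counts). Status counts always sum to the
#'   number of inputs.
#' @examples
#' out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60,
#'                                thetaBc = 35))
#' res <- runBatch(list(out$curve))
#' res$manifest$counts
#' @export
runBatch <- function(inputs, config = list(), label = fvlLabelTemplate(),
                     digit = fvlDigitTemplate(), metadata = NULL) {
  if (length(inputs) == 0L)
    .fvlStop("fvlInvalidInput", "inputs must be non-empty")
  if (!is.list(inputs)) inputs <- as.list(inputs)
  cfg <- utils::modifyList(
    list(hashThreshold = 4L, intensityThreshold = 128, aspect = 1,
         bFraction = 0.75, margin = c(10, 10, 300, 290)),
    config)
  ids <- vapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (is.character(x)) x
    else if (is(x, "ReportPage")) x@sourceId
    else sprintf("input_%03d", i)
  }, character(1))

  statuses <- character(length(inputs))
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    id <- ids[i]
    if (!is.null(metadata)) {
      hit <- match(id, metadata$source_id)
      if (!is.na(hit) && is.finite(metadata$fev1_fvc[hit]) &&
          metadata$fev1_fvc[hit] <= 0.7) {
        statuses[i] <- "excluded"
        next
      }
    }
    res <- tryCatch({
      curve <- .asCurve(inputs[[i]], cfg, label, digit)
      idx <- computeIndices(curve, aspect = cfg$aspect,
                            bFraction = cfg$bFraction)
      list(status = "ok", row = indicesRow(idx, sourceId = id))
    },
    fvlPanelNotFound = function(e) list(status = "panel-not-found"),
    fvlCalibrationFailed = function(e) list(status = "calibration-failed"),
    fvlTraceFailed = function(e) list(status = "trace-failed"),
    fvlDegenerateCurve = function(e) list(status = "degenerate-curve"),
    error = function(e) list(status = "error",
                             message = conditionMessage(e)))
    statuses[i] <- res$status
    if (res$status == "ok") rows[[i]] <- res$row
  }
  indices <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(indices))
    indices <- data.frame(source_id = character(), angle_abc_deg = numeric(),
                          angle_bcx_deg = numeric(),
                          log_bc_over_ax = numeric(),
                          peak_flow_lps = numeric(), fvc_l = numeric(),
                          ab_slope = numeric(), ab_rmse = numeric(),
                          bc_slope = numeric(), bc_rmse = numeric(),
                          stringsAsFactors = FALSE)
  manifest <- list(
    tool = "fvlSAD",
    version = as.character(utils::packageVersion("fvlSAD")),
    configHash = .fnv1a(.configString(cfg)),
    nInputs = length(inputs),
    status = data.frame(source_id = ids, status = statuses,
                        stringsAsFactors = FALSE),
    counts = as.list(table(statuses)))
  list(indices = indices, manifest = manifest)
}

# Resolve one batch input to an ExpiratoryCurve, digitizing pages.
.asCurve <- function(x, cfg, label, digit) {
  if (is(x, "ExpiratoryCurve")) return(x)
  if (is.character(x)) {
    ext <- tolower(tools::file_ext(x))
    if (ext == "csv") return(readCurve(x))
    x <- readReportPage(x)
  }
  stopifnot(is(x, "ReportPage"))
  region <- locatePanel(x, label, threshold = cfg$hashThreshold,
                        margin = cfg$margin)
  cal <- calibrateAxes(x, region, digit, threshold = cfg$hashThreshold,
                       intensityThreshold = cfg$intensityThreshold)
  traceCurve(x, region, cal, intensityThreshold = cfg$intensityThreshold)
}

#' Write a run manifest as JSON
#'
#' @param manifest the manifest from [runBatch()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
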