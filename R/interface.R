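# File-level workflow wrappers: segment an image file into artifacts, score
# mask files, and run the model comparison over the synthetic suite.  These
# back the shell interface in inst/cli/lfac.

#' Segment an image file and write the result artifacts
#'
#' Runs [fac()] or [lfac()] on a raster file and writes, into `out_dir`:
#' `mask.png` (8-bit, 0/255), `membership.tif` (32-bit float),
#' `trace.csv` (per-iteration energy, band size, accepted updates) and
#' `report.json` (the fully resolved parameter set plus iteration count,
#' final energy, and — when `truth` is supplied — the `p_mp` score). The run
#' is fully reproducible from the report.
#'
#' @param input image path (PNG/TIFF/PGM), or a numeric matrix.
#' @param out_dir output directory (created if missing).
#' @param ... model parameters passed on to [lfac()] / [fac()]. Arguments
#'   after `...` must be given by full name (the short model parameter `m`
#'   would otherwise partially match `model`).
#' @param model `"lfac"` or `"fac"`.
#' @param truth optional ground-truth mask (path or matrix) for scoring.
#' @param init optional init mask path or matrix (see [fac()]).
#' @return the fitted model, invisibly; artifacts on disk as a side effect.
#' @export
segment_image <- function(input, out_dir, ..., model = c("lfac", "fac"),
                          truth = NULL, init = NULL) {
  model <- match.arg(model)
  img <- if (is.character(input)) read_gray_image(input) else as_gray_image(input)
  if (is.character(init)) init <- read_mask(init)
  fit <- if (model == "lfac") lfac(img, init = init, ...)
         else fac(img, init = init, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mask_png(fit$mask, file.path(out_dir, "mask.png"))
  write_membership_tiff(fit$membership, file.path(out_dir, "membership.tif"))
  tr <- data.frame(iteration = seq_along(fit$energy_trace),
                   energy = fit$energy_trace,
                   band = fit$band_trace,
                   accepted = fit$accepted_trace)
  utils::write.csv(tr, file.path(out_dir, "trace.csv"), row.names = FALSE)
  report <- list(model = model, params = fit$params, dim = fit$dim,
                 iterations = fit$iterations, converged = fit$converged,
                 reason = fit$reason, final_energy = fit$energy,
                 updates = fit$updates)
  if (!is.null(truth)) {
    if (is.character(truth)) truth <- read_mask(truth)
    report$p_mp <- p_mp(truth, fit)
  }
  writeLines(simple_json(report), file.path(out_dir, "report.json"))
  invisible(fit)
}

#' Score two mask rasters
#'
#' @param truth_path,predicted_path mask raster paths (any intensity above
#'   half scale counts as object).
#' @return the [p_mp()] percentage.
#' @export
score_masks <- function(truth_path, predicted_path) {
  p_mp(read_mask(truth_path), read_mask(predicted_path))
}

#' Compare FAC and LFAC over a scene list
#'
#' Fits each requested model on each scene and tabulates the
#' percentage-of-mislabelled-pixels score (reported to two decimals), the
#' iteration count and the total number of pixel updates. Per-scene failures
#' are recorded (`NA` score) and the run continues.
#'
#' @param scenes named list of scenes (`image` + `truth`), e.g.
#'   [scene_suite()]. An empty list gives an empty table.
#' @param ... parameters forwarded to the model fits. Arguments after `...`
#'   must be given by full name.
#' @param models character vector out of `"fac"`, `"lfac"`.
#' @return data frame with one row per scene x model: `scene`, `model`,
#'   `p_mp`, `iterations`, `updates`, `converged`.
#' @examples
#' \donttest{
#' benchmark_models(scene_suite(seed = 1))
#' }
#' @export
benchmark_models <- function(scenes, ..., models = c("fac", "lfac")) {
  models <- match.arg(models, several.ok = TRUE)
  rows <- list()
  for (sn in names(scenes)) {
    for (md in models) {
      res <- tryCatch({
        fit <- if (md == "lfac") lfac(scenes[[sn]]$image, ...)
               else fac(scenes[[sn]]$image, ...)
        data.frame(scene = sn, model = md,
                   p_mp = round(p_mp(scenes[[sn]]$truth, fit), 2),
                   iterations = fit$iterations, updates = fit$updates,
                   converged = fit$converged)
      }, error = function(e) {
        warning(sprintf("scene %s / model %s failed: %s",
                        sn, md, conditionMessage(e)), call. = FALSE)
        data.frame(scene = sn, model = md, p_mp = NA_real_,
                   iterations = NA_integer_, updates = NA_integer_,
                   converged = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L)
    return(data.frame(scene = character(), model = character(),
                      p_mp = numeric(), iterations = integer(),
                      updates = integer(), converged = logical()))
  do.call(rbind, rows)
}

# Minimal JSON writer for the run report (scalars, vectors, nested lists);
# avoids a hard dependency for one artifact.
simple_json <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  if (is.list(x)) {
    items <- vapply(names(x), function(nm) {
      sprintf("%s  \"%s\": %s", pad, nm, simple_json(x[[nm]], indent + 2))
    }, character(1))
    sprintf("{\n%s\n%s}", paste(items, collapse = ",\n"), pad)
  } else if (is.character(x)) {
    if (length(x) == 1L) sprintf("\"%s\"", x)
    else sprintf("[%s]", paste(sprintf("\"%s\"", x), collapse = ", "))
  } else if (is.logical(x)) {
    v <- ifelse(x, "true", "false")
    if (length(x) == 1L) v else sprintf("[%s]", paste(v, collapse = ", "))
  } else {
    v <- vapply(x, function(e) sprintf("%.17g", e), character(1))
    if (length(x) == 1L) v else sprintf("[%s]", paste(v, collapse = ", "))
  }
}
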