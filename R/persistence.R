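# Model persistence: a directory bundle with a plain-text manifest (scheme,
# strategy, decision, algorithm, weighting, format version) plus the
# serialized base models.

.bundle_format <- "incidenttriage-bundle-1"

#' Save / load a fitted ensemble as a directory bundle
#'
#' The bundle holds `manifest.json` (format version, scheme, strategy,
#' decision, algorithm, weighting) and the serialized base models with
#' their vocabularies and calibrations.
#'
#' @param ensemble A fitted `incident_ensemble`.
#' @param path Bundle directory (created if needed).
#' @return `save_ensemble`: `path`, invisibly; `load_ensemble`: the
#'   restored `incident_ensemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "incident_ensemble"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(format = .bundle_format,
         labels = ensemble$scheme$labels,
         strategy = ensemble$strategy,
         decision = ensemble$decision,
         algorithm = ensemble$algorithm,
         weighting = ensemble$weighting,
         n_base_models = length(ensemble$base_models)),
    file.path(path, "manifest.json"), auto_unbox = TRUE)
  saveRDS(ensemble$base_models, file.path(path, "base_models.rds"))
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  man <- jsonlite::fromJSON(file.path(path, "manifest.json"))
  if (!identical(man$format, .bundle_format)) {
    stop("unsupported bundle format: ", man$format)
  }
  models <- readRDS(file.path(path, "base_models.rds"))
  if (length(models) != man$n_base_models) {
    stop("bundle is corrupt: model count does not match manifest")
  }
  structure(list(scheme = label_scheme(man$labels),
                 strategy = man$strategy, decision = man$decision,
                 base_models = models, algorithm = man$algorithm,
                 weighting = man$weighting),
            class = "incident_ensemble")
}
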