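#' Classifier configuration for membrane binding and productive orientation
#'
#' Bundles the geometric criteria used to call a domain "membrane bound" and a
#' pose "productive". Binding is judged from the z-position of a selection's
#' top atom relative to the phosphorus layer of the proximal monolayer; the
#' cutoff depends on resolution (coarse-grained vs atomistic) and bilayer
#' composition because PIP3 headgroups keep protein atoms further from the
#' phosphocholine phosphates. Orientation is judged from the angle between the
#' cross product of two anchor vectors and the membrane normal (+z).
#'
#' Default cutoffs (Angstrom, boundary inclusive — a top atom exactly at the
#' cutoff counts as bound): atomistic/POPC 0, atomistic/POPC+PIP3 -4,
#' coarse-grained/POPC -2, coarse-grained/POPC+PIP3 -12. The productive band
#' is the closed interval 0-30 degrees. Coarse-grained times are converted to
#' effective times with a factor of 4.
#'
#' @param binding_cutoffs_A Named numeric vector keyed `"<resolution>/<bilayer>"`
#'   with resolution in `c("at", "cg")` and bilayer in
#'   `c("popc", "popc_pip3")`; units Angstrom.
#' @param productive_angle_deg Length-2 numeric, closed angle band in degrees
#'   within `[0, 180]`.
#' @param cg_time_factor Multiplier converting raw coarse-grained simulation
#'   time to effective time.
#' @param cross_order Either `"v1xv2"` (default) or `"v2xv1"`; which order the
#'   orientation cross product is taken in (the two differ by reflection,
#'   angle vs 180 - angle).
#' @param plane_estimator `"mean"` (default) or `"median"` z of the proximal
#'   phosphorus atoms.
#'
#' @return An object of class `vsp_classifier_config` (a list).
#' @examples
#' cfg <- classifier_config()
#' cfg$binding_cutoffs_A
#' @export
classifier_config <- function(binding_cutoffs_A = c(
                                "at/popc" = 0, "at/popc_pip3" = -4,
                                "cg/popc" = -2, "cg/popc_pip3" = -12
                              ),
                              productive_angle_deg = c(0, 30),
                              cg_time_factor = 4,
                              cross_order = c("v1xv2", "v2xv1"),
                              plane_estimator = c("mean", "median")) {
  cross_order <- match.arg(cross_order)
  plane_estimator <- match.arg(plane_estimator)
  required <- c("at/popc", "at/popc_pip3", "cg/popc", "cg/popc_pip3")
  if (!setequal(names(binding_cutoffs_A), required)) {
    abort(paste0(
      "`binding_cutoffs_A` must be keyed by exactly: ",
      paste(required, collapse = ", ")
    ), class = "vsp_config_error")
  }
  if (length(productive_angle_deg) != 2 ||
      any(productive_angle_deg < 0) || any(productive_angle_deg > 180) ||
      productive_angle_deg[1] > productive_angle_deg[2]) {
    abort("`productive_angle_deg` must be an increasing pair within [0, 180]",
      class = "vsp_config_error")
  }
  structure(
    list(
      binding_cutoffs_A = binding_cutoffs_A[required],
      productive_angle_deg = as.numeric(productive_angle_deg),
      cg_time_factor = cg_time_factor,
      cross_order = cross_order,
      plane_estimator = plane_estimator
    ),
    class = "vsp_classifier_config"
  )
}

#' @export
print.vsp_classifier_config <- function(x, ...) {
  cat("<vsp_classifier_config>\n")
  cat("  binding cutoffs (A):",
    paste(names(x$binding_cutoffs_A), x$binding_cutoffs_A,
      sep = " = ", collapse = ", "), "\n")
  cat(sprintf(
    "  productive angle: [%g, %g] deg (%s); CG time factor: %g; plane: %s\n",
    x$productive_angle_deg[1], x$productive_angle_deg[2], x$cross_order,
    x$cg_time_factor, x$plane_estimator
  ))
  invisible(x)
}

binding_cutoff <- function(resolution, bilayer, config) {
  key <- paste0(resolution, "/", bilayer)
  if (!key %in% names(config$binding_cutoffs_A)) {
    abort(sprintf("no binding cutoff configured for system '%s'", key),
      class = "vsp_config_error")
  }
  unname(config$binding_cutoffs_A[[key]])
}

#' Effective simulation time
#'
#' Coarse-grained dynamics run on a smoothed energy landscape, so raw
#' coarse-grained simulation time is conventionally rescaled by a factor of 4
#' to an effective time; atomistic time is reported unchanged.
#'
#' @param raw_time Non-negative numeric vector, any time unit.
#' @param resolution `"cg"` or `"at"`.
#' @param config A [classifier_config()].
#' @return `raw_time` scaled to effective time, same unit.
#' @examples
#' effective_time(500, "cg") # 2000
#' effective_time(100, "at") # 100
#' @export
effective_time <- function(raw_time, resolution = c("at", "cg"),
                           config = classifier_config()) {
  resolution <- match.arg(resolution)
  stopifnot(all(raw_time >= 0))
  if (resolution == "cg") raw_time * config$cg_time_factor else raw_time
}
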