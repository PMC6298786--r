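#' Annotated trajectory tables
#'
#' A trajectory is a long-format tibble with one row per atom per frame and
#' columns `frame` (integer), `time_ps`, `atom_id`, `role`, `monolayer`,
#' `x_nm`, `y_nm`, `z_nm` and optionally `mass_amu`. The z axis is the
#' membrane normal; +z points from the cytoplasmic (protein) side toward the
#' proximal monolayer, so a protein below the phosphorus layer has negative
#' relative z. Recognised roles:
#'
#' * `"phosphorus"` — lipid phosphorus atoms, with `monolayer` either
#'   `"proximal"` or `"distal"`;
#' * `"pd"`, `"c2"`, `"spine"` — generic atoms of the phosphatase domain, C2
#'   domain and hydrophobic spine (Leu-284 + Phe-285);
#' * anchor atoms `"arg281_ca"`, `"lys516_ca"`, `"arg520_ca"`, `"lys555_ca"`,
#'   `"lys558_ca"`, `"his332_cb"`, `"lys367_ca"` used by the orientation
#'   classifier and catalytic-depth diagnostic.
#'
#' @param traj A trajectory tibble.
#' @return `validate_trajectory()` returns `traj` invisibly after checking the
#'   contract (shared atom roster, strictly increasing frame times, at least
#'   one phosphorus atom per monolayer in every frame).
#' @name annotated-trajectory
NULL

.anchor_roles <- c(
  "arg281_ca", "lys516_ca", "arg520_ca", "lys555_ca", "lys558_ca",
  "his332_cb", "lys367_ca"
)

.pd_roles <- c("pd", "spine", "arg281_ca", "his332_cb", "lys367_ca")
.c2_roles <- c("c2", "lys516_ca", "arg520_ca", "lys555_ca", "lys558_ca")

selection_roles <- function(selection) {
  switch(selection,
    pd = .pd_roles,
    c2 = .c2_roles,
    spine = "spine",
    protein = c(.pd_roles, .c2_roles),
    abort(sprintf("unknown selection '%s'", selection),
      class = "vsp_selection_error")
  )
}

#' @rdname annotated-trajectory
#' @export
validate_trajectory <- function(traj) {
  need <- c("frame", "time_ps", "atom_id", "role", "x_nm", "y_nm", "z_nm")
  missing_cols <- setdiff(need, names(traj))
  if (length(missing_cols)) {
    abort(paste0("trajectory is missing columns: ",
      paste(missing_cols, collapse = ", ")), class = "vsp_trajectory_error")
  }
  ft <- dplyr::distinct(traj, .data$frame, .data$time_ps) |>
    dplyr::arrange(.data$frame)
  if (anyDuplicated(ft$frame)) {
    abort("frames carry inconsistent times", class = "vsp_trajectory_error")
  }
  if (nrow(ft) > 1 && any(diff(ft$time_ps) <= 0)) {
    abort("frame times must be strictly increasing",
      class = "vsp_trajectory_error")
  }
  rosters <- tapply(traj$atom_id, traj$frame, function(x) paste(sort(x), collapse = "|"))
  if (length(unique(rosters)) > 1) {
    abort("all frames must share the same atom roster",
      class = "vsp_trajectory_error")
  }
  p <- dplyr::filter(traj, .data$role == "phosphorus")
  for (mono in c("proximal", "distal")) {
    per_frame <- table(p$frame[p$monolayer == mono])
    if (length(per_frame) < nrow(ft) || any(per_frame < 1)) {
      abort(sprintf("every frame needs >= 1 phosphorus atom in the %s monolayer", mono),
        class = "vsp_missing_annotation")
    }
  }
  invisible(traj)
}

#' Read a long-format trajectory CSV
#'
#' Reads the documented per-frame CSV fallback format (columns `frame`,
#' `time_ps`, `atom_id`, `role`, `monolayer`, `x_nm`, `y_nm`, `z_nm`,
#' `mass_amu`) and validates it.
#'
#' @param path Path to a CSV file.
#' @return A validated trajectory tibble.
#' @export
read_trajectory_csv <- function(path) {
  traj <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if ("monolayer" %in% names(traj)) {
    traj$monolayer[traj$monolayer %in% c("", "NA")] <- NA_character_
  }
  validate_trajectory(traj)
  traj
}

#' Read a single structure frame from a PDB file
#'
#' Thin adapter over `bio3d::read.pdb()` that turns one structure into a
#' single-frame trajectory table. Roles must be assigned by the caller via a
#' mapping from residue number + atom name; atoms not covered by the mapping
#' are dropped. Coordinates are converted from Angstrom (PDB convention) to nm.
#'
#' @param path Path to a PDB file.
#' @param role_map A data frame with columns `resno`, `elety` (atom name) and
#'   `role`, plus optionally `monolayer`.
#' @return A single-frame trajectory tibble (time 0 ps).
#' @export
read_structure_frame <- function(path, role_map) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("the 'bio3d' package is required to read PDB files")
  }
  pdb <- bio3d::read.pdb(path)
  at <- as_tibble(pdb$atom)
  if (!"monolayer" %in% names(role_map)) role_map$monolayer <- NA_character_
  at <- dplyr::inner_join(at, as_tibble(role_map), by = c("resno", "elety"))
  tibble(
    frame = 1L, time_ps = 0,
    atom_id = at$eleno, role = at$role, monolayer = at$monolayer,
    x_nm = at$x / 10, y_nm = at$y / 10, z_nm = at$z / 10,
    mass_amu = NA_real_
  )
}

#' z-position of the phosphorus layer
#'
#' The depth reference for all binding measurements: the plane of lipid
#' phosphorus atoms of one monolayer, estimated per frame as the mean (or
#' median) z of those atoms.
#'
#' @param frame A single-frame trajectory tibble.
#' @param monolayer `"proximal"` (default) or `"distal"`.
#' @param estimator `"mean"` (default) or `"median"`.
#' @return Plane z in nm.
#' @examples
#' fr <- tibble::tibble(
#'   frame = 1L, time_ps = 0, atom_id = 1:2, role = "phosphorus",
#'   monolayer = "proximal", x_nm = 0, y_nm = 0, z_nm = c(4.8, 5.2)
#' )
#' phosphorus_plane_z(fr) # 5
#' @export
phosphorus_plane_z <- function(frame, monolayer = c("proximal", "distal"),
                               estimator = c("mean", "median")) {
  monolayer <- match.arg(monolayer)
  estimator <- match.arg(estimator)
  z <- frame$z_nm[frame$role == "phosphorus" &
    !is.na(frame$monolayer) & frame$monolayer == monolayer]
  if (!length(z)) {
    abort(sprintf("no phosphorus atoms annotated for the %s monolayer", monolayer),
      class = "vsp_missing_annotation")
  }
  if (estimator == "mean") mean(z) else median(z)
}

#' Top-atom depth of a selection relative to the phosphorus layer
#'
#' The binding criterion tracks the protein atom with the highest z coordinate
#' (the "top atom") in a selection. Returns its z minus the phosphorus-layer z,
#' in Angstrom; negative values are below the layer.
#'
#' @param frame A single-frame trajectory tibble.
#' @param selection One of `"pd"`, `"c2"`, `"spine"`, `"protein"`.
#' @param plane_z_nm Optional precomputed plane z (nm); computed from `frame`
#'   when `NULL`.
#' @param estimator Passed to [phosphorus_plane_z()].
#' @return Relative top-atom z in Angstrom.
#' @export
rel_top_z <- function(frame, selection, plane_z_nm = NULL,
                      estimator = c("mean", "median")) {
  z <- frame$z_nm[frame$role %in% selection_roles(selection)]
  if (!length(z)) {
    abort(sprintf("selection '%s' is empty in this frame", selection),
      class = "vsp_selection_error")
  }
  if (is.null(plane_z_nm)) {
    plane_z_nm <- phosphorus_plane_z(frame, "proximal", match.arg(estimator))
  }
  (max(z) - plane_z_nm) * 10
}

#' Binding-state call from top-atom depth
#'
#' A domain is bound when its top atom sits at or above the system-specific
#' cutoff relative to the phosphorus layer (boundary inclusive).
#'
#' @param rel_top_z_A Numeric vector, relative top-atom depth in Angstrom.
#' @param resolution `"at"` or `"cg"`.
#' @param bilayer `"popc"` or `"popc_pip3"`.
#' @param config A [classifier_config()].
#' @return Logical vector.
#' @examples
#' binding_state(-3, "at", "popc") # FALSE (cutoff 0)
#' binding_state(-3, "at", "popc_pip3") # TRUE (cutoff -4)
#' @export
binding_state <- function(rel_top_z_A, resolution, bilayer,
                          config = classifier_config()) {
  rel_top_z_A >= binding_cutoff(resolution, bilayer, config)
}

anchor_position <- function(frame, role) {
  i <- which(frame$role == role)
  if (length(i) != 1) {
    abort(sprintf("anchor atom '%s' missing (or duplicated) in frame", role),
      class = "vsp_missing_annotation")
  }
  c(frame$x_nm[i], frame$y_nm[i], frame$z_nm[i])
}

#' Orientation anchor vectors
#'
#' Two vectors rooted at the Arg-281 Calpha of the phosphatase domain: v1 to
#' the midpoint of the Lys-516/Arg-520 Calpha pair (the CBR3-like loop of the
#' C2 domain) and v2 to the midpoint of the Lys-555/Lys-558 Calpha pair (the
#' beta 8-9 loop). Their cross product defines the orientation of the
#' catalytic region relative to the membrane normal.
#'
#' @param frame A single-frame trajectory tibble containing the five anchors.
#' @return A list with 3-vectors `v1`, `v2` (nm) and a logical `degenerate`
#'   flag, set when either vector is zero or the two are collinear.
#' @export
orientation_vectors <- function(frame) {
  origin <- anchor_position(frame, "arg281_ca")
  v1 <- (anchor_position(frame, "lys516_ca") +
    anchor_position(frame, "arg520_ca")) / 2 - origin
  v2 <- (anchor_position(frame, "lys555_ca") +
    anchor_position(frame, "lys558_ca")) / 2 - origin
  cr <- cross3(v1, v2)
  list(v1 = v1, v2 = v2,
    degenerate = sqrt(sum(cr^2)) <= 1e-12 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Productive-orientation angle
#'
#' Angle between the cross product of the two anchor vectors and the +z axis
#' (the membrane normal), in degrees within \[0, 180\].
#'
#' @param v1,v2 Numeric 3-vectors from [orientation_vectors()].
#' @param cross_order `"v1xv2"` (default) or `"v2xv1"`; the two conventions
#'   give supplementary angles.
#' @return Angle in degrees.
#' @examples
#' productive_angle(c(1, 0, 0), c(0, 1, 0)) # 0
#' productive_angle(c(1, 0, 0), c(0, 0, 1)) # 90
#' @export
productive_angle <- function(v1, v2, cross_order = c("v1xv2", "v2xv1")) {
  cross_order <- match.arg(cross_order)
  cr <- if (cross_order == "v1xv2") cross3(v1, v2) else cross3(v2, v1)
  n <- sqrt(sum(cr^2))
  if (n <= 1e-12 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2)))) {
    abort("orientation vectors are collinear: cross product is zero",
      class = "vsp_degenerate_orientation")
  }
  acos(pmin(1, pmax(-1, cr[3] / n))) * 180 / pi
}

#' Productive-orientation call
#'
#' @param angle_deg Numeric vector of angles in degrees within \[0, 180\].
#' @param config A [classifier_config()]; the default band is the closed
#'   interval \[0, 30\] degrees.
#' @return Logical vector.
#' @export
classify_productive <- function(angle_deg, config = classifier_config()) {
  stopifnot(all(angle_deg >= 0 & angle_deg <= 180, na.rm = TRUE))
  angle_deg >= config$productive_angle_deg[1] &
    angle_deg <= config$productive_angle_deg[2]
}

#' Center-of-mass depth of a selection
#'
#' Mass-weighted mean z of a selection relative to the phosphorus layer, in
#' Angstrom. Uniform weights are used when masses are absent (e.g.,
#' coarse-grained beads without assigned masses).
#'
#' @inheritParams rel_top_z
#' @param use_mass Use the `mass_amu` column when present and complete.
#' @return Center-of-mass depth in Angstrom.
#' @export
com_z <- function(frame, selection, plane_z_nm = NULL, use_mass = TRUE,
                  estimator = c("mean", "median")) {
  idx <- frame$role %in% selection_roles(selection)
  if (!any(idx)) {
    abort(sprintf("selection '%s' is empty in this frame", selection),
      class = "vsp_selection_error")
  }
  z <- frame$z_nm[idx]
  w <- rep(1, length(z))
  if (use_mass && "mass_amu" %in% names(frame)) {
    m <- frame$mass_amu[idx]
    if (!anyNA(m)) w <- m
  }
  if (is.null(plane_z_nm)) {
    plane_z_nm <- phosphorus_plane_z(frame, "proximal", match.arg(estimator))
  }
  (sum(w * z) / sum(w) - plane_z_nm) * 10
}

#' Catalytic-center depth asymmetry
#'
#' Diagnostic for the productive pose: in the productive orientation the
#' His-332 Cbeta and Lys-367 Calpha atoms of the catalytic center sit at
#' nearly equal depths (difference below about 0.3 Angstrom). Returns
#' `|z(His-332 Cbeta) - z(Lys-367 Calpha)|` in Angstrom. Not used by the
#' classifier.
#'
#' @param frame A single-frame trajectory tibble.
#' @return Absolute z difference in Angstrom.
#' @export
catalytic_depth_asymmetry <- function(frame) {
  abs(anchor_position(frame, "his332_cb")[3] -
    anchor_position(frame, "lys367_ca")[3]) * 10
}

#' Frame-by-frame binding and orientation trace
#'
#' Applies the binding and productive-orientation classifiers to every frame
#' of a trajectory: phosphorus-layer depth, top-atom depths and binding calls
#' for the phosphatase and C2 domains, the orientation angle and productive
#' call, center-of-mass depths of both domains and the hydrophobic spine, and
#' the catalytic-center depth asymmetry.
#'
#' Frames whose orientation vectors are collinear (zero cross product) are
#' flagged `degenerate` and counted as non-productive, with a warning.
#'
#' @param traj A validated trajectory tibble (see [annotated-trajectory]).
#' @param resolution `"at"` or `"cg"`.
#' @param bilayer `"popc"` or `"popc_pip3"`.
#' @param config A [classifier_config()].
#' @return A `vsp_binding_trace` tibble with one row per frame: `frame`,
#'   `time_ps`, `effective_time_ps`, `pd_rel_top_A`, `c2_rel_top_A`,
#'   `pd_bound`, `c2_bound`, `angle_deg`, `productive`, `degenerate`,
#'   `pd_com_A`, `c2_com_A`, `spine_com_A`, `catalytic_asym_A`.
#' @seealso [summarize_binding()] for Table-1-style time fractions.
#' @export
analyze_trajectory <- function(traj, resolution = c("at", "cg"),
                               bilayer = c("popc", "popc_pip3"),
                               config = classifier_config()) {
  resolution <- match.arg(resolution)
  bilayer <- match.arg(bilayer)
  validate_trajectory(traj)
  cutoff <- binding_cutoff(resolution, bilayer, config) # fail fast
  frames <- split(traj, traj$frame)
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    tryCatch({
      plane <- phosphorus_plane_z(fr, "proximal", config$plane_estimator)
      ov <- orientation_vectors(fr)
      angle <- if (ov$degenerate) NA_real_ else {
        productive_angle(ov$v1, ov$v2, config$cross_order)
      }
      tibble(
        frame = fr$frame[1], time_ps = fr$time_ps[1],
        pd_rel_top_A = rel_top_z(fr, "pd", plane),
        c2_rel_top_A = rel_top_z(fr, "c2", plane),
        angle_deg = angle,
        degenerate = ov$degenerate,
        pd_com_A = com_z(fr, "pd", plane),
        c2_com_A = com_z(fr, "c2", plane),
        spine_com_A = com_z(fr, "spine", plane),
        catalytic_asym_A = catalytic_depth_asymmetry(fr)
      )
    }, error = function(e) {
      abort(sprintf("frame %d: %s", fr$frame[1], conditionMessage(e)),
        class = "vsp_trajectory_error", parent = e)
    })
  })
  trace <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      effective_time_ps = effective_time(.data$time_ps, resolution, config),
      pd_bound = .data$pd_rel_top_A >= cutoff,
      c2_bound = .data$c2_rel_top_A >= cutoff,
      productive = !.data$degenerate &
        classify_productive(dplyr::coalesce(.data$angle_deg, 180), config)
    ) |>
    dplyr::relocate("effective_time_ps", .after = "time_ps") |>
    dplyr::relocate("pd_bound", "c2_bound", .after = "c2_rel_top_A") |>
    dplyr::relocate("productive", .after = "angle_deg")
  if (any(trace$degenerate)) {
    warn(sprintf("%d frame(s) had collinear orientation vectors; counted as non-productive",
      sum(trace$degenerate)))
  }
  structure(trace,
    class = c("vsp_binding_trace", class(trace)),
    resolution = resolution, bilayer = bilayer, config = config
  )
}

#' Time fractions of binding and productive orientation
#'
#' Summarizes a binding trace into the three headline time fractions: percent
#' of frames with the phosphatase domain bound, with the C2 domain bound, and
#' with the productive orientation while both domains are bound. Fractions are
#' frame counts over total frames when spacing is uniform; with `weighting =
#' "trapezoid"` frames are weighted by trapezoidal time intervals for
#' non-uniform sampling.
#'
#' @param trace A `vsp_binding_trace` (or any tibble with `pd_bound`,
#'   `c2_bound`, `productive` and `time_ps`).
#' @param weighting `"frames"` (default) or `"trapezoid"`.
#' @return A one-row tibble: `n_frames`, `fraction_pd`, `fraction_c2`,
#'   `fraction_productive_both_bound` (percent).
#' @export
summarize_binding <- function(trace, weighting = c("frames", "trapezoid")) {
  weighting <- match.arg(weighting)
  if (!nrow(trace)) abort("empty binding trace", class = "vsp_trajectory_error")
  w <- if (weighting == "frames" || nrow(trace) == 1) {
    rep(1, nrow(trace))
  } else {
    t <- trace$time_ps
    dt <- diff(t)
    c(dt[1] / 2, (dt[-length(dt)] + dt[-1]) / 2, dt[length(dt)] / 2)
  }
  frac <- function(x) 100 * sum(w * x) / sum(w)
  tibble(
    n_frames = nrow(trace),
    fraction_pd = frac(trace$pd_bound),
    fraction_c2 = frac(trace$c2_bound),
    fraction_productive_both_bound =
      frac(trace$productive & trace$pd_bound & trace$c2_bound)
  )
}
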