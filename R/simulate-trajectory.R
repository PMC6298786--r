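#' Internal: run code with a local, restorable RNG stream
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Ground truth of a synthetic dataset
#'
#' Every generator attaches a `ground_truth` attribute: the generator name,
#' seed and all generative parameters, sufficient to predict the noiseless
#' downstream result in closed form and to regenerate the dataset
#' bit-identically.
#'
#' @param x A generated object.
#' @return The ground-truth list.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Binding/orientation schedules for synthetic trajectories
#'
#' `schedule_block()` prescribes exact occupancies deterministically: the
#' phosphatase domain is bound in the first `round(f_pd * n)` frames, the C2
#' domain in the first `round(f_c2 * n)`, and the orientation is productive in
#' the first `round(f_productive * n)` (which must not exceed the other two,
#' so the productive-and-both-bound fraction equals `f_productive` exactly).
#'
#' `schedule_telegraph()` draws each channel from a stationary two-state
#' Markov chain whose stationary occupancy equals the requested fraction;
#' `switch_scale` sets how fast states flip (transition probabilities
#' `switch_scale * p` and `switch_scale * (1 - p)`).
#'
#' @param n_frames Number of frames.
#' @param f_pd,f_c2,f_productive Target occupancy fractions in \[0, 1\].
#' @param switch_scale Telegraph switching scale in (0, 1\].
#' @param seed RNG seed for the telegraph draw.
#' @return A tibble with logical columns `pd_bound`, `c2_bound`, `productive`.
#' @export
schedule_block <- function(n_frames, f_pd, f_c2, f_productive) {
  stopifnot(n_frames >= 1, f_pd >= 0, f_pd <= 1, f_c2 >= 0, f_c2 <= 1,
    f_productive >= 0, f_productive <= 1)
  n_prod <- round(f_productive * n_frames)
  if (n_prod > min(round(f_pd * n_frames), round(f_c2 * n_frames))) {
    abort("f_productive must not exceed min(f_pd, f_c2) in a block schedule",
      class = "vsp_parameter_error")
  }
  idx <- seq_len(n_frames)
  tibble(
    pd_bound = idx <= round(f_pd * n_frames),
    c2_bound = idx <= round(f_c2 * n_frames),
    productive = idx <= n_prod
  )
}

#' @rdname schedule_block
#' @export
schedule_telegraph <- function(n_frames, f_pd, f_c2, f_productive,
                               switch_scale = 0.1, seed = 1) {
  stopifnot(switch_scale > 0, switch_scale <= 1)
  draw <- function(p) {
    if (p <= 0) return(rep(FALSE, n_frames))
    if (p >= 1) return(rep(TRUE, n_frames))
    a <- switch_scale * p       # off -> on
    b <- switch_scale * (1 - p) # on -> off
    s <- logical(n_frames)
    s[1] <- runif(1) < p
    for (i in seq_len(n_frames - 1L)) {
      s[i + 1L] <- if (s[i]) runif(1) >= b else runif(1) < a
    }
    s
  }
  with_seed(seed, {
    sch <- tibble(
      pd_bound = draw(f_pd), c2_bound = draw(f_c2),
      productive = draw(f_productive)
    )
  })
  # productive orientation is only meaningful as an AND with both bound;
  # keep channels independent, downstream summaries apply the AND.
  sch
}

# deterministic local geometry of a domain blob: z offsets from the top atom
.blob_dz <- function(n) -seq(0, 0.6, length.out = n)

#' Generate a synthetic annotated trajectory
#'
#' Builds a minimal planar-bilayer system whose classification is controlled
#' exactly by a schedule: phosphorus lattices for both monolayers, rigid
#' pseudo-atom blobs for the phosphatase and C2 domains whose top atoms sit a
#' fixed margin above (bound) or below (unbound) the system's binding cutoff,
#' hydrophobic-spine atoms riding on the phosphatase domain, and anchor
#' residues on a rigid internal frame rotated to a productive or
#' non-productive orientation angle. Gaussian positional jitter may be added;
#' it must be small enough (guaranteed margin of at least 3 standard
#' deviations, for the angle via a conservative linearised bound) that no
#' scheduled state can flip.
#'
#' @param schedule A tibble from [schedule_block()] or [schedule_telegraph()].
#' @param resolution,bilayer System key selecting the binding cutoff.
#' @param seed RNG seed (only used when `jitter_sd_nm > 0`).
#' @param jitter_sd_nm Isotropic Gaussian jitter SD per coordinate, nm.
#' @param dt_ps Frame spacing, ps.
#' @param margin_A Distance of scheduled top atoms from the cutoff, Angstrom.
#' @param productive_angle_deg,nonproductive_angle_deg Orientation angles
#'   realised for scheduled productive / non-productive frames, degrees.
#' @param config A [classifier_config()].
#' @return A trajectory tibble (see [annotated-trajectory]) with a
#'   [ground_truth()] attribute carrying the schedule and expected time
#'   fractions.
#' @export
sim_membrane_trajectory <- function(schedule,
                                    resolution = c("at", "cg"),
                                    bilayer = c("popc", "popc_pip3"),
                                    seed = 1,
                                    jitter_sd_nm = 0,
                                    dt_ps = 200,
                                    margin_A = 5,
                                    productive_angle_deg = 10,
                                    nonproductive_angle_deg = 90,
                                    config = classifier_config()) {
  resolution <- match.arg(resolution)
  bilayer <- match.arg(bilayer)
  stopifnot(all(c("pd_bound", "c2_bound", "productive") %in% names(schedule)),
    nrow(schedule) >= 1, margin_A > 0, jitter_sd_nm >= 0)
  n <- nrow(schedule)
  cutoff_A <- binding_cutoff(resolution, bilayer, config)

  if (jitter_sd_nm * 10 * 3 > margin_A) {
    abort("jitter_sd_nm too large: 3 SD must fit inside the binding margin",
      class = "vsp_parameter_error")
  }
  d_anchor <- 1 # nm, anchor vector length
  band <- config$productive_angle_deg
  angle_margin <- min(
    abs(productive_angle_deg - band[2]),
    abs(nonproductive_angle_deg - band[2]), abs(nonproductive_angle_deg - band[1])
  )
  angle_sd_deg <- (180 / pi) * 2 * jitter_sd_nm / d_anchor # conservative bound
  if (3 * angle_sd_deg > angle_margin) {
    abort("jitter_sd_nm too large: 3 SD of the induced angle jitter must fit inside the angle margin",
      class = "vsp_parameter_error")
  }

  plane_z <- 4 # nm, proximal phosphorus layer
  grid <- expand.grid(x = seq(-1.6, 1.6, by = 0.8), y = seq(-1.6, 1.6, by = 0.8))
  n_p <- nrow(grid)

  # one frame of atoms (local template, z of blobs set per frame)
  n_blob <- 12
  pd_dz <- .blob_dz(n_blob)
  c2_dz <- .blob_dz(n_blob)

  base_anchors <- function(theta_deg) {
    th <- theta_deg * pi / 180
    rot_x <- function(p) c(p[1], p[2] * cos(th) - p[3] * sin(th),
      p[2] * sin(th) + p[3] * cos(th))
    e <- 0.35
    pts <- list(
      arg281_ca = c(0, 0, 0),
      lys516_ca = c(d_anchor, e, 0), arg520_ca = c(d_anchor, -e, 0),
      lys555_ca = c(e, d_anchor, 0), lys558_ca = c(-e, d_anchor, 0),
      his332_cb = c(0.3, 0.3, -0.1), lys367_ca = c(-0.3, 0.3, -0.1)
    )
    lapply(pts, rot_x)
  }
  anch_prod <- base_anchors(productive_angle_deg)
  anch_nonprod <- base_anchors(nonproductive_angle_deg)
  anchor_center <- c(0, 0, plane_z - 3.5)

  frames <- vector("list", n)
  for (i in seq_len(n)) {
    pd_top <- plane_z + (cutoff_A + if (schedule$pd_bound[i]) margin_A else -margin_A) / 10
    c2_top <- plane_z + (cutoff_A + if (schedule$c2_bound[i]) margin_A else -margin_A) / 10
    anch <- if (schedule$productive[i]) anch_prod else anch_nonprod
    ax <- unname(vapply(anch, function(p) p[1] + anchor_center[1], numeric(1)))
    ay <- unname(vapply(anch, function(p) p[2] + anchor_center[2], numeric(1)))
    az <- unname(vapply(anch, function(p) p[3] + anchor_center[3], numeric(1)))
    frames[[i]] <- tibble(
      frame = i, time_ps = (i - 1) * dt_ps,
      atom_id = seq_len(2 * n_p + 2 * n_blob + 2 + length(anch)),
      role = c(rep("phosphorus", 2 * n_p), rep("pd", n_blob), rep("c2", n_blob),
        rep("spine", 2), names(anch)),
      monolayer = c(rep("proximal", n_p), rep("distal", n_p),
        rep(NA_character_, 2 * n_blob + 2 + length(anch))),
      x_nm = c(grid$x, grid$x, -1.5 + 0.05 * seq_len(n_blob),
        1.5 + 0.05 * seq_len(n_blob), -1.5, -1.45, ax),
      y_nm = c(grid$y, grid$y, 0.04 * seq_len(n_blob),
        0.5 + 0.04 * seq_len(n_blob), 0.1, -0.1, ay),
      z_nm = c(rep(plane_z, n_p), rep(plane_z + 3.8, n_p), pd_top + pd_dz,
        c2_top + c2_dz, pd_top - 0.15, pd_top - 0.25, az),
      mass_amu = NA_real_
    )
  }
  traj <- dplyr::bind_rows(frames)
  if (jitter_sd_nm > 0) {
    with_seed(seed, {
      traj$x_nm <- traj$x_nm + rnorm(nrow(traj), 0, jitter_sd_nm)
      traj$y_nm <- traj$y_nm + rnorm(nrow(traj), 0, jitter_sd_nm)
      traj$z_nm <- traj$z_nm + rnorm(nrow(traj), 0, jitter_sd_nm)
    })
  }
  expected <- tibble(
    fraction_pd = 100 * mean(schedule$pd_bound),
    fraction_c2 = 100 * mean(schedule$c2_bound),
    fraction_productive_both_bound =
      100 * mean(schedule$productive & schedule$pd_bound & schedule$c2_bound)
  )
  structure(traj, ground_truth = list(
    generator = "membrane_trajectory", seed = seed,
    params = list(
      resolution = resolution, bilayer = bilayer, jitter_sd_nm = jitter_sd_nm,
      dt_ps = dt_ps, margin_A = margin_A,
      productive_angle_deg = productive_angle_deg,
      nonproductive_angle_deg = nonproductive_angle_deg
    ),
    schedule = schedule, expected_summary = expected
  ))
}
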