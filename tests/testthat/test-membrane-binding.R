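test_that("phosphorus plane is the mean z of the annotated monolayer", {
  fr <- make_flat_frame(z_p = 5)
  expect_equal(phosphorus_plane_z(fr, "proximal"), 5)

  fr2 <- make_flat_frame()
  fr2$z_nm[fr2$monolayer == "proximal"] <- c(4.8, 5.2)
  expect_equal(phosphorus_plane_z(fr2, "proximal"), 5)

  # brute-force summation oracle on jittered atoms
  set.seed(11)
  z <- 5 + rnorm(100, 0, 0.15)
  fr3 <- tibble::tibble(
    frame = 1L, time_ps = 0, atom_id = seq_along(z), role = "phosphorus",
    monolayer = "proximal", x_nm = runif(100), y_nm = runif(100), z_nm = z
  )
  expect_equal(phosphorus_plane_z(fr3, "proximal"), sum(z) / length(z))

  fr4 <- fr3
  fr4$monolayer <- "distal"
  expect_error(phosphorus_plane_z(fr4, "proximal"),
    class = "vsp_missing_annotation")
})

test_that("top-atom depth converts nm to Angstrom and takes the maximum", {
  one <- make_flat_frame(extra = tibble::tibble(
    role = "pd", x_nm = 0, y_nm = 0, z_nm = 5 - 0.3))
  expect_equal(rel_top_z(one, "pd"), -3)

  three <- make_flat_frame(extra = tibble::tibble(
    role = "pd", x_nm = 0:2, y_nm = 0, z_nm = 5 + c(-0.5, -0.2, -0.8)))
  expect_equal(rel_top_z(three, "pd"), -2)

  set.seed(12)
  zr <- 5 + rnorm(50, -0.5, 0.3)
  many <- make_flat_frame(extra = tibble::tibble(
    role = "c2", x_nm = runif(50), y_nm = runif(50), z_nm = zr))
  expect_equal(rel_top_z(many, "c2"), (max(zr) - 5) * 10)

  expect_error(rel_top_z(make_flat_frame(), "pd"),
    class = "vsp_selection_error")
})

test_that("binding cutoffs are system-specific and boundary inclusive", {
  expect_false(binding_state(-3, "at", "popc"))
  expect_true(binding_state(-3, "at", "popc_pip3"))
  expect_true(binding_state(-12, "cg", "popc_pip3")) # exactly at the cutoff
  expect_true(binding_state(0, "at", "popc"))
  expect_false(binding_state(-2.0001, "cg", "popc"))

  expect_error(binding_state(-3, "at", "dppc"), class = "vsp_config_error")

  # monotonicity: bound at z0 implies bound at any z >= z0
  set.seed(13)
  for (key in list(c("at", "popc"), c("cg", "popc_pip3"))) {
    z0 <- runif(50, -20, 5)
    b0 <- binding_state(z0, key[1], key[2])
    b_up <- binding_state(z0 + runif(50, 0, 10), key[1], key[2])
    expect_true(all(b_up[b0]))
  }
})

test_that("orientation vectors are anchored midpoint differences", {
  fr <- make_flat_frame(extra = tibble::tibble(
    role = c("arg281_ca", "lys516_ca", "arg520_ca", "lys555_ca", "lys558_ca"),
    x_nm = c(0, 2, 0, 0, 0), y_nm = c(0, 0, 2, 1, -1), z_nm = c(0, 0, 0, 1, 1)
  ))
  ov <- orientation_vectors(fr)
  expect_equal(ov$v1, c(1, 1, 0))
  expect_equal(ov$v2, c(0, 0, 1))
  expect_false(ov$degenerate)

  # all anchors coincident -> degenerate
  fr0 <- make_flat_frame(extra = tibble::tibble(
    role = c("arg281_ca", "lys516_ca", "arg520_ca", "lys555_ca", "lys558_ca"),
    x_nm = 1, y_nm = 1, z_nm = 1))
  expect_true(orientation_vectors(fr0)$degenerate)

  # random anchors match the midpoint oracle
  set.seed(14)
  for (rep in 1:20) {
    xyz <- matrix(rnorm(15), ncol = 3)
    fr_r <- make_flat_frame(extra = tibble::tibble(
      role = c("arg281_ca", "lys516_ca", "arg520_ca", "lys555_ca", "lys558_ca"),
      x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3]))
    ov_r <- orientation_vectors(fr_r)
    expect_equal(ov_r$v1, (xyz[2, ] + xyz[3, ]) / 2 - xyz[1, ])
    expect_equal(ov_r$v2, (xyz[4, ] + xyz[5, ]) / 2 - xyz[1, ])
  }

  # missing anchor names the role
  fr_m <- make_flat_frame(extra = tibble::tibble(
    role = c("arg281_ca", "lys516_ca", "arg520_ca", "lys555_ca"),
    x_nm = 0:3, y_nm = 0, z_nm = 0))
  expect_error(orientation_vectors(fr_m), "lys558_ca",
    class = "vsp_missing_annotation")
})

test_that("productive angle is the cross product's angle to +z", {
  expect_equal(productive_angle(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(productive_angle(c(1, 0, 0), c(0, 0, 1)), 90)
  # reversed order reflects the angle
  expect_equal(productive_angle(c(1, 0, 0), c(0, 1, 0), "v2xv1"), 180)

  expect_error(productive_angle(c(1, 0, 0), c(2, 0, 0)),
    class = "vsp_degenerate_orientation")

  # random pairs match an acos oracle computed from explicit components
  set.seed(15)
  for (rep in 1:50) {
    v1 <- rnorm(3)
    v2 <- rnorm(3)
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
      v1[3] * v2[1] - v1[1] * v2[3],
      v1[1] * v2[2] - v1[2] * v2[1])
    expected <- acos(sum(cr * c(0, 0, 1)) / sqrt(sum(cr^2))) * 180 / pi
    expect_equal(productive_angle(v1, v2), expected, tolerance = 1e-12)
  }
})

test_that("productive band is closed at 0 and 30 degrees", {
  expect_true(classify_productive(0))
  expect_true(classify_productive(30))
  expect_false(classify_productive(30.1))
  expect_equal(classify_productive(c(15, 90, 29.999)),
    c(TRUE, FALSE, TRUE))
})

test_that("center-of-mass depth supports mass weighting", {
  fr <- make_flat_frame(extra = tibble::tibble(
    role = "pd", x_nm = 0:1, y_nm = 0, z_nm = 5 + c(-0.2, -0.4),
    mass_amu = c(1, 1)))
  expect_equal(com_z(fr, "pd"), -3)

  frw <- make_flat_frame(extra = tibble::tibble(
    role = "pd", x_nm = 0:1, y_nm = 0, z_nm = 5 + c(-0.2, -0.4),
    mass_amu = c(1, 3)))
  expect_equal(com_z(frw, "pd"), -3.5)

  # missing masses fall back to uniform weights
  frn <- make_flat_frame(extra = tibble::tibble(
    role = "pd", x_nm = 0:1, y_nm = 0, z_nm = 5 + c(-0.2, -0.4),
    mass_amu = c(1, NA)))
  expect_equal(com_z(frn, "pd"), -3)

  # weighted-sum oracle
  set.seed(16)
  z <- 5 + rnorm(30, -1, 0.5)
  m <- runif(30, 1, 20)
  frr <- make_flat_frame(extra = tibble::tibble(
    role = "c2", x_nm = runif(30), y_nm = runif(30), z_nm = z, mass_amu = m))
  expect_equal(com_z(frr, "c2"), (sum(m * z) / sum(m) - 5) * 10)
})

test_that("catalytic-center depth asymmetry is |delta z| in Angstrom", {
  fr <- make_flat_frame(extra = tibble::tibble(
    role = c("his332_cb", "lys367_ca"), x_nm = 0:1, y_nm = 0,
    z_nm = c(4, 4)))
  expect_equal(catalytic_depth_asymmetry(fr), 0)

  fr2 <- make_flat_frame(extra = tibble::tibble(
    role = c("his332_cb", "lys367_ca"), x_nm = 0:1, y_nm = 0,
    z_nm = c(4, 3.975)))
  expect_equal(catalytic_depth_asymmetry(fr2), 0.25)
  expect_lt(catalytic_depth_asymmetry(fr2), 0.3)

  set.seed(17)
  for (rep in 1:10) {
    z <- rnorm(2, 3, 1)
    frr <- make_flat_frame(extra = tibble::tibble(
      role = c("his332_cb", "lys367_ca"), x_nm = 0:1, y_nm = 0, z_nm = z))
    expect_equal(catalytic_depth_asymmetry(frr), abs(z[1] - z[2]) * 10)
  }
})

test_that("trajectory classification agrees with the brute-force oracle", {
  sch <- schedule_telegraph(60, 0.5, 0.7, 0.4, seed = 21)
  traj <- sim_membrane_trajectory(sch, "cg", "popc_pip3", seed = 21,
    jitter_sd_nm = 0.02)
  trace <- analyze_trajectory(traj, "cg", "popc_pip3")
  frames <- split(traj, traj$frame)
  for (i in seq_along(frames)) {
    o <- oracle_classify_frame(frames[[i]], "cg", "popc_pip3")
    expect_equal(trace$pd_bound[i], o$pd_bound)
    expect_equal(trace$c2_bound[i], o$c2_bound)
    expect_equal(trace$productive[i], o$productive)
    expect_equal(trace$angle_deg[i], o$angle, tolerance = 1e-10)
    expect_equal(trace$pd_rel_top_A[i], o$pd_rel_top, tolerance = 1e-10)
  }
})

test_that("angle and classification are invariant to z-rotation and translation", {
  sch <- schedule_block(20, 0.5, 0.5, 0.5)
  traj <- sim_membrane_trajectory(sch, "at", "popc", seed = 3,
    jitter_sd_nm = 0.05)
  trace <- analyze_trajectory(traj, "at", "popc")
  moved <- rotate_translate_traj(traj, phi = 0.73, shift = c(2.5, -1.1, 0.6))
  trace2 <- analyze_trajectory(moved, "at", "popc")
  expect_equal(trace2$angle_deg, trace$angle_deg, tolerance = 1e-9)
  expect_equal(trace2$pd_bound, trace$pd_bound)
  expect_equal(trace2$c2_bound, trace$c2_bound)
  expect_equal(trace2$productive, trace$productive)
  # depths shift with the frame, relative depths do not
  expect_equal(trace2$pd_rel_top_A, trace$pd_rel_top_A, tolerance = 1e-9)
})

test_that("binding summary counts frames and respects the AND bound", {
  sch <- schedule_block(100, 0.43, 0.43, 0.43)
  traj <- sim_membrane_trajectory(sch, "at", "popc")
  sm <- summarize_binding(analyze_trajectory(traj, "at", "popc"))
  expect_equal(sm$fraction_pd, 43)

  # saturated case
  sch_all <- schedule_block(25, 1, 1, 1)
  traj_all <- sim_membrane_trajectory(sch_all, "at", "popc")
  sm_all <- summarize_binding(analyze_trajectory(traj_all, "at", "popc"))
  expect_equal(sm_all$fraction_pd, 100)
  expect_equal(sm_all$fraction_c2, 100)
  expect_equal(sm_all$fraction_productive_both_bound, 100)

  # inequality holds on random schedules
  for (s in 1:5) {
    scr <- schedule_telegraph(200, 0.6, 0.5, 0.5, seed = s)
    smr <- summarize_binding(
      analyze_trajectory(sim_membrane_trajectory(scr, "at", "popc"), "at", "popc"))
    expect_lte(smr$fraction_productive_both_bound,
      min(smr$fraction_pd, smr$fraction_c2) + 1e-9)
  }
  expect_error(summarize_binding(tibble::tibble()),
    class = "vsp_trajectory_error")
})

test_that("lowering a cutoff never decreases a binding fraction", {
  sch <- schedule_telegraph(100, 0.5, 0.5, 0.3, seed = 7)
  traj <- sim_membrane_trajectory(sch, "at", "popc", seed = 7,
    jitter_sd_nm = 0.05)
  cuts <- c(0, -2, -4, -12)
  fr_pd <- vapply(cuts, function(cut) {
    cfg <- classifier_config(binding_cutoffs_A = c(
      "at/popc" = cut, "at/popc_pip3" = -4, "cg/popc" = -2,
      "cg/popc_pip3" = -12))
    summarize_binding(analyze_trajectory(traj, "at", "popc", cfg))$fraction_pd
  }, numeric(1))
  expect_true(all(diff(fr_pd) >= 0))
})

test_that("effective time multiplies CG time by four and leaves AT alone", {
  expect_equal(effective_time(500, "cg"), 2000)
  expect_equal(effective_time(100, "at"), 100)
  expect_equal(effective_time(0, "cg"), 0)
})

test_that("trajectory CSV roundtrip preserves the analysis", {
  sch <- schedule_block(10, 0.5, 0.6, 0.4)
  traj <- sim_membrane_trajectory(sch, "at", "popc")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(traj, path, row.names = FALSE)
  traj2 <- read_trajectory_csv(path)
  expect_equal(
    summarize_binding(analyze_trajectory(traj2, "at", "popc")),
    summarize_binding(analyze_trajectory(traj, "at", "popc"))
  )
})

test_that("degenerate orientation frames are flagged and non-productive", {
  sch <- schedule_block(3, 1, 1, 1)
  traj <- sim_membrane_trajectory(sch, "at", "popc")
  # collapse the anchors of frame 2 onto one point
  idx <- traj$frame == 2 &
    traj$role %in% c("arg281_ca", "lys516_ca", "arg520_ca",
      "lys555_ca", "lys558_ca")
  traj$x_nm[idx] <- 0
  traj$y_nm[idx] <- 0
  traj$z_nm[idx] <- 1
  expect_warning(trace <- analyze_trajectory(traj, "at", "popc"),
    "collinear")
  expect_true(trace$degenerate[2])
  expect_false(trace$productive[2])
  expect_true(all(trace$productive[c(1, 3)]))
})
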