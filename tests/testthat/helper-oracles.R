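# Independent brute-force oracles used to cross-check the classifiers and
# fits. These deliberately re-derive everything from raw coordinates with
# plain base R (loops, explicit formulas), sharing no code with the package.

oracle_cutoffs <- c("at/popc" = 0, "at/popc_pip3" = -4,
  "cg/popc" = -2, "cg/popc_pip3" = -12)

oracle_pd_roles <- c("pd", "spine", "arg281_ca", "his332_cb", "lys367_ca")
oracle_c2_roles <- c("c2", "lys516_ca", "arg520_ca", "lys555_ca", "lys558_ca")

oracle_classify_frame <- function(fr, resolution, bilayer) {
  zsum <- 0
  np <- 0
  for (i in seq_len(nrow(fr))) {
    if (fr$role[i] == "phosphorus" && !is.na(fr$monolayer[i]) &&
        fr$monolayer[i] == "proximal") {
      zsum <- zsum + fr$z_nm[i]
      np <- np + 1
    }
  }
  plane <- zsum / np
  top <- function(roles) {
    best <- -Inf
    for (i in seq_len(nrow(fr))) {
      if (fr$role[i] %in% roles && fr$z_nm[i] > best) best <- fr$z_nm[i]
    }
    (best - plane) * 10
  }
  pos <- function(role) {
    i <- which(fr$role == role)
    c(fr$x_nm[i], fr$y_nm[i], fr$z_nm[i])
  }
  o <- pos("arg281_ca")
  m1 <- (pos("lys516_ca") + pos("arg520_ca")) / 2
  m2 <- (pos("lys555_ca") + pos("lys558_ca")) / 2
  v1 <- m1 - o
  v2 <- m2 - o
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
    v1[3] * v2[1] - v1[1] * v2[3],
    v1[1] * v2[2] - v1[2] * v2[1])
  angle <- acos(cr[3] / sqrt(sum(cr^2))) * 180 / pi
  cutoff <- oracle_cutoffs[[paste0(resolution, "/", bilayer)]]
  list(
    pd_rel_top = top(oracle_pd_roles),
    c2_rel_top = top(oracle_c2_roles),
    pd_bound = top(oracle_pd_roles) >= cutoff,
    c2_bound = top(oracle_c2_roles) >= cutoff,
    angle = angle,
    productive = angle >= 0 && angle <= 30
  )
}

# rotation of a trajectory about the z axis plus translation (for invariance
# properties)
rotate_translate_traj <- function(traj, phi, shift = c(0, 0, 0)) {
  x <- traj$x_nm * cos(phi) - traj$y_nm * sin(phi) + shift[1]
  y <- traj$x_nm * sin(phi) + traj$y_nm * cos(phi) + shift[2]
  traj$x_nm <- x
  traj$y_nm <- y
  traj$z_nm <- traj$z_nm + shift[3]
  traj
}

# textbook two-sample equal-variance t statistic and two-sided p
oracle_t_p <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}

# textbook Pearson r from sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

make_flat_frame <- function(z_p = 5, extra = NULL) {
  base <- tibble::tibble(
    frame = 1L, time_ps = 0,
    atom_id = 1:4,
    role = "phosphorus",
    monolayer = c("proximal", "proximal", "distal", "distal"),
    x_nm = c(0, 1, 0, 1), y_nm = 0, z_nm = c(z_p, z_p, z_p + 4, z_p + 4),
    mass_amu = NA_real_
  )
  if (!is.null(extra)) {
    extra$frame <- 1L
    extra$time_ps <- 0
    extra$atom_id <- seq(5, 4 + nrow(extra))
    if (!"monolayer" %in% names(extra)) extra$monolayer <- NA_character_
    if (!"mass_amu" %in% names(extra)) extra$mass_amu <- NA_real_
    base <- dplyr::bind_rows(base, extra)
  }
  base
}
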