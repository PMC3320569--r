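shell_at <- function(n, r, center = c(0, 0, 0), prefix = "w",
                     role = "water-O", residue = NA, species = NA) {
  lapply(seq_len(n), function(i)
    list(id = paste0(prefix, i), role = role, residue = residue,
         species = species,
         x = center[1] + r * cospi(2 * i / n),
         y = center[2] + r * sinpi(2 * i / n), z = center[3]))
}

na_probe <- function(extra, ion = list(id = "ion", role = "ion",
                                       species = "Na", x = 0, y = 0, z = 0)) {
  generate_structure_fixture(c(list(ion), extra))
}

test_that("coordination counts apply the strict species cutoffs", {
  fr <- na_probe(c(shell_at(6, 2.5), shell_at(2, 3.0, prefix = "far")))
  cp <- coordination_shell(fr, "ion")
  expect_equal(cp$total, 6)
  expect_equal(cp$water, 6)
  expect_equal(cp$cutoff, 2.8)
  # oxygen at exactly the cutoff distance is excluded ("closer than")
  fr2 <- na_probe(list(list(id = "edge", role = "water-O",
                            x = 2.8, y = 0, z = 0)))
  expect_equal(coordination_shell(fr2, "ion")$total, 0)
  fr3 <- na_probe(list(list(id = "in", role = "water-O",
                            x = 2.8 - 1e-9, y = 0, z = 0)))
  expect_equal(coordination_shell(fr3, "ion")$total, 1)
})

test_that("K+ shells use 3.2 A and partition counts by oxygen source", {
  fr <- generate_structure_fixture(c(
    list(list(id = "k", role = "ion", species = "K", x = 0, y = 0, z = 0),
         list(id = "glu", role = "sidechain-O", residue = "GLU177",
              x = 2.6, y = 0, z = 0),
         list(id = "ser", role = "sidechain-O", residue = "SER178",
              x = 0, y = 3.1, z = 0)),
    shell_at(4, 3.0)))
  cp <- coordination_shell(fr, "k")
  expect_equal(cp$cutoff, 3.2)
  expect_equal(cp$total, 6)
  expect_equal(cp$water, 4)
  expect_equal(cp$backbone, 0)
  expect_equal(cp$sidechain[["GLU177"]], 1)
  expect_equal(cp$sidechain[["SER178"]], 1)
  expect_equal(cp$total, cp$water + cp$backbone + sum(cp$sidechain))
  expect_error(coordination_shell(fr, "glu"), "not found")
})

test_that("coordination is invariant under rigid rotation and translation", {
  fr <- na_probe(c(shell_at(5, 2.5), shell_at(3, 2.9, prefix = "x"),
                   shell_at(4, 1.9, prefix = "y")))
  ref <- coordination_shell(fr, "ion")
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% R
  fr2 <- fr
  fr2$x <- xyz[, 1] + 5; fr2$y <- xyz[, 2] - 3; fr2$z <- xyz[, 3] + 11
  rot <- coordination_shell(fr2, "ion")
  expect_equal(rot$total, ref$total)
  expect_equal(rot$water, ref$water)
})

filter_frame <- function(ion_z = 5, ion_xy = c(1, 0)) {
  generate_structure_fixture(c(
    shell_at(4, 3, c(0, 0, 0), prefix = "thr", role = "backbone-O",
             residue = "THR175"),
    shell_at(4, 3, c(0, 0, 3), prefix = "leu", role = "backbone-O",
             residue = "LEU176"),
    shell_at(4, 3, c(0, 0, 9), prefix = "glu", role = "sidechain-O",
             residue = "GLU177"),
    list(list(id = "ion", role = "ion", species = "Na",
              x = ion_xy[1], y = ion_xy[2], z = ion_z))))
}

test_that("off-axis displacement and band assignment follow the landmarks", {
  fr <- filter_frame(ion_z = 5, ion_xy = c(1, 0))
  d <- xy_displacement(fr, "ion")
  expect_equal(d$r, 1.0)
  expect_equal(d$band, "B")      # between Leu176 (z=3) and z=6
  expect_equal(xy_displacement(filter_frame(ion_xy = c(0, 0)), "ion")$r, 0)
  # band edges: A = [0, 3), C = [6, 8), D = [8, 10]
  expect_equal(xy_displacement(filter_frame(ion_z = 1), "ion")$band, "A")
  expect_equal(xy_displacement(filter_frame(ion_z = 7), "ion")$band, "C")
  expect_equal(xy_displacement(filter_frame(ion_z = 9.5), "ion")$band, "D")
  expect_equal(xy_displacement(filter_frame(ion_z = 11), "ion")$band,
               "outside")
  expect_equal(xy_displacement(filter_frame(ion_z = -2), "ion")$band,
               "outside")
  # every in-range z maps to exactly one band
  tb <- resolve_bands(fr)
  for (z in seq(0, 9.99, 0.37)) {
    hits <- sum(z >= tb$lower & z < tb$upper)
    expect_equal(hits, 1)
  }
  bad <- axial_band_spec(list(Z = list(lower = landmark("GLY1"),
                                       upper = landmark("THR175"))))
  expect_error(xy_displacement(fr, "ion", bands = bad), "no atoms")
})

test_that("cavity water counting respects the slab and radial cutoff", {
  inside <- shell_at(45, 3, c(0, 0, -4))
  outside <- c(shell_at(5, 9, c(0, 0, -4), prefix = "farr"),
               shell_at(5, 3, c(0, 0, 6), prefix = "above"))
  fr <- generate_structure_fixture(c(
    shell_at(4, 3, c(0, 0, 0), prefix = "thr", role = "backbone-O",
             residue = "THR175"),
    inside, outside))
  expect_equal(cavity_water_count(fr), 45)
  expect_equal(cavity_water_count(fr, zlim = c(0, 0)), 0)
  expect_equal(cavity_water_count(generate_structure_fixture(list())), 0)
})

test_that("frame subsampling picks one frame per 20 ps after equilibration", {
  traj <- lapply(seq(0, 449), function(t)
    generate_structure_fixture(list(list(id = "ion", role = "ion",
                                         species = "Na", x = 0, y = 0,
                                         z = t / 100)), time = t))
  picked <- subsample_frames(traj, stride = 20, t_start = 50)
  expect_length(picked, 20)
  expect_equal(vapply(picked, frame_time, numeric(1)), seq(50, 430, by = 20))
  # a 500-frame, 1-ps trajectory yields 23 snapshots up to t = 490
  traj500 <- lapply(seq(0, 499), function(t)
    generate_structure_fixture(list(list(id = "i", role = "ion",
                                         species = "Na", x = 0, y = 0,
                                         z = 0)), time = t))
  expect_length(subsample_frames(traj500, 20, 50), 23)
  expect_length(subsample_frames(traj500, 499, 0), 2)
  expect_error(subsample_frames(traj500, 20, 1000), "beyond")
})
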