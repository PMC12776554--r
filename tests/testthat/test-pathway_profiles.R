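make_water_traj <- function(xyz_by_frame, box = c(40, 40, 160)) {
  parts <- do.call(rbind, lapply(seq_along(xyz_by_frame), function(i) {
    m <- xyz_by_frame[[i]]
    data.frame(time_ns = (i - 1) * 0.25, id = seq_len(nrow(m)),
               species = "water", x = m[, 1], y = m[, 2], z = m[, 3],
               stringsAsFactors = FALSE)
  }))
  trajectory(parts, box = box)
}

test_that("density grid counts land in the right voxels and are conserved", {
  one <- lapply(1:10, function(i) matrix(c(0.1, 0.1, 0.1), ncol = 3))
  tr <- make_water_traj(one)
  g <- water_density_grid(tr)
  expect_equal(sum(g$counts), 10)
  expect_equal(max(g$counts), 10)  # a single voxel holds everything

  set.seed(4)
  rnd <- lapply(1:5, function(i)
    cbind(runif(200, -12, 12), runif(200, -17, 17), runif(200, -74, 74)))
  tr2 <- make_water_traj(rnd)
  g2 <- water_density_grid(tr2)
  expect_equal(sum(g2$counts), 1000)  # all observations in the box
})

test_that("uniform occupancy gives Poisson-distributed voxel counts", {
  set.seed(8)
  ## many points in a small box -> per-voxel counts ~ Poisson(lambda)
  n <- 20000
  rnd <- list(cbind(runif(n, -5, 5), runif(n, -5, 5), runif(n, -5, 5)))
  tr <- make_water_traj(rnd, box = c(12, 12, 12))
  g <- water_density_grid(tr, box_spec = list(center = c(0, 0, 0),
                                              dims = c(10, 10, 10),
                                              spacing = 1))
  counts <- as.vector(g$counts)
  lam <- mean(counts)
  ## chi-square GOF against Poisson(lambda), pooling the tail
  kmax <- max(counts)
  obs <- tabulate(counts + 1, nbins = kmax + 1)
  p <- stats::dpois(0:kmax, lam)
  p[kmax + 1] <- 1 - sum(p[1:kmax])
  keep <- p * length(counts) >= 5
  chi <- sum((obs[keep] - length(counts) * p[keep])^2 /
             (length(counts) * p[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 2, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("pathway spline of a straight water cylinder is the axis", {
  set.seed(5)
  frames <- lapply(1:20, function(i) {
    n <- 2000
    r <- sqrt(runif(n)) * 3
    a <- runif(n, 0, 2 * pi)
    cbind(2 + r * cos(a), -1 + r * sin(a), runif(n, -70, 70))
  })
  tr <- make_water_traj(frames)
  g <- water_density_grid(tr)
  sp <- pathway_spline(g, node_spacing = 0.5)
  expect_lt(max(abs(sp$nodes[, "x"] - 2)), 0.5)
  expect_lt(max(abs(sp$nodes[, "y"] + 1)), 0.5)
  ## node spacing within 1%
  d <- sqrt(rowSums(diff(sp$nodes)^2))
  expect_lt(max(abs(d - 0.5)), 0.005)
})

test_that("pathway spline recovers an analytic helix within 0.6 A RMSD", {
  ## waters laid tightly on a helix of radius 3 A
  helix <- function(z) cbind(3 * cos(2 * pi * z / 120), 3 * sin(2 * pi * z / 120), z)
  set.seed(6)
  frames <- lapply(1:10, function(i) {
    z <- runif(2000, -70, 70)
    helix(z) + cbind(rnorm(2000, 0, 0.2), rnorm(2000, 0, 0.2), 0)
  })
  tr <- make_water_traj(frames)
  g <- water_density_grid(tr)
  sp <- pathway_spline(g, node_spacing = 0.5)
  truth <- helix(sp$nodes[, "z"])
  rmsd <- sqrt(mean(rowSums((sp$nodes - truth)^2)))
  expect_lt(rmsd, 0.6)
})

test_that("pathway spline is equivariant under rotation about z", {
  set.seed(9)
  frames <- lapply(1:10, function(i) {
    r <- sqrt(runif(400)) * 2
    a <- runif(400, 0, 2 * pi)
    cbind(3 + r * cos(a), r * sin(a), runif(400, -70, 70))
  })
  th <- 70 * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  tr <- make_water_traj(frames)
  tr_rot <- make_water_traj(lapply(frames, function(m) m %*% t(rot)))
  sp <- pathway_spline(water_density_grid(tr), node_spacing = 2.5)
  sp_rot <- pathway_spline(water_density_grid(tr_rot), node_spacing = 2.5)
  n <- min(nrow(sp$nodes), nrow(sp_rot$nodes))
  expect_lt(max(abs(sp$nodes[1:n, ] %*% t(rot) - sp_rot$nodes[1:n, ])), 0.7)
})

test_that("ion density profile handles empty and single-ion cases", {
  path <- straight_path(c(-20, 20), 0.5)
  ## no ions at all
  w <- trajectory(data.frame(time_ns = 0, id = 1, species = "water",
                             x = 0, y = 0, z = 0), box = c(10, 10, 40))
  prof <- ion_density_profile(w, path)
  expect_true(all(prof$value == 0))
  expect_error(ion_density_profile(w, path, radial_cutoff = 0), "positive")
  ## single ion held at s = 0 occupies exactly one bin
  tr <- traj_from_z(rep(0, 6))
  prof2 <- ion_density_profile(tr, path)
  expect_equal(sum(attr(prof2, "counts") > 0), 1)
  expect_equal(sum(attr(prof2, "counts")), 6)
})

test_that("profile counts are conserved", {
  set.seed(2)
  tr <- traj_from_z_list(replicate(4, runif(50, -30, 30), simplify = FALSE))
  path <- straight_path(c(-20, 20), 0.5)
  prof <- ion_density_profile(tr, path, radial_cutoff = 7, bin = 0.5)
  ## every observation within the cutoff of its nearest node is binned; on
  ## the axis the distance to the terminal node is |z| - 20, so everything
  ## with |z| <= 27 counts
  nn_in <- sum(pmax(abs(tr$particles$z) - 20, 0) <= 7)
  expect_equal(sum(attr(prof, "counts")), nn_in)
})

test_that("Boltzmann inversion recovers the landscape from its own density", {
  ls <- landscape_preset("paper2Ca")
  cfg <- bd_config(seed = 1)
  dens <- equilibrium_density(ls, cfg, bin = 0.5)
  fe <- free_energy_profile(dens)
  expect_true(all(abs(fe$value[!fe$mask] -
                      landscape_energy(ls, fe$s[!fe$mask])) < 0.1))
  ## uniform density -> identically zero energy
  flat <- profile_1d(s = seq(-30, 30, 1), value = rep(2.5, 61), bin = 1)
  fe0 <- free_energy_profile(flat)
  expect_true(all(abs(fe0$value) < 1e-12))
  ## all-zero bulk is an error
  dead <- profile_1d(s = seq(-30, 30, 1), value = rep(0, 61), bin = 1)
  expect_error(free_energy_profile(dead), "bulk")
})

test_that("inversion is the identity on random landscapes (property)", {
  set.seed(77)
  cfg <- bd_config(seed = 1)
  for (i in 1:20) {
    ls <- random_landscape()
    fe <- free_energy_profile(equilibrium_density(ls, cfg, bin = 0.5))
    ok <- !fe$mask
    expect_lt(max(abs(fe$value[ok] - landscape_energy(ls, fe$s[ok]))), 0.1)
  }
})

test_that("zero-count bins are masked, not infinite", {
  dens <- profile_1d(s = seq(-20, 20, 1), value = c(rep(1, 18), 0, 0, 0,
                                                    rep(1, 20)), bin = 1)
  fe <- free_energy_profile(dens, bulk_region = list(c(-20, -15), c(15, 20)))
  expect_equal(sum(fe$mask), 3)
  expect_true(all(is.finite(fe$value[!fe$mask])))
  ## readout interpolates across gaps of <= 2 bins, else undefined
  expect_true(is.na(profile_value_at(fe, -1)))
  dens2 <- profile_1d(s = seq(-20, 20, 1), value = c(rep(1, 19), 0,
                                                     rep(1, 21)), bin = 1)
  fe2 <- free_energy_profile(dens2, bulk_region = list(c(-20, -15), c(15, 20)))
  expect_false(is.na(profile_value_at(fe2, -1)))
})

test_that("radius profile is the vdW-reduced distance, capped when empty", {
  path <- straight_path(c(0, 0), 0.5)
  ## single carbon (vdW 1.7) at 5 A from the node
  frame <- data.frame(x = 5, y = 0, z = 0, element = "C")
  r <- radius_profile(frame, path)
  expect_equal(r$value, 3.3, tolerance = 1e-12)
  ## ring of 12 nitrogen atoms at radius 4 around the axis
  a <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- data.frame(x = 4 * cos(a), y = 4 * sin(a), z = 0, element = "N")
  r2 <- radius_profile(ring, path)
  expect_equal(r2$value, 4 - 1.55, tolerance = 1e-12)
  ## nothing within 20 A -> capped
  far <- data.frame(x = 100, y = 0, z = 0, element = "C")
  expect_equal(radius_profile(far, path)$value, 20)
  expect_error(radius_profile(frame[0, ], path), "no protein atoms")
})
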