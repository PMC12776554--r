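# Fixture builders shared across the test files. Everything is generated
# in code at test time; no stored data files.

# trajectory from a per-frame z-series of a single ion on the z axis
traj_from_z <- function(z, dt = 0.25, species = "ion:Cl", id = 1L) {
  trajectory(data.frame(
    time_ns = (seq_along(z) - 1) * dt, id = id, species = species,
    x = 0, y = 0, z = z, stringsAsFactors = FALSE),
    box = c(10, 10, max(1, diff(range(z)))))
}

# multi-particle trajectory from a list of z-series (shared time base)
traj_from_z_list <- function(zl, dt = 0.25, species = "ion:Cl") {
  nf <- length(zl[[1]])
  parts <- do.call(rbind, lapply(seq_along(zl), function(i) {
    data.frame(time_ns = (seq_len(nf) - 1) * dt, id = i, species = species,
               x = 0, y = 0, z = zl[[i]], stringsAsFactors = FALSE)
  }))
  trajectory(parts, box = c(10, 10, max(1, diff(range(unlist(zl))))))
}

# independent brute-force permeation scanner: walks the full z-series of
# one ion and counts completed traversals with an explicit state machine
# (deliberately different in structure from detect_permeation)
oracle_count_events <- function(z, s_lo, s_hi) {
  outward <- inward <- 0L
  came_from <- 0L  # -1 entered from below, +1 from above, 0 not inside
  for (v in z) {
    if (v < s_lo) {
      if (came_from == 1L) inward <- inward + 1L
      came_from <- -999L  # mark "currently below"
    } else if (v > s_hi) {
      if (came_from == -1L) outward <- outward + 1L
      came_from <- 999L
    } else {
      if (came_from == -999L) came_from <- -1L
      if (came_from == 999L) came_from <- 1L
      # if already -1/+1, keep the original entry side
      if (came_from == 0L) came_from <- 0L  # started inside: no credit
    }
  }
  c(outward = outward, inward = inward)
}

# a flat landscape (no wells or barriers) spanning [-s, s]
flat_landscape <- function(s_half = 44) {
  pore_landscape(c(C = -10, B = 0, A = 10), c(C = 0, B = 0, A = 0),
    data.frame(name = c("bulk_int-C", "C-B", "B-A", "A-bulk_ext"),
               s = c(-15, -5, 5, 15), G = 0, stringsAsFactors = FALSE),
    s_lo = -s_half, s_hi = s_half)
}

# mirror-symmetric two-well landscape
symmetric_landscape <- function(well = -1.5, barrier = 2) {
  pore_landscape(c(C = -10, B = 0, A = 10),
                 c(C = well, B = 0, A = well),
    data.frame(name = c("bulk_int-C", "C-B", "B-A", "A-bulk_ext"),
               s = c(-15, -5, 5, 15),
               G = c(barrier / 2, barrier, barrier, barrier / 2),
               stringsAsFactors = FALSE),
    s_lo = -20, s_hi = 20)
}

# random landscape generator for property-style tests
random_landscape <- function() {
  se <- c(C = runif(1, -3, 1), B = runif(1, -2, 1), A = runif(1, -2, 1))
  tops <- c(max(0, se["C"]), max(se["C"], se["B"]),
            max(se["B"], se["A"]), max(se["A"], 0)) + runif(4, 0.3, 3)
  pore_landscape(c(C = -10, B = 0, A = 10), se,
    data.frame(name = c("bulk_int-C", "C-B", "B-A", "A-bulk_ext"),
               s = c(-15, -5, 5, 15), G = tops, stringsAsFactors = FALSE),
    s_lo = -20, s_hi = 20)
}

# ideal alpha-helix C-alpha coordinates, optionally bent at the centre
helix_ca <- function(n = 11, radius = 2.3, rise = 1.5, twist = 100,
                     bend_deg = 0) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  m <- cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
  if (bend_deg != 0) {
    mid <- (n + 1) / 2
    ang <- bend_deg * pi / 180
    rot <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0,
                    -sin(ang), 0, cos(ang)), 3, 3, byrow = TRUE)
    pivot <- m[mid, ]
    upper <- seq_len(n) > mid
    m[upper, ] <- sweep(sweep(m[upper, , drop = FALSE], 2, pivot) %*% t(rot),
                        2, pivot, "+")
  }
  m
}

traj_from_atoms <- function(coords, atom = NULL, species = "protein-atom",
                            times = 0) {
  n <- nrow(coords)
  parts <- do.call(rbind, lapply(times, function(tt) {
    data.frame(time_ns = tt, id = seq_len(n), species = species,
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               atom = if (is.null(atom)) "CA" else atom,
               stringsAsFactors = FALSE)
  }))
  trajectory(parts, box = c(50, 50, 50))
}

# minimal CHARMM-style DCD writer (binary fixture generated at test time)
write_minimal_dcd <- function(coords, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    bytes <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(bytes), con, size = 4)
    writeBin(bytes, con)
    writeBin(length(bytes), con, size = 4)
  }
  nf <- as.integer(length(coords))
  natom <- as.integer(nrow(coords[[1]]))
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L
    icntrl[4] <- nf; icntrl[20] <- 24L
    writeBin(as.integer(icntrl), c2, size = 4)
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4)
    writeChar(formatC("generated fixture", width = 80, flag = "-"), c2,
              nchars = 80, eos = NULL)
  })
  rec(function(c2) writeBin(natom, c2, size = 4))
  for (f in coords) {
    for (ax in 1:3) {
      rec(function(c2) writeBin(as.numeric(f[, ax]), c2, size = 4))
    }
  }
  invisible(path)
}

# minimal PDB writer via bio3d for topology fixtures
write_minimal_pdb <- function(resid, path, elety = NULL) {
  n <- length(resid)
  if (is.null(elety)) {
    elety <- ifelse(resid %in% c("CLA", "POT", "CAL"),
                    substr(resid, 1, 2),
                    ifelse(resid %in% c("TIP3", "HOH"), "OH2", "CA"))
  }
  bio3d::write.pdb(file = path,
                   xyz = rep(0, 3 * n),
                   resno = seq_len(n), resid = resid, elety = elety)
  invisible(path)
}
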