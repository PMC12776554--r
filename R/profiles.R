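#' 1D profile along the pore coordinate
#'
#' Container for values (density, free energy, radius, potential) on a
#' uniform grid of the path coordinate s.
#'
#' @param s Bin centres (A), uniform spacing.
#' @param value Values per bin.
#' @param bin Bin width (A).
#' @param mask Logical, `TRUE` where the value is undefined (default: no
#'   masked bins).
#' @param unit Free-text unit tag.
#' @param radial_cutoff Radial cutoff used when counting (A), if any.
#' @return Object of class `"profile_1d"`.
#' @export
profile_1d <- function(s, value, bin, mask = NULL, unit = "",
                       radial_cutoff = NA_real_) {
  stopifnot(length(s) == length(value))
  if (length(s) > 1) {
    stopifnot(max(abs(diff(s) - bin)) < 1e-6 * bin)
  }
  if (is.null(mask)) mask <- rep(FALSE, length(s))
  structure(list(s = as.numeric(s), value = as.numeric(value),
                 mask = as.logical(mask), bin = bin, unit = unit,
                 radial_cutoff = radial_cutoff),
            class = "profile_1d")
}

#' @export
print.profile_1d <- function(x, ...) {
  cat("profile_1d:", length(x$s), "bins of", x$bin, "A over [",
      min(x$s), ",", max(x$s), "];", sum(x$mask), "masked;",
      "unit:", x$unit, "\n")
  invisible(x)
}

#' @export
as.data.frame.profile_1d <- function(x, ...) {
  data.frame(s = x$s, value = x$value, mask = x$mask)
}

#' Read a profile value at arbitrary s
#'
#' Linear interpolation between unmasked bins. Masked gaps of at most
#' `max_gap` consecutive bins are bridged; a query falling in a wider gap
#' (or outside the grid) returns `NA` - finite sampling must not fabricate
#' values across large unsampled stretches.
#'
#' @param profile A [profile_1d()].
#' @param s Query positions (A).
#' @param max_gap Widest masked run (in bins) to interpolate across.
#' @return Numeric vector of values (NA where undefined).
#' @export
profile_value_at <- function(profile, s, max_gap = 2) {
  ok <- !profile$mask & is.finite(profile$value)
  if (sum(ok) < 2) return(rep(NA_real_, length(s)))
  sg <- profile$s[ok]
  vg <- profile$value[ok]
  out <- stats::approx(sg, vg, xout = s, rule = 1)$y
  ## invalidate queries bridging gaps wider than max_gap bins
  gap_limit <- (max_gap + 1) * profile$bin + 1e-9
  for (k in seq_along(s)) {
    if (is.na(out[k])) next
    i_hi <- findInterval(s[k], sg)
    if (i_hi >= 1 && i_hi < length(sg)) {
      if ((sg[i_hi + 1] - sg[i_hi]) > gap_limit) out[k] <- NA_real_
    }
  }
  out
}

.default_box_spec <- function(center = c(0, 0, 0)) {
  list(center = center, dims = c(25, 35, 150), spacing = 0.5)
}

#' 3D water (or ion) occupancy-count grid
#'
#' Counts particle observations in voxels of an analysis box (default
#' 25 x 35 x 150 A^3 at 0.5 A resolution) centred on a reference point.
#' Voxel assignment is `floor((r - origin)/spacing)` with half-open voxels.
#'
#' @param traj A [trajectory()].
#' @param box_spec List with `center` (length-3), `dims` (box edge lengths,
#'   A) and `spacing` (A); see defaults.
#' @param species Species to count (default water).
#' @return Object of class `"density_grid"`: list with the 3D `counts`
#'   array, axis voxel-centre coordinates `xc`,`yc`,`zc`, `origin`,
#'   `spacing`, `n_frames` and `species`.
#' @export
water_density_grid <- function(traj, box_spec = .default_box_spec(),
                               species = "water") {
  p <- traj_species(traj, species)
  if (nrow(p) == 0) stop("trajectory has no '", species, "' particles")
  sp <- box_spec$spacing
  nvox <- as.integer(round(box_spec$dims / sp))
  origin <- box_spec$center - box_spec$dims / 2
  ix <- floor((p$x - origin[1]) / sp)
  iy <- floor((p$y - origin[2]) / sp)
  iz <- floor((p$z - origin[3]) / sp)
  inb <- ix >= 0 & ix < nvox[1] & iy >= 0 & iy < nvox[2] & iz >= 0 & iz < nvox[3]
  if (!any(inb)) {
    warning("analysis box lies outside the coordinate range; empty grid")
  }
  counts <- array(0L, dim = nvox)
  if (any(inb)) {
    flat <- 1 + ix[inb] + nvox[1] * (iy[inb] + nvox[2] * iz[inb])
    tab <- tabulate(flat, nbins = prod(nvox))
    counts <- array(tab, dim = nvox)
  }
  axc <- function(k) origin[k] + (seq_len(nvox[k]) - 0.5) * sp
  structure(list(counts = counts, xc = axc(1), yc = axc(2), zc = axc(3),
                 origin = origin, spacing = sp, n_frames = n_frames(traj),
                 species = species),
            class = "density_grid")
}

#' Pore pathway from a water-density grid
#'
#' For each z slice of the density grid the density-weighted centroid
#' (x, y) is computed; a smoothing spline is fit through the centroid
#' sequence (smoothness chosen so the residual per populated slice is at
#' most one voxel, 0.5 A) and the curve is resampled at uniform arc-length
#' spacing. The arc-length coordinate s is zeroed where the curve crosses
#' the reference z (the grid centre) and increases with z (extracellular).
#'
#' @param grid A [water_density_grid()].
#' @param node_spacing Arc-length node spacing (A); 0.5 for density
#'   profiling, 2.5 for flux binning.
#' @param z_ref Reference z for s = 0 (default: grid centre).
#' @return Object of class `"path_spline"`: list with `nodes` (n x 3
#'   matrix), `s` (arc length, A) and `spacing`.
#' @export
pathway_spline <- function(grid, node_spacing = 0.5, z_ref = NULL) {
  if (is.null(z_ref)) z_ref <- mean(range(grid$zc))
  slice_tot <- apply(grid$counts, 3, sum)
  pop <- slice_tot > 0
  if (sum(pop) < 4) stop("fewer than 4 populated z-slices in the grid")
  cx <- cy <- rep(NA_real_, length(grid$zc))
  xm <- apply(grid$counts, c(1, 3), sum)  # x-by-z marginal
  ym <- apply(grid$counts, c(2, 3), sum)
  cx[pop] <- colSums(xm[, pop, drop = FALSE] * grid$xc) / slice_tot[pop]
  cy[pop] <- colSums(ym[, pop, drop = FALSE] * grid$yc) / slice_tot[pop]
  if (any(!pop)) {
    message(sum(!pop), " empty z-slice(s); centroids interpolated from ",
            "nearest populated neighbours")
    cx <- stats::approx(grid$zc[pop], cx[pop], xout = grid$zc, rule = 2)$y
    cy <- stats::approx(grid$zc[pop], cy[pop], xout = grid$zc, rule = 2)$y
  }
  zc <- grid$zc
  w <- pmax(slice_tot, 1)
  fit_axis <- function(v) {
    n_pop <- sum(pop)
    for (df in unique(pmin(c(4, 8, 16, 32, 64, n_pop), n_pop))) {
      f <- stats::smooth.spline(zc, v, w = w, df = df)
      if (max(abs(stats::predict(f, zc[pop])$y - v[pop])) <= 0.5) return(f)
    }
    f
  }
  fx <- fit_axis(cx)
  fy <- fit_axis(cy)
  zf <- seq(min(zc), max(zc), length.out = max(2000, 10 * length(zc)))
  xf <- stats::predict(fx, zf)$y
  yf <- stats::predict(fy, zf)$y
  seg <- sqrt(diff(xf)^2 + diff(yf)^2 + diff(zf)^2)
  arc <- c(0, cumsum(seg))
  arc_ref <- stats::approx(zf, arc, xout = z_ref)$y
  s_all <- arc - arc_ref
  s_nodes <- seq(ceiling(min(s_all) / node_spacing) * node_spacing,
                 floor(max(s_all) / node_spacing) * node_spacing,
                 by = node_spacing)
  nodes <- cbind(stats::approx(s_all, xf, xout = s_nodes)$y,
                 stats::approx(s_all, yf, xout = s_nodes)$y,
                 stats::approx(s_all, zf, xout = s_nodes)$y)
  colnames(nodes) <- c("x", "y", "z")
  structure(list(nodes = nodes, s = s_nodes, spacing = node_spacing),
            class = "path_spline")
}

#' Straight pore path along the z axis
#'
#' Convenience constructor for analyses of the synthetic cylindrical pore,
#' whose pathway is the z axis by construction.
#'
#' @param s_range Length-2 range of s (A).
#' @param spacing Node spacing (A).
#' @return A `"path_spline"` object.
#' @export
straight_path <- function(s_range, spacing = 0.5) {
  s <- seq(s_range[1], s_range[2], by = spacing)
  nodes <- cbind(x = 0, y = 0, z = s)
  structure(list(nodes = nodes, s = s, spacing = spacing),
            class = "path_spline")
}

#' @export
print.path_spline <- function(x, ...) {
  cat("path_spline:", nrow(x$nodes), "nodes every", x$spacing, "A, s in [",
      min(x$s), ",", max(x$s), "]\n")
  invisible(x)
}

#' Ion (or water) density profile along the pathway
#'
#' Each particle observation is assigned to its nearest path node and
#' counted if its distance to the path is at most `radial_cutoff`; counts
#' are binned along s and normalised per frame and per bin volume
#' (pi cutoff^2 x bin).
#'
#' @param traj A [trajectory()].
#' @param path A path from [pathway_spline()] or [straight_path()].
#' @param radial_cutoff Radial cutoff (A), must be positive.
#' @param bin Bin width along s (A).
#' @param species Species to count.
#' @return A [profile_1d()] in counts/A^3 per frame, with attribute
#'   `"counts"` (raw in-cutoff counts per bin).
#' @export
ion_density_profile <- function(traj, path, radial_cutoff = 7, bin = 0.5,
                                species = "ion:Cl") {
  if (radial_cutoff <= 0) stop("radial_cutoff must be positive")
  p <- traj_species(traj, species)
  edges <- seq(min(path$s) - bin / 2, max(path$s) + bin / 2, by = bin)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- rep(0L, length(centers))
  if (nrow(p) > 0) {
    nn <- nearest_node_cpp(p$x, p$y, p$z, path$nodes)
    keep <- nn$dist <= radial_cutoff
    if (any(keep)) {
      s_obs <- path$s[nn$index[keep]]
      bi <- findInterval(s_obs, edges, rightmost.closed = TRUE)
      tab <- tabulate(bi, nbins = length(centers))
      counts <- tab
    }
  }
  vol <- pi * radial_cutoff^2 * bin
  prof <- profile_1d(s = centers, value = counts / (n_frames(traj) * vol),
                     bin = bin, unit = "counts/A^3/frame",
                     radial_cutoff = radial_cutoff)
  attr(prof, "counts") <- counts
  prof
}

#' Free-energy profile by Boltzmann inversion
#'
#' G(s) = -ln(rho(s)/rho_bulk) in kT, where rho_bulk is the mean density
#' over the designated bulk bins. Zero-count bins are masked (undefined)
#' rather than set to +Inf.
#'
#' @param density A density [profile_1d()].
#' @param bulk_region Either a logical vector over bins, a length-2 s
#'   interval list `list(c(lo,hi), c(lo,hi))`, or `NULL` for the default:
#'   the outer 15 A of the profiled range on each side.
#' @return A [profile_1d()] in kT, zero (on average) in the bulk region.
#' @export
free_energy_profile <- function(density, bulk_region = NULL) {
  s <- density$s
  if (is.null(bulk_region)) {
    bulk <- s <= min(s) + 15 | s >= max(s) - 15
  } else if (is.logical(bulk_region)) {
    bulk <- bulk_region
  } else {
    bulk <- rep(FALSE, length(s))
    for (iv in bulk_region) bulk <- bulk | (s >= iv[1] & s <= iv[2])
  }
  if (!any(bulk)) stop("empty bulk region")
  rho_bulk <- mean(density$value[bulk])
  if (!is.finite(rho_bulk) || rho_bulk <= 0) {
    stop("bulk region has no density; cannot set the energy reference")
  }
  mask <- density$value <= 0
  g <- rep(NA_real_, length(s))
  g[!mask] <- -log(density$value[!mask] / rho_bulk)
  profile_1d(s = s, value = g, bin = density$bin, mask = mask, unit = "kT",
             radial_cutoff = density$radial_cutoff)
}

.vdw_table <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
.vdw_default <- 1.7

#' Pore radius profile from a single frame
#'
#' At each path node the radius is the minimum over protein atoms of
#' (centre distance - atom van der Waals radius), from a built-in element
#' table, capped at 20 A when no atom is nearby. A simplified geometric
#' stand-in for sphere-inflation pore profilers.
#'
#' @param frame data.frame of protein atoms (columns `x`,`y`,`z`, and
#'   `element` or `atom` to infer the element).
#' @param path A path object.
#' @param cap Radius cap (A).
#' @return A [profile_1d()] of radii (A).
#' @export
radius_profile <- function(frame, path, cap = 20) {
  if (nrow(frame) == 0) stop("no protein atoms in frame")
  if (!is.null(frame$element)) {
    el <- toupper(frame$element)
  } else if (!is.null(frame$atom)) {
    el <- toupper(substr(gsub("[0-9]", "", frame$atom), 1, 1))
  } else {
    el <- rep("C", nrow(frame))
  }
  vdw <- .vdw_table[el]
  vdw[is.na(vdw)] <- .vdw_default
  n <- nrow(path$nodes)
  r <- numeric(n)
  for (j in seq_len(n)) {
    d <- sqrt((frame$x - path$nodes[j, 1])^2 +
              (frame$y - path$nodes[j, 2])^2 +
              (frame$z - path$nodes[j, 3])^2) - vdw
    r[j] <- min(min(d), cap)
  }
  spacing <- if (n > 1) path$s[2] - path$s[1] else 1
  profile_1d(s = path$s, value = r, bin = spacing, unit = "A")
}
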