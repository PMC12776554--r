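#' Pore free-energy landscape
#'
#' A one-dimensional free-energy landscape G(s) along the pore axis
#' (s in Angstrom, increasing towards the extracellular side, s = 0 at the
#' pore centre), defined by three ion-binding sites A (outer), B (central)
#' and C (inner/cytoplasmic), the four barriers separating them from each
#' other and from the two bulk solutions, and bulk boundaries
#' `s_lo < s_hi`. G is interpolated through the site minima and barrier
#' maxima with a natural cubic spline and is identically 0 (bulk reference)
#' outside `[s_lo, s_hi]`.
#'
#' @param sites Named numeric, positions of sites `C`, `B`, `A`
#'   (must satisfy s_C < s_B < s_A).
#' @param site_energies Named numeric `C`, `B`, `A` in kT.
#' @param barriers data.frame with columns `name` (one of
#'   `"bulk_int-C"`, `"C-B"`, `"B-A"`, `"A-bulk_ext"`), `s` (position, A)
#'   and `G` (barrier top energy, kT).
#' @param s_lo,s_hi Bulk boundaries (Angstrom).
#' @return Object of class `"pore_landscape"`.
#' @seealso [landscape_preset()], [landscape_energy()]
#' @export
pore_landscape <- function(sites, site_energies, barriers, s_lo, s_hi) {
  sites <- sites[c("C", "B", "A")]
  site_energies <- site_energies[c("C", "B", "A")]
  if (anyNA(sites) || anyNA(site_energies)) stop("sites C, B, A must all be given")
  if (!(sites["C"] < sites["B"] && sites["B"] < sites["A"])) {
    stop("site order must be s_C < s_B < s_A (C is cytoplasmic/inner)")
  }
  if (!(s_lo < sites["C"] && sites["A"] < s_hi)) {
    stop("bulk boundaries must bracket the sites")
  }
  need <- c("bulk_int-C", "C-B", "B-A", "A-bulk_ext")
  if (!all(need %in% barriers$name)) {
    stop("barriers must include: ", paste(need, collapse = ", "))
  }
  barriers <- barriers[match(need, barriers$name), , drop = FALSE]
  ## each barrier top must sit at or above both adjacent levels
  adj <- rbind(
    c(0, site_energies["C"]),
    c(site_energies["C"], site_energies["B"]),
    c(site_energies["B"], site_energies["A"]),
    c(site_energies["A"], 0)
  )
  if (any(barriers$G < pmax(adj[, 1], adj[, 2]) - 1e-9)) {
    stop("barrier energies must be >= adjacent site energies")
  }
  s_knots <- c(s_lo, barriers$s[1], sites["C"], barriers$s[2], sites["B"],
               barriers$s[3], sites["A"], barriers$s[4], s_hi)
  if (any(diff(s_knots) <= 0)) stop("barrier positions must interleave the sites")
  g_knots <- c(0, barriers$G[1], site_energies["C"], barriers$G[2],
               site_energies["B"], barriers$G[3], site_energies["A"],
               barriers$G[4], 0)
  sf <- stats::splinefun(s_knots, g_knots, method = "natural")
  structure(
    list(sites = sites, site_energies = site_energies, barriers = barriers,
         s_lo = s_lo, s_hi = s_hi,
         s_knots = as.numeric(s_knots), g_knots = as.numeric(g_knots),
         spline = sf),
    class = "pore_landscape"
  )
}

#' @export
print.pore_landscape <- function(x, ...) {
  cat("pore_landscape over [", x$s_lo, ",", x$s_hi, "] A\n")
  cat("  sites (A / kT):",
      paste(sprintf("%s: %.1f / %.2f", names(x$sites), x$sites,
                    x$site_energies), collapse = "; "), "\n")
  cat("  barriers (A / kT):",
      paste(sprintf("%s: %.1f / %.2f", x$barriers$name, x$barriers$s,
                    x$barriers$G), collapse = "; "), "\n")
  invisible(x)
}

#' Evaluate the landscape free energy G(s)
#'
#' @param landscape A [pore_landscape()].
#' @param s Positions along the pore axis (Angstrom); vectorised.
#' @param deriv 0 for G (kT) or 1 for dG/ds (kT/Angstrom).
#' @return Numeric vector; 0 outside `[s_lo, s_hi]`.
#' @export
landscape_energy <- function(landscape, s, deriv = 0) {
  out <- landscape$spline(s, deriv = deriv)
  out[s <= landscape$s_lo | s >= landscape$s_hi] <- 0
  out
}

#' Named landscape presets
#'
#' `"paper2Ca"` is the doubly Ca2+-bound conduction landscape: sites A and B
#' level with solution (0 kT), site C stabilised at -2.5 kT, a ~2 kT barrier
#' between A and B, a ~1 kT entrance bump from the extracellular bulk, and
#' the two large barriers flanking site C at +3.5 kT, so that the climbs out
#' of site C are 6 kT on both sides (the cytoplasmic entrance barrier is
#' 3.5 kT as seen from bulk). `"paper1Ca"` encodes the effect of removing
#' the lower (cytoplasmic) Ca2+: site C destabilised by 4 kT (to +1.5 kT)
#' with both flanking barriers raised by 2 kT; sites A and B are essentially
#' unchanged.
#'
#' @param name `"paper2Ca"` or `"paper1Ca"`.
#' @return A [pore_landscape()].
#' @export
landscape_preset <- function(name = c("paper2Ca", "paper1Ca")) {
  name <- match.arg(name)
  sites <- c(C = -10, B = 0, A = 10)
  s_b <- c(-15, -5, 5, 15)
  bn <- c("bulk_int-C", "C-B", "B-A", "A-bulk_ext")
  if (name == "paper2Ca") {
    se <- c(C = -2.5, B = 0, A = 0)
    gb <- c(3.5, 3.5, 2, 1)
  } else {
    se <- c(C = 1.5, B = 0, A = 0)
    gb <- c(5.5, 5.5, 2, 1)
  }
  pore_landscape(sites, se,
                 data.frame(name = bn, s = s_b, G = gb,
                            stringsAsFactors = FALSE),
                 s_lo = -20, s_hi = 20)
}

#' Write / read a landscape as JSON
#'
#' @param landscape A [pore_landscape()].
#' @param path JSON file path.
#' @return `path` (write) or a [pore_landscape()] (read).
#' @export
write_landscape <- function(landscape, path) {
  jsonlite::write_json(
    list(sites = as.list(landscape$sites),
         site_energies = as.list(landscape$site_energies),
         barriers = landscape$barriers,
         s_lo = landscape$s_lo, s_hi = landscape$s_hi),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pore_landscape(unlist(j$sites), unlist(j$site_energies), j$barriers,
                 j$s_lo, j$s_hi)
}
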