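#' @useDynLib porekinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default residue-name to species mapping
#'
#' Maps force-field residue names to the particle species used by the
#' analysis functions. Extend or override by passing a modified copy to
#' [read_trajectory()]; naming schemes vary between force fields.
#'
#' @return Named character vector, names are residue names, values are
#'   species strings (`"ion:Cl"`, `"ion:K"`, `"ion:Ca"`, `"water"`).
#' @export
default_species_map <- function() {
  c(CLA = "ion:Cl", CL = "ion:Cl",
    POT = "ion:K",  K = "ion:K",
    CAL = "ion:Ca", CA2 = "ion:Ca",
    TIP3 = "water", TIP3P = "water", HOH = "water", WAT = "water",
    SOL = "water", SPC = "water")
}

.known_species <- c("ion:Cl", "ion:K", "ion:Ca", "water", "protein-atom")

#' Construct a trajectory object
#'
#' A trajectory is a time-ordered set of frames of labelled particle
#' coordinates. It is stored in long form: one row per particle per frame.
#'
#' @param particles data.frame with columns `time_ns`, `id`, `species`,
#'   `x`, `y`, `z` (coordinates in Angstrom). Optional columns `resname`,
#'   `resno`, `atom` annotate protein atoms.
#' @param box Numeric length-3 box lengths (Angstrom). If `NULL`, taken as
#'   the coordinate range per axis.
#' @return Object of class `"trajectory"`: a list with elements
#'   `particles`, `times` (sorted unique frame times, ns) and `box`.
#' @export
trajectory <- function(particles, box = NULL) {
  req <- c("time_ns", "id", "species", "x", "y", "z")
  missing_cols <- setdiff(req, names(particles))
  if (length(missing_cols) > 0) {
    stop("particle table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  particles$species <- as.character(particles$species)
  bad <- setdiff(unique(particles$species), .known_species)
  if (length(bad) > 0) {
    stop("unknown species label(s): ", paste(bad, collapse = ", "))
  }
  xyz <- as.matrix(particles[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  times <- sort(unique(particles$time_ns))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  ## persistent particles: identical id set in every frame
  n_per_frame <- table(particles$time_ns)
  if (length(unique(as.integer(n_per_frame))) != 1) {
    stop("particle count varies between frames; persistent particles required")
  }
  if (is.null(box)) {
    box <- apply(xyz, 2, function(v) diff(range(v)))
    box[box <= 0] <- 1
  }
  if (length(box) != 3 || any(box <= 0)) stop("box lengths must be 3 positive values")
  structure(
    list(particles = particles, times = times, box = as.numeric(box)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  sp <- table(x$particles$species) / length(x$times)
  cat("trajectory:", length(x$times), "frames,",
      nrow(x$particles) / length(x$times), "particles/frame\n")
  cat("  time span:", min(x$times), "-", max(x$times), "ns\n")
  cat("  box (A):", paste(signif(x$box, 4), collapse = " x "), "\n")
  cat("  species:", paste(names(sp), round(as.numeric(sp)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Subset a trajectory by species
#' @param traj A [trajectory()].
#' @param species Character vector of species labels to keep.
#' @return data.frame of the matching particle rows.
#' @export
traj_species <- function(traj, species) {
  traj$particles[traj$particles$species %in% species, , drop = FALSE]
}

#' Read a trajectory
#'
#' Reads either a PDB topology plus a DCD coordinate file, or the
#' documented plain-CSV dialect (`time_ns,id,species,x,y,z`, one row per
#' particle per frame) used for hand-built fixtures and the synthetic pore
#' generator. Species for PDB/DCD input are assigned from residue names via
#' `species_map`; unmapped residues become `"protein-atom"` only when they
#' look like amino-acid residues, otherwise an error names the offending
#' residue so the map can be extended.
#'
#' @param topology_path PDB file (for binary coordinate input), or `NULL`.
#' @param coords_path DCD coordinate file, or `NULL`.
#' @param table_path CSV fixture file, or `NULL`. Exactly one of
#'   `coords_path`/`table_path` must be given.
#' @param dt_ns Frame spacing in ns for DCD input (frames carry no time
#'   stamps; the default matches a 0.25 ns save interval).
#' @param species_map Residue-name mapping, see [default_species_map()].
#' @param box Optional box lengths (Angstrom) for CSV input.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(topology_path = NULL, coords_path = NULL,
                            table_path = NULL, dt_ns = 0.25,
                            species_map = default_species_map(),
                            box = NULL) {
  if (!is.null(table_path)) {
    if (!file.exists(table_path)) stop("file not found: ", table_path)
    tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
    req <- c("time_ns", "id", "species", "x", "y", "z")
    if (!all(req %in% names(tab))) {
      stop("CSV trajectory must have header: ", paste(req, collapse = ","))
    }
    ## allow raw residue names in the species column of fixtures
    raw <- tab$species
    mapped <- ifelse(raw %in% .known_species, raw,
                     unname(species_map[raw]))
    if (anyNA(mapped)) {
      off <- unique(raw[is.na(mapped)])
      stop("unknown species naming scheme; offending residue name(s): ",
           paste(off, collapse = ", "))
    }
    tab$species <- mapped
    return(trajectory(tab, box = box))
  }
  if (is.null(coords_path) || is.null(topology_path)) {
    stop("provide either table_path, or both topology_path and coords_path")
  }
  if (!file.exists(topology_path)) stop("file not found: ", topology_path)
  if (!file.exists(coords_path)) stop("file not found: ", coords_path)
  pdb <- bio3d::read.pdb(topology_path)
  dcd <- bio3d::read.dcd(coords_path, verbose = FALSE)
  resid <- pdb$atom$resid
  species <- unname(species_map[resid])
  is_protein <- is.na(species) & resid %in% bio3d::aa.table$aa3
  species[is_protein] <- "protein-atom"
  if (anyNA(species)) {
    off <- unique(resid[is.na(species)])
    stop("unknown species naming scheme; offending residue name(s): ",
         paste(off, collapse = ", "))
  }
  n_atoms <- nrow(pdb$atom)
  n_fr <- nrow(dcd)
  idx <- seq_len(n_atoms)
  parts <- data.frame(
    time_ns = rep((seq_len(n_fr) - 1) * dt_ns, each = n_atoms),
    id = rep(idx, n_fr),
    species = rep(species, n_fr),
    x = as.vector(t(dcd[, 3 * idx - 2, drop = FALSE])),
    y = as.vector(t(dcd[, 3 * idx - 1, drop = FALSE])),
    z = as.vector(t(dcd[, 3 * idx, drop = FALSE])),
    resname = rep(resid, n_fr),
    resno = rep(pdb$atom$resno, n_fr),
    atom = rep(pdb$atom$elety, n_fr),
    stringsAsFactors = FALSE
  )
  trajectory(parts, box = box)
}

#' Write a trajectory in the CSV dialect
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$particles[, c("time_ns", "id", "species", "x", "y", "z")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tabular result with schema check
#'
#' @param rows data.frame of results.
#' @param path Output CSV path.
#' @param schema Optional character vector of required column names; a
#'   mismatch is an error.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, schema = NULL) {
  if (!is.null(schema)) {
    if (!identical(sort(schema), sort(names(rows)))) {
      stop("schema mismatch: expected columns {",
           paste(schema, collapse = ", "), "}, got {",
           paste(names(rows), collapse = ", "), "}")
    }
    rows <- rows[, schema, drop = FALSE]
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tabular result written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
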