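# Trajectory container and I/O.
#
# A trajectory_view holds an atom table (one row per atom), an nframes x 3N
# coordinate matrix in bio3d xyz layout (x1,y1,z1,x2,...) in Angstrom, and
# frame timestamps in ps (strictly increasing, regularly spaced).

#' Construct a trajectory view
#'
#' @param atoms data.frame with columns `atom_id`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `is_heavy`, `vdw`.
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns
#'   (bio3d xyz layout), coordinates in Angstrom.
#' @param times numeric vector of frame times in ps.
#' @return object of class `trajectory_view`.
#' @export
trajectory_view <- function(atoms, xyz, times) {
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("coordinate/atom count mismatch: ", ncol(xyz) / 3, " vs ", nrow(atoms),
         " atoms", call. = FALSE)
  if (nrow(xyz) != length(times))
    stop("frame/time count mismatch", call. = FALSE)
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-6)
      stop("frame times must be regularly spaced (within 1e-6 ps)", call. = FALSE)
  }
  structure(list(atoms = atoms, xyz = xyz, times = as.numeric(times)),
            class = "trajectory_view")
}

#' @export
print.trajectory_view <- function(x, ...) {
  cat("trajectory_view:", nrow(x$atoms), "atoms,", nrow(x$xyz), "frames,",
      if (length(x$times) > 1) paste0("dt = ", diff(x$times)[1], " ps") else "single frame",
      "\n")
  invisible(x)
}

n_frames <- function(tv) nrow(tv$xyz)
n_atoms <- function(tv) nrow(tv$atoms)

#' Coordinates of one frame as an N x 3 matrix
#'
#' @param tv trajectory_view.
#' @param frame frame index (1-based).
#' @return N x 3 matrix of coordinates in Angstrom.
#' @export
frame_coords <- function(tv, frame = 1L) {
  matrix(tv$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Restrict a trajectory view to a selection
#'
#' @param tv trajectory_view.
#' @param selection selection string (see [select_atoms()]) or integer indices.
#' @return trajectory_view with the selected atoms only.
#' @export
subset_trajectory <- function(tv, selection) {
  idx <- if (is.numeric(selection)) as.integer(selection)
         else select_atoms(tv$atoms, selection)
  if (length(idx) == 0L)
    stop("selection matched no atoms: '", selection, "'", call. = FALSE)
  cols <- as.vector(t(outer(idx - 1L, 1:3, function(i, k) 3L * i + k)))
  trajectory_view(tv$atoms[idx, , drop = FALSE], tv$xyz[, cols, drop = FALSE],
                  tv$times)
}

.atoms_from_pdb <- function(pdb) {
  ele <- tryCatch(suppressWarnings(suppressMessages(bio3d::atom2ele(pdb))),
                  error = function(e) NULL)
  if (is.null(ele)) {
    # fall back: first alphabetic character of the atom name
    ele <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", pdb$atom$elety)), 1, 1))
  }
  data.frame(
    atom_id = seq_len(nrow(pdb$atom)),
    name = pdb$atom$elety,
    element = ele,
    resname = pdb$atom$resid,
    resid = pdb$atom$resno,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    is_heavy = toupper(ele) != "H",
    vdw = vdw_radius(ele),
    stringsAsFactors = FALSE
  )
}

#' Load a trajectory from disk
#'
#' Reads a PDB topology and, optionally, a separate coordinate trajectory.
#' Supported coordinate formats: DCD and multi-model PDB (when
#' `trajectory_path` is `NULL`, the models of the topology file are used as
#' frames). XTC/TRR are not readable here; convert to DCD or multi-model PDB
#' first.
#'
#' @param topology_path path to a PDB file.
#' @param trajectory_path optional path to a DCD or multi-model PDB file.
#' @param selection selection string, default `"all"`.
#' @param dt_ps frame spacing in ps used to stamp frame times (formats read
#'   here carry no time axis), default 10.
#' @param t0_ps time of the first frame in ps, default 0.
#' @return a [trajectory_view()] restricted to the selection.
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL,
                            selection = "all", dt_ps = 10, t0_ps = 0) {
  if (!file.exists(topology_path))
    stop("topology file not found: ", topology_path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("unreadable PDB topology '", topology_path,
                                           "': ", conditionMessage(e), call. = FALSE))
  atoms <- .atoms_from_pdb(pdb)
  if (is.null(trajectory_path)) {
    xyz <- rbind(pdb$xyz)
  } else {
    if (!file.exists(trajectory_path))
      stop("trajectory file not found: ", trajectory_path, call. = FALSE)
    ext <- tolower(tools::file_ext(trajectory_path))
    xyz <- switch(ext,
      dcd = tryCatch(bio3d::read.dcd(trajectory_path, verbose = FALSE),
                     error = function(e) stop("unreadable DCD '", trajectory_path,
                                              "': ", conditionMessage(e), call. = FALSE)),
      pdb = rbind(tryCatch(bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE),
                           error = function(e) stop("unreadable PDB trajectory '",
                                                    trajectory_path, "': ",
                                                    conditionMessage(e), call. = FALSE))$xyz),
      xtc = ,
      trr = stop("XTC/TRR reading is not supported; convert '", trajectory_path,
                 "' to DCD or multi-model PDB", call. = FALSE),
      stop("unrecognised trajectory format '.", ext, "' for ", trajectory_path,
           call. = FALSE)
    )
  }
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("atom-count mismatch between topology (", nrow(atoms),
         " atoms) and trajectory (", ncol(xyz) / 3, " atoms)", call. = FALSE)
  times <- t0_ps + dt_ps * (seq_len(nrow(xyz)) - 1)
  tv <- trajectory_view(atoms, xyz, times)
  subset_trajectory(tv, selection)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param tv trajectory_view.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(tv, path) {
  a <- tv$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(tv))) {
    co <- frame_coords(tv, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$atom_id %% 100000L,
      ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
      a$resname, substr(paste0(a$chain, " "), 1, 1), a$resid %% 10000L,
      co[, 1], co[, 2], co[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
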