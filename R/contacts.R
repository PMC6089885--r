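# Monomer-monomer interface contact maps.
#
# Two heavy atoms of different monomers are "in contact" when their distance
# is within a cutoff (default 4.0 A); an atom pair is persistent when the
# contact holds in at least a minimum fraction of frames (default 70%).
# Persistent atom pairs are aggregated to residue pairs and normalised by
# the map's maximum to give contact frequencies.

#' Contact criteria
#'
#' @param distance_cutoff contact distance in Angstrom, default 4.0.
#' @param min_fraction minimum fraction of frames, default 0.70.
#' @param heavy_atoms_only restrict to non-hydrogen atoms, default TRUE.
#' @return object of class `contact_criteria`.
#' @export
contact_criteria <- function(distance_cutoff = 4.0, min_fraction = 0.70,
                             heavy_atoms_only = TRUE) {
  if (distance_cutoff <= 0) stop("distance_cutoff must be > 0", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  structure(list(distance_cutoff = distance_cutoff,
                 min_fraction = min_fraction,
                 heavy_atoms_only = heavy_atoms_only),
            class = "contact_criteria")
}

.contact_sets <- function(tv, sel_A, sel_B, criteria) {
  ia <- if (is.numeric(sel_A)) as.integer(sel_A) else select_atoms(tv$atoms, sel_A)
  ib <- if (is.numeric(sel_B)) as.integer(sel_B) else select_atoms(tv$atoms, sel_B)
  if (criteria$heavy_atoms_only) {
    ia <- ia[tv$atoms$is_heavy[ia]]
    ib <- ib[tv$atoms$is_heavy[ib]]
  }
  if (length(ia) == 0L || length(ib) == 0L)
    stop("contact selection matched no atoms", call. = FALSE)
  if (length(intersect(ia, ib)) > 0L)
    stop("atom sets A and B overlap", call. = FALSE)
  list(ia = ia, ib = ib)
}

# Squared distance matrix between two atom index sets at one frame.
.pair_dist2 <- function(tv, frame, ia, ib) {
  co <- frame_coords(tv, frame)
  A <- co[ia, , drop = FALSE]; B <- co[ib, , drop = FALSE]
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

#' Inter-monomer atom contacts in one frame
#'
#' All (heavy) atom pairs across two disjoint atom sets within the distance
#' cutoff, found exactly.
#'
#' @param traj trajectory_view.
#' @param frame frame index.
#' @param sel_A,sel_B selections (strings or atom indices) of the two
#'   monomers; must be disjoint.
#' @param criteria contact_criteria.
#' @return data.frame with columns `atom_A`, `atom_B` (atom ids) and
#'   `distance` (Angstrom).
#' @export
frame_contacts <- function(traj, frame, sel_A, sel_B,
                           criteria = contact_criteria()) {
  s <- .contact_sets(traj, sel_A, sel_B, criteria)
  d2 <- .pair_dist2(traj, frame, s$ia, s$ib)
  hit <- which(d2 <= criteria$distance_cutoff^2, arr.ind = TRUE)
  data.frame(atom_A = traj$atoms$atom_id[s$ia[hit[, 1]]],
             atom_B = traj$atoms$atom_id[s$ib[hit[, 2]]],
             distance = sqrt(pmax(d2[hit], 0)))
}

#' Persistent interface contact map
#'
#' Atom pairs within the cutoff in at least `min_fraction` of frames are
#' persistent; persistent atom pairs are counted per residue pair and the
#' counts normalised by the map maximum.
#'
#' @param traj trajectory_view (>= 10 frames).
#' @param sel_A,sel_B monomer selections; disjoint.
#' @param criteria contact_criteria.
#' @return object of class `contact_matrix`: `rows`/`cols` (residue labels
#'   `"<resname><resid>"` of monomers A and B), `count` (persistent atom
#'   pairs per residue pair), `frequency` (count / max count), `persistent`
#'   (logical), `atom_fraction` (data.frame of persistent atom pairs with
#'   their contact fractions), `criteria`.
#' @export
persistent_contact_map <- function(traj, sel_A, sel_B,
                                   criteria = contact_criteria()) {
  if (n_frames(traj) < 10L)
    stop("need at least 10 frames for persistence statistics", call. = FALSE)
  s <- .contact_sets(traj, sel_A, sel_B, criteria)
  nf <- n_frames(traj)
  cut2 <- criteria$distance_cutoff^2
  hits <- matrix(0L, length(s$ia), length(s$ib))
  for (f in seq_len(nf)) hits <- hits + (.pair_dist2(traj, f, s$ia, s$ib) <= cut2)
  frac <- hits / nf
  persist <- frac >= criteria$min_fraction - 1e-12
  resA <- paste0(traj$atoms$resname[s$ia], traj$atoms$resid[s$ia])
  resB <- paste0(traj$atoms$resname[s$ib], traj$atoms$resid[s$ib])
  ulabA <- unique(resA[order(traj$atoms$resid[s$ia])])
  ulabB <- unique(resB[order(traj$atoms$resid[s$ib])])
  count <- matrix(0L, length(ulabA), length(ulabB),
                  dimnames = list(ulabA, ulabB))
  pp <- which(persist, arr.ind = TRUE)
  if (nrow(pp)) {
    tab <- table(factor(resA[pp[, 1]], levels = ulabA),
                 factor(resB[pp[, 2]], levels = ulabB))
    count[] <- as.integer(tab)
  }
  mx <- max(count)
  structure(list(rows = ulabA, cols = ulabB, count = count,
                 frequency = if (mx > 0) count / mx else count * 0,
                 persistent = count >= 1L,
                 atom_fraction = data.frame(
                   atom_A = traj$atoms$atom_id[s$ia[pp[, 1]]],
                   atom_B = traj$atoms$atom_id[s$ib[pp[, 2]]],
                   fraction = frac[pp]),
                 criteria = criteria),
            class = "contact_matrix")
}

#' Contact difference map
#'
#' Cellwise `frequency(map1) - frequency(map2)` on the union of residue
#' pairs; pairs missing from one map contribute 0. For cross-paralog
#' comparisons, `mapping` translates map2 residue labels into map1's
#' coordinate system (e.g. from a sequence alignment).
#'
#' @param map1,map2 contact_matrix objects.
#' @param mapping optional named character vectors `list(rows = c(old =
#'   new), cols = c(old = new))` renaming map2 labels into map1's system.
#' @return matrix of signed frequency differences with map-union dimnames.
#' @export
contact_difference_map <- function(map1, map2, mapping = NULL) {
  r2 <- map2$rows; c2 <- map2$cols
  if (!is.null(mapping)) {
    if (!is.null(mapping$rows)) {
      bad <- setdiff(r2, names(mapping$rows))
      if (length(bad))
        stop("unmappable row labels in map2: ", paste(bad, collapse = ", "),
             call. = FALSE)
      r2 <- unname(mapping$rows[r2])
    }
    if (!is.null(mapping$cols)) {
      bad <- setdiff(c2, names(mapping$cols))
      if (length(bad))
        stop("unmappable column labels in map2: ", paste(bad, collapse = ", "),
             call. = FALSE)
      c2 <- unname(mapping$cols[c2])
    }
  }
  rows <- union(map1$rows, r2); cols <- union(map1$cols, c2)
  d <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  d[map1$rows, map1$cols] <- d[map1$rows, map1$cols] + map1$frequency
  d[r2, c2] <- d[r2, c2] - map2$frequency
  d
}
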