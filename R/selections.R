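# Atom selection grammar and van der Waals radius assignment.

# Bondi-style radii (Angstrom); used by the pore profiler and contact maps.
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
.vdw_default <- 1.70

.water_resnames <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "TIP4", "SPC", "H2O")

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "MSE")

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @param table named numeric vector of radii in Angstrom overriding the
#'   built-in Bondi-style defaults (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20).
#' @return numeric vector of radii; unknown elements get 1.70 A.
#' @export
vdw_radius <- function(element, table = NULL) {
  tab <- .vdw_table
  if (!is.null(table)) tab[names(table)] <- table
  r <- unname(tab[toupper(element)])
  r[is.na(r)] <- .vdw_default
  r
}

#' Select atoms by a simple selection expression
#'
#' The grammar is a conjunction of clauses joined by `" and "`. Clauses:
#' \describe{
#'   \item{`all`}{every atom}
#'   \item{`protein`}{standard amino-acid residue names}
#'   \item{`water`}{common water residue names (HOH, SOL, TIP3, ...)}
#'   \item{`heavy`}{non-hydrogen atoms}
#'   \item{`name N1 N2 ...`}{atom names}
#'   \item{`resname R1 R2 ...`}{residue names}
#'   \item{`resid 5 8:12 ...`}{residue ids, single or `lo:hi` ranges}
#'   \item{`chain A B ...`}{chain / monomer labels}
#'   \item{`element O N ...`}{element symbols}
#'   \item{`not <clause>`}{negation of one clause}
#' }
#'
#' @param atoms data.frame of atom records (see [load_trajectory()]).
#' @param selection selection string.
#' @return integer vector of row indices into `atoms`.
#' @export
select_atoms <- function(atoms, selection) {
  if (!is.character(selection) || length(selection) != 1L || !nzchar(trimws(selection)))
    stop("selection must be a single non-empty string", call. = FALSE)
  clauses <- strsplit(trimws(selection), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) keep <- keep & .eval_clause(atoms, trimws(cl))
  which(keep)
}

.eval_clause <- function(atoms, clause) {
  if (startsWith(clause, "not ")) return(!.eval_clause(atoms, trimws(sub("^not ", "", clause))))
  toks <- strsplit(clause, "\\s+")[[1]]
  key <- tolower(toks[1])
  args <- toks[-1]
  switch(key,
    all = rep(TRUE, nrow(atoms)),
    protein = atoms$resname %in% .aa3,
    water = atoms$resname %in% .water_resnames,
    heavy = atoms$is_heavy,
    name = atoms$name %in% args,
    resname = atoms$resname %in% args,
    resid = atoms$resid %in% .parse_ranges(args),
    chain = atoms$chain %in% args,
    element = toupper(atoms$element) %in% toupper(args),
    stop("unknown selection clause: '", clause, "'", call. = FALSE)
  )
}

.parse_ranges <- function(args) {
  out <- integer(0)
  for (a in args) {
    if (grepl(":", a, fixed = TRUE)) {
      lohi <- as.integer(strsplit(a, ":", fixed = TRUE)[[1]])
      out <- c(out, seq.int(lohi[1], lohi[2]))
    } else out <- c(out, as.integer(a))
  }
  out
}
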