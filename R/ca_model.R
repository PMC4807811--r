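#' @keywords internal
"_PACKAGE"

# Average amino-acid residue masses (Da), i.e. monomer mass minus water,
# lumped at the Calpha position.
.residue_mass_table <- c(
  ALA = 71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY = 57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO = 97.1167, SER = 87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL = 99.1326
)

.aa_one_letter <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Residue masses for three-letter residue names
#'
#' Looks up average amino-acid residue masses (monomer minus water, in Da).
#' Unknown residue names fall back to the mean of the twenty standard
#' residues, with a warning.
#'
#' @param resnames character vector of three-letter residue names.
#' @return numeric vector of masses in atomic mass units.
#' @export
residue_masses <- function(resnames) {
  m <- .residue_mass_table[toupper(resnames)]
  if (anyNA(m)) {
    warning("unknown residue name(s): ",
            paste(unique(resnames[is.na(m)]), collapse = ", "),
            "; using mean residue mass")
    m[is.na(m)] <- mean(.residue_mass_table)
  }
  unname(m)
}

#' Construct a Calpha model
#'
#' A `ca_model` is the node set of the elastic network: one Calpha per
#' residue with a position (in nanometres) and a mass (in Da). Masses
#' default to full residue masses lumped at the Calpha; pass
#' `masses = "unit"` for unit masses.
#'
#' @param coords N x 3 numeric matrix of Calpha positions, nanometres.
#' @param atoms data.frame with columns `chain`, `resno`, `ins`, `resname`;
#'   defaults to a single chain "A", sequential numbering, alanines.
#' @param masses numeric vector of N positive masses (Da), or `"residue"`
#'   (default, from `resname`) or `"unit"`.
#' @param label free-text identifier for the structure.
#' @return object of class `ca_model` with fields `atoms`, `coords`,
#'   `masses`, `mass_convention`, `label`.
#' @export
ca_model <- function(coords, atoms = NULL, masses = "residue", label = "model") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 2L) stop("a ca_model needs at least 2 atoms")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(atoms)) {
    atoms <- data.frame(chain = "A", resno = seq_len(n), ins = "",
                        resname = "ALA", stringsAsFactors = FALSE)
  }
  if (nrow(atoms) != n) stop("atoms and coords disagree on N")
  key <- paste(atoms$chain, atoms$resno, atoms$ins)
  if (anyDuplicated(key)) stop("duplicate (chain, resno, ins) atom identifiers")
  mass_convention <- "explicit"
  if (is.character(masses)) {
    masses <- match.arg(masses, c("residue", "unit"))
    mass_convention <- masses
    masses <- if (mass_convention == "unit") rep(1, n) else residue_masses(atoms$resname)
  }
  masses <- as.numeric(masses)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be N positive finite numbers")
  structure(list(atoms = atoms, coords = coords, masses = masses,
                 mass_convention = mass_convention, label = label),
            class = "ca_model")
}

#' @export
print.ca_model <- function(x, ...) {
  cat(sprintf("<ca_model> %s: %d Calpha atoms, %d chain(s), masses: %s\n",
              x$label, nrow(x$coords), length(unique(x$atoms$chain)),
              x$mass_convention))
  invisible(x)
}

#' Number of atoms in a Calpha model
#' @param model a `ca_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$coords)

#' Pairwise Calpha--Calpha distance matrix (nm)
#' @param model a `ca_model`.
#' @return N x N symmetric matrix of Euclidean distances in nanometres.
#' @export
ca_distances <- function(model) {
  as.matrix(stats::dist(model$coords))
}

#' Apply a rigid transformation to a model
#'
#' Utility used by the invariance tests and the synthetic generator:
#' rotates coordinates by `rotation` and then translates by `translation`.
#'
#' @param model a `ca_model`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector, nm.
#' @return transformed `ca_model`.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  model$coords <- model$coords %*% t(rotation) +
    matrix(translation, nrow(model$coords), 3, byrow = TRUE)
  model
}
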