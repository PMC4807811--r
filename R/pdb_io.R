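#' Read Calpha atoms from a PDB file into a `ca_model`
#'
#' One Calpha per residue (highest-occupancy altloc, first-listed on
#' ties); coordinates are converted from Angstrom to nanometres. Several
#' chains can be selected into one model (biological-assembly analysis);
#' residue ranges are inclusive of both endpoints in author numbering.
#'
#' @param path PDB file path.
#' @param chain chain identifier(s) to keep, or NULL for all chains.
#' @param residue_range `c(lo, hi)` inclusive author-numbering range
#'   applied to every selected chain, or NULL for all residues.
#' @param model_index which MODEL block to read (default 1).
#' @param masses passed to [ca_model()] ("residue" or "unit").
#' @param label structure label; defaults to the file name.
#' @return a [ca_model()].
#' @export
read_pdb_ca <- function(path, chain = NULL, residue_range = NULL,
                        model_index = 1L, masses = "residue", label = NULL) {
  pdb <- bio3d::read.pdb(path, multi = model_index > 1L, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) {
    if (!all(chain %in% at$chain))
      stop("chain(s) not in file: ",
           paste(setdiff(chain, at$chain), collapse = ", "))
    at <- at[at$chain %in% chain, , drop = FALSE]
  }
  if (!is.null(residue_range))
    at <- at[at$resno >= residue_range[1] & at$resno <= residue_range[2], ,
             drop = FALSE]
  if (nrow(at) == 0L) stop("empty selection")
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, at$ins)
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(unique(key), paste(ca$chain, ca$resno, ca$ins))
  if (length(missing_ca))
    stop("residue(s) lacking a Calpha: ", paste(missing_ca, collapse = "; "))
  # altloc: highest occupancy, ties to the first-listed record
  cakey <- paste(ca$chain, ca$resno, ca$ins)
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(cakey, unique(cakey))),
                        function(ix) ix[which.max(occ[ix])]))
  ca <- ca[sort(keep), , drop = FALSE]
  coords <- as.matrix(ca[, c("x", "y", "z")])
  if (model_index > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index)
      stop("model_index ", model_index, " not present")
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    coords <- xyz[ca$eleno, , drop = FALSE]
  }
  atoms <- data.frame(chain = ca$chain, resno = ca$resno, ins = ca$ins,
                      resname = ca$resid, stringsAsFactors = FALSE)
  ca_model(coords / 10, atoms, masses = masses,
           label = label %||% sub("\\.pdb$", "", basename(path)))
}

#' Write a `ca_model` as a Calpha-only PDB file
#'
#' Single-model ATOM records (element CA), coordinates converted
#' nanometres to Angstrom.
#'
#' @param model a `ca_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(model, path) {
  n <- n_atoms(model)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(model$coords * 10)),
                   resno = model$atoms$resno,
                   resid = model$atoms$resname,
                   chain = model$atoms$chain,
                   insert = ifelse(model$atoms$ins == "", NA, model$atoms$ins),
                   eleno = seq_len(n),
                   elety = rep("CA", n))
  invisible(path)
}
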