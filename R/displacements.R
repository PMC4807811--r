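#' Secondary-structure annotation as residue index ranges
#'
#' Records the strand/helix/accessory elements of a barrel fold as
#' inclusive residue-index ranges (1-based positions in the Calpha model).
#' The eight strand ranges form the barrel set and the eight helix ranges
#' the bundle set of the idealized-displacement analysis.
#'
#' @param strands,helices,accessory each a 2-column matrix or list of
#'   `c(start, end)` ranges (inclusive); `accessory` may be empty.
#' @return object of class `sse_annotation` with a data.frame `elements`
#'   (`kind`, `ordinal`, `start`, `end`).
#' @export
sse_annotation <- function(strands, helices, accessory = list()) {
  as_ranges <- function(x, kind) {
    if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    if (length(x) == 0L) return(NULL)
    data.frame(kind = kind, ordinal = seq_along(x),
               start = vapply(x, `[`, 0, 1), end = vapply(x, `[`, 0, 2))
  }
  el <- rbind(as_ranges(strands, "strand"), as_ranges(helices, "helix"),
              as_ranges(accessory, "accessory"))
  if (any(el$end < el$start)) stop("range end before start")
  for (k in unique(el$kind)) {
    r <- el[el$kind == k, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
      stop("overlapping ", k, " ranges")
  }
  structure(list(elements = el), class = "sse_annotation")
}

#' Residue indices covered by an annotation kind
#' @param sse an [sse_annotation()].
#' @param kind "strand", "helix" or "accessory"; or an ordinal-filtered
#'   selection via `ordinal`.
#' @param ordinal optional element ordinal within the kind.
#' @return integer vector of residue indices.
#' @export
sse_residues <- function(sse, kind, ordinal = NULL) {
  el <- sse$elements[sse$elements$kind == kind, , drop = FALSE]
  if (!is.null(ordinal)) el <- el[el$ordinal %in% ordinal, , drop = FALSE]
  if (nrow(el) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(el)), function(i) seq.int(el$start[i], el$end[i])))
}

#' Principal axis of inertia of a residue selection
#'
#' The axis with the smallest moment of inertia (the long axis) of the
#' selected Calpha masses, with its sign fixed to point from the
#' N-terminal toward the C-terminal end of the selection. A nearly
#' degenerate inertia spectrum (relative gap below 1e-6) triggers a
#' warning; ties are broken deterministically by eigen's ordering.
#'
#' @param model a `ca_model`.
#' @param selection integer vector of residue indices, length >= 3.
#' @return list `axis` (unit 3-vector), `center` (mass-weighted centre),
#'   `moments` (ascending), `degenerate` (logical).
#' @export
principal_axis <- function(model, selection) {
  if (length(selection) < 3L) stop("selection must contain at least 3 atoms")
  x <- model$coords[selection, , drop = FALSE]
  m <- model$masses[selection]
  center <- colSums(x * m) / sum(m)
  xc <- sweep(x, 2, center)
  r2 <- rowSums(xc^2)
  I <- diag(sum(m * r2), 3) - t(xc * m) %*% xc
  e <- eigen(I, symmetric = TRUE)
  moments <- rev(e$values)           # ascending
  axis <- e$vectors[, 3]             # smallest moment
  degenerate <- (moments[2] - moments[1]) <= 1e-6 * max(abs(moments))
  if (degenerate)
    warning("near-degenerate inertia spectrum; axis chosen deterministically")
  # orient from N-terminal half toward C-terminal half of the selection
  half <- ceiling(length(selection) / 2)
  dirvec <- colMeans(x[seq.int(half + 1, length(selection)), , drop = FALSE]) -
    colMeans(x[seq_len(half), , drop = FALSE])
  if (sum(axis * dirvec) < 0) axis <- -axis
  list(axis = axis, center = center, moments = moments, degenerate = degenerate)
}

.ideal <- function(field, motion, target, geometry, n) {
  v <- as.vector(t(field))
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("zero ideal displacement field")
  structure(list(vector = v / nrm, motion = motion, target = target,
                 geometry = geometry),
            class = "ideal_displacement")
}

#' Idealized rigid-group displacement of a selection
#'
#' Translation along, or infinitesimal rotation about, the selection's
#' principal axis of inertia. Components outside the selection are zero;
#' the 3N vector is normalised to unit Euclidean length. The vector lives
#' in Cartesian coordinates; [omega_w()] converts to the mode convention.
#'
#' @param model a `ca_model`.
#' @param selection residue indices of the group.
#' @param motion "translation" or "rotation".
#' @return an `ideal_displacement` object.
#' @export
group_displacement <- function(model, selection,
                               motion = c("translation", "rotation")) {
  motion <- match.arg(motion)
  pa <- principal_axis(model, selection)
  n <- n_atoms(model)
  field <- matrix(0, n, 3)
  if (motion == "translation") {
    field[selection, ] <- matrix(pa$axis, length(selection), 3, byrow = TRUE)
  } else {
    rel <- sweep(model$coords[selection, , drop = FALSE], 2, pa$center)
    # omega x r for unit omega along the axis
    field[selection, ] <- cbind(
      pa$axis[2] * rel[, 3] - pa$axis[3] * rel[, 2],
      pa$axis[3] * rel[, 1] - pa$axis[1] * rel[, 3],
      pa$axis[1] * rel[, 2] - pa$axis[2] * rel[, 1])
  }
  .ideal(field, paste0("group_", motion), selection, pa, n)
}

#' Idealized per-helix displacement vectors
#'
#' Five named motions of a single helix (all unit 3N vectors, zero outside
#' the helix):
#' \describe{
#'   \item{vertical}{uniform translation along the helix's own principal
#'     axis.}
#'   \item{horizontal}{uniform translation along the radial direction
#'     (structure centre of mass to helix centre of mass, orthogonalised
#'     against the barrel axis).}
#'   \item{tilt}{N- and C-terminal halves displaced radially in opposite
#'     directions, magnitude growing linearly from the helix midpoint.}
#'   \item{bend_N, bend_C}{only the named terminal half displaced radially
#'     with a linear ramp from the midpoint; the other half stays put.}
#' }
#' Halves split at the median residue; odd lengths give the extra residue
#' to the N-half.
#'
#' @param model a `ca_model`.
#' @param sse an [sse_annotation()].
#' @param helix ordinal of the helix (1-8).
#' @param motion one of "vertical", "horizontal", "tilt", "bend_N", "bend_C".
#' @param barrel_axis unit 3-vector of the barrel's principal axis; default
#'   recomputed from the annotation's strand residues.
#' @return an `ideal_displacement` object.
#' @export
helix_displacement <- function(model, sse, helix,
                               motion = c("vertical", "horizontal", "tilt",
                                          "bend_N", "bend_C"),
                               barrel_axis = NULL) {
  motion <- match.arg(motion)
  sel <- sse_residues(sse, "helix", helix)
  if (length(sel) < 4L) stop("helix must have at least 4 residues")
  if (is.null(barrel_axis))
    barrel_axis <- principal_axis(model, sse_residues(sse, "strand"))$axis
  n <- n_atoms(model)
  m <- model$masses
  com_all <- colSums(model$coords * m) / sum(m)
  hx <- model$coords[sel, , drop = FALSE]
  com_helix <- colSums(hx * m[sel]) / sum(m[sel])
  radial <- com_helix - com_all
  radial <- radial - sum(radial * barrel_axis) * barrel_axis
  if (sqrt(sum(radial^2)) < 1e-9)
    stop("helix centre of mass coincides with structure centre: radial direction undefined")
  radial <- radial / sqrt(sum(radial^2))
  L <- length(sel)
  n_half <- seq_len(ceiling(L / 2))          # N-half, gets the extra residue
  c_half <- seq.int(ceiling(L / 2) + 1L, L)
  mid <- (L + 1) / 2
  ramp <- abs(seq_len(L) - mid)              # linear, zero at midpoint
  field <- matrix(0, n, 3)
  if (motion == "vertical") {
    ax <- principal_axis(model, sel)$axis
    field[sel, ] <- matrix(ax, L, 3, byrow = TRUE)
  } else if (motion == "horizontal") {
    field[sel, ] <- matrix(radial, L, 3, byrow = TRUE)
  } else {
    w <- numeric(L)
    if (motion == "tilt") { w[n_half] <- ramp[n_half]; w[c_half] <- -ramp[c_half] }
    if (motion == "bend_N") w[n_half] <- ramp[n_half]
    if (motion == "bend_C") w[c_half] <- ramp[c_half]
    field[sel, ] <- outer(w, radial)
  }
  .ideal(field, paste0("helix_", motion), sel,
         list(radial = radial, barrel_axis = barrel_axis), n)
}

#' Eigenvalue-weighted overlap of a displacement with the modes
#'
#' `Omega_w = sum_m lambda_m (z . v_m)^2` over all non-trivial modes: the
#' energetic cost of the idealized displacement as carried by the mode
#' spectrum. Low scores mean the displacement projects onto soft
#' (low-energy) modes and is therefore favourable.
#'
#' `z` may be supplied in the mass-weighted space of the eigenvectors
#' (`space = "mass"`) or in Cartesian coordinates (`space = "cartesian"`,
#' the convention of the geometric constructors), in which case it is
#' mass-weighted internally and renormalised.
#'
#' @param modes a `mode_set`.
#' @param z an `ideal_displacement` or a numeric 3N vector.
#' @param space coordinate convention of `z`; defaults to "cartesian" for
#'   `ideal_displacement` inputs and "mass" for bare vectors.
#' @return object of class `overlap_result`: `omega_w`, `motion`.
#' @export
omega_w <- function(modes, z, space = NULL) {
  motion <- "custom"
  if (inherits(z, "ideal_displacement")) {
    motion <- z$motion
    if (is.null(space)) space <- "cartesian"
    z <- z$vector
  }
  if (is.null(space)) space <- "mass"
  space <- match.arg(space, c("mass", "cartesian"))
  if (length(z) != length(modes$values)) stop("dimension mismatch")
  if (space == "cartesian") {
    z <- z * sqrt(rep(modes$masses, each = 3L))
    z <- z / sqrt(sum(z^2))
  }
  nrm <- sqrt(sum(z^2))
  if (abs(nrm - 1) > 1e-8) {
    warning("non-unit displacement vector; normalising")
    z <- z / nrm
  }
  nt <- nontrivial_modes(modes)
  ov <- as.vector(crossprod(modes$vectors[, nt, drop = FALSE], z))
  structure(list(omega_w = sum(modes$values[nt] * ov^2), motion = motion),
            class = "overlap_result")
}

#' Overlap-score table for a full barrel annotation
#'
#' Scores the four collective motions (rotation and translation of the
#' barrel core and of the helical bundle) and the five per-helix motions
#' for each of the eight helices: 44 rows for a complete annotation.
#'
#' @param modes a `mode_set`.
#' @param model the matching `ca_model`.
#' @param sse an [sse_annotation()] with barrel and bundle sets.
#' @return data.frame `structure`, `motion`, `sse`, `ordinal`, `omega_w`.
#' @export
overlap_report <- function(modes, model, sse) {
  barrel <- sse_residues(sse, "strand")
  bundle <- sse_residues(sse, "helix")
  rows <- list()
  for (grp in c("barrel", "bundle")) {
    selection <- if (grp == "barrel") barrel else bundle
    for (mo in c("rotation", "translation")) {
      om <- omega_w(modes, group_displacement(model, selection, mo))
      rows[[length(rows) + 1L]] <- data.frame(
        structure = modes$label, motion = paste0("group_", mo), sse = grp,
        ordinal = NA_integer_, omega_w = om$omega_w)
    }
  }
  helix_ords <- sort(unique(
    sse$elements$ordinal[sse$elements$kind == "helix"]))
  barrel_axis <- principal_axis(model, barrel)$axis
  for (h in helix_ords) {
    for (mo in c("vertical", "horizontal", "tilt", "bend_N", "bend_C")) {
      om <- omega_w(modes, helix_displacement(model, sse, h, mo, barrel_axis))
      rows[[length(rows) + 1L]] <- data.frame(
        structure = modes$label, motion = paste0("helix_", mo), sse = "helix",
        ordinal = h, omega_w = om$omega_w)
    }
  }
  do.call(rbind, rows)
}
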