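#' Normalised per-residue fluctuations
#'
#' The fluctuation of residue i is the squared norm of its per-mode
#' displacement summed over all non-trivial modes, each weighted by the
#' inverse eigenvalue (the diagonal of the mode covariance; "theoretical
#' B-factors"). The profile is then normalised: by its mean (default, so
#' the profile averages 1), by its sum, or not at all.
#'
#' @param modes a `mode_set` from [normal_modes()].
#' @param normalization one of "mean", "sum", "none".
#' @return object of class `fluctuation_profile`: `values` (length N),
#'   `raw`, `normalization`, `label`.
#' @export
fluctuations <- function(modes, normalization = c("mean", "sum", "none")) {
  normalization <- match.arg(normalization)
  nt <- nontrivial_modes(modes)
  if (length(nt) == 0L) stop("mode set has no non-trivial modes")
  d <- modes$displacements[, nt, drop = FALSE]
  lam <- modes$values[nt]
  n <- length(modes$masses)
  sq <- d^2
  # per-atom squared norm in each mode: sum of x,y,z components
  atom_sq <- sq[seq(1, 3 * n, 3), , drop = FALSE] +
    sq[seq(2, 3 * n, 3), , drop = FALSE] +
    sq[seq(3, 3 * n, 3), , drop = FALSE]
  raw <- as.vector(atom_sq %*% (1 / lam))
  values <- switch(normalization,
                   mean = raw / mean(raw),
                   sum = raw / sum(raw),
                   none = raw)
  structure(list(values = values, raw = raw, normalization = normalization,
                 label = modes$label),
            class = "fluctuation_profile")
}

#' Per-residue deformation energies
#'
#' For one displacement field d the deformation energy of atom i measures
#' the local elastic strain relative to its neighbours:
#' `E_i = N / sum_j |d_j|^2 * 1/2 * sum_j k_ij ((d_i - d_j) . u_ij)^2`
#' with `u_ij` the unit equilibrium pair vector. Rigid translations and
#' infinitesimal rotations give zero. The profile `D_i` averages `E_i`
#' over all non-trivial modes; a min-max normalised copy in [0, 1] is kept
#' alongside the raw values.
#'
#' @param modes a `mode_set`.
#' @param network the `elastic_network` the modes came from.
#' @return object of class `deformation_profile`: `raw` (D_i), `normalized`
#'   (min-max scaled), `label`.
#' @export
deformation_energies <- function(modes, network) {
  n <- length(modes$masses)
  if (n != n_atoms(network$model)) stop("modes and network disagree on N")
  nt <- nontrivial_modes(modes)
  D <- numeric(n)
  for (m in nt) {
    d <- matrix(modes$displacements[, m], ncol = 3, byrow = TRUE)
    D <- D + deformation_field_energy(network, d)
  }
  raw <- D / length(nt)
  rng <- range(raw)
  normalized <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else rep(0, n)
  structure(list(raw = raw, normalized = normalized, label = modes$label),
            class = "deformation_profile")
}

#' Deformation energy of one displacement field
#'
#' Single-field building block of [deformation_energies()]: for a
#' displacement field d over the network's atoms,
#' `E_i = N / sum_j |d_j|^2 * 1/2 * sum_j k_ij ((d_i - d_j) . u_ij)^2`.
#' Zero for rigid translations and infinitesimal rotations.
#'
#' @param network an `elastic_network`.
#' @param field N x 3 displacement matrix (any overall scale).
#' @return numeric vector of per-atom deformation energies.
#' @export
deformation_field_energy <- function(network, field) {
  n <- n_atoms(network$model)
  field <- as.matrix(field)
  if (nrow(field) != n) stop("field and network disagree on N")
  p <- network$pairs
  dvec <- network$model$coords[p$j, , drop = FALSE] -
    network$model$coords[p$i, , drop = FALSE]
  u <- dvec / p$r0
  rel <- field[p$i, , drop = FALSE] - field[p$j, , drop = FALSE]
  contrib <- p$k * (rowSums(rel * u))^2   # pair term, counted for both members
  e <- numeric(n)
  acc <- tapply(contrib, p$i, sum)
  e[as.integer(names(acc))] <- acc
  acc <- tapply(contrib, p$j, sum)
  e[as.integer(names(acc))] <- e[as.integer(names(acc))] + acc
  e * (n / sum(field^2)) / 2
}

#' Dynamic cross-correlation matrix
#'
#' The normalised expected inner product of the displacements of atoms i
#' and j over all non-trivial modes (Ichiye-Karplus dynamic
#' cross-correlation): `C_ij = cov_ij / sqrt(cov_ii * cov_jj)` where
#' `cov_ij` is the 3x3-block trace of the mode covariance
#' `sum_m v_m v_m^T / lambda_m`. Values lie in [-1, 1] with unit diagonal.
#'
#' @param modes a `mode_set`.
#' @return object of class `correlation_matrix` with field `values`
#'   (N x N), `label`.
#' @export
correlations <- function(modes) {
  nt <- nontrivial_modes(modes)
  if (length(nt) == 0L) stop("mode set has no non-trivial modes")
  v <- modes$vectors[, nt, drop = FALSE]
  lam <- modes$values[nt]
  n <- length(modes$masses)
  vw <- sweep(v, 2, sqrt(lam), "/")
  idx <- function(a) seq(a, 3 * n, 3)
  cov_ij <- vw[idx(1), , drop = FALSE] %*% t(vw[idx(1), , drop = FALSE]) +
    vw[idx(2), , drop = FALSE] %*% t(vw[idx(2), , drop = FALSE]) +
    vw[idx(3), , drop = FALSE] %*% t(vw[idx(3), , drop = FALSE])
  s <- sqrt(diag(cov_ij))
  C <- cov_ij / outer(s, s)
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  C <- (C + t(C)) / 2
  structure(list(values = C, label = modes$label), class = "correlation_matrix")
}

#' Nearest-rank percentile of a numeric vector
#'
#' Deterministic nearest-rank definition: the smallest value such that at
#' least p percent of the multiset is at or below it.
#'
#' @param x numeric vector.
#' @param p percentile in (0, 100].
#' @return the nearest-rank percentile value.
#' @export
nearest_rank_percentile <- function(x, p) {
  if (p <= 0 || p > 100) stop("percentile must be in (0, 100]")
  xs <- sort(x)
  xs[max(1L, ceiling(p / 100 * length(xs)))]
}

#' Significance-filtered correlation pairs
#'
#' Retains residue pairs whose absolute correlation is at or above the
#' nearest-rank percentile threshold of all |C_ij| (i < j) AND whose
#' Calpha--Calpha distance in the input configuration is at least
#' `min_distance`. The percentile is computed before the distance filter,
#' over all pairs. Retained pairs are labelled by correlation sign and
#' grouped into connected "objects": components of the graph whose nodes
#' are residues and edges the retained pairs.
#'
#' @param corr a `correlation_matrix`.
#' @param model the `ca_model` the correlations refer to.
#' @param percentile rank threshold in (0, 100]; default 95.
#' @param min_distance nm; default 0.8 (8 Angstrom).
#' @return object of class `significant_pairs`: `pairs` (data.frame `i`,
#'   `j`, `c`, `distance`, `sign`, `object`), `threshold`, `percentile`,
#'   `min_distance`, `label`.
#' @export
significant_pairs <- function(corr, model, percentile = 95, min_distance = 0.8) {
  if (min_distance < 0) stop("min_distance must be >= 0")
  C <- corr$values
  n <- nrow(C)
  if (n != n_atoms(model)) stop("correlation matrix and model disagree on N")
  ut <- upper.tri(C)
  absC <- abs(C[ut])
  threshold <- nearest_rank_percentile(absC, percentile)
  dmat <- ca_distances(model)
  keep <- ut & abs(C) >= threshold & dmat >= min_distance
  idx <- which(keep, arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2],
                      c = C[keep], distance = dmat[keep])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$sign <- ifelse(pairs$c >= 0, "positive", "negative")
  pairs$object <- .pair_objects(pairs, n)
  structure(list(pairs = pairs, threshold = threshold,
                 percentile = percentile, min_distance = min_distance,
                 label = corr$label),
            class = "significant_pairs")
}

.pair_objects <- function(pairs, n) {
  if (nrow(pairs) == 0L) return(integer(0))
  g <- igraph::graph_from_edgelist(as.matrix(pairs[, c("i", "j")]),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber objects 1..k in order of first appearance along the pair list
  obj <- memb[pairs$i]
  as.integer(factor(obj, levels = unique(obj)))
}

#' Short-range significant correlations touching beta-strands
#'
#' The strand-focused variant of [significant_pairs()]: the score threshold
#' is raised to the 97.5th percentile rank while the distance floor is
#' lowered to 4 Angstrom (the approximate Calpha spacing of adjacent
#' strands), and the retained set is restricted to pairs with at least one
#' member on an annotated beta-strand.
#'
#' @param corr a `correlation_matrix`.
#' @param model the matching `ca_model`.
#' @param sse an [sse_annotation()] with at least one strand.
#' @param percentile default 97.5.
#' @param min_distance nm, default 0.4.
#' @return a `significant_pairs` object (objects recomputed after the
#'   strand restriction).
#' @export
strand_short_range_pairs <- function(corr, model, sse,
                                     percentile = 97.5, min_distance = 0.4) {
  strand_res <- sse_residues(sse, "strand")
  if (length(strand_res) == 0L) stop("no beta-strands annotated")
  sp <- significant_pairs(corr, model, percentile, min_distance)
  keep <- sp$pairs$i %in% strand_res | sp$pairs$j %in% strand_res
  sp$pairs <- sp$pairs[keep, , drop = FALSE]
  rownames(sp$pairs) <- NULL
  sp$pairs$object <- .pair_objects(sp$pairs, n_atoms(model))
  sp
}

#' Write a per-residue profile as TSV
#'
#' @param profile a `fluctuation_profile` or `deformation_profile`.
#' @param model the matching `ca_model` (for residue identifiers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, model, path) {
  if (inherits(profile, "fluctuation_profile")) {
    df <- data.frame(chain = model$atoms$chain, resno = model$atoms$resno,
                     raw = profile$raw, normalized = profile$values)
    hdr <- sprintf("# fluctuations (%s-normalized) for %s",
                   profile$normalization, profile$label)
  } else {
    df <- data.frame(chain = model$atoms$chain, resno = model$atoms$resno,
                     raw = profile$raw, normalized = profile$normalized)
    hdr <- sprintf("# deformation energies (min-max normalized) for %s",
                   profile$label)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write significant pairs as TSV
#' @param sp a `significant_pairs` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(sp, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(
    "# significant correlations for %s: percentile %.4g (|C| >= %.6g), min distance %.4g nm",
    sp$label, sp$percentile, sp$threshold, sp$min_distance), con)
  utils::write.table(sp$pairs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a PyMOL-dialect stick script for significant pairs
#'
#' Draws a distance object per retained pair between the two Calpha atoms,
#' coloured red for positive and blue for negative correlations.
#'
#' @param sp a `significant_pairs` object.
#' @param model the matching `ca_model`.
#' @param path output `.pml` path.
#' @param object_name prefix for the PyMOL objects.
#' @return `path`, invisibly.
#' @export
write_pymol_sticks <- function(sp, model, path, object_name = "corr") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# correlation sticks for %s (red: positive, blue: negative)",
                     sp$label), con)
  if (nrow(sp$pairs) > 0) {
    sel <- function(k) sprintf("chain %s and resi %s and name CA",
                               model$atoms$chain[k], model$atoms$resno[k])
    nm <- sprintf("%s_%s_%04d", object_name, substr(sp$pairs$sign, 1, 3),
                  seq_len(nrow(sp$pairs)))
    writeLines(sprintf("distance %s, %s, %s", nm,
                       vapply(sp$pairs$i, sel, ""), vapply(sp$pairs$j, sel, "")), con)
    writeLines(c(sprintf("color red, %s_pos_*", object_name),
                 sprintf("color blue, %s_neg_*", object_name),
                 "hide labels"), con)
  }
  invisible(path)
}
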