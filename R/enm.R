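#' Calpha force-field parameters
#'
#' Parameters of the distance-dependent pair force constant of the Calpha
#' elastic network (Hinsen parameterisation). The force constant between two
#' Calpha atoms at equilibrium separation r0 (nm) is
#' `a*r0 - b` for `r0 < d` (the covalently-linked, short-range branch) and
#' `c*r0^-6` for `r0 >= d` (the long-range branch).
#'
#' @param a kJ mol^-1 nm^-3, slope of the short-range branch.
#' @param b kJ mol^-1 nm^-2, intercept of the short-range branch.
#' @param c kJ mol^-1 nm^4, amplitude of the r^-6 branch.
#' @param d nm, branch-switch distance.
#' @param cutoff nm, interaction truncation radius, or `NULL` (default) for
#'   no truncation: every pair interacts, with the r^-6 decay providing the
#'   effective locality.
#' @return object of class `ff_params`.
#' @export
ff_params <- function(a = 8.6e5, b = 2.39e5, c = 128, d = 0.4, cutoff = NULL) {
  stopifnot(a > 0, c > 0, d > 0)
  if (!is.null(cutoff) && cutoff <= 0) stop("cutoff must be positive or NULL")
  structure(list(a = a, b = b, c = c, d = d, cutoff = cutoff),
            class = "ff_params")
}

#' Pair force constant as a function of equilibrium distance
#'
#' @param r0 numeric vector of pair distances in nm, all > 0.
#' @param params a [ff_params()] object.
#' @return force constants in kJ mol^-1 nm^-2 (never negative; the linear
#'   branch is clamped at zero with a warning if it dips below).
#' @export
pair_force_constant <- function(r0, params = ff_params()) {
  if (any(!is.finite(r0)) || any(r0 <= 0)) stop("pair distances must be positive")
  k <- ifelse(r0 < params$d, params$a * r0 - params$b, params$c * r0^-6)
  if (any(k < 0)) {
    warning("linear-branch force constant negative at some distance(s); clamped at 0")
    k[k < 0] <- 0
  }
  k
}

#' Build the elastic network for a Calpha model
#'
#' Every unordered atom pair within the cutoff (all pairs when
#' `params$cutoff` is `NULL`) is stored once with its force constant and its
#' equilibrium distance taken from the input configuration.
#'
#' @param model a [ca_model()].
#' @param params a [ff_params()] object.
#' @return object of class `elastic_network`: fields `model`, `pairs`
#'   (data.frame `i`, `j`, `k`, `r0` with `i < j`), `params`.
#' @export
build_network <- function(model, params = ff_params()) {
  n <- n_atoms(model)
  if (n < 2L) stop("need at least 2 atoms")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  d <- model$coords[j, , drop = FALSE] - model$coords[i, , drop = FALSE]
  r0 <- sqrt(rowSums(d * d))
  if (any(r0 == 0)) stop("duplicate coordinates: zero pair distance")
  if (!is.null(params$cutoff)) {
    keep <- r0 <= params$cutoff
    i <- i[keep]; j <- j[keep]; r0 <- r0[keep]
  }
  k <- pair_force_constant(r0, params)
  structure(list(model = model,
                 pairs = data.frame(i = i, j = j, k = k, r0 = r0),
                 params = params),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("<elastic_network> %s: %d atoms, %d springs (cutoff: %s)\n",
              x$model$label, n_atoms(x$model), nrow(x$pairs),
              if (is.null(x$params$cutoff)) "none" else
                paste0(x$params$cutoff, " nm")))
  invisible(x)
}

#' Mass-weighted Hessian of the elastic network
#'
#' Assembles the analytic second-derivative matrix of the harmonic pair
#' potential at the input configuration. At the energy minimum each pair
#' contributes the rank-one block `k * u %o% u` (u the unit pair vector) to
#' the diagonal blocks and its negative to the off-diagonal blocks. The
#' Cartesian Hessian is then symmetrically scaled by inverse square-root
#' masses.
#'
#' @param network an [build_network()] result.
#' @param mass_weighted scale by `1/sqrt(m_i m_j)` (default TRUE); FALSE
#'   returns the Cartesian Hessian.
#' @return dense symmetric 3N x 3N matrix, kJ mol^-1 nm^-2 (amu-weighted
#'   when `mass_weighted`).
#' @export
hessian <- function(network, mass_weighted = TRUE) {
  model <- network$model
  n <- n_atoms(model)
  p <- network$pairs
  d <- model$coords[p$j, , drop = FALSE] - model$coords[p$i, , drop = FALSE]
  u <- d / p$r0
  # 9 entries per pair for each of the 4 block positions (ii, jj, ij, ji),
  # accumulated by sparseMatrix's duplicate-summing into a dense matrix.
  ab <- expand.grid(a = 1:3, b = 1:3)
  np <- nrow(p)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  ia <- 3L * (p$i - 1L); ja <- 3L * (p$j - 1L)
  for (q in seq_len(9)) {
    a <- ab$a[q]; b <- ab$b[q]
    kuu <- p$k * u[, a] * u[, b]
    rows <- c(rows, ia + a, ja + a, ia + a, ja + a)
    cols <- c(cols, ia + b, ja + b, ja + b, ia + b)
    vals <- c(vals, kuu, kuu, -kuu, -kuu)
  }
  H <- as.matrix(Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                      dims = c(3L * n, 3L * n)))
  if (mass_weighted) {
    w <- 1 / sqrt(rep(model$masses, each = 3L))
    H <- H * outer(w, w)
  }
  (H + t(H)) / 2  # enforce exact symmetry
}

#' Normal modes of the elastic network
#'
#' Full symmetric eigendecomposition of the mass-weighted Hessian.
#' Eigenvalues (squared angular frequencies) are returned ascending; modes
#' with eigenvalue below `zero_tolerance * max(eigenvalue)` are flagged
#' trivial (rigid-body motions). A connected three-dimensional network must
#' have exactly six; any other count is an error (more indicates a
#' disconnected network, fewer a tolerance problem).
#'
#' Cartesian displacement fields are stored alongside the raw eigenvectors:
#' each eigenvector is divided component-wise by `sqrt(m_i)` and
#' renormalised to unit Euclidean length (convention recorded in the
#' object; set `renormalize = FALSE` to keep the bare de-weighted fields).
#'
#' @param network an [build_network()] result.
#' @param zero_tolerance relative eigenvalue threshold for trivial modes.
#' @param renormalize renormalise displacement fields to unit length.
#' @return object of class `mode_set`: `values` (3N eigenvalues, ascending),
#'   `vectors` (3N x 3N orthonormal, columns), `displacements` (3N x 3N),
#'   `n_trivial`, `tolerance`, `masses`, `mass_convention`,
#'   `displacement_convention`, `label`.
#' @export
normal_modes <- function(network, zero_tolerance = 1e-9, renormalize = TRUE) {
  model <- network$model
  H <- hessian(network, mass_weighted = TRUE)
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  tol <- zero_tolerance * max(values)
  if (min(values) < -tol)
    stop("negative eigenvalue beyond tolerance: not at an energy minimum?")
  n_trivial <- sum(values < tol)
  if (n_trivial > 6L) {
    comp <- .network_components(network)
    if (comp$no > 1L)
      stop(sprintf(paste0("disconnected network: %d trivial modes; %d components ",
                          "with sizes %s"), n_trivial, comp$no,
                   paste(comp$csize, collapse = ", ")))
    stop(sprintf(paste0("%d near-zero modes on a connected network: degenerate ",
                        "(collinear or planar) geometry"), n_trivial))
  }
  if (n_trivial < 6L)
    stop(sprintf("only %d near-zero modes found; zero_tolerance=%g too tight",
                 n_trivial, zero_tolerance))
  w <- 1 / sqrt(rep(model$masses, each = 3L))
  disp <- vectors * w
  if (renormalize) disp <- sweep(disp, 2, sqrt(colSums(disp^2)), "/")
  structure(list(values = values, vectors = vectors, displacements = disp,
                 n_trivial = n_trivial, tolerance = zero_tolerance,
                 masses = model$masses,
                 mass_convention = model$mass_convention,
                 displacement_convention = if (renormalize)
                   "deweighted-renormalized" else "deweighted",
                 label = model$label),
            class = "mode_set")
}

.network_components <- function(network) {
  g <- igraph::graph_from_edgelist(
    as.matrix(network$pairs[network$pairs$k > 0, c("i", "j")]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_atoms(network$model) - igraph::vcount(g)))
  igraph::components(g)
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %s: %d modes (%d trivial), masses: %s, d: %s\n",
              x$label, length(x$values), x$n_trivial, x$mass_convention,
              x$displacement_convention))
  invisible(x)
}

#' Indices of non-trivial modes
#' @param modes a `mode_set`.
#' @return integer vector of column indices of the non-rigid-body modes.
#' @export
nontrivial_modes <- function(modes) {
  seq.int(modes$n_trivial + 1L, length(modes$values))
}
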