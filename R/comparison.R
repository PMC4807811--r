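#' Read a multiple alignment into an alignment map
#'
#' Parses a FASTA multiple alignment (gap characters `-` and `.` both
#' honoured) and maps every column to the per-structure residue index by
#' counting non-gap characters. The conserved set is the gap-free columns:
#' the comparable Calpha positions used by the Bhattacharyya comparison.
#'
#' @param fasta path to a FASTA alignment file.
#' @return an `alignment_map`: `labels`, `sequences` (aligned strings),
#'   `columns` (L x n integer matrix of residue indices, NA at gaps),
#'   `conserved` (indices of gap-free columns).
#' @export
read_alignment <- function(fasta) {
  lines <- readLines(fasta)
  hdr <- grep("^>", lines)
  if (length(hdr) < 2L) stop("alignment needs at least 2 records")
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    paste(lines[seq.int(hdr[k] + 1L, ends[k])], collapse = "")
  }, "")
  seqs <- gsub("\\s", "", seqs)
  alignment_map(labels, seqs)
}

#' Build an alignment map from labels and aligned strings
#'
#' @param labels unique record labels.
#' @param seqs aligned strings of equal length; `-` and `.` are gaps.
#' @return an `alignment_map` (see [read_alignment()]).
#' @export
alignment_map <- function(labels, seqs) {
  if (anyDuplicated(labels)) stop("duplicate alignment labels")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged alignment: unequal sequence lengths")
  chars <- vapply(seqs, function(s) strsplit(s, "")[[1]], character(L))
  chars <- matrix(chars, nrow = L)
  is_gap <- chars == "-" | chars == "."
  columns <- apply(!is_gap, 2, cumsum)
  columns[is_gap] <- NA_integer_
  storage.mode(columns) <- "integer"
  colnames(columns) <- labels
  structure(list(labels = labels, sequences = stats::setNames(seqs, labels),
                 columns = columns,
                 conserved = which(rowSums(is_gap) == 0L)),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map> %d sequences, L = %d, %d conserved columns\n",
              length(x$labels), nrow(x$columns), length(x$conserved)))
  invisible(x)
}

#' Extract the sub-alignment of a subset of records
#'
#' Keeps the selected records with their aligned strings unchanged, drops
#' all-gap columns, and recomputes the conserved set for the subset (the
#' conserved set must never be inherited from the superset alignment).
#'
#' @param map an `alignment_map`.
#' @param labels records to keep.
#' @return an `alignment_map` over the subset.
#' @export
sub_alignment <- function(map, labels) {
  missing <- setdiff(labels, map$labels)
  if (length(missing)) stop("unknown labels: ", paste(missing, collapse = ", "))
  seqs <- map$sequences[labels]
  chars <- do.call(rbind, strsplit(unname(seqs), ""))
  all_gap <- apply(chars == "-" | chars == ".", 2, all)
  seqs <- apply(chars[, !all_gap, drop = FALSE], 1, paste, collapse = "")
  alignment_map(labels, seqs)
}

#' Pairwise sequence identity over an alignment
#'
#' `100 * I / L` where I counts positions with identical non-gap
#' characters and L is the full alignment length including gap columns.
#'
#' @param a,b aligned strings of equal length.
#' @return identity percentage in [0, 100].
#' @export
sequence_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned strings must have equal length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  gap <- ca %in% c("-", ".") | cb %in% c("-", ".")
  100 * sum(!gap & ca == cb) / nchar(a)
}

#' Mode covariance restricted to aligned atoms
#'
#' Assembles the covariance `sum_m lambda_m^-1 v_m v_m^T` over the n
#' softest non-trivial modes, restricted to the 3 coordinates of each
#' aligned atom, and divides by its trace. n is the smallest number of
#' lowest-frequency modes whose cumulative `lambda^-1` reaches
#' `mode_variance` of the total over all non-trivial modes (the
#' covariance-trace reading of "variance retained").
#'
#' @param modes a `mode_set`.
#' @param aligned_atoms integer atom indices (1-based) to keep.
#' @param mode_variance fraction in (0, 1]; default 0.95.
#' @return list `cov` (3k x 3k matrix, unit trace), `n_modes`.
#' @export
aligned_covariance <- function(modes, aligned_atoms, mode_variance = 0.95) {
  if (length(aligned_atoms) == 0L) stop("empty aligned-atom selection")
  n <- length(modes$masses)
  if (any(aligned_atoms < 1L | aligned_atoms > n)) stop("atom index out of range")
  if (mode_variance <= 0 || mode_variance > 1) stop("mode_variance in (0,1]")
  nt <- nontrivial_modes(modes)
  w <- 1 / modes$values[nt]               # ascending lambda => descending w
  cum <- cumsum(w) / sum(w)
  nm <- which(cum >= mode_variance - 1e-12)[1]
  sel <- nt[seq_len(nm)]
  rows <- as.vector(t(outer(aligned_atoms - 1L, 1:3, function(a, b) 3L * a + b)))
  v <- modes$vectors[rows, sel, drop = FALSE]
  cov <- v %*% (t(v) / modes$values[sel])
  cov <- (cov + t(cov)) / 2
  list(cov = cov / sum(diag(cov)), n_modes = nm)
}

#' Bhattacharyya coefficient of two covariances
#'
#' Projects both trace-normalised covariances onto the s leading
#' eigenvectors of their average that capture `joint_variance` of its
#' variance, then evaluates
#' `BC = exp(-1/2 * ( logdet((A~+B~)/2) - 1/2 (logdet A~ + logdet B~) ))`
#' through eigenvalue-based log-determinants (raw determinants of
#' trace-normalised matrices underflow at realistic dimensions).
#' Eigenvalues below numerical zero are clamped.
#'
#' @param covA,covB square matrices of equal dimension (trace-normalised).
#' @param joint_variance fraction in (0, 1]; default 0.75.
#' @return list `bc` in (0, 1], `s` (projection rank).
#' @export
bc_score <- function(covA, covB, joint_variance = 0.75) {
  if (!all(dim(covA) == dim(covB))) stop("covariance dimension mismatch")
  if (joint_variance <= 0 || joint_variance > 1) stop("joint_variance in (0,1]")
  M <- (covA + covB) / 2
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  cum <- cumsum(ev) / sum(ev)
  s <- which(cum >= joint_variance - 1e-12)[1]
  P <- e$vectors[, seq_len(s), drop = FALSE]
  logdet <- function(X) {
    lam <- eigen((X + t(X)) / 2, symmetric = TRUE, only.values = TRUE)$values
    sum(log(pmax(lam, .Machine$double.eps)))
  }
  At <- crossprod(P, covA %*% P)
  Bt <- crossprod(P, covB %*% P)
  bc <- exp(-0.5 * (logdet((At + Bt) / 2) - 0.5 * (logdet(At) + logdet(Bt))))
  list(bc = min(bc, 1), s = s)
}

#' Bhattacharyya configuration
#' @param mode_variance per-structure variance retention, default 0.95.
#' @param joint_variance joint projection retention, default 0.75.
#' @return a `bc_config` list.
#' @export
bc_config <- function(mode_variance = 0.95, joint_variance = 0.75) {
  stopifnot(mode_variance > 0, mode_variance <= 1,
            joint_variance > 0, joint_variance <= 1)
  structure(list(mode_variance = mode_variance, joint_variance = joint_variance),
            class = "bc_config")
}

#' Pairwise Bhattacharyya coefficients over an aligned structure set
#'
#' For every structure pair, restricts each mode covariance to the atoms of
#' the alignment's conserved (gap-free) columns, trace-normalises, and
#' scores the pair with [bc_score()]. The conserved set is recomputed from
#' the supplied alignment, never inherited from a superset.
#'
#' @param modesets named list of `mode_set` objects; names must cover the
#'   alignment labels.
#' @param alignment an `alignment_map`.
#' @param config a [bc_config()].
#' @return a `bc_result`: `labels`, `matrix` (symmetric, unit diagonal),
#'   `ranks` (data.frame `a`, `b`, `n`, `m`, `s`), `config`.
#' @export
bc_matrix <- function(modesets, alignment, config = bc_config()) {
  labels <- alignment$labels
  missing <- setdiff(labels, names(modesets))
  if (length(missing)) stop("no mode set for: ", paste(missing, collapse = ", "))
  if (length(alignment$conserved) == 0L) stop("alignment has no conserved columns")
  covs <- lapply(labels, function(lb) {
    atoms <- alignment$columns[alignment$conserved, lb]
    aligned_covariance(modesets[[lb]], atoms, config$mode_variance)
  })
  names(covs) <- labels
  k <- length(labels)
  B <- diag(1, k); dimnames(B) <- list(labels, labels)
  ranks <- NULL
  for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k)) {
    sc <- bc_score(covs[[a]]$cov, covs[[b]]$cov, config$joint_variance)
    B[a, b] <- B[b, a] <- sc$bc
    ranks <- rbind(ranks, data.frame(
      a = labels[a], b = labels[b],
      n = covs[[a]]$n_modes, m = covs[[b]]$n_modes, s = sc$s))
  }
  structure(list(labels = labels, matrix = B, ranks = ranks, config = config),
            class = "bc_result")
}

#' Hierarchical clustering of a BC matrix
#'
#' Agglomerative clustering on the dissimilarity `1 - BC`. Ties are broken
#' deterministically by label order (hclust's implementation order over the
#' label-ordered dissimilarity).
#'
#' @param result a `bc_result`.
#' @param linkage hclust method, default "average".
#' @return an `hclust` object.
#' @export
cluster_bc <- function(result, linkage = "average") {
  if (length(result$labels) < 2L) stop("need at least 2 items to cluster")
  stats::hclust(stats::as.dist(1 - result$matrix), method = linkage)
}

#' Write a BC matrix (TSV), dendrogram (Newick) and rank diagnostics (TSV)
#'
#' @param result a `bc_result`.
#' @param path_matrix,path_tree,path_ranks output paths (NULL to skip one).
#' @param linkage linkage for the dendrogram.
#' @return invisible NULL.
#' @export
write_bc_result <- function(result, path_matrix = NULL, path_tree = NULL,
                            path_ranks = NULL, linkage = "average") {
  if (!is.null(path_matrix)) {
    con <- file(path_matrix, "w")
    writeLines(sprintf("# BC matrix; mode_variance=%g joint_variance=%g",
                       result$config$mode_variance, result$config$joint_variance),
               con)
    utils::write.table(result$matrix, con, sep = "\t", quote = FALSE)
    close(con)
  }
  if (!is.null(path_tree)) {
    hc <- cluster_bc(result, linkage)
    ape::write.tree(ape::as.phylo(hc), file = path_tree)
  }
  if (!is.null(path_ranks)) {
    utils::write.table(result$ranks, path_ranks, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
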