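#' Specification of a synthetic Calpha-only barrel
#'
#' Parametric geometry emulating an eight-fold strand/helix barrel:
#' parallel strands on an inner cylinder, ideal helical Calpha traces on an
#' outer cylinder running antiparallel to the strands, joined by loops.
#' Defaults give a 240-residue, 8-repeat barrel with dimensions in the
#' range of real folds: inner Calpha barrel radius 0.6 nm (inter-strand
#' Calpha spacing ~0.46 nm), helix axes at 1.35 nm.
#'
#' @param n_repeats number of strand-helix repeats (>= 3), default 8.
#' @param strand_length,helix_length,loop_length residues per element
#'   (two loops per repeat), defaults 8/14/4.
#' @param barrel_radius,bundle_radius nm, inner and outer cylinder radii.
#' @param strand_rise nm per residue along a strand, default 0.33.
#' @param helix_rise nm per residue along a helix axis, default 0.15.
#' @param helix_twist degrees per residue of the helical wheel, default 100.
#' @param helix_radius nm, Calpha radius about the helix axis, default 0.23.
#' @param seed integer seed for the collision-resolving jitter.
#' @return a `barrel_spec` list.
#' @export
barrel_spec <- function(n_repeats = 8, strand_length = 8, helix_length = 14,
                        loop_length = 4, barrel_radius = 0.6,
                        bundle_radius = 1.35, strand_rise = 0.33,
                        helix_rise = 0.15, helix_twist = 100,
                        helix_radius = 0.23, seed = 1L) {
  stopifnot(n_repeats >= 3, strand_length >= 3, helix_length >= 3,
            loop_length >= 3, bundle_radius > barrel_radius)
  structure(as.list(environment()), class = "barrel_spec")
}

# deterministic 'sequence' so residue masses vary by element type
.element_resnames <- c(strand = "VAL", helix = "GLU", loop = "GLY")

# loop between two anchor points: quadratic Bezier whose control-point
# offset along `dir` grows until consecutive Calpha spacing reaches
# `spacing` (so short anchor gaps produce a bulged, not compressed, loop)
.loop_block <- function(p0, p2, k, dir, spacing = 0.36) {
  dir <- dir / sqrt(sum(dir^2))
  mid <- (p0 + p2) / 2
  for (mag in seq(0.2, 2, by = 0.05)) {
    pts <- .quad_bezier(p0, mid + mag * dir, p2, k)
    gaps <- sqrt(rowSums(diff(rbind(p0, pts, p2))^2))
    if (min(gaps) >= spacing) return(pts)
  }
  pts
}

.quad_bezier <- function(p0, p1, p2, k) {
  # k interior points at equal arc-length fractions of the quadratic Bezier
  # (uniform-t sampling clusters points where the curve slows down)
  tt <- seq(0, 1, length.out = 201)
  dense <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) + outer(tt^2, p2)
  seg <- sqrt(rowSums(diff(dense)^2))
  arc <- c(0, cumsum(seg))
  want <- arc[length(arc)] * seq_len(k) / (k + 1)
  t_at <- stats::approx(arc, tt, xout = want)$y
  outer((1 - t_at)^2, p0) + outer(2 * t_at * (1 - t_at), p1) + outer(t_at^2, p2)
}

#' Generate a synthetic barrel structure with its SSE annotation
#'
#' Places `n_repeats` parallel strands at equal angular spacing on the
#' inner cylinder (running +z), ideal alpha-helical traces on the outer
#' cylinder running back down (-z), and quadratic Bezier loops with a
#' radial bulge between them. Deterministic for a fixed spec; if any two
#' Calpha atoms fall closer than 0.25 nm the geometry is regenerated with
#' a small seeded jitter (bounded retries).
#'
#' @param spec a [barrel_spec()].
#' @return list `model` (a [ca_model()]) and `sse` (an [sse_annotation()]).
#' @export
make_barrel <- function(spec = barrel_spec()) {
  for (attempt in 0:9) {
    out <- .make_barrel_once(spec, attempt)
    d <- stats::dist(out$coords)
    if (min(d) >= 0.25) {
      atoms <- data.frame(chain = "A", resno = seq_len(nrow(out$coords)),
                          ins = "", resname = out$resnames,
                          stringsAsFactors = FALSE)
      model <- ca_model(out$coords, atoms, masses = "residue",
                        label = sprintf("synthetic_barrel_seed%d", spec$seed))
      return(list(model = model,
                  sse = sse_annotation(out$strands, out$helices)))
    }
  }
  stop("could not generate a collision-free barrel after 10 attempts")
}

.make_barrel_once <- function(spec, attempt) {
  coords <- NULL; resnames <- character(0)
  strands <- list(); helices <- list()
  s_len <- spec$strand_length; h_len <- spec$helix_length; l_len <- spec$loop_length
  s_height <- (s_len - 1) * spec$strand_rise
  h_height <- (h_len - 1) * spec$helix_rise
  z0_h <- (s_height - h_height) / 2          # centre helix against strand
  jit <- 0
  if (attempt > 0) {
    set.seed(spec$seed + 7L * attempt)
    jit <- attempt * 0.005
  }
  add <- function(block, kind) {
    if (jit > 0) block <- block + matrix(stats::rnorm(length(block), 0, jit),
                                         nrow(block), 3)
    coords <<- rbind(coords, block)
    resnames <<- c(resnames, rep(.element_resnames[[kind]], nrow(block)))
  }
  for (r in seq_len(spec$n_repeats)) {
    th_s <- 2 * pi * (r - 1) / spec$n_repeats
    th_h <- th_s + pi / spec$n_repeats
    # strand: straight, +z, on the inner cylinder
    sblk <- cbind(spec$barrel_radius * cos(th_s),
                  spec$barrel_radius * sin(th_s),
                  spec$strand_rise * (seq_len(s_len) - 1))
    start <- nrow(coords %||% matrix(0, 0, 3)) + 1L
    add(sblk, "strand")
    strands[[r]] <- c(start, start + s_len - 1L)
    # helix: ideal alpha trace about a vertical axis on the outer cylinder,
    # running back down (-z)
    axis_xy <- c(spec$bundle_radius * cos(th_h), spec$bundle_radius * sin(th_h))
    ang <- (seq_len(h_len) - 1) * spec$helix_twist * pi / 180
    hz <- z0_h + h_height - (seq_len(h_len) - 1) * spec$helix_rise
    hblk <- cbind(axis_xy[1] + spec$helix_radius * cos(ang + th_h),
                  axis_xy[2] + spec$helix_radius * sin(ang + th_h),
                  hz)
    # loop (top): strand end -> helix start, bulging radially out and up
    p0 <- sblk[s_len, ]; p2 <- hblk[1, ]
    mid <- (p0 + p2) / 2
    dir_out <- c(mid[1], mid[2], 0) / sqrt(sum(mid[1:2]^2))
    add(.loop_block(p0, p2, l_len, dir_out + c(0, 0, 1.2)), "loop")
    start <- nrow(coords) + 1L
    add(hblk, "helix")
    helices[[r]] <- c(start, start + h_len - 1L)
    # loop (bottom): helix end -> next strand start
    th_next <- 2 * pi * r / spec$n_repeats
    p0 <- hblk[h_len, ]
    p2 <- c(spec$barrel_radius * cos(th_next), spec$barrel_radius * sin(th_next), 0)
    mid <- (p0 + p2) / 2
    dir_out <- c(mid[1], mid[2], 0) / sqrt(sum(mid[1:2]^2))
    add(.loop_block(p0, p2, l_len, dir_out - c(0, 0, 1.2)), "loop")
  }
  list(coords = coords, resnames = resnames,
       strands = strands, helices = helices)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Perturb a model with Gaussian coordinate noise
#'
#' @param model a `ca_model`.
#' @param sigma standard deviation per coordinate, nm (>= 0).
#' @param seed integer seed.
#' @return a perturbed copy of the model.
#' @export
perturb <- function(model, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma > 0) {
    set.seed(seed)
    model$coords <- model$coords +
      matrix(stats::rnorm(length(model$coords), 0, sigma),
             nrow(model$coords), 3)
  }
  model$label <- sprintf("%s_perturbed_s%g_seed%d", model$label, sigma, seed)
  model
}

#' Generate a synthetic homologue family with a gapped alignment
#'
#' Members are perturbed copies of a reference barrel; per member, loop
#' residues are deleted independently at `deletion_rate` (deletions are
#' confined to loops so the SSE annotation stays valid for every member).
#' The emitted alignment has one column per reference residue, with gaps
#' where a member's residue was deleted; the ground-truth conserved count
#' (columns with no deletion in any member) is stored.
#'
#' @param spec a [barrel_spec()] for the reference.
#' @param n_members number of family members (>= 2).
#' @param sigmas noise sigma (nm) per member, recycled.
#' @param deletion_rate per-loop-residue deletion probability in [0, 1).
#' @param seed integer seed.
#' @return a `synthetic_family`: `reference` (model), `sse`, `members`
#'   (list of `ca_model`), `sigmas`, `deletions` (list of deleted reference
#'   indices), `alignment` (an `alignment_map`), `conserved_truth`.
#' @export
make_family <- function(spec = barrel_spec(), n_members = 5,
                        sigmas = 0.03, deletion_rate = 0.08, seed = 1L) {
  if (n_members < 2) stop("need at least 2 members")
  if (deletion_rate >= 1 || deletion_rate < 0) stop("deletion_rate in [0, 1)")
  ref <- make_barrel(spec)
  n <- n_atoms(ref$model)
  loop_res <- setdiff(seq_len(n), c(sse_residues(ref$sse, "strand"),
                                    sse_residues(ref$sse, "helix")))
  sigmas <- rep_len(sigmas, n_members)
  one_letter <- .aa_one_letter[ref$model$atoms$resname]
  members <- list(); deletions <- list(); seqs <- character(n_members)
  labels <- sprintf("member%02d", seq_len(n_members))
  for (k in seq_len(n_members)) {
    m <- perturb(ref$model, sigmas[k], seed = seed + 1000L * k)
    set.seed(seed + 1000L * k + 1L)
    del <- loop_res[stats::runif(length(loop_res)) < deletion_rate]
    if (length(del)) {
      m$coords <- m$coords[-del, , drop = FALSE]
      m$atoms <- m$atoms[-del, , drop = FALSE]
      m$atoms$resno <- seq_len(nrow(m$atoms))
      m$masses <- m$masses[-del]
    }
    m$label <- labels[k]
    members[[k]] <- m
    deletions[[k]] <- sort(del)
    aln <- one_letter
    aln[del] <- "-"
    seqs[k] <- paste(aln, collapse = "")
  }
  names(members) <- labels
  alignment <- alignment_map(labels, seqs)
  deleted_any <- unique(unlist(deletions))
  structure(list(reference = ref$model, sse = ref$sse, members = members,
                 sigmas = sigmas, deletions = deletions,
                 alignment = alignment,
                 conserved_truth = n - length(deleted_any)),
            class = "synthetic_family")
}

#' Write a family's alignment as FASTA and its ground truth as JSON
#'
#' @param family a `synthetic_family`.
#' @param fasta_path output FASTA path.
#' @param json_path optional ground-truth sidecar (conserved count, sigmas,
#'   deletion lists).
#' @return invisible NULL.
#' @export
write_family_alignment <- function(family, fasta_path, json_path = NULL) {
  con <- file(fasta_path, "w")
  for (lb in family$alignment$labels) {
    writeLines(c(paste0(">", lb), family$alignment$sequences[[lb]]), con)
  }
  close(con)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(conserved_count = family$conserved_truth,
           sigmas = family$sigmas,
           deletions = family$deletions),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(NULL)
}
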