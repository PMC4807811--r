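test_that("alignment maps count conserved columns and residue indices correctly", {
  # hand case: "AC-G" / "ACTG" -> conserved columns 1, 2, 4
  am <- alignment_map(c("s1", "s2"), c("AC-G", "ACTG"))
  expect_identical(am$conserved, c(1L, 2L, 4L))
  expect_identical(am$columns[, "s1"], c(1L, 2L, NA, 3L))
  expect_identical(am$columns[, "s2"], 1:4)
  # ungapped identical sequences: every column conserved
  am2 <- alignment_map(c("a", "b"), c("ACDEFGH", "ACDEFGH"))
  expect_length(am2$conserved, 7L)
  # '.' honoured as gap; ragged and duplicate inputs rejected
  am3 <- alignment_map(c("a", "b"), c("A.CG", "AACG"))
  expect_identical(am3$conserved, c(1L, 3L, 4L))
  expect_error(alignment_map(c("a", "b"), c("AC", "ACG")), "ragged")
  expect_error(alignment_map(c("a", "a"), c("AC", "AC")), "duplicate")
})

test_that("FASTA round trip reproduces the generator's conserved count", {
  fam <- make_family(small_spec(), n_members = 4, sigmas = 0.02,
                     deletion_rate = 0.1, seed = 5)
  fasta <- withr::local_tempfile(fileext = ".fasta")
  json <- withr::local_tempfile(fileext = ".json")
  write_family_alignment(fam, fasta, json)
  am <- read_alignment(fasta)
  expect_identical(length(am$conserved), as.integer(fam$conserved_truth))
  expect_identical(am$labels, fam$alignment$labels)
  truth <- jsonlite::read_json(json)
  expect_identical(truth$conserved_count, fam$conserved_truth)
})

test_that("sequence identity counts identical non-gap positions over the full length", {
  expect_equal(sequence_identity("ACDG", "ACDG"), 100)
  expect_equal(sequence_identity("AC-G", "ACTG"), 75)   # I = 3, L = 4
  expect_equal(sequence_identity("----", "ACDG"), 0)
  expect_error(sequence_identity("AC", "ACD"), "equal length")
})

test_that("sub-alignments recompute conserved columns, never fewer than inherited", {
  fam <- make_family(small_spec(), n_members = 5, sigmas = 0.02,
                     deletion_rate = 0.12, seed = 11)
  full <- fam$alignment
  sub <- sub_alignment(full, full$labels[1:2])
  # conserved count restricted to the same two structures from the superset
  chars <- do.call(rbind, strsplit(unname(full$sequences[full$labels[1:2]]), ""))
  inherited <- sum(colSums(chars == "-") == 0)
  expect_gte(length(sub$conserved), inherited)
  expect_error(sub_alignment(full, "nope"), "unknown")
})

test_that("aligned covariance selects modes by cumulative variance and normalises its trace", {
  sm <- small_modes()
  n <- length(sm$modes$masses)
  full <- aligned_covariance(sm$modes, seq_len(n), mode_variance = 1.0)
  expect_equal(full$n_modes, length(nontrivial_modes(sm$modes)))
  expect_equal(sum(diag(full$cov)), 1)
  part <- aligned_covariance(sm$modes, seq_len(n), mode_variance = 0.95)
  expect_lt(part$n_modes, full$n_modes)
  # restriction equals rows/columns of the densely assembled covariance
  atoms <- c(2L, 5L, 9L, 20L)
  rows <- as.vector(sapply(atoms, function(a) (3 * a - 2):(3 * a)))
  dense <- matrix(0, 3 * n, 3 * n)
  nt <- nontrivial_modes(sm$modes)
  sel <- nt[seq_len(part$n_modes)]
  for (m in sel)
    dense <- dense + tcrossprod(sm$modes$vectors[, m]) / sm$modes$values[m]
  want <- dense[rows, rows]
  got <- aligned_covariance(sm$modes, atoms, 0.95)
  expect_equal(got$cov, want / sum(diag(want)), tolerance = 1e-10)
  expect_error(aligned_covariance(sm$modes, integer(0)), "empty")
})

test_that("Bhattacharyya score satisfies its closed-form and symmetry contracts", {
  A <- diag(c(3, 2, 1)) / 6
  B <- diag(c(1, 2, 3)) / 6
  # self-comparison is exactly 1
  expect_equal(bc_score(A, A, 1.0)$bc, 1, tolerance = 1e-10)
  # diagonal case against explicit determinants:
  # det((A+B)/2) = 1/27, det(A) = det(B) = 1/36 -> BC = sqrt(3)/2
  sc <- bc_score(A, B, 1.0)
  expect_equal(sc$bc, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(sc$bc, bc_score(B, A, 1.0)$bc)
  expect_error(bc_score(A, diag(2)), "dimension")
})

test_that("BC of a structure with itself is 1 and matrices are symmetric in (0,1]", {
  fam <- make_family(small_spec(), n_members = 3, sigmas = c(0, 0.03, 0.06),
                     deletion_rate = 0, seed = 3)
  ms <- lapply(fam$members,
               function(m) normal_modes(suppressWarnings(build_network(m))))
  # duplicate structure: off-diagonal 1 against itself
  dup <- alignment_map(c("member01", "copy"),
                       c(fam$alignment$sequences[[1]], fam$alignment$sequences[[1]]))
  ms_dup <- list(member01 = ms[[1]], copy = ms[[1]])
  bc_dup <- bc_matrix(ms_dup, dup)
  expect_equal(bc_dup$matrix["member01", "copy"], 1, tolerance = 1e-10)
  bc <- bc_matrix(ms, fam$alignment)
  expect_equal(bc$matrix, t(bc$matrix))
  expect_equal(unname(diag(bc$matrix)), rep(1, 3))
  off <- bc$matrix[upper.tri(bc$matrix)]
  expect_true(all(off > 0 & off <= 1))
  # rank diagnostics cover every pair
  expect_identical(nrow(bc$ranks), 3L)
  expect_error(bc_matrix(ms[1:2], fam$alignment), "no mode set")
})

test_that("within-family BC decreases as structural perturbation grows", {
  sp <- small_spec()
  means <- sapply(c(0.01, 0.05, 0.1), function(sigma) {
    vals <- sapply(1:3, function(seed) {
      fam <- make_family(sp, n_members = 3, sigmas = sigma,
                         deletion_rate = 0.05, seed = seed)
      ms <- lapply(fam$members,
                   function(m) normal_modes(suppressWarnings(build_network(m))))
      bc <- bc_matrix(ms, fam$alignment)
      mean(bc$matrix[upper.tri(bc$matrix)])
    })
    mean(vals)
  })
  expect_true(all(diff(means) < 0))
})

test_that("BC clustering recovers planted families and writes standard outputs", {
  # two perfect families as a block-diagonal BC matrix
  B <- matrix(0.1, 4, 4)
  B[1:2, 1:2] <- 0.9; B[3:4, 3:4] <- 0.9; diag(B) <- 1
  dimnames(B) <- list(letters[1:4], letters[1:4])
  res <- structure(list(labels = letters[1:4], matrix = B,
                        ranks = NULL, config = bc_config()),
                   class = "bc_result")
  hc <- cluster_bc(res)
  expect_identical(sort(unname(cutree(hc, 2)[c("a", "b")])), c(1L, 1L))
  expect_identical(length(unique(cutree(hc, 2))), 2L)
  # two items merge at 1 - BC
  B2 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  res2 <- structure(list(labels = c("x", "y"), matrix = B2, ranks = NULL,
                         config = bc_config()), class = "bc_result")
  expect_equal(cluster_bc(res2)$height, 0.2)
  # three-family synthetic fixture with controlled noise
  sp <- small_spec()
  specs <- list(sp,
                barrel_spec(strand_length = 5, helix_length = 8,
                            loop_length = 3, barrel_radius = 0.68,
                            bundle_radius = 1.5),
                barrel_spec(strand_length = 5, helix_length = 8,
                            loop_length = 3, barrel_radius = 0.64,
                            bundle_radius = 1.42))
  models <- list(); truth <- integer(0)
  for (fi in seq_along(specs)) {
    ref <- make_barrel(specs[[fi]])$model
    for (k in 1:2) {
      lbl <- sprintf("f%d_m%d", fi, k)
      mdl <- perturb(ref, 0.015, seed = 100 * fi + k)
      mdl$label <- lbl
      models[[lbl]] <- mdl
      truth <- c(truth, fi)
    }
  }
  # align across families on the common core (equal lengths by construction)
  stopifnot(length(unique(sapply(models, n_atoms))) == 1L)
  seqs <- rep(paste(rep("A", n_atoms(models[[1]])), collapse = ""), 6)
  am <- alignment_map(names(models), seqs)
  ms <- lapply(models, function(m) normal_modes(build_network(m)))
  bc <- bc_matrix(ms, am)
  cl <- cutree(cluster_bc(bc), 3)
  expect_identical(length(unique(tapply(cl, truth, unique))), 3L)
  # outputs
  tsv <- withr::local_tempfile(fileext = ".tsv")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  rk <- withr::local_tempfile(fileext = ".tsv")
  write_bc_result(bc, tsv, nwk, rk)
  expect_match(readLines(tsv, n = 1), "mode_variance")
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, names(models))
  expect_identical(nrow(utils::read.delim(rk)), 15L)
})
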