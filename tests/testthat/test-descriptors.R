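test_that("fluctuations match the mode-sum and pseudo-inverse covariance oracles", {
  # unit masses: raw eigenvectors, displacement fields and the covariance
  # all live in one space, so both oracle routes must agree exactly
  net <- build_network(random_model(12, seed = 7))
  modes <- normal_modes(net)
  f <- fluctuations(modes, "none")
  # mode-sum covariance oracle assembled from the displacement fields
  nt <- nontrivial_modes(modes)
  cov_ms <- matrix(0, 36, 36)
  for (m in nt)
    cov_ms <- cov_ms + tcrossprod(modes$displacements[, m]) / modes$values[m]
  f_oracle <- sapply(1:12, function(i) block_trace(cov_ms, i, i))
  expect_equal(f$values, f_oracle, tolerance = 1e-10)
  # Hessian pseudo-inverse route
  cov_pinv <- pinv_covariance(net)
  f_pinv <- sapply(1:12, function(i) block_trace(cov_pinv, i, i))
  expect_equal(f$values, f_pinv, tolerance = 1e-8)
  # default scheme has unit mean
  expect_equal(mean(fluctuations(modes)$values), 1)
  expect_true(all(fluctuations(modes)$values >= 0))
})

test_that("correlations equal normalised pseudo-inverse block traces and are bounded", {
  net <- build_network(random_model(12, seed = 8, masses = "residue"))
  modes <- normal_modes(net)
  C <- correlations(modes)$values
  cov_pinv <- pinv_covariance(net)
  C_oracle <- outer(1:12, 1:12, Vectorize(function(i, j)
    block_trace(cov_pinv, i, j) /
      sqrt(block_trace(cov_pinv, i, i) * block_trace(cov_pinv, j, j))))
  expect_equal(C, C_oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(diag(C), rep(1, 12))
  expect_true(all(abs(C) <= 1))
  expect_equal(C, t(C))
})

test_that("deformation energy vanishes for rigid fields and matches the diatomic hand case", {
  net <- build_network(random_model(10, seed = 9))
  n <- n_atoms(net$model)
  # uniform translation
  tr <- matrix(rep(c(1, 2, -1), each = n), n, 3)
  expect_lt(max(abs(deformation_field_energy(net, tr))), 1e-18)
  # infinitesimal rotation about the centroid
  ctr <- colMeans(net$model$coords)
  rel <- sweep(net$model$coords, 2, ctr)
  om <- c(0.3, -1, 0.5)
  rot <- cbind(om[2] * rel[, 3] - om[3] * rel[, 2],
               om[3] * rel[, 1] - om[1] * rel[, 3],
               om[1] * rel[, 2] - om[2] * rel[, 1])
  e_rot <- deformation_field_energy(net, rot)
  expect_lt(max(abs(e_rot)), 1e-16 * max(net$pairs$k))
  # diatomic stretched along its bond by +-1/2: E = 2k on both atoms
  d2 <- ca_model(rbind(c(0, 0, 0), c(0.35, 0, 0)), masses = "unit")
  net2 <- build_network(d2)
  k <- pair_force_constant(0.35)
  e <- deformation_field_energy(net2, rbind(c(0.5, 0, 0), c(-0.5, 0, 0)))
  expect_equal(e, rep(2 * k, 2))
})

test_that("deformation profile averages modes and min-max normalises", {
  sm <- small_modes()
  prof <- deformation_energies(sm$modes, sm$net)
  expect_true(all(prof$raw >= 0))
  expect_equal(range(prof$normalized), c(0, 1))
  expect_error(deformation_energies(sm$modes,
                                    build_network(random_model(5, 1))),
               "disagree")
})

test_that("descriptors are invariant under rigid transformation", {
  net <- build_network(random_model(10, seed = 10, masses = "residue"))
  modes <- normal_modes(net)
  moved <- transform_model(net$model, random_rotation(77), c(-1, 4, 2))
  net2 <- build_network(moved)
  modes2 <- normal_modes(net2)
  expect_equal(fluctuations(modes2)$values, fluctuations(modes)$values,
               tolerance = 1e-8)
  expect_equal(correlations(modes2)$values, correlations(modes)$values,
               tolerance = 1e-8)
  expect_equal(deformation_energies(modes2, net2)$raw,
               deformation_energies(modes, net)$raw, tolerance = 1e-8)
})

test_that("significance filter equals brute-force enumeration on a hand-built case", {
  C <- diag(5)
  vals <- c(0.9, -0.8, 0.3, 0.75, -0.2, 0.5, 0.85, -0.6, 0.1, 0.4)
  C[upper.tri(C)] <- vals
  C <- C + t(C) - diag(diag(C))
  coords <- matrix(c(0, 0, 0,  1, 0, 0,  0, 1.2, 0,  2, 2, 0,  0.3, 0.1, 0.2),
                   5, 3, byrow = TRUE)
  model <- ca_model(coords, masses = "unit")
  corr <- structure(list(values = C, label = "hand"),
                    class = "correlation_matrix")
  for (p in c(50, 80, 95, 100)) for (dmin in c(0, 0.5, 0.9)) {
    got <- significant_pairs(corr, model, p, dmin)
    want <- brute_significant(C, coords, p, dmin)
    expect_equal(got$threshold, want$threshold)
    got_ij <- as.matrix(got$pairs[, c("i", "j")])
    if (is.null(want$pairs)) {
      expect_identical(nrow(got_ij), 0L)
    } else {
      expect_equal(unname(got_ij), unname(want$pairs), ignore_attr = TRUE)
    }
  }
  # sign labels follow the correlation sign
  got <- significant_pairs(corr, model, 50, 0)
  expect_identical(got$pairs$sign, ifelse(got$pairs$c >= 0, "positive", "negative"))
  # percentile 100 retains at most the argmax pair(s)
  top <- significant_pairs(corr, model, 100, 0)
  expect_lte(nrow(top$pairs), 1L)
  expect_equal(abs(top$pairs$c), max(abs(vals)))
  # an impossible distance floor empties the set without error
  none <- significant_pairs(corr, model, 50, 100)
  expect_identical(nrow(none$pairs), 0L)
})

test_that("retained-pair counts are monotone in percentile and distance", {
  sm <- small_modes()
  b <- small_barrel()
  corr <- correlations(sm$modes)
  counts_p <- sapply(c(80, 90, 95, 99),
                     function(p) nrow(significant_pairs(corr, b$model, p, 0.8)$pairs))
  expect_true(all(diff(counts_p) <= 0))
  counts_d <- sapply(c(0, 0.4, 0.8, 1.6),
                     function(d) nrow(significant_pairs(corr, b$model, 95, d)$pairs))
  expect_true(all(diff(counts_d) <= 0))
})

test_that("connected objects partition the retained pairs", {
  sm <- small_modes()
  b <- small_barrel()
  sp <- significant_pairs(correlations(sm$modes), b$model, 95, 0.8)
  expect_gt(nrow(sp$pairs), 0)
  expect_false(anyNA(sp$pairs$object))
  # two pairs sharing a residue share an object
  g <- igraph::graph_from_edgelist(as.matrix(sp$pairs[, c("i", "j")]),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  expect_true(all(tapply(memb[sp$pairs$i], sp$pairs$object,
                         function(v) length(unique(v)) == 1L)))
})

test_that("strand-focused filter uses tighter score and looser distance thresholds", {
  # toy two-strand parallel sheet, 0.45 nm apart, 0.3 nm rise, pleated in y
  # (a strictly planar network is degenerate for pair-spring models)
  pleat <- 0.05 * c(-1, 1, -1)
  coords <- rbind(cbind(0, pleat, 0.3 * (0:2)), cbind(0.45, pleat, 0.3 * (0:2)))
  model <- ca_model(coords, masses = "unit")
  sse <- sse_annotation(strands = list(c(1, 3), c(4, 6)), helices = list())
  modes <- normal_modes(build_network(model))
  corr <- correlations(modes)
  sp4 <- strand_short_range_pairs(corr, model, sse)
  # cross-strand contacts survive the 4 A floor ...
  expect_gt(nrow(sp4$pairs), 0)
  strand_res <- sse_residues(sse, "strand")
  expect_true(all(sp4$pairs$i %in% strand_res | sp4$pairs$j %in% strand_res))
  expect_true(all(sp4$pairs$distance >= 0.4))
  # ... and none survive an 8 A floor on this geometry (diameter < 0.8 nm)
  sp8 <- significant_pairs(corr, model, 97.5, 0.8)
  expect_identical(nrow(sp8$pairs), 0L)
  # score threshold at 97.5 is at least the 95th-percentile threshold
  sm <- small_modes(); b <- small_barrel()
  c2 <- correlations(sm$modes)
  expect_gte(strand_short_range_pairs(c2, b$model, b$sse)$threshold,
             significant_pairs(c2, b$model, 95, 0.8)$threshold)
  expect_error(strand_short_range_pairs(corr, model,
                                        sse_annotation(list(), list(c(1, 3)))),
               "strand")
})

test_that("profile, pair and stick outputs are written with headers", {
  sm <- small_modes(); b <- small_barrel()
  f <- fluctuations(sm$modes)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(f, b$model, p1)
  expect_match(readLines(p1, n = 1), "fluctuations")
  got <- utils::read.delim(p1, skip = 1)
  expect_equal(got$normalized, f$values)
  sp <- significant_pairs(correlations(sm$modes), b$model)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(sp, p2)
  expect_match(readLines(p2, n = 1), "percentile")
  p3 <- withr::local_tempfile(fileext = ".pml")
  write_pymol_sticks(sp, b$model, p3)
  expect_equal(sum(grepl("^distance ", readLines(p3))), nrow(sp$pairs))
})
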