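# Shared fixtures and independent oracles. Expensive objects are computed
# lazily once per test run and cached in this environment.

.fix <- new.env()

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# random connected Calpha cloud (all-pairs network) with a minimum
# separation of 0.3 nm so no pair falls in the clamped region of the
# short-range force-constant branch; varied residues when masses="residue"
random_model <- function(n, seed, masses = "unit", spread = 1.2) {
  set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- stats::runif(3, 0, spread)
  for (i in 2:n) {
    repeat {
      cand <- stats::runif(3, 0, spread)
      d2 <- rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2, cand)^2)
      if (min(d2) >= 0.3^2) break
    }
    pts[i, ] <- cand
  }
  atoms <- data.frame(chain = "A", resno = seq_len(n), ins = "",
                      resname = sample(names(barreldyn:::.residue_mass_table),
                                       n, replace = TRUE),
                      stringsAsFactors = FALSE)
  ca_model(pts, atoms, masses = masses, label = paste0("rand", seed))
}

# small barrel shared by most descriptor/displacement tests
small_spec <- function(seed = 1L) {
  barrel_spec(strand_length = 5, helix_length = 8, loop_length = 3, seed = seed)
}

small_barrel <- function() fixture("small_barrel", function() {
  make_barrel(small_spec())
})

small_modes <- function() fixture("small_modes", function() {
  b <- small_barrel()
  net <- build_network(b$model)
  list(net = net, modes = normal_modes(net))
})

default_barrel <- function() fixture("default_barrel", function() {
  make_barrel(barrel_spec())
})

# --- independent oracles -----------------------------------------------

# Total elastic energy of a configuration (flat 3N vector, nm), written
# directly from the pair potential: sum over pairs of k/2 (|r| - r0)^2.
enm_potential <- function(network, vec) {
  cc <- matrix(vec, ncol = 3, byrow = TRUE)
  p <- network$pairs
  d <- cc[p$i, , drop = FALSE] - cc[p$j, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  sum(p$k / 2 * (r - p$r0)^2)
}

# central finite-difference Hessian of the potential (Cartesian, step in nm)
fd_hessian <- function(network, h = 1e-6) {
  x0 <- as.vector(t(network$model$coords))
  n3 <- length(x0)
  H <- matrix(0, n3, n3)
  for (a in seq_len(n3)) {
    ea <- numeric(n3); ea[a] <- h
    for (b in a:n3) {
      eb <- numeric(n3); eb[b] <- h
      H[a, b] <- H[b, a] <-
        (enm_potential(network, x0 + ea + eb) -
           enm_potential(network, x0 + ea - eb) -
           enm_potential(network, x0 - ea + eb) +
           enm_potential(network, x0 - ea - eb)) / (4 * h^2)
    }
  }
  H
}

# 3x3-block trace of a 3N x 3N matrix
block_trace <- function(M, i, j) {
  sum(diag(M[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j), drop = FALSE]))
}

# pseudo-inverse covariance oracle of the mass-weighted Hessian
pinv_covariance <- function(network) {
  MASS::ginv(hessian(network, mass_weighted = TRUE))
}

# brute-force enumeration oracle for the significance filter
brute_significant <- function(C, coords, percentile, min_distance) {
  n <- nrow(C)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) vals <- c(vals, abs(C[i, j]))
  thr <- sort(vals)[max(1, ceiling(percentile / 100 * length(vals)))]
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dd <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (abs(C[i, j]) >= thr && dd >= min_distance)
      out <- rbind(out, c(i, j))
  }
  list(threshold = thr, pairs = out)
}

random_rotation <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]   # proper rotation
  Q
}
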