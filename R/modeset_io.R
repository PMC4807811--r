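#' Write a mode set to a plain-text file
#'
#' Documented columnar format: `#`-prefixed header records N, the mass and
#' displacement conventions, the trivial-mode tolerance and count, and the
#' masses; then one block per mode (`MODE <index> <eigenvalue>` followed by
#' N lines of three eigenvector components). Values are printed with 17
#' significant digits so a round trip is lossless to well below 1e-12.
#'
#' @param modes a `mode_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_modeset <- function(modes, path) {
  n <- length(modes$masses)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c(
    "# barreldyn modeset v1",
    sprintf("# label: %s", modes$label),
    sprintf("# n_atoms: %d", n),
    sprintf("# mass_convention: %s", modes$mass_convention),
    sprintf("# displacement_convention: %s", modes$displacement_convention),
    sprintf("# tolerance: %s", fmt(modes$tolerance)),
    sprintf("# n_trivial: %d", modes$n_trivial),
    paste("# masses:", paste(fmt(modes$masses), collapse = " "))
  ), con)
  for (m in seq_along(modes$values)) {
    writeLines(sprintf("MODE %d %s", m, fmt(modes$values[m])), con)
    v <- matrix(modes$vectors[, m], ncol = 3, byrow = TRUE)
    writeLines(paste(fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
  }
  invisible(path)
}

#' Read a mode set written by [write_modeset()]
#'
#' @param path file path.
#' @return a `mode_set` object; displacement fields are rebuilt from the
#'   stored eigenvectors and masses under the recorded convention.
#' @export
read_modeset <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (length(ln) != 1L) stop("missing header field: ", key)
    sub(paste0("^# ", key, ": ?"), "", ln)
  }
  n <- as.integer(get("n_atoms"))
  masses <- as.numeric(strsplit(get("masses"), " ")[[1]])
  body <- lines[!startsWith(lines, "#")]
  mode_starts <- grep("^MODE ", body)
  if (length(mode_starts) != 3L * n) stop("expected ", 3L * n, " mode blocks")
  values <- numeric(3L * n)
  vectors <- matrix(0, 3L * n, 3L * n)
  for (q in seq_along(mode_starts)) {
    hd <- strsplit(body[mode_starts[q]], " +")[[1]]
    values[q] <- as.numeric(hd[3])
    block <- body[(mode_starts[q] + 1L):(mode_starts[q] + n)]
    xyz <- matrix(as.numeric(unlist(strsplit(block, " +"))), ncol = 3, byrow = TRUE)
    vectors[, q] <- as.vector(t(xyz))
  }
  disp_conv <- get("displacement_convention")
  w <- 1 / sqrt(rep(masses, each = 3L))
  disp <- vectors * w
  if (disp_conv == "deweighted-renormalized")
    disp <- sweep(disp, 2, sqrt(colSums(disp^2)), "/")
  structure(list(values = values, vectors = vectors, displacements = disp,
                 n_trivial = as.integer(get("n_trivial")),
                 tolerance = as.numeric(get("tolerance")),
                 masses = masses, mass_convention = get("mass_convention"),
                 displacement_convention = disp_conv, label = get("label")),
            class = "mode_set")
}
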