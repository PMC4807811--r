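#' Run the full comparative-dynamics pipeline on a set of structures
#'
#' For each structure: elastic network, normal modes, fluctuation and
#' deformation profiles, correlation matrix, significance-filtered pairs
#' and overlap table; then the pairwise Bhattacharyya matrix across the
#' aligned set. This is the programmatic equivalent of chaining the
#' numbered analysis scripts; all outputs are optional files plus a
#' returned list of in-memory results, and a JSON run manifest records
#' every convention in play.
#'
#' @param models named list of `ca_model` objects (names must cover the
#'   alignment labels when `alignment` is given).
#' @param alignment optional `alignment_map` for the BC comparison.
#' @param sse optional [sse_annotation()] shared by all structures (as for
#'   a synthetic family) enabling the overlap table and strand-pair sets.
#' @param params a [ff_params()].
#' @param config a [bc_config()].
#' @param percentile,min_distance significance-filter settings (defaults
#'   95, 0.8 nm).
#' @param out_dir optional output directory for TSV/Newick/manifest files.
#' @param seed recorded in the manifest.
#' @return list with per-structure `modes`, `fluctuations`, `deformation`,
#'   `correlations`, `pairs`, `overlaps` and, when aligned, `bc`.
#' @export
run_pipeline <- function(models, alignment = NULL, sse = NULL,
                         params = ff_params(), config = bc_config(),
                         percentile = 95, min_distance = 0.8,
                         out_dir = NULL, seed = NA_integer_) {
  res <- list(structures = list())
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (nm in names(models)) {
    model <- models[[nm]]
    net <- build_network(model, params)
    modes <- normal_modes(net)
    fl <- fluctuations(modes)
    de <- deformation_energies(modes, net)
    co <- correlations(modes)
    sp <- significant_pairs(co, model, percentile, min_distance)
    ov <- if (!is.null(sse)) overlap_report(modes, model, sse) else NULL
    res$structures[[nm]] <- list(modes = modes, fluctuations = fl,
                                 deformation = de, correlations = co,
                                 pairs = sp, overlaps = ov)
    if (!is.null(out_dir)) {
      write_profile_tsv(fl, model, file.path(out_dir, paste0(nm, "_fluct.tsv")))
      write_profile_tsv(de, model, file.path(out_dir, paste0(nm, "_deform.tsv")))
      write_pairs_tsv(sp, file.path(out_dir, paste0(nm, "_pairs.tsv")))
      write_pymol_sticks(sp, model, file.path(out_dir, paste0(nm, "_sticks.pml")))
      if (!is.null(ov))
        utils::write.table(ov, file.path(out_dir, paste0(nm, "_overlap.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(alignment)) {
    modesets <- lapply(res$structures, `[[`, "modes")
    res$bc <- bc_matrix(modesets[alignment$labels], alignment, config)
    if (!is.null(out_dir))
      write_bc_result(res$bc,
                      path_matrix = file.path(out_dir, "bc_matrix.tsv"),
                      path_tree = file.path(out_dir, "bc_dendrogram.nwk"),
                      path_ranks = file.path(out_dir, "bc_ranks.tsv"))
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(
      package = "barreldyn",
      version = as.character(utils::packageVersion("barreldyn")),
      seed = seed,
      n_structures = length(models),
      force_field = unclass(params)[c("a", "b", "c", "d")],
      cutoff = if (is.null(params$cutoff)) "none" else params$cutoff,
      percentile = percentile, min_distance_nm = min_distance,
      bc = unclass(config),
      mass_convention = models[[1]]$mass_convention
    ), file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
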