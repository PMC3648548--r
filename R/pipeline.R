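#' Assemble a pipeline run configuration
#'
#' A run is fully determined by its configuration plus the input structure
#' bytes; every field is a plain value so the config serializes cleanly.
#'
#' @param structure path to a PDB file (always a local, user-supplied file;
#'   accession strings are labels only — the pipeline never touches the
#'   network).
#' @param chains optional chain filter.
#' @param cutoff contact cutoff in Angstroms (default 4.5).
#' @param diagonal_mode `"zero"` or `"self_atoms"`.
#' @param cost_mode `"inverse"` or `"neglog"`.
#' @param sites named list of residue-key vectors, the perturbation sites.
#' @param gate_resno channel gate residue number.
#' @param start_chain chain carrying the perturbations (default `"B"`).
#' @param k paths per (source, scenario) query (default 10).
#' @param times model-time grid (default [time_grid()]).
#' @param regions named list of residue-number vectors for path
#'   classification (default [glic_regions()]).
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(structure, sites, gate_resno,
                            chains = NULL, cutoff = 4.5,
                            diagonal_mode = "zero", cost_mode = "inverse",
                            start_chain = "B", k = 10, times = time_grid(),
                            regions = glic_regions(), out_dir = ".") {
  structure(list(structure = structure, chains = chains, cutoff = cutoff,
                 diagonal_mode = diagonal_mode, cost_mode = cost_mode,
                 sites = sites, gate_resno = gate_resno,
                 start_chain = start_chain, k = k, times = times,
                 regions = regions, out_dir = out_dir),
            class = "run_config")
}

#' Run the full perturbation-transmission pipeline
#'
#' parse -> contact network -> flux propagation (one trajectory per
#' perturbation site) -> path protocol -> classification -> report.
#' Writes, under `config$out_dir`: one trajectory CSV per site, a path TSV,
#' and a summary JSON (counts, per-region path fractions, equilibrium
#' distribution); returns everything in memory plus a manifest of the files
#' written. Reruns on identical inputs produce identical outputs.
#'
#' @param config a `run_config` from [pipeline_config()].
#' @param model optionally, an already-loaded `structure_model` (the
#'   `structure` path is then ignored).
#' @return list with `model`, `tm`, `trajectories`, `paths` (classified),
#'   `report`, `fractions`, `equilibrium`, `manifest`.
#' @export
run_pipeline <- function(config, model = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(model))
    model <- read_structure(config$structure, chains = config$chains)
  net <- count_contacts(model, cutoff = config$cutoff)
  tm <- build_transition_model(net, diagonal_mode = config$diagonal_mode)

  conn <- connectivity_report(tm)
  if (conn$n_components > 1)
    warning("contact graph has ", conn$n_components,
            " components; paths are restricted to components")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)

  trajectories <- list()
  for (site in names(config$sites)) {
    pert <- uniform_perturbation(tm, config$sites[[site]])
    traj <- propagate(tm, pert, times = config$times)
    trajectories[[site]] <- traj
    f <- file.path(config$out_dir, paste0("trajectory_", site, ".csv"))
    export_trajectory(traj, f)
    manifest <- c(manifest, f)
  }

  paths <- run_protocol(tm, config$sites, config$gate_resno,
                        start_chain = config$start_chain,
                        adjacency = model, k = config$k,
                        cost_mode = config$cost_mode)
  paths <- classify_paths(paths, config$regions, tm)
  report <- path_report(paths)
  f <- file.path(config$out_dir, "paths.tsv")
  export_paths(report, f)
  manifest <- c(manifest, f)

  pi_eq <- equilibrium_distribution(tm)
  summary <- list(
    structure = config$structure %||% model$source_id,
    n_residues = nrow(tm$residues),
    cutoff = config$cutoff,
    diagonal_mode = config$diagonal_mode,
    cost_mode = config$cost_mode,
    n_paths = nrow(paths),
    region_fractions = as.list(attr(paths, "fractions")),
    scenario_counts = apply(report$counts, 1, sum),
    equilibrium = setNames(pi_eq, tm$residues$key))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    f <- file.path(config$out_dir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA)
    manifest <- c(manifest, f)
  }

  list(model = model, tm = tm, trajectories = trajectories, paths = paths,
       report = report, fractions = attr(paths, "fractions"),
       equilibrium = pi_eq, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a user-supplied deposited structure file
#'
#' Coordinates of deposited structures are never downloaded by this package;
#' the user drops the PDB files where the package can find them. The lookup
#' order for an accession like `"4F8H"` is: `<dir>/<id>.pdb` for `dir` in
#' `getOption("allopath.structure_dir")` (if set), then the package's
#' `structures/` installation directory. Case-insensitive on the id.
#'
#' @param id accession-style label, e.g. `"4F8H"`.
#' @return the file path, or `NA_character_` when not found.
#' @export
find_structure <- function(id) {
  dirs <- c(getOption("allopath.structure_dir"),
            system.file("structures", package = "allopath"))
  dirs <- dirs[nzchar(dirs)]
  for (d in dirs) {
    for (f in file.path(d, paste0(c(tolower(id), toupper(id)), ".pdb")))
      if (file.exists(f)) return(f)
  }
  NA_character_
}

#' Perturbation sites of the GLIC study system
#'
#' The two functionally characterized extracellular perturbation sites of
#' GLIC, as residue keys in a given start chain: the C-loop salt-bridge
#' (NQN) site D91/E177/D178 and the inter-subunit ketamine pocket
#' N152/D153/D154 (complementary side) + F174/L176/K183 (principal side).
#' The GLIC gate is I233 (9'); see [pipeline_config()].
#' @param start_chain chain carrying the perturbation (default `"B"`).
#' @return named list of residue-key vectors (`nqn`, `ketamine`).
#' @export
glic_sites <- function(start_chain = "B") {
  list(nqn = residue_key(start_chain, c(91, 177, 178)),
       ketamine = residue_key(start_chain, c(152, 153, 154, 174, 176, 183)))
}
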