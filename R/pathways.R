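#' k highest-probability signaling paths between two residues
#'
#' Runs Yen's loopless k-shortest-path algorithm on the directed cost graph
#' of the transmission model. With the default cost `1/m_ij`, low summed cost
#' is the model's proxy for high transmission probability; `"neglog"` uses
#' `-log(m_ij)` so that minimizing the sum exactly maximizes the path
#' probability product (the two objectives can rank paths differently — both
#' are available, the inverse is the default).
#'
#' Paths are simple (loopless), returned in nondecreasing cost order; the
#' rank-1 path is the Dijkstra shortest path. Equal-cost paths are ordered by
#' the lexicographic order of their node index sequences, making the output
#' deterministic.
#'
#' @param tm a `transition_model`.
#' @param source,target residue keys (see [residue_key()]); must differ.
#' @param k number of paths requested (default 10); fewer are returned when
#'   the graph is exhausted.
#' @param cost_mode `"inverse"` (default, `1/m`) or `"neglog"` (`-log m`).
#' @return a `signal_paths` data.frame: one row per path with `source`,
#'   `target`, `rank`, `cost`, `probability` (product of `m_ij` along the
#'   path), `n_nodes`, `nodes` (keys joined by `"->"`), and list column
#'   `node_index`.
#' @export
yen_k_shortest <- function(tm, source, target, k = 10,
                           cost_mode = c("inverse", "neglog")) {
  stopifnot(inherits(tm, "transition_model"))
  cost_mode <- match.arg(cost_mode)
  if (k < 1) stop("k must be >= 1")
  src <- resolve_residues(tm, source)
  dst <- resolve_residues(tm, target)
  if (src == dst) stop("source and target must differ")
  t3 <- as(as(tm$M, "TsparseMatrix"), "generalMatrix")
  w <- if (cost_mode == "inverse") 1 / t3@x else -log(t3@x)
  res <- .yen_cpp(nrow(tm$M), t3@i + 1L, t3@j + 1L, w,
                  src, dst, as.integer(k))
  if (length(res$paths) == 0)
    stop("no path from ", source, " to ", target,
         " (different connected components?)")
  M <- tm$M
  keys <- tm$residues$key
  out <- data.frame(
    source = source, target = target,
    rank = seq_along(res$paths),
    cost = res$costs,
    probability = vapply(res$paths, function(p) {
      prod(M[cbind(p[-length(p)], p[-1])])
    }, numeric(1)),
    n_nodes = lengths(res$paths),
    nodes = vapply(res$paths, function(p) paste(keys[p], collapse = "->"),
                   character(1)))
  out$node_index <- res$paths
  class(out) <- c("signal_paths", "data.frame")
  out
}

#' Subunit adjacency around the pore axis
#'
#' Orders the chains of a multi-chain structure by the angular position of
#' their centers of mass around the global center (projected on the xy
#' plane, viewed from +z) and reports each chain's counterclockwise and
#' clockwise neighbors. Adjacency is geometric, not alphabetical: chain IDs
#' carry no guarantee about spatial order around the pore.
#'
#' @param model a `structure_model` with >= 2 chains.
#' @return data.frame with `chain`, `angle` (radians), `ccw`, `cw`.
#' @export
chain_adjacency <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  cx <- mean(a$x); cy <- mean(a$y)
  ang <- vapply(model$chains, function(ch) {
    sel <- a$chain == ch
    atan2(mean(a$y[sel]) - cy, mean(a$x[sel]) - cx)
  }, numeric(1))
  ord <- order(ang)
  chains <- model$chains[ord]
  nc <- length(chains)
  data.frame(chain = chains, angle = sort(ang),
             ccw = chains[c(2:nc, 1)[seq_len(nc)]],
             cw = chains[c(nc, seq_len(nc - 1))])
}

#' Full perturbation-to-gate path protocol
#'
#' For every perturbed residue (source, in `start_chain`) and each of three
#' ending-subunit scenarios — gate of the same subunit (`intra`), of the
#' counterclockwise neighbor (`ccw`) and of the clockwise neighbor (`cw`) —
#' runs [yen_k_shortest()] with the given `k` and collects all paths tagged
#' by site, source and scenario. With 9 perturbed residues, k = 10 and 3
#' scenarios this is the 270-path protocol.
#'
#' @param tm a `transition_model`.
#' @param sites named list of character vectors of residue keys; names label
#'   the perturbation sites (e.g. `nqn`, `ketamine`).
#' @param gate_resno residue number of the channel gate (must exist in every
#'   involved chain).
#' @param start_chain chain in which all perturbations are placed
#'   (default `"B"`).
#' @param adjacency chain adjacency, either a `structure_model` (geometric
#'   adjacency is computed) or a data.frame from [chain_adjacency()].
#' @param k paths per (source, scenario) query (default 10).
#' @param cost_mode passed to [yen_k_shortest()].
#' @return a `signal_paths` data.frame with additional columns `site`,
#'   `scenario` (`intra`/`ccw`/`cw`), `target_chain`.
#' @export
run_protocol <- function(tm, sites, gate_resno, start_chain = "B",
                         adjacency, k = 10,
                         cost_mode = c("inverse", "neglog")) {
  cost_mode <- match.arg(cost_mode)
  if (inherits(adjacency, "structure_model"))
    adjacency <- chain_adjacency(adjacency)
  row <- adjacency[adjacency$chain == start_chain, ]
  if (nrow(row) != 1) stop("start chain '", start_chain, "' not in adjacency")
  targets <- c(intra = start_chain, ccw = row$ccw, cw = row$cw)
  out <- list()
  for (site in names(sites)) {
    for (source in sites[[site]]) {
      for (sc in names(targets)) {
        target <- residue_key(targets[[sc]], gate_resno)
        p <- yen_k_shortest(tm, source, target, k = k, cost_mode = cost_mode)
        p$site <- site
        p$scenario <- sc
        p$target_chain <- targets[[sc]]
        out[[length(out) + 1]] <- p
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("signal_paths", "data.frame")
  res
}

#' Classify paths by structural region
#'
#' Labels each path with the region(s) its interior nodes traverse.
#' Membership is chain-agnostic residue numbers (a region exists in every
#' subunit); endpoints are excluded, since sources and targets are fixed by
#' the protocol and would otherwise classify every path. A path touching
#' exactly one region gets that region's label; touching several is
#' `"ambiguous"`, touching none is `"other"` — both reported explicitly
#' rather than silently binned.
#'
#' @param paths a `signal_paths` data.frame.
#' @param regions named list of integer vectors of residue numbers, e.g.
#'   `list(beta1_beta2_loop = 32:37, pre_TM1 = 192:200)` (see
#'   [glic_regions()]).
#' @param residues residue table of the model the paths were computed on
#'   (a `transition_model` is also accepted).
#' @return `paths` with a `region` column added; attribute `"fractions"`
#'   holds the per-label path fractions.
#' @export
classify_paths <- function(paths, regions, residues) {
  if (!is.null(residues$residues)) residues <- residues$residues
  if (any(duplicated(unlist(regions))))
    stop("regions overlap; membership sets must be disjoint")
  resno <- residues$resno
  lab <- vapply(paths$node_index, function(p) {
    interior <- p[-c(1, length(p))]
    if (length(interior) == 0) return("other")
    hit <- names(regions)[vapply(regions, function(r)
      any(resno[interior] %in% r), logical(1))]
    if (length(hit) == 0) "other"
    else if (length(hit) > 1) "ambiguous"
    else hit
  }, character(1))
  paths$region <- lab
  levels <- c(names(regions), "ambiguous", "other")
  frac <- if (nrow(paths) == 0) setNames(rep(0, length(levels)), levels)
          else table(factor(lab, levels = levels)) / nrow(paths)
  attr(paths, "fractions") <- as.numeric(frac) |> setNames(levels)
  paths
}

#' Default GLIC region definitions
#'
#' Residue-number membership (per chain) of the two coupling regions that
#' dominate the highest-probability EC-to-gate paths in GLIC: the beta1-beta2
#' loop (loop 2) at the EC-TM interface, and pre-TM1, the stretch covalently
#' linking the EC domain to TM1. Bounds are inferred from the residues
#' canonically assigned to these elements (D32..F37; Q193..N200) and are
#' fully configurable — classification fractions are sensitive to them.
#' @return named list of integer vectors.
#' @export
glic_regions <- function() {
  list(beta1_beta2_loop = 32:37, pre_TM1 = 192:200)
}

#' Tabular path summary
#'
#' Flattens a classified path collection into a report table plus a
#' scenario-by-region count matrix (row totals = paths per scenario).
#' @param paths a classified `signal_paths` data.frame (see
#'   [classify_paths()]); an unclassified one gets a single `"unclassified"`
#'   region.
#' @return list with `table` (data.frame: site, source, scenario, rank,
#'   nodes, cost, probability, region) and `counts` (matrix).
#' @export
path_report <- function(paths) {
  if (is.null(paths$region)) paths$region <- "unclassified"
  if (is.null(paths$site)) paths$site <- ""
  if (is.null(paths$scenario)) paths$scenario <- "intra"
  tab <- paths[, c("site", "source", "scenario", "rank", "nodes",
                   "cost", "probability", "region")]
  counts <- table(scenario = paths$scenario, region = paths$region)
  list(table = tab, counts = unclass(counts))
}

#' Write a path table as TSV
#' @param report output of [path_report()], or a `signal_paths` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_paths <- function(report, path) {
  tab <- if (is.data.frame(report)) {
    report$node_index <- NULL
    report
  } else report$table
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
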