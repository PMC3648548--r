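# Synthetic structures with known contact topology. Pseudo-residues are
# written as GLY with a single CA atom, so atom-atom contact counts are 0/1
# and the ground-truth contact matrix can be constructed from the placement
# rules rather than measured. All generators are fully determined by their
# arguments (random_cloud additionally by `seed`).

ca_model <- function(chain, resno, x, y, z, source_id) {
  atoms <- data.frame(type = "ATOM", eleno = seq_along(x),
                      elety = "CA", alt = "", resid = "GLY",
                      chain = chain, resno = resno, insert = "",
                      x = x, y = y, z = z, o = 1, elesy = "C")
  build_structure_model(atoms, source_id = source_id)
}

rotate_chain <- function(xyz, angle) {
  cbind(xyz[, 1] * cos(angle) - xyz[, 2] * sin(angle),
        xyz[, 1] * sin(angle) + xyz[, 2] * cos(angle),
        xyz[, 3])
}

edges_to_matrix <- function(edges, keys) {
  N <- length(keys)
  n <- matrix(0, N, N, dimnames = list(keys, keys))
  if (nrow(edges) > 0) {
    ia <- match(edges[[1]], keys); ib <- match(edges[[2]], keys)
    for (e in seq_along(ia)) {
      n[ia[e], ib[e]] <- n[ia[e], ib[e]] + 1
      n[ib[e], ia[e]] <- n[ib[e], ia[e]] + 1
    }
  }
  n
}

#' Generate a synthetic structure with known contact topology
#'
#' Builds small seeded test structures together with the analytically known
#' ground-truth contact matrix at the 4.5 Angstrom cutoff — the matrix is
#' derived from the placement rules (or, for `random_cloud`, by direct
#' enumeration over the generated coordinates), never by calling
#' [count_contacts()], so it can serve as an independent oracle.
#'
#' Kinds:
#' * `dipeptide` — two single-atom residues `spacing` apart on one chain;
#' * `helix` — one chain of `n_residues_per_chain` residues on an ideal
#'   helical trace (rise 1.5 A, radius 2.3 A, 100 degrees/residue);
#' * `ring_pentamer` — `n_chains` chains (default 5) of vertical residue
#'   stacks (3.8 A rise) placed on a ring tight enough that each residue
#'   touches its two chain neighbors plus the same-numbered residue of both
#'   adjacent chains; exactly C5-symmetric (chain k is chain 1 rotated by
#'   `360/n_chains * k` degrees about z);
#' * `random_cloud` — `n_residues_per_chain` residues uniform in a cube,
#'   seeded.
#'
#' @param kind fixture kind (see above).
#' @param n_residues_per_chain residues per chain (default 20; `dipeptide`
#'   is fixed at 2).
#' @param n_chains number of chains (only `ring_pentamer`; default 5).
#' @param spacing inter-residue spacing in Angstroms (default 3.8; for
#'   `random_cloud` the cube side is `spacing * n^(1/3)`).
#' @param seed integer seed (`random_cloud` only).
#' @return list with `model` (a `structure_model`), `n_true` (ground-truth
#'   contact count matrix, residue keys as dimnames), and the generating
#'   parameters.
#' @export
make_fixture <- function(kind = c("dipeptide", "helix", "ring_pentamer",
                                  "random_cloud"),
                         n_residues_per_chain = 20, n_chains = 5,
                         spacing = 3.8, seed = 1) {
  kind <- match.arg(kind)
  if (spacing <= 0) stop("spacing must be positive")
  cutoff <- 4.5
  if (kind == "dipeptide") {
    model <- ca_model("A", 1:2, c(0, spacing), c(0, 0), c(0, 0),
                      "synthetic dipeptide")
    edges <- if (spacing <= cutoff) data.frame(a = "A:1", b = "A:2")
             else data.frame(a = character(0), b = character(0))
    return(list(model = model, n_true = edges_to_matrix(edges,
                model$residues$key), kind = kind, spacing = spacing))
  }
  if (kind == "helix") {
    n <- n_residues_per_chain
    i <- seq_len(n) - 1
    ang <- i * 100 * pi / 180
    x <- 2.3 * cos(ang); y <- 2.3 * sin(ang); z <- 1.5 * i
    model <- ca_model("A", seq_len(n), x, y, z, "synthetic helix")
    # ground truth by direct distance evaluation of the generative trace
    d <- as.matrix(stats::dist(cbind(x, y, z)))
    nt <- (d <= cutoff) * 1
    diag(nt) <- 0
    dimnames(nt) <- list(model$residues$key, model$residues$key)
    return(list(model = model, n_true = nt, kind = kind))
  }
  if (kind == "ring_pentamer") {
    n <- n_residues_per_chain
    step <- 2 * pi / n_chains
    radius <- 4.0 / (2 * sin(step / 2))  # adjacent-chain partners at 4.0 A
    base <- cbind(rep(radius, n), rep(0, n), spacing * (seq_len(n) - 1))
    chains <- LETTERS[seq_len(n_chains)]
    coords <- do.call(rbind, lapply(seq_len(n_chains), function(k)
      rotate_chain(base, step * (k - 1))))
    model <- ca_model(rep(chains, each = n), rep(seq_len(n), n_chains),
                      coords[, 1], coords[, 2], coords[, 3],
                      "synthetic ring pentamer")
    edges <- rbind(
      # chain neighbors i,i+1
      do.call(rbind, lapply(chains, function(ch)
        data.frame(a = residue_key(ch, seq_len(n - 1)),
                   b = residue_key(ch, 2:n)))),
      # same-numbered residue of the next chain around the ring
      do.call(rbind, lapply(seq_len(n_chains), function(k)
        data.frame(a = residue_key(chains[k], seq_len(n)),
                   b = residue_key(chains[k %% n_chains + 1], seq_len(n))))))
    return(list(model = model, n_true = edges_to_matrix(edges,
                model$residues$key), kind = kind, radius = radius))
  }
  # random_cloud
  n <- n_residues_per_chain
  side <- spacing * n^(1 / 3)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  xyz <- matrix(stats::runif(3 * n, 0, side), ncol = 3)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  model <- ca_model("A", seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3],
                    sprintf("synthetic random cloud (seed %d)", seed))
  d <- as.matrix(stats::dist(xyz))
  nt <- (d <= cutoff) * 1
  diag(nt) <- 0
  dimnames(nt) <- list(model$residues$key, model$residues$key)
  list(model = model, n_true = nt, kind = kind, seed = seed)
}

#' Synthetic pore-forming pentamer with annotated gate and interface
#'
#' A minimal C5-symmetric analogue of a pentameric channel for end-to-end
#' protocol tests. Each of the 5 chains has 14 single-atom residues: an
#' extracellular column (residues 1-6, radius 9 A), a linker (7-8) tapering
#' inward, and a pore-lining column (9-12). The upper pore residues (9-10,
#' radius 4.5 A) are splayed apart so chains do not touch there; at the gate
#' level (residues 11-12, radius 3.4 A) the same-numbered residues of
#' adjacent chains pack against each other — the only transmembrane
#' crossing. In the extracellular domain, residue 13 of each chain reaches
#' toward the next chain around the ring and touches residue 14 of that
#' chain — the only extracellular crossing. Residue 11 is the designated
#' gate (the 9'-like position).
#'
#' A signal from the extracellular side therefore reaches the gate of an
#' adjacent subunit either by crossing early at the interface pair and
#' descending the neighbor's own column, or by descending its own column
#' and crossing within the tightly packed gate-level ring — the synthetic
#' analogues of the extracellular-interface and TM-level coupling routes of
#' a real channel. The two routes are mutually exclusive in the residue
#' numbers they traverse, so region classification on `regions` yields
#' clean labels: `interface` = 13:14, `pore` = 11:12 (intra-subunit paths
#' touch neither as interior nodes and classify as `"other"`).
#'
#' @return list with `model`, `n_true` (ground-truth contact matrix),
#'   `gate_resno` (11), `pore_resnos` (9:12), `interface_resnos` (13:14),
#'   and `regions` for [classify_paths()].
#' @export
make_pore_pentamer <- function() {
  ec_z <- seq(30.8, 11.8, by = -3.8)           # residues 1-6, radius 9
  p6 <- c(9, 0, 11.8); tm_top <- c(4.5, 0, 4.2)
  u <- (tm_top - p6) / 3
  linker <- rbind(p6 + u, p6 + 2 * u)          # residues 7-8
  upper <- rbind(c(4.5, 0, 4.2), c(4.5, 0, 0.4))    # residues 9-10
  gate <- rbind(c(3.4, 0, -3.4), c(3.4, 0, -7.2))   # residues 11-12
  delta <- asin(2 / 9)                         # interface partners at 4.0 A
  a13 <- pi / 5 - delta
  iface <- rbind(c(9 * cos(a13), 9 * sin(a13), 23.2),     # residue 13
                 c(9 * cos(a13), -9 * sin(a13), 23.2))    # residue 14
  base <- rbind(cbind(9, 0, ec_z), linker, upper, gate, iface)
  chains <- LETTERS[1:5]
  coords <- do.call(rbind, lapply(0:4, function(k)
    rotate_chain(base, 2 * pi / 5 * k)))
  n_per <- nrow(base)
  model <- ca_model(rep(chains, each = n_per), rep(seq_len(n_per), 5),
                    coords[, 1], coords[, 2], coords[, 3],
                    "synthetic pore pentamer")
  intra <- data.frame(a = 1:11, b = 2:12)          # the backbone trace
  intra <- rbind(intra, data.frame(a = c(3, 3), b = c(13, 14)))
  edges <- do.call(rbind, lapply(seq_len(5), function(k) rbind(
    data.frame(a = residue_key(chains[k], intra$a),
               b = residue_key(chains[k], intra$b)),
    # interface: residue 13 touches residue 14 of the next chain (ccw)
    data.frame(a = residue_key(chains[k], 13),
               b = residue_key(chains[k %% 5 + 1], 14)),
    # gate-level ring: same-numbered residues 11, 12 of adjacent chains
    data.frame(a = residue_key(chains[k], 11:12),
               b = residue_key(chains[k %% 5 + 1], 11:12)))))
  list(model = model,
       n_true = edges_to_matrix(edges, model$residues$key),
       gate_resno = 11, pore_resnos = 9:12, interface_resnos = 13:14,
       regions = list(interface = 13:14, pore = 11:12))
}
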