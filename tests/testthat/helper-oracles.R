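# Independent oracles and hand-written fixtures. Everything here is kept
# deliberately naive (double loops, exhaustive recursion) so it cannot share
# a defect with the implementation it checks.

# O(N^2 * atoms^2) contact counting by direct double loop.
brute_contacts <- function(model, cutoff = 4.5) {
  a <- model$atoms
  N <- nrow(model$residues)
  n <- matrix(0, N, N)
  for (i in seq_len(nrow(a) - 1)) {
    for (j in (i + 1):nrow(a)) {
      ri <- a$res_index[i]; rj <- a$res_index[j]
      if (ri == rj) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
      if (d <= cutoff) {
        n[ri, rj] <- n[ri, rj] + 1
        n[rj, ri] <- n[rj, ri] + 1
      }
    }
  }
  n
}

# Exhaustive enumeration of all simple paths src -> dst on a dense cost
# matrix (Inf = no edge); returns them sorted by (cost, lexicographic node
# sequence) — the same order contract as the Yen implementation.
enumerate_simple_paths <- function(cost, src, dst) {
  n <- nrow(cost)
  paths <- list(); costs <- numeric(0)
  visit <- function(v, acc, c_acc) {
    if (v == dst) {
      paths[[length(paths) + 1]] <<- acc
      costs[length(costs) + 1] <<- c_acc
      return()
    }
    for (w in seq_len(n)) {
      if (is.finite(cost[v, w]) && !(w %in% acc))
        visit(w, c(acc, w), c_acc + cost[v, w])
    }
  }
  visit(src, src, 0)
  if (length(paths) == 0) return(list(paths = list(), costs = numeric(0)))
  key <- vapply(paths, function(p)
    paste(formatC(p, width = 4, flag = "0"), collapse = ""), character(1))
  ord <- order(costs, key)
  list(paths = paths[ord], costs = costs[ord])
}

# Minimal transition_model wrapper around an arbitrary positive transition
# matrix (for path tests the rows need not be stochastic).
fake_tm <- function(M) {
  n <- nrow(M)
  res <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                    resid = "GLY", index = seq_len(n),
                    key = residue_key("A", seq_len(n)))
  structure(list(M = methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                             "generalMatrix"), "CsparseMatrix"),
                 residues = res),
            class = "transition_model")
}

# transition model straight from a symmetric count matrix
tm_from_counts <- function(n) {
  N <- nrow(n)
  res <- data.frame(chain = "A", resno = seq_len(N), insert = "",
                    resid = "GLY", index = seq_len(N),
                    key = residue_key("A", seq_len(N)))
  net <- structure(list(n = methods::as(Matrix::Matrix(n, sparse = TRUE),
                                        "generalMatrix"),
                        residues = res, cutoff = 4.5, diagonal = "zero",
                        atoms_per_residue = rep(1L, N)),
                   class = "contact_network")
  build_transition_model(net)
}

# random weighted digraph as a dense cost matrix (Inf off-edges); weights
# are continuous so path costs are tie-free
random_cost_matrix <- function(n, p = 0.45, seed = 1) {
  set.seed(seed)
  cost <- matrix(Inf, n, n)
  on <- matrix(runif(n * n) < p, n, n)
  diag(on) <- FALSE
  cost[on] <- runif(sum(on), 0.5, 10)
  cost
}

# Hand-written GLY-ALA dipeptide: 4 + 5 = 9 heavy atoms, one chain.
dipeptide_pdb_lines <- function() c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      6  CA  ALA A   2       3.988   2.839   0.000  1.00  0.00           C",
  "ATOM      7  C   ALA A   2       5.504   2.693   0.000  1.00  0.00           C",
  "ATOM      8  O   ALA A   2       6.030   1.580   0.000  1.00  0.00           O",
  "ATOM      9  CB  ALA A   2       3.561   3.664   1.221  1.00  0.00           C",
  "END")

write_pdb_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# single-chain CA-only model from a coordinate matrix, via the PDB writer
ca_fixture_model <- function(xyz) {
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), seq_len(nrow(xyz)), xyz[, 1], xyz[, 2], xyz[, 3])
  read_structure(write_pdb_fixture(c(lines, "END")))
}

# brute-force rigid-body superposition: minimize RMSD over rotations by
# multi-start optimization on Euler angles (after centering both sets)
brute_rmsd <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  a <- sweep(xa, 2, ca); b <- sweep(xb, 2, cb)
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(ang) sqrt(mean(rowSums((b %*% rotmat(ang) - a)^2)))
  best <- Inf
  set.seed(42)
  for (s in 1:40) {
    r <- stats::optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (r$value < best) best <- r$value
  }
  best
}
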