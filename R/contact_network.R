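#' Count heavy-atom contacts between residues
#'
#' For every unordered pair of distinct residues i, j, `n[i, j]` is the number
#' of heavy-atom pairs (one atom in each residue) whose Euclidean distance is
#' less than or equal to `cutoff` (the comparison is inclusive). The matrix is
#' symmetric by construction; residues adjacent in sequence are counted like
#' any others. The default 4.5 Angstrom cutoff is the value at which signal
#' propagation through this class of network is fastest across perturbation
#' sites.
#'
#' @param model a `structure_model` from [read_structure()] or a fixture
#'   generator.
#' @param cutoff contact distance in Angstroms (default 4.5).
#' @return a `contact_network`: list with `n` (sparse symmetric
#'   `Matrix::dgCMatrix` of counts), `residues` (the model's residue table),
#'   `cutoff`, and `diagonal` (how the diagonal is populated; `"zero"` here,
#'   see [build_transition_model()]).
#' @export
count_contacts <- function(model, cutoff = 4.5) {
  stopifnot(inherits(model, "structure_model"))
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- model$atoms
  if (nrow(a) == 0) stop("empty structure")
  N <- nrow(model$residues)
  tr <- .count_contacts_cpp(a$x, a$y, a$z, as.integer(a$res_index), cutoff)
  n <- Matrix::sparseMatrix(i = c(tr$i, tr$j), j = c(tr$j, tr$i),
                            x = as.numeric(c(tr$count, tr$count)),
                            dims = c(N, N))
  structure(list(n = n, residues = model$residues, cutoff = cutoff,
                 diagonal = "zero",
                 atoms_per_residue = tabulate(a$res_index, nbins = N)),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  nz <- Matrix::nnzero(x$n)
  cat("contact_network:", nrow(x$residues), "residues, cutoff",
      x$cutoff, "A\n")
  cat(" ", nz / 2, "contacting residue pairs,",
      sum(x$n@x) / 2, "atom-atom contacts; diagonal:", x$diagonal, "\n")
  invisible(x)
}

#' Build the Markov transmission model from a contact network
#'
#' Row-normalizes the contact counts into the transition matrix
#' `m_ij = n_ij / sum_k n_ik`: the probability that a signal at residue i is
#' passed to residue j in one step. Also derives the rate matrix `R = M - I`
#' of the master equation and the cost matrix `cost_ij = 1 / m_ij` (finite
#' only where `m_ij > 0`) used for highest-probability path search.
#'
#' Although `n` is symmetric, row sums differ between residues, so `M` is
#' generally asymmetric and the path graph is directed.
#'
#' @param net a `contact_network`.
#' @param diagonal_mode `"zero"` (default; no self-transitions, pure
#'   inter-residue transmission) or `"self_atoms"` (`n_ii` set to the heavy
#'   atom count of residue i; rescales time, leaves shortest paths unchanged
#'   since self-loops never shorten a simple path).
#' @return a `transition_model`: list with sparse `M`, `R`, `cost`
#'   (`Matrix` classes), `n` (counts actually normalized, diagonal included),
#'   `residues`, `cutoff`, `diagonal_mode`.
#' @export
build_transition_model <- function(net, diagonal_mode = c("zero", "self_atoms")) {
  stopifnot(inherits(net, "contact_network"))
  diagonal_mode <- match.arg(diagonal_mode)
  n <- net$n
  if (diagonal_mode == "self_atoms")
    Matrix::diag(n) <- as.numeric(net$atoms_per_residue)
  deg <- Matrix::rowSums(n)
  if (any(deg == 0)) {
    bad <- net$residues$key[deg == 0]
    stop("isolated residue(s) with no contacts under diagonal_mode='",
         diagonal_mode, "': ", paste(bad, collapse = ", "),
         " (consider a larger cutoff or diagonal_mode='self_atoms')")
  }
  M <- Matrix::Diagonal(x = 1 / deg) %*% n
  M <- as(M, "generalMatrix")
  R <- M - Matrix::Diagonal(nrow(M))
  cost <- M
  cost@x <- 1 / cost@x
  structure(list(M = M, R = R, cost = cost, n = n, residues = net$residues,
                 cutoff = net$cutoff, diagonal_mode = diagonal_mode),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("transition_model:", nrow(x$residues), "residues (diagonal:",
      x$diagonal_mode, ")\n")
  invisible(x)
}

#' Connected components of the contact graph
#'
#' Labels the connected components of the undirected graph with an edge
#' wherever `n_ij > 0`, and reports whether a given residue selection falls
#' inside the largest component. Path queries require source and target in
#' one component.
#'
#' @param tm a `transition_model` or `contact_network`.
#' @param check_keys optional character vector of residue keys to verify.
#' @return list with `component` (integer label per residue, 1 = largest),
#'   `n_components`, and `all_in_largest` (`NA` when `check_keys` is `NULL`).
#' @export
connectivity_report <- function(tm, check_keys = NULL) {
  n <- tm$n
  N <- nrow(n)
  adj <- as(n, "TsparseMatrix")
  # union-find over edges
  parent <- seq_len(N)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ii <- adj@i + 1L; jj <- adj@j + 1L
  keep <- adj@x > 0 & ii < jj
  for (e in which(keep)) {
    a <- find(ii[e]); b <- find(jj[e])
    if (a != b) parent[a] <- b
  }
  root <- vapply(seq_len(N), find, integer(1))
  sizes <- table(root)
  lab <- match(root, names(sort(sizes, decreasing = TRUE)))
  all_in <- NA
  if (!is.null(check_keys)) {
    idx <- resolve_residues(tm, check_keys)
    all_in <- all(lab[idx] == 1L)
  }
  list(component = lab, n_components = length(sizes), all_in_largest = all_in)
}

#' Export a sparse network matrix as triplet text
#'
#' Writes `(row_key, col_key, value)` rows for the nonzero entries of one of
#' the model matrices, a plain-text interchange format for downstream tools.
#' @param tm a `transition_model` or `contact_network`.
#' @param path output TSV path.
#' @param which one of `"n"`, `"M"`, `"cost"` (for a `contact_network`, only
#'   `"n"`).
#' @return `path`, invisibly.
#' @export
export_network <- function(tm, path, which = c("n", "M", "cost")) {
  which <- match.arg(which)
  m <- tm[[which]]
  if (is.null(m)) stop("matrix '", which, "' not available in this object")
  t3 <- as(as(m, "TsparseMatrix"), "generalMatrix")
  df <- data.frame(from = tm$residues$key[t3@i + 1L],
                   to = tm$residues$key[t3@j + 1L],
                   value = t3@x)
  df <- df[order(t3@i, t3@j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
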