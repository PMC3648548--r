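#' Read a multi-chain structure from a PDB file
#'
#' Loads heavy-atom coordinates from a PDB file into a `structure_model`:
#' an atom table plus a residue index table whose order defines the row/column
#' ordering of every matrix downstream. The loading contract is fixed so that
#' the contact network is reproducible from the same input bytes:
#'
#' * only the first `MODEL` of a multi-model file is used;
#' * hydrogens (and deuteriums) are removed — the transmission network is
#'   computed from the heavy-atom structure;
#' * for alternate-location duplicates of an atom, the highest-occupancy
#'   conformer is kept (ties broken by alphabetical altloc code);
#' * waters are always excluded; other `HETATM` groups (detergents, lipids,
#'   ions, buffer molecules) are excluded unless `include_hetero = TRUE`;
#' * residues are indexed contiguously `1..N`, ordered by
#'   (chain, residue number, insertion code), chains in file order.
#'
#' @param path path to a PDB-format file.
#' @param chains optional character vector of chain identifiers to keep.
#'   Unknown chain labels are an error.
#' @param include_hetero keep non-water `HETATM` residues as network nodes
#'   (default `FALSE`: the network is over protein residues).
#' @return an object of class `structure_model`: a list with elements
#'   `atoms` (data.frame: `chain`, `resno`, `insert`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`, `o`, `res_index`), `residues` (data.frame:
#'   `chain`, `resno`, `insert`, `resid`, `index`, `key`), `chains`
#'   (character), and `source_id`.
#' @seealso [write_structure()], [count_contacts()], [superpose_rmsd()]
#' @export
read_structure <- function(path, chains = NULL, include_hetero = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  build_structure_model(pdb$atom, chains = chains,
                        include_hetero = include_hetero,
                        source_id = basename(path))
}

# Shared constructor from a bio3d-style atom data.frame.
build_structure_model <- function(atom, chains = NULL, include_hetero = FALSE,
                                  source_id = "") {
  atom$chain[is.na(atom$chain)] <- " "
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  if (is.null(atom$elesy) || all(is.na(atom$elesy)) || all(atom$elesy == "")) {
    atom$elesy <- guess_element(atom$elety)
  } else {
    miss <- is.na(atom$elesy) | atom$elesy == ""
    atom$elesy[miss] <- guess_element(atom$elety[miss])
  }
  atom$elesy <- toupper(trimws(atom$elesy))

  # heavy atoms only
  atom <- atom[!(atom$elesy %in% c("H", "D")), , drop = FALSE]
  # waters never participate
  atom <- atom[!(atom$resid %in% c("HOH", "WAT", "DOD", "H2O")), , drop = FALSE]
  if (!include_hetero) atom <- atom[atom$type == "ATOM", , drop = FALSE]

  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(atom$chain))
    if (length(missing) > 0)
      stop("chain(s) not present in structure: ",
           paste(missing, collapse = ", "))
    atom <- atom[atom$chain %in% chains, , drop = FALSE]
  }
  if (nrow(atom) == 0) stop("empty structure: no heavy atoms after filtering")

  # altloc resolution: one conformer per (residue, atom name), highest
  # occupancy, ties by alphabetical altloc code
  atom$o[is.na(atom$o)] <- 1
  akey <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(akey, -atom$o, atom$alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(akey[ord]), , drop = FALSE]

  chain_order <- unique(atom$chain)
  atom <- atom[order(match(atom$chain, chain_order), atom$resno, atom$insert,
                     atom$eleno), , drop = FALSE]

  rkey <- paste(atom$chain, atom$resno, atom$insert, sep = "\r")
  residues <- atom[!duplicated(rkey), c("chain", "resno", "insert", "resid")]
  rownames(residues) <- NULL
  residues$index <- seq_len(nrow(residues))
  residues$key <- residue_key(residues$chain, residues$resno, residues$insert)
  atom$res_index <- match(rkey, rkey[!duplicated(rkey)])

  atoms <- atom[, c("chain", "resno", "insert", "resid", "elety", "elesy",
                    "x", "y", "z", "o", "res_index")]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, residues = residues, chains = chain_order,
                 source_id = source_id),
            class = "structure_model")
}

# Element from PDB atom name when the element column is absent; digits and
# primes are stripped, a leading H/D after a digit (e.g. "1HB") is hydrogen.
guess_element <- function(elety) {
  nm <- toupper(trimws(elety))
  nm <- sub("^[0-9]+", "", nm)
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "CU", "SE")
  # side-chain names like "CA","CB" are carbon; only match 2-letter elements
  # for HETATM-style names that are not standard protein atoms
  el[two %in% known2 & !(nm %in% c("CA", "CB", "CD", "CE", "CG", "CZ",
                                   "ND", "NE", "NH", "NZ", "SD", "SE",
                                   "CD1", "CD2", "CE1", "CE2", "CE3",
                                   "CG1", "CG2", "CZ2", "CZ3"))] <-
    two[two %in% known2 & !(nm %in% c("CA", "CB", "CD", "CE", "CG", "CZ",
                                      "ND", "NE", "NH", "NZ", "SD", "SE",
                                      "CD1", "CD2", "CE1", "CE2", "CE3",
                                      "CG1", "CG2", "CZ2", "CZ3"))]
  el
}

#' Canonical residue key string
#'
#' `chain:resno` with the insertion code appended when present, e.g. `"B:91"`
#' or `"A:100A"`. Used to address residues in perturbation sets, path queries
#' and region definitions.
#' @param chain,resno,insert vectors of chain id, residue number, insertion
#'   code (recycled).
#' @return character vector of keys.
#' @export
residue_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, insert)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", x$source_id, "\n")
  cat(" ", length(x$chains), "chain(s):", paste(x$chains, collapse = " "), "\n")
  cat(" ", nrow(x$residues), "residues,", nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Number of residues in a structure or network object
#' @param x a `structure_model`, `contact_network` or `transition_model`.
#' @return integer residue count.
#' @export
n_residues <- function(x) {
  if (inherits(x, "structure_model")) return(nrow(x$residues))
  if (!is.null(x$residues)) return(nrow(x$residues))
  stop("no residue table in object")
}

#' Resolve residue selections to matrix indices
#'
#' Accepts keys of the form `"B:91"` (see [residue_key()]) and returns the
#' dense matrix indices, erroring with the full list of unknown keys.
#' @param x object with a residue table.
#' @param keys character vector of residue keys.
#' @return integer vector of indices into the residue ordering.
#' @export
resolve_residues <- function(x, keys) {
  tab <- if (inherits(x, "structure_model")) x$residues else x$residues
  idx <- match(keys, tab$key)
  if (anyNA(idx))
    stop("unknown residue key(s): ", paste(keys[is.na(idx)], collapse = ", "))
  tab$index[idx]
}

#' Write a structure model to a PDB file
#'
#' Emits fixed-column PDB `ATOM` records (plus optional `REMARK` header
#' lines); coordinates round-trip through [read_structure()] to the format's
#' 1e-3 Angstrom precision.
#' @param model a `structure_model`.
#' @param path output file path.
#' @param remarks optional character vector written as `REMARK` records.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, remarks = NULL) {
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    formatC(ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
            width = -4),
    a$resid, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, a$o, 0,
    formatC(a$elesy, width = 2)
  )
  hdr <- if (is.null(remarks)) character(0) else sprintf("REMARK 250 %s", remarks)
  writeLines(c(hdr, lines, "END"), path)
  invisible(path)
}

#' RMSD after optimal rigid-body superposition
#'
#' Pairs residues of two structures by chain and residue number (insertion
#' code included), selects the named atoms, performs least-squares rigid-body
#' superposition (Kabsch) and returns the root-mean-square deviation of the
#' fitted coordinates in Angstroms. Residue pairs whose residue names differ
#' are dropped unless `allow_mutations = TRUE` (point mutants such as D91N
#' keep their backbone comparable).
#'
#' @param model_a,model_b `structure_model` objects.
#' @param atom_names atoms used for the fit (default `"CA"`, the conventional
#'   backbone trace).
#' @param allow_mutations pair residues whose names differ (default `FALSE`).
#' @return RMSD in Angstroms (numeric scalar).
#' @export
superpose_rmsd <- function(model_a, model_b, atom_names = "CA",
                           allow_mutations = FALSE) {
  sel_a <- model_a$atoms[model_a$atoms$elety %in% atom_names, , drop = FALSE]
  sel_b <- model_b$atoms[model_b$atoms$elety %in% atom_names, , drop = FALSE]
  ka <- paste(sel_a$chain, sel_a$resno, sel_a$insert, sel_a$elety, sep = "\r")
  kb <- paste(sel_b$chain, sel_b$resno, sel_b$insert, sel_b$elety, sep = "\r")
  common <- intersect(ka, kb)
  ia <- match(common, ka); ib <- match(common, kb)
  if (!allow_mutations) {
    same <- sel_a$resid[ia] == sel_b$resid[ib]
    ia <- ia[same]; ib <- ib[same]
  }
  if (length(ia) < 3)
    stop("insufficient paired atoms for superposition (need >= 3, got ",
         length(ia), ")")
  xa <- as.matrix(sel_a[ia, c("x", "y", "z")])
  xb <- as.matrix(sel_b[ib, c("x", "y", "z")])
  kabsch_rmsd(xa, xb)
}

# Kabsch least-squares superposition of paired coordinate sets (rows).
kabsch_rmsd <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  a <- sweep(xa, 2, ca); b <- sweep(xb, 2, cb)
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- b %*% rot
  sqrt(mean(rowSums((fit - a)^2)))
}
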