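#' Uniform initial perturbation over a residue set
#'
#' Builds the initial probability vector p(0): equal mass `1/|set|` on every
#' perturbed residue, zero elsewhere — the standard way a binding event or a
#' cluster of mutations is injected into the transmission network.
#'
#' @param tm a `transition_model`.
#' @param keys non-empty character vector of residue keys (see
#'   [residue_key()]).
#' @return a `perturbation`: list with `p0` (length-N numeric, sums to 1),
#'   `perturbed` (keys), `index` (matrix indices).
#' @export
uniform_perturbation <- function(tm, keys) {
  if (length(keys) == 0) stop("perturbation set must be non-empty")
  idx <- resolve_residues(tm, keys)
  p0 <- numeric(nrow(tm$residues))
  p0[idx] <- 1 / length(idx)
  structure(list(p0 = p0, perturbed = keys, index = idx),
            class = "perturbation")
}

#' Default model-time grid
#'
#' `t = 0` followed by `n` log-spaced points between `tmin` and `tmax`
#' (arbitrary model-time units — one unit is one expected Markov step).
#' @param tmin,tmax grid range (defaults 1e-3, 1e3).
#' @param n number of log-spaced points (default 200).
#' @return increasing numeric vector starting at 0.
#' @export
time_grid <- function(tmin = 1e-3, tmax = 1e3, n = 200) {
  c(0, 10^seq(log10(tmin), log10(tmax), length.out = n))
}

# Spectral decomposition of R = M - I. Because M = D^{-1} n with n symmetric,
# M is similar to the symmetric S = D^{-1/2} n D^{-1/2}; one symmetric
# eigendecomposition gives the exact action of exp(tR) at any t.
transition_spectrum <- function(tm) {
  deg <- Matrix::rowSums(tm$n)
  s <- sqrt(deg)
  S <- Matrix::Diagonal(x = 1 / s) %*% tm$n %*% Matrix::Diagonal(x = 1 / s)
  e <- eigen(as.matrix(Matrix::forceSymmetric(S)), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, s = s)
}

#' Propagate a perturbation through the master equation
#'
#' Solves `dp/dt = p R`, `R = M - I`, with `p(0)` from the perturbation, and
#' returns per-residue probabilities and probability fluxes on the time grid.
#' The flux `f(t) = p(t) R` is the net probability flow into (positive) or
#' out of (negative) each residue. `normalized_F` rescales the flux by its
#' global maximum absolute value to `[-1, 1]`, the single color scale used in
#' flux heat maps.
#'
#' The propagator is spectral: `M` is similar to a symmetric matrix via the
#' degree weighting, so one symmetric eigendecomposition yields the exact
#' matrix-exponential action at every grid time (it agrees with a dense
#' `expm` evaluation to full precision; see the package tests).
#'
#' @param tm a `transition_model`.
#' @param pert a `perturbation`, or a bare probability vector of length N.
#' @param times increasing time grid with `times[1] >= 0`
#'   (default [time_grid()]).
#' @return a `flux_trajectory`: list with `times`, `P` (N x T probabilities),
#'   `F` (N x T fluxes), `normalized_F`, `residues`, `perturbed`.
#' @export
propagate <- function(tm, pert, times = time_grid()) {
  stopifnot(inherits(tm, "transition_model"))
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("time grid must be strictly increasing and start at t >= 0")
  if (inherits(pert, "perturbation")) {
    p0 <- pert$p0
    perturbed <- pert$perturbed
  } else {
    p0 <- as.numeric(pert)
    perturbed <- tm$residues$key[p0 > 0]
  }
  N <- nrow(tm$residues)
  if (length(p0) != N) stop("p0 has length ", length(p0), ", expected ", N)
  if (abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
    stop("p0 must be a probability vector")

  sp <- transition_spectrum(tm)
  # p(t) = p0 D^{-1/2} V exp(t(L-1)) V' D^{1/2}
  a <- drop(crossprod(sp$vectors, p0 / sp$s))            # length N
  expt <- exp(outer(sp$values - 1, times))               # N x T
  P <- (sp$vectors %*% (a * expt)) * sp$s                # N x T
  P <- as.matrix(P)
  Fm <- as.matrix(Matrix::crossprod(tm$R, P))            # f(t) = p(t) R
  fmax <- max(abs(Fm))
  structure(list(times = times, P = P, F = Fm,
                 normalized_F = if (fmax > 0) Fm / fmax else Fm,
                 residues = tm$residues, perturbed = perturbed),
            class = "flux_trajectory")
}

#' @export
print.flux_trajectory <- function(x, ...) {
  cat("flux_trajectory:", nrow(x$P), "residues x", length(x$times),
      "times; perturbed:", paste(x$perturbed, collapse = " "), "\n")
  invisible(x)
}

#' Time of maximal probability flux per residue
#'
#' For each residue, the grid time at which its flux peaks — the model's
#' arrival time of the perturbation signal. By convention the signed flux is
#' maximized (net inflow peak, matching the sign convention of the flux heat
#' maps); for initially perturbed residues, whose flux is negative
#' throughout, the signed maximum sits where outflow is weakest. Set
#' `signed = FALSE` to use the peak of |f| instead. Ties take the earliest
#' time.
#'
#' @param traj a `flux_trajectory`.
#' @param signed maximize signed flux (default) or absolute flux.
#' @return data.frame with `key`, `chain`, `resno`, `max_flux_time`,
#'   `max_flux`.
#' @export
max_flux_time <- function(traj, signed = TRUE) {
  m <- if (signed) traj$F else abs(traj$F)
  pick <- apply(m, 1, which.max)  # which.max returns the first (earliest) tie
  data.frame(key = traj$residues$key,
             chain = traj$residues$chain,
             resno = traj$residues$resno,
             max_flux_time = traj$times[pick],
             max_flux = traj$F[cbind(seq_len(nrow(m)), pick)])
}

#' Equilibrium distribution of the transmission network
#'
#' The stationary distribution `pi` with `pi M = pi`. Because `M` is the
#' row-normalization of a symmetric contact-count matrix, the chain is
#' reversible and the stationary mass of a residue is its contact degree:
#' `pi_i = sum_j n_ij / sum_ij n_ij`. Where the perturbation ends up at
#' `t = infinity` therefore depends only on the network, not on where the
#' signal started.
#'
#' @param tm a `transition_model`.
#' @return length-N probability vector.
#' @export
equilibrium_distribution <- function(tm) {
  rep_ <- connectivity_report(tm)
  if (rep_$n_components > 1)
    stop("contact graph has ", rep_$n_components,
         " components; equilibrium is not unique")
  deg <- Matrix::rowSums(tm$n)
  deg / sum(deg)
}

#' Export a flux trajectory as long-format CSV
#'
#' One row per (residue, time): `key`, `chain`, `resno`, `time`, `p`, `flux`,
#' `normalized_flux`.
#' @param traj a `flux_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  nT <- length(traj$times)
  N <- nrow(traj$P)
  df <- data.frame(
    key = rep(traj$residues$key, times = nT),
    chain = rep(traj$residues$chain, times = nT),
    resno = rep(traj$residues$resno, times = nT),
    time = rep(traj$times, each = N),
    p = as.vector(traj$P),
    flux = as.vector(traj$F),
    normalized_flux = as.vector(traj$normalized_F))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flux heat map of a trajectory
#'
#' Residue-by-time map of the normalized probability flux: x = model time
#' (log scale), y = residue index grouped by chain, diverging palette
#' centered at zero (red = net inflow, blue = net outflow). Requires ggplot2.
#' @param traj a `flux_trajectory`.
#' @return a ggplot object.
#' @export
plot_flux_heatmap <- function(traj) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_flux_heatmap requires ggplot2")
  nT <- length(traj$times)
  N <- nrow(traj$P)
  keep <- traj$times > 0
  df <- data.frame(
    time = rep(traj$times, each = N),
    residue = rep(seq_len(N), times = nT),
    chain = rep(traj$residues$chain, times = nT),
    flux = as.vector(traj$normalized_F))
  df <- df[rep(keep, each = N), ]
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = residue, fill = flux)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::facet_grid(chain ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "model time (arbitrary units)", y = "residue",
                  fill = "normalized\nflux")
}
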