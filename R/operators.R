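# Product-operator machinery for density-matrix simulation.
#
# All operators live on the 2^n-dimensional Hilbert space of n spin-1/2 nuclei,
# built as Kronecker products of single-spin operators. Hamiltonians are
# returned in angular-frequency units (rad/s) so that the propagator over an
# interval t seconds is expm(-1i * H * t).

.op_cache <- new.env(parent = emptyenv())

single_spin_ops <- function() {
  list(
    ix = matrix(c(0, 0.5, 0.5, 0), 2, 2),
    iy = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
    iz = matrix(c(0.5, 0, 0, -0.5), 2, 2),
    id = diag(2)
  )
}

#' Spin operators for an n-proton system
#'
#' Returns the single-spin Cartesian operators embedded in the full product
#' space, the totals Fx/Fy/Fz, the raising operator F+ and the vector of total
#' z quantum numbers of the computational basis states (used for
#' coherence-order bookkeeping).
#'
#' @param n Number of spin-1/2 nuclei (capped at 8 for tractability).
#' @return List with elements `Ix`, `Iy`, `Iz` (lists of length n), `Fx`, `Fy`,
#'   `Fz`, `Fp`, `m` and `dim`.
#' @export
spin_operators <- function(n) {
  stopifnot(n >= 1)
  if (n > 8) stop("spin systems with more than 8 protons are not supported")
  key <- as.character(n)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  ss <- single_spin_ops()
  dim <- 2^n
  embed <- function(op, k) {
    m <- matrix(1 + 0i, 1, 1)
    for (j in seq_len(n)) {
      m <- kronecker(m, if (j == k) op else ss$id)
    }
    m
  }
  Ix <- lapply(seq_len(n), function(k) embed(ss$ix, k))
  Iy <- lapply(seq_len(n), function(k) embed(ss$iy, k))
  Iz <- lapply(seq_len(n), function(k) embed(ss$iz, k))
  Fx <- Reduce(`+`, Ix); Fy <- Reduce(`+`, Iy); Fz <- Reduce(`+`, Iz)
  ops <- list(
    Ix = Ix, Iy = Iy, Iz = Iz, Fx = Fx, Fy = Fy, Fz = Fz,
    Fp = Fx + 1i * Fy,
    m = Re(diag(Fz)),
    dim = dim
  )
  .op_cache[[key]] <- ops
  ops
}

#' Free-evolution Hamiltonian of a spin system
#'
#' Builds the standard high-resolution liquid-state Hamiltonian in the rotating
#' frame of the receiver centre: Zeeman offset terms plus the full isotropic
#' scalar-coupling terms \eqn{2\pi J_{ij} (I_i \cdot I_j)}. The strong-coupling
#' (I.I) form is used throughout because myo-inositol at 3 T is strongly
#' coupled and the echo-time behaviour of its multiplet depends on it.
#'
#' @param system A [spin_system()].
#' @param ctx A [spectrometer_context()].
#' @return Hermitian complex matrix of dimension `2^n_protons`, rad/s.
#' @export
#' @examples
#' ctx <- spectrometer_context()
#' gly <- spin_system("Gly", c(3.548, 3.548))
#' H <- build_hamiltonian(gly, ctx)
#' max(Mod(H - Conj(t(H))))  # Hermitian
build_hamiltonian <- function(system, ctx) {
  stopifnot(inherits(system, "spin_system"), inherits(ctx, "spectrometer_context"))
  n <- system$n_protons
  ops <- spin_operators(n)
  H <- matrix(0i, ops$dim, ops$dim)
  offs <- ppm_to_offset_hz(system$shifts, ctx)
  for (k in seq_len(n)) {
    H <- H + 2 * pi * offs[k] * ops$Iz[[k]]
  }
  J <- system$couplings
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && J[i, j] != 0) {
        H <- H + 2 * pi * J[i, j] *
          (ops$Ix[[i]] %*% ops$Ix[[j]] +
           ops$Iy[[i]] %*% ops$Iy[[j]] +
           ops$Iz[[i]] %*% ops$Iz[[j]])
      }
    }
  }
  H
}

# Eigendecomposition of a Hermitian matrix: values real ascending, vectors
# unitary. Used for delay propagators and fast acquisition.
herm_eigen <- function(H) {
  e <- eigen(H, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

# Unitary propagator exp(-1i * H * t) for Hermitian H (t in seconds).
propagator <- function(H, t, eig = NULL) {
  if (is.null(eig)) eig <- herm_eigen(H)
  V <- eig$vectors
  ph <- exp(-1i * eig$values * t)
  V %*% (ph * Conj(t(V)))
}

# Conjugate a density matrix by a unitary: U rho U^H.
conj_by <- function(U, rho) U %*% rho %*% Conj(t(U))

# Keep only the elements of rho with total coherence order p
# (p = m_row - m_col). This is the infinite-crusher limit of the gradient
# scheme that selects the doubly-refocused pathway in PRESS.
project_coherence <- function(rho, m, p) {
  keep <- outer(m, m, `-`) == p
  rho * keep
}

# Free evolution of rho for t seconds under the eigendecomposed Hamiltonian:
# phases applied directly in the eigenbasis would require a basis change per
# call; for the moderate dimensions used here a dense propagator is fine.
evolve <- function(rho, eig, t) {
  if (t == 0) return(rho)
  V <- eig$vectors
  ph <- exp(-1i * eig$values * t)
  # V diag(ph) V^H rho V diag(conj(ph)) V^H
  rho_e <- Conj(t(V)) %*% rho %*% V
  rho_e <- (ph %o% Conj(ph)) * rho_e
  V %*% rho_e %*% Conj(t(V))
}
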