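# Spin-1/2 product operators on the 2^N Hilbert space.
# Dense complex matrices; systems here are small (<= 9 spins).

spin_half_ops <- function() {
  list(
    x = matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i,
    y = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
    z = matrix(c(0.5, 0, 0, -0.5), 2, 2) + 0i,
    e = diag(2) + 0i
  )
}

#' Single-spin operator embedded in an N-spin space
#'
#' @param n number of spins.
#' @param k index of the spin the operator acts on (1-based).
#' @param op one of `"x"`, `"y"`, `"z"`.
#' @return A `2^n x 2^n` complex matrix.
#' @keywords internal
single_spin_op <- function(n, k, op) {
  s <- spin_half_ops()
  out <- matrix(1 + 0i, 1, 1)
  for (j in seq_len(n)) {
    out <- kronecker(out, if (j == k) s[[op]] else s$e)
  }
  out
}

# Sum of single-spin operators over a subset of spins.
total_spin_op <- function(n, which_spins, op) {
  out <- matrix(0i, 2^n, 2^n)
  for (k in which_spins) out <- out + single_spin_op(n, k, op)
  out
}

# Secular homonuclear dipolar pair operator: 3IzIz - I.I = 2IzIz - IxIx - IyIy.
homonuclear_pair_op <- function(n, i, j) {
  2 * single_spin_op(n, i, "z") %*% single_spin_op(n, j, "z") -
    single_spin_op(n, i, "x") %*% single_spin_op(n, j, "x") -
    single_spin_op(n, i, "y") %*% single_spin_op(n, j, "y")
}

# Truncated heteronuclear pair operator: 2IzSz.
heteronuclear_pair_op <- function(n, i, j) {
  2 * single_spin_op(n, i, "z") %*% single_spin_op(n, j, "z")
}

# Ideal rotation pulse exp(-i * angle * sum_k I_k,phase) on selected spins.
pulse_operator <- function(n, which_spins, angle, phase = "x") {
  gen <- total_spin_op(n, which_spins, phase)
  ed <- eigen(gen, symmetric = TRUE)
  ed$vectors %*% diag(exp(-1i * angle * ed$values)) %*% Conj(t(ed$vectors))
}
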