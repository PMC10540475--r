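# Independent oracles used by the tests. Deliberately naive: straight
# loops and textbook formulas, sharing no code with the package internals
# they check.

# Voxel-face estimate of isosurface area: count faces separating inside
# from outside voxels and weight by face area. The staircase surface of a
# smooth shape overestimates its area by a factor 3/2 on average (the mean
# of |n_x| + |n_y| + |n_z| over an isotropic distribution of unit normals),
# so the standard stereological 2/3 correction is applied.
voxel_face_area <- function(grid, isovalue) {
  v <- grid$values
  d <- dim(v)
  sp <- sqrt(rowSums(grid$axes^2))
  inside <- v > isovalue
  faces <- 0
  faces <- faces + sum(inside[-d[1], , ] != inside[-1, , ]) * sp[2] * sp[3]
  faces <- faces + sum(inside[, -d[2], ] != inside[, -1, ]) * sp[1] * sp[3]
  faces <- faces + sum(inside[, , -d[3]] != inside[, , -1]) * sp[1] * sp[2]
  faces * 2 / 3
}

# Brute-force atomic ALIE: explicit double loop over voxels and orbitals,
# nearest-nucleus assignment, total-density weighting. Only for tiny grids.
alie_on_atom_oracle <- function(ods, atom_index) {
  ref <- ods$orbitals[[1]]$density
  d <- dim(ref$values)
  atoms <- ods$atoms
  num_w <- 0
  den_w <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- ref$origin +
      (i - 1) * ref$axes[1, ] + (j - 1) * ref$axes[2, ] +
      (k - 1) * ref$axes[3, ]
    num <- 0; den <- 0
    for (o in ods$orbitals) {
      w <- o$occupation * o$density$values[i, j, k]
      num <- num + w * abs(o$energy)
      den <- den + w
    }
    if (den < 1e-12) next
    d2 <- (p[1] - atoms$x)^2 + (p[2] - atoms$y)^2 + (p[3] - atoms$z)^2
    if (which.min(d2) != atom_index) next
    num_w <- num_w + den * (num / den)
    den_w <- den_w + den
  }
  (num_w / den_w) * 27.211386245988
}

# Textbook normal-equations OLS.
ols_oracle <- function(X, y) {
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# Naive leave-one-out Q2: n refits, each omitting one observation.
loo_q2_naive <- function(x, y) {
  X <- cbind(1, as.matrix(as.data.frame(x)))
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    b <- solve(t(X[-i, ]) %*% X[-i, ], t(X[-i, ]) %*% y[-i])
    press <- press + (y[i] - sum(X[i, ] * b))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Zero-descriptor row for published-model evaluation.
zero_descriptors <- function(base_t = 0) {
  data.frame(delta_e = 0, delta_hl_gap = 0, chi_m = 0, npsa_percent = 0,
             delta_alie_n = 0, base_t = base_t)
}
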