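# independent single-axis rotation oracles (brute-force product reference)
oracle_Rx <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
}
oracle_Ry <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
}
oracle_Rz <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}
oracle_rotation <- function(angles) {
  oracle_Rx(angles[1]) %*% oracle_Ry(angles[2]) %*% oracle_Rz(angles[3])
}

# quiet phantom pair (no noise, no bias) for geometric checks
clean_phantom <- function(shape = c(64L, 64L, 64L)) {
  generate_skull_phantom(phantom_config(shape = shape,
                                        noise_sd = c(0, 0),
                                        bias_field_amplitude = 0))
}

# a small smooth volume for interpolation checks
smooth_volume <- function(n = 32L, spacing = 2.5) {
  g <- seq(0, 4 * pi, length.out = n)
  d <- outer(outer(sin(g), cos(g / 2)), sin(g / 3)) * 100 + 200
  volume3d(d, spacing = rep(spacing, 3),
           origin = rep(-(n - 1) / 2 * spacing, 3))
}
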