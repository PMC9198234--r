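# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_femurfe <- function(msg, class) {
  rlang::abort(msg, class = c(class, "femurfe_error"))
}

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_femurfe(sprintf("`%s` must be a finite numeric scalar.", name),
                  "femurfe_parameter_error")
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort_femurfe(sprintf("`%s` must be %s %s.", name,
                          if (strict) ">" else ">=", format(lower)),
                  "femurfe_parameter_error")
  }
  invisible(x)
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels, zero-padded
# boundary). Used for phantom texture fields and optional pre-smoothing of
# binary masks before isosurfacing.
gaussian_smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    # move `axis` to the first dimension, convolve columns, move back
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    mm <- matrix(m, nrow = dm[1])
    n <- dm[1]
    out <- matrix(0, n, ncol(mm))
    for (j in seq(-r, r)) {
      w <- k[j + r + 1L]
      src <- seq_len(n) - j
      keep <- src >= 1L & src <= n
      out[keep, ] <- out[keep, ] + w * mm[src[keep], ]
    }
    dim(out) <- dm
    aperm(out, order(perm))
  }
  for (axis in 1:3) arr <- conv_axis(arr, axis)
  arr
}

# Rotation matrix taking unit vector `a` onto unit vector `b` (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-24) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * ref[3] - a[3] * ref[2],
           a[3] * ref[1] - a[1] * ref[3],
           a[1] * ref[2] - a[2] * ref[1])
    v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

# World coordinates of voxel centers along one axis (1-based indices).
axis_coords <- function(n, origin, spacing) origin + (seq_len(n) - 1) * spacing
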