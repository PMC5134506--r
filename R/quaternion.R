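# Quaternion helpers. Convention throughout: q = (w, x, y, z), unit norm,
# representing the device->world rotation; R(q) %*% v_device = v_world.

quat_normalize <- function(q) {
  if (is.matrix(q)) q / sqrt(rowSums(q^2)) else q / sqrt(sum(q^2))
}

quat_conjugate <- function(q) {
  if (is.matrix(q)) cbind(q[, 1L], -q[, 2L], -q[, 3L], -q[, 4L])
  else c(q[1L], -q[2L], -q[3L], -q[4L])
}

# Hamilton product, vectorized over rows when given matrices.
quat_multiply <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, 1L)
  if (!is.matrix(b)) b <- matrix(b, 1L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[, 1L] * b[, 1L] - a[, 2L] * b[, 2L] - a[, 3L] * b[, 3L] - a[, 4L] * b[, 4L]
  x <- a[, 1L] * b[, 2L] + a[, 2L] * b[, 1L] + a[, 3L] * b[, 4L] - a[, 4L] * b[, 3L]
  y <- a[, 1L] * b[, 3L] - a[, 2L] * b[, 4L] + a[, 3L] * b[, 1L] + a[, 4L] * b[, 2L]
  z <- a[, 1L] * b[, 4L] + a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L] + a[, 4L] * b[, 1L]
  out <- cbind(w, x, y, z)
  colnames(out) <- NULL
  if (nrow(out) == 1L) drop(out) else out
}

quat_from_axis_angle <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle_rad / 2), axis * sin(angle_rad / 2))
}

# Rotate device-frame vector(s) into the world frame.
# R(q) v = v + 2 w (r x v) + 2 r x (r x v), with r = (x, y, z).
quat_rotate <- function(q, v) {
  single <- !is.matrix(q)
  if (single) q <- matrix(q, 1L)
  if (!is.matrix(v)) v <- matrix(v, nrow(q), 3L, byrow = TRUE)
  w <- q[, 1L]; r <- q[, 2:4, drop = FALSE]
  cx <- r[, 2L] * v[, 3L] - r[, 3L] * v[, 2L]
  cy <- r[, 3L] * v[, 1L] - r[, 1L] * v[, 3L]
  cz <- r[, 1L] * v[, 2L] - r[, 2L] * v[, 1L]
  c2x <- r[, 2L] * cz - r[, 3L] * cy
  c2y <- r[, 3L] * cx - r[, 1L] * cz
  c2z <- r[, 1L] * cy - r[, 2L] * cx
  out <- cbind(v[, 1L] + 2 * (w * cx + c2x),
               v[, 2L] + 2 * (w * cy + c2y),
               v[, 3L] + 2 * (w * cz + c2z))
  colnames(out) <- NULL
  if (single) drop(out) else out
}

quat_to_dcm <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    w * w + x * x - y * y - z * z, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w * w - x * x + y * y - z * z, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w * w - x * x - y * y + z * z
  ), 3L, 3L, byrow = TRUE)
}

# Shepperd's method; returns q with non-negative scalar part.
dcm_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1L] < 0) q <- -q
  quat_normalize(q)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}
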