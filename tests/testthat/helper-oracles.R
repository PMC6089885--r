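# Independent oracles and fixture helpers shared across the suite.
# Everything here is deliberately naive (loops, enumeration) so it cannot
# share defects with the vectorised implementations it checks.

# random proper rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  M <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(M) < 0) M[, 1] <- -M[, 1]
  M
}

# apply a rigid transform x -> x R + t to every frame of a trajectory_view
rigid_transform_traj <- function(tv, R, t) {
  xyz <- tv$xyz
  for (f in seq_len(nrow(xyz))) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) %*% R
    co <- sweep(co, 2, t, `+`)
    xyz[f, ] <- as.vector(t(co))
  }
  trajectory_view(tv$atoms, xyz, tv$times)
}

# transform a channel geometry with the same rigid map
rigid_transform_geom <- function(geom, R, t) {
  channel_geometry(axis = as.vector(geom$axis %*% R),
                   origin = as.vector(geom$origin %*% R) + t,
                   z_lower = geom$z_lower, z_upper = geom$z_upper,
                   lateral_cutoff = geom$lateral_cutoff,
                   pore_length = geom$pore_length)
}

# frame-by-frame state classification straight from coordinates
brute_states <- function(tv, geom) {
  nf <- nrow(tv$xyz); na <- nrow(tv$atoms)
  out <- matrix("", nf, na)
  for (f in seq_len(nf)) {
    co <- matrix(tv$xyz[f, ], ncol = 3, byrow = TRUE)
    for (j in seq_len(na)) {
      d <- co[j, ] - geom$origin
      z <- sum(d * geom$axis)
      lat <- sqrt(max(sum(d * d) - z^2, 0))
      out[f, j] <-
        if (z < geom$z_lower) "below"
        else if (z > geom$z_upper) "above"
        else if (lat <= geom$lateral_cutoff) "inside"
        else "outside_lateral"
    }
  }
  out
}

# per-frame finite-state-machine event counter (the spec of the permeation
# semantics, written as the obvious loop)
brute_count_events <- function(states, z) {
  up <- 0L; down <- 0L
  for (j in seq_len(ncol(states))) {
    side <- NA_character_; inside_seen <- FALSE
    for (f in seq_len(nrow(states))) {
      s <- states[f, j]
      if (s == "inside") { inside_seen <- TRUE; next }
      cur <- if (s == "outside_lateral") {
        if (z[f, j] <= 0) "below" else "above"
      } else s
      if (s != "outside_lateral" && inside_seen && !is.na(side) && side != cur) {
        if (cur == "above") up <- up + 1L else down <- down + 1L
      }
      side <- cur; inside_seen <- FALSE
    }
  }
  list(up = up, down = down, total = up + down)
}

# Mann-Whitney exact p by full enumeration with explicit pairwise counting
brute_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  N <- n1 + n2
  gt <- outer(pooled, pooled, `>`) + 0.5 * outer(pooled, pooled, `==`)
  u_of <- function(A) {
    B <- setdiff(seq_len(N), A)
    u1 <- sum(gt[A, B])
    min(u1, n1 * n2 - u1)
  }
  u_obs <- u_of(seq_len(n1))
  sets <- utils::combn(N, n1)
  us <- apply(sets, 2, u_of)
  mean(us <= u_obs + 1e-9)
}

# brute-force optimal global affine-gap alignment score by path enumeration
brute_align_score <- function(s1, s2, sm, gap_open, gap_extend) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  best <- -Inf
  # state: i, j consumed; last move ("M","I","D"); running score
  rec <- function(i, j, last, sc) {
    if (i == length(a) && j == length(b)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i < length(a) && j < length(b))
      rec(i + 1, j + 1, "M", sc + sm[a[i + 1], b[j + 1]])
    if (i < length(a))
      rec(i + 1, j, "D",
          sc - (if (last == "D") gap_extend else gap_open + gap_extend))
    if (j < length(b))
      rec(i, j + 1, "I",
          sc - (if (last == "I") gap_extend else gap_open + gap_extend))
  }
  rec(0, 0, "M", 0)
  best
}

# small helper: maximal principal angle (deg) between two subspaces
subspace_angle_deg <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  sv <- svd(crossprod(qu, qv))$d
  acos(min(1, max(-1, min(sv)))) * 180 / pi
}

# Kabsch rotation R minimizing ||A R - B|| for N x 3 point sets
kabsch_rotation <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# rotate each 3N mode vector (columns) atom-wise by rotation R
rotate_modes <- function(V, R) {
  apply(V, 2, function(v) as.vector(t(matrix(v, ncol = 3, byrow = TRUE) %*% R)))
}

# dense grid-search oracle for one pore slice (disk |xy| <= rmax)
grid_slice_radius <- function(wall, vdw, z, rmax, res = 0.02) {
  gx <- seq(-rmax, rmax, by = res)
  best <- -Inf
  for (x in gx) {
    ok <- x^2 + gx^2 <= rmax^2
    if (!any(ok)) next
    d <- sqrt((wall[, 1] - x)^2 + outer(wall[, 2], gx, `-`)^2 +
                (wall[, 3] - z)^2) - vdw
    m <- apply(d, 2, min)
    m[!ok] <- -Inf
    best <- max(best, max(m))
  }
  best
}
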