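# Shared fixtures and independent oracles for the test suite.

default_subject <- function() subject_params(M = 75, BH = 1.75)

# max per-frame relative error between predicted and reference forces
max_rel_err <- function(pred, ref, bw) {
  max(sqrt(rowSums((pred - ref)^2)) /
        pmax(sqrt(rowSums(ref^2)), 1e-6 * bw))
}

# point-in-convex-hull test in the xy plane (independent of the COP code):
# grDevices::chull gives the hull vertices in clockwise order; the point is
# inside iff every edge cross product is non-positive (within tolerance).
in_hull_xy <- function(p, pts, tol = 1e-9) {
  pts <- pts[, 1:2, drop = FALSE]
  p <- p[1:2]
  if (nrow(pts) == 1L) return(sqrt(sum((p - pts[1L, ])^2)) <= tol)
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) < 3L) {
    a <- poly[1L, ]; b <- poly[nrow(poly), ]
    ab <- b - a
    tt <- if (sum(ab^2) == 0) 0 else min(max(sum((p - a) * ab) / sum(ab^2), 0), 1)
    return(sqrt(sum((a + tt * ab - p)^2)) <= tol)
  }
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1L, ]
    cr <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
    if (cr > tol * max(sqrt(sum((b - a)^2)), 1)) return(FALSE)
  }
  TRUE
}

# build a "foot_contact" sequence directly from given COPs (all defined)
fake_foot <- function(t, cop) {
  cop <- if (is.null(dim(cop))) {
    matrix(cop, nrow = length(t), ncol = 3L, byrow = TRUE)
  } else cop
  structure(list(t = t, cop = cop, w_total = rep(1, length(t)),
                 defined = rep(TRUE, length(t)),
                 weights = matrix(1, length(t), 1L)),
            class = "foot_contact")
}

# undefined (airborne) foot for dispatch tests
airborne_foot <- function(t) {
  structure(list(t = t, cop = matrix(NA_real_, length(t), 3L),
                 w_total = rep(0, length(t)),
                 defined = rep(FALSE, length(t)),
                 weights = matrix(0, length(t), 1L)),
            class = "foot_contact")
}

# mirror a trial across the sagittal plane (y -> -y), swapping the feet
mirror_trial <- function(trial) {
  m <- trial
  flip <- function(cp) {
    pos <- cp$pos
    pos[, , 2L] <- -pos[, , 2L]
    contact_points(cp$t, pos)
  }
  m$contacts_l <- flip(trial$contacts_r)
  m$contacts_r <- flip(trial$contacts_l)
  v <- trial$com$v
  v[, 2L] <- -v[, 2L]
  m$com <- trajectory(trial$com$t, v)
  m
}
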