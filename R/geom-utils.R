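# Small 3D vector utilities shared by the generator and the annotator.
# All coordinates are plain numeric length-3 vectors or n x 3 matrices, in
# Angstrom. Nothing here is exported; these are internal primitives.

vdot <- function(a, b) sum(a * b)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis (Rodrigues form)
#' @noRd
rotation_matrix <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy,
                uz, 0, -ux,
                -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180].
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- vdot(n1, n2); y <- vdot(m1, n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Natural-extension (NeRF) atom placement: position D given three reference
# atoms A-B-C, the bond length |C-D|, the angle B-C-D (deg) and the torsion
# A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- deg2rad(angle_deg); ph <- deg2rad(torsion_deg)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          -bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Least-squares plane through points (n x 3). Returns list(center, normal,
# rms) where rms is the root-mean-square out-of-plane deviation.
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  nrm <- sv$v[, 3]
  dev <- as.numeric(sweep(xyz, 2, ctr) %*% nrm)
  list(center = ctr, normal = nrm, rms = sqrt(mean(dev^2)))
}

# Principal axis through a set of points (direction of largest spread).
principal_axis <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 2) return(unitv(xyz[2, ] - xyz[1, ]))
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  unitv(sv$v[, 1])
}

# Orthonormal in-plane frame (e1, e2) completing axis u to a right-handed
# triad (e1, e2, u).
axis_frame <- function(u) {
  u <- unitv(u)
  seed <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(seed - vdot(seed, u) * u)
  e2 <- vcross(u, e1)
  list(e1 = e1, e2 = e2, u = u)
}

# Azimuth (deg) of point p about axis u through origin o, measured in the
# right-handed frame (e1, e2, u). With u oriented top -> bottom, increasing
# azimuth is CLOCKWISE for a viewer looking down from the top.
azimuth_about <- function(p, o, frame) {
  v <- p - o
  rad2deg(atan2(vdot(v, frame$e2), vdot(v, frame$e1)))
}

# Signed smallest angular difference b - a in degrees, in (-180, 180].
angle_diff <- function(a, b) {
  d <- (b - a) %% 360
  if (d > 180) d <- d - 360
  d
}
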