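#' @useDynLib synapsemap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rbinom rnorm rpois sd fisher.test p.adjust
#' @importFrom utils head read.csv write.csv
NULL

# Canonical pattern vocabulary.  "none" is the external (CSV) spelling of the
# no-accumulation class; "no_accumulation" is accepted as an alias on input.
PATTERNS <- c("none", "central", "invagination", "diffuse", "lamellal",
              "peripheral", "asymmetric")

#' Interface pattern labels
#'
#' The seven mutually exclusive per-frame classes: six accumulation patterns
#' plus `"none"` (interface enrichment below the 35% rule).
#' @return character vector of the seven labels.
#' @export
pattern_levels <- function() PATTERNS

normalize_pattern <- function(x) {
  x <- as.character(x)
  x[x %in% c("no_accumulation", "no-accumulation", "noacc")] <- "none"
  bad <- setdiff(unique(x), PATTERNS)
  if (length(bad))
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  x
}

# Physical coordinate arrays (micrometres) for an array of dim (n1,n2,n3)
# with per-axis spacing; axis order is (z, y, x) throughout the package.
coord_arrays <- function(dims, spacing) {
  list(
    z = array(rep((seq_len(dims[1]) - 1) * spacing[1], times = dims[2] * dims[3]), dims),
    y = array(rep(rep((seq_len(dims[2]) - 1) * spacing[2], each = dims[1]),
                  times = dims[3]), dims),
    x = array(rep((seq_len(dims[3]) - 1) * spacing[3], each = dims[1] * dims[2]), dims)
  )
}

# Shift a 3D array by integer voxels (d1,d2,d3), padding with `fill`.
shift3d <- function(a, d1, d2, d3, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  src1 <- max(1, 1 - d1):min(dm[1], dm[1] - d1)
  src2 <- max(1, 1 - d2):min(dm[2], dm[2] - d2)
  src3 <- max(1, 1 - d3):min(dm[3], dm[3] - d3)
  if (!length(src1) || !length(src2) || !length(src3)) return(out)
  out[src1 + d1, src2 + d2, src3 + d3] <- a[src1, src2, src3]
  out
}

neighbour_offsets <- function(connectivity = 26) {
  g <- expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1)
  manh <- abs(g$d1) + abs(g$d2) + abs(g$d3)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh %in% c(1, 2), manh >= 1)
  g[keep, ]
}

# One binary dilation step (26- or 6-connectivity) done as an OR of shifts.
dilate3d <- function(mask, steps = 1L, connectivity = 26) {
  off <- neighbour_offsets(connectivity)
  for (s in seq_len(steps)) {
    out <- mask
    for (i in seq_len(nrow(off)))
      out <- out | shift3d(mask, off$d1[i], off$d2[i], off$d3[i])
    mask <- out
  }
  mask
}

erode3d <- function(mask, steps = 1L, connectivity = 26) {
  !dilate3d(!mask, steps = steps, connectivity = connectivity)
}

# Boundary voxels of a mask: mask voxels with a face-neighbour outside.
boundary3d <- function(mask) mask & !erode3d(mask, 1L, connectivity = 6)

# Mean filter over the in-plane (y, x) axes only; z untouched so that depth
# statistics stay crisp on the coarse axial grid.
smooth_xy <- function(a, half = 1L) {
  acc <- array(0, dim(a))
  cnt <- array(0, dim(a))
  ones <- array(1, dim(a))
  for (dy in -half:half) for (dx in -half:half) {
    acc <- acc + shift3d(a, 0L, dy, dx, fill = 0)
    cnt <- cnt + shift3d(ones, 0L, dy, dx, fill = 0)
  }
  acc / cnt
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins)), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Trilinear interpolation of a 3D array at fractional (continuous, 1-based)
# indices given as an m x 3 matrix; outside values -> `fill`.
trilinear <- function(a, idx, fill = 0) {
  dm <- dim(a)
  i1 <- idx[, 1]; i2 <- idx[, 2]; i3 <- idx[, 3]
  f1 <- floor(i1); f2 <- floor(i2); f3 <- floor(i3)
  w1 <- i1 - f1; w2 <- i2 - f2; w3 <- i3 - f3
  ok <- f1 >= 1 & f1 <= dm[1] - 0 & i1 >= 1 & i1 <= dm[1] &
        i2 >= 1 & i2 <= dm[2] & i3 >= 1 & i3 <= dm[3]
  out <- rep(fill, nrow(idx))
  if (!any(ok)) return(out)
  f1 <- pmin(pmax(f1[ok], 1), dm[1] - 1)
  f2 <- pmin(pmax(f2[ok], 1), dm[2] - 1)
  f3 <- pmin(pmax(f3[ok], 1), dm[3] - 1)
  w1 <- i1[ok] - f1; w2 <- i2[ok] - f2; w3 <- i3[ok] - f3
  at <- function(a1, a2, a3) a[cbind(a1, a2, a3)]
  v <-
    at(f1,     f2,     f3)     * (1 - w1) * (1 - w2) * (1 - w3) +
    at(f1 + 1, f2,     f3)     * w1       * (1 - w2) * (1 - w3) +
    at(f1,     f2 + 1, f3)     * (1 - w1) * w2       * (1 - w3) +
    at(f1 + 1, f2 + 1, f3)     * w1       * w2       * (1 - w3) +
    at(f1,     f2,     f3 + 1) * (1 - w1) * (1 - w2) * w3 +
    at(f1 + 1, f2,     f3 + 1) * w1       * (1 - w2) * w3 +
    at(f1,     f2 + 1, f3 + 1) * (1 - w1) * w2       * w3 +
    at(f1 + 1, f2 + 1, f3 + 1) * w1       * w2       * w3
  out[ok] <- v
  out
}

# Orthonormal basis (e1, e2) perpendicular to unit vector n, chosen
# deterministically from the least-aligned canonical axis.
plane_basis <- function(n) {
  ax <- diag(3)
  a <- ax[, which.min(abs(n))]
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Rotation matrix carrying unit vector a onto unit vector b (Rodrigues,
# minimal rotation; handles the antiparallel case).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # 180 degrees about any axis perpendicular to a
    e <- plane_basis(a)$e1
    K <- matrix(c(0, -e[3], e[2], e[3], 0, -e[1], -e[2], e[1], 0), 3, 3,
                byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

circ_coverage_deg <- function(theta_deg, bin_deg = 10) {
  if (!length(theta_deg)) return(0)
  bins <- unique(floor(((theta_deg %% 360) / bin_deg)))
  length(bins) * bin_deg
}

# Smallest angular sector (degrees) containing all given angles.
min_sector_deg <- function(theta_deg) {
  if (!length(theta_deg)) return(0)
  th <- sort(theta_deg %% 360)
  gaps <- diff(c(th, th[1] + 360))
  360 - max(gaps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
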