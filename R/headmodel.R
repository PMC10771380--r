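#' @useDynLib megstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.dist cor cov cutree dist fft hclust kmeans mvfft qnorm quantile rgamma rnorm runif sd var
#' @importFrom utils head read.csv read.table tail write.csv write.table
NULL

# Quasi-uniform points on the unit sphere (Fibonacci lattice); deterministic.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) + 1) * i          # golden-angle longitude
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Tangential unit vector at each point of a sphere ("east"; falls back to a
# fixed tangent at the poles).  Radial dipoles in a sphere are magnetically
# silent, so source moments must be tangential.
tangential_orientation <- function(pos) {
  rad <- pos / sqrt(rowSums(pos^2))
  zax <- matrix(rep(c(0, 0, 1), each = nrow(pos)), ncol = 3)
  tang <- cbind(
    zax[, 2] * rad[, 3] - zax[, 3] * rad[, 2],
    zax[, 3] * rad[, 1] - zax[, 1] * rad[, 3],
    zax[, 1] * rad[, 2] - zax[, 2] * rad[, 1]
  )
  nrm <- sqrt(rowSums(tang^2))
  degen <- nrm < 1e-8
  if (any(degen)) {
    tang[degen, ] <- matrix(rep(c(1, 0, 0), each = sum(degen)), ncol = 3)
    nrm[degen] <- 1
  }
  tang / nrm
}

#' Magnetometer field of current dipoles in a conducting sphere
#'
#' Closed-form (Sarvas) magnetic field of a tangential current dipole inside
#' a homogeneous conducting sphere centered at the origin, projected onto
#' each magnetometer's orientation.  Radial dipoles produce zero field.
#'
#' @param dipole_pos n x 3 dipole positions (m), inside the sphere.
#' @param dipole_mom n x 3 dipole moments (A m).
#' @param sensor_pos m x 3 magnetometer positions (m), outside the sphere.
#' @param sensor_ori m x 3 magnetometer orientations (unit vectors).
#' @return m x n gain matrix in tesla per unit dipole moment.
#' @export
sarvas_field <- function(dipole_pos, dipole_mom, sensor_pos, sensor_ori) {
  dipole_pos <- rbind(dipole_pos); dipole_mom <- rbind(dipole_mom)
  sensor_pos <- rbind(sensor_pos); sensor_ori <- rbind(sensor_ori)
  mu0_4pi <- 1e-7
  n_dip <- nrow(dipole_pos); n_sens <- nrow(sensor_pos)
  gain <- matrix(0, n_sens, n_dip)
  for (d in seq_len(n_dip)) {
    r0 <- dipole_pos[d, ]; q <- dipole_mom[d, ]
    qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
              q[3] * r0[1] - q[1] * r0[3],
              q[1] * r0[2] - q[2] * r0[1])
    a_vec <- sweep(sensor_pos, 2, r0)              # r - r0
    a <- sqrt(rowSums(a_vec^2))
    r <- sqrt(rowSums(sensor_pos^2))
    adotr <- rowSums(a_vec * sensor_pos)
    r0dotr <- as.vector(sensor_pos %*% r0)
    f <- a * (r * a + r^2 - r0dotr)
    c1 <- a^2 / r + adotr / a + 2 * a + 2 * r
    c2 <- a + 2 * r + adotr / a
    grad_f <- sensor_pos * c1 - matrix(r0, n_sens, 3, byrow = TRUE) * c2
    qxr0_dot_r <- as.vector(sensor_pos %*% qxr0)
    b <- (matrix(qxr0, n_sens, 3, byrow = TRUE) * f - grad_f * qxr0_dot_r) *
      (mu0_4pi / f^2)
    gain[, d] <- rowSums(b * sensor_ori)
  }
  gain
}

new_source_space <- function(pos, ori, roi, hemisphere) {
  structure(list(pos = pos, ori = ori, roi = as.integer(roi),
                 hemisphere = hemisphere),
            class = "megstates_source_space")
}

new_leadfield <- function(gain, source_space, sensor_pos, sensor_ori) {
  lf <- structure(list(gain = gain, source_space = source_space,
                       sensor_pos = sensor_pos, sensor_ori = sensor_ori),
                  class = "megstates_leadfield")
  validate_leadfield(lf)
}

validate_leadfield <- function(lf) {
  if (any(!is.finite(lf$gain))) {
    bad <- which(rowSums(!is.finite(lf$gain)) > 0)
    stop("non-finite gain entries in channel(s) ", paste(bad, collapse = ", "))
  }
  if (ncol(lf$gain) != nrow(lf$source_space$pos))
    stop("gain has ", ncol(lf$gain), " columns but geometry describes ",
         nrow(lf$source_space$pos), " vertices")
  rois <- sort(unique(lf$source_space$roi))
  if (!identical(rois, 1:68))
    stop("parcellation must contain exactly ROI labels 1..68; found ",
         length(rois), " distinct labels")
  for (h in c("left", "right")) {
    n_roi_h <- length(unique(lf$source_space$roi[lf$source_space$hemisphere == h]))
    if (n_roi_h != 34)
      stop("hemisphere '", h, "' has ", n_roi_h, " ROIs; expected 34")
  }
  lf
}

#' Number of channels / vertices of a leadfield
#' @param lf a leadfield.
#' @return integer count.
#' @export
n_channels <- function(lf) nrow(lf$gain)

#' @rdname n_channels
#' @export
n_vertices <- function(lf) ncol(lf$gain)

#' @export
print.megstates_leadfield <- function(x, ...) {
  cat("<megstates_leadfield> ", nrow(x$gain), " channels x ", ncol(x$gain),
      " vertices, 68-ROI parcellation\n", sep = "")
  invisible(x)
}

#' Build an analytic single-sphere magnetometer leadfield
#'
#' Places `n_vertices` quasi-uniform cortical vertices on a sphere of radius
#' 8 cm and `n_channels` magnetometers on a concentric sphere of radius
#' 11 cm (radial orientation), computes the Sarvas single-sphere field of a
#' unit tangential dipole at every vertex, and partitions each hemisphere
#' (sign of the x coordinate; x = 0 assigned left) into 34 ROIs by spatial
#' k-means, giving a 68-region parcellation.
#'
#' @param n_vertices number of source vertices (>= 68).
#' @param n_channels number of magnetometers (>= 16).
#' @param seed integer seed (ROI k-means); geometry itself is deterministic.
#' @param source_radius,sensor_radius sphere radii in meters.
#' @return a `megstates_leadfield`.
#' @examples
#' lf <- build_spherical_leadfield(200, 32, seed = 1)
#' dim(lf$gain)
#' @export
build_spherical_leadfield <- function(n_vertices, n_channels, seed = 1,
                                      source_radius = 0.08,
                                      sensor_radius = 0.11) {
  if (n_vertices < 68) stop("n_vertices must be >= 68 to form 68 ROIs")
  if (n_channels < 16) stop("n_channels must be >= 16")
  src_pos <- fibonacci_sphere(n_vertices) * source_radius
  src_ori <- tangential_orientation(src_pos)
  sens_pos <- fibonacci_sphere(n_channels) * sensor_radius
  sens_ori <- sens_pos / sensor_radius
  gain <- sarvas_field(src_pos, src_ori, sens_pos, sens_ori)
  hemi <- ifelse(src_pos[, 1] > 0, "right", "left")
  roi <- integer(n_vertices)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  for (h in c("left", "right")) {
    idx <- which(hemi == h)
    if (length(idx) < 34)
      stop("hemisphere '", h, "' has fewer than 34 vertices; increase n_vertices")
    km <- kmeans(src_pos[idx, , drop = FALSE], centers = 34,
                 nstart = 5, iter.max = 50)
    roi[idx] <- km$cluster + if (h == "left") 0L else 34L
  }
  new_leadfield(gain, new_source_space(src_pos, src_ori, roi, hemi),
                sens_pos, sens_ori)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Load a leadfield from a gain matrix file and a geometry table
#'
#' @param gain_file whitespace-delimited dense channels x vertices matrix.
#' @param geometry_file CSV with columns
#'   `vertex_id,x,y,z,nx,ny,nz,roi,hemisphere` (coordinates in meters,
#'   `vertex_id` 0-based, `hemisphere` in `left`/`right`).
#' @return a validated `megstates_leadfield` (sensor geometry unknown: NULL).
#' @export
load_leadfield <- function(gain_file, geometry_file) {
  gain <- as.matrix(read.table(gain_file))
  dimnames(gain) <- NULL
  geom <- read.csv(geometry_file)
  required <- c("vertex_id", "x", "y", "z", "nx", "ny", "nz", "roi", "hemisphere")
  missing_cols <- setdiff(required, names(geom))
  if (length(missing_cols))
    stop("geometry table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (ncol(gain) != nrow(geom))
    stop("gain has ", ncol(gain), " columns but geometry table has ",
         nrow(geom), " rows")
  geom <- geom[order(geom$vertex_id), ]
  new_leadfield(gain,
                new_source_space(as.matrix(geom[, c("x", "y", "z")]),
                                 as.matrix(geom[, c("nx", "ny", "nz")]),
                                 geom$roi, geom$hemisphere),
                sensor_pos = NULL, sensor_ori = NULL)
}

#' Write a leadfield to the plain-text formats read by [load_leadfield()]
#' @param lf leadfield.
#' @param gain_file,geometry_file output paths.
#' @return invisibly, `lf`.
#' @export
write_leadfield <- function(lf, gain_file, geometry_file) {
  write.table(lf$gain, gain_file, row.names = FALSE, col.names = FALSE)
  ss <- lf$source_space
  geom <- data.frame(vertex_id = seq_len(nrow(ss$pos)) - 1L,
                     x = ss$pos[, 1], y = ss$pos[, 2], z = ss$pos[, 3],
                     nx = ss$ori[, 1], ny = ss$ori[, 2], nz = ss$ori[, 3],
                     roi = ss$roi, hemisphere = ss$hemisphere)
  write.csv(geom, geometry_file, row.names = FALSE)
  invisible(lf)
}
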