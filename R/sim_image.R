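#' Simulate a two-channel nuclei image with known integrated densities
#'
#' Builds a nuclear-stain channel (bright disks on a dark background) and a
#' protein channel in which each nucleus carries its own flat intensity on
#' top of a background level, plus optional Gaussian noise. The returned
#' truth table lists each nucleus' pixel area and noiseless integrated
#' density (intensity x area), the quantity the measurement chain should
#' recover.
#'
#' Nuclei are placed by rejection sampling so that every disk lies fully
#' inside the image and disks are separated by at least `margin` pixels;
#' explicit `centers`/`radii` are validated against the same rules and
#' rejected (an error) when they violate them.
#'
#' @param n_nuclei Number of nuclei (0 allowed: uniform background).
#' @param shape Image dimensions `c(rows, cols)`.
#' @param radius_range Min/max disk radius in pixels.
#' @param intensity_range Min/max per-nucleus protein intensity.
#' @param background Protein-channel background level; intensities must be
#'   at or above it.
#' @param nuclear_level,nuclear_background Nuclear-channel disk and
#'   background levels.
#' @param noise_sd Gaussian noise s.d. added to both channels; default 0.
#' @param margin Minimum gap between disk rims, in pixels.
#' @param centers Optional `n x 2` matrix of (row, col) centers.
#' @param radii Optional radii matching `centers`.
#' @param intensities Optional per-nucleus protein intensities.
#' @param seed Integer seed.
#' @param max_attempts Placement attempts before failing.
#' @return List of class `sim_image` with `nuclear`, `protein` (numeric
#'   matrices) and `truth` (data frame `nucleus`, `row`, `col`, `radius`,
#'   `area`, `intensity`, `integrated_density`).
#' @export
gen_nuclei_image <- function(n_nuclei = 10, shape = c(256, 256),
                             radius_range = c(8, 12),
                             intensity_range = c(100, 1000),
                             background = 10, nuclear_level = 800,
                             nuclear_background = 20, noise_sd = 0,
                             margin = 3, centers = NULL, radii = NULL,
                             intensities = NULL, seed = NULL,
                             max_attempts = 10000) {
  stop_if_not_scalar_count(n_nuclei, "n_nuclei", min = 0)
  stopifnot(length(shape) == 2L, all(shape >= 1))
  if (any(intensity_range < background))
    stop("nucleus intensities must be >= background", call. = FALSE)
  nr <- shape[[1]]; nc <- shape[[2]]
  with_seed(seed, {
    if (is.null(radii) && !is.null(centers))
      radii <- rep(mean(radius_range), nrow(centers))
    if (is.null(centers)) {
      centers <- matrix(numeric(0), ncol = 2)
      radii <- numeric(0)
      attempts <- 0L
      while (nrow(centers) < n_nuclei) {
        if (attempts >= max_attempts)
          stop("could not place non-overlapping nuclei within the image",
               call. = FALSE)
        attempts <- attempts + 1L
        r <- runif(1, radius_range[[1]], radius_range[[2]])
        cy <- runif(1, r + 1, nr - r)
        cx <- runif(1, r + 1, nc - r)
        ok <- nrow(centers) == 0L ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
              radii + r + margin)
        if (ok) { centers <- rbind(centers, c(cy, cx)); radii <- c(radii, r) }
      }
    } else {
      centers <- as.matrix(centers)
      stopifnot(ncol(centers) == 2L, length(radii) == nrow(centers))
      if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
      if (any(centers[, 1] - radii < 1) || any(centers[, 1] + radii > nr) ||
          any(centers[, 2] - radii < 1) || any(centers[, 2] + radii > nc))
        stop("nuclei must lie fully within the image bounds", call. = FALSE)
      if (nrow(centers) > 1L) {
        d <- as.matrix(dist(centers))
        lim <- outer(radii, radii, `+`) + margin
        diag(d) <- Inf
        if (any(d <= lim))
          stop("nuclei overlap (margin enforced)", call. = FALSE)
      }
      n_nuclei <- nrow(centers)
    }
    if (is.null(intensities))
      intensities <- if (n_nuclei > 0)
        runif(n_nuclei, intensity_range[[1]], intensity_range[[2]])
      else numeric(0)
    if (any(intensities < background))
      stop("nucleus intensities must be >= background", call. = FALSE)

    nuclear <- matrix(nuclear_background, nr, nc)
    protein <- matrix(background, nr, nc)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    area <- integer(n_nuclei)
    for (i in seq_len(n_nuclei)) {
      disk <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= radii[i]^2
      nuclear[disk] <- nuclear_level
      protein[disk] <- intensities[i]
      area[i] <- sum(disk)
    }
    if (noise_sd > 0) {
      nuclear <- pmax(nuclear + rnorm(nr * nc, sd = noise_sd), 0)
      protein <- pmax(protein + rnorm(nr * nc, sd = noise_sd), 0)
    }
    truth <- data.frame(nucleus = seq_len(n_nuclei),
                        row = centers[, 1], col = centers[, 2],
                        radius = radii, area = area,
                        intensity = intensities,
                        integrated_density = intensities * area)
    structure(list(nuclear = nuclear, protein = protein, truth = truth),
              class = "sim_image")
  })
}

#' @export
print.sim_image <- function(x, ...) {
  cat(sprintf("sim_image: %d x %d pixels, %d nuclei\n",
              nrow(x$nuclear), ncol(x$nuclear), nrow(x$truth)))
  invisible(x)
}
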