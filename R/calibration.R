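#' Fit a linear contrast-to-mass calibration
#'
#' Mass photometry reports a dimensionless ratiometric contrast per landing
#' event; contrast is proportional to molecular mass. The instrument is
#' calibrated by measuring protein standards of known mass (e.g. a globular
#' dynamin construct) before and after each set of experiments and fitting
#' `mass = slope * contrast + intercept` by ordinary least squares. Runs
#' from before and after are pooled into a single unweighted fit; the
#' per-run slope difference can be inspected with [calibration_drift()].
#'
#' @param standards data frame with columns `known_mass_kda` and
#'   `mean_contrast` (optionally `name` and `run`); at least two standards
#'   with distinct contrasts.
#' @return A `mass_calibration` object: `slope` (kDa per contrast unit),
#'   `intercept` (kDa), `r_squared`, and the standards table.
#' @examples
#' std <- data.frame(name = c("monomer", "dimer"),
#'                   known_mass_kda = c(100, 200),
#'                   mean_contrast = c(1, 2))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  standards <- as.data.frame(standards)
  stopifnot(all(c("known_mass_kda", "mean_contrast") %in% names(standards)))
  if (nrow(standards) < 2) stop("at least 2 calibration standards required")
  if (length(unique(standards$mean_contrast)) < 2)
    stop("calibration standards have identical contrasts; fit is singular")
  fit <- stats::lm(known_mass_kda ~ mean_contrast, data = standards)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((standards$known_mass_kda -
                   mean(standards$known_mass_kda))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 standards = standards),
            class = "mass_calibration")
}

#' Slope drift between calibration runs
#'
#' When the standards table carries a `run` column (e.g. "before"/"after"),
#' reports the difference between the per-run slopes. Drift is reported for
#' inspection only; the pooled fit is always used for mass conversion.
#'
#' @param standards standards table with a `run` column and >= 2 points per
#'   run.
#' @return Named list with per-run slopes and their difference (max - min).
#' @export
calibration_drift <- function(standards) {
  standards <- as.data.frame(standards)
  if (is.null(standards$run)) stop("standards table has no 'run' column")
  slopes <- vapply(split(standards, standards$run),
                   function(d) fit_calibration(d)$slope, numeric(1))
  list(slopes = slopes, drift = max(slopes) - min(slopes))
}

#' Convert event contrasts to masses
#'
#' Applies a fitted [fit_calibration()] line per event:
#' `mass_kda = slope * contrast + intercept`.
#'
#' @param events an `event_table` (or data frame) with a `contrast` column.
#' @param cal a `mass_calibration`.
#' @return The event table with `mass_kda` filled.
#' @export
apply_calibration <- function(events, cal) {
  stopifnot(inherits(cal, "mass_calibration"))
  if (nrow(events) == 0) return(events)
  bad <- which(!is.finite(events$contrast))
  if (length(bad) > 0)
    stop("events with missing contrast at rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "")
  events$mass_kda <- cal$slope * events$contrast + cal$intercept
  events
}

#' Gaussian kernel-density mass spectrum
#'
#' Places a Gaussian kernel of width `kernel_sigma` (default 5 kDa, the
#' standard choice for peptidisc spectra) on every event mass and evaluates
#' the resulting density on a uniform kDa grid spanning the data range plus
#' 5 kernel widths on either side. The density is normalized to unit
#' trapezoidal integral; the event count is carried separately in
#' `n_events` because all downstream ratios are scale-invariant.
#'
#' @param masses numeric vector of event masses in kDa (>= 1 event).
#' @param kernel_sigma Gaussian kernel width in kDa (> 0).
#' @param grid_spacing grid step in kDa; must satisfy
#'   `grid_spacing <= kernel_sigma / 2` so peaks are resolved.
#' @return A `mass_spectrum` object: `grid` (kDa), `density` (per kDa),
#'   `kernel_sigma`, `n_events`.
#' @examples
#' sp <- kde_spectrum(c(128, 130, 131, 132), kernel_sigma = 5)
#' sp$grid[which.max(sp$density)]
#' @export
kde_spectrum <- function(masses, kernel_sigma = 5, grid_spacing = 1) {
  masses <- as.numeric(masses)
  if (length(masses) == 0 || any(!is.finite(masses)))
    stop("at least one finite mass is required")
  stopifnot(kernel_sigma > 0, grid_spacing > 0)
  if (grid_spacing > kernel_sigma / 2)
    stop("'grid_spacing' must be <= kernel_sigma / 2")
  lo <- min(masses) - 5 * kernel_sigma
  hi <- max(masses) + 5 * kernel_sigma
  grid <- seq(lo, hi, by = grid_spacing)
  if (grid[length(grid)] < hi) grid <- c(grid, grid[length(grid)] +
                                           grid_spacing)
  dens <- numeric(length(grid))
  # chunk the event loop: full outer product can be large at n = 1e5
  chunk <- 2048L
  for (start in seq(1L, length(masses), by = chunk)) {
    m <- masses[start:min(start + chunk - 1L, length(masses))]
    dens <- dens + colSums(matrix(
      stats::dnorm(rep(grid, each = length(m)), mean = m, sd = kernel_sigma),
      nrow = length(m)))
  }
  dens <- dens / length(masses)
  dens <- dens / trapz(grid, dens)
  structure(list(grid = grid, density = dens, kernel_sigma = kernel_sigma,
                 n_events = length(masses)),
            class = "mass_spectrum")
}

# trapezoidal integral of y over x (uniform or not)
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Detect peaks in a mass spectrum
#'
#' Local maxima of the density whose height exceeds a fraction of the global
#' maximum.
#'
#' @param spectrum a `mass_spectrum`.
#' @param min_prominence_fraction minimal peak height as a fraction of the
#'   global maximum.
#' @return Data frame with columns `peak_mass` (kDa) and `height`, sorted by
#'   mass; may have zero rows.
#' @export
find_peaks <- function(spectrum, min_prominence_fraction = 0.05) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  d <- spectrum$density
  n <- length(d)
  if (n < 3) return(data.frame(peak_mass = numeric(0), height = numeric(0)))
  is_max <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] &
                d[2:(n - 1)] >= d[3:n], FALSE)
  idx <- which(is_max & d > min_prominence_fraction * max(d))
  out <- data.frame(peak_mass = spectrum$grid[idx], height = d[idx])
  out[order(out$peak_mass), , drop = FALSE]
}

#' Full width at half maximum of a spectral peak
#'
#' Walks left and right from the peak until the density crosses half the
#' peak height, interpolating linearly between grid points. For a Gaussian
#' peak of total width sigma the result is `2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param spectrum a `mass_spectrum`.
#' @param peak_mass location of a detected peak in kDa.
#' @return FWHM in kDa.
#' @export
peak_fwhm <- function(spectrum, peak_mass) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  g <- spectrum$grid
  d <- spectrum$density
  i0 <- which.min(abs(g - peak_mass))
  if (i0 <= 1L || i0 >= length(g))
    stop("half height not crossed within the spectrum grid")
  half <- d[i0] / 2
  cross <- function(indices) {
    prev <- i0
    for (i in indices) {
      if (d[i] <= half) {
        # linear interpolation between grid points i and prev
        return(g[i] + (g[prev] - g[i]) * (half - d[i]) / (d[prev] - d[i]))
      }
      prev <- i
    }
    stop("half height not crossed within the spectrum grid")
  }
  right <- cross(seq(i0 + 1L, length(g)))
  left <- cross(seq(i0 - 1L, 1L))
  right - left
}

#' Read / write calibrant tables and spectra as CSV
#'
#' Calibrant CSVs carry `name`, `known_mass_kda`, `mean_contrast`
#' (optionally `run`); spectrum CSVs carry `grid_kda`, `density`.
#'
#' @param path CSV file path.
#' @param spectrum a `mass_spectrum`.
#' @return `read_calibrants` returns a data frame; `write_spectrum` returns
#'   `path` invisibly; `read_spectrum` returns a `mass_spectrum` (kernel
#'   width recovered from the sidecar-free CSV is taken from the
#'   `kernel_sigma` argument).
#' @export
read_calibrants <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("known_mass_kda", "mean_contrast") %in% names(out)))
  out
}

#' @rdname read_calibrants
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  utils::write.csv(data.frame(grid_kda = spectrum$grid,
                              density = spectrum$density),
                   path, row.names = FALSE)
  invisible(path)
}
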