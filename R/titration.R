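#' Assemble a titration point table
#'
#' One row per incubation condition of a binding titration: the titrated
#' ligand total, the nominal receptor total and its purity-scaled effective
#' value, and the raw bound fraction from the two-component decomposition.
#' Baseline correction, free-ligand computation and the inclusion filter
#' are applied by [baseline_correct()], [compute_free_ligand()] and
#' [filter_points()].
#'
#' @param ligand_total titrated ligand concentrations in nM.
#' @param fraction_raw raw bound fractions from [fit_two_component()].
#' @param receptor_total_nominal nominal receptor concentration(s) in nM.
#' @param purity receptor sample purity in (0, 1] from
#'   [fit_receptor_only()]; scales nominal to effective receptor.
#' @param replicate optional replicate label.
#' @return A `titration_points` data frame.
#' @export
titration_points <- function(ligand_total, fraction_raw,
                             receptor_total_nominal, purity = 1,
                             replicate = 1L) {
  stopifnot(all(ligand_total >= 0), all(receptor_total_nominal > 0),
            purity > 0, purity <= 1)
  out <- data.frame(
    replicate = replicate,
    ligand_total = as.numeric(ligand_total),
    receptor_total_nominal = as.numeric(receptor_total_nominal),
    receptor_total_effective = purity * as.numeric(receptor_total_nominal),
    fraction_raw = as.numeric(fraction_raw),
    fraction_corrected = NA_real_,
    ligand_free = NA_real_,
    included = NA)
  class(out) <- c("titration_points", class(out))
  out
}

#' Compute free ligand with depletion correction
#'
#' At comparable receptor and ligand concentrations the free ligand is
#' materially below the titrated total: the amount locked up in complexes,
#' `fraction_corrected * receptor_total_effective`, is subtracted from the
#' titrated ligand. Negative results are permitted here (they arise from
#' fit noise near zero) and are removed downstream by the inclusion
#' filter.
#'
#' @param points a `titration_points` table with `fraction_corrected` set.
#' @return The table with `ligand_free` filled (nM).
#' @export
compute_free_ligand <- function(points) {
  if (any(!is.finite(points$fraction_corrected)))
    stop("'fraction_corrected' must be set before computing free ligand")
  points$ligand_free <- points$ligand_total -
    points$fraction_corrected * points$receptor_total_effective
  points
}

#' Flag titration points with too little free ligand
#'
#' Conditions with apparent free ligand below `min_free` (default 1 nM) are
#' excluded from the Hill fit: so few events fall under the corresponding
#' peaks that the bound fraction is unreliable. Points are flagged, never
#' deleted, and order is preserved.
#'
#' @param points a `titration_points` table with `ligand_free` computed.
#' @param min_free inclusion threshold in nM.
#' @return The table with the `included` flag set.
#' @export
filter_points <- function(points, min_free = 1) {
  if (any(!is.finite(points$ligand_free)))
    stop("'ligand_free' must be computed before filtering")
  points$included <- points$ligand_free >= min_free
  if (!any(points$included))
    stop("all titration points excluded (free ligand < ", min_free,
         " nM); no fit is possible")
  points
}

#' The binding isotherm (Hill form, coefficient 1)
#'
#' `A + (B - A) * L / (K_D + L)`: baseline `A`, saturation `B` (both in
#' percent bound) and half-saturation at `L = K_D`.
#'
#' @param L free ligand concentration in nM.
#' @param kd dissociation constant in nM.
#' @param a,b baseline and saturation bound percentages.
#' @return Percent bound.
#' @export
hill_fraction <- function(L, kd, a, b) {
  a + (b - a) * L / (kd + L)
}

#' Bounded Hill fit of a binding titration
#'
#' Least-squares fit of percent bound versus free ligand to
#' `A + (B - A) L / (K_D + L)` with box constraints
#' `0 <= A, B <= 100` (percent) and `K_D > 0`; the Hill coefficient is
#' fixed at 1. The fit is unweighted. Initialization is deterministic and
#' scale-free: `K_D` starts at the geometric mean of the included free
#' ligand values, `A` at 0, `B` at the largest observed fraction. Standard
#' errors come from the Gauss-Newton covariance
#' `RSS / (n - 3) * (J'J)^-1` at the optimum.
#'
#' @param points a `titration_points` table with inclusion flags set, or a
#'   data frame with `ligand_free`, `fraction_corrected`, `included`.
#' @param min_span included free-ligand values must span at least this
#'   factor (default 10) for the isotherm to be identifiable.
#' @return A `hill_fit`: `kd` (nM), `a`, `b` (percent), `se` (named
#'   standard errors), `n_points_used`, `rss`, `flagged_bounds` (non-empty
#'   when a parameter stopped at a constraint with the objective still
#'   decreasing outward -- treat such fits as unreliable).
#' @export
fit_hill <- function(points, min_span = 10) {
  use <- points[which(points$included), , drop = FALSE]
  if (nrow(use) < 4)
    stop("need at least 4 included titration points, got ", nrow(use))
  x <- use$ligand_free
  y <- 100 * use$fraction_corrected
  pos <- x[x > 0]
  if (max(pos) / min(pos) < min_span)
    stop("included free-ligand values must span at least a factor ",
         min_span)
  obj <- function(p) sum((hill_fraction(x, p[1], p[2], p[3]) - y)^2)
  k0 <- exp(mean(log(pos)))
  b0 <- min(max(max(y), 1), 100)
  lower <- c(1e-9, 0, 0)
  upper <- c(Inf, 100, 100)
  fit <- stats::optim(c(k0, 0, b0), obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
  if (fit$convergence != 0)
    stop("Hill fit did not converge (code ", fit$convergence, "): ",
         fit$message)
  pn <- c("kd", "a", "b")
  flagged <- flag_active_bounds(obj, fit$par, lower, upper, pn)
  # A pinned at 0 is the expected baseline-corrected solution
  flagged <- setdiff(flagged, if (fit$par[2] <= 1e-9) "a" else character(0))
  if (length(flagged) > 0)
    warning("Hill fit stopped at constraint bound(s): ",
            paste(flagged, collapse = ", "), "; estimates are unreliable")
  se <- tryCatch({
    J <- vapply(seq_along(fit$par), function(i) {
      h <- 1e-6 * max(1, abs(fit$par[i]))
      up <- fit$par; up[i] <- up[i] + h
      dn <- fit$par; dn[i] <- dn[i] - h
      (hill_fraction(x, up[1], up[2], up[3]) -
         hill_fraction(x, dn[1], dn[2], dn[3])) / (2 * h)
    }, numeric(length(x)))
    s2 <- fit$value / max(nrow(use) - 3, 1)
    sqrt(diag(s2 * solve(crossprod(J))))
  }, error = function(e) rep(NA_real_, 3))
  names(se) <- pn
  structure(list(kd = fit$par[1], a = fit$par[2], b = fit$par[3],
                 se = se, n_points_used = nrow(use), rss = fit$value,
                 flagged_bounds = flagged),
            class = "hill_fit")
}

#' Summarize replicate titrations
#'
#' Reports per-replicate dissociation constants with their mean and
#' standard deviation, a pooled Hill fit over all included points of all
#' replicates jointly (combining all measurements into one fit), and
#' mean +/- s.d. bound percentages in log-spaced free-ligand bins for
#' plotting (free ligand differs between replicates even at equal titrated
#' totals, so fixed-condition averaging is not possible; geometric bin
#' centers are reported).
#'
#' @param points_list list of `titration_points` tables, one per replicate,
#'   with inclusion flags set.
#' @param fits optional list of per-replicate `hill_fit`s; computed with
#'   [fit_hill()] when omitted.
#' @param n_bins number of log-spaced free-ligand bins for the display
#'   summary.
#' @return A list: `kd_per_replicate`, `kd_mean`, `kd_sd` (`NA` for a
#'   single replicate), `pooled` (`hill_fit` over all points), `binned`
#'   (data frame `ligand_free`, `mean_percent`, `sd_percent`, `n`).
#' @export
summarize_replicates <- function(points_list, fits = NULL, n_bins = 8) {
  stopifnot(length(points_list) >= 1)
  if (is.null(fits)) fits <- lapply(points_list, fit_hill)
  kds <- vapply(fits, function(f) f$kd, numeric(1))
  all_pts <- do.call(rbind, lapply(points_list, as.data.frame))
  pooled <- fit_hill(all_pts)
  inc <- all_pts[which(all_pts$included), , drop = FALSE]
  lf <- inc$ligand_free
  edges <- exp(seq(log(min(lf)), log(max(lf)), length.out = n_bins + 1))
  bin <- cut(lf, breaks = edges, include.lowest = TRUE)
  binned <- do.call(rbind, lapply(split(inc, bin), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(ligand_free = exp(mean(log(d$ligand_free))),
               mean_percent = mean(100 * d$fraction_corrected),
               sd_percent = if (nrow(d) > 1)
                 stats::sd(100 * d$fraction_corrected) else NA_real_,
               n = nrow(d))
  }))
  rownames(binned) <- NULL
  list(kd_per_replicate = kds,
       kd_mean = mean(kds),
       kd_sd = if (length(kds) > 1) stats::sd(kds) else NA_real_,
       pooled = pooled,
       binned = binned)
}

#' Run the full titration analysis on a series of event tables
#'
#' End-to-end path from per-condition landing-event tables to a
#' dissociation constant: (1) a receptor-only single-Gaussian fit on the
#' zero-ligand measurement gives the sample purity and the shared component
#' width `sigma_fixed` (a warning is raised if it falls outside the
#' typical 10-15 kDa range); (2) every condition is decomposed with the
#' constrained two-Gaussian model; (3) the zero-ligand apparent fraction is
#' subtracted as baseline; (4) free ligand is computed with depletion
#' correction using the purity-scaled receptor concentration; (5) points
#' with free ligand below `min_free` are excluded; (6) the bounded Hill
#' equation is fitted.
#'
#' @param tables list of `event_table`s, one per condition, each carrying
#'   `nominal_receptor_total` / `nominal_ligand_total` attributes; exactly
#'   one condition must have zero ligand.
#' @param receptor_mass experimentally determined receptor mass in kDa.
#' @param ligand_mass ligand sequence mass in kDa.
#' @param purity override for the receptor purity; default is the value
#'   from the zero-ligand receptor-only fit.
#' @param min_free free-ligand inclusion threshold in nM.
#' @param mu_tolerance,kernel_sigma,grid_spacing,method forwarded to the
#'   decomposition fits.
#' @param sigma_expected_range typical width range in kDa; a `sigma_fixed`
#'   outside it triggers a warning but is still used.
#' @param replicate replicate label stored on the point table.
#' @return A list: `points` (`titration_points`), `hill` (`hill_fit`),
#'   `sigma_fixed`, `purity`, `baseline` (zero-ligand apparent fraction),
#'   `fits` (per-condition `fit_result`s).
#' @export
analyze_titration <- function(tables, receptor_mass, ligand_mass,
                              purity = NULL, min_free = 1,
                              mu_tolerance = 1, kernel_sigma = 5,
                              grid_spacing = 1,
                              method = c("kde", "histogram"),
                              sigma_expected_range = c(10, 15),
                              replicate = 1L) {
  method <- match.arg(method)
  ligand_totals <- vapply(tables, function(t)
    as.numeric(attr(t, "nominal_ligand_total")), numeric(1))
  receptor_totals <- vapply(tables, function(t)
    as.numeric(attr(t, "nominal_receptor_total")), numeric(1))
  if (any(!is.finite(ligand_totals)) || any(!is.finite(receptor_totals)))
    stop("every event table needs nominal receptor/ligand totals")
  i0 <- which(ligand_totals == 0)
  if (length(i0) != 1)
    stop("exactly one zero-ligand condition is required, found ",
         length(i0))
  ref <- fit_receptor_only(tables[[i0]]$mass_kda, mu_init = receptor_mass,
                           kernel_sigma = kernel_sigma,
                           grid_spacing = grid_spacing, method = method)
  sigma_fixed <- ref$sigma
  if (sigma_fixed < sigma_expected_range[1] ||
      sigma_fixed > sigma_expected_range[2])
    warning(sprintf(
      "fitted receptor width %.1f kDa is outside the typical %g-%g kDa range",
      sigma_fixed, sigma_expected_range[1], sigma_expected_range[2]))
  if (is.null(purity)) purity <- ref$purity
  fits <- lapply(tables, function(t)
    fit_two_component(t$mass_kda, receptor_mass, ligand_mass,
                      sigma_fixed = sigma_fixed,
                      mu_tolerance = mu_tolerance,
                      kernel_sigma = kernel_sigma,
                      grid_spacing = grid_spacing, method = method))
  raw <- vapply(fits, function(f) f$fraction_complex, numeric(1))
  baseline <- raw[i0]
  pts <- titration_points(ligand_totals, raw, receptor_totals,
                          purity = purity, replicate = replicate)
  pts$fraction_corrected <- baseline_correct(raw, baseline)
  pts <- compute_free_ligand(pts)
  pts <- filter_points(pts, min_free = min_free)
  hill <- fit_hill(pts)
  list(points = pts, hill = hill, sigma_fixed = sigma_fixed,
       purity = purity, baseline = baseline, fits = fits)
}
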