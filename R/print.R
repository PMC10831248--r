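#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf("Contrast-to-mass calibration: mass = %.6g * contrast + %.6g kDa (r^2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Constrained two-Gaussian decomposition\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("fraction_complex = %.4f (residual norm %.3g, %d events)\n",
              x$fraction_complex, x$residual_norm, x$n_events))
  if (length(x$flagged_bounds) > 0)
    cat("flagged at bounds:", paste(x$flagged_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (coefficient 1): K_D = %.3g nM (se %.3g), A = %.3g%%, B = %.3g%%, n = %d points\n",
              x$kd, x$se[["kd"]], x$a, x$b, x$n_points_used))
  if (length(x$flagged_bounds) > 0)
    cat("flagged at bounds:", paste(x$flagged_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.disc_composition <- function(x, ...) {
  cat(sprintf(paste0(
    "Peptidisc composition: measured %.4g kDa = protein %.4g kDa",
    " + lipid %.4g kDa (%.3g lipids x %.3g kDa)",
    " + scaffold %.4g kDa (~%d peptides x %.3g kDa)\n"),
    x$mass_measured, x$mass_protein, x$lipid_mass, x$lipids_per_disc,
    x$lipid_unit_mass, x$scaffold_mass, x$n_peptides, x$peptide_unit_mass))
  invisible(x)
}

#' @export
print.stoich_assignment <- function(x, ...) {
  cat("Stoichiometry:",
      paste(sprintf("%d x %s", x$counts, names(x$counts)), collapse = " + "),
      sprintf("-> %.4g kDa (relative error %.2f%%)\n",
              x$predicted_mass, 100 * x$relative_error))
  invisible(x)
}
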