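#' Fit a phosphate-assay standard curve
#'
#' Colorimetric phosphorous quantification: absorbance at 820 nm is a
#' linear function of nanomoles of phosphate. Duplicate measurements of the
#' same standard are averaged before the unweighted least-squares fit, and
#' phosphate content of unknowns is obtained by inverse prediction
#' `nmol = (A - intercept) / slope`.
#'
#' @param standards data frame with columns `nmol_phosphate` and
#'   `absorbance` (replicated rows per level allowed); >= 3 distinct
#'   phosphate amounts.
#' @return A `phosphate_curve`: `slope` (AU per nmol), `intercept` (AU),
#'   `r_squared`, and the averaged standards.
#' @export
fit_phosphate_curve <- function(standards) {
  standards <- as.data.frame(standards)
  stopifnot(all(c("nmol_phosphate", "absorbance") %in% names(standards)))
  avg <- stats::aggregate(absorbance ~ nmol_phosphate, data = standards,
                          FUN = mean)
  if (nrow(avg) == 1)
    stop("standards have zero variance in phosphate amount; fit is singular")
  if (nrow(avg) < 3)
    stop("at least 3 distinct phosphate standards are required")
  fit <- stats::lm(absorbance ~ nmol_phosphate, data = avg)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((avg$absorbance - mean(avg$absorbance))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 standards = avg),
            class = "phosphate_curve")
}

#' @rdname fit_phosphate_curve
#' @param curve a `phosphate_curve`.
#' @param absorbance measured absorbance(s) at 820 nm.
#' @export
predict_nmol <- function(curve, absorbance) {
  stopifnot(inherits(curve, "phosphate_curve"))
  (absorbance - curve$intercept) / curve$slope
}

#' Lipids per disc from phosphate analysis
#'
#' The molar ratio of phospholipid (one phosphate per lipid) to peptidisc
#' particles. Replicate phosphate measurements yield a mean ratio with its
#' sample standard deviation.
#'
#' @param nmol_phosphate nanomoles of phosphate; a vector is treated as
#'   replicate measurements of the same sample.
#' @param nmol_disc nanomoles of disc particles (> 0).
#' @return List with `ratio` (mean lipids per disc) and `sd` (`NA` for a
#'   single measurement).
#' @export
lipids_per_disc <- function(nmol_phosphate, nmol_disc) {
  if (!is.finite(nmol_disc) || nmol_disc <= 0)
    stop("'nmol_disc' must be > 0")
  if (any(nmol_phosphate < 0)) stop("'nmol_phosphate' must be >= 0")
  r <- nmol_phosphate / nmol_disc
  list(ratio = mean(r),
       sd = if (length(r) > 1) stats::sd(r) else NA_real_)
}

#' Decompose a measured peptidisc mass into protein, lipid and scaffold
#'
#' A peptidisc particle's mass photometry mass is the sum of the
#' reconstituted protein complex, its annular phospholipids, and the
#' amphipathic scaffold peptides wrapping the transmembrane region. Given
#' the lipid count from phosphate analysis, the lipid contribution is
#' `lipids_per_disc * 0.8 kDa` (800 Da average phospholipid); the scaffold
#' contribution is what remains of the measured mass; and the scaffold
#' peptide count is the nearest integer of scaffold mass over the 4.5 kDa
#' scaffold peptide.
#'
#' @param mass_measured particle mass from mass photometry, kDa.
#' @param mass_protein sequence-based mass of the reconstituted protein
#'   complex, kDa.
#' @param lipids_per_disc lipid count per disc (from phosphate analysis).
#' @param lipid_unit_mass average phospholipid mass, kDa.
#' @param peptide_unit_mass scaffold peptide mass, kDa.
#' @return A `disc_composition`: the inputs plus `lipid_mass`,
#'   `scaffold_mass` (kDa) and `n_peptides` (integer).
#' @examples
#' disc_composition(185, 100, 24)  # AqpZ-like disc: 19.2 / 65.8 / 15
#' disc_composition(130, 85, 23)   # MscL-like disc: 18.4 / 26.6 / 6
#' @export
disc_composition <- function(mass_measured, mass_protein, lipids_per_disc,
                             lipid_unit_mass = 0.8,
                             peptide_unit_mass = 4.5) {
  stopifnot(mass_measured > 0, mass_protein >= 0, lipids_per_disc >= 0,
            lipid_unit_mass > 0, peptide_unit_mass > 0)
  if (mass_measured < mass_protein)
    stop("measured mass is below the protein mass; inputs are inconsistent")
  lipid_mass <- lipids_per_disc * lipid_unit_mass
  scaffold_mass <- mass_measured - mass_protein - lipid_mass
  if (scaffold_mass < 0)
    stop("negative scaffold mass; lipid content exceeds the measured mass")
  structure(list(mass_measured = mass_measured,
                 mass_protein = mass_protein,
                 lipids_per_disc = lipids_per_disc,
                 lipid_unit_mass = lipid_unit_mass,
                 peptide_unit_mass = peptide_unit_mass,
                 lipid_mass = lipid_mass,
                 scaffold_mass = scaffold_mass,
                 # half-up rounding: integer counts are reported
                 n_peptides = as.integer(floor(
                   scaffold_mass / peptide_unit_mass + 0.5))),
            class = "disc_composition")
}

#' Assign an integer stoichiometry to a species mass
#'
#' Exhaustively enumerates integer count vectors over the given components
#' (0 to `max_count_per_component` copies each, not all zero) and returns
#' the combination whose predicted mass is closest to the observed species
#' mass, provided the relative error `|observed - predicted| / predicted`
#' does not exceed `rel_tolerance`. Ties are broken deterministically by
#' smaller total copy number, then lexicographically by component order.
#' Used e.g. to read a 420 kDa species as antibody bound to one 270 kDa
#' receptor complex and a 670 kDa species as antibody bridging two.
#'
#' @param species_mass observed species mass in kDa.
#' @param components data frame with columns `name` and `mass` (kDa), or a
#'   named numeric vector of component masses.
#' @param max_count_per_component maximal copies of each component.
#' @param rel_tolerance maximal acceptable relative error (default 5%).
#' @return A `stoich_assignment` (`counts` named integer vector,
#'   `predicted_mass`, `relative_error`) or `NULL` when no combination is
#'   acceptable.
#' @examples
#' comps <- c(BAM = 270, mAB1 = 156)
#' assign_stoichiometry(420, comps)  # 1 BAM + 1 mAB1, predicted 426
#' assign_stoichiometry(670, comps)  # 2 BAM + 1 mAB1, predicted 696
#' @export
assign_stoichiometry <- function(species_mass, components,
                                 max_count_per_component = 4,
                                 rel_tolerance = 0.05) {
  if (is.numeric(components) && !is.null(names(components)))
    components <- data.frame(name = names(components), mass = components)
  components <- as.data.frame(components)
  stopifnot(all(c("name", "mass") %in% names(components)),
            all(components$mass > 0), species_mass > 0,
            max_count_per_component >= 1)
  grid <- do.call(expand.grid,
                  rep(list(0:max_count_per_component), nrow(components)))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  predicted <- as.matrix(grid) %*% components$mass
  rel_err <- abs(species_mass - predicted) / predicted
  # deterministic tie-breaks: error, then total copies, then lexicographic
  ord <- do.call(order, c(list(rel_err, rowSums(grid)),
                          as.list(grid)))
  best <- ord[1]
  if (rel_err[best] > rel_tolerance) return(NULL)
  counts <- as.integer(grid[best, ])
  names(counts) <- components$name
  structure(list(counts = counts,
                 predicted_mass = as.numeric(predicted[best]),
                 relative_error = as.numeric(rel_err[best])),
            class = "stoich_assignment")
}
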