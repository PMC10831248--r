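#' Species specification for the simulator
#'
#' Describes one molecular species landing on the coverslip: a label, its
#' true particle mass (protein + lipid + scaffold for a peptidisc) and a
#' relative abundance. Vectors are accepted so a whole mixture can be built
#' in one call.
#'
#' @param name character vector of species labels.
#' @param true_mass numeric vector of true particle masses in kDa; must be
#'   positive.
#' @param weight numeric vector of relative abundances (>= 0, not all zero);
#'   normalized internally.
#' @return A `species_spec` data frame with columns `name`, `true_mass`,
#'   `weight`.
#' @examples
#' species_spec(c("BtuCD", "BtuCD-BtuF"), c(208, 237.4), c(0.7, 0.3))
#' @export
species_spec <- function(name, true_mass, weight = 1) {
  name <- as.character(name)
  true_mass <- as.numeric(true_mass)
  weight <- rep_len(as.numeric(weight), length(name))
  if (length(name) == 0L) stop("at least one species is required")
  if (length(true_mass) != length(name))
    stop("'name' and 'true_mass' must have equal length")
  if (any(!is.finite(true_mass)) || any(true_mass <= 0))
    stop("'true_mass' must be finite and > 0")
  if (any(!is.finite(weight)) || any(weight < 0))
    stop("'weight' must be finite and >= 0")
  if (sum(weight) <= 0) stop("species weights must sum to a positive value")
  out <- data.frame(name = name, true_mass = true_mass, weight = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_spec", class(out))
  out
}

#' Instrument model for the simulator
#'
#' Collects the parameters of an idealized mass photometer: the per-event
#' mass error (the spread of single-particle mass estimates around the true
#' species mass), the low-mass detection floor below which landing events are
#' not registered, the linear contrast response, and the expected number of
#' landing events per movie.
#'
#' The default mass error of 12 kDa sits in the middle of the 10-15 kDa
#' range typical for ~200 kDa membrane-protein peptidiscs, and the default
#' 40 kDa detection floor hides a ~30 kDa free ligand while passing all
#' receptor-sized particles.
#'
#' @param mass_sigma per-event mass standard deviation in kDa (> 0).
#' @param detection_limit minimal detectable mass in kDa (>= 0).
#' @param contrast_slope ratiometric contrast per kDa (non-zero).
#' @param contrast_intercept contrast offset.
#' @param events_expected mean number of landing events per movie (> 0),
#'   used when no fixed event count is requested.
#' @return An `instrument_model` list.
#' @export
instrument_model <- function(mass_sigma = 12, detection_limit = 40,
                             contrast_slope = 1e-3, contrast_intercept = 0,
                             events_expected = 5000) {
  stopifnot(is.finite(mass_sigma), mass_sigma > 0,
            is.finite(detection_limit), detection_limit >= 0,
            is.finite(contrast_slope), contrast_slope != 0,
            is.finite(contrast_intercept),
            is.finite(events_expected), events_expected > 0)
  structure(list(mass_sigma = mass_sigma,
                 detection_limit = detection_limit,
                 contrast_slope = contrast_slope,
                 contrast_intercept = contrast_intercept,
                 events_expected = events_expected),
            class = "instrument_model")
}

#' Ground-truth binding parameters for a simulated titration
#'
#' The true dissociation constant and Hill asymptotes used to generate a
#' titration series; the estimated quantities downstream are compared against
#' this record.
#'
#' @param kd_true true dissociation constant in nM (> 0).
#' @param receptor_total receptor concentration in nM, held constant across
#'   the series (the experiment holds the receptor at ~200 nM).
#' @param ligand_totals numeric vector of titrated ligand concentrations in
#'   nM; must contain 0 (the no-ligand baseline condition).
#' @param a_true baseline bound fraction in `[0, 1]`.
#' @param b_true saturation bound fraction in `[a_true, 1]`.
#' @param seed integer seed controlling all randomness in the series.
#' @return A `binding_truth` list.
#' @export
binding_truth <- function(kd_true, receptor_total,
                          ligand_totals = c(0, 25, 50, 100, 150, 225, 300,
                                            450, 600, 900),
                          a_true = 0, b_true = 1, seed) {
  stopifnot(is.finite(kd_true), kd_true > 0,
            is.finite(receptor_total), receptor_total > 0,
            all(is.finite(ligand_totals)), all(ligand_totals >= 0))
  if (!any(ligand_totals == 0))
    stop("'ligand_totals' must include 0 (the no-ligand baseline condition)")
  if (!(a_true >= 0 && a_true <= b_true && b_true <= 1))
    stop("need 0 <= a_true <= b_true <= 1")
  if (missing(seed)) stop("an explicit 'seed' is required")
  structure(list(kd_true = kd_true, receptor_total = receptor_total,
                 ligand_totals = as.numeric(ligand_totals),
                 a_true = a_true, b_true = b_true,
                 seed = as.integer(seed)),
            class = "binding_truth")
}

#' Exact 1:1 mass-action bound fraction with ligand depletion
#'
#' Solves the equilibrium `R + L <-> RL` for the fraction of receptor bound,
#' accounting for ligand depletion (free ligand materially below total ligand
#' when receptor and ligand concentrations are comparable):
#' `f = ((R + L + K) - sqrt((R + L + K)^2 - 4 R L)) / (2 R)`.
#'
#' @param receptor_total total receptor concentration in nM (> 0).
#' @param ligand_total total ligand concentration in nM (>= 0).
#' @param kd dissociation constant in nM (>= 0); `kd = 0` is the
#'   infinitely tight limit `f = min(L, R) / R`.
#' @return Bound fraction in `[0, 1]`; vectorized over its arguments.
#' @examples
#' equilibrium_fraction_bound(200, 0, 50)    # 0
#' equilibrium_fraction_bound(100, 200, 0)   # 1
#' equilibrium_fraction_bound(7, 7, 7)       # (3 - sqrt(5)) / 2
#' @export
equilibrium_fraction_bound <- function(receptor_total, ligand_total, kd) {
  if (any(!is.finite(receptor_total)) || any(!is.finite(ligand_total)) ||
      any(!is.finite(kd)))
    stop("inputs must be finite")
  if (any(receptor_total <= 0)) stop("'receptor_total' must be > 0")
  if (any(ligand_total < 0)) stop("'ligand_total' must be >= 0")
  if (any(kd < 0)) stop("'kd' must be >= 0")
  s <- receptor_total + ligand_total + kd
  disc <- pmax(s^2 - 4 * receptor_total * ligand_total, 0)
  f <- (s - sqrt(disc)) / (2 * receptor_total)
  pmin(pmax(f, 0), 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # force RNG initialization
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulate one mass-photometry measurement
#'
#' Draws landing events from a species mixture under an instrument model.
#' Events are assigned to species with probability proportional to weight;
#' each event's mass is Normal(true mass, `mass_sigma`); events whose drawn
#' mass falls below the detection floor are discarded; contrast follows
#' deterministically from the drawn mass through the linear contrast model,
#' so calibration round-trips are exact.
#'
#' @param species a [species_spec] mixture.
#' @param instrument an [instrument_model].
#' @param n_events fixed number of events to draw before detection-limit
#'   censoring, or `NULL` to draw the count from
#'   Poisson(`events_expected`).
#' @param seed integer seed (mandatory; the simulator has no implicit global
#'   randomness).
#' @param sample_id label stored on the table.
#' @param dilution_factor dilution applied immediately before measurement
#'   (>= 1). Affects only the expected event count (events scale with the
#'   diluted concentration), never the equilibrium fractions: the mixture is
#'   assumed to still reflect the pre-dilution equilibrium on the measurement
#'   timescale.
#' @param nominal_receptor_total,nominal_ligand_total metadata in nM.
#' @return An `event_table`: a data frame with columns `event_index`,
#'   `contrast`, `mass_kda` and sample metadata in attributes. A warning is
#'   raised if every drawn event fell below the detection limit.
#' @examples
#' inst <- instrument_model(mass_sigma = 12)
#' tab <- simulate_sample(species_spec("MscL disc", 130), inst,
#'                        n_events = 200, seed = 1)
#' head(tab)
#' @export
simulate_sample <- function(species, instrument, n_events = NULL, seed,
                            sample_id = "sample", dilution_factor = 1,
                            nominal_receptor_total = NA_real_,
                            nominal_ligand_total = NA_real_) {
  if (!inherits(species, "species_spec"))
    species <- species_spec(species$name, species$true_mass, species$weight)
  stopifnot(inherits(instrument, "instrument_model"),
            is.finite(dilution_factor), dilution_factor >= 1)
  if (missing(seed)) stop("an explicit 'seed' is required")
  with_seed(seed, {
    n <- if (is.null(n_events)) {
      stats::rpois(1, instrument$events_expected / dilution_factor)
    } else {
      as.integer(n_events)
    }
    if (n > 0) {
      idx <- sample.int(nrow(species), n, replace = TRUE,
                        prob = species$weight / sum(species$weight))
      mass <- stats::rnorm(n, mean = species$true_mass[idx],
                           sd = instrument$mass_sigma)
      keep <- mass >= instrument$detection_limit
      mass <- mass[keep]
    } else {
      mass <- numeric(0)
    }
    if (n > 0 && length(mass) == 0)
      warning("all simulated events fell below the detection limit; ",
              "returning an empty event table")
    contrast <- instrument$contrast_slope * mass +
      instrument$contrast_intercept
    out <- data.frame(event_index = seq_along(mass),
                      contrast = contrast, mass_kda = mass)
    attr(out, "sample_id") <- sample_id
    attr(out, "dilution_factor") <- dilution_factor
    attr(out, "nominal_receptor_total") <- nominal_receptor_total
    attr(out, "nominal_ligand_total") <- nominal_ligand_total
    class(out) <- c("event_table", class(out))
    out
  })
}

#' Simulate a full binding titration
#'
#' For each titrated ligand concentration the true bound fraction is
#' `f* = a_true + (b_true - a_true) * f_eq`, with `f_eq` the exact
#' depletion-aware mass-action occupancy from
#' [equilibrium_fraction_bound()]. Receptor-population events are split
#' between the free receptor mass and the receptor+ligand complex mass with
#' weights `(1 - f*, f*)`; free-ligand events are included in proportion to
#' the free ligand concentration but are censored by the instrument's
#' detection floor (a ~30 kDa ligand is invisible under the 40 kDa default).
#'
#' @param truth a [binding_truth] record.
#' @param receptor_mass receptor particle mass in kDa.
#' @param ligand_mass ligand mass in kDa.
#' @param instrument an [instrument_model].
#' @param n_events fixed event count per condition, or `NULL` for Poisson
#'   counts.
#' @param dilution_factor dilution applied just before measurement. The
#'   default 11 reflects diluting a 2 uL aliquot of the binding mixture into
#'   20 uL of clean buffer (22/2). It thins the expected event count only;
#'   equilibrium fractions are taken to survive the dilution on the
#'   measurement timescale (valid for slow off-rates).
#' @return A list with `tables` (one `event_table` per ligand concentration),
#'   `truth` (the input record) and `true_fractions` (the per-condition
#'   ground-truth bound fractions).
#' @export
simulate_titration <- function(truth, receptor_mass, ligand_mass, instrument,
                               n_events = NULL, dilution_factor = 11) {
  stopifnot(inherits(truth, "binding_truth"),
            is.finite(receptor_mass), receptor_mass > 0,
            is.finite(ligand_mass), ligand_mass > 0)
  f_eq <- equilibrium_fraction_bound(truth$receptor_total,
                                     truth$ligand_totals, truth$kd_true)
  f_star <- truth$a_true + (truth$b_true - truth$a_true) * f_eq
  free_ligand <- truth$ligand_totals - f_star * truth$receptor_total
  tables <- vector("list", length(truth$ligand_totals))
  for (i in seq_along(truth$ligand_totals)) {
    w <- c(1 - f_star[i], f_star[i],
           max(free_ligand[i], 0) / truth$receptor_total)
    keep <- w > 0
    sp <- species_spec(
      c("receptor", "complex", "free_ligand")[keep],
      c(receptor_mass, receptor_mass + ligand_mass, ligand_mass)[keep],
      w[keep])
    tables[[i]] <- simulate_sample(
      sp, instrument, n_events = n_events,
      seed = truth$seed + i,
      sample_id = sprintf("L%03d", i),
      dilution_factor = dilution_factor,
      nominal_receptor_total = truth$receptor_total,
      nominal_ligand_total = truth$ligand_totals[i])
  }
  list(tables = tables, truth = truth, true_fractions = f_star)
}

#' Write / read an event table as CSV with a JSON metadata sidecar
#'
#' The CSV carries the columns `event_index`, `contrast`, `mass_kda`; sample
#' metadata (id, dilution factor, nominal concentrations) goes to
#' `<path>.json`.
#'
#' @param events an `event_table`.
#' @param path CSV file path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns the reconstructed `event_table`.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("event_index", "contrast",
                                             "mass_kda")],
                   path, row.names = FALSE)
  meta <- list(sample_id = attr(events, "sample_id"),
               dilution_factor = attr(events, "dilution_factor"),
               nominal_receptor_total = attr(events, "nominal_receptor_total"),
               nominal_ligand_total = attr(events, "nominal_ligand_total"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("event_index", "contrast") %in% names(out)))
  if (is.null(out$mass_kda)) out$mass_kda <- NA_real_
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  grab <- function(key, default) {
    v <- meta[[key]]
    if (is.null(v)) default else v
  }
  attr(out, "sample_id") <- grab("sample_id", basename(path))
  attr(out, "dilution_factor") <- grab("dilution_factor", 1)
  attr(out, "nominal_receptor_total") <- as.numeric(
    grab("nominal_receptor_total", NA_real_))
  attr(out, "nominal_ligand_total") <- as.numeric(
    grab("nominal_ligand_total", NA_real_))
  class(out) <- c("event_table", class(out))
  out
}
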