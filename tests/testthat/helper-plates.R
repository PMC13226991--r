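# Builders for exact (noise-free) synthetic plates used across tests.

# One plate whose tracks follow g * f(conc) exactly.
exact_plate <- function(curve, plate_id = "P1", g = 1,
                        levels = c(62.5, 125, 250, 500, 1000),
                        sample_conc = c(200, 400, 700),
                        replicates = 1) {
  f <- function(conc) curve$a2 * conc^2 + curve$a1 * conc + curve$a0
  standards <- tibble::tibble(
    plate_id = plate_id, kind = "standard",
    id = sprintf("L%g", levels),
    concentration = levels,
    peak_area = g * f(levels),
    rf = NA_real_
  )
  samples <- NULL
  if (length(sample_conc) > 0) {
    samples <- tibble::tibble(
      plate_id = plate_id, kind = "sample",
      id = rep(sprintf("%s-S%d", plate_id, seq_along(sample_conc)),
        each = replicates
      ),
      concentration = NA_real_,
      peak_area = rep(g * f(sample_conc), each = replicates),
      rf = 0.58
    )
  }
  plate_table(dplyr::bind_rows(standards, samples))
}

# A linear response curve (zero quadratic term) for exactness tests.
linear_curve <- function(b = 2e-5, conc_range = c(62.5, 2000)) {
  calibration_curve(a2 = 0, a1 = b, a0 = 0, conc_range = conc_range)
}

# Hand-built simulated_study wrapper so strategy scoring can run on exact
# plates with known g and truth.
exact_study <- function(curve, gs, sample_conc = c(200, 400, 700),
                        levels = c(62.5, 125, 250, 500, 1000)) {
  plates <- purrr::imap(gs, function(g, i) {
    exact_plate(curve,
      plate_id = sprintf("P%02d", i), g = g,
      levels = levels, sample_conc = sample_conc
    )
  }) |> purrr::list_rbind()
  truth <- purrr::imap(gs, function(g, i) {
    tibble::tibble(
      plate_id = sprintf("P%02d", i),
      sample_id = sprintf("P%02d-S%d", i, seq_along(sample_conc)),
      true_conc = sample_conc, g = g
    )
  }) |> purrr::list_rbind()
  structure(
    list(
      plates = plate_table(plates), truth = truth,
      plate_effects = tibble::tibble(
        plate_id = sprintf("P%02d", seq_along(gs)), g = gs
      ),
      config = NULL
    ),
    class = "simulated_study"
  )
}
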