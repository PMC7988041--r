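#' Load a bundled cohort table
#'
#' The package ships the two study cohort tables verbatim: per-subject
#' maximum CSF pressures in the subarachnoid space (SAS) and cerebral
#' aqueduct (CA) under boundary-condition schemes A/B/C, compartment
#' volumes, and (patients only) the invasively measured intracranial
#' pressure, which is available for patients 1-10 and missing (`NA`) for
#' patient 11.  Values are stored exactly as printed.
#'
#' @param which `"healthy"` (8 subjects) or `"patient"` (11 subjects).
#' @return A `csf_cohort` tibble in long format with columns `group`,
#'   `subject`, `variable`, `unit`, `value`.
#' @examples
#' tab <- load_cohort_fixture("patient")
#' dplyr::filter(tab, variable == "ventricular_volume")
#' @export
load_cohort_fixture <- function(which = c("healthy", "patient")) {
  which <- match.arg(which)
  path <- extdata_path(paste0("cohort_", which, ".csv"))
  raw <- readr::read_csv(path, col_types = readr::cols(
    variable = readr::col_character(),
    unit = readr::col_character(),
    .default = readr::col_double()
  ))
  expect_n <- if (which == "healthy") 8L else 11L
  subj_cols <- setdiff(names(raw), c("variable", "unit"))
  if (length(subj_cols) != expect_n) {
    abort(sprintf("corrupt fixture '%s': expected %d subject columns, found %d.",
                  path, expect_n, length(subj_cols)))
  }
  long <- tidyr::pivot_longer(raw, cols = dplyr::all_of(subj_cols),
                              names_to = "subject", values_to = "value")
  out <- dplyr::transmute(long,
    group = which,
    subject = sub("^s", paste0(substr(which, 1, 1), "_"), .data$subject),
    variable = .data$variable,
    unit = .data$unit,
    value = .data$value
  )
  new_cohort_table(out)
}

new_cohort_table <- function(x) {
  stopifnot(all(c("group", "subject", "variable", "unit", "value") %in% names(x)))
  counts <- dplyr::count(dplyr::distinct(x, .data$variable, .data$subject), .data$variable)
  if (length(unique(counts$n)) != 1L) {
    abort("cohort table is ragged: variables cover different subject sets.")
  }
  class(x) <- c("csf_cohort", setdiff(class(x), "csf_cohort"))
  x
}

#' Load the printed summary cells for a bundled cohort table
#'
#' The Mean / SD / SE / CV / 95% CI columns of the cohort tables, exactly as
#' printed, used by the full-table regression check that recomputes every
#' cell from the per-subject rows.
#'
#' @inheritParams load_cohort_fixture
#' @return Tibble with columns `variable`, `mean`, `sd`, `se`, `cv_percent`,
#'   `ci_lower`, `ci_upper`.
#' @export
load_printed_summary <- function(which = c("healthy", "patient")) {
  which <- match.arg(which)
  readr::read_csv(extdata_path(paste0("printed_summary_", which, ".csv")),
                  col_types = readr::cols(variable = readr::col_character(),
                                          .default = readr::col_double()))
}

#' Load the bundled mesh-convergence table
#'
#' Maximum SAS pressure, maximum CA pressure and maximum CA velocity of the
#' eleven patients on coarse/medium/fine computational grids, plus the
#' fine-grid element counts.  Shipped for reference; the reduced-order
#' solver in this package has no spatial mesh.
#'
#' @return Long tibble with columns `quantity`, `unit`, `grid`, `patient`,
#'   `value`.
#' @export
load_mesh_convergence <- function() {
  raw <- readr::read_csv(extdata_path("mesh_convergence.csv"),
                         col_types = readr::cols(
                           quantity = readr::col_character(),
                           unit = readr::col_character(),
                           grid = readr::col_character(),
                           .default = readr::col_double()
                         ))
  long <- tidyr::pivot_longer(raw, cols = dplyr::starts_with("p"),
                              names_to = "patient", values_to = "value")
  dplyr::mutate(long, patient = as.integer(sub("^p", "", .data$patient)))
}

load_reynolds_printed <- function() {
  readr::read_csv(extdata_path("reynolds_printed.csv"),
                  col_types = readr::cols(group = readr::col_character(),
                                          scheme = readr::col_character(),
                                          .default = readr::col_double()))
}

load_printed_claims <- function() {
  readr::read_csv(extdata_path("printed_claims.csv"),
                  col_types = readr::cols(claim = readr::col_character(),
                                          printed = readr::col_double(),
                                          digits = readr::col_integer(),
                                          category = readr::col_character()))
}

#' Extract one variable of a cohort table as a numeric vector
#'
#' @param cohort A `csf_cohort` tibble.
#' @param variable Variable name, e.g. `"max_pressure_SAS_BC_C"`.
#' @param drop_missing Drop `NA` cells (e.g. the unmeasured patient-11 ICP)?
#' @return Named numeric vector (names are subject ids, in table order).
#' @export
cohort_values <- function(cohort, variable, drop_missing = FALSE) {
  rows <- dplyr::filter(cohort, .data$variable == !!variable)
  if (nrow(rows) == 0) {
    abort(sprintf("cohort table has no variable named '%s'.", variable))
  }
  out <- setNames(rows$value, rows$subject)
  if (drop_missing) out <- out[!is.na(out)]
  out
}
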