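# broom-style tidiers for the package's result objects

#' Tidy a simulation into long format
#'
#' @param x A `csf_sim`.
#' @param last_cycle_only Restrict to the reporting cycle?
#' @param ... Unused.
#' @return Long tibble: `time`, `series`, `value`.
#' @export
tidy.csf_sim <- function(x, last_cycle_only = FALSE, ...) {
  s <- if (last_cycle_only) last_cycle(x) else x$series
  tidyr::pivot_longer(s, cols = -"time", names_to = "series",
                      values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x A `csf_sim`.
#' @param ... Unused.
#' @export
glance.csf_sim <- function(x, ...) {
  lc <- last_cycle(x)
  tibble(
    scheme = x$scheme, mode = x$mode, group = x$group, dt = x$dt,
    n_cycles = x$n_cycles,
    peak_P_sas = max(lc$P_sas), peak_P_ventricle = max(lc$P_ventricle),
    peak_Q_aqueduct = max(abs(lc$Q_aqueduct)),
    cycle_periodicity = x$cycle_periodicity,
    max_mass_residual = x$max_mass_residual
  )
}

#' @export
tidy.csf_claims <- function(x, ...) as_tibble(x)

#' One-row summary of a claims report
#'
#' @param x A `csf_claims` tibble.
#' @param ... Unused.
#' @export
glance.csf_claims <- function(x, ...) {
  tibble(
    n_claims = nrow(x),
    n_hard = sum(x$category == "hard"),
    n_hard_pass = sum(x$pass & x$category == "hard"),
    n_discordant = sum(x$category == "discordant"),
    all_hard_pass = all(x$pass[x$category == "hard"])
  )
}

#' @export
tidy.csf_reproduction <- function(x, ...) x$claims

#' @export
glance.csf_reproduction <- function(x, ...) {
  dplyr::mutate(glance(x$claims), ok = x$ok,
                n_cells_checked = x$n_cells_checked,
                n_cells_match = sum(x$cells$match[!x$cells$known_misprint]))
}

#' @export
print.csf_reproduction <- function(x, ...) {
  cat(sprintf("Cohort-table reproduction: %s\n",
              if (x$ok) "all checks pass" else "FAILURES present"))
  cat(sprintf("  summary cells recomputed: %d (all match: %s)\n",
              x$n_cells_checked,
              all(x$cells$match[!x$cells$known_misprint])))
  g <- glance(x$claims)
  cat(sprintf("  claims: %d total, %d hard (%d pass), %d discordant with the printed tables\n",
              g$n_claims, g$n_hard, g$n_hard_pass, g$n_discordant))
  invisible(x)
}
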