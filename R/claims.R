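#' Recompute every printed summary cell of the bundled cohort tables
#'
#' Full-table regression: for every variable of both cohort tables the
#' mean, SD, SE, CV and 95% CI are recomputed from the per-subject rows
#' and compared with the printed summary cells at one unit of the last
#' printed decimal (rounding half up).  The patients' experimental-ICP CI
#' cells print the mean in both positions — a typesetting defect of the
#' source table (a t-based CI from the printed rows is (2553.5, 2723.5)) —
#' and are flagged with `known_misprint = TRUE`.
#'
#' @param tol Tolerance, in units of the last printed decimal (default 1).
#' @return Tibble with one row per (group, variable, statistic):
#'   `recomputed`, `printed`, `match`, `known_misprint`.
#' @export
table_regression <- function(tol = 1) {
  stats_cols <- c("mean", "sd", "se", "cv_percent", "ci_lower", "ci_upper")
  purrr::map_dfr(c("healthy", "patient"), function(which) {
    cohort <- load_cohort_fixture(which)
    printed <- load_printed_summary(which)
    desc <- cohort_descriptives(cohort)
    joined <- dplyr::inner_join(desc, printed, by = "variable",
                                suffix = c("_rec", "_prn"))
    purrr::map_dfr(stats_cols, function(stat) {
      rec <- joined[[paste0(stat, "_rec")]]
      prn <- joined[[paste0(stat, "_prn")]]
      tibble(
        group = which, variable = joined$variable, statistic = stat,
        recomputed = rec, printed = prn,
        match = abs(round_half_up(rec, 1) - prn) <= tol * 0.1 + 1e-9,
        known_misprint = which == "patient" &
          joined$variable == "experimental_ICP_SAS" &
          stat %in% c("ci_lower", "ci_upper")
      )
    })
  })
}

#' Recompute the derived cohort claims from the bundled tables
#'
#' Every derived in-text quantity of the boundary-condition comparison is
#' recomputed from its defined inputs and checked against the printed
#' value at the printed precision (round half up; tolerance one unit in
#' the last printed digit):
#' * volume ratios and percent changes between group means;
#' * patient/healthy ratios of mean maximum CSF pressure per scheme and
#'   site;
#' * Reynolds-number group differences from the printed group means (the
#'   per-subject Reynolds data are not part of the printed tables);
#' * agreement between simulated and invasively measured SAS pressure as
#'   `|mean_sim - mean_exp| / mean_exp` (simulated mean over all 11
#'   patients, measured mean over the 10 instrumented patients — the
#'   group-mean reading, the only one consistent with the printed
#'   percentages);
#' * Pearson correlations between maximum SAS pressure and ventricular
#'   volume across patients, and their relative reductions versus
#'   scheme C.
#'
#' Claim categories: `"hard"` claims must reproduce; the scheme-A
#' ICP-agreement figure sits exactly on a rounding boundary and is
#' `"borderline"`; the printed correlation values cannot be recomputed
#' from the printed table rows under any reading (see the methods
#' vignette) and are `"discordant"` — reported, but excluded from the
#' reproduction verdict.
#'
#' @param table_healthy,table_patient Cohort tables (default: the bundled
#'   fixtures).
#' @return A `csf_claims` tibble: `claim`, `recomputed`, `printed`,
#'   `category`, `pass`, `inputs`.
#' @export
claims_report <- function(table_healthy = load_cohort_fixture("healthy"),
                          table_patient = load_cohort_fixture("patient")) {
  h <- function(v) cohort_values(table_healthy, v)
  p <- function(v) cohort_values(table_patient, v)
  re_printed <- load_reynolds_printed()
  re_mean <- function(grp, sch) {
    re_printed$mean[re_printed$group == grp & re_printed$scheme == sch]
  }
  vent_h <- mean(h("ventricular_volume")); vent_p <- mean(p("ventricular_volume"))
  brain_h <- mean(h("brain_volume")); brain_p <- mean(p("brain_volume"))
  sas_h <- mean(h("sas_volume")); sas_p <- mean(p("sas_volume"))
  icp <- p("experimental_ICP_SAS")
  icp_mean <- mean(icp, na.rm = TRUE)

  rows <- list(
    list("ventricular_volume_ratio", vent_p / vent_h,
         "group means of ventricular volume (patient / healthy)"),
    list("brain_volume_reduction_pct", 100 * (brain_h - brain_p) / brain_h,
         "group means of brain-tissue volume"),
    list("sas_volume_increase_pct", 100 * (sas_p - sas_h) / sas_h,
         "group means of SAS volume")
  )
  for (sch in c("A", "B", "C")) {
    rows <- c(rows, list(
      list(paste0("sas_pressure_ratio_BC_", sch),
           mean(p(paste0("max_pressure_SAS_BC_", sch))) /
             mean(h(paste0("max_pressure_SAS_BC_", sch))),
           sprintf("per-subject max SAS pressure rows, scheme %s", sch)),
      list(paste0("ca_pressure_ratio_BC_", sch),
           mean(p(paste0("max_pressure_CA_BC_", sch))) /
             mean(h(paste0("max_pressure_CA_BC_", sch))),
           sprintf("per-subject max CA pressure rows, scheme %s", sch)),
      list(paste0("reynolds_group_diff_BC_", sch, "_pct"),
           100 * (re_mean("patient", sch) - re_mean("healthy", sch)) /
             re_mean("healthy", sch),
           sprintf("printed group-mean Reynolds numbers, scheme %s", sch)),
      list(paste0("icp_agreement_BC_", sch, "_pct"),
           100 * abs(mean(p(paste0("max_pressure_SAS_BC_", sch))) - icp_mean) /
             icp_mean,
           sprintf("simulated SAS pressure (n=11) vs measured ICP (n=10), scheme %s", sch))
    ))
  }
  vent <- p("ventricular_volume")
  r <- vapply(c("A", "B", "C"), function(sch) {
    pearson_correlation(p(paste0("max_pressure_SAS_BC_", sch)), vent)$r
  }, numeric(1))
  rows <- c(rows,
    purrr::map(c("A", "B", "C"), function(sch) {
      list(paste0("pcc_BC_", sch), r[[sch]],
           sprintf("max SAS pressure scheme %s vs ventricular volume, n=11", sch))
    }),
    list(
      list("pcc_reduction_BC_A_pct", 100 * (r[["C"]] - r[["A"]]) / r[["C"]],
           "Pearson r of schemes A and C"),
      list("pcc_reduction_BC_B_pct", 100 * (r[["C"]] - r[["B"]]) / r[["C"]],
           "Pearson r of schemes B and C")
    ))

  rec <- tibble(
    claim = purrr::map_chr(rows, 1),
    recomputed = purrr::map_dbl(rows, 2),
    inputs = purrr::map_chr(rows, 3)
  )
  printed <- load_printed_claims()
  out <- dplyr::inner_join(rec, printed, by = "claim") |>
    dplyr::mutate(
      pass = abs(round_half_up(.data$recomputed, .data$digits) - .data$printed) <=
        10^(-.data$digits) + 1e-9
    ) |>
    dplyr::select("claim", "recomputed", "printed", "digits", "category",
                  "pass", "inputs")
  class(out) <- c("csf_claims", class(out))
  out
}

#' Reproduce the cohort claims from the bundled tables
#'
#' Runs the full-table regression and the claims report and combines them
#' into a single reproduction verdict: `ok` is TRUE when every recomputed
#' summary cell matches (outside the known misprint) and every `"hard"`
#' claim passes.  Optionally writes the report as JSON.
#'
#' @param out Optional path for a JSON report.
#' @return A `csf_reproduction` list: `claims`, `cells`, `ok`,
#'   `n_cells_checked`, `manifest`.
#' @export
reproduce_claims <- function(out = NULL) {
  cells <- table_regression()
  claims <- claims_report()
  ok <- all(cells$match[!cells$known_misprint]) &&
    all(claims$pass[claims$category == "hard"])
  res <- structure(list(
    claims = claims, cells = cells, ok = ok,
    n_cells_checked = sum(!cells$known_misprint),
    manifest = run_manifest(inputs = c(
      extdata_path("cohort_healthy.csv"), extdata_path("cohort_patient.csv"),
      extdata_path("printed_summary_healthy.csv"),
      extdata_path("printed_summary_patient.csv"),
      extdata_path("reynolds_printed.csv"), extdata_path("printed_claims.csv")
    ))
  ), class = "csf_reproduction")
  if (!is.null(out)) {
    jsonlite::write_json(
      list(ok = res$ok, n_cells_checked = res$n_cells_checked,
           claims = claims, cells_failing = dplyr::filter(cells, !.data$match),
           manifest = unclass(res$manifest)),
      out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}
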