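# Run-configuration files: YAML with sections subject / material / bc /
# solver.  Unknown keys are rejected so typos fail loudly; omitted keys get
# the documented defaults (notably dt = 0.01 s, n_cycles = 5, period = 1 s,
# and the standard brain-tissue material parameters).

config_schema <- function() {
  list(
    subject = c("id", "group", "ventricular_volume_ml", "brain_volume_ml",
                "sas_volume_ml", "aqueduct_radius_m", "aqueduct_length_m",
                "baseline_pressure_pa"),
    material = c("elastic_modulus", "poisson_ratio", "prony_g", "prony_tau",
                 "void_ratio", "permeability"),
    bc = c("scheme", "mean_inflow_ml_min", "outlet_means_ml_min",
           "pulsatile_amplitude_m3s", "period"),
    solver = c("dt", "n_cycles", "mode", "sas_compliance", "r_out", "r_prod",
               "darcy_leak", "leak_path_length", "leak_path_area")
  )
}

#' Load and validate a simulation configuration
#'
#' @param path Path to a YAML file with (optional) sections `subject`,
#'   `material`, `bc`, `solver`.  `bc$scheme` is required and must be one of
#'   `"A"`, `"B"`, `"C"`; every other key is optional and filled with its
#'   default.  Unknown keys raise an error naming them.
#' @return A named list of class `csf_config` with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

validate_config <- function(raw) {
  raw <- raw %||% list()
  schema <- config_schema()
  bad_sections <- setdiff(names(raw), names(schema))
  if (length(bad_sections) > 0) {
    abort(sprintf("unknown config section(s): %s.", paste(bad_sections, collapse = ", ")))
  }
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(bad) > 0) {
      abort(sprintf("unknown key(s) in section '%s': %s.",
                    sec, paste(bad, collapse = ", ")))
    }
  }
  bc <- raw$bc %||% list()
  if (is.null(bc$scheme)) {
    abort("missing required key: bc.scheme (one of \"A\", \"B\", \"C\").")
  }
  if (!bc$scheme %in% c("A", "B", "C")) {
    abort(sprintf("bc.scheme = \"%s\" is not allowed; must be one of {A, B, C}.",
                  bc$scheme))
  }
  solver <- raw$solver %||% list()
  material <- raw$material %||% list()
  subject <- raw$subject %||% list()
  cfg <- list(
    subject = utils::modifyList(list(
      id = "subject_1", group = "healthy",
      ventricular_volume_ml = 20.3, brain_volume_ml = 1297.0,
      sas_volume_ml = 105.9, aqueduct_radius_m = 1.0e-3,
      aqueduct_length_m = 15e-3, baseline_pressure_pa = NA_real_
    ), subject),
    material = do.call(material_model, material),
    bc = utils::modifyList(list(
      scheme = bc$scheme, mean_inflow_ml_min = 0.35,
      outlet_means_ml_min = c(0.18, 0.17),
      pulsatile_amplitude_m3s = 1e-7, period = 1
    ), bc),
    solver = utils::modifyList(list(
      dt = 0.01, n_cycles = 5L, mode = "FSI", sas_compliance = 1e-9,
      r_out = 1.1e10, r_prod = 1e10, darcy_leak = FALSE,
      leak_path_length = 0.05, leak_path_area = 1e-3
    ), solver)
  )
  if (!cfg$subject$group %in% c("healthy", "patient")) {
    abort("subject.group must be \"healthy\" or \"patient\".")
  }
  if (is.na(cfg$subject$baseline_pressure_pa)) {
    cfg$subject$baseline_pressure_pa <- outlet_pressure(cfg$subject$group)
  }
  check_number(cfg$solver$dt, "solver.dt", lower = 0, strict_lower = TRUE)
  check_number(cfg$bc$period, "bc.period", lower = 0, strict_lower = TRUE)
  structure(cfg, class = "csf_config")
}
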