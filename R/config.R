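# Structured run configuration (YAML): geometry, charge, basis, cavity and
# algorithm settings, mirroring the command-line tool's input contract.

#' Load a run configuration file
#'
#' Reads a YAML configuration describing a complete calculation. Required
#' keys: `geometry` (XYZ path, resolved relative to the config file),
#' `basis`, `coupling` (lambda, a.u.), `frequency_ev`, `polarization`
#' (length-3 unit vector). Optional: `charge` (default 0), `algorithm`
#' (default "tr-nr"), `energy_threshold`, `gradient_threshold`,
#' `max_iterations`, `diis_dim`, `eta_step`, `trust_radius_init`.
#'
#' @param path path to the YAML file.
#' @return list with `molecule`, `cavity`, `algorithm`, `control`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  req <- c("geometry", "basis", "coupling", "frequency_ev", "polarization")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stop("config is missing required key(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(cfg$coupling) || cfg$coupling < 0) {
    stop("coupling must be a nonnegative number (a.u.)")
  }
  cav <- cavity(lambda = cfg$coupling, omega_ev = cfg$frequency_ev,
                polarization = cfg$polarization)
  geom <- cfg$geometry
  if (!file.exists(geom)) {
    geom2 <- file.path(dirname(path), geom)
    if (file.exists(geom2)) geom <- geom2
  }
  mol <- read_xyz(geom, charge = cfg$charge %||% 0L, basis = cfg$basis)
  algorithm <- cfg$algorithm %||% "tr-nr"
  if (!algorithm %in% c("tr-nr", "gb-dbi", "gb-diis")) {
    stop("unknown algorithm: ", algorithm)
  }
  ctrl_args <- cfg[intersect(names(cfg),
                             c("energy_threshold", "gradient_threshold",
                               "max_iterations", "diis_dim", "eta_step",
                               "trust_radius_init"))]
  control <- do.call(scf_control, ctrl_args)
  list(molecule = mol, cavity = cav, algorithm = algorithm, control = control)
}
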