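# Run configuration files (YAML or JSON), all values in clinical units:
#   ventilator: {pip, peep, rr, ie: [i, e]}
#   splitter:   {topology, r_i, r_e, r_v1, r_v2}
#   patients:   [ "A", {c_l: ..., r_l: ..., r_ett: ...}, ... ]

#' Read a run configuration file
#'
#' Parses a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration into the
#' package's domain objects.
#'
#' @param path configuration file path.
#' @return A list with elements `settings` ([ventilator_settings()]),
#'   `splitter` ([splitter_config()]) and `patients` (list of
#'   [lung_model()]s).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yml = ,
                yaml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                stop("unsupported config format: .", ext))
  vent <- cfg$ventilator %||% list()
  settings <- ventilator_settings(
    pip = vent$pip %||% 15, peep = vent$peep %||% 5,
    rr = vent$rr %||% 15, ie = unlist(vent$ie %||% c(1, 2)))
  spl <- cfg$splitter %||% list()
  splitter <- splitter_config(
    topology = spl$topology %||% "standard",
    r_i = spl$r_i %||% 0.06, r_e = spl$r_e %||% 0.06,
    r_v1 = spl$r_v1 %||% 0, r_v2 = spl$r_v2 %||% 0)
  patients <- lapply(cfg$patients %||% list("A", "A"), function(p) {
    if (is.character(p)) {
      lung_preset(p)
    } else {
      lung_model(c_l = p$c_l, r_l = p$r_l %||% 2, r_ett = p$r_ett %||% 8,
                 label = p$label %||% "custom")
    }
  })
  n_need <- if (splitter$topology == "single") 1L else 2L
  if (length(patients) < n_need) {
    stop("topology '", splitter$topology, "' needs ", n_need, " patient(s)")
  }
  list(settings = settings, splitter = splitter, patients = patients)
}

#' Build a netlist from a parsed configuration
#'
#' @param cfg a list as returned by [read_config()].
#' @return A [netlist()].
#' @export
build_from_config <- function(cfg) {
  build_splitter(cfg$patients[[1]],
                 if (length(cfg$patients) > 1) cfg$patients[[2]],
                 cfg$splitter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
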