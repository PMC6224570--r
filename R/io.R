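#' Read a run configuration (TOML subset or JSON)
#'
#' Configuration units are fixed at the interface: photon energy in eV, g
#' and dipoles in au, times in fs (sampling windows in ps), angles in
#' degrees. JSON is parsed with jsonlite; TOML support covers the subset
#' needed for flat run configurations: `[section]` headers,
#' `key = value` pairs with numbers, booleans, quoted strings, and inline
#' arrays.
#'
#' @param path configuration file (`.json`, `.toml`, or content-sniffed).
#' @return nested named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE) ||
    grepl("^\\s*\\{", paste(txt, collapse = ""))
  if (is_json) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
  } else {
    parse_toml_subset(txt)
  }
}

parse_toml_subset <- function(lines) {
  out <- list()
  section <- NULL
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    m <- regmatches(line, regexec("^\\[([A-Za-z0-9_.-]+)\\]$", line))[[1]]
    if (length(m) == 2) {
      section <- m[2]
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$",
                                   line))[[1]]
    if (length(kv) != 3)
      stop("cannot parse TOML line: ", raw)
    val <- parse_toml_value(trimws(kv[3]))
    if (is.null(section)) out[[kv[2]]] <- val
    else out[[section]][[kv[2]]] <- val
  }
  out
}

parse_toml_value <- function(s) {
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(substr(s, 2, nchar(s) - 1))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(trimws(parts), parse_toml_value)))
  }
  if (grepl('^".*"$', s)) return(substr(s, 2, nchar(s) - 1))
  if (s %in% c("true", "false")) return(s == "true")
  x <- suppressWarnings(as.numeric(s))
  if (!is.na(x)) return(x)
  s
}

#' Validate and resolve a run configuration
#'
#' Fills defaults, checks required keys, and returns the fully resolved
#' configuration (which every run writes next to its outputs for
#' reproducibility).
#'
#' @param cfg list from [read_config()] (or built in code).
#' @return resolved configuration list with class `polhop_config`.
#' @export
resolve_config <- function(cfg) {
  bad <- character()
  model_name <- cfg$model$name
  if (is.null(model_name)) bad <- c(bad, "model.name")
  cav <- cfg$cavity
  if (is.null(cav$photon_energy_ev)) bad <- c(bad, "cavity.photon_energy_ev")
  if (is.null(cav$g)) bad <- c(bad, "cavity.g")
  if (length(bad))
    stop("config schema error; missing keys: ", paste(bad, collapse = ", "))
  defaults <- list(
    cavity = list(polarization = c(0, 0, 1), n_photon = 2),
    sampling = list(temperature_K = 300, total_time_ps = 10,
                    equilibration_ps = 1, stride_fs = 10, tau_fs = 100,
                    dt_fs = 0.5),
    simulation = list(dt_fs = 0.1, t_total_fs = 300, n_trajectories = 300,
                      decoherence = TRUE, decoherence_alpha_ha = 0.1,
                      drift_tol_ev = 0.5),
    losses = list(tau_c_fs = c(10, 50, 100), replicas = 5),
    seed = 1,
    output_dir = "polhop-out")
  merged <- utils::modifyList(defaults, cfg)
  structure(merged, class = c("polhop_config", "list"))
}

#' Instantiate objects from a resolved configuration
#'
#' @param cfg a resolved `polhop_config`.
#' @return list with `model`, `cavity`, `sampling`, `simulation` objects.
#' @export
config_objects <- function(cfg) {
  margs <- cfg$model$params
  model <- if (is.null(margs)) polhop_model(cfg$model$name)
           else do.call(polhop_model, c(list(cfg$model$name), as.list(margs)))
  cavity <- cavity_mode(cfg$cavity$photon_energy_ev, cfg$cavity$g,
                        cfg$cavity$polarization,
                        n_photon = cfg$cavity$n_photon)
  sampling <- thermal_sampling_settings(
    temperature_K = cfg$sampling$temperature_K,
    total_time_ps = cfg$sampling$total_time_ps,
    equilibration_ps = cfg$sampling$equilibration_ps,
    stride_fs = cfg$sampling$stride_fs, tau_fs = cfg$sampling$tau_fs,
    dt_fs = cfg$sampling$dt_fs, seed = cfg$seed)
  simulation <- simulation_settings(
    dt_fs = cfg$simulation$dt_fs, t_total_fs = cfg$simulation$t_total_fs,
    decoherence = isTRUE(cfg$simulation$decoherence),
    decoherence_alpha = cfg$simulation$decoherence_alpha_ha,
    drift_tol_ev = cfg$simulation$drift_tol_ev, seed = cfg$seed)
  list(model = model, cavity = cavity, sampling = sampling,
       simulation = simulation)
}

#' Write a table as CSV with a unit-comment header
#'
#' @param df data frame; `path` output file; `comment` header line.
#' @export
write_table_csv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path file path.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write / read sampled phase points
#'
#' CSV with columns `theta_deg, alpha_deg, p_theta, p_alpha` (or generic
#' `q*/p*` for other models).
#'
#' @param points data frame from [thermal_sample()]; `path` file path.
#' @name phase_points_io
#' @export
write_phase_points <- function(points, path) {
  write_table_csv(points, path,
                  comment = "phase points: angles deg, momenta au")
}

#' @rdname phase_points_io
#' @export
read_phase_points <- function(path) read_table_csv(path)

#' Write the resolved configuration beside the outputs
#'
#' @param cfg resolved config; `dir` output directory.
#' @export
write_resolved_config <- function(cfg, dir) {
  path <- file.path(dir, "config-resolved.json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
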