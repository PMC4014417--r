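#' Load a validated parameter bundle from a config file
#'
#' The config is YAML (JSON is valid YAML) with up to four top-level
#' sections: `mech` (fields of [mech_params()]), `adhesion`
#' ([adhesion_params()]), `protocol` ([clamp_protocol()]) and `motor`
#' ([motor_model()]). Missing sections and fields take the documented
#' defaults; unknown sections or keys are errors (no silent typos), as are
#' invariant violations, with the offending key named.
#'
#' @param path Path to a YAML/JSON config file. An empty file yields all
#'   defaults.
#' @return A `param_bundle` list with elements `mech`, `adhesion`,
#'   `protocol`, `motor`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("mech", "adhesion", "protocol", "motor")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("load_config: unknown section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  build <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    if (length(bad)) {
      stop("load_config: unknown key(s) in `", section, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(fn, args)
  }
  mech <- build("mech", mech_params)
  adh_args <- raw$adhesion
  if (is.null(adh_args)) adh_args <- list()
  if (is.null(adh_args$n_nodes)) adh_args$n_nodes <- mech$n_nodes
  bad <- setdiff(names(adh_args), names(formals(adhesion_params)))
  if (length(bad)) {
    stop("load_config: unknown key(s) in `adhesion`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- list(
    mech = mech,
    adhesion = do.call(adhesion_params, adh_args),
    protocol = build("protocol", clamp_protocol),
    motor = build("motor", motor_model)
  )
  class(out) <- "param_bundle"
  out
}

#' Write a parameter bundle back to YAML
#'
#' `load_config(dump_config(b, path))` reproduces `b` (round-trip identity).
#'
#' @param bundle A `param_bundle` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(bundle, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(list(mech = strip(bundle$mech),
                        adhesion = strip(bundle$adhesion),
                        protocol = strip(bundle$protocol),
                        motor = strip(bundle$motor)), path, precision = 15)
  invisible(path)
}

#' Write a tidy CSV table
#'
#' Deterministic column order (as given), UTF-8, `.` decimal separator;
#' an empty table yields a header-only file.
#'
#' @param rows A data frame / tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the parameter snapshot, seed, package version, timestamps and
#' output files of a run, so the run can be reproduced bit-for-bit.
#'
#' @param path Output JSON path.
#' @param config Parameter snapshot (any list; e.g. a `param_bundle`).
#' @param seed Integer seed used for the run.
#' @param outputs Character vector of output file paths.
#' @param started POSIXct start time.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs = character(),
                           started = Sys.time()) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  manifest <- list(
    package = "glidemech",
    version = as.character(utils::packageVersion("glidemech")),
    seed = seed,
    config = strip(config),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
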