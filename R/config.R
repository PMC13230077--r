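#' Load a model configuration file
#'
#' Reads a YAML configuration with two top-level blocks: `parameters`
#' (one entry per model input, each a mapping with keys `base`, `low`,
#' `high`, `distribution`, `role`) and `settings` (any of the arguments of
#' [default_settings()]). Keys omitted from either block fall back to the
#' packaged defaults, so a config need only state overrides. An optional
#' `metadata` block (free-form; e.g. the daily drug prices the annual
#' costs derive from) is returned as-is.
#'
#' The packaged default configuration, which spells out every input
#' explicitly, is at `system.file("extdata", "default_config.yaml",
#' package = "ezcua")`.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `parameters` (`"cua_parameters"`),
#'   `settings` (`"cua_settings"`) and `metadata` (list, possibly empty).
#' @examples
#' cfg <- load_config(system.file("extdata", "default_config.yaml",
#'                                package = "ezcua"))
#' cfg$parameters$p_mi_statin$base
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  defaults <- default_parameters()
  params <- defaults
  for (nm in names(raw$parameters)) {
    if (!nm %in% names(defaults)) {
      stop("configuration error: unknown parameter key '", nm, "'",
           call. = FALSE)
    }
    entry <- raw$parameters[[nm]]
    if (is.null(entry$base)) {
      stop("configuration error: parameter '", nm, "' is missing ",
           "mandatory key 'base'", call. = FALSE)
    }
    old <- defaults[[nm]]
    params[[nm]] <- parameter_spec(
      name = nm,
      base = entry$base,
      low = if (is.null(entry$low)) old$low else entry$low,
      high = if (is.null(entry$high)) old$high else entry$high,
      dist = if (is.null(entry$distribution)) old$dist else entry$distribution,
      role = if (is.null(entry$role)) old$role else entry$role)
  }
  validate_parameters(params)

  known <- names(formals(default_settings))
  extra <- setdiff(names(raw$settings), known)
  if (length(extra)) {
    stop("configuration error: unknown settings key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  settings <- do.call(default_settings, raw$settings %||% list())

  list(parameters = params, settings = settings,
       metadata = raw$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a parameter set to canonical CSV
#'
#' Writes the flat audit form of a parameter set (columns `name`, `base`,
#' `low`, `high`, `distribution`, `role`, canonical row order, 15
#' significant digits) so that loading and re-serialising a configuration
#' is byte-identical.
#'
#' @param params A `"cua_parameters"` object.
#' @param path Output file path, or `""` to return the CSV text invisibly
#'   without writing.
#' @return The CSV text, invisibly.
#' @export
write_parameters_csv <- function(params, path = "") {
  df <- as.data.frame(params)
  num <- vapply(df$base, format, character(1), digits = 15)
  lo <- vapply(df$low, format, character(1), digits = 15)
  hi <- vapply(df$high, format, character(1), digits = 15)
  lines <- c("name,base,low,high,distribution,role",
             paste(df$name, num, lo, hi, df$distribution, df$role, sep = ","))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (nzchar(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL)
  }
  invisible(txt)
}
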