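#' Read a clock model from a configuration file
#'
#' Reads a flat key-value configuration (JSON or YAML, chosen by file
#' extension) whose keys are the arguments of [clock_model()], merges it
#' over the package defaults, and returns the model. Keys absent from the
#' file keep their default values, so an empty file (or the `"defaults"`
#' preset) reproduces the reference parameter set exactly.
#'
#' @param path path to a `.json`, `.yaml`/`.yml` file, or the string
#'   `"defaults"` for the built-in preset.
#' @param ... named overrides applied on top of the file (highest
#'   precedence), e.g. from command-line flags.
#' @return A [clock_model()].
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' writeLines('{"alpha": 180, "N": 2}', cfg)
#' read_clock_config(cfg)
#' @export
read_clock_config <- function(path = "defaults", ...) {
  vals <- if (identical(path, "defaults")) list()
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else stop("config must be a .json or .yaml file, or \"defaults\"")
  if (!is.list(vals)) stop("config must be a flat key-value mapping")
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(clock_model))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown parameter(s) in config: ", paste(bad, collapse = ", "))
  do.call(clock_model, vals)
}
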