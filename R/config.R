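#' Example histone proteoform mixture
#'
#' A plausible asynchronous-cell mixture used by the CLI demo and the
#' examples: abundance falls steeply with acetyl degree (hyperacetylated
#' tails are rare) while the K4 methyl stoichiometry shifts towards higher
#' methyl states with increasing acetylation, the coupling the targeted
#' assay is designed to resolve.
#'
#' @return A [mixture_spec].
#' @export
example_mixture <- function() {
  pi <- rbind(
    c(92.0, 6.0, 1.5, 0.5),
    c(80.0, 14.0, 4.0, 2.0),
    c(65.0, 22.0, 9.0, 4.0),
    c(45.0, 30.0, 17.0, 8.0),
    c(30.0, 32.0, 24.0, 14.0),
    c(18.0, 27.0, 30.0, 25.0)) / 100
  mixture_spec(abundance = c(55, 25, 10, 5, 3, 2), pi = pi)
}

.default_config <- function() {
  list(
    acquisition = list(
      rt_windows = DEFAULT_RT_WINDOWS,
      ms1_range = DEFAULT_MS1_RANGE,
      ms2_range = DEFAULT_MS2_RANGE,
      scan_interval = 2, peak_width = 1,
      noise_cv = 0, baseline = 0, n_background = 20,
      include_ms1 = TRUE, isotope_envelope = FALSE),
    quant = list(prec_tol = 0.05, frag_tol = 0.3, snr_min = 3,
                 bin_width = 0.1, intensity_method = "max",
                 var_equal = TRUE, p_adjust = FALSE),
    kinetics = list(E_nM = 4, alpha = 0.05,
                    conversion_factor = 1, conversion_time_min = 1),
    dose = list(hook_frac = 0.1, F = c(50, 80)),
    seed = 1L,
    out_dir = ".")
}

.check_keys <- function(x, ref, path = "") {
  extra <- setdiff(names(x), names(ref))
  if (length(extra))
    stop("invalid config: unknown key(s) ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (k in names(x)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]]))
      .check_keys(x[[k]], ref[[k]], paste0(path, k, "."))
  }
}

.merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load a suite configuration from YAML
#'
#' Reads a YAML config, validates it (unknown keys are rejected; retention
#' windows and ranges must be well-formed), and fills every unset field
#' with the package default. An empty file yields all defaults, whose
#' acquisition values are the standard targeted scheme (RT windows per
#' acetyl degree, 585-640 MS1 and 470-530 MS2 scan ranges).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated `suite_config` list.
#' @seealso [save_config()]
#' @export
load_config <- function(path = NULL) {
  defaults <- .default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()     # empty file
  .check_keys(user, defaults)
  cfg <- .merge_config(defaults, user)
  # YAML does not distinguish integer from double; normalize so that a
  # config survives a save/load round trip unchanged
  cfg <- rapply(cfg, as.numeric, classes = "integer", how = "replace")
  if (!is.null(names(cfg$acquisition$rt_windows)))
    cfg$acquisition$rt_windows <-
      lapply(cfg$acquisition$rt_windows, as.numeric)
  # constructing the acquisition config validates windows and ranges
  do.call(acquisition_config, cfg$acquisition)
  if (cfg$quant$frag_tol <= 0 || cfg$quant$prec_tol <= 0 ||
      cfg$quant$bin_width <= 0)
    stop("invalid config: quant tolerances must be > 0", call. = FALSE)
  if (any(cfg$dose$F <= 0 | cfg$dose$F >= 100))
    stop("invalid config: dose.F values must be in (0, 100)", call. = FALSE)
  structure(cfg, class = "suite_config")
}

#' Save a suite configuration to YAML
#'
#' @param cfg a `suite_config` (from [load_config()]).
#' @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# acquisition_config from the nested suite config
.acq_from_config <- function(cfg) do.call(acquisition_config, cfg$acquisition)
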