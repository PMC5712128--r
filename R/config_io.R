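config_defaults <- function() {
  list(T = 40, C = 40, D = 20,
       k_g = 2e-3, r_g_scale = 2e-3, k_m_scale = 5e-3, k_p_scale = 1e-2,
       k_d_scale = 1e-3, r_d = 1e-1, r_m = 3e-3,
       loci = list(ori = list(L = 0, copies = 1), ter = list(L = 1, copies = 2)),
       seed = NULL, t_end_hours = 10, record_dt_s = 60,
       init = "symmetric", burnin_generations = 20)
}

#' Load (or build) a resolved run configuration
#'
#' Reads a YAML or JSON configuration, fills in the default kinetic
#' parametrization and default gene placement (one copy at ori, two at ter),
#' and validates. An empty or missing-file-free call returns the full default
#' configuration. Unknown keys are a hard error, as is a missing seed when
#' `require_seed` is set (stochastic commands refuse to run unseeded).
#'
#' @param path path to a `.yml`/`.yaml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @param overrides named list applied on top of the file (flags win).
#' @param require_seed error when the resolved config has no seed.
#' @return a list of class `toggle_config` with entries `cc`
#'   ([cell_cycle_params()]), `rc` ([rate_constants()]), `loci`, `seed`,
#'   `t_end_hours`, `record_dt_s`, `init`, `burnin_generations` and the raw
#'   resolved key set in `raw`.
#' @export
load_config <- function(path = NULL, overrides = list(),
                        require_seed = FALSE) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  for (k in names(overrides)) raw[[k]] <- overrides[[k]]
  def <- config_defaults()
  unknown <- setdiff(names(raw), c(names(def), "rg"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$rg)) { raw$r_g_scale <- rg_label(raw$rg); raw$rg <- NULL }
  cfg <- utils::modifyList(def, raw)
  for (g in c("ori", "ter")) {
    bad <- setdiff(names(cfg$loci[[g]]), c("L", "copies"))
    if (length(bad))
      stop("unknown config keys in loci ", g, ": ",
           paste(bad, collapse = ", "), " (use 'L' and 'copies')",
           call. = FALSE)
  }
  num_keys <- c("T", "C", "D", "k_g", "r_g_scale", "k_m_scale", "k_p_scale",
                "k_d_scale", "r_d", "r_m", "t_end_hours", "record_dt_s",
                "burnin_generations")
  for (k in num_keys)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || !is.finite(cfg[[k]]))
      stop(sprintf("config key '%s' must be a single finite number", k),
           call. = FALSE)
  if (require_seed && is.null(cfg$seed))
    stop("this command needs an explicit 'seed' in the config or flags",
         call. = FALSE)
  out <- list(
    cc = cell_cycle_params(cfg$T, cfg$C, cfg$D),
    rc = rate_constants(cfg$k_g, cfg$r_g_scale, cfg$k_m_scale, cfg$k_p_scale,
                        cfg$k_d_scale, cfg$r_d, cfg$r_m),
    loci = list(ori = locus_spec(cfg$loci$ori$L, cfg$loci$ori$copies),
                ter = locus_spec(cfg$loci$ter$L, cfg$loci$ter$copies)),
    seed = cfg$seed, t_end_hours = cfg$t_end_hours,
    record_dt_s = cfg$record_dt_s, init = cfg$init,
    burnin_generations = cfg$burnin_generations,
    raw = cfg)
  class(out) <- "toggle_config"
  out
}

#' Write a configuration back to disk
#'
#' Round-trips with [load_config()]: `load_config(write_config(cfg, f))`
#' resolves to the same configuration.
#'
#' @param config a `toggle_config` (or the raw key list).
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- if (inherits(config, "toggle_config")) config$raw else config
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run manifest
#'
#' Records the resolved configuration, seeds and output paths of a run so
#' that exact and deterministic outputs can be reproduced byte-identically.
#'
#' @param config a `toggle_config`.
#' @param seeds seeds used.
#' @param outputs named character vector of output paths.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, outputs = character(0)) {
  structure(list(
    config = if (inherits(config, "toggle_config")) config$raw else config,
    seeds = seeds,
    outputs = as.list(outputs),
    package_version = as.character(utils::packageVersion("growthtoggle")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write analysis results with their manifest
#'
#' Data frames go to CSV at full precision, everything else to JSON; the
#' manifest is written alongside as `<stem>_manifest.json` (without its
#' wall-clock stamp the payload files are reproducible from config + seed).
#'
#' @param results named list of data frames and/or scalar-report lists.
#' @param manifest a [run_manifest()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(results, manifest, dir = ".", stem = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, sprintf("%s_%s.csv", stem, nm))
      utils::write.csv(format(x, digits = 17, trim = TRUE), f,
                       row.names = FALSE, quote = FALSE)
    } else {
      f <- file.path(dir, sprintf("%s_%s.json", stem, nm))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
    }
    paths <- c(paths, f)
  }
  mf <- file.path(dir, sprintf("%s_manifest.json", stem))
  manifest$outputs <- as.list(paths)
  jsonlite::write_json(unclass(manifest), mf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, mf))
}
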