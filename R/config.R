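#' Assemble a validated run configuration
#'
#' Flat configuration with a versioned schema covering web generation
#' (`S`, `C`, `Z`, `tol`), life-history structure (`t_max`, Leslie `stay`/
#' `advance`), every bioenergetic constant (see [atn_params()]), and the
#' ensemble layout (`n_webs`, `burn_in`, `analysis`, `seed`,
#' `model_types`). Defaults are the standard parameter set of the
#' allometrically scaled aquatic web (S = 30, C = 0.15, Z = 100, K = 540,
#' y = 10, h = 1.2, fa = 0.4, fm = 0.1, ...). Unknown keys are rejected.
#'
#' @param ... named overrides of any default key.
#' @return A list of class `atn_config`.
#' @seealso [load_config()], [save_config()]
#' @export
atn_config <- function(...) {
  defaults <- list(
    schema = "atnfish-config-1",
    S = 30L, C = 0.15, Z = 100, tol = 0.05,
    t_max = 3L, stay = 0.1, advance = 0.9,
    on_empty_diet = "reject",
    n_webs = 500L, burn_in = 200L, analysis = 100L,
    seed = 1L,
    model_types = c("original", "unlinked", "linked"))
  defaults <- c(defaults, unclass(atn_params()))
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == ""))
      stop("unknown configuration key(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
           call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  cfg <- defaults
  # revalidate the dynamics subset through its own constructor
  pnames <- names(unclass(atn_params()))
  do.call(atn_params, cfg[pnames])
  if (cfg$C <= 0 || cfg$C >= 0.5) stop("key `C` must lie in (0, 0.5)", call. = FALSE)
  if (cfg$S < 2) stop("key `S` must be >= 2", call. = FALSE)
  if (abs(cfg$stay + cfg$advance - 1) > 1e-12)
    stop("keys `stay` and `advance` must sum to 1", call. = FALSE)
  class(cfg) <- "atn_config"
  cfg
}

#' Extract the dynamics parameters from a configuration
#' @param cfg an `atn_config`.
#' @export
config_params <- function(cfg) {
  pnames <- names(unclass(atn_params()))
  do.call(atn_params, unclass(cfg)[pnames])
}

#' Read / write a configuration file
#'
#' YAML (or JSON, by extension) serialization of an [atn_config()];
#' missing keys take their defaults and unknown keys are rejected with the
#' offending name. `save_config()` then `load_config()` round-trips to an
#' identical configuration.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw$schema <- NULL
  for (k in c("S", "n_webs", "burn_in", "analysis", "seed", "t_max"))
    if (!is.null(raw[[k]])) raw[[k]] <- as.integer(raw[[k]])
  do.call(atn_config, raw)
}

#' @rdname load_config
#' @param cfg an `atn_config`.
#' @export
save_config <- function(cfg, path) {
  obj <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Write a reproducible output bundle for an ensemble
#'
#' Emits per-run and per-species CSV tables, the survivor-frequency table,
#' the headline fractions and regression table as JSON, the configuration
#' echo, and a manifest with an MD5 content hash for every file, so any
#' summary number can be recomputed and audited from the bundle alone.
#' Failed runs remain in the run table with their status and are flagged
#' in the manifest.
#'
#' @param ensemble an `atn_ensemble` from [run_ensemble()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_run_bundle <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  paths <- character()
  wr <- function(fname, writer) {
    p <- file.path(dir, fname)
    writer(p)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  wr("runs.csv", function(p)
    utils::write.csv(ensemble$runs, p, row.names = FALSE))
  if (!is.null(ensemble$species))
    wr("species.csv", function(p)
      utils::write.csv(ensemble$species, p, row.names = FALSE))
  wr("survivor_freq.csv", function(p)
    utils::write.csv(as.data.frame(ensemble$survivor_freq), p,
                     row.names = FALSE))
  wr("fractions.json", function(p)
    writeLines(jsonlite::toJSON(ensemble$fractions, auto_unbox = TRUE,
                                digits = NA), p))
  if (!is.null(ensemble$regression))
    wr("regression.csv", function(p)
      utils::write.csv(ensemble$regression, p, row.names = FALSE))
  wr("config.yaml", function(p) {
    cfg <- ensemble$config
    cfg$params <- unclass(cfg$params)
    yaml::write_yaml(cfg, p)
  })
  failed <- ensemble$runs[ensemble$runs$status != "ok" |
                            is.na(ensemble$runs$model_type), , drop = FALSE]
  manifest <- list(
    files = lapply(paths, function(p)
      list(name = basename(p), md5 = unname(tools::md5sum(p)))),
    n_runs = nrow(ensemble$runs),
    failed_runs = if (nrow(failed)) failed[, c("web", "model_type", "status")]
                  else NULL,
    seed = ensemble$config$seed)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Write an edge-list TSV for a web
#'
#' Two tab-separated columns, `consumer` and `resource`, 1-based ids.
#'
#' @param web a `niche_web`.
#' @param path output path.
#' @export
write_edge_list <- function(web, path) {
  links <- which(web$A == 1L, arr.ind = TRUE)
  df <- data.frame(consumer = links[, 1L], resource = links[, 2L])
  df <- df[order(df$consumer, df$resource), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
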