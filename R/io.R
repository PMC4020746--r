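# Configuration files (YAML), result serialization (CSV + JSON run manifest)
# and the command-line interface.

# component template: constructor + config section name
config_sections <- function() {
  list(pop = population_params, move = movement_params, dive = dive_params,
       ac = acoustic_params, ves = vessel_params, wx = weather_params)
}

#' Load a survey configuration from a YAML file
#'
#' The file may name a preset (`preset: kaikoura` or `preset: antarctic`)
#' whose values fill every key not given explicitly; remaining keys override
#' the preset (or the documented defaults). Unknown keys are rejected with an
#' error naming the key; all parameter invariants are validated. Distances are
#' km, times hours, angles degrees throughout.
#'
#' @param path Path to a YAML file.
#' @return An [survey_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  preset <- raw$preset
  raw$preset <- NULL
  cfg <- if (is.null(preset)) {
    survey_config()
  } else if (preset == "kaikoura") {
    preset_kaikoura()
  } else if (preset == "antarctic") {
    preset_antarctic()
  } else stop("unknown preset: ", preset, call. = FALSE)

  top_keys <- c("area", "duration", "dt", "survey_mode", "overnight_acoustics",
                "start_hour", "label")
  secs <- config_sections()
  for (key in names(raw)) {
    if (key %in% top_keys) {
      cfg[[key]] <- if (key == "area") as.numeric(raw[[key]]) else raw[[key]]
    } else if (key %in% names(secs)) {
      sub <- raw[[key]]
      legal <- names(formals(secs[[key]]))
      for (f in names(sub)) {
        if (!f %in% legal)
          stop("unknown configuration key: ", key, ".", f, call. = FALSE)
        cfg[[key]][[f]] <- sub[[f]]
      }
      # re-run the constructor so invariants are checked with clear messages
      cfg[[key]] <- tryCatch(
        do.call(secs[[key]], cfg[[key]][legal[legal %in% names(cfg[[key]])]]),
        error = function(e) stop("invalid configuration in `", key, "`: ",
                                 conditionMessage(e), call. = FALSE))
    } else stop("unknown configuration key: ", key, call. = FALSE)
  }
  validate_config(cfg)
}

#' Write battery results, per-replicate rates and a run manifest
#'
#' Writes `summary.csv` (the battery rows), `replicates.csv` (per-replicate
#' rates when attached) and `manifest.json` (the fully resolved configuration,
#' root seed, package version and timestamp; re-running from the manifest
#' reproduces results bit-identically).
#'
#' @param battery An `amr_battery` result.
#' @param out_dir Output directory (created if needed).
#' @param cfg The configuration the battery was run from.
#' @param seed The root seed used.
#' @return Character vector of the paths written, invisibly.
#' @export
write_results <- function(battery, out_dir, cfg = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, "summary.csv")
  utils::write.csv(as.data.frame(battery), paths[1], row.names = FALSE)
  reps <- attr(battery, "reps")
  if (!is.null(reps)) {
    paths <- c(paths, file.path(out_dir, "replicates.csv"))
    utils::write.csv(reps, paths[2], row.names = FALSE)
  }
  man <- list(package = "amrsim",
              version = as.character(utils::packageVersion("amrsim")),
              timestamp = format(Sys.time(), tz = "UTC"),
              seed = seed,
              config = if (!is.null(cfg)) unclass_config(cfg))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, mp))
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  for (s in names(config_sections())) out[[s]] <- unclass(out[[s]])
  out
}

#' Command-line interface
#'
#' Thin wrapper over the package functions, used by the `amrsim` Rscript in
#' `inst/cli/`. Subcommands: `run` (a replicate battery from a YAML config),
#' `presets` (emit a preset config as YAML), `sweep` (a one-parameter
#' sensitivity sweep) and `plot` (render rate-vs-density from a summary CSV to
#' PNG). Common flags: `--config`, `--name`, `--seed`, `--reps`, `--out`,
#' `--parameter`, `--values` (comma separated), `--densities` (comma
#' separated).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
amr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: amrsim <run|presets|sweep|plot> [options]",
    "  run     --config FILE [--reps N] [--seed S] [--out DIR] [--track-log FILE]",
    "  presets --name <kaikoura|antarctic> [--out FILE]",
    "  sweep   --config FILE --parameter PATH --values a,b,c",
    "          [--densities d1,d2] [--reps N] [--seed S] [--out DIR]",
    "  plot    --summary FILE --out FILE.png", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(reps = 100L, seed = 1L, out = ".")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!grepl("^--", args[i]) || i == length(args)) {
      message("bad usage near: ", args[i], "\n", usage)
      return(invisible(1L))
    }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opt$reps <- as.integer(opt$reps); opt$seed <- as.integer(opt$seed)
  status <- tryCatch({
    if (cmd == "run") {
      cfg <- load_config(opt$config)
      bat <- run_battery(cfg, opt$reps, opt$seed)
      write_results(bat, opt$out, cfg, opt$seed)
      if (!is.null(opt[["track-log"]])) {
        # per-tick vessel state of the battery's first replicate
        r1 <- run_survey(cfg, derive_seed(opt$seed, 0L, 1L), track = TRUE)
        utils::write.csv(r1$track, opt[["track-log"]], row.names = FALSE)
      }
      print(bat)
      0L
    } else if (cmd == "presets") {
      cfg <- switch(opt$name, kaikoura = preset_kaikoura(),
                    antarctic = preset_antarctic(),
                    stop("unknown preset: ", opt$name, call. = FALSE))
      txt <- yaml::as.yaml(unclass_config(cfg), precision = 12)
      if (is.null(opt$out) || opt$out == ".") cat(txt) else writeLines(txt, opt$out)
      0L
    } else if (cmd == "sweep") {
      cfg <- load_config(opt$config)
      vals <- as.numeric(strsplit(opt$values, ",")[[1]])
      dens <- if (!is.null(opt$densities))
        as.numeric(strsplit(opt$densities, ",")[[1]]) else NA_real_
      bat <- sweep_parameter(cfg, opt$parameter, vals, dens, opt$reps, opt$seed)
      write_results(bat, opt$out, cfg, opt$seed)
      print(bat)
      0L
    } else if (cmd == "plot") {
      bat <- utils::read.csv(opt$summary)
      grDevices::png(opt$out, width = 700, height = 500)
      on.exit(grDevices::dev.off())
      class(bat) <- c("amr_battery", "data.frame")
      plot(bat)
      0L
    } else {
      message("unknown subcommand: ", cmd, "\n", usage)
      1L
    }
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
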