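#' Run the end-to-end trait-variation and spectrum analysis
#'
#' Orchestrates the full analysis: simulate (or read) a paired-plot
#' survey, compute per-unit trait indices, compare per-trait phenotypic
#' variation with ANOVA + Tukey letters, fit the 21 pairwise
#' log-trait SMA regressions and the LPI-LTI spectrum SMA, and run one
#' exhaustive multimodel-inference attribution per requested response
#' (the seven per-trait PVIs and the LTI/LPI spectrum ratio by default).
#'
#' @param config A named list or path to a YAML file. Recognised fields:
#'   \describe{
#'     \item{seed}{integer, required when simulating (default 1)}
#'     \item{traits, environment}{paths to input CSVs; when absent a
#'       survey is simulated}
#'     \item{scope}{`"plot"` (default, one unit per plot pair) or
#'       `"population"` (site-averaged units)}
#'     \item{responses}{subset of the seven trait names and `"spectrum"`}
#'     \item{level}{cumulative-weight level for model averaging (0.95)}
#'     \item{conditional}{conditional instead of full averaging (FALSE)}
#'     \item{out_dir}{directory to write interchange CSVs into (optional)}
#'     \item{log}{emit progress messages (TRUE)}
#'   }
#' @return An object of class `report_bundle`: `indices`, `anova`,
#'   `sma_traits`, `sma_spectrum`, `mmi` (named list of `mmi_fit`s),
#'   `failures`, `metadata` (config hash, seed, versions).
#' @export
#' @examples
#' rb <- run_pipeline(list(seed = 3, responses = c("ldmc", "spectrum"),
#'                         log = FALSE))
#' names(rb$mmi)
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, scope = "plot",
                   responses = c(trait_names(), "spectrum"),
                   level = 0.95, conditional = FALSE, out_dir = NULL,
                   log = TRUE)
  cfg <- modifyList(defaults, config)
  say <- function(...) if (isTRUE(cfg$log)) message("[leafspectra] ", ...)
  bad_resp <- setdiff(cfg$responses, c(trait_names(), "spectrum"))
  if (length(bad_resp) > 0) {
    abort(paste0("stage config: unknown response(s): ",
                 paste(bad_resp, collapse = ", ")),
          class = "leafspectra_schema_error")
  }

  # --- inputs -------------------------------------------------------
  if (!is.null(cfg$traits)) {
    say("reading trait/environment tables")
    traits <- readr::read_csv(cfg$traits, show_col_types = FALSE,
                              progress = FALSE)
    env <- if (!is.null(cfg$environment)) {
      readr::read_csv(cfg$environment, show_col_types = FALSE,
                      progress = FALSE)
    } else {
      NULL
    }
  } else {
    say("simulating survey (seed ", cfg$seed, ")")
    sv <- simulate_survey(seed = cfg$seed)
    traits <- sv$traits
    env <- sv$environment
  }
  if (!is.null(env)) {
    if (!identical(traits$unit_id, env$unit_id)) {
      abort("stage inputs: trait and environment tables must share unit ids and order.",
            class = "leafspectra_schema_error")
    }
  }
  if (identical(cfg$scope, "population")) {
    say("aggregating to population scope")
    if (is.null(env) || !"site" %in% names(env)) {
      abort("stage scope: population scope needs an environment table with a site column.",
            class = "leafspectra_schema_error")
    }
    traits <- aggregate_to_populations(dplyr::bind_cols(env["site"], traits[-1]))
    env <- aggregate_to_populations(env)
  }

  # --- indices ------------------------------------------------------
  say("stage indices")
  indices <- trait_indices(traits)

  # --- ANOVA --------------------------------------------------------
  say("stage anova")
  anova_fit <- pvi_anova(pvi_long(indices))

  # --- SMA ----------------------------------------------------------
  say("stage sma")
  sma_traits <- sma_all_pairs(traits, log = TRUE)
  sma_spectrum <- sma_fit(indices$lti, indices$lpi, log = FALSE)

  # --- MMI ----------------------------------------------------------
  mmi_fits <- list()
  failures <- character(0)
  if (!is.null(env)) {
    schema <- predictor_schema()
    dat <- dplyr::bind_cols(env,
                            indices[, setdiff(names(indices), "unit_id")])
    for (resp in cfg$responses) {
      col <- if (resp == "spectrum") "spectrum_ratio" else paste0("pvi_", resp)
      say("stage mmi: ", resp)
      fit <- tryCatch(
        mmi(dat, col, schema = schema, level = cfg$level,
            conditional = isTRUE(cfg$conditional)),
        error = function(e) {
          failures[[resp]] <<- conditionMessage(e)
          NULL
        }
      )
      if (!is.null(fit)) {
        fit$response <- resp
        mmi_fits[[resp]] <- fit
      }
    }
  } else {
    say("no environment table: skipping attribution stage")
  }

  metadata <- list(
    config = cfg[setdiff(names(cfg), "log")],
    config_hash = rlang::hash(cfg[setdiff(names(cfg), c("out_dir", "log"))]),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("leafspectra")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    failures = failures
  )

  bundle <- structure(
    list(indices = indices, anova = anova_fit, sma_traits = sma_traits,
         sma_spectrum = sma_spectrum, mmi = mmi_fits, failures = failures,
         metadata = metadata),
    class = "report_bundle"
  )
  if (!is.null(cfg$out_dir)) write_report(bundle, cfg$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", nrow(x$indices), " units; ",
      length(x$mmi), " attribution run(s)",
      if (length(x$failures) > 0) paste0("; ", length(x$failures), " failed"),
      "\n", sep = "")
  invisible(x)
}

#' Write a report bundle as interchange CSVs
#'
#' Writes `indices.csv`, `pvi_anova.csv`, `sma_fits.csv`, and per response
#' `contributions_<resp>.csv`, `averaged_coefficients_<resp>.csv` and
#' `model_set_<resp>.csv` (top 20 models), plus `report.yaml` metadata.
#' Floats are written at 12 significant digits so reruns are
#' byte-identical.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory.
#' @param top_models Number of top-ranked models written per response.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir, top_models = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_stable(bundle$indices, file.path(dir, "indices.csv"))
  write_csv_stable(bundle$anova$summary, file.path(dir, "pvi_anova.csv"))
  sma <- bind_rows(
    bundle$sma_traits,
    tibble(x = "lti", y = "lpi", slope = bundle$sma_spectrum$slope,
           intercept = bundle$sma_spectrum$intercept,
           r_squared = bundle$sma_spectrum$r_squared,
           p_value = bundle$sma_spectrum$p_value, n = bundle$sma_spectrum$n)
  )
  write_csv_stable(sma, file.path(dir, "sma_fits.csv"))
  for (resp in names(bundle$mmi)) {
    fit <- bundle$mmi[[resp]]
    write_csv_stable(fit$contributions$predictors,
                     file.path(dir, paste0("contributions_", resp, ".csv")))
    write_csv_stable(fit$coefficients,
                     file.path(dir, paste0("averaged_coefficients_", resp, ".csv")))
    write_csv_stable(head(fit$model_set$models, top_models),
                     file.path(dir, paste0("model_set_", resp, ".csv")))
  }
  yaml::write_yaml(bundle$metadata, file.path(dir, "report.yaml"))
  invisible(dir)
}

# ---------------------------------------------------------------------
# Command-line entry point (argv level). A thin Rscript wrapper lives in
# inst/cli/leafspectra.

cli_usage <- function() {
  paste(
    "usage: leafspectra <command> [options]",
    "commands:",
    "  simulate --seed <int> --out <dir>",
    "  indices  --traits <csv> --out <dir>",
    "  spectrum --traits <csv> --out <dir>",
    "  mmi      --traits <csv> --environment <csv> --response <name> --out <dir>",
    "  report   --config <yaml> | --seed <int> --out <dir>",
    sep = "\n"
  )
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--") || i == length(args)) {
      abort(paste0("cannot parse argument '", a, "'"),
            class = "leafspectra_usage_error")
    }
    flags[[substring(a, 3)]] <- args[[i + 1]]
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `indices`, `spectrum`, `mmi` and
#' `report` over the package's pipeline functions, reading and writing the
#' interchange CSVs. Returns an exit status instead of calling `quit()` so
#' it can be driven in-process; the installed `inst/cli/leafspectra`
#' script forwards `commandArgs()` and exits with the returned status.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly: 0 on success, 1 on a runtime
#'   error, 2 on a usage error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (length(args) == 0) {
      message(cli_usage())
      return(2L)
    }
    cmd <- args[[1]]
    flags <- parse_flags(args[-1])
    out <- flags$out %||% "."
    seed <- as.integer(flags$seed %||% "1")
    switch(
      cmd,
      simulate = {
        sv <- simulate_survey(seed = seed)
        write_survey(sv, out)
        message("wrote survey to ", out)
        0L
      },
      indices = {
        traits <- readr::read_csv(flags$traits, show_col_types = FALSE,
                                  progress = FALSE)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_csv_stable(trait_indices(traits),
                         file.path(out, "indices.csv"))
        0L
      },
      spectrum = {
        traits <- readr::read_csv(flags$traits, show_col_types = FALSE,
                                  progress = FALSE)
        idx <- trait_indices(traits)
        fit <- sma_fit(idx$lti, idx$lpi)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_csv_stable(glance(fit), file.path(out, "spectrum_sma.csv"))
        0L
      },
      mmi = {
        traits <- readr::read_csv(flags$traits, show_col_types = FALSE,
                                  progress = FALSE)
        env <- readr::read_csv(flags$environment, show_col_types = FALSE,
                               progress = FALSE)
        resp <- flags$response %||% "spectrum"
        idx <- trait_indices(traits)
        col <- if (resp == "spectrum") "spectrum_ratio" else paste0("pvi_", resp)
        fit <- mmi(dplyr::bind_cols(env, idx[, setdiff(names(idx), "unit_id")]),
                   col)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_csv_stable(fit$contributions$predictors,
                         file.path(out, "contributions.csv"))
        write_csv_stable(fit$coefficients,
                         file.path(out, "averaged_coefficients.csv"))
        0L
      },
      report = {
        cfg <- if (!is.null(flags$config)) {
          yaml::read_yaml(flags$config)
        } else {
          list(seed = seed)
        }
        cfg$out_dir <- flags$out %||% cfg$out_dir %||% "."
        run_pipeline(cfg)
        0L
      },
      {
        message("unknown command '", cmd, "'\n", cli_usage())
        2L
      }
    )
  }
  status <- tryCatch(
    run(),
    leafspectra_usage_error = function(e) {
      message(conditionMessage(e), "\n", cli_usage())
      2L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}
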