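PARTICIPANT_SCHEMA <- "quitinc-participants/v1"

#' Write a participant table as versioned CSV
#'
#' The first line is a schema comment (`# schema: quitinc-participants/v1`);
#' readers reject files with an unknown schema so silently mismatched
#' columns cannot flow into an analysis.
#'
#' @param table participant tibble
#' @param path output path
#' @return `path` invisibly
#' @export
write_participants <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", PARTICIPANT_SCHEMA), con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a versioned participant CSV
#'
#' @param path file written by [write_participants()]
#' @return participant tibble
#' @export
read_participants <- function(path) {
  first <- readLines(path, n = 1)
  schema <- sub("^# schema: *", "", first)
  if (!identical(schema, PARTICIPANT_SCHEMA)) {
    stop_field("path", paste("unknown participant schema:", first))
  }
  tb <- tibble::as_tibble(read.csv(path, comment.char = "#",
                                   stringsAsFactors = FALSE))
  for (cl in c("covid_era", "engaged", "saliva_provided", "late_award",
               "miscarriage", "withdrew")) {
    if (cl %in% names(tb)) tb[[cl]] <- as.logical(tb[[cl]])
  }
  tb
}

#' Load unit costs and the voucher schedule from a YAML/JSON config
#'
#' A single config file carries the voucher schedule and the unit-cost
#' table, stamped with the price year. Missing keys fall back to the
#' package defaults, so a config may override only what it changes.
#'
#' @param path YAML (or JSON) file
#' @return list with `schedule` ([voucher_schedule()]) and `unit_costs`
#'   ([unit_cost_table()])
#' @export
read_cost_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sch <- do.call(voucher_schedule,
                 cfg$voucher_schedule %||% list())
  uc_args <- cfg$unit_costs %||% list()
  for (f in c("adviser_rate_per_hour", "neonatal_per_day",
              "neonatal_los_days")) {
    if (!is.null(uc_args[[f]])) uc_args[[f]] <- unlist(uc_args[[f]])
  }
  uc <- do.call(unit_cost_table, uc_args)
  list(schedule = sch, unit_costs = uc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Record a run manifest
#'
#' Captures what produced a set of outputs: the command label, config
#' file hashes, the master seed, package version, timestamp and the
#' output file list. The same manifest plus inputs implies byte-identical
#' numeric outputs (all randomness flows from the seed).
#'
#' @param command label of the pipeline stage
#' @param config_paths character vector of config files (hashed)
#' @param seed master seed of the run
#' @param outputs character vector of files written
#' @param path if non-NULL, write the manifest JSON here
#' @return the manifest list, invisibly if written
#' @export
run_manifest <- function(command, config_paths = character(), seed = NA,
                         outputs = character(), path = NULL) {
  hashes <- if (length(config_paths)) {
    as.list(tools::md5sum(config_paths))
  } else {
    list()
  }
  manifest <- list(command = command,
                   configs = hashes,
                   seed = seed,
                   package = "quitinc",
                   version = as.character(packageVersion("quitinc")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   outputs = as.list(outputs))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}

#' Cost-effectiveness plane scatter
#'
#' @param samples tibble with `delta_cost`, `delta_effect`
#' @param wtp reference threshold drawn as a line through the origin
#' @param effect_label axis label for the effect
#' @return a ggplot object
#' @export
ce_plane_plot <- function(samples, wtp = 20000,
                          effect_label = "Incremental QALYs") {
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = effect_label, y = "Incremental cost (£)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve tibble from [ceac()]
#' @return a ggplot object
#' @export
ceac_plot <- function(curve) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$threshold, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness-to-pay threshold (£ per QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
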