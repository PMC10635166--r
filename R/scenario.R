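# Named scenarios and parameter sweeps; file output for the CLI.

scenario_presets <- c("fig1", "fig3a", "fig3b", "fig4", "fig5")

#' Build a scenario specification
#'
#' A scenario is a parameter bundle plus the doses to run and, for
#' comparison scenarios, a second cell type. Shipped presets:
#' \describe{
#'   \item{\code{"fig1"}}{Oxygen profile before/after FLASH depletion at
#'     S_ROD = 160 and 15.3 mmHg/s.}
#'   \item{\code{"fig3a"}}{Depletion-only survival profile (kr = 0,
#'     S_ROD = 160 mmHg/s) at 10 Gy.}
#'   \item{\code{"fig3b"}}{Depletion-only overall survival at
#'     5, 10, 15, 20 Gy.}
#'   \item{\code{"fig4"}}{Depletion-only (S_ROD = 160) versus
#'     depletion + global ROS (S_ROD = 15.3) overall survival across
#'     doses.}
#'   \item{\code{"fig5"}}{Tumor versus healthy cells at S_ROD = 15.3,
#'     10 Gy, ROS term on.}
#' }
#'
#' @param name Preset name, or any identifier when the remaining arguments
#'   are given explicitly.
#' @param bundle Parameter bundle (\code{model}/\code{cell}/\code{survival})
#'   as returned by \code{\link{flash_preset}} or \code{\link{load_params}}.
#' @param doses Dose levels to run (Gy, non-empty).
#' @param cell2 Optional second cell type for paired comparison.
#' @param include_ros Include the sigmoid ROS term.
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(name, bundle = NULL, doses = NULL, cell2 = NULL,
                          include_ros = TRUE) {
  if (is.null(bundle) && name %in% scenario_presets) {
    spec <- switch(name,
      "fig1" = list(bundle = flash_preset("fig1"), doses = 10,
                    include_ros = FALSE),
      "fig3a" = list(bundle = flash_preset("fig1"), doses = 10,
                     include_ros = FALSE),
      "fig3b" = list(bundle = flash_preset("fig1"),
                     doses = c(5, 10, 15, 20), include_ros = FALSE),
      "fig4" = list(bundle = flash_preset("fig4-global-ros"),
                    doses = c(5, 10, 15, 20), include_ros = TRUE),
      "fig5" = list(bundle = flash_preset("table1-healthy"),
                    doses = 10, cell2 = cell_params("tumor"),
                    include_ros = TRUE))
    bundle <- spec$bundle
    if (is.null(doses)) doses <- spec$doses
    if (is.null(cell2)) cell2 <- spec$cell2
    include_ros <- spec$include_ros
  }
  if (is.null(bundle))
    stop("unknown scenario '", name, "' and no parameter bundle given; ",
         "presets: ", paste(scenario_presets, collapse = ", "),
         call. = FALSE)
  if (is.null(doses)) doses <- bundle$model$dose
  if (!length(doses) || any(doses < 0))
    stop("doses must be a non-empty vector of non-negative values",
         call. = FALSE)
  structure(list(name = name, bundle = bundle, doses = doses,
                 cell2 = cell2, include_ros = include_ros),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': cell '%s'%s, doses %s Gy, ROS term %s\n",
              x$name, x$bundle$cell$label,
              if (!is.null(x$cell2)) paste0(" vs '", x$cell2$label, "'")
              else "",
              paste(x$doses, collapse = "/"),
              if (x$include_ros) "on" else "off"))
  invisible(x)
}

num_fmt <- function(x) sprintf("%.12g", x)

#' Run a scenario and write its artifacts
#'
#' Executes every stage in order (steady-state oxygen, depletion, ROS
#' difference, survival, aggregation) for each dose and cell type in the
#' specification, writing CSV tables, a JSON summary and a plain-text log
#' to \code{out_dir}. Deterministic: the model contains no randomness, and
#' numbers are written with 12 significant digits.
#'
#' @param spec A \code{\link{scenario_spec}} (or a preset name).
#' @param out_dir Output directory, created if needed.
#' @param plot Also write an SVG figure per cell type (never affects the
#'   numeric outputs).
#' @return Character vector of the files written (the manifest), invisibly
#'   classed as \code{scenario_manifest} with the summary attached.
#' @export
run_scenario <- function(spec, out_dir, plot = FALSE) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- sprintf("scenario %s", spec$name)
  manifest <- character()

  cells <- c(list(spec$bundle$cell),
             if (!is.null(spec$cell2)) list(spec$cell2))
  summary_rows <- list()

  for (cell in cells) {
    model <- spec$bundle$model
    prof <- solve_steady_oxygen(
      validate_flash_params(structure(
        utils::modifyList(unclass(model), list(Sm = cell$Sm)),
        class = "flash_params")))
    f_ox <- file.path(out_dir,
                      sprintf("oxygen_profile_%s.csv", cell$label))
    write_oxygen_csv(prof, f_ox)
    manifest <- c(manifest, f_ox)
    log_lines <- c(log_lines,
                   sprintf("steady oxygen [%s]: r0 = %s mm", cell$label,
                           num_fmt(prof$r0_mm)))

    for (dose in spec$doses) {
      m <- validate_flash_params(structure(
        utils::modifyList(unclass(model), list(dose = dose)),
        class = "flash_params"))
      fit <- flash_spheroid(m, cell, spec$bundle$survival,
                            include_ros = spec$include_ros)
      f_sv <- file.path(out_dir,
                        sprintf("survival_%s_%sGy.csv", cell$label,
                                num_fmt(dose)))
      df <- as.data.frame(fit)
      con <- file(f_sv, "w")
      writeLines("r_mm,ps_mmHg,log10_sf_conv,log10_sf_flash", con)
      writeLines(paste(num_fmt(df$r_mm), num_fmt(df$ps_mmHg),
                       num_fmt(df$log10_sf_conv),
                       num_fmt(df$log10_sf_flash), sep = ","), con)
      close(con)
      manifest <- c(manifest, f_sv)
      summary_rows[[length(summary_rows) + 1L]] <- list(
        cell = cell$label, dose = dose, dose_rate = m$dose_rate,
        S_ROD = m$S_ROD, r0_mm = prof$r0_mm,
        overall_sf_conv = fit$overall_sf_conv,
        overall_sf_flash = fit$overall_sf_flash,
        params = params_hash(m))
      log_lines <- c(log_lines,
                     sprintf("survival [%s, %s Gy]: overall SF conv %s flash %s",
                             cell$label, num_fmt(dose),
                             num_fmt(fit$overall_sf_conv),
                             num_fmt(fit$overall_sf_flash)))
      if (plot) {
        f_plot <- file.path(out_dir,
                            sprintf("survival_%s_%sGy.svg", cell$label,
                                    num_fmt(dose)))
        grDevices::svg(f_plot)
        plot(fit)
        grDevices::dev.off()
        manifest <- c(manifest, f_plot)
      }
    }
  }

  f_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(scenario = spec$name, results = summary_rows),
                       f_json, auto_unbox = TRUE, digits = NA)
  f_log <- file.path(out_dir, "run.log")
  writeLines(log_lines, f_log)
  manifest <- c(manifest, f_json, f_log)
  structure(manifest, class = c("scenario_manifest", "character"),
            summary = summary_rows)
}

#' Sweep one numeric parameter of a scenario
#'
#' Re-runs the scenario's survival computation for each value of a single
#' numeric parameter and returns a long-format table sorted by the swept
#' value. Recognised parameters: any \code{flash_params} field
#' (\code{dose}, \code{S_ROD}, \code{dose_rate}, \code{Sm}, ...),
#' or \code{kr} of the survival constants.
#'
#' @param spec A \code{\link{scenario_spec}} (or preset name).
#' @param parameter Name of the numeric field to vary.
#' @param values Non-empty numeric vector of values.
#' @return A data frame with one row per value and cell type, columns
#'   \code{value}, \code{cell}, \code{dose}, \code{overall_sf_conv},
#'   \code{overall_sf_flash}.
#' @examples
#' sweep_scenario(scenario_spec("fig3a"), "dose", c(5, 10))
#' @export
sweep_scenario <- function(spec, parameter, values) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  if (!length(values) || !is.numeric(values))
    stop("values must be a non-empty numeric vector", call. = FALSE)
  model_fields <- c("R", "H", "D_sph", "D_med", "p_air", "Sm", "S_ROD",
                    "dose", "dose_rate")
  sv_fields <- c("alpha0", "beta0", "m", "K", "kr", "a", "b")
  if (!parameter %in% c(model_fields, sv_fields))
    stop("unknown sweep parameter '", parameter, "'", call. = FALSE)
  values <- sort(values)

  cells <- c(list(spec$bundle$cell),
             if (!is.null(spec$cell2)) list(spec$cell2))
  rows <- list()
  for (v in values) {
    model <- spec$bundle$model
    sp <- spec$bundle$survival
    if (parameter %in% model_fields) {
      model <- validate_flash_params(structure(
        utils::modifyList(unclass(model), stats::setNames(list(v), parameter)),
        class = "flash_params"))
    } else {
      sp <- validate_survival_params(structure(
        utils::modifyList(unclass(sp), stats::setNames(list(v), parameter)),
        class = "survival_params"))
    }
    for (cell in cells) {
      fit <- flash_spheroid(model, cell, sp,
                            include_ros = spec$include_ros)
      rows[[length(rows) + 1L]] <- data.frame(
        value = v, cell = cell$label, dose = fit$dose,
        overall_sf_conv = fit$overall_sf_conv,
        overall_sf_flash = fit$overall_sf_flash)
    }
  }
  do.call(rbind, rows)
}
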