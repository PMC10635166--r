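# Parameter containers, presets and configuration I/O.
#
# Unit conventions (fixed, not configurable):
#   lengths          mm at the user interface, cm internally
#   oxygen tension   mmHg everywhere except the ROS forcing term (uM)
#   diffusion        cm^2/s
#   dose             Gy, dose rate Gy/s
# Henry-law conversion: 0.77 mmHg dissolved O2 corresponds to 1 uM O2.

#' Conversion between oxygen tension and concentration
#'
#' Dissolved oxygen at 0.77 mmHg partial pressure corresponds to a
#' concentration of 1 uM; the conversion is linear. Oxygen enters the
#' diffusion and depletion equations as a tension (mmHg) and the ROS
#' production term as a concentration (uM), so this is the only unit
#' bridge in the model.
#'
#' @param p Oxygen tension in mmHg (non-negative, vectorised).
#' @return Oxygen concentration in uM.
#' @examples
#' mmHg_to_uM(0.77)  # 1
#' mmHg_to_uM(160)   # atmospheric interface tension in uM
#' @export
mmHg_to_uM <- function(p) {
  if (any(p < 0)) stop("oxygen tension must be non-negative", call. = FALSE)
  p / 0.77
}

# mmHg of O2 tension per uM of O2 concentration
MMHG_PER_UM <- 0.77

#' Spheroid geometry, transport and irradiation parameters
#'
#' Bundles every scenario-level constant: the cell spheroid of radius
#' \code{R} sits at the centre of a medium sphere of radius \code{H}; oxygen
#' diffuses with coefficient \code{D_sph} inside the spheroid and
#' \code{D_med} in the medium, is held at \code{p_air} at the medium/air
#' interface, and is consumed metabolically at rate \code{Sm} inside the
#' spheroid only. During irradiation, radiolysis depletes oxygen at rate
#' \code{S_ROD}; if the depletion-per-unit-dose coefficient \code{L_ROD} is
#' given, \code{S_ROD = L_ROD * dose_rate}.
#'
#' @param R Spheroid radius (mm).
#' @param H Medium outer radius (mm); must exceed \code{R}.
#' @param D_sph Oxygen diffusion coefficient in the spheroid (cm^2/s).
#' @param D_med Oxygen diffusion coefficient in the medium (cm^2/s).
#' @param p_air Oxygen tension at the medium/air interface (mmHg).
#' @param Sm Metabolic oxygen consumption rate inside the spheroid (mmHg/s).
#' @param S_ROD Radiolytic oxygen depletion rate (mmHg/s). Ignored (and
#'   recomputed) when \code{L_ROD} is supplied.
#' @param L_ROD Optional oxygen depletion per unit dose (mmHg/Gy).
#' @param dose Total physical dose (Gy).
#' @param dose_rate Instantaneous dose rate (Gy/s); the beam-on window is
#'   \code{dose / dose_rate}.
#' @return An object of class \code{flash_params}.
#' @examples
#' flash_params()                          # Table-of-constants defaults
#' flash_params(L_ROD = 0.17, dose_rate = 90)  # S_ROD = 15.3 mmHg/s
#' @export
flash_params <- function(R = 0.5, H = 6,
                         D_sph = 2.2e-5, D_med = 2.7e-5,
                         p_air = 160, Sm = 4.2,
                         S_ROD = 15.3, L_ROD = NULL,
                         dose = 10, dose_rate = 90) {
  if (!is.null(L_ROD)) {
    check_nonneg(L_ROD, "L_ROD")
    S_ROD <- L_ROD * dose_rate
  }
  p <- structure(
    list(R = R, H = H, D_sph = D_sph, D_med = D_med, p_air = p_air,
         Sm = Sm, S_ROD = S_ROD, L_ROD = L_ROD,
         dose = dose, dose_rate = dose_rate),
    class = "flash_params")
  validate_flash_params(p)
}

validate_flash_params <- function(p) {
  for (f in c("R", "H", "D_sph", "D_med", "p_air", "Sm", "S_ROD",
              "dose", "dose_rate")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  check_pos(p$R, "R"); check_pos(p$H, "H")
  if (p$R >= p$H)
    stop("spheroid radius R (", p$R, " mm) must be smaller than medium ",
         "radius H (", p$H, " mm)", call. = FALSE)
  check_pos(p$D_sph, "D_sph"); check_pos(p$D_med, "D_med")
  check_pos(p$p_air, "p_air"); check_pos(p$dose_rate, "dose_rate")
  check_nonneg(p$Sm, "Sm"); check_nonneg(p$S_ROD, "S_ROD")
  check_nonneg(p$dose, "dose")
  if (!is.null(p$L_ROD) &&
      abs(p$S_ROD - p$L_ROD * p$dose_rate) >
        1e-12 * max(1, abs(p$S_ROD)))
    stop("S_ROD must equal L_ROD * dose_rate", call. = FALSE)
  # store as double regardless of how the config file typed the literal
  for (f in names(p)) if (is.numeric(p[[f]])) p[[f]] <- as.numeric(p[[f]])
  p
}

#' @export
print.flash_params <- function(x, ...) {
  cat("FLASH scenario parameters\n")
  cat(sprintf("  spheroid R = %g mm inside medium H = %g mm\n", x$R, x$H))
  cat(sprintf("  D_sph = %g, D_med = %g cm^2/s; p_air = %g mmHg\n",
              x$D_sph, x$D_med, x$p_air))
  cat(sprintf("  Sm = %g mmHg/s; S_ROD = %g mmHg/s%s\n", x$Sm, x$S_ROD,
              if (!is.null(x$L_ROD))
                sprintf(" (L_ROD = %g mmHg/Gy)", x$L_ROD) else ""))
  cat(sprintf("  dose = %g Gy at %g Gy/s (beam-on %.4g s)\n",
              x$dose, x$dose_rate, x$dose / x$dose_rate))
  invisible(x)
}

#' Cell-type constants for the ROS difference kinetics
#'
#' Tumor and healthy cells differ in their metabolic oxygen consumption
#' \code{Sm}, their ROS production coefficient \code{cp} (per second;
#' multiplies the oxygen concentration deficit in uM) and their first-order
#' ROS degeneration rate \code{k_ROS}. Tumor cells degrade ROS roughly an
#' order of magnitude more slowly than healthy cells, which is what gives
#' healthy tissue the extra FLASH protection in this model.
#'
#' Presets:
#' \describe{
#'   \item{\code{"tumor"}}{Sm = 4.2 mmHg/s, cp = 0.8e-4 /s, k_ROS = 0.8e-3 /s}
#'   \item{\code{"healthy"}}{Sm = 3.2 mmHg/s, cp = 1e-3 /s, k_ROS = 1e-2 /s}
#'   \item{\code{"global-ros"}}{Sm = 4.2 mmHg/s, cp = 4.5e-4 /s,
#'     k_ROS = 0.5e-2 /s: a single cell-type-agnostic calibration that,
#'     combined with the measured depletion rate 15.3 mmHg/s, reproduces the
#'     survival curves of the depletion-only model run at 160 mmHg/s.}
#' }
#'
#' @param type Preset name, one of \code{"tumor"}, \code{"healthy"},
#'   \code{"global-ros"}.
#' @param Sm,cp,k_ROS Optional overrides of the preset values.
#' @return An object of class \code{cell_params}.
#' @examples
#' cell_params("healthy")
#' cell_params("tumor", Sm = 5)
#' @export
cell_params <- function(type = c("tumor", "healthy", "global-ros"),
                        Sm = NULL, cp = NULL, k_ROS = NULL) {
  type <- match.arg(type)
  def <- switch(type,
    "tumor"      = list(Sm = 4.2, cp = 0.8e-4, k_ROS = 0.8e-3),
    "healthy"    = list(Sm = 3.2, cp = 1e-3,   k_ROS = 1e-2),
    "global-ros" = list(Sm = 4.2, cp = 4.5e-4, k_ROS = 0.5e-2))
  out <- structure(
    list(label = type,
         Sm    = if (is.null(Sm)) def$Sm else Sm,
         cp    = if (is.null(cp)) def$cp else cp,
         k_ROS = if (is.null(k_ROS)) def$k_ROS else k_ROS),
    class = "cell_params")
  validate_cell_params(out)
}

validate_cell_params <- function(x) {
  check_nonneg(x$Sm, "Sm")
  check_nonneg(x$cp, "cp")
  if (!is.numeric(x$k_ROS) || x$k_ROS <= 0)
    stop("k_ROS must be > 0", call. = FALSE)
  for (f in c("Sm", "cp", "k_ROS")) x[[f]] <- as.numeric(x[[f]])
  x
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("cell type '%s': Sm = %g mmHg/s, cp = %g /s, k_ROS = %g /s\n",
              x$label, x$Sm, x$cp, x$k_ROS))
  invisible(x)
}

#' Linear-quadratic, OER and oxidative-stress survival constants
#'
#' The surviving fraction follows a linear-quadratic (LQ) model whose
#' coefficients are scaled by the oxygen enhancement ratio
#' \code{OER(p) = (m*p + K)/(p + K)}: \code{alpha(p) = alpha0 * OER(p)},
#' \code{beta(p) = beta0 * OER(p)^2}. The oxidative-stress relief term is a
#' sigmoid \code{kr / (1 + exp(a + b * dROS))} of the FLASH-minus-CONV ROS
#' difference (uM); it is essentially zero at \code{dROS = 0} and approaches
#' \code{kr} as the ROS deficit grows.
#'
#' @param alpha0 LQ linear coefficient at zero oxygen (1/Gy).
#' @param beta0 LQ quadratic coefficient at zero oxygen (1/Gy^2).
#' @param m Maximum oxygen enhancement ratio (dimensionless, >= 1).
#' @param K OER half-saturation oxygen tension (mmHg).
#' @param kr Sigmoid amplitude (1/s); \code{kr = 0} switches the ROS term off.
#' @param a Sigmoid offset (dimensionless).
#' @param b Sigmoid slope (1/uM).
#' @param oer_orientation Which reading of the OER ratio to use; the default
#'   \code{"standard"} is \code{(m*p + K)/(p + K)} so that oxygenated cells
#'   are more radiosensitive. \code{"inverse"} uses \code{(m*K + p)/(K + p)}
#'   for sensitivity analysis only.
#' @return An object of class \code{survival_params}.
#' @examples
#' survival_params()
#' @export
survival_params <- function(alpha0 = 0.44, beta0 = 0.44,
                            m = 2.6, K = 1.9,
                            kr = 3e-2, a = 8, b = 200,
                            oer_orientation = c("standard", "inverse")) {
  oer_orientation <- match.arg(oer_orientation)
  x <- structure(
    list(alpha0 = alpha0, beta0 = beta0, m = m, K = K,
         kr = kr, a = a, b = b, oer_orientation = oer_orientation),
    class = "survival_params")
  validate_survival_params(x)
}

validate_survival_params <- function(x) {
  check_nonneg(x$alpha0, "alpha0")
  check_nonneg(x$beta0, "beta0")
  if (x$m < 1) stop("OER parameter m must be >= 1", call. = FALSE)
  check_pos(x$K, "K")
  check_nonneg(x$kr, "kr")
  for (f in c("alpha0", "beta0", "m", "K", "kr", "a", "b"))
    x[[f]] <- as.numeric(x[[f]])
  x
}

#' @export
print.survival_params <- function(x, ...) {
  cat(sprintf("LQ/OER survival: alpha0 = %g /Gy, beta0 = %g /Gy^2, m = %g, K = %g mmHg\n",
              x$alpha0, x$beta0, x$m, x$K))
  cat(sprintf("ROS sigmoid: kr = %g /s, a = %g, b = %g /uM (%s OER)\n",
              x$kr, x$a, x$b, x$oer_orientation))
  invisible(x)
}

# ---------------------------------------------------------------------------
# presets and config files

preset_names <- c("table1-tumor", "table1-healthy", "fig1", "fig4-global-ros")

#' Named parameter presets
#'
#' Returns the full parameter bundle (scenario, cell-type and survival
#' constants) for a named configuration:
#' \describe{
#'   \item{\code{"table1-tumor"}}{Tumor spheroid with the measured depletion
#'     rate S_ROD = 15.3 mmHg/s.}
#'   \item{\code{"table1-healthy"}}{Same geometry populated by healthy cells
#'     (Sm = 3.2 mmHg/s), S_ROD = 15.3 mmHg/s.}
#'   \item{\code{"fig1"}}{Depletion-only tumor spheroid with
#'     S_ROD = 160 mmHg/s and the ROS term disabled (kr = 0).}
#'   \item{\code{"fig4-global-ros"}}{S_ROD = 15.3 mmHg/s with the global
#'     (cell-type-agnostic) ROS calibration cp = 4.5e-4 /s,
#'     k_ROS = 0.5e-2 /s.}
#' }
#'
#' @param name Preset name.
#' @return A list with elements \code{model}, \code{cell}, \code{survival}.
#' @examples
#' flash_preset("table1-healthy")
#' @export
flash_preset <- function(name = preset_names) {
  name <- match.arg(name)
  switch(name,
    "table1-tumor" = list(
      model    = flash_params(Sm = 4.2, S_ROD = 15.3),
      cell     = cell_params("tumor"),
      survival = survival_params()),
    "table1-healthy" = list(
      model    = flash_params(Sm = 3.2, S_ROD = 15.3),
      cell     = cell_params("healthy"),
      survival = survival_params()),
    "fig1" = list(
      model    = flash_params(Sm = 4.2, S_ROD = 160),
      cell     = cell_params("tumor"),
      survival = survival_params(kr = 0)),
    "fig4-global-ros" = list(
      model    = flash_params(Sm = 4.2, S_ROD = 15.3),
      cell     = cell_params("global-ros"),
      survival = survival_params()))
}

# allowed config keys per section
config_schema <- list(
  geometry    = c("R", "H"),
  transport   = c("D_sph", "D_med", "p_air"),
  irradiation = c("Sm", "S_ROD", "L_ROD", "dose", "dose_rate"),
  ros         = c("type", "Sm", "cp", "k_ROS"),
  survival    = c("alpha0", "beta0", "m", "K", "kr", "a", "b",
                  "oer_orientation"))

#' Load a parameter bundle from a config file or list
#'
#' Reads a YAML or JSON configuration with sections \code{geometry},
#' \code{transport}, \code{irradiation}, \code{ros} and \code{survival},
#' plus an optional top-level \code{preset} naming one of the shipped
#' presets (see \code{\link{flash_preset}}). Explicit section values
#' override the preset; fields absent from both fall back to the default
#' constants. Unknown sections or keys are rejected.
#'
#' @param config Path to a \code{.yaml}/\code{.yml}/\code{.json} file, or an
#'   already-parsed named list with the same structure.
#' @return A list with elements \code{model} (\code{flash_params}),
#'   \code{cell} (\code{cell_params}) and \code{survival}
#'   (\code{survival_params}).
#' @examples
#' load_params(list(preset = "table1-tumor",
#'                  irradiation = list(dose = 20)))
#' @export
load_params <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    cfg <- switch(ext,
      "yaml" = , "yml" = yaml::read_yaml(config),
      "json" = jsonlite::fromJSON(config, simplifyVector = TRUE),
      stop("unsupported config format '.", ext,
           "' (use YAML or JSON)", call. = FALSE))
  } else if (is.list(config)) {
    cfg <- config
  } else {
    stop("config must be a file path or a named list", call. = FALSE)
  }
  if (length(cfg) && is.null(names(cfg)))
    stop("config must be a named list", call. = FALSE)

  unknown <- setdiff(names(cfg), c("preset", names(config_schema)))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in intersect(names(cfg), names(config_schema))) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  base <- if (!is.null(cfg$preset)) {
    if (!cfg$preset %in% preset_names)
      stop("unknown preset '", cfg$preset, "'; available: ",
           paste(preset_names, collapse = ", "), call. = FALSE)
    flash_preset(cfg$preset)
  } else {
    list(model = flash_params(), cell = cell_params("tumor"),
         survival = survival_params())
  }

  mod <- unclass(base$model)
  for (sec in c("geometry", "transport", "irradiation"))
    for (k in names(cfg[[sec]])) mod[[k]] <- cfg[[sec]][[k]]
  # a fresh L_ROD re-derives S_ROD unless S_ROD itself was also overridden
  if (!is.null(cfg$irradiation$L_ROD) && is.null(cfg$irradiation$S_ROD))
    mod$S_ROD <- mod$L_ROD * mod$dose_rate
  model <- validate_flash_params(structure(mod, class = "flash_params"))

  cell <- base$cell
  if (!is.null(cfg$ros)) {
    type <- if (!is.null(cfg$ros$type)) cfg$ros$type else cell$label
    cell <- cell_params(type,
                        Sm = cfg$ros$Sm, cp = cfg$ros$cp,
                        k_ROS = cfg$ros$k_ROS)
  }

  sv <- unclass(base$survival)
  for (k in names(cfg$survival)) sv[[k]] <- cfg$survival[[k]]
  survival <- validate_survival_params(
    structure(sv, class = "survival_params"))

  list(model = model, cell = cell, survival = survival)
}

#' Serialise a parameter bundle
#'
#' Writes the bundle produced by \code{\link{load_params}} or
#' \code{\link{flash_preset}} back to YAML or JSON; loading the result
#' reproduces the same values exactly.
#'
#' @param bundle A list with \code{model}, \code{cell}, \code{survival}.
#' @param path Output file; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
save_params <- function(bundle, path) {
  m <- bundle$model; ce <- bundle$cell; sv <- bundle$survival
  cfg <- list(
    geometry    = list(R = m$R, H = m$H),
    transport   = list(D_sph = m$D_sph, D_med = m$D_med, p_air = m$p_air),
    irradiation = c(list(Sm = m$Sm, S_ROD = m$S_ROD),
                    if (!is.null(m$L_ROD)) list(L_ROD = m$L_ROD),
                    list(dose = m$dose, dose_rate = m$dose_rate)),
    ros         = list(type = ce$label, Sm = ce$Sm, cp = ce$cp,
                       k_ROS = ce$k_ROS),
    survival    = list(alpha0 = sv$alpha0, beta0 = sv$beta0, m = sv$m,
                       K = sv$K, kr = sv$kr, a = sv$a, b = sv$b,
                       oer_orientation = sv$oer_orientation))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path, precision = 17)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config format '.", ext, "'", call. = FALSE)
  }
  invisible(path)
}

# small validators -----------------------------------------------------------

check_pos <- function(x, name) {
  if (!is.numeric(x) || any(x <= 0))
    stop("parameter '", name, "' must be > 0", call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(x < 0))
    stop("parameter '", name, "' must be >= 0", call. = FALSE)
  invisible(x)
}
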