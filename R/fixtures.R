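#' Shipped synthetic data-generating fixtures
#'
#' A registry of repository-constant truth models used by the simulation
#' study and the tests:
#' \describe{
#'   \item{os_like}{Royston-Parmar model with 3 internal knots and a gently
#'     varying, unimodal hazard; overall-survival-like, with 5-year survival
#'     near 0.44.}
#'   \item{pfs_like}{Royston-Parmar model with 6 internal knots and a sharp
#'     early hazard peak (max near 1.3/yr around 7 months) followed by a
#'     decline; progression-free-survival-like, 5-year survival near 0.29.}
#'   \item{s1 .. s4}{four treatment-effect scenarios relative to the control
#'     hazard: constant HR = 0.7; immediate effect waning to 1; delayed
#'     effect then waning; and a log-linear-in-time HR giving crossing
#'     survival curves, tuned so that the true 5-year RMSTD is ~0.}
#' }
#'
#' These parameter values are synthetic constants of this package, chosen to
#' emulate the qualitative shapes of published oncology trial hazards; they
#' are not estimates from any trial dataset. Alternative parameter sets
#' (e.g. models fitted to real reconstructed trial data) can be supplied via
#' [dgm_from_config()] / [scenario_from_config()].
#'
#' @return named list with `rp_dgm` entries `os_like`, `pfs_like` and
#'   `hr_scenario` entries `s1`..`s4`.
#' @export
fixture_dgms <- function() {
  os <- rp_dgm(knots = log(c(0.05, 0.6, 1.6, 3.5, 12)),
               coefs = c(-2.348293602, 1.608636088, 0.012250117,
                         -0.170251409, 0.263456287),
               label = "os_like (synthetic)")
  pfs <- rp_dgm(knots = log(c(0.04, 0.15, 0.35, 0.7, 1.3, 2.5, 4.5, 15)),
                coefs = c(0.344991516, 1.589474262, -0.126654675,
                          0.096159522, 0.053128806, 0.076283671,
                          0.098925915, -0.267482167),
                label = "pfs_like (synthetic)")
  list(
    os_like = os,
    pfs_like = pfs,
    s1 = hr_scenario("constant", list(hr = 0.7), id = 1,
                     label = "constant effect (proportional hazards)"),
    s2 = hr_scenario("waning", list(a = 0.5, t0 = 2, r = 0.6), id = 2,
                     label = "immediate effect, waning"),
    s3 = hr_scenario("delayed_waning",
                     list(a = 0.6, d = 0.75, r1 = 0.25, w = 3.5, r2 = 0.75),
                     id = 3, label = "delayed effect, then waning"),
    s4 = hr_scenario("loglinear", list(c0 = -0.6, c1 = 0.29324), id = 4,
                     label = "crossing survival curves (RMSTD(5) ~ 0)"))
}

#' Load a Royston-Parmar DGM or hazard-ratio scenario from a YAML config
#'
#' Allows the shipped synthetic fixtures to be replaced by externally
#' estimated parameter sets. A DGM config has fields `knots` (log-time),
#' `coefs` and optional `label`; a scenario config has `form`, `pars` and
#' optional `id`, `label` (see [hr_scenario()] for the forms).
#'
#' @param path YAML file path.
#' @return an [rp_dgm()] or [hr_scenario()].
#' @export
dgm_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rp_dgm(knots = as.numeric(cfg$knots), coefs = as.numeric(cfg$coefs),
         label = cfg$label %||% "")
}

#' @rdname dgm_from_config
#' @export
scenario_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  hr_scenario(form = cfg$form, pars = cfg$pars, id = cfg$id %||% NA,
              label = cfg$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
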