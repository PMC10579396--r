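# Mutant and functional-submodule scenarios -----------------------------------

SCENARIO_NAMES <- c("WT", "bem1_delta", "bem1_bem3_delta", "cdc42_immobile",
                    "gap_fast", "gef_boost")

#' Apply a mutant / submodule scenario to a model configuration
#'
#' Scenarios encode the genetic and biophysical perturbations studied with the
#' model as transformations of the parameter set and copy numbers:
#'
#' \describe{
#'   \item{`WT`}{identity.}
#'   \item{`bem1_delta`}{Bem1 knockout. `N_Bem1` is set to 0 and the three
#'     Bem1-containing species (`c_B`, `m_b`, `m_bf`) are removed from the
#'     dynamical system, leaving a reduced 5-membrane / 2-cytosol model. The
#'     structural reduction is dynamically identical to running the full system
#'     at `N_Bem1 = 0` but keeps all Jacobians nonsingular.}
#'   \item{`bem1_bem3_delta`}{`bem1_delta` plus a reduction of the total GAP
#'     copy number by the `bem3_fraction` knob (default 0.25, the approximate
#'     share of Bem3 in the total Cdc42-GAP pool).}
#'   \item{`cdc42_immobile`}{suppresses all Cdc42 redistribution: attachment,
#'     detachment and recruitment rates of Cdc42 (`k_D`, `k_tD`, `k_bfD`,
#'     `k_d`) are set to 0, all Cdc42 is placed on the membrane, and the
#'     membrane diffusion constant of the Cdc42 species is set to the
#'     `immobile_D_m` knob (default 1e-4 um^2/s; a small positive value keeps
#'     the stability matrices well-conditioned).}
#'   \item{`gap_fast`}{disables polar GAP saturation by multiplying the
#'     GAP-Cdc42 complex dissociation rate `k_gt` by `gap_fast_factor`
#'     (default 1e3), so complexes dissociate before free GAPs can be
#'     appreciably sequestered. With `gap_fast_preserve_ratio = TRUE` the
#'     complex formation rate `k_tg` is scaled by the same factor, preserving
#'     the equilibrium constant while removing sequestration; optionally the
#'     free-GAP membrane diffusion constant is raised by `gap_D_m_factor`.}
#'   \item{`gef_boost`}{multiplies the GEF catalytic activities `k_fd` and
#'     `k_bfd` by `gef_boost_factor` (default 2), emulating a global relief of
#'     Cdc24 auto-inhibition.}
#' }
#'
#' Scenarios compose: `scenario` may be a character vector, applied in order,
#' e.g. `c("bem1_delta", "gap_fast")` disables both polar activation and polar
#' GAP saturation.
#'
#' @param params A [parameter_set()].
#' @param targets A [copy_numbers()] object.
#' @param scenario Character vector of scenario names (see above).
#' @param knobs Named list of magnitude knobs: `bem3_fraction`,
#'   `immobile_D_m`, `gap_fast_factor`, `gap_fast_preserve_ratio`,
#'   `gap_D_m_factor`, `gef_boost_factor`.
#' @return An object of class `"cdc42_system"`: transformed `params` and
#'   `targets`, integer index vectors `m_active` / `c_active` of the membrane
#'   and cytosolic species kept in the dynamical system, a `reduced` flag,
#'   a `cdc42_on_membrane` flag used when constructing initial states, and the
#'   scenario labels.
#' @export
apply_scenario <- function(params, targets, scenario = "WT", knobs = list()) {
  stopifnot(inherits(params, "cdc42_params"),
            inherits(targets, "cdc42_copy_numbers"))
  if (!is.character(scenario) || !length(scenario))
    stop("apply_scenario: 'scenario' must be a character vector", call. = FALSE)
  unknown <- setdiff(scenario, SCENARIO_NAMES)
  if (length(unknown))
    stop("apply_scenario: unknown scenario name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  kn <- utils::modifyList(list(bem3_fraction = 0.25, immobile_D_m = 1e-4,
                               gap_fast_factor = 1e3,
                               gap_fast_preserve_ratio = FALSE,
                               gap_D_m_factor = 1, gef_boost_factor = 2),
                          knobs)
  if (kn$bem3_fraction < 0 || kn$bem3_fraction > 1)
    stop("apply_scenario: 'bem3_fraction' must lie in [0, 1]", call. = FALSE)
  if (kn$immobile_D_m < 0 || kn$gap_fast_factor <= 0 || kn$gef_boost_factor <= 0)
    stop("apply_scenario: scenario knobs must be positive", call. = FALSE)

  tg <- unclass(targets)
  m_active <- seq_along(MEM_SPECIES)
  c_active <- seq_along(CYT_SPECIES)
  cdc42_on_membrane <- FALSE

  for (sc in scenario) {
    switch(sc,
      WT = NULL,
      bem1_delta = {
        tg[["N_Bem1"]] <- 0
        m_active <- setdiff(m_active, match(c("m_b", "m_bf"), MEM_SPECIES))
        c_active <- setdiff(c_active, match("c_B", CYT_SPECIES))
      },
      bem1_bem3_delta = {
        tg[["N_Bem1"]] <- 0
        m_active <- setdiff(m_active, match(c("m_b", "m_bf"), MEM_SPECIES))
        c_active <- setdiff(c_active, match("c_B", CYT_SPECIES))
        tg[["N_GAPs"]] <- (1 - kn$bem3_fraction) * tg[["N_GAPs"]]
      },
      cdc42_immobile = {
        params <- update_params(params, k_D = 0, k_tD = 0, k_bfD = 0, k_d = 0,
                                D_m = c(m_d = kn$immobile_D_m,
                                        m_t = kn$immobile_D_m,
                                        m_tg = kn$immobile_D_m))
        # with all exchange rates zero the cytosolic Cdc42 pool decouples;
        # all Cdc42 lives on the membrane and c_D is dropped from the system
        c_active <- setdiff(c_active, match("c_D", CYT_SPECIES))
        cdc42_on_membrane <- TRUE
      },
      gap_fast = {
        params <- update_params(params,
          k_gt = params$rates[["k_gt"]] * kn$gap_fast_factor)
        if (isTRUE(kn$gap_fast_preserve_ratio))
          params <- update_params(params,
            k_tg = params$rates[["k_tg"]] * kn$gap_fast_factor)
        if (kn$gap_D_m_factor != 1)
          params <- update_params(params,
            D_m = c(m_g = params$D_m[["m_g"]] * kn$gap_D_m_factor))
      },
      gef_boost = {
        params <- update_params(params,
          k_fd = params$rates[["k_fd"]] * kn$gef_boost_factor,
          k_bfd = params$rates[["k_bfd"]] * kn$gef_boost_factor)
      }
    )
  }

  structure(list(params = params,
                 targets = do.call(copy_numbers, as.list(tg)),
                 m_active = m_active, c_active = c_active,
                 reduced = length(m_active) < length(MEM_SPECIES),
                 cdc42_on_membrane = cdc42_on_membrane,
                 scenario = scenario, knobs = kn),
            class = "cdc42_system")
}

#' @export
print.cdc42_system <- function(x, ...) {
  cat("Cdc42 model system, scenario:", paste(x$scenario, collapse = " + "), "\n")
  cat("  active membrane species:",
      paste(MEM_SPECIES[x$m_active], collapse = ", "), "\n")
  cat("  active cytosolic species:",
      paste(CYT_SPECIES[x$c_active], collapse = ", "), "\n")
  cat("  targets:", paste(sprintf("%s=%g", names(unclass(x$targets)),
                                  unclass(x$targets)), collapse = ", "), "\n")
  invisible(x)
}

# Conserved pools present in a (possibly reduced) system
active_pools <- function(sys) {
  keep <- vapply(PROTEIN_POOLS, function(p) {
    any(match(p$m, MEM_SPECIES) %in% sys$m_active) ||
      any(match(p$c, CYT_SPECIES) %in% sys$c_active)
  }, logical(1))
  # a pool matters only if its total can be nonzero in the reduced system
  if (!"c_B" %in% CYT_SPECIES[sys$c_active] &&
      !any(c("m_b", "m_bf") %in% MEM_SPECIES[sys$m_active]))
    keep[["N_Bem1"]] <- FALSE
  names(keep)[keep]
}
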