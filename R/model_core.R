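# Species bookkeeping ---------------------------------------------------------

#' Species names of the Cdc42 polarization model
#'
#' The model tracks three cytosolic (bulk) species and seven membrane species.
#' Cytosolic concentrations carry units of molecules/um^3, membrane
#' concentrations molecules/um^2. The ordering below is fixed and used for all
#' vectors and matrices in the package.
#'
#' * `c_D` cytosolic Cdc42-GDP (potentially GDI-bound, lumped)
#' * `c_B` cytosolic Bem1
#' * `c_F` cytosolic GEF (Cdc24)
#' * `m_d` membrane-bound free Cdc42-GDP
#' * `m_t` membrane-bound Cdc42-GTP
#' * `m_tg` heterodimeric GAP-Cdc42 complexes
#' * `m_g` membrane-bound free GAP
#' * `m_b` membrane-bound Bem1
#' * `m_bf` heterodimeric Bem1-GEF complexes
#' * `m_f` membrane-bound free GEF
#'
#' @format Character vectors.
#' @name species
#' @keywords internal
NULL

CYT_SPECIES <- c("c_D", "c_B", "c_F")
MEM_SPECIES <- c("m_d", "m_t", "m_tg", "m_g", "m_b", "m_bf", "m_f")

RATE_NAMES <- c("k_D", "k_tD", "k_bfD", "k_d", "k_fd", "k_bfd", "k_tg",
                "k_gt", "k_tB", "k_b", "k_bF", "k_bf", "k_F", "k_f")

# Geometry ---------------------------------------------------------------------

#' Spherical cell geometry
#'
#' The cell is modelled as a sphere of radius `R` with a diffusive cytosol
#' (bulk) inside and the membrane on its surface. Volume and surface area are
#' always derived from `R` and cannot be set independently.
#'
#' @param R Sphere radius in micrometres; must be positive.
#' @return An object of class `"cdc42_geometry"` with fields `R`, `V`
#'   (volume, um^3) and `S` (surface area, um^2).
#' @examples
#' geom <- geometry(2.5)
#' geom$V / geom$S   # = R/3
#' @export
geometry <- function(R) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("geometry: 'R' must be a single positive number", call. = FALSE)
  structure(list(R = R, V = 4 / 3 * pi * R^3, S = 4 * pi * R^2),
            class = "cdc42_geometry")
}

#' @export
print.cdc42_geometry <- function(x, ...) {
  cat(sprintf("Spherical geometry: R = %g um, V = %g um^3, S = %g um^2\n",
              x$R, x$V, x$S))
  invisible(x)
}

# Parameter set ----------------------------------------------------------------

#' Kinetic and transport parameters of the Cdc42 model
#'
#' Collects the 14 mass-action rate constants of the reaction network together
#' with the cytosolic diffusion constant `D_c` (shared by all bulk species) and
#' the per-species membrane diffusion constants `D_m`.
#'
#' Units follow from the concentration units (bulk um^-3, membrane um^-2):
#' \describe{
#'   \item{k_D}{basal Cdc42-GDP membrane attachment, um/s}
#'   \item{k_tD}{Cdc42-GTP-mediated recruitment of cytosolic Cdc42-GDP, um^3/s}
#'   \item{k_bfD}{Bem1-GEF-complex-mediated recruitment-and-activation of
#'     cytosolic Cdc42-GDP, um^3/s}
#'   \item{k_d}{Cdc42-GDP detachment, 1/s}
#'   \item{k_fd}{Cdc42-GDP activation by membrane-bound free GEF, um^2/s}
#'   \item{k_bfd}{Cdc42-GDP activation by Bem1-GEF complexes, um^2/s}
#'   \item{k_tg}{GAP + Cdc42-GTP complex formation, um^2/s}
#'   \item{k_gt}{GAP-Cdc42 complex dissociation (hydrolysis completion), 1/s}
#'   \item{k_tB}{Bem1 recruitment by Cdc42-GTP, um^3/s}
#'   \item{k_b}{Bem1 detachment, 1/s}
#'   \item{k_bF}{Bem1-GEF complex formation from cytosolic GEF, um^3/s}
#'   \item{k_bf}{Bem1-GEF complex dissociation, 1/s}
#'   \item{k_F}{basal GEF attachment, um/s}
#'   \item{k_f}{GEF detachment, 1/s}
#' }
#'
#' @param ... Named rate constants (see above). Unnamed rates default to 0.
#' @param D_c Cytosolic diffusion constant, um^2/s (one shared value).
#' @param D_m Membrane diffusion constant(s), um^2/s. Either a single shared
#'   value or a named vector over the membrane species
#'   (`m_d`, `m_t`, `m_tg`, `m_g`, `m_b`, `m_bf`, `m_f`).
#' @return An object of class `"cdc42_params"`: a list with a named `rates`
#'   vector, `D_c`, and a full named `D_m` vector.
#' @examples
#' p <- parameter_set(k_D = 0.1, k_d = 1, D_c = 10, D_m = 0.01)
#' p$rates[["k_d"]]
#' @export
parameter_set <- function(..., D_c = 10, D_m = 0.01) {
  supplied <- list(...)
  if (length(supplied) && (is.null(names(supplied)) || any(names(supplied) == "")))
    stop("parameter_set: all rate constants must be named", call. = FALSE)
  unknown <- setdiff(names(supplied), RATE_NAMES)
  if (length(unknown))
    stop("parameter_set: unknown rate name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rates <- stats::setNames(numeric(length(RATE_NAMES)), RATE_NAMES)
  rates[names(supplied)] <- vapply(supplied, as.numeric, numeric(1))
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("parameter_set: all rates must be finite and >= 0", call. = FALSE)
  if (!is.numeric(D_c) || length(D_c) != 1L || D_c <= 0)
    stop("parameter_set: 'D_c' must be a single positive number", call. = FALSE)
  D_m_full <- expand_D_m(D_m)
  structure(list(rates = rates, D_c = as.numeric(D_c), D_m = D_m_full),
            class = "cdc42_params")
}

expand_D_m <- function(D_m) {
  if (length(D_m) == 1L && is.null(names(D_m))) {
    D_m_full <- stats::setNames(rep(as.numeric(D_m), length(MEM_SPECIES)),
                                MEM_SPECIES)
  } else {
    if (is.null(names(D_m)) || !all(names(D_m) %in% MEM_SPECIES))
      stop("'D_m' must be a single value or named over the membrane species",
           call. = FALSE)
    D_m_full <- stats::setNames(rep(NA_real_, length(MEM_SPECIES)), MEM_SPECIES)
    D_m_full[names(D_m)] <- as.numeric(D_m)
    if (anyNA(D_m_full))
      stop("'D_m' must cover every membrane species when given as a named vector",
           call. = FALSE)
  }
  if (any(!is.finite(D_m_full)) || any(D_m_full < 0))
    stop("'D_m' entries must be finite and >= 0", call. = FALSE)
  D_m_full
}

#' Modify rates or diffusion constants of a parameter set
#'
#' @param params A [parameter_set()].
#' @param ... Named rate constants to overwrite.
#' @param D_c,D_m Optional replacement diffusion constants.
#' @return A new `"cdc42_params"` object.
#' @export
update_params <- function(params, ..., D_c = NULL, D_m = NULL) {
  stopifnot(inherits(params, "cdc42_params"))
  repl <- list(...)
  rates <- params$rates
  if (length(repl)) {
    unknown <- setdiff(names(repl), RATE_NAMES)
    if (length(unknown))
      stop("update_params: unknown rate name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    rates[names(repl)] <- vapply(repl, as.numeric, numeric(1))
  }
  out <- params
  out$rates <- rates
  if (!is.null(D_c)) out$D_c <- as.numeric(D_c)
  if (!is.null(D_m)) {
    if (length(D_m) == 1L && is.null(names(D_m))) {
      out$D_m <- expand_D_m(D_m)
    } else {
      dm <- out$D_m
      dm[names(D_m)] <- as.numeric(D_m)
      out$D_m <- expand_D_m(dm)
    }
  }
  if (any(out$rates < 0) || out$D_c <= 0 || any(out$D_m < 0))
    stop("update_params: invalid (negative) parameter value", call. = FALSE)
  out
}

#' @export
print.cdc42_params <- function(x, ...) {
  cat("Cdc42 model parameter set\n")
  print(signif(x$rates, 4))
  cat(sprintf("D_c = %g um^2/s; D_m in [%g, %g] um^2/s\n",
              x$D_c, min(x$D_m), max(x$D_m)))
  invisible(x)
}

# Copy numbers -----------------------------------------------------------------

#' Conserved protein copy numbers
#'
#' Total molecule counts of the four conserved proteins. These are the primary
#' control parameters of the model: the reaction-diffusion dynamics redistribute
#' each protein between its cytosolic and membrane-bound forms but never change
#' the totals. GAPs are purely membrane-resident (no cytosolic pool).
#'
#' @param N_Cdc42,N_GAPs,N_Bem1,N_GEF Nonnegative molecule counts.
#' @return An object of class `"cdc42_copy_numbers"` (named numeric vector).
#' @export
copy_numbers <- function(N_Cdc42 = 0, N_GAPs = 0, N_Bem1 = 0, N_GEF = 0) {
  x <- c(N_Cdc42 = as.numeric(N_Cdc42), N_GAPs = as.numeric(N_GAPs),
         N_Bem1 = as.numeric(N_Bem1), N_GEF = as.numeric(N_GEF))
  if (any(!is.finite(x)) || any(x < 0))
    stop("copy_numbers: counts must be finite and >= 0", call. = FALSE)
  structure(x, class = "cdc42_copy_numbers")
}

# Concentration point ----------------------------------------------------------

#' A laterally uniform concentration point
#'
#' Bundles the three cytosolic and seven membrane concentrations at which
#' reaction terms are evaluated.
#'
#' @param c Numeric 3-vector `(c_D, c_B, c_F)` in um^-3 (names optional).
#' @param m Numeric 7-vector `(m_d, m_t, m_tg, m_g, m_b, m_bf, m_f)` in um^-2.
#' @return An object of class `"cdc42_point"` with named `c` and `m` fields.
#' @export
concentration_point <- function(c = numeric(3), m = numeric(7)) {
  c <- as.numeric(c); m <- as.numeric(m)
  if (length(c) != 3L || length(m) != 7L)
    stop("concentration_point: need 3 cytosolic and 7 membrane concentrations",
         call. = FALSE)
  if (any(!is.finite(c)) || any(!is.finite(m)) || any(c < 0) || any(m < 0))
    stop("concentration_point: concentrations must be finite and >= 0",
         call. = FALSE)
  structure(list(c = stats::setNames(c, CYT_SPECIES),
                 m = stats::setNames(m, MEM_SPECIES)),
            class = "cdc42_point")
}

validate_point <- function(point) {
  if (!inherits(point, "cdc42_point"))
    point <- concentration_point(point$c, point$m)
  if (any(point$c < 0) || any(point$m < 0))
    stop("negative concentrations are not a valid model state", call. = FALSE)
  point
}

# Reaction terms ---------------------------------------------------------------

#' Attachment-detachment bulk fluxes f
#'
#' Net fluxes of the three cytosol-exchangeable proteins through the membrane,
#' in um^-2 s^-1. Positive values are net flux from the membrane into the bulk
#' (detachment exceeding attachment). These fluxes enter the bulk diffusion
#' problem as a Robin boundary condition and the membrane balance with opposite
#' sign, so that each attachment or detachment event moves mass exactly between
#' the two compartments.
#'
#' @param point A [concentration_point()].
#' @param params A [parameter_set()].
#' @return Named numeric 3-vector `(f_D, f_B, f_F)`.
#' @export
reaction_flux_f <- function(point, params) {
  point <- validate_point(point)
  k <- params$rates
  cc <- point$c; m <- point$m
  f_D <- k[["k_d"]] * m[["m_d"]] -
    (k[["k_D"]] + k[["k_tD"]] * m[["m_t"]] + k[["k_bfD"]] * m[["m_bf"]]) * cc[["c_D"]]
  f_B <- k[["k_b"]] * m[["m_b"]] - k[["k_tB"]] * m[["m_t"]] * cc[["c_B"]]
  f_F <- k[["k_f"]] * m[["m_f"]] + k[["k_bf"]] * m[["m_bf"]] -
    (k[["k_F"]] + k[["k_bF"]] * m[["m_b"]]) * cc[["c_F"]]
  c(f_D = f_D, f_B = f_B, f_F = f_F)
}

#' Membrane reaction rates g
#'
#' Net production rates of the seven membrane species, in um^-2 s^-1,
#' from the mass-action network: basal and Cdc42-GTP-mediated attachment of
#' Cdc42-GDP, recruitment-and-activation by Bem1-GEF complexes, activation by
#' free GEF and by complexes, catalytic hydrolysis through a transient
#' GAP-Cdc42 complex, Bem1 recruitment by Cdc42-GTP, Bem1-GEF complex
#' formation, and basal GEF membrane cycling. The scheme conserves each
#' protein: the membrane rates of every protein's species sum to minus its
#' bulk flux (see [reaction_flux_f()]), and GAP species satisfy
#' `g_g + g_tg = 0` identically.
#'
#' @inheritParams reaction_flux_f
#' @return Named numeric 7-vector `(g_d, g_t, g_tg, g_g, g_b, g_bf, g_f)`.
#' @export
reaction_rate_g <- function(point, params) {
  point <- validate_point(point)
  k <- params$rates
  cc <- point$c; m <- point$m
  act <- k[["k_fd"]] * m[["m_f"]] + k[["k_bfd"]] * m[["m_bf"]]  # GEF activity on m_d
  g_d <- (k[["k_D"]] + k[["k_tD"]] * m[["m_t"]]) * cc[["c_D"]] +
    k[["k_gt"]] * m[["m_tg"]] - act * m[["m_d"]] - k[["k_d"]] * m[["m_d"]]
  g_t <- act * m[["m_d"]] + k[["k_bfD"]] * m[["m_bf"]] * cc[["c_D"]] -
    k[["k_tg"]] * m[["m_t"]] * m[["m_g"]]
  g_tg <- k[["k_tg"]] * m[["m_t"]] * m[["m_g"]] - k[["k_gt"]] * m[["m_tg"]]
  g_g <- -g_tg
  g_b <- k[["k_tB"]] * m[["m_t"]] * cc[["c_B"]] - k[["k_b"]] * m[["m_b"]] +
    k[["k_bf"]] * m[["m_bf"]] - k[["k_bF"]] * m[["m_b"]] * cc[["c_F"]]
  g_bf <- k[["k_bF"]] * m[["m_b"]] * cc[["c_F"]] - k[["k_bf"]] * m[["m_bf"]]
  g_f <- k[["k_F"]] * cc[["c_F"]] - k[["k_f"]] * m[["m_f"]]
  c(g_d = g_d, g_t = g_t, g_tg = g_tg, g_g = g_g, g_b = g_b, g_bf = g_bf,
    g_f = g_f)
}

#' Exact Jacobians of the reaction terms
#'
#' Partial derivatives of the membrane rates `g` and bulk fluxes `f` with
#' respect to the membrane and cytosolic concentrations, evaluated at a point.
#' These are the building blocks of the linearized dynamics used by the
#' stability analysis.
#'
#' @inheritParams reaction_flux_f
#' @return A list of four matrices: `G_m` (7x7, dg/dm), `G_c` (7x3, dg/dc),
#'   `F_m` (3x7, df/dm), `F_c` (3x3, df/dc), with species dimnames.
#' @export
reaction_jacobians <- function(point, params) {
  point <- validate_point(point)
  k <- params$rates
  cc <- point$c; m <- point$m
  G_m <- matrix(0, 7, 7, dimnames = list(MEM_SPECIES, MEM_SPECIES))
  G_c <- matrix(0, 7, 3, dimnames = list(MEM_SPECIES, CYT_SPECIES))
  F_m <- matrix(0, 3, 7, dimnames = list(CYT_SPECIES, MEM_SPECIES))
  F_c <- matrix(0, 3, 3, dimnames = list(CYT_SPECIES, CYT_SPECIES))
  act <- k[["k_fd"]] * m[["m_f"]] + k[["k_bfd"]] * m[["m_bf"]]

  # f_D row
  F_c["c_D", "c_D"] <- -(k[["k_D"]] + k[["k_tD"]] * m[["m_t"]] +
                           k[["k_bfD"]] * m[["m_bf"]])
  F_m["c_D", "m_d"] <- k[["k_d"]]
  F_m["c_D", "m_t"] <- -k[["k_tD"]] * cc[["c_D"]]
  F_m["c_D", "m_bf"] <- -k[["k_bfD"]] * cc[["c_D"]]
  # f_B row
  F_c["c_B", "c_B"] <- -k[["k_tB"]] * m[["m_t"]]
  F_m["c_B", "m_t"] <- -k[["k_tB"]] * cc[["c_B"]]
  F_m["c_B", "m_b"] <- k[["k_b"]]
  # f_F row
  F_c["c_F", "c_F"] <- -(k[["k_F"]] + k[["k_bF"]] * m[["m_b"]])
  F_m["c_F", "m_f"] <- k[["k_f"]]
  F_m["c_F", "m_bf"] <- k[["k_bf"]]
  F_m["c_F", "m_b"] <- -k[["k_bF"]] * cc[["c_F"]]

  # g_d row
  G_m["m_d", "m_d"] <- -act - k[["k_d"]]
  G_m["m_d", "m_t"] <- k[["k_tD"]] * cc[["c_D"]]
  G_m["m_d", "m_tg"] <- k[["k_gt"]]
  G_m["m_d", "m_bf"] <- -k[["k_bfd"]] * m[["m_d"]]
  G_m["m_d", "m_f"] <- -k[["k_fd"]] * m[["m_d"]]
  G_c["m_d", "c_D"] <- k[["k_D"]] + k[["k_tD"]] * m[["m_t"]]
  # g_t row
  G_m["m_t", "m_d"] <- act
  G_m["m_t", "m_t"] <- -k[["k_tg"]] * m[["m_g"]]
  G_m["m_t", "m_g"] <- -k[["k_tg"]] * m[["m_t"]]
  G_m["m_t", "m_bf"] <- k[["k_bfd"]] * m[["m_d"]] + k[["k_bfD"]] * cc[["c_D"]]
  G_m["m_t", "m_f"] <- k[["k_fd"]] * m[["m_d"]]
  G_c["m_t", "c_D"] <- k[["k_bfD"]] * m[["m_bf"]]
  # g_tg row and g_g = -g_tg
  G_m["m_tg", "m_t"] <- k[["k_tg"]] * m[["m_g"]]
  G_m["m_tg", "m_g"] <- k[["k_tg"]] * m[["m_t"]]
  G_m["m_tg", "m_tg"] <- -k[["k_gt"]]
  G_m["m_g", ] <- -G_m["m_tg", ]
  # g_b row
  G_m["m_b", "m_t"] <- k[["k_tB"]] * cc[["c_B"]]
  G_m["m_b", "m_b"] <- -k[["k_b"]] - k[["k_bF"]] * cc[["c_F"]]
  G_m["m_b", "m_bf"] <- k[["k_bf"]]
  G_c["m_b", "c_B"] <- k[["k_tB"]] * m[["m_t"]]
  G_c["m_b", "c_F"] <- -k[["k_bF"]] * m[["m_b"]]
  # g_bf row
  G_m["m_bf", "m_b"] <- k[["k_bF"]] * cc[["c_F"]]
  G_m["m_bf", "m_bf"] <- -k[["k_bf"]]
  G_c["m_bf", "c_F"] <- k[["k_bF"]] * m[["m_b"]]
  # g_f row
  G_m["m_f", "m_f"] <- -k[["k_f"]]
  G_c["m_f", "c_F"] <- k[["k_F"]]

  list(G_m = G_m, G_c = G_c, F_m = F_m, F_c = F_c)
}

# Copy-number audit ------------------------------------------------------------

#' Copy numbers implied by a spatially uniform state
#'
#' Integrates a laterally uniform concentration point over the cell: each
#' protein's total is the bulk volume times its cytosolic concentration plus
#' the surface area times the sum of its membrane species.
#'
#' @param point A [concentration_point()], interpreted as spatially uniform.
#' @param geom A [geometry()].
#' @return A [copy_numbers()] object.
#' @export
copy_numbers_of <- function(point, geom) {
  stopifnot(inherits(geom, "cdc42_geometry"))
  cc <- point$c; m <- point$m
  copy_numbers(
    N_Cdc42 = geom$V * cc[["c_D"]] +
      geom$S * (m[["m_d"]] + m[["m_t"]] + m[["m_tg"]]),
    N_GAPs = geom$S * (m[["m_g"]] + m[["m_tg"]]),
    N_Bem1 = geom$V * cc[["c_B"]] + geom$S * (m[["m_b"]] + m[["m_bf"]]),
    N_GEF = geom$V * cc[["c_F"]] + geom$S * (m[["m_f"]] + m[["m_bf"]])
  )
}

# Membership of each membrane/cytosol species in a conserved protein pool,
# used by steady-state constraints and conservation audits.
PROTEIN_POOLS <- list(
  N_Cdc42 = list(c = "c_D", m = c("m_d", "m_t", "m_tg")),
  N_GAPs = list(c = character(0), m = c("m_g", "m_tg")),
  N_Bem1 = list(c = "c_B", m = c("m_b", "m_bf")),
  N_GEF = list(c = "c_F", m = c("m_f", "m_bf"))
)
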