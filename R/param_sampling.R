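# Parameter-space sampling with phenotype viability filtering -----------------

#' Default log-uniform sampling ranges for the 14 kinetic rates
#'
#' Each rate is sampled log-uniformly over four orders of magnitude centred on
#' a dimensional estimate for its rate class: first-order detachment and
#' dissociation rates 1e-2 to 1e2 per second; basal attachment rates 1e-2 to
#' 1e2 um/s; bulk-bimolecular recruitment rates 1e-2 to 1e2 um^3/s; and
#' membrane-bimolecular rates 1e-3 to 1e1 um^2/s.
#'
#' @return Named list of `c(lo, hi)` ranges over the rate names.
#' @export
default_rate_ranges <- function() {
  r <- list()
  for (k in c("k_d", "k_gt", "k_b", "k_bf", "k_f"))   r[[k]] <- c(1e-2, 1e2)
  for (k in c("k_D", "k_F"))                          r[[k]] <- c(1e-2, 1e2)
  for (k in c("k_tD", "k_bfD", "k_tB", "k_bF"))       r[[k]] <- c(1e-2, 1e2)
  for (k in c("k_fd", "k_bfd", "k_tg"))               r[[k]] <- c(1e-3, 1e1)
  r[RATE_NAMES]
}

#' Default wild-type copy-number anchors
#'
#' Order-of-magnitude molecule counts at which the viability predicates are
#' evaluated.
#' @return A [copy_numbers()] object.
#' @export
default_anchors <- function() {
  copy_numbers(N_Cdc42 = 5000, N_GAPs = 2000, N_Bem1 = 2000, N_GEF = 1000)
}

#' Sampling specification
#'
#' @param n Number of parameter sets to draw.
#' @param seed Integer RNG seed; the emitted stream is bit-reproducible and
#'   stable in order (draw i is the same for any n >= i).
#' @param ranges Named list of `c(lo, hi)` log-uniform ranges per rate;
#'   defaults to [default_rate_ranges()]. Degenerate ranges (`lo == hi`) pin a
#'   rate.
#' @param anchors Copy-number anchors for the phenotype predicates; defaults
#'   to [default_anchors()].
#' @param D_c,D_m,R Fixed transport/geometry values attached to every draw.
#' @return An object of class `"cdc42_sampling_spec"`.
#' @export
sampling_spec <- function(n, seed = 1L, ranges = default_rate_ranges(),
                          anchors = default_anchors(), D_c = 10, D_m = 0.01,
                          R = 2.5) {
  stopifnot(n >= 1)
  unknown <- setdiff(names(ranges), RATE_NAMES)
  if (length(unknown))
    stop("sampling_spec: unknown rate(s) in ranges: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  full <- default_rate_ranges()
  full[names(ranges)] <- ranges
  for (k in names(full)) {
    rg <- full[[k]]
    if (length(rg) != 2L || any(rg <= 0) || rg[1] > rg[2])
      stop("sampling_spec: range for ", k, " must satisfy 0 < lo <= hi",
           call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed), ranges = full,
                 anchors = anchors, D_c = D_c, D_m = D_m, R = R),
            class = "cdc42_sampling_spec")
}

#' Draw log-uniform parameter sets
#'
#' Draws `spec$n` independent parameter sets, each rate log-uniform over its
#' range. The uniform variates are consumed draw-major so that the stream is
#' stable: the i-th parameter set is identical for every `n >= i` at fixed
#' seed.
#'
#' @param spec A [sampling_spec()].
#' @return List with `draws` (n x 14 matrix of rates, columns in canonical
#'   rate order) and `params` (list of [parameter_set()] objects).
#' @export
sample_parameter_sets <- function(spec) {
  stopifnot(inherits(spec, "cdc42_sampling_spec"))
  np <- length(RATE_NAMES)
  u <- local({
    set.seed(spec$seed)
    matrix(stats::runif(spec$n * np), ncol = np, byrow = TRUE)
  })
  lo <- log(vapply(spec$ranges, `[`, numeric(1), 1L))
  hi <- log(vapply(spec$ranges, `[`, numeric(1), 2L))
  draws <- exp(sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`))
  colnames(draws) <- RATE_NAMES
  params <- lapply(seq_len(spec$n), function(i) {
    do.call(parameter_set,
            c(as.list(draws[i, ]), list(D_c = spec$D_c, D_m = spec$D_m)))
  })
  list(draws = draws, params = params)
}

#' Mutant-phenotype viability filter
#'
#' Evaluates, by linear stability analysis, the four phenotype predicates that
#' a parameter set must satisfy to be consistent with the observed mutant
#' behaviour:
#' \describe{
#'   \item{P1}{wild type polarizes: WT laterally unstable at the anchor copy
#'     numbers.}
#'   \item{P2}{Bem1 deletion does not polarize: `bem1_delta` stable at the
#'     anchors.}
#'   \item{P3}{the additional loss of Bem3 rescues: `bem1_delta` with the GAP
#'     copy number reduced to 75% is laterally unstable.}
#'   \item{P4}{the WT mechanism tolerates low Cdc42 expression: WT laterally
#'     unstable with `N_Cdc42` scaled by `cdc42_low_factor` (default 0.2).}
#' }
#'
#' @param params A [parameter_set()].
#' @param anchors A [copy_numbers()] with the WT anchor counts.
#' @param geom A [geometry()].
#' @param bem3_fraction GAP copy-number share removed with Bem3 (default
#'   0.25).
#' @param cdc42_low_factor Cdc42 reduction factor for P4 (default 0.2).
#' @param l_max Largest mode scanned.
#' @param short_circuit If `TRUE`, stop at the first failed predicate and
#'   leave the remaining ones unevaluated (`NA`); the overall `pass` flag is
#'   unaffected. Used by large screens.
#' @return List with logical `P1..P4`, overall `pass`, and a `reason` string
#'   for the first failed or errored predicate (`NA` if viable).
#' @export
viability_filter <- function(params, anchors, geom, bem3_fraction = 0.25,
                             cdc42_low_factor = 0.2, l_max = 20L,
                             short_circuit = FALSE) {
  an <- unclass(anchors)
  pred <- function(targets, scenario, want_unstable, knobs = list()) {
    cl <- tryCatch(
      suppressWarnings(classify(params, targets, geom, scenario, knobs,
                                l_max = l_max, compute_sigma = FALSE,
                                early_exit = TRUE, relax_first = FALSE)),
      error = function(e) NULL)
    if (is.null(cl)) return(NA)
    if (cl$classification == "no_valid_base_state") return(NA)
    (cl$classification == "laterally_unstable") == want_unstable
  }
  P1 <- P2 <- P3 <- P4 <- NA
  ok <- function(x) !short_circuit || isTRUE(x)
  P1 <- pred(anchors, "WT", TRUE)
  if (ok(P1))
    P2 <- pred(anchors, "bem1_delta", FALSE)
  if (ok(P1) && ok(P2))
    P3 <- pred(anchors, "bem1_bem3_delta", TRUE,
               knobs = list(bem3_fraction = bem3_fraction))
  if (ok(P1) && ok(P2) && ok(P3))
    P4 <- pred(copy_numbers(N_Cdc42 = cdc42_low_factor * an[["N_Cdc42"]],
                            N_GAPs = an[["N_GAPs"]], N_Bem1 = an[["N_Bem1"]],
                            N_GEF = an[["N_GEF"]]),
               "WT", TRUE)
  out <- c(P1 = P1, P2 = P2, P3 = P3, P4 = P4)
  pass <- all(!is.na(out) & out)
  failed <- names(out)[is.na(out) | !out]
  reason <- if (pass) NA_character_ else
    paste0(failed[1], if (is.na(out[failed[1]])) " (no valid base state)" else "")
  list(P1 = isTRUE(P1), P2 = isTRUE(P2), P3 = isTRUE(P3), P4 = isTRUE(P4),
       predicate_raw = out, pass = pass, reason = reason)
}

#' Run the sampling screen
#'
#' Draws parameter sets, applies the [viability_filter()] to each, and
#' tabulates the outcomes. The full pipeline is deterministic given the seed.
#'
#' @param spec A [sampling_spec()].
#' @param progress Print a progress line every `progress` draws (0 = quiet).
#' @return List with `table` (data frame: 14 rate columns, `P1..P4`, `pass`,
#'   `reason`), `viable` (list of viable [parameter_set()] objects),
#'   `viable_index` (row indices), and the `spec`.
#' @export
run_screen <- function(spec, progress = 0L) {
  smp <- sample_parameter_sets(spec)
  geom <- geometry(spec$R)
  n <- spec$n
  P <- matrix(FALSE, n, 4, dimnames = list(NULL, c("P1", "P2", "P3", "P4")))
  pass <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    vf <- viability_filter(smp$params[[i]], spec$anchors, geom,
                           short_circuit = TRUE)
    P[i, ] <- c(vf$P1, vf$P2, vf$P3, vf$P4)
    pass[i] <- vf$pass
    reason[i] <- if (is.na(vf$reason)) "" else vf$reason
    if (progress > 0 && i %% progress == 0)
      message(sprintf("screen: %d/%d draws, %d viable", i, n, sum(pass)))
  }
  table <- data.frame(smp$draws, P, pass = pass, reason = reason)
  list(table = table, viable = smp$params[pass],
       viable_index = which(pass), spec = spec)
}

#' Representative (reference) parameter set of a viable ensemble
#'
#' Returns the viable member closest, in Euclidean distance over the log rate
#' constants, to the coordinate-wise mean of the logs. Ties are broken by draw
#' order.
#'
#' @param viable Nonempty list of [parameter_set()] objects.
#' @return The selected [parameter_set()], with attribute `"index"` giving its
#'   position in `viable`.
#' @export
reference_set <- function(viable) {
  if (!length(viable))
    stop("reference_set: viable set is empty", call. = FALSE)
  L <- t(vapply(viable, function(p) log(p$rates), numeric(length(RATE_NAMES))))
  ctr <- colMeans(L)
  d2 <- rowSums(sweep(L, 2, ctr)^2)
  i <- which.min(d2)  # which.min takes the first minimum: draw-order ties
  out <- viable[[i]]
  attr(out, "index") <- i
  out
}

#' Representative parameter set for the functional-submodule dissection
#'
#' The four default viability predicates constrain the wild-type and
#' Bem1-deletion behaviour but say nothing about the third, transport-
#' independent polarization mechanism (Bem1-mediated recruitment plus GAP
#' saturation with immobilized Cdc42). A viable set selected by
#' [reference_set()] may therefore lack an immobile-Cdc42 instability regime
#' altogether. For analyses that dissect all three mechanisms, this selector
#' restricts the ensemble to members for which every single-submodule
#' knockout (Bem1 deletion, disabled GAP saturation, immobilized Cdc42)
#' leaves a nonempty instability regime somewhere on a copy-number grid,
#' then applies the same log-mean-proximity rule. Deterministic given its
#' inputs.
#'
#' @param viable Nonempty list of [parameter_set()] objects.
#' @param anchors A [copy_numbers()] with the fixed `N_Bem1`, `N_GEF`.
#' @param geom A [geometry()].
#' @param N_Cdc42,N_GAPs Grid axes scanned for the immobile regime (defaults:
#'   8 log-spaced points over anchors x/÷ 10).
#' @param l_max Largest mode scanned.
#' @return The selected [parameter_set()] with attribute `"index"` (position
#'   in `viable`), or `NULL` if no member exhibits the immobile regime.
#' @export
dissection_reference <- function(viable, anchors, geom,
                                 N_Cdc42 = NULL, N_GAPs = NULL, l_max = 16L) {
  an <- unclass(anchors)
  if (is.null(N_Cdc42))
    N_Cdc42 <- log_axis(an[["N_Cdc42"]] / 10, an[["N_Cdc42"]] * 10, 8)
  if (is.null(N_GAPs))
    N_GAPs <- log_axis(an[["N_GAPs"]] / 10, an[["N_GAPs"]] * 10, 8)
  # each single-submodule knockout must leave a nonempty instability regime
  # on the scan grid; saturation is disabled through both of its levers
  # (fast complex dissociation and fast free-GAP diffusion)
  singles <- list(list(sc = "cdc42_immobile", kb = list()),
                  list(sc = "bem1_delta", kb = list()),
                  list(sc = "gap_fast",
                       kb = list(gap_fast_factor = 1e3,
                                 gap_D_m_factor = 100)))
  exhibits_all <- vapply(viable, function(p) {
    for (cf in singles) {
      d <- stability_diagram(p, N_Cdc42, N_GAPs, anchors, geom,
                             scenario = cf$sc, knobs = cf$kb, l_max = l_max)
      if (!any(d$cells$class == "laterally_unstable")) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(exhibits_all)) return(NULL)
  out <- reference_set(viable[exhibits_all])
  attr(out, "index") <- which(exhibits_all)[attr(out, "index")]
  out
}

#' Per-parameter spread of a viable ensemble
#'
#' Decades spanned by each rate across the viable sets; large spreads echo the
#' sloppiness of the model.
#'
#' @param viable List of [parameter_set()] objects.
#' @return Named vector of log10 ranges per rate.
#' @export
viable_spread <- function(viable) {
  L <- t(vapply(viable, function(p) log10(p$rates), numeric(length(RATE_NAMES))))
  apply(L, 2, function(x) diff(range(x)))
}
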