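#' Kinetic parameters of the stage process
#'
#' Hazards are per copy, per hour. The exposure-to-excision chain (CID
#' assembly, recombinase reconstitution, recombination) is lumped into a
#' single first-order event while the cognate ligand is active; in the
#' absence of ligand the same transition proceeds at the much smaller leak
#' hazard (spontaneous split-recombinase reconstitution).
#'
#' @param excision_hazard Excision hazard (h^-1) at full cognate ligand
#'   activity.
#' @param leak_hazard Ligand-free leak hazard (h^-1).
#' @param payload_protein_halflife PEST-tagged payload protein half-life (h).
#' @param sgRNA_halflife sgRNA decay half-life after excision (h).
#' @param self_deletion_hazard Hazard (h^-1) of whole-circuit self-deletion at
#'   the PhiC31 stage of an att-wrapped design while GIB is active.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(excision_hazard = 0.2, leak_hazard = 5e-4,
                           payload_protein_halflife = 2, sgRNA_halflife = 12,
                           self_deletion_hazard = 0) {
  stopifnot(excision_hazard >= 0, leak_hazard >= 0,
            payload_protein_halflife > 0, sgRNA_halflife > 0,
            self_deletion_hazard >= 0)
  structure(list(excision_hazard = excision_hazard, leak_hazard = leak_hazard,
                 payload_protein_halflife = payload_protein_halflife,
                 sgRNA_halflife = sgRNA_halflife,
                 self_deletion_hazard = self_deletion_hazard),
            class = "kinetic_params")
}

#' Calibrated kinetic preset
#'
#' `"paper-2021"`: excision hazard 0.2 h^-1 (~99% completion of a single GPC
#' within 24 h), leak 5e-4 h^-1 (~10% loss over 8 ligand-free days), 2 h
#' PEST protein half-life, 12 h sgRNA half-life (editing equilibrates by
#' ~96 h), and a self-deletion hazard giving 78% circuit removal over one
#' 48-h GIB window.
#'
#' @param name Preset name.
#' @return A [kinetic_params()].
#' @export
kinetic_preset <- function(name = "paper-2021") {
  if (name != "paper-2021") stop("unknown kinetic preset '", name, "'")
  kinetic_params(excision_hazard = 0.2, leak_hazard = 5e-4,
                 payload_protein_halflife = 2, sgRNA_halflife = 12,
                 self_deletion_hazard = -log(1 - 0.78) / 48)
}

#' Copy-number model
#'
#' Distribution of circuit copies per cell. The default is a single copy,
#' matching piggyBac integration titrated to an average copy number close to
#' one; multi-copy support exists to expose the synchronization caveat (one
#' resistant copy rescues the whole cell).
#'
#' @param probs Named numeric vector: names are copy counts (>= 1),
#'   values probabilities summing to 1.
#' @return An object of class `copy_number_model`.
#' @export
copy_number_model <- function(probs = c(`1` = 1)) {
  counts <- as.integer(names(probs))
  stopifnot(all(counts >= 1), abs(sum(probs) - 1) < 1e-9)
  structure(list(counts = counts, probs = as.numeric(probs)),
            class = "copy_number_model")
}

stage_ligands <- function(design)
  vapply(design$gpcs, function(u) u$recombinase$ligand, "")

phi_stage_index <- function(design) {
  i <- which(vapply(design$gpcs, function(u) u$recombinase$name, "") == "PhiC31")
  if (length(i)) i[1] else NA_integer_
}

#' Stage-transition hazard of one circuit copy
#'
#' Expression gating: only the promoter-proximal GPC is transcribed, so only
#' it contributes hazard; querying any downstream GPC returns 0. At the
#' proximal GPC the hazard interpolates between the leak hazard (no ligand)
#' and the excision hazard (full cognate activity):
#' `h = leak + (excision - leak) * activity(cognate ligand)`. Stage N+1 and
#' deleted copies have hazard 0.
#'
#' @param design A valid [circuit_design()].
#' @param copy_stage Current stage of the copy (1..N+1).
#' @param activities Named numeric, e.g. `c(GIB = 1, ABA = 0)`.
#' @param params A [kinetic_params()].
#' @param gpc_index Which GPC's contribution to report; defaults to the
#'   proximal one.
#' @return Hazard in h^-1.
#' @export
transition_hazard <- function(design, copy_stage, activities, params,
                              gpc_index = copy_stage) {
  N <- n_stages(design)
  if (copy_stage > N || gpc_index != copy_stage) return(0)
  lig <- design$gpcs[[copy_stage]]$recombinase$ligand
  a <- activities[[lig]]
  params$leak_hazard + (params$excision_hazard - params$leak_hazard) * a
}

# --------------------------------------------------------------------------
# Inhomogeneous-exponential event sampling over piecewise activity profiles.
# A hazard is (const + sum_j coef_j * a_j(t)) with each a_j piecewise
# a0*exp(-rate*(t-start)). Event times are drawn by exact inversion of the
# integrated hazard: walk the merged piece grid, accumulate, then solve
# within the final piece (closed form when constant, uniroot otherwise).

cumhaz_component <- function(pieces, s, t) {
  if (t <= s) return(0)
  ps <- pieces[, "start"]; pe <- pieces[, "end"]
  tot <- 0
  i <- max(findInterval(s, ps), 1L)
  while (i <= nrow(pieces) && ps[i] < t) {
    a <- max(s, ps[i]); b <- min(t, pe[i])
    if (b > a) {
      a0 <- pieces[i, "a0"]; r <- pieces[i, "rate"]
      tot <- tot + if (r == 0) a0 * (b - a) else
        a0 / r * (exp(-r * (a - ps[i])) - exp(-r * (b - ps[i])))
    }
    i <- i + 1L
  }
  # beyond the last piece activity is 0
  tot
}

# comps: list of list(pieces = <matrix start/end/a0/rate>, coef = <numeric>);
# const: baseline hazard; bps: precomputed merged breakpoints over [0, horizon]
sample_event_time <- function(t_start, horizon, const, comps, u, bps = NULL) {
  if (is.null(bps))
    bps <- sort(unique(c(0, horizon,
                         unlist(lapply(comps, function(cmp)
                           c(cmp$pieces[, "start"], cmp$pieces[, "end"]))))))
  bps <- bps[bps <= horizon]
  k0 <- findInterval(t_start, bps)
  cum <- 0
  for (i in k0:(length(bps) - 1L)) {
    s <- max(bps[i], t_start); e <- bps[i + 1L]
    if (e <= s) next
    dcum <- const * (e - s)
    for (cmp in comps) dcum <- dcum + cmp$coef * cumhaz_component(cmp$pieces, s, e)
    if (cum + dcum >= u) {
      # constant-rate piece: invert linearly
      rates_const <- all(vapply(comps, function(cmp) {
        j <- max(findInterval(s, cmp$pieces[, "start"]), 1L)
        j > nrow(cmp$pieces) || cmp$pieces[j, "rate"] == 0
      }, TRUE))
      if (rates_const) return(s + (u - cum) * (e - s) / dcum)
      f <- function(t) {
        v <- cum + const * (t - s) - u
        for (cmp in comps) v <- v + cmp$coef * cumhaz_component(cmp$pieces, s, t)
        v
      }
      return(stats::uniroot(f, c(s, e), tol = 1e-10)$root)
    }
    cum <- cum + dcum
  }
  Inf
}

# hazard value at a time (for competing-event attribution)
hazard_value <- function(t, const, comps) {
  const + sum(vapply(comps, function(cmp) {
    p <- cmp$pieces
    i <- findInterval(t, p[, "start"])
    if (i < 1 || i > nrow(p) || t >= p[i, "end"]) return(0)
    cmp$coef * p[i, "a0"] * exp(-p[i, "rate"] * (t - p[i, "start"]))
  }, 0))
}

cell_seed <- function(seed, cell) {
  as.integer((as.double(seed) * 7919 + as.double(cell) * 104729) %% 2147483647)
}
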