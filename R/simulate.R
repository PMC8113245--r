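#' Simulate a cell population through a ligand schedule
#'
#' Each cell carries one or more circuit copies; each copy runs an
#' independent continuous-time pure-birth stage process with
#' expression-gated hazards (see [transition_hazard()]). Event times are
#' drawn by exact inversion of the integrated hazard over the piecewise
#' ligand-activity profile, so there is no fixed-timestep discretization
#' error. At the PhiC31 stage of an att-wrapped design the recombination
#' event joins the upstream attP to the cassette attB, so it deletes the
#' whole circuit instead of advancing the stage (hazard
#' `leak + (self_deletion_hazard - leak) * GIB activity`).
#' Per-cell random substreams are derived
#' deterministically from `(seed, cell index)`, so a cell's path does not
#' depend on the population size.
#'
#' @param design A valid [circuit_design()].
#' @param params [kinetic_params()].
#' @param pk Named list of [pk_params()]; see [pk_preset()].
#' @param copy_model [copy_number_model()].
#' @param schedule [ligand_schedule()].
#' @param n Number of cells.
#' @param seed Integer seed.
#' @param times Sample times for the trajectory (defaults to an even grid
#'   plus all window boundaries).
#' @param init_stage Stage every copy starts in (default 1).
#' @return An object of class `gpc_trajectory`: fields `times`, `occupancy`
#'   (fractions per stage, plus `deleted` for att-wrapped designs),
#'   `payload_means`, `population`, `seed`, `n`.
#' @export
simulate_population <- function(design, params = kinetic_preset(),
                                pk = pk_preset("ga4"),
                                copy_model = copy_number_model(),
                                schedule, n, seed = 1, times = NULL,
                                init_stage = 1L) {
  assert_valid_design(design)
  stopifnot(n >= 1)
  N <- n_stages(design)
  horizon <- schedule$horizon_h
  ligs <- stage_ligands(design)
  pieces <- list(GIB = activity_pieces(schedule, pk, "GIB", horizon),
                 ABA = activity_pieces(schedule, pk, "ABA", horizon))
  has_wrap <- !is.null(design$att_wrapper)
  phi <- if (has_wrap) phi_stage_index(design) else NA_integer_
  sd_haz <- if (has_wrap && !is.na(phi)) params$self_deletion_hazard else 0

  # per-stage hazard components and merged breakpoints, shared by all cells
  stage_comps <- lapply(seq_len(N), function(k) {
    is_phi <- !is.na(phi) && k == phi
    coef <- if (is_phi) sd_haz - params$leak_hazard
            else params$excision_hazard - params$leak_hazard
    lig <- if (is_phi) "GIB" else ligs[k]
    list(list(pieces = pieces[[lig]], coef = coef))
  })
  stage_bps <- lapply(seq_len(N), function(k)
    sort(unique(c(0, horizon,
                  unlist(lapply(stage_comps[[k]], function(cmp)
                    c(cmp$pieces[, "start"], cmp$pieces[, "end"])))))))

  cells <- integer(0); entry_rows <- list(); deleted <- numeric(0)
  for (i in seq_len(n)) {
    set.seed(cell_seed(seed, i))
    k_copies <- if (length(copy_model$counts) == 1L) copy_model$counts else
      sample(copy_model$counts, 1L, prob = copy_model$probs)
    for (cp in seq_len(k_copies)) {
      res <- simulate_copy(N, stage_comps, stage_bps, params, horizon,
                           init_stage, phi)
      cells <- c(cells, i)
      entry_rows[[length(entry_rows) + 1L]] <- res$entry
      deleted <- c(deleted, res$deleted_at)
    }
  }
  entry <- do.call(rbind, entry_rows)
  colnames(entry) <- paste0("stage", seq_len(N + 1L))
  pop <- structure(list(design = design, params = params, pk = pk,
                        schedule = schedule, cell = cells, entry = entry,
                        deleted_at = deleted,
                        alive = rep(TRUE, n), n_cells = n,
                        horizon = horizon, seed = seed),
                   class = "gpc_population")
  if (is.null(times)) {
    step <- max(horizon / 100, 1)
    times <- sort(unique(c(seq(0, horizon, by = step), horizon,
                           schedule$windows$start_h, schedule$windows$end_h)))
  }
  trajectory_from_population(pop, times)
}

# one copy: returns entry times into stages 1..N+1 and the deletion time.
# At the PhiC31 stage of an att-wrapped design the recombination event joins
# the upstream attP to the cassette attB and deletes the whole circuit.
simulate_copy <- function(N, stage_comps, stage_bps, params, horizon,
                          init_stage, phi) {
  entry <- rep(Inf, N + 1L)
  entry[seq_len(init_stage)] <- 0
  deleted_at <- Inf
  t <- 0; stage <- init_stage
  while (stage <= N && t < horizon) {
    u <- stats::rexp(1)
    t_ev <- sample_event_time(t, horizon, params$leak_hazard,
                              stage_comps[[stage]], u, stage_bps[[stage]])
    if (!is.finite(t_ev)) break
    if (!is.na(phi) && stage == phi) { deleted_at <- t_ev; break }
    stage <- stage + 1L
    entry[stage] <- t_ev
    t <- t_ev
  }
  list(entry = entry, deleted_at = deleted_at)
}

#' Per-copy stage index at a time point
#'
#' @param population A `gpc_population`.
#' @param t Time (h).
#' @return Integer vector over copies; `NA` marks self-deleted copies.
#' @export
stage_at <- function(population, t) {
  s <- rowSums(population$entry <= t)
  s[population$deleted_at <= t] <- NA_integer_
  as.integer(s)
}

occupancy_at <- function(population, t, alive_only = TRUE) {
  keep <- if (alive_only) population$alive[population$cell] else TRUE
  s <- stage_at(population, t)[keep]
  N <- n_stages(population$design)
  k <- length(s)
  frac <- vapply(seq_len(N + 1L), function(j) sum(s == j, na.rm = TRUE) / k, 0)
  names(frac) <- paste0("stage", seq_len(N + 1L))
  if (!is.null(population$design$att_wrapper))
    frac <- c(frac, deleted = sum(is.na(s)) / k)
  frac
}

#' Deterministic payload level of each copy
#'
#' Payload proteins are produced at unit rate while their stage is
#' promoter-proximal and decay first-order with the PEST-shortened
#' half-life; levels are in units of hours of accumulated production.
#'
#' @param population A `gpc_population`.
#' @param t Time (h).
#' @return Matrix copies x payloads of mean levels (before cell-to-cell
#'   noise, which the flow model adds).
#' @export
payload_levels <- function(population, t) {
  design <- population$design
  N <- n_stages(design)
  delta <- log(2) / population$params$payload_protein_halflife
  ent <- population$entry
  del <- population$deleted_at
  payloads <- payload_stage_map(design)
  out <- matrix(0, nrow(ent), nrow(payloads),
                dimnames = list(NULL, payloads$name))
  for (j in seq_len(nrow(payloads))) {
    k <- payloads$stage[j]
    s0 <- ent[, k]
    s1 <- if (k <= N) pmin(ent[, k + 1L], del) else del
    on <- t > s0
    tp <- pmin(t, s1)
    lvl <- (1 / delta) * (1 - exp(-delta * (tp - s0)))
    lvl <- lvl * exp(-delta * pmax(0, t - s1))
    out[, j] <- ifelse(on, lvl, 0)
  }
  out
}

payload_stage_map <- function(design) {
  rows <- list()
  for (u in design$gpcs) for (p in u$payloads)
    rows[[length(rows) + 1L]] <- data.frame(name = p$name, stage = u$index,
                                            kind = p$kind,
                                            locus = if (is.null(p$locus)) NA_character_ else p$locus,
                                            stringsAsFactors = FALSE)
  for (p in design$terminal_payloads)
    rows[[length(rows) + 1L]] <- data.frame(name = p$name,
                                            stage = n_stages(design) + 1L,
                                            kind = p$kind,
                                            locus = if (is.null(p$locus)) NA_character_ else p$locus,
                                            stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

trajectory_from_population <- function(population, times) {
  occ <- t(vapply(times, function(tt) occupancy_at(population, tt),
                  occupancy_at(population, 0)))
  pls <- t(vapply(times, function(tt) colMeans(payload_levels(population, tt)),
                  colMeans(payload_levels(population, 0))))
  structure(list(times = times, occupancy = occ, payload_means = pls,
                 population = population, seed = population$seed,
                 n = population$n_cells),
            class = "gpc_trajectory")
}

#' @export
print.gpc_trajectory <- function(x, ...) {
  cat(sprintf("<gpc_trajectory: %d cells, %d copies, %d sample times, horizon %g h>\n",
              x$n, nrow(x$population$entry), length(x$times),
              x$population$horizon))
  last <- round(x$occupancy[nrow(x$occupancy), ], 4)
  cat("  final occupancy:", paste(names(last), last, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Trajectory as a tidy data.frame (CSV-ready)
#' @param x A `gpc_trajectory`.
#' @param ... unused.
#' @return data.frame with time_h, per-stage fractions, per-payload means.
#' @export
as.data.frame.gpc_trajectory <- function(x, ...) {
  occ <- as.data.frame(x$occupancy)
  names(occ) <- paste0(names(occ), "_fraction")
  pls <- as.data.frame(x$payload_means)
  names(pls) <- paste0(names(pls), "_level")
  cbind(data.frame(time_h = x$times), occ, pls)
}

#' Closed-form stage occupancy of the single-copy Markov chain
#'
#' Analytic twin of the simulator: the per-copy stage process is a pure-birth
#' continuous-time Markov chain whose rates are piecewise constant over the
#' ligand-activity piece grid (decay pieces are subdivided and averaged
#' exactly). Occupancy is propagated by matrix exponentials of the generator
#' over each piece.
#'
#' @param design A valid [circuit_design()].
#' @param params [kinetic_params()].
#' @param pk Named list of [pk_params()].
#' @param schedule [ligand_schedule()].
#' @param times Times (h) at which occupancy is reported.
#' @param init_stage Starting stage.
#' @param subdivide Subintervals per first-order-decay piece.
#' @return Matrix `length(times)` x states; rows sum to 1. States are
#'   stage1..stage(N+1) plus `deleted` for att-wrapped designs.
#' @export
expected_occupancy <- function(design, params = kinetic_preset(),
                               pk = pk_preset("ga4"), schedule, times,
                               init_stage = 1L, subdivide = 40L) {
  assert_valid_design(design)
  N <- n_stages(design)
  ligs <- stage_ligands(design)
  horizon <- max(c(schedule$horizon_h, times))
  pieces <- list(GIB = activity_pieces(schedule, pk, "GIB", horizon),
                 ABA = activity_pieces(schedule, pk, "ABA", horizon))
  has_wrap <- !is.null(design$att_wrapper)
  phi <- if (has_wrap) phi_stage_index(design) else NA_integer_
  sd_haz <- if (has_wrap && !is.na(phi)) params$self_deletion_hazard else 0
  n_states <- N + 1L + as.integer(has_wrap)

  bps <- sort(unique(c(0, times, unlist(lapply(pieces, function(p)
    c(p[, "start"], p[, "end"]))))))
  bps <- bps[bps >= 0 & bps <= horizon]
  # subdivide pieces where activity decays within the interval
  grid <- c()
  for (i in seq_len(length(bps) - 1L)) {
    s <- bps[i]; e <- bps[i + 1L]
    decaying <- any(vapply(pieces, function(p) {
      j <- max(findInterval(s, p[, "start"]), 1L)
      j <= nrow(p) && p[j, "rate"] > 0
    }, TRUE))
    m <- if (decaying) subdivide else 1L
    grid <- c(grid, seq(s, e, length.out = m + 1L)[-(m + 1L)])
  }
  grid <- sort(unique(c(grid, horizon)))

  pvec <- numeric(n_states); pvec[init_stage] <- 1
  out <- matrix(NA_real_, length(grid), n_states)
  out[1, ] <- pvec
  mean_act <- function(lig, s, e)
    cumhaz_component(pieces[[lig]], s, e) / (e - s)
  for (i in seq_len(length(grid) - 1L)) {
    s <- grid[i]; e <- grid[i + 1L]
    Q <- matrix(0, n_states, n_states)
    for (k in seq_len(N)) {
      a <- mean_act(ligs[k], s, e)
      if (!is.na(phi) && k == phi) {
        # att-wrapped PhiC31 stage: the recombination event deletes the circuit
        Q[k, n_states] <- params$leak_hazard + (sd_haz - params$leak_hazard) * a
      } else {
        Q[k, k + 1L] <- params$leak_hazard +
          (params$excision_hazard - params$leak_hazard) * a
      }
    }
    diag(Q) <- -rowSums(Q)
    P <- as.matrix(Matrix::expm(Q * (e - s)))
    pvec <- as.numeric(pvec %*% P)
    out[i + 1L, ] <- pvec
  }
  res <- out[match(times, grid), , drop = FALSE]
  colnames(res) <- c(paste0("stage", seq_len(N + 1L)),
                     if (has_wrap) "deleted")
  rownames(res) <- times
  res
}

#' Antibiotic synchronization (selection at a marker stage)
#'
#' A cell survives with probability `survival_with` if *any* of its circuit
#' copies sits at `marker_stage` at selection time (one resistant copy is
#' enough), and with `survival_without` otherwise. With multiple copies per
#' cell this is exactly the mechanism that limits synchronization purity.
#'
#' @param population A `gpc_population`.
#' @param marker_stage Stage carrying the resistance payload.
#' @param survival_with,survival_without Survival probabilities in `[0,1]`.
#' @param time Selection time (h), default the simulation horizon.
#' @param seed Integer seed for survival draws.
#' @return The population with `alive` updated.
#' @export
apply_selection <- function(population, marker_stage, survival_with = 1,
                            survival_without = 0,
                            time = population$horizon, seed = 1) {
  stopifnot(survival_with >= 0, survival_with <= 1,
            survival_without >= 0, survival_without <= 1)
  s <- stage_at(population, time)
  has_marker <- vapply(seq_len(population$n_cells), function(i)
    any(s[population$cell == i] == marker_stage, na.rm = TRUE), TRUE)
  set.seed(seed)
  p <- ifelse(has_marker, survival_with, survival_without)
  survive <- stats::runif(population$n_cells) < p
  population$alive <- population$alive & survive
  population
}

#' Self-deletion of an att-wrapped circuit
#'
#' Runs an additional ligand schedule during which every non-deleted copy
#' currently at the PhiC31 stage self-deletes with hazard
#' `self_deletion_hazard * GIB activity`. Deleted copies express nothing and
#' retain only the ITR flanks and att scar.
#'
#' @param population A `gpc_population` of an att-wrapped design.
#' @param params [kinetic_params()] (supplies `self_deletion_hazard`).
#' @param pk Named list of [pk_params()].
#' @param schedule [ligand_schedule()] for the deletion treatment (times are
#'   relative to the current population horizon).
#' @param seed Integer seed.
#' @return The population with `deleted_at` updated and the horizon extended.
#' @export
self_delete <- function(population, params = population$params,
                        pk = population$pk, schedule, seed = 1) {
  design <- population$design
  if (is.null(design$att_wrapper))
    gpc_error("population design has no att wrapper", "gpcsim_no_att_wrapper")
  phi <- phi_stage_index(design)
  if (is.na(phi)) gpc_error("design has no PhiC31 stage", "gpcsim_no_att_wrapper")
  T_add <- schedule$horizon_h
  pieces_gib <- activity_pieces(schedule, pk, "GIB", T_add)
  s <- stage_at(population, population$horizon)
  eligible <- which(!is.na(s) & s == phi)
  comps <- list(list(pieces = pieces_gib, coef = params$self_deletion_hazard))
  for (i in eligible) {
    set.seed(cell_seed(seed, i))
    u <- stats::rexp(1)
    t_ev <- sample_event_time(0, T_add, 0, comps, u)
    if (is.finite(t_ev))
      population$deleted_at[i] <- population$horizon + t_ev
  }
  population$horizon <- population$horizon + T_add
  population
}

#' Fit a hazard from a stage-retention time course
#'
#' Binomial maximum-likelihood fit of a single exponential rate to observed
#' fractions: `leak` fits the fraction *remaining* at a stage,
#' `p(t) = exp(-q t)` (memory-retention experiments); `excision` fits the
#' fraction already transitioned, `p(t) = 1 - exp(-q t)`. The confidence
#' interval is a parametric bootstrap (percentile method).
#'
#' @param time_h Times (h), at least 2.
#' @param fraction Observed fractions in `[0,1]`.
#' @param n Cells per observation (binomial denominator).
#' @param model `"leak"` or `"excision"`.
#' @param B Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return list(hazard, ci, model); hazard in h^-1.
#' @export
fit_hazard_from_timecourse <- function(time_h, fraction, n = 10000,
                                       model = c("leak", "excision"),
                                       B = 1000, conf = 0.95, seed = 1) {
  model <- match.arg(model)
  stopifnot(length(time_h) >= 2, length(fraction) == length(time_h),
            all(fraction >= 0 & fraction <= 1))
  o <- order(time_h); time_h <- time_h[o]; fraction <- fraction[o]
  drift <- diff(fraction)
  if ((model == "leak" && any(drift > 0.02)) ||
      (model == "excision" && any(drift < -0.02)))
    warning("fractions are not monotone-compatible with the ", model,
            " model; best fit returned anyway")
  counts <- round(fraction * n)
  fit_one <- function(cts) {
    nll <- function(q) {
      p <- if (model == "leak") exp(-q * time_h) else 1 - exp(-q * time_h)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(stats::dbinom(cts, n, p, log = TRUE))
    }
    # bracket the optimum on a log grid first: the likelihood is needle-sharp
    # on the hazard scale and blows up to +Inf for large q
    qs <- c(0, exp(seq(log(1e-9), log(10), length.out = 200)))
    vals <- vapply(qs, nll, 0)
    i <- which.min(vals)
    if (i == 1) return(0)
    opt <- stats::optimize(nll, c(qs[max(i - 1L, 1L)], qs[min(i + 1L, length(qs))]),
                           tol = 1e-12)
    if (nll(0) <= opt$objective) 0 else opt$minimum
  }
  q_hat <- fit_one(counts)
  set.seed(seed)
  p_hat <- if (model == "leak") exp(-q_hat * time_h) else 1 - exp(-q_hat * time_h)
  boot <- vapply(seq_len(B), function(b)
    fit_one(stats::rbinom(length(time_h), n, p_hat)), 0)
  alpha <- (1 - conf) / 2
  list(hazard = q_hat,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       model = model)
}
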