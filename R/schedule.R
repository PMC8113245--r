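#' Ligand exposure schedule
#'
#' Piecewise ligand program: an ordered set of exposure windows for GIB and
#' ABA. Windows of the same ligand must not overlap.
#'
#' @param windows data.frame with columns `ligand` ("GIB"/"ABA"), `start_h`,
#'   `end_h`, or NULL for an empty (ligand-free) schedule.
#' @param horizon_h Total simulated horizon; defaults to the last window end.
#' @return An object of class `ligand_schedule`.
#' @export
ligand_schedule <- function(windows = NULL, horizon_h = NULL) {
  if (is.null(windows))
    windows <- data.frame(ligand = character(), start_h = numeric(),
                          end_h = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("ligand", "start_h", "end_h") %in% names(windows)))
  windows <- windows[order(windows$start_h), , drop = FALSE]
  rownames(windows) <- NULL
  if (!all(windows$ligand %in% c("GIB", "ABA")))
    stop("unknown ligand in schedule; must be GIB or ABA")
  if (any(windows$end_h <= windows$start_h)) stop("window end must exceed start")
  for (lig in unique(windows$ligand)) {
    w <- windows[windows$ligand == lig, , drop = FALSE]
    if (nrow(w) > 1 && any(w$start_h[-1] < w$end_h[-nrow(w)]))
      stop("overlapping windows for ligand ", lig)
  }
  if (is.null(horizon_h)) horizon_h <- if (nrow(windows)) max(windows$end_h) else 0
  structure(list(windows = windows, horizon_h = horizon_h),
            class = "ligand_schedule")
}

#' Build the standard alternating schedule
#'
#' The default cascade program: each stage gets one ligand window of
#' `stage_hours` (48 h by default, 96 h for sgRNA cascades), separated by
#' `gap_hours` (12 h) washout gaps so the previous ligand clears before the
#' next window starts.
#'
#' @param ligands Character vector of per-stage ligands, e.g.
#'   `c("GIB","ABA","GIB")`; may also be a `circuit_design` from which the
#'   ligand order is taken.
#' @param stage_hours Window duration per stage (h).
#' @param gap_hours Gap between windows (h).
#' @param extra_h Extra ligand-free time appended after the last window.
#' @return A [ligand_schedule()].
#' @export
build_schedule <- function(ligands, stage_hours = 48, gap_hours = 12, extra_h = 0) {
  if (inherits(ligands, "circuit_design"))
    ligands <- vapply(ligands$gpcs, function(u) u$recombinase$ligand, "")
  n <- length(ligands)
  starts <- (seq_len(n) - 1) * (stage_hours + gap_hours)
  w <- data.frame(ligand = ligands, start_h = starts,
                  end_h = starts + stage_hours, stringsAsFactors = FALSE)
  ligand_schedule(w, horizon_h = max(w$end_h) + extra_h)
}

#' @export
print.ligand_schedule <- function(x, ...) {
  cat(sprintf("<ligand_schedule: %d window(s), horizon %g h>\n",
              nrow(x$windows), x$horizon_h))
  if (nrow(x$windows)) print(x$windows)
  invisible(x)
}

#' Ligand pharmacokinetics
#'
#' Clearance behaviour after a window closes. `instant` drops intracellular
#' activity to zero at the window end (GA4, ABA: cleared by the next
#' switch). `first_order` decays with the given half-life and is floored to
#' zero below 0.01 (GA3-AM: esterase-trapped, >12 h to clear).
#'
#' @param mode `"instant"` or `"first_order"`.
#' @param halflife_h Clearance half-life (h; first_order only).
#' @param trapped Logical; AM-ester intracellular trapping (annotation only).
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(mode = c("instant", "first_order"), halflife_h = NA_real_,
                      trapped = FALSE) {
  mode <- match.arg(mode)
  if (mode == "first_order" && !(is.finite(halflife_h) && halflife_h > 0))
    stop("first_order clearance needs a positive halflife_h")
  structure(list(mode = mode, halflife_h = halflife_h, trapped = trapped),
            class = "pk_params")
}

#' Pharmacokinetic presets for both ligands
#'
#' `"ga4"` (default): both GIB (as GA4) and ABA are cleared instantly at
#' washout, consistent with complete clearance within the 12-h gap.
#' `"ga3am"`: GIB as the trapped AM-ester with a 4-h clearance half-life
#' (>12 h to fully clear), ABA instant.
#'
#' @param name `"ga4"` or `"ga3am"`.
#' @return Named list of [pk_params()], one per ligand.
#' @export
pk_preset <- function(name = c("ga4", "ga3am")) {
  name <- match.arg(name)
  switch(name,
    ga4 = list(GIB = pk_params("instant"), ABA = pk_params("instant")),
    ga3am = list(GIB = pk_params("first_order", halflife_h = 4, trapped = TRUE),
                 ABA = pk_params("instant")))
}

ACTIVITY_FLOOR <- 0.01

#' Intracellular ligand activity
#'
#' Activity is 1 inside an exposure window; after the window it is 0
#' (instant clearance) or `2^(-dt/halflife)` floored to 0 below 0.01
#' (first-order clearance), until the next window of the same ligand.
#'
#' @param schedule A [ligand_schedule()].
#' @param pk Named list of [pk_params()] per ligand (see [pk_preset()]).
#' @param ligand `"GIB"` or `"ABA"`.
#' @param t Time(s) in hours.
#' @return Numeric activity in `[0, 1]`, vectorized over `t`.
#' @export
ligand_activity <- function(schedule, pk, ligand, t) {
  if (!ligand %in% c("GIB", "ABA")) stop("unknown ligand '", ligand, "'")
  stopifnot(all(t >= 0))
  p <- activity_pieces(schedule, pk, ligand, max(c(t, schedule$horizon_h)))
  idx <- findInterval(t, p[, "start"])
  idx[idx < 1] <- 1L
  a <- p[idx, "a0"] * exp(-p[idx, "rate"] * (t - p[idx, "start"]))
  a[a < ACTIVITY_FLOOR & p[idx, "rate"] > 0] <- 0
  unname(pmin(pmax(a, 0), 1))
}

# Piecewise description of a(t): matrix rows (start, end, a0, rate) with
# a(t) = a0 * exp(-rate * (t - start)) on [start, end). Decay pieces are cut
# at the 0.01 floor. Covers [0, horizon].
activity_pieces <- function(schedule, pk, ligand, horizon) {
  w <- schedule$windows[schedule$windows$ligand == ligand, , drop = FALSE]
  pkl <- pk[[ligand]]
  if (is.null(pkl)) stop("no pk_params for ligand ", ligand)
  pieces <- list(); t0 <- 0
  add <- function(s, e, a0, rate)
    pieces[[length(pieces) + 1L]] <<- c(start = s, end = e, a0 = a0, rate = rate)
  for (i in seq_len(nrow(w))) {
    if (w$start_h[i] > t0) add(t0, w$start_h[i], 0, 0)  # may overwrite decay: handled below
    add(w$start_h[i], w$end_h[i], 1, 0)
    t0 <- w$end_h[i]
    if (pkl$mode == "first_order") {
      rate <- log(2) / pkl$halflife_h
      t_floor <- t0 + log(1 / ACTIVITY_FLOOR) / rate
      nxt <- if (i < nrow(w)) w$start_h[i + 1] else Inf
      dend <- min(t_floor, nxt, max(horizon, t0))
      if (dend > t0) { add(t0, dend, 1, rate); t0 <- dend }
    }
  }
  if (t0 < horizon || length(pieces) == 0) add(t0, max(horizon, t0), 0, 0)
  m <- do.call(rbind, pieces)
  m[m[, "end"] > m[, "start"], , drop = FALSE]
}
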