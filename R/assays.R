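#' Flow-cytometry gating configuration
#'
#' Single-channel idealization: a payload is "positive" when its modeled
#' level exceeds a threshold. The default threshold is a fixed fraction of
#' the steady-state level (`halflife/log(2)` production-hours).
#'
#' @param design A [circuit_design()].
#' @param params [kinetic_params()] (for the protein half-life).
#' @param frac Threshold as a fraction of the steady-state level.
#' @param thresholds Optional named numeric vector overriding per-payload
#'   thresholds.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(design, params = kinetic_preset(), frac = 0.2,
                          thresholds = NULL) {
  pm <- payload_stage_map(design)
  ss <- params$payload_protein_halflife / log(2)
  th <- stats::setNames(rep(frac * ss, nrow(pm)), pm$name)
  if (!is.null(thresholds)) th[names(thresholds)] <- thresholds
  stopifnot(all(th > 0))
  structure(list(thresholds = th), class = "gating_config")
}

#' Flow-cytometry readout of a population
#'
#' Computes per-payload positive fractions at a time point after adding
#' log-normal cell-to-cell expression noise, assigns each cell to the
#' highest-stage positive payload, and reports the payload-switching metric
#' `%after+ / (%after+ or %before+)` for the first excision (the fraction of
#' fluorescent cells that have undergone recombination).
#'
#' @param population A `gpc_population`.
#' @param gating A [gating_config()].
#' @param time Readout time (h), default the horizon.
#' @param noise_cv Log-normal cell-to-cell coefficient of variation.
#' @param seed Seed for the noise draw.
#' @return An object of class `flow_summary`: `positive_fraction`,
#'   `stage_assignment`, `switching_metric`, `time`.
#' @export
flow_readout <- function(population, gating, time = population$horizon,
                         noise_cv = 0.3, seed = 1) {
  lv <- payload_levels(population, time)
  keep <- population$alive[population$cell]
  lv <- lv[keep, , drop = FALSE]
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(length(lv), -sdlog^2 / 2, sdlog),
                    nrow(lv), ncol(lv))
    lv <- lv * noise
  }
  th <- gating$thresholds[colnames(lv)]
  pos <- sweep(lv, 2, th, `>`)
  pos_frac <- colMeans(pos)
  pm <- payload_stage_map(population$design)
  stages <- pm$stage[match(colnames(lv), pm$name)]
  # exclusive assignment: the latest-stage positive payload wins
  assign_idx <- apply(pos, 1, function(r) if (any(r)) max(which(r)) else NA_integer_)
  stage_assignment <- table(factor(colnames(lv)[assign_idx], levels = colnames(lv)))
  stage_assignment <- as.numeric(stage_assignment) / nrow(lv)
  names(stage_assignment) <- colnames(lv)
  # switching metric over the first payload of the two earliest stages
  ust <- sort(unique(stages))
  if (length(ust) < 2) stop("switching metric needs payloads at two stages")
  before <- colnames(lv)[stages == ust[1]][1]
  after <- colnames(lv)[stages == ust[2]][1]
  denom <- mean(pos[, after] | pos[, before])
  metric <- if (denom == 0) {
    warning("no cells positive for '", before, "' or '", after,
            "'; switching metric undefined (NaN)")
    NaN
  } else mean(pos[, after]) / denom
  structure(list(positive_fraction = pos_frac,
                 stage_assignment = stage_assignment,
                 switching_metric = metric,
                 metric_payloads = c(before = before, after = after),
                 time = time),
            class = "flow_summary")
}

#' Payload-switching metric from positive counts
#'
#' The recombination-efficiency metric: of all cells positive for either the
#' pre-excision or the post-excision payload, the fraction positive for the
#' post-excision one.
#'
#' @param n_after,n_before,n_double Counts of cells positive for only the
#'   post-excision payload, only the pre-excision payload, and both.
#' @return Numeric in `[0,1]`, `NaN` when no cell is positive.
#' @export
switching_metric <- function(n_after, n_before, n_double = 0) {
  denom <- n_after + n_before + n_double
  if (denom == 0) return(NaN)
  (n_after + n_double) / denom
}

# -- CRISPR editing kinetics ------------------------------------------------

#' Editing-kinetics parameters
#'
#' @param hazards Named numeric: per-locus editing hazard (h^-1 per allele)
#'   while the cognate sgRNA is at unit abundance.
#' @param ploidy Alleles per locus per cell.
#' @param sgRNA_halflife sgRNA decay half-life (h) after its GPC is excised.
#' @return An object of class `editing_params`.
#' @export
editing_params <- function(hazards, ploidy = 2L, sgRNA_halflife = 12) {
  stopifnot(all(hazards >= 0), ploidy >= 1, sgRNA_halflife > 0)
  structure(list(hazards = hazards, ploidy = as.integer(ploidy),
                 sgRNA_halflife = sgRNA_halflife),
            class = "editing_params")
}

# integrated sgRNA exposure G(t) for one copy: abundance 1 on [s0, s1),
# exponential decay (rate d) afterwards
sgrna_exposure <- function(t, s0, s1, d) {
  G <- pmax(pmin(t, s1) - s0, 0)
  post <- pmax(t - s1, 0)
  G + ifelse(is.finite(s1) & t > s1, (1 - exp(-d * post)) / d, 0)
}

#' Simulate indel accumulation at sgRNA target loci
#'
#' Each sgRNA is expressed while its GPC is promoter-proximal and keeps
#' cutting as it decays after excision (the post-excision editing lag). Per
#' allele, the indel probability by time t is `1 - exp(-h * G(t))` with
#' `G(t)` the integrated sgRNA abundance. Alleles are flipped by drawing one
#' exponential threshold per allele, which makes every allele's edit status
#' (and hence every frequency curve) monotone in time by construction.
#'
#' @param trajectory A `gpc_trajectory` (or `gpc_population`) from a design
#'   with sgRNA payloads.
#' @param params An [editing_params()]; loci without an sgRNA in the design
#'   are dropped with a warning.
#' @param seed Integer seed.
#' @param times Report times; default the trajectory sample times.
#' @return An object of class `editing_result`: tidy data.frame
#'   `$frequencies` (locus, time_h, indel_fraction) plus allele-level detail.
#' @export
simulate_editing <- function(trajectory, params, seed = 1, times = NULL) {
  pop <- if (inherits(trajectory, "gpc_trajectory")) trajectory$population else trajectory
  if (is.null(times))
    times <- if (inherits(trajectory, "gpc_trajectory")) trajectory$times
             else seq(0, pop$horizon, length.out = 50)
  pm <- payload_stage_map(pop$design)
  pm <- pm[pm$kind == "sgRNA" & !is.na(pm$locus), , drop = FALSE]
  loci <- intersect(names(params$hazards), pm$locus)
  missing <- setdiff(names(params$hazards), pm$locus)
  if (length(missing))
    warning("no sgRNA in the design targets locus/loci: ",
            paste(missing, collapse = ", "), "; excluded")
  if (!length(loci)) stop("no locus in `params$hazards` is targeted by the design")
  d <- log(2) / params$sgRNA_halflife
  N <- n_stages(pop$design)
  n_cells <- pop$n_cells
  res <- list(); allele_u <- list()
  set.seed(seed)
  for (lc in loci) {
    k <- pm$stage[match(lc, pm$locus)]
    h <- params$hazards[[lc]]
    # per-cell exposure summed over copies
    s0 <- pop$entry[, k]
    s1 <- if (k <= N) pmin(pop$entry[, k + 1L], pop$deleted_at) else pop$deleted_at
    u <- matrix(stats::rexp(n_cells * params$ploidy), n_cells, params$ploidy)
    allele_u[[lc]] <- u
    cell_f <- factor(pop$cell, levels = seq_len(n_cells))
    for (tt in times) {
      Gcopy <- sgrna_exposure(tt, s0, s1, d)
      Gcell <- as.numeric(tapply(Gcopy, cell_f, sum))
      edited <- u <= h * Gcell   # recycles Gcell down columns
      res[[length(res) + 1L]] <- data.frame(
        locus = lc, time_h = tt,
        indel_fraction = mean(edited[pop$alive, , drop = FALSE]))
    }
  }
  freq <- do.call(rbind, res)
  structure(list(frequencies = freq, ploidy = params$ploidy, loci = loci,
                 allele_thresholds = allele_u),
            class = "editing_result")
}

# -- scar-amplicon sequencing with PCR length bias --------------------------

#' PCR length-bias model
#'
#' Per-cycle amplification efficiency declines linearly with amplicon
#' length: `E(L) = clamp(e_max - k_len * L, 0, 1)`; after `C` cycles an
#' amplicon's weight is multiplied by `(1 + E(L))^C`, so shorter scar
#' amplicons (earlier stages) are overrepresented.
#'
#' @param e_max Maximum per-cycle efficiency.
#' @param k_len Efficiency loss per bp.
#' @param cycles Number of PCR cycles.
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(e_max = 0.9, k_len = 0, cycles = 25L) {
  stopifnot(e_max >= 0, e_max <= 1, k_len >= 0, cycles >= 1)
  structure(list(e_max = e_max, k_len = k_len, cycles = as.integer(cycles)),
            class = "bias_model")
}

#' Scar-amplicon bias preset
#'
#' `"paper-2021-scarseq"`: `e_max = 0.9`, 25 cycles, and `k_len` solved so an
#' equimolar 156 bp amplicon is overrepresented ~2.8-fold relative to a
#' ~196-bp amplicon, the middle of the reported 2.72-2.84-fold range for
#' stage-1 vs stage-2/3 scar amplicons.
#'
#' @param name Preset name.
#' @return A [bias_model()].
#' @export
bias_preset <- function(name = "paper-2021-scarseq") {
  if (name != "paper-2021-scarseq") stop("unknown bias preset '", name, "'")
  e_max <- 0.9; cycles <- 25L
  r <- 2.78^(1 / cycles)   # target per-cycle weight ratio, 156 vs 196.5 bp
  k_len <- (1 + e_max) * (r - 1) / (r * 196.5 - 156)
  bias_model(e_max = e_max, k_len = k_len, cycles = cycles)
}

cycle_weight <- function(bias, lengths) {
  E <- pmin(pmax(bias$e_max - bias$k_len * lengths, 0), 1)
  (1 + E)^bias$cycles
}

#' Simulate observed scar-amplicon read counts
#'
#' Expected read weight of amplicon i is `m_i * (1 + E(L_i))^C`; observed
#' counts are multinomial at the given depth.
#'
#' @param molar_fractions True molar fractions (sum to 1).
#' @param lengths_bp Amplicon lengths (bp).
#' @param bias A [bias_model()].
#' @param read_depth Total reads.
#' @param seed Integer seed.
#' @return Integer vector of read counts.
#' @export
pcr_observe <- function(molar_fractions, lengths_bp, bias, read_depth = 1e5,
                        seed = 1) {
  stopifnot(abs(sum(molar_fractions) - 1) < 1e-8, all(lengths_bp > 0),
            length(molar_fractions) == length(lengths_bp))
  w <- molar_fractions * cycle_weight(bias, lengths_bp)
  set.seed(seed)
  as.integer(stats::rmultinom(1, read_depth, w / sum(w)))
}

#' Correct read counts for PCR length bias
#'
#' Inverts the [pcr_observe()] expectation: estimates are proportional to
#' `count_i / (1 + E(L_i))^C`, normalized. Confidence intervals come from a
#' nonparametric bootstrap over multinomial resampling of the reads
#' (percentile method).
#'
#' @param counts Observed read counts.
#' @param lengths_bp Amplicon lengths (bp).
#' @param bias A [bias_model()].
#' @param B Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return data.frame with estimate, lower, upper per amplicon.
#' @export
bias_correct <- function(counts, lengths_bp, bias, B = 1000, conf = 0.95,
                         seed = 1) {
  stopifnot(length(counts) == length(lengths_bp), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("zero total read counts; nothing to correct")
  w <- cycle_weight(bias, lengths_bp)
  est <- (counts / w) / sum(counts / w)
  set.seed(seed)
  boot <- matrix(NA_real_, B, length(counts))
  for (b in seq_len(B)) {
    cts <- as.integer(stats::rmultinom(1, total, counts / total))
    boot[b, ] <- (cts / w) / sum(cts / w)
  }
  alpha <- (1 - conf) / 2
  data.frame(length_bp = lengths_bp,
             estimate = est,
             lower = apply(boot, 2, stats::quantile, probs = alpha),
             upper = apply(boot, 2, stats::quantile, probs = 1 - alpha))
}

#' Per-stage fractions from scar-amplicon counts
#'
#' One amplicon per stage (lengths increase with stage); returns the
#' bias-corrected molar-fraction estimates labeled by stage.
#'
#' @param counts Read counts, one per stage.
#' @param lengths_bp Amplicon lengths, one per stage.
#' @param bias A [bias_model()].
#' @param stages Stage labels; default 1..k.
#' @param ... Passed to [bias_correct()].
#' @return data.frame stage, length_bp, estimate, lower, upper.
#' @export
estimate_stage_fractions <- function(counts, lengths_bp, bias,
                                     stages = seq_along(counts), ...) {
  out <- bias_correct(counts, lengths_bp, bias, ...)
  cbind(data.frame(stage = stages), out)
}

#' qPCR circuit-removal ratio
#'
#' Ratio of copies still carrying the internal circuit (Cas9 amplicon) to
#' all copies (the piggyBac ITR persists after self-deletion and serves as
#' the denominator). 1 with no deletion, 0 when every copy self-deleted.
#'
#' @param population A `gpc_population`.
#' @param time Assay time (h), default the horizon.
#' @return An object of class `qpcr_result` with `$ratio`.
#' @export
qpcr_excision_ratio <- function(population, time = population$horizon) {
  keep <- population$alive[population$cell]
  if (!any(keep)) stop("no copies in the surviving population")
  deleted <- population$deleted_at[keep] <= time
  structure(list(ratio = 1 - mean(deleted), n_copies = sum(keep), time = time),
            class = "qpcr_result")
}
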