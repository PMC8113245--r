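#' Built-in circuit presets
#'
#' Four ready-made circuits mirroring the published architectures, with
#' deterministic placeholder part sequences (the source plasmids are not
#' public):
#' \describe{
#'   \item{gpcv2-fluor}{GIB-Cre+BFP(+Zeo) -> ABA-Flp+GFP -> GIB-PhiC31+mCherry
#'     -> terminal iRFP720; the four-color gene expression cascade.}
#'   \item{gpcv2-crispra}{sgRNA cascade RHOXF2 -> ASCL1 -> HBG1 -> TTN for
#'     sequential transcriptional activation (96-h stages).}
#'   \item{gpcv2-crispr}{sgRNA cascade APC -> MLH1 -> SMAD4 -> TP53 for
#'     sequential tumor-suppressor editing (96-h stages).}
#'   \item{attp-gpcv2-crispr}{sgAPC -> sgMLH1 -> PuroR-sgSMAD4 with an attP
#'     wrapper and piggyBac ITRs: puromycin synchronization at stage 3 and
#'     GIB-driven whole-circuit self-deletion.}
#' }
#'
#' Each preset bundles the circuit design, the `"paper-2021"` kinetic
#' calibration, GA4/ABA pharmacokinetics and a default schedule builder.
#'
#' @param name Preset name (see above).
#' @return An object of class `gpc_preset` with fields `name`, `design`,
#'   `params`, `pk`, `stage_hours`, `gap_hours`, `provenance`.
#' @export
load_preset <- function(name) {
  builders <- list(
    "gpcv2-fluor" = preset_fluor,
    "gpcv2-crispra" = function() preset_crispr_generic(
      "gpcv2-crispra", c("RHOXF2", "ASCL1", "HBG1", "TTN")),
    "gpcv2-crispr" = function() preset_crispr_generic(
      "gpcv2-crispr", c("APC", "MLH1", "SMAD4", "TP53")),
    "attp-gpcv2-crispr" = preset_attp_crispr)
  if (!name %in% names(builders))
    stop("unknown preset '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  preset <- builders[[name]]()
  assert_valid_design(preset$design)
  preset
}

#' List available presets
#' @return Character vector of preset names.
#' @export
list_presets <- function()
  c("gpcv2-fluor", "gpcv2-crispra", "gpcv2-crispr", "attp-gpcv2-crispr")

new_preset <- function(name, design, stage_hours, provenance) {
  structure(list(name = name, design = design,
                 params = kinetic_preset("paper-2021"),
                 pk = pk_preset("ga4"),
                 stage_hours = stage_hours, gap_hours = 12,
                 provenance = provenance),
            class = "gpc_preset")
}

#' Default schedule of a preset
#' @param preset A `gpc_preset`.
#' @param extra_h Ligand-free tail appended after the last window.
#' @return A [ligand_schedule()].
#' @export
preset_schedule <- function(preset, extra_h = 0)
  build_schedule(preset$design, stage_hours = preset$stage_hours,
                 gap_hours = preset$gap_hours, extra_h = extra_h)

preset_fluor <- function() {
  gpcs <- list(
    gpc_unit(1, recombinase_module("Cre", "GIB"),
             list(payload_block("BFP"),
                  payload_block("Zeo", tags = c("PEST", "P2A", "Zeo")))),
    gpc_unit(2, recombinase_module("Flp", "ABA"), list(payload_block("GFP"))),
    gpc_unit(3, recombinase_module("PhiC31", "GIB"),
             list(payload_block("mCherry"))))
  design <- circuit_design("v2", gpcs,
                           terminal_payloads = list(payload_block("iRFP720")),
                           name = "gpcv2-fluor")
  new_preset("gpcv2-fluor", design, stage_hours = 48, provenance = c(
    recombinase_order = "Cre(GIB) -> Flp(ABA) -> PhiC31(GIB)",
    payload_order = "BFP -> GFP -> mCherry -> iRFP720",
    stage_hours = "48 h ligand windows, 12 h washout gaps",
    zeo = "zeocin marker carried in the first cassette"))
}

preset_crispr_generic <- function(name, loci) {
  recs <- list(c("Cre", "GIB"), c("Flp", "ABA"), c("PhiC31", "GIB"))
  gpcs <- lapply(1:3, function(k)
    gpc_unit(k, recombinase_module(recs[[k]][1], recs[[k]][2]),
             list(payload_block(paste0("sg", loci[k]), kind = "sgRNA"))))
  design <- circuit_design("v2", gpcs,
                           terminal_payloads = list(
                             payload_block(paste0("sg", loci[4]), kind = "sgRNA")),
                           name = name)
  new_preset(name, design, stage_hours = 96, provenance = c(
    loci = paste(loci, collapse = " -> "),
    stage_hours = "96 h windows: editing equilibrates by ~96 h (12 h sgRNA half-life)",
    sgRNA_format = "Csy4 20-nt core flanks, MALAT1 triple helix"))
}

preset_attp_crispr <- function() {
  gpcs <- list(
    gpc_unit(1, recombinase_module("Cre", "GIB"),
             list(payload_block("sgAPC", kind = "sgRNA"))),
    gpc_unit(2, recombinase_module("Flp", "ABA"),
             list(payload_block("sgMLH1", kind = "sgRNA"))),
    gpc_unit(3, recombinase_module("PhiC31", "GIB"),
             list(payload_block("PuroR", tags = c("PEST", "P2A", "PuroR")),
                  payload_block("sgSMAD4", kind = "sgRNA"))))
  wrap <- site_pair("attW", builtin_parts()$attP, builtin_parts()$attB,
                    symmetric = FALSE)
  design <- circuit_design("v2", gpcs, terminal_payloads = list(),
                           att_wrapper = wrap, itr_flanks = TRUE,
                           name = "attp-gpcv2-crispr")
  new_preset("attp-gpcv2-crispr", design, stage_hours = 96, provenance = c(
    cascade = "sgAPC -> sgMLH1 -> PuroR-sgSMAD4",
    synchronization = "puromycin selection at stage 3 (PuroR payload)",
    self_deletion = "GIB at stage 3 recombines upstream attP with cassette attB; 78% removal per 48-h window",
    itr = "piggyBac ITR flanks persist after deletion (qPCR denominator)"))
}

#' @export
print.gpc_preset <- function(x, ...) {
  cat(sprintf("<gpc_preset '%s': %d-h stages, %d-h gaps>\n",
              x$name, x$stage_hours, x$gap_hours))
  print(x$design)
  invisible(x)
}

#' Random valid circuit design (property-test generator)
#'
#' Deterministic per seed: `n_stages` GPCs with alternating ligands, distinct
#' synthetic site pairs (so no cross-reaction violations even when
#' recombinase names repeat), synthetic 30-bp parts, and frame-safe payload
#' lengths.
#'
#' @param seed Integer seed.
#' @param n_stages Number of GPCs (1..8).
#' @param version `"v2"` or `"v1"`.
#' @param part_bp Length of synthetic recombinase-half/payload parts.
#' @return A valid [circuit_design()].
#' @export
random_design <- function(seed, n_stages, version = "v2", part_bp = 30) {
  stopifnot(n_stages >= 1, n_stages <= 8)
  base <- as.integer(seed) * 131L + 17L
  ligs <- rep(c("GIB", "ABA"), length.out = n_stages)
  gpcs <- lapply(seq_len(n_stages), function(k) {
    h <- base + k * 9973L
    site_len <- 30L + as.integer(synthetic_dna(1, h + 1L) == "A") * 3L
    sp <- site_pair(paste0("synthSite", k),
                    synthetic_dna(site_len, h + 2L, frame_safe = TRUE))
    rec <- recombinase_module(paste0("synthRec", k), ligs[k], sp,
                              split_halves = c(
                                synthetic_dna(part_bp, h + 3L, frame_safe = TRUE),
                                synthetic_dna(part_bp, h + 4L, frame_safe = TRUE)))
    gpc_unit(k, rec,
             list(payload_block(paste0("payload", k),
                                sequence = synthetic_dna(part_bp, h + 5L,
                                                         frame_safe = TRUE))),
             terminator = synthetic_dna(40, h + 6L))
  })
  design <- circuit_design(version, gpcs,
                           terminal_payloads = list(payload_block(
                             "terminalPayload",
                             sequence = synthetic_dna(part_bp, base + 7L,
                                                      frame_safe = TRUE))),
                           promoter = synthetic_dna(50, base + 8L),
                           promoter_name = "synthP",
                           name = paste0("random", seed))
  assert_valid_design(design)
}
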