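#' Deterministic synthetic DNA
#'
#' Generates a pseudo-random DNA string from a small multiplicative
#' linear-congruential generator, without touching R's global RNG state.
#' Used for placeholder parts (promoters, coding sequences, att sites) so that
#' shipped presets are reproducible and clearly non-physiological.
#'
#' @param n Length in bases.
#' @param seed Positive integer seed.
#' @param frame_safe If `TRUE`, post-process so the string, read in frame 0,
#'   contains no stop codon (TAA/TAG/TGA are rewritten to TCA/TCG/TCA).
#' @return A character scalar of `n` bases.
#' @export
synthetic_dna <- function(n, seed, frame_safe = FALSE) {
  stopifnot(n >= 0, seed >= 1)
  if (n == 0) return("")
  state <- as.double(seed)
  m <- 2147483647; a <- 48271
  idx <- integer(n)
  for (i in seq_len(n)) {
    state <- (a * state) %% m
    idx[i] <- as.integer(state %% 4) + 1L
  }
  s <- paste(c("A", "C", "G", "T")[idx], collapse = "")
  if (frame_safe) s <- strip_stops(s)
  s
}

# rewrite in-frame stop codons (frame 0) to near-neighbour sense codons
strip_stops <- function(s) {
  v <- substring(s, seq(1, nchar(s) - nchar(s) %% 3, 3),
                 pmin(seq(3, nchar(s), 3), nchar(s)))
  v[v == "TAA"] <- "TCA"; v[v == "TAG"] <- "TCG"; v[v == "TGA"] <- "TCA"
  tail <- if (nchar(s) %% 3 > 0) substring(s, nchar(s) - nchar(s) %% 3 + 1, nchar(s)) else ""
  paste0(paste(v, collapse = ""), tail)
}

# -- canonical / placeholder parts ------------------------------------------
# loxP and FRT are the canonical 34-bp sites; att sites and everything marked
# "synthetic" are deterministic placeholders of canonical length, shipped
# because the source plasmid sequences are not public. All length-dependent
# logic is parameterized on the actual strings, never on these constants.

#' Built-in DNA parts
#'
#' Canonical recombinase recognition sites (loxP, FRT) plus deterministic
#' synthetic placeholders (att sites, P2A, Csy4 core, promoter, terminator,
#' piggyBac ITRs). Placeholders are labeled NON-PHYSIOLOGICAL in GenBank
#' output.
#' @return Named list of DNA strings.
#' @export
builtin_parts <- function() {
  list(
    loxP        = "ATAACTTCGTATAATGTATGCTATACGAAGTTAT",
    FRT         = "GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC",
    attB        = synthetic_dna(50, 101),
    attP        = synthetic_dna(54, 102),
    P2A         = "GGAAGCGGAGCTACTAACTTCAGCCTGCTGAAGCAGGCTGGAGACGTGGAGGAGAACCCTGGACCT",
    csy4_core   = "GTTCACTGCCGTATAGGCAG",
    malat1_th   = synthetic_dna(60, 103),
    CAGp        = paste0(synthetic_dna(74, 104), "GCCACC"),
    terminator  = synthetic_dna(120, 105),  # stands in for 3xBGHpA + 2xcHS4
    itr_left    = synthetic_dna(35, 106),
    itr_right   = synthetic_dna(35, 107)
  )
}

#' Recombination site pair
#'
#' A pair of recognition sites for one recombinase, plus the scar sequence a
#' single excision leaves behind. Symmetric systems (Cre/loxP, Flp/FRT) have
#' identical left/right/scar sites; the PhiC31 attB x attP pair is asymmetric
#' and leaves an attL-like hybrid scar.
#'
#' @param name Site name, e.g. `"loxP"`, `"FRT"`, `"att"`.
#' @param left_site,right_site DNA strings of the two sites as laid out 5'->3'.
#' @param scar_site DNA string left behind after excision; defaults to
#'   `left_site` for symmetric pairs and to an attL-like hybrid
#'   (5' half of `left_site` + 3' half of `right_site`) otherwise.
#' @param symmetric Logical; `TRUE` when both sites are the same sequence.
#' @return An object of class `site_pair`.
#' @export
site_pair <- function(name, left_site, right_site = left_site,
                      scar_site = NULL, symmetric = identical(left_site, right_site)) {
  left_site <- toupper(left_site); right_site <- toupper(right_site)
  if (is.null(scar_site)) {
    scar_site <- if (symmetric) left_site else
      paste0(substr(left_site, 1, nchar(left_site) %/% 2),
             substr(right_site, nchar(right_site) %/% 2 + 1, nchar(right_site)))
  }
  scar_site <- toupper(scar_site)
  stopifnot(nzchar(scar_site))
  if (symmetric && !(identical(left_site, right_site) && identical(left_site, scar_site)))
    stop("symmetric site pair must have identical left/right/scar sites")
  structure(list(name = name, left_site = left_site, right_site = right_site,
                 scar_site = scar_site, symmetric = symmetric),
            class = "site_pair")
}

#' Canonical site pair for a recombinase
#' @param recombinase One of `"Cre"`, `"Flp"`, `"PhiC31"`.
#' @return A [site_pair()].
#' @export
canonical_site_pair <- function(recombinase) {
  p <- builtin_parts()
  switch(recombinase,
    Cre    = site_pair("loxP", p$loxP),
    Flp    = site_pair("FRT", p$FRT),
    PhiC31 = site_pair("att", p$attB, p$attP, symmetric = FALSE),
    stop("no canonical site pair for recombinase '", recombinase, "'")
  )
}

#' Ligand-inducible split recombinase module
#'
#' A split recombinase reconstituted by chemically induced dimerization (CID):
#' gibberellin (GIB) or abscisic acid (ABA) brings the two halves together,
#' activating excision at the cognate site pair.
#'
#' @param name Recombinase name (`"Cre"`, `"Flp"`, `"PhiC31"`, or a synthetic
#'   name for generated test designs).
#' @param ligand `"GIB"` or `"ABA"`.
#' @param sites A [site_pair()]; defaults to the canonical pair for known
#'   recombinases.
#' @param split_halves Character vector of two coding DNA strings (placeholders
#'   by default).
#' @param nls Logical; extra nuclear localization signal appended.
#' @return An object of class `recombinase_module`.
#' @export
recombinase_module <- function(name, ligand, sites = NULL, split_halves = NULL,
                               nls = TRUE) {
  if (!ligand %in% c("GIB", "ABA")) stop("ligand must be 'GIB' or 'ABA'")
  if (is.null(sites)) sites <- canonical_site_pair(name)
  if (name %in% c("Cre", "Flp", "PhiC31")) {
    want <- c(Cre = "loxP", Flp = "FRT", PhiC31 = "att")[[name]]
    if (sites$name != want)
      stop(name, " must use ", want, " sites, got '", sites$name, "'")
  }
  if (is.null(split_halves)) {
    h <- abs(sum(utf8ToInt(name))) + 11L
    split_halves <- c(synthetic_dna(60, h, frame_safe = TRUE),
                      synthetic_dna(60, h + 1L, frame_safe = TRUE))
  }
  structure(list(name = name, ligand = ligand, sites = sites,
                 split_halves = toupper(split_halves), nls = isTRUE(nls)),
            class = "recombinase_module")
}

#' @export
print.site_pair <- function(x, ...) {
  cat(sprintf("<site_pair %s: L=%d bp, R=%d bp, scar=%d bp, %s>\n", x$name,
              nchar(x$left_site), nchar(x$right_site), nchar(x$scar_site),
              if (x$symmetric) "symmetric" else "asymmetric"))
  invisible(x)
}
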