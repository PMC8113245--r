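#' Payload block
#'
#' One payload within a GPC: a protein coding sequence (delivered through a
#' P2A junction) or an sgRNA spacer (released from the Pol II transcript by
#' Csy4 cleavage at flanking 20-nt core sites, with the upstream mRNA
#' stabilized by a MALAT1 triple helix).
#'
#' @param name Payload name (e.g. `"BFP"`, `"sgAPC"`).
#' @param kind `"protein"` or `"sgRNA"`.
#' @param sequence Coding DNA (protein; length divisible by 3) or 20-nt spacer
#'   (sgRNA). Defaults to a deterministic placeholder.
#' @param tags Character vector of annotations; sgRNAs get
#'   `"Csy4_20nt_core"` and `"MALAT1_triple_helix"` by default, proteins get
#'   `"PEST"` and `"P2A"`.
#' @param locus For sgRNA payloads, the genomic locus targeted (used by the
#'   editing model); defaults to `name` stripped of a leading `"sg"`.
#' @return An object of class `payload_block`.
#' @export
payload_block <- function(name, kind = c("protein", "sgRNA"), sequence = NULL,
                          tags = NULL, locus = NULL) {
  kind <- match.arg(kind)
  if (is.null(sequence)) {
    h <- abs(sum(utf8ToInt(name))) * 7L + 5L
    sequence <- if (kind == "protein") synthetic_dna(60, h, frame_safe = TRUE)
                else synthetic_dna(20, h)
  }
  sequence <- toupper(sequence)
  if (is.null(tags))
    tags <- if (kind == "sgRNA") c("Csy4_20nt_core", "MALAT1_triple_helix")
            else c("PEST", "P2A")
  if (is.null(locus) && kind == "sgRNA") locus <- sub("^sg", "", name)
  structure(list(name = name, kind = kind, sequence = sequence,
                 tags = unique(tags), locus = locus),
            class = "payload_block")
}

#' Gene perturbation cassette (GPC) unit
#'
#' One self-excising unit of the tandem array: a ligand-inducible split
#' recombinase, its payloads, and a strong terminator block (modeled after
#' 3xBGHpA + 2xcHS4) that gates expression of everything downstream.
#'
#' @param index 1-based stage position in the array.
#' @param recombinase A [recombinase_module()].
#' @param payloads List of [payload_block()]s, in 5'->3' order.
#' @param terminator DNA string; must be non-empty.
#' @return An object of class `gpc_unit`.
#' @export
gpc_unit <- function(index, recombinase, payloads = list(),
                     terminator = builtin_parts()$terminator) {
  stopifnot(index >= 1, inherits(recombinase, "recombinase_module"))
  if (inherits(payloads, "payload_block")) payloads <- list(payloads)
  structure(list(index = as.integer(index), recombinase = recombinase,
                 payloads = payloads, terminator = toupper(terminator)),
            class = "gpc_unit")
}

#' Tandem GPC circuit design
#'
#' Declarative description of a complete circuit: promoter, v2 translation
#' leader, the ordered GPC array, terminal payloads expressed after the last
#' excision, an optional attP wrapper enabling whole-circuit self-deletion,
#' and optional piggyBac ITR flanks.
#'
#' @param version `"v1"` (scars accumulate in the 5'UTR) or `"v2"` (scars are
#'   translated behind an upstream ATG and cleaved off by 2A peptides).
#' @param gpcs List of [gpc_unit()]s in promoter-proximal order.
#' @param terminal_payloads List of [payload_block()]s expressed at stage N+1.
#' @param promoter,promoter_name Promoter sequence and label.
#' @param leader DNA between promoter and array; v2 default `"ATG"`, v1 `""`.
#' @param att_wrapper Optional [site_pair()] spanning the whole circuit; when
#'   set, activation of the PhiC31 stage can delete the entire circuit.
#' @param itr_flanks Logical; flank the construct with piggyBac ITRs.
#' @param frame_pad Logical (v2): pad scar units so the translated frame is
#'   preserved across excisions (see [frame_pad_for_site()]).
#' @param name Circuit name used in output files.
#' @return An object of class `circuit_design`.
#' @export
circuit_design <- function(version = c("v2", "v1"), gpcs = list(),
                           terminal_payloads = list(),
                           promoter = builtin_parts()$CAGp,
                           promoter_name = "CAGp",
                           leader = NULL,
                           att_wrapper = NULL, itr_flanks = FALSE,
                           frame_pad = TRUE, name = "circuit") {
  version <- match.arg(version)
  if (is.null(leader)) leader <- if (version == "v2") "ATG" else ""
  if (inherits(gpcs, "gpc_unit")) gpcs <- list(gpcs)
  if (inherits(terminal_payloads, "payload_block"))
    terminal_payloads <- list(terminal_payloads)
  structure(list(version = version, name = name,
                 promoter = toupper(promoter), promoter_name = promoter_name,
                 leader = toupper(leader), gpcs = gpcs,
                 terminal_payloads = terminal_payloads,
                 att_wrapper = att_wrapper, itr_flanks = isTRUE(itr_flanks),
                 frame_pad = isTRUE(frame_pad)),
            class = "circuit_design")
}

#' Number of GPC stages in a design
#' @param design A [circuit_design()].
#' @return Integer N (the terminal stage is N+1).
#' @export
n_stages <- function(design) length(design$gpcs)

#' @export
print.circuit_design <- function(x, ...) {
  cat(sprintf("<circuit_design '%s' %s: %d GPCs + %d terminal payload(s)%s%s>\n",
              x$name, x$version, n_stages(x), length(x$terminal_payloads),
              if (!is.null(x$att_wrapper)) ", att-wrapped" else "",
              if (x$itr_flanks) ", ITR-flanked" else ""))
  for (u in x$gpcs)
    cat(sprintf("  stage %d: %s(%s) -> %s\n", u$index, u$recombinase$name,
                u$recombinase$ligand,
                paste(vapply(u$payloads, `[[`, "", "name"), collapse = "+")))
  if (length(x$terminal_payloads))
    cat(sprintf("  stage %d: %s\n", n_stages(x) + 1L,
                paste(vapply(x$terminal_payloads, `[[`, "", "name"), collapse = "+")))
  invisible(x)
}

#' Validate a circuit design
#'
#' Returns a character vector of rule violations (empty for a valid design).
#' Checked rules: unique sequential stage indices; non-empty terminators;
#' known-recombinase/site consistency; v2 leader starting with ATG (v1 leader
#' empty); consecutive stages reusing the same site pair (premature
#' co-excision); duplicate site pairs anywhere (scar cross-reaction); sgRNA
#' payloads missing Csy4 core flanks; protein payloads with length not
#' divisible by 3; v2 scar frame breaks. Ligand alternation is *reported* via
#' the `"notes"` attribute, not enforced: two stages may share a ligand
#' because expression gating keeps downstream recombinases inert.
#'
#' @param design A [circuit_design()].
#' @return Character vector of violations, with a `"notes"` attribute.
#' @export
validate_design <- function(design) {
  v <- character(); notes <- character()
  gpcs <- design$gpcs
  N <- length(gpcs)
  idx <- vapply(gpcs, `[[`, integer(1), "index")
  if (N > 0 && !identical(idx, seq_len(N)))
    v <- c(v, "stage indices must be unique and sequential from 1")
  if (design$version == "v2" && substr(design$leader, 1, 3) != "ATG")
    v <- c(v, "v2 leader must start with ATG")
  if (design$version == "v1" && nzchar(design$leader))
    v <- c(v, "v1 leader must be empty (scar sits in the 5'UTR)")
  for (u in gpcs) {
    r <- u$recombinase
    if (!nzchar(u$terminator))
      v <- c(v, sprintf("stage %d: empty terminator (downstream GPCs would leak)", u$index))
    if (r$name %in% c("Cre", "Flp", "PhiC31")) {
      want <- c(Cre = "loxP", Flp = "FRT", PhiC31 = "att")[[r$name]]
      if (r$sites$name != want)
        v <- c(v, sprintf("stage %d: %s paired with '%s' sites, expected %s",
                          u$index, r$name, r$sites$name, want))
    }
    if (!r$ligand %in% c("GIB", "ABA"))
      v <- c(v, sprintf("stage %d: unknown ligand '%s'", u$index, r$ligand))
    for (p in u$payloads) v <- c(v, check_payload(p, u$index))
  }
  for (p in design$terminal_payloads) v <- c(v, check_payload(p, N + 1L))
  if (N >= 2) {
    sites <- vapply(gpcs, function(u) u$recombinase$sites$left_site, "")
    snames <- vapply(gpcs, function(u) u$recombinase$sites$name, "")
    for (k in seq_len(N - 1)) {
      if (sites[k] == sites[k + 1])
        v <- c(v, sprintf(
          "stages %d-%d: same recombinase in consecutive stages: premature co-excision",
          k, k + 1))
    }
    for (k in 2:N)
      if (sites[k] %in% sites[seq_len(k - 1)] && sites[k] != sites[k - 1])
        v <- c(v, sprintf("stage %d: duplicate site pair '%s' could cross-react with an earlier scar",
                          k, snames[k]))
    ligs <- vapply(gpcs, function(u) u$recombinase$ligand, "")
    if (any(ligs[-N] == ligs[-1]))
      notes <- c(notes, "adjacent stages share a ligand (allowed: expression gating)")
  }
  if (design$version == "v2" && N > 0) {
    for (k in 1 + seq_len(N)) {
      sp <- scar_peptide(design, k, .validate = FALSE)
      if (!sp$frame_ok) {
        v <- c(v, sprintf("stage %d: scar frame break (cumulative scar %d bp%s)",
                          k, nchar(sp$scar),
                          if (nchar(sp$scar) %% 3 == 0) ", internal stop codon" else ""))
        break
      }
    }
  }
  structure(v, notes = notes)
}

check_payload <- function(p, stage) {
  v <- character()
  if (p$kind == "sgRNA" && !"Csy4_20nt_core" %in% p$tags)
    v <- c(v, sprintf("stage %d payload '%s': sgRNA missing Csy4_20nt_core flanks", stage, p$name))
  if (p$kind == "protein" && nchar(p$sequence) %% 3 != 0)
    v <- c(v, sprintf("stage %d payload '%s': protein length %d not divisible by 3",
                      stage, p$name, nchar(p$sequence)))
  v
}

#' Assert a design is valid
#' @param design A [circuit_design()].
#' @return The design, invisibly; stops with all violations otherwise.
#' @export
assert_valid_design <- function(design) {
  v <- validate_design(design)
  if (length(v))
    stop("invalid circuit design:\n", paste("  -", v, collapse = "\n"), call. = FALSE)
  invisible(design)
}
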