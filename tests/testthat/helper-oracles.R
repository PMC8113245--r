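# Independent oracles used across test files. These deliberately avoid the
# package's sequence/feature machinery: plain string concatenation, substring
# search and a hard-coded codon table.

# brute-force stage-1 assembly straight from the documented layout
oracle_assemble <- function(design) {
  parts <- builtin_parts()
  pieces <- character()
  push <- function(x) pieces <<- c(pieces, x)
  if (design$itr_flanks) push(parts$itr_left)
  if (!is.null(design$att_wrapper)) push(design$att_wrapper$left_site)
  push(design$promoter); push(design$leader)
  for (u in design$gpcs) {
    pads <- if (design$version == "v2" && design$frame_pad)
      frame_pad_for_site(u$recombinase$sites$scar_site) else list(pre = "", post = "")
    push(pads$pre); push(u$recombinase$sites$left_site)
    if (design$version == "v2") push(parts$P2A)
    push(u$recombinase$split_halves[1]); push(parts$P2A)
    push(u$recombinase$split_halves[2])
    for (p in u$payloads) push(oracle_payload(p, parts))
    push(u$terminator); push(u$recombinase$sites$right_site); push(pads$post)
  }
  for (p in design$terminal_payloads) push(oracle_payload(p, parts))
  if (length(design$terminal_payloads)) push(parts$terminator)
  if (!is.null(design$att_wrapper)) push(design$att_wrapper$right_site)
  if (design$itr_flanks) push(parts$itr_right)
  paste(pieces, collapse = "")
}

oracle_payload <- function(p, parts) {
  if (p$kind == "protein") return(paste0(parts$P2A, p$sequence))
  out <- paste0(parts$csy4_core, p$sequence, parts$csy4_core)
  if ("MALAT1_triple_helix" %in% p$tags) out <- paste0(out, parts$malat1_th)
  out
}

# brute-force excision: locate the sites by substring search, replace the
# whole left..right span by the scar
oracle_excise <- function(seq, left_site, right_site, scar) {
  i <- as.integer(regexpr(left_site, seq, fixed = TRUE))
  stopifnot(i > 0)
  rest <- substr(seq, i + nchar(left_site), nchar(seq))
  j_rel <- as.integer(regexpr(right_site, rest, fixed = TRUE))
  stopifnot(j_rel > 0)
  j_end <- i + nchar(left_site) - 1L + j_rel + nchar(right_site) - 1L
  paste0(substr(seq, 1, i - 1L), scar, substr(seq, j_end + 1L, nchar(seq)))
}

# independent translation with a hard-coded standard codon table
CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

# independent reverse complement (no Biostrings)
revcomp_str <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracle_translate <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  paste(CODON_TABLE[codons], collapse = "")
}

# hand-built population: one single-copy cell per element of `stages`,
# frozen at that stage (used by selection/flow/qpcr unit tests)
make_population <- function(design, stages, copies_per_cell = NULL,
                            horizon = 100, params = kinetic_preset()) {
  if (is.null(copies_per_cell)) copies_per_cell <- rep(1L, length(stages))
  stopifnot(length(stages) == sum(copies_per_cell) || length(stages) == length(copies_per_cell))
  N <- n_stages(design)
  cell <- rep(seq_along(copies_per_cell), copies_per_cell)
  entry <- t(vapply(stages, function(s)
    c(rep(0, s), rep(Inf, N + 1L - s)), numeric(N + 1L)))
  colnames(entry) <- paste0("stage", seq_len(N + 1L))
  structure(list(design = design, params = params, pk = pk_preset("ga4"),
                 schedule = ligand_schedule(NULL, horizon_h = horizon),
                 cell = cell, entry = entry,
                 deleted_at = rep(Inf, length(stages)),
                 alive = rep(TRUE, length(copies_per_cell)),
                 n_cells = length(copies_per_cell),
                 horizon = horizon, seed = 1L),
            class = "gpc_population")
}

# compiler-vs-oracle sweep over random designs; returns number of mismatches
compiler_oracle_sweep <- function(n_designs, seed0 = 1000) {
  bad <- 0L
  for (i in seq_len(n_designs)) {
    nst <- 1L + (i %% 4L)
    version <- if (i %% 3L == 0L) "v1" else "v2"
    d <- random_design(seed0 + i, nst, version)
    cc <- compile_design(d)
    expected <- oracle_assemble(d)
    if (!identical(cc$sequence, expected)) bad <- bad + 1L
    seq_o <- expected
    for (k in seq_len(nst)) {
      s <- d$gpcs[[k]]$recombinase$sites
      seq_o <- oracle_excise(seq_o, s$left_site, s$right_site, s$scar_site)
      cc <- excise_stage(cc)
      if (!identical(cc$sequence, seq_o)) bad <- bad + 1L
    }
  }
  bad
}

t1_params <- function() kinetic_params(excision_hazard = 0.087, leak_hazard = 5e-4)

t1_schedule <- function() build_schedule(c("GIB", "ABA", "GIB"))
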