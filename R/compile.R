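# condition helpers --------------------------------------------------------
gpc_error <- function(msg, class) stop(errorCondition(msg, class = c(class, "gpcsim_error")))

count_matches <- function(seq, pat) {
  if (!nzchar(pat) || nchar(pat) > nchar(seq)) return(0L)
  m <- gregexpr(pat, seq, fixed = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

.gpcsim_cache <- new.env(parent = emptyenv())

codon_lookup <- function() {
  if (is.null(.gpcsim_cache$codons))
    .gpcsim_cache$codons <- Biostrings::GENETIC_CODE
  .gpcsim_cache$codons
}

translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n < 3) return("")
  aa <- codon_lookup()[substring(x, seq(1, n, 3), seq(3, n, 3))]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

has_inframe_stop <- function(x) grepl("\\*", translate_dna(x))

#' Frame padding for a scar unit
#'
#' In v2 designs the accumulating scar is translated, so each excision must
#' leave a scar unit whose length is a multiple of 3 and which is free of
#' in-frame stop codons. Canonical sites do not guarantee either (loxP is
#' 34 bp; FRT read at offset 0 contains TAG), so the compiler brackets each
#' unit with a deterministic pre/post pad: `pre + scar_site + post`, total
#' length divisible by 3, pads chosen by a fixed search so the unit has no
#' in-frame stop. The pre-pad sits 5' of the left site and the post-pad 3' of
#' the right site, so both survive excision.
#'
#' @param scar_site DNA string left after excision.
#' @return list with `pre` and `post` pad strings (possibly empty).
#' @export
frame_pad_for_site <- function(scar_site) {
  key <- paste0("pad_", scar_site)
  hit <- .gpcsim_cache[[key]]
  if (!is.null(hit)) return(hit)
  fillers <- c("GGCGGC", "GCCGCC", "CAGCAG", "AGCAGC", "ACCACC")
  base_pad <- (3 - nchar(scar_site) %% 3) %% 3
  for (total in c(base_pad, base_pad + 3L)) {
    for (pre_n in 0:total) {
      post_n <- total - pre_n
      for (f1 in fillers) for (f2 in fillers) {
        pre <- substr(f1, 1, pre_n); post <- substr(f2, 1, post_n)
        unit <- paste0(pre, scar_site, post)
        if (nchar(unit) %% 3 == 0 && !has_inframe_stop(unit)) {
          .gpcsim_cache[[key]] <- list(pre = pre, post = post)
          return(.gpcsim_cache[[key]])
        }
      }
    }
  }
  stop("no stop-free frame padding found for scar site")  # pathological site
}

unit_pads <- function(design, k) {
  if (design$version != "v2" || !design$frame_pad) return(list(pre = "", post = ""))
  frame_pad_for_site(design$gpcs[[k]]$recombinase$sites$scar_site)
}

# --------------------------------------------------------------------------
# sequence assembly: a tiny builder accumulating (label, type, role, stage,
# strand) features in 0-based half-open coordinates on the top strand.

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$seq <- character(); env$feat <- list(); env$pos <- 0L
  env
}

add_seg <- function(b, seq, label, type, stage = NA_integer_, role = NA_character_) {
  n <- nchar(seq)
  if (n == 0) return(invisible())
  b$feat[[length(b$feat) + 1L]] <-
    data.frame(label = label, type = type, role = role, stage = stage,
               start = b$pos, end = b$pos + n, strand = "+",
               expressed = FALSE, stringsAsFactors = FALSE)
  b$seq <- c(b$seq, seq); b$pos <- b$pos + n
  invisible()
}

payload_segments <- function(b, p, stage, parts) {
  if (p$kind == "protein") {
    add_seg(b, parts$P2A, "P2A", "linker", stage)
    add_seg(b, p$sequence, p$name, "payload", stage)
  } else {
    add_seg(b, parts$csy4_core, "Csy4_20nt_core", "cleavage_site", stage)
    add_seg(b, p$sequence, p$name, "payload", stage)
    add_seg(b, parts$csy4_core, "Csy4_20nt_core", "cleavage_site", stage)
    if ("MALAT1_triple_helix" %in% p$tags)
      add_seg(b, parts$malat1_th, "MALAT1_triple_helix", "stability_element", stage)
  }
}

#' Compile a circuit design into its stage-1 construct
#'
#' Lays out `promoter . leader . [pad . left_site . 2A-recombinase .
#' payloads . terminator . right_site . pad] x N . terminal payloads`,
#' optionally wrapped in an att pair and piggyBac ITRs, and annotates every
#' part. Only elements of the promoter-proximal GPC (and nothing downstream
#' of its terminator) are flagged `expressed`.
#'
#' @param design A valid [circuit_design()].
#' @return An object of class `gpc_construct` at stage 1.
#' @export
compile_design <- function(design) {
  assert_valid_design(design)
  parts <- builtin_parts()
  b <- new_builder()
  if (design$itr_flanks) add_seg(b, parts$itr_left, "ITR_L", "itr", role = "itr_L")
  if (!is.null(design$att_wrapper))
    add_seg(b, design$att_wrapper$left_site,
            paste0(design$att_wrapper$name, "_wrap_L"), "site", role = "wrap_L")
  add_seg(b, design$promoter, design$promoter_name, "promoter")
  add_seg(b, design$leader, "leader", "leader")
  N <- n_stages(design)
  for (k in seq_len(N)) {
    u <- design$gpcs[[k]]; s <- u$recombinase$sites
    pads <- unit_pads(design, k)
    add_seg(b, pads$pre, "frame_pad", "pad", k)
    add_seg(b, s$left_site, paste0(s$name, "_L"), "site", k, role = "site_L")
    if (design$version == "v2") add_seg(b, parts$P2A, "P2A", "linker", k)
    add_seg(b, u$recombinase$split_halves[1],
            paste0(u$recombinase$name, "_N"), "recombinase", k)
    add_seg(b, parts$P2A, "P2A", "linker", k)
    add_seg(b, u$recombinase$split_halves[2],
            paste0(u$recombinase$name, "_C"), "recombinase", k)
    for (p in u$payloads) payload_segments(b, p, k, parts)
    add_seg(b, u$terminator, "3xBGHpA_2xcHS4", "terminator", k)
    add_seg(b, s$right_site, paste0(s$name, "_R"), "site", k, role = "site_R")
    add_seg(b, pads$post, "frame_pad", "pad", k)
  }
  for (p in design$terminal_payloads) payload_segments(b, p, N + 1L, parts)
  if (length(design$terminal_payloads))
    add_seg(b, parts$terminator, "3xBGHpA_2xcHS4", "terminator", N + 1L)
  if (!is.null(design$att_wrapper))
    add_seg(b, design$att_wrapper$right_site,
            paste0(design$att_wrapper$name, "_wrap_R"), "site", role = "wrap_R")
  if (design$itr_flanks) add_seg(b, parts$itr_right, "ITR_R", "itr", role = "itr_R")

  construct <- structure(
    list(stage = 1L, deleted = FALSE, design = design,
         sequence = paste(b$seq, collapse = ""),
         features = do.call(rbind, b$feat),
         scar = list(segments = character(), cumulative = "",
                     peptide = NA_character_, frame_ok = TRUE)),
    class = "gpc_construct")
  mark_expressed(construct)
}

mark_expressed <- function(construct) {
  f <- construct$features
  f$expressed <- FALSE
  N <- n_stages(construct$design)
  if (!construct$deleted) {
    k <- construct$stage
    f$expressed[!is.na(f$stage) & f$stage == k &
                f$type %in% c("recombinase", "payload")] <- TRUE
    if (k == N + 1L)
      f$expressed[!is.na(f$stage) & f$stage == k & f$type == "payload"] <- TRUE
  }
  construct$features <- f
  if (construct$design$version == "v2" && !construct$deleted) {
    sp <- scar_peptide(construct$design, construct$stage, .validate = FALSE)
    construct$scar$peptide <- sp$peptide
    construct$scar$frame_ok <- sp$frame_ok
  }
  construct
}

#' @export
print.gpc_construct <- function(x, ...) {
  cat(sprintf("<gpc_construct '%s' stage %s: %d bp, %d features, scar %d bp>\n",
              x$design$name, if (x$deleted) "DELETED" else x$stage,
              nchar(x$sequence), nrow(x$features), nchar(x$scar$cumulative)))
  invisible(x)
}

#' Excise the promoter-proximal GPC
#'
#' Applies one recombination event: the span from the proximal unit's left
#' site through its right site is replaced by the pair's single scar site
#' (for symmetric pairs this is identical to leaving one site behind). The
#' stage counter increments, features are re-mapped, and the scar record is
#' extended by `pre-pad + scar_site + post-pad`.
#'
#' @param construct A `gpc_construct`.
#' @return The next-stage `gpc_construct`.
#' @export
excise_stage <- function(construct) {
  N <- n_stages(construct$design)
  if (construct$deleted || construct$stage > N)
    gpc_error(sprintf("no GPC left to excise at stage %s",
                      if (construct$deleted) "DELETED" else construct$stage),
              "gpcsim_no_more_stages")
  k <- construct$stage
  f <- construct$features
  iL <- which(!is.na(f$stage) & f$stage == k & f$role %in% "site_L")
  iR <- which(!is.na(f$stage) & f$stage == k & f$role %in% "site_R")
  stopifnot(length(iL) == 1, length(iR) == 1)
  sites <- construct$design$gpcs[[k]]$recombinase$sites
  span_start <- f$start[iL]; span_end <- f$end[iR]
  scar <- sites$scar_site
  construct$sequence <- paste0(substr(construct$sequence, 1, span_start),
                               scar,
                               substr(construct$sequence, span_end + 1,
                                      nchar(construct$sequence)))
  shift <- nchar(scar) - (span_end - span_start)
  keep <- f$start < span_start | f$end > span_end
  f <- f[keep, , drop = FALSE]
  after <- f$start >= span_end
  f$start[after] <- f$start[after] + shift
  f$end[after] <- f$end[after] + shift
  scar_feat <- data.frame(label = paste0(sites$name, "_scar"), type = "scar",
                          role = NA_character_, stage = k, start = span_start,
                          end = span_start + nchar(scar), strand = "+",
                          expressed = FALSE, stringsAsFactors = FALSE)
  f <- rbind(f, scar_feat)
  f <- f[order(f$start, f$end), , drop = FALSE]
  rownames(f) <- NULL
  construct$features <- f
  construct$stage <- k + 1L
  pads <- unit_pads(construct$design, k)
  seg <- paste0(pads$pre, scar, pads$post)
  construct$scar$segments <- c(construct$scar$segments, seg)
  construct$scar$cumulative <- paste0(construct$scar$cumulative, seg)
  mark_expressed(construct)
}

#' Self-deletion construct
#'
#' The post-self-deletion state of an att-wrapped circuit: everything from
#' the wrapper's left site through its right site is replaced by the wrapper
#' scar, leaving only the ITR flanks (if any) and the att scar.
#'
#' @param design An att-wrapped [circuit_design()].
#' @return A `gpc_construct` with `deleted = TRUE`.
#' @export
deleted_construct <- function(design) {
  if (is.null(design$att_wrapper))
    gpc_error("design has no att wrapper; self-deletion impossible", "gpcsim_no_att_wrapper")
  c1 <- compile_design(design)
  f <- c1$features
  iL <- which(f$role %in% "wrap_L"); iR <- which(f$role %in% "wrap_R")
  stopifnot(length(iL) == 1, length(iR) == 1)
  scar <- design$att_wrapper$scar_site
  span_start <- f$start[iL]; span_end <- f$end[iR]
  c1$sequence <- paste0(substr(c1$sequence, 1, span_start), scar,
                        substr(c1$sequence, span_end + 1, nchar(c1$sequence)))
  shift <- nchar(scar) - (span_end - span_start)
  keep <- f$start < span_start | f$end > span_end
  f <- f[keep, , drop = FALSE]
  after <- f$start >= span_end
  f$start[after] <- f$start[after] + shift
  f$end[after] <- f$end[after] + shift
  f <- rbind(f, data.frame(label = paste0(design$att_wrapper$name, "_scar"),
                           type = "scar", role = NA_character_, stage = NA_integer_,
                           start = span_start, end = span_start + nchar(scar),
                           strand = "+", expressed = FALSE, stringsAsFactors = FALSE))
  f <- f[order(f$start, f$end), , drop = FALSE]
  rownames(f) <- NULL
  c1$features <- f
  c1$deleted <- TRUE
  c1$stage <- NA_integer_
  c1$scar <- list(segments = character(), cumulative = scar,
                  peptide = NA_character_, frame_ok = NA)
  mark_expressed(c1)
}

#' Enumerate every stage of a design
#'
#' @param design A valid [circuit_design()].
#' @return List of `N+1` constructs (stage 1..N+1), plus a `DELETED`
#'   construct appended when the design carries an att wrapper.
#' @export
enumerate_stages <- function(design) {
  out <- vector("list", n_stages(design) + 1L)
  out[[1]] <- compile_design(design)
  for (k in seq_len(n_stages(design))) out[[k + 1L]] <- excise_stage(out[[k]])
  names(out) <- paste0("stage", seq_along(out))
  if (!is.null(design$att_wrapper)) out$DELETED <- deleted_construct(design)
  out
}

#' Translated scar peptide (v2)
#'
#' v2 circuits place an initiation codon upstream of the array so that the
#' accumulating scar is translated rather than loaded into the 5'UTR; a 2A
#' peptide at the 5' end of each recombinase releases the scar peptide.
#' Returns the translation of leader + cumulative scar at a given stage and
#' whether the reading frame is intact (cumulative scar divisible by 3, no
#' internal stop).
#'
#' @param design A v2 [circuit_design()].
#' @param stage Stage 1..N+1.
#' @param .validate Internal; skip design validation.
#' @return list(peptide, frame_ok, scar).
#' @export
scar_peptide <- function(design, stage, .validate = TRUE) {
  if (design$version != "v2")
    gpc_error("scar peptide is only defined for v2 designs (v1 scar is 5'UTR)",
              "gpcsim_unsupported_version")
  N <- n_stages(design)
  if (stage < 1 || stage > N + 1) stop("stage must be in 1..", N + 1)
  if (.validate) assert_valid_design(design)
  segs <- vapply(seq_len(stage - 1), function(k) {
    pads <- unit_pads(design, k)
    paste0(pads$pre, design$gpcs[[k]]$recombinase$sites$scar_site, pads$post)
  }, "")
  scar <- paste(segs, collapse = "")
  atg <- regexpr("ATG", design$leader, fixed = TRUE)
  orf <- paste0(substr(design$leader, atg, nchar(design$leader)), scar)
  pep <- translate_dna(orf)
  frame_ok <- nchar(orf) %% 3 == 0 && !grepl("\\*", pep)
  list(peptide = pep, frame_ok = frame_ok, scar = scar)
}

#' Predict a PCR amplicon
#'
#' Both primers are given 5'->3' as supplied to the PCR: the forward primer
#' must match the top strand exactly once, the reverse primer the bottom
#' strand exactly once, with the forward site upstream. For primers flanking
#' the scar region the amplicon length grows with every completed stage,
#' which is how the stage of a cascade is read out by amplicon sequencing.
#'
#' @param construct A `gpc_construct`.
#' @param fwd_primer,rev_primer Primer sequences (5'->3').
#' @return list(length, sequence) of the inclusive amplicon.
#' @export
predict_amplicon <- function(construct, fwd_primer, rev_primer) {
  seq <- construct$sequence
  fwd <- toupper(fwd_primer); rev <- toupper(rev_primer)
  rev_rc <- revcomp(rev)
  n_f_top <- count_matches(seq, fwd); n_f_bot <- count_matches(seq, revcomp(fwd))
  n_r_bot <- count_matches(seq, rev_rc); n_r_top <- count_matches(seq, rev)
  if (n_f_top + n_f_bot != 1 || n_f_top != 1)
    gpc_error(sprintf("forward primer matches top strand %d time(s), bottom %d",
                      n_f_top, n_f_bot), "gpcsim_ambiguous_primer")
  if (n_r_bot + n_r_top != 1 || n_r_bot != 1)
    gpc_error(sprintf("reverse primer matches bottom strand %d time(s), top %d",
                      n_r_bot, n_r_top), "gpcsim_ambiguous_primer")
  fwd_start <- as.integer(regexpr(fwd, seq, fixed = TRUE))
  rev_end <- as.integer(regexpr(rev_rc, seq, fixed = TRUE)) + nchar(rev_rc) - 1L
  if (fwd_start >= rev_end)
    gpc_error("forward primer is not upstream of the reverse primer",
              "gpcsim_ambiguous_primer")
  amp <- substr(seq, fwd_start, rev_end)
  list(length = nchar(amp), sequence = amp)
}

#' Per-stage summary table of a design
#'
#' @param design A valid [circuit_design()].
#' @return data.frame with stage, expressed payloads, sequence length,
#'   cumulative scar length and frame status.
#' @export
stage_table <- function(design) {
  stages <- enumerate_stages(design)
  do.call(rbind, lapply(names(stages), function(nm) {
    cc <- stages[[nm]]
    expr <- cc$features$label[cc$features$expressed & cc$features$type == "payload"]
    data.frame(stage = if (cc$deleted) "DELETED" else as.character(cc$stage),
               expressed_payloads = paste(expr, collapse = "+"),
               length_bp = nchar(cc$sequence),
               scar_bp = nchar(cc$scar$cumulative),
               frame_ok = cc$scar$frame_ok,
               stringsAsFactors = FALSE)
  }))
}
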