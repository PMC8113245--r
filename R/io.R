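# GenBank flat-file writer/parser -----------------------------------------
# Minimal but standard-conformant subset: LOCUS/DEFINITION/COMMENT, a
# FEATURES table of misc_feature entries with /label, /note qualifiers, and a
# 60-column ORIGIN block. Internal coordinates are 0-based half-open on the
# top strand; GenBank locations are written 1-based inclusive.

#' Write a construct as a GenBank flat file
#'
#' @param construct A `gpc_construct`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(construct, path) {
  seq <- tolower(construct$sequence)
  n <- nchar(seq)
  name <- gsub("[^A-Za-z0-9_.-]", "_",
               paste0(construct$design$name, "_stage",
                      if (construct$deleted) "DELETED" else construct$stage))
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN 01-JAN-2024",
            substr(name, 1, 16), n),
    sprintf("DEFINITION  %s stage %s.", construct$design$name,
            if (construct$deleted) "DELETED" else construct$stage),
    "COMMENT     Placeholder part sequences: synthetic, NON-PHYSIOLOGICAL.",
    "FEATURES             Location/Qualifiers")
  f <- construct$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
      sprintf("     misc_feature    %s", loc),
      sprintf("                     /label=\"%s\"", f$label[i]),
      sprintf("                     /note=\"type=%s;stage=%s;expressed=%s\"",
              f$type[i],
              if (is.na(f$stage[i])) "NA" else f$stage[i],
              if (f$expressed[i]) "yes" else "no"))
  }
  lines <- c(lines, "ORIGIN")
  for (off in seq(1, n, by = 60)) {
    chunk <- substr(seq, off, min(off + 59, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param path GenBank file path.
#' @return list with `name`, `sequence` (uppercase) and `features`
#'   (data.frame in 0-based half-open coordinates).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  name <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[grepl("^LOCUS", lines)][1])
  fi <- which(grepl("^FEATURES", lines))
  oi <- which(grepl("^ORIGIN", lines))
  feats <- list(); cur <- NULL
  if (length(fi) && length(oi)) {
    for (ln in lines[(fi + 1):(oi - 1)]) {
      if (grepl("^     \\S", ln)) {
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        loc <- trimws(sub("^\\s*\\S+\\s+", "", ln))
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"; loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        cur <- list(start = se[1] - 1L, end = se[2], strand = strand,
                    label = NA_character_, type = NA_character_,
                    role = NA_character_, stage = NA_integer_, expressed = FALSE)
      } else if (grepl("/label=", ln)) {
        cur$label <- sub('^.*?/label="(.*)"\\s*$', "\\1", ln)
      } else if (grepl("/note=", ln)) {
        note <- sub('^.*?/note="(.*)"\\s*$', "\\1", ln)
        kv <- strsplit(strsplit(note, ";")[[1]], "=")
        for (p in kv) {
          if (p[1] == "type") cur$type <- p[2]
          if (p[1] == "stage" && p[2] != "NA") cur$stage <- as.integer(p[2])
          if (p[1] == "expressed") cur$expressed <- identical(p[2], "yes")
        }
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }
  seq_lines <- lines[(oi + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  features <- if (length(feats)) {
    do.call(rbind, lapply(feats, function(x)
      data.frame(label = x$label, type = x$type, role = x$role, stage = x$stage,
                 start = x$start, end = x$end, strand = x$strand,
                 expressed = x$expressed, stringsAsFactors = FALSE)))
  } else data.frame()
  list(name = name, sequence = sequence, features = features)
}

#' Write per-stage GenBank + FASTA files and the stage table
#'
#' @param design A valid [circuit_design()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_stage_files <- function(design, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- enumerate_stages(design)
  files <- character()
  seqs <- Biostrings::DNAStringSet(vapply(stages, `[[`, "", "sequence"))
  names(seqs) <- paste0(design$name, "_", names(stages))
  for (nm in names(stages)) {
    gb <- file.path(out_dir, paste0(design$name, "_", nm, ".gb"))
    write_genbank(stages[[nm]], gb)
    files <- c(files, gb)
  }
  fa <- file.path(out_dir, paste0(design$name, "_stages.fasta"))
  Biostrings::writeXStringSet(seqs, fa, width = 70)
  tab <- file.path(out_dir, paste0(design$name, "_stage_table.csv"))
  utils::write.csv(stage_table(design), tab, row.names = FALSE)
  invisible(c(files, fa, tab))
}

# YAML design (de)serialization --------------------------------------------

design_to_list <- function(design) {
  list(
    name = design$name, version = design$version,
    promoter = list(name = design$promoter_name, sequence = design$promoter),
    leader = design$leader,
    gpcs = lapply(design$gpcs, function(u) list(
      index = u$index,
      recombinase = list(name = u$recombinase$name, ligand = u$recombinase$ligand,
                         nls = u$recombinase$nls,
                         split_halves = as.list(u$recombinase$split_halves),
                         sites = unclass(u$recombinase$sites)),
      payloads = lapply(u$payloads, function(p)
        list(name = p$name, kind = p$kind, sequence = p$sequence,
             tags = as.list(p$tags),
             locus = if (is.null(p$locus)) NULL else p$locus)),
      terminator = u$terminator)),
    terminal_payloads = lapply(design$terminal_payloads, function(p)
      list(name = p$name, kind = p$kind, sequence = p$sequence,
           tags = as.list(p$tags),
           locus = if (is.null(p$locus)) NULL else p$locus)),
    att_wrapper = if (is.null(design$att_wrapper)) NULL else unclass(design$att_wrapper),
    itr_flanks = design$itr_flanks, frame_pad = design$frame_pad)
}

list_to_design <- function(x) {
  payload_from <- function(p)
    payload_block(p$name, p$kind, p$sequence, unlist(p$tags), p$locus)
  gpcs <- lapply(x$gpcs, function(u) {
    s <- u$recombinase$sites
    gpc_unit(u$index,
             recombinase_module(u$recombinase$name, u$recombinase$ligand,
                                site_pair(s$name, s$left_site, s$right_site,
                                          s$scar_site, isTRUE(s$symmetric)),
                                unlist(u$recombinase$split_halves),
                                isTRUE(u$recombinase$nls)),
             lapply(u$payloads, payload_from), u$terminator)
  })
  wrap <- if (!is.null(x$att_wrapper))
    site_pair(x$att_wrapper$name, x$att_wrapper$left_site, x$att_wrapper$right_site,
              x$att_wrapper$scar_site, isTRUE(x$att_wrapper$symmetric)) else NULL
  circuit_design(version = x$version, gpcs = gpcs,
                 terminal_payloads = lapply(x$terminal_payloads, payload_from),
                 promoter = x$promoter$sequence, promoter_name = x$promoter$name,
                 leader = x$leader, att_wrapper = wrap,
                 itr_flanks = isTRUE(x$itr_flanks),
                 frame_pad = !isFALSE(x$frame_pad),
                 name = if (is.null(x$name)) "circuit" else x$name)
}

#' Write / read a circuit design as YAML
#'
#' @param design A [circuit_design()].
#' @param path YAML file path.
#' @return `write_design_yaml`: `path` invisibly; `read_design_yaml`: the design.
#' @export
write_design_yaml <- function(design, path) {
  yaml::write_yaml(design_to_list(design), path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) list_to_design(yaml::read_yaml(path))

#' Stable content hash of a design
#'
#' MD5 of the canonical YAML serialization; used to freeze presets and to
#' stamp run manifests.
#' @param design A [circuit_design()].
#' @return Character MD5 digest.
#' @export
design_hash <- function(design) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_design_yaml(design, tf)
  unname(tools::md5sum(tf))
}
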