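#' Read sequence records
#'
#' Reads FASTA (via Biostrings) or flat-file GenBank into a records tibble.
#' The format is inferred from the extension when `format = "auto"`
#' (`.gb`/`.gbk`/`.genbank` vs anything else). GenBank records keep their
#' LOCUS topology and their features; FASTA records get `topology = NA` and
#' no features. An empty file returns an empty tibble with a warning.
#'
#' @param path Input file.
#' @param format `"auto"`, `"fasta"` or `"genbank"`.
#' @return A tibble with columns `name`, `sequence`, `length`, `topology`
#'   and `features` (list column of tibbles or `NULL`).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "gibsim_error_io")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    warn(sprintf("Empty file: %s", path))
    return(tibble(name = character(0), sequence = character(0),
                  length = integer(0), topology = character(0),
                  features = list()))
  }
  if (format == "fasta") read_fasta_checked(path, lines)
  else read_genbank_lines(lines, path)
}

# Validate FASTA line-by-line (naming the offending line), then parse.
read_fasta_checked <- function(path, lines) {
  in_record <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) { in_record <- TRUE; next }
    if (!in_record) {
      abort(sprintf("Malformed FASTA: sequence before any header at line %d of %s.",
                    i, path), class = "gibsim_error_io")
    }
    if (grepl("[^ACGTNRYSWKMBDHVacgtnryswkmbdhv]", line)) {
      abort(sprintf("Illegal sequence character at line %d of %s.", i, path),
            class = "gibsim_error_io")
    }
  }
  set <- Biostrings::readDNAStringSet(path)
  tibble(name = sub("\\s.*$", "", names(set)),
         sequence = str_to_upper(as.character(set)),
         length = Biostrings::width(set),
         topology = NA_character_,
         features = rep(list(NULL), length(set)))
}

#' Write sequence records
#'
#' @param x A tibble with columns `name` and `sequence` (and optionally
#'   `topology`, `features` for GenBank).
#' @param path Output file.
#' @param format `"fasta"` or `"genbank"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x), all(c("name", "sequence") %in% names(x)))
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(x$sequence)
    names(set) <- x$name
    Biostrings::writeXStringSet(set, path, width = 70L)
  } else {
    txt <- unlist(lapply(seq_len(nrow(x)), function(i) {
      genbank_record_text(
        name = x$name[i], sequence = x$sequence[i],
        topology = if ("topology" %in% names(x))
          x$topology[i] %||% "linear" else "linear",
        features = if ("features" %in% names(x)) x$features[[i]] else NULL)
    }))
    writeLines(txt, path)
  }
  invisible(path)
}

# ---- GenBank flat file (minimal dialect) -----------------------------------
# Only the pieces the platform needs: LOCUS name/length/topology, FEATURES
# with simple span or complement(span) locations and /note + /label
# qualifiers, ORIGIN sequence, // terminator. misc_feature with note
# qualifiers is used for maximal portability.

genbank_record_text <- function(name, sequence, topology = "linear",
                                features = NULL) {
  sequence <- str_to_upper(sequence)
  n <- nchar(sequence)
  topology <- if (identical(topology, "circular")) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN",
                   substr(gsub("\\s", "_", name), 1, 17), n, topology),
           sprintf("DEFINITION  %s.", name),
           "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     source          1..%d", n))
  if (!is.null(features) && nrow(features) > 0L) {
    for (i in seq_len(nrow(features))) {
      loc <- sprintf("%d..%d", features$start[i], features$end[i])
      if (!is.null(features$strand) && identical(features$strand[i], "-")) {
        loc <- sprintf("complement(%s)", loc)
      }
      out <- c(out, sprintf("     %-15s %s",
                            features$type[i] %||% "misc_feature", loc))
      if (!is.null(features$label) && !is.na(features$label[i])) {
        out <- c(out, sprintf("                     /label=\"%s\"",
                              features$label[i]))
      }
      if (!is.null(features$note) && !is.na(features$note[i])) {
        out <- c(out, sprintf("                     /note=\"%s\"",
                              features$note[i]))
      }
    }
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(sequence, s, min(s + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
  }
  c(out, "//")
}

read_genbank_lines <- function(lines, path = "<genbank>") {
  records <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "LOCUS")) { i <- i + 1L; next }
    locus <- strsplit(trimws(sub("^LOCUS", "", lines[i])), "\\s+")[[1]]
    name <- locus[1]
    topology <- if (any(locus == "circular")) "circular" else "linear"
    feats <- list()
    seq_chars <- character(0)
    mode <- "header"
    current_feat <- NULL
    i <- i + 1L
    while (i <= length(lines) && !startsWith(lines[i], "//")) {
      line <- lines[i]
      if (startsWith(line, "FEATURES")) {
        mode <- "features"
      } else if (startsWith(line, "ORIGIN")) {
        if (!is.null(current_feat)) {
          feats[[length(feats) + 1L]] <- current_feat; current_feat <- NULL
        }
        mode <- "origin"
      } else if (mode == "features") {
        if (grepl("^\\s{5}\\S", line)) {
          if (!is.null(current_feat)) {
            feats[[length(feats) + 1L]] <- current_feat
          }
          parts <- strsplit(trimws(line), "\\s+")[[1]]
          loc <- parts[2]
          strand <- if (grepl("^complement", loc)) "-" else "+"
          nums <- as.integer(
            strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1]])
          current_feat <- list(type = parts[1], start = nums[1],
                               end = nums[length(nums)], strand = strand,
                               label = NA_character_, note = NA_character_)
        } else if (grepl("^\\s+/", line) && !is.null(current_feat)) {
          q <- trimws(line)
          if (startsWith(q, "/label=")) {
            current_feat$label <- gsub("^/label=\"?|\"$", "", q)
          } else if (startsWith(q, "/note=")) {
            current_feat$note <- gsub("^/note=\"?|\"$", "", q)
          }
        }
      } else if (mode == "origin") {
        chunk <- gsub("[0-9 /]", "", line)
        if (nzchar(chunk)) {
          if (grepl("[^ACGTNacgtn]", chunk)) {
            abort(sprintf("Illegal sequence character at line %d of %s.",
                          i, path), class = "gibsim_error_io")
          }
          seq_chars <- c(seq_chars, chunk)
        }
      }
      i <- i + 1L
    }
    if (i > length(lines)) {
      abort(sprintf("Malformed GenBank record '%s' in %s: missing // terminator (near line %d).",
                    name, path, min(i, length(lines))),
            class = "gibsim_error_io")
    }
    seq <- str_to_upper(paste(seq_chars, collapse = ""))
    ftbl <- if (length(feats)) {
      bind_rows(lapply(feats, as_tibble))
    } else NULL
    records[[length(records) + 1L]] <- tibble(
      name = name, sequence = seq, length = nchar(seq),
      topology = topology, features = list(ftbl))
    i <- i + 1L
  }
  if (length(records) == 0L) {
    abort(sprintf("No GenBank records found in %s.", path),
          class = "gibsim_error_io")
  }
  bind_rows(records)
}

#' Write an assembled product as GenBank
#'
#' One `misc_feature` per source fragment and one per junction (site id in
#' the note qualifier), plus the circular topology in the LOCUS line.
#'
#' @param product A `gibson_assembly`.
#' @param path Output file.
#' @param name Record name; defaults to the fragment chain.
#' @return `path`, invisibly.
#' @export
write_assembly_genbank <- function(product, path, name = NULL) {
  stopifnot(inherits(product, "gibson_assembly"))
  name <- name %||% paste(product$fragment_order$name, collapse = "_")
  n <- product$total_length
  fo <- product$fragment_order
  frag_feats <- tibble(
    type = "misc_feature",
    start = fo$start + 1L,
    end = pmin(fo$start + fo$length, n),
    strand = ifelse(fo$orientation == "reverse", "-", "+"),
    label = fo$name,
    note = sprintf("source fragment %d/%d%s", fo$position, nrow(fo),
                   ifelse(fo$start + fo$length > n, "; spans origin", "")))
  jx <- product$junctions
  jx_feats <- tibble(
    type = "misc_feature",
    start = jx$position + 1L,
    end = jx$position + jx$overlap_length,
    strand = "+",
    label = ifelse(is.na(jx$site_id), "junction",
                   sprintf("site_%d", jx$site_id)),
    note = ifelse(is.na(jx$site_id),
                  sprintf("assembly junction (%d bp overlap)",
                          jx$overlap_length),
                  sprintf("assembly junction; overlap site #%d",
                          jx$site_id)))
  recs <- tibble(name = name, sequence = product$sequence,
                 topology = "circular",
                 features = list(bind_rows(frag_feats, jx_feats)))
  write_sequences(recs, path, format = "genbank")
}

#' Persist a part registry
#'
#' The registry is stored as a FASTA of flanked part sequences plus a
#' tab-delimited index (name, role, slot, core length, warnings).
#'
#' @param parts A parts tibble.
#' @param fasta,index Output paths.
#' @return A list with the two paths, invisibly.
#' @export
write_registry <- function(parts, fasta, index) {
  write_sequences(parts, fasta, format = "fasta")
  idx <- tibble(name = parts$name, role = parts$role, slot = parts$slot,
                core_length = parts$core_length,
                warnings = map_chr(parts$warnings, paste, collapse = "; "))
  readr::write_tsv(idx, index)
  invisible(list(fasta = fasta, index = index))
}

#' Load a part registry
#'
#' Reads the FASTA + index pair written by [write_registry()], re-derives
#' each core from its slot's flanks and re-validates every part. GenBank
#' input is accepted in place of FASTA (the record sequence must be the
#' full flanked sequence).
#'
#' @param fasta,index Input paths.
#' @return A parts tibble.
#' @export
read_registry <- function(fasta, index) {
  recs <- read_sequences(fasta)
  idx <- readr::read_tsv(index, show_col_types = FALSE, progress = FALSE)
  parts <- lapply(seq_len(nrow(recs)), function(i) {
    slot <- idx$slot[match(recs$name[i], idx$name)]
    if (is.na(slot)) {
      abort(sprintf("Registry index has no entry for record '%s'.",
                    recs$name[i]), class = "gibsim_error_io")
    }
    observed <- classify_fragment(recs$sequence[i])
    if (!identical(observed, slot)) {
      abort(sprintf(
        "Registry record '%s' is indexed as slot %s but its flanks classify as %s.",
        recs$name[i], slot, observed %||% "none"),
        class = "gibsim_error_io")
    }
    core <- str_sub(recs$sequence[i], SITE_LEN + 1L, -(SITE_LEN + 1L))
    make_flanked_part(core, slot, name = recs$name[i])
  })
  bind_rows(parts)
}
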