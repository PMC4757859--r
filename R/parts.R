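#' Build a flanked part for a slot
#'
#' Appends the slot's left and right 30 bp overlap sites to a core sequence,
#' producing the full amplicon that the platform's overhang PCR would
#' generate. Internal occurrences of any canonical overlap site or of a
#' screening-panel recognition sequence inside the core are recorded as
#' warnings, not errors: real inserts may legitimately contain them, but
#' they can confound assembly (stray homology) or diagnostic digests.
#'
#' @param core Core sequence (promoter or gene body), `{A,C,G,T}` only,
#'   case-insensitive, non-empty.
#' @param slot Slot label (see [slot_grammar()]).
#' @param name Part name; defaults to the slot label.
#' @return A one-row tibble with columns `name`, `role`, `slot`,
#'   `core_sequence`, `sequence` (the flanked part, left site + core + right
#'   site), `core_length`, `length` and `warnings` (list column of character
#'   vectors).
#' @examples
#' part <- make_flanked_part(strrep("ACGT", 10), "gB")
#' nchar(part$sequence)  # 30 + 40 + 30
#' @export
make_flanked_part <- function(core, slot, name = slot) {
  core <- dna_clean(core, arg = "core")
  flanks <- flanks_for_slot(slot)
  seq <- paste0(flanks$sequence[1], core, flanks$sequence[2])
  tibble(
    name = as.character(name),
    role = slot_grammar()$role[slot_grammar()$slot == slot],
    slot = slot,
    core_sequence = core,
    sequence = seq,
    core_length = nchar(core),
    length = nchar(seq),
    warnings = list(core_warnings(core))
  )
}

# Warnings for internal overlap sites / screening recognitions in a core.
core_warnings <- function(core) {
  w <- character(0)
  sites <- overlap_sites()
  for (i in seq_len(nrow(sites))) {
    if (str_detect(core, fixed(sites$sequence[i]))) {
      w <- c(w, sprintf("core contains overlap site #%d internally",
                        sites$site_id[i]))
    }
  }
  panel <- screening_panel()
  for (i in seq_len(nrow(panel))) {
    if (str_detect(core, fixed(panel$recognition[i]))) {
      w <- c(w, sprintf("core contains %s recognition site (%s)",
                        panel$enzyme[i], panel$recognition[i]))
    }
  }
  w
}

#' Classify a fragment by its terminal overlap sites
#'
#' Reads the first and last 30 bases of a sequence and returns the unique
#' slot whose (left, right) overlap sites they match, or `NA` when no slot
#' matches.
#'
#' @param seq A DNA string of length >= 60.
#' @return A slot label, or `NA_character_`.
#' @examples
#' part <- make_flanked_part(strrep("ACGT", 10), "gC")
#' classify_fragment(part$sequence)
#' @export
classify_fragment <- function(seq) {
  seq <- dna_clean(seq)
  if (nchar(seq) < 2L * SITE_LEN) {
    abort(sprintf(
      "Sequence of length %d is too short to carry two 30 bp terminal sites (need >= 60).",
      nchar(seq)), class = "gibsim_error_input")
  }
  first <- str_sub(seq, 1L, SITE_LEN)
  last <- str_sub(seq, -SITE_LEN, -1L)
  sites <- overlap_sites()
  left <- sites$site_id[match(first, sites$sequence)]
  right <- sites$site_id[match(last, sites$sequence)]
  if (is.na(left) || is.na(right)) return(NA_character_)
  grammar <- slot_grammar()
  hit <- grammar$slot[grammar$left_site == left & grammar$right_site == right]
  if (length(hit) == 1L) hit else NA_character_
}

#' Enumerate designs that fill a backbone
#'
#' Lists every chain of slots whose flanking sites tile consecutively from a
#' backbone's chain start site to its chain end site (path enumeration over
#' the six grammar edges). A (1,5) backbone admits exactly three designs:
#' the two-fragment pA:gC and pC:gB and the four-fragment pA:gA-pB:gB.
#'
#' @param backbone A backbone row (from [new_backbone()] or
#'   [generate_fixture_backbone()]), or `NULL` when `chain_start` /
#'   `chain_end` are given directly.
#' @param chain_start,chain_end Terminal site ids (integers in 1..5,
#'   start < end); ignored when `backbone` is supplied.
#' @return A tibble ordered by fewest fragments first, then lexicographically
#'   by the slot sequence, with columns `design` (e.g. `"pA:gC"`),
#'   `n_fragments` and `slots` (list column of slot labels). Zero rows when
#'   no design tiles the interval.
#' @examples
#' enumerate_fills(chain_start = 1, chain_end = 5)
#' @export
enumerate_fills <- function(backbone = NULL, chain_start = NULL,
                            chain_end = NULL) {
  if (!is.null(backbone)) {
    chain_start <- backbone$chain_start_site[1]
    chain_end <- backbone$chain_end_site[1]
  }
  chain_start <- as.integer(chain_start)
  chain_end <- as.integer(chain_end)
  if (is.na(chain_start) || is.na(chain_end) ||
      !chain_start %in% 1:5 || !chain_end %in% 1:5 ||
      chain_start >= chain_end) {
    abort("Chain sites must be integers in 1..5 with start < end.",
          class = "gibsim_error_input")
  }
  grammar <- slot_grammar()
  paths <- list()
  walk <- function(at, used, trail) {
    if (at == chain_end) {
      paths[[length(paths) + 1L]] <<- trail
      return(invisible())
    }
    nxt <- which(grammar$left_site == at & !(grammar$slot %in% used))
    for (i in nxt) {
      if (grammar$right_site[i] <= chain_end) {
        walk(grammar$right_site[i], c(used, grammar$slot[i]),
             c(trail, grammar$slot[i]))
      }
    }
  }
  walk(chain_start, character(0), character(0))
  if (length(paths) == 0L) {
    return(tibble(design = character(0), n_fragments = integer(0),
                  slots = list()))
  }
  out <- tibble(
    design = map_chr(paths, paste, collapse = ":"),
    n_fragments = map_int(paths, length),
    slots = paths
  )
  arrange(out, .data$n_fragments, .data$design)
}

#' Validate a part against the slot grammar
#'
#' Checks that a part's sequence begins and ends with the overlap sites its
#' slot prescribes, that those flanks are intact 30-mers, that the core is
#' non-empty ACGT, and reports (as warning-severity rows, which do not fail
#' validation) any internal overlap sites or screening-panel recognitions in
#' the core. A part built by [make_flanked_part()] always passes.
#'
#' @param part A one-row part tibble (as produced by [make_flanked_part()]).
#' @return A tibble with columns `check`, `severity` (`"error"` or
#'   `"warning"`), `pass` and `detail`. The part is valid when every
#'   error-severity row passes.
#' @examples
#' validate_part(make_flanked_part("ACGTACGT", "pA"))
#' @export
validate_part <- function(part) {
  stopifnot(is.data.frame(part), nrow(part) == 1L)
  checks <- list()
  add <- function(check, severity, pass, detail = "") {
    checks[[length(checks) + 1L]] <<-
      tibble(check = check, severity = severity, pass = pass, detail = detail)
  }
  slot_ok <- part$slot %in% slot_grammar()$slot
  add("slot_label", "error", slot_ok,
      if (slot_ok) "" else sprintf("unknown slot '%s'", part$slot))
  seq_ok <- !is.na(part$sequence) && grepl("^[ACGT]+$", part$sequence)
  add("alphabet", "error", seq_ok,
      if (seq_ok) "" else "sequence contains non-ACGT characters")
  core_ok <- !is.na(part$core_sequence) && nchar(part$core_sequence) >= 1L
  add("core_nonempty", "error", core_ok,
      if (core_ok) "" else "core sequence is empty")
  if (slot_ok && seq_ok) {
    flanks <- flanks_for_slot(part$slot)
    ok_len <- all(nchar(flanks$sequence) == SITE_LEN)
    add("site_length_30", "error", ok_len, "")
    left_ok <- str_sub(part$sequence, 1L, SITE_LEN) == flanks$sequence[1]
    add("left_flank", "error", left_ok,
        if (left_ok) "" else sprintf(
          "sequence does not begin with site #%d", flanks$site_id[1]))
    right_ok <- str_sub(part$sequence, -SITE_LEN, -1L) == flanks$sequence[2]
    add("right_flank", "error", right_ok,
        if (right_ok) "" else sprintf(
          "sequence does not end with site #%d", flanks$site_id[2]))
    recon <- paste0(flanks$sequence[1], part$core_sequence,
                    flanks$sequence[2])
    add("flank_identity", "error", identical(recon, part$sequence),
        if (identical(recon, part$sequence)) "" else
          "sequence != left site + core + right site")
  }
  if (core_ok && seq_ok) {
    w <- core_warnings(part$core_sequence)
    add("no_internal_sites", "warning", length(w) == 0L,
        paste(w, collapse = "; "))
  }
  bind_rows(checks)
}

#' Construct a backbone record
#'
#' A backbone is a linearized destination vector whose termini carry overlap
#' sites: reading 5'->3' it begins with the chain end site and ends with the
#' chain start site, so that inserts tiling start -> end close the circle.
#'
#' @param sequence Linearized backbone sequence.
#' @param chain_start,chain_end Terminal site ids (start < end).
#' @param name Backbone name.
#' @param source_note Free-text provenance note.
#' @return A one-row tibble with columns `name`, `role` (`"backbone"`),
#'   `sequence`, `length`, `chain_start_site`, `chain_end_site`,
#'   `source_note`.
#' @export
new_backbone <- function(sequence, chain_start, chain_end, name = "backbone",
                         source_note = "") {
  sequence <- dna_clean(sequence, arg = "sequence")
  chain_start <- as.integer(chain_start)
  chain_end <- as.integer(chain_end)
  if (!chain_start %in% 1:5 || !chain_end %in% 1:5 ||
      chain_start >= chain_end) {
    abort("Chain sites must be integers in 1..5 with start < end.",
          class = "gibsim_error_input")
  }
  starts_with_end <- str_sub(sequence, 1L, SITE_LEN) ==
    site_sequence(chain_end)
  ends_with_start <- str_sub(sequence, -SITE_LEN, -1L) ==
    site_sequence(chain_start)
  if (!starts_with_end || !ends_with_start) {
    abort(sprintf(
      "Backbone termini must carry the chain sites: expected to begin with site #%d and end with site #%d.",
      chain_end, chain_start), class = "gibsim_error_input")
  }
  tibble(name = name, role = "backbone", sequence = sequence,
         length = nchar(sequence), chain_start_site = chain_start,
         chain_end_site = chain_end, source_note = source_note)
}

#' Classify a linear sequence as a backbone
#'
#' Inspects the terminal 30-mers of a linear sequence and, when one terminus
#' is a canonical site and the other a lower-numbered canonical site,
#' returns the corresponding backbone record.
#'
#' @param seq Linear DNA sequence (length >= 60).
#' @param name Name for the resulting backbone record.
#' @return A backbone tibble row, or `NULL` when the termini are not a valid
#'   site pair.
#' @export
classify_backbone <- function(seq, name = "backbone") {
  seq <- dna_clean(seq)
  if (nchar(seq) < 2L * SITE_LEN) return(NULL)
  sites <- overlap_sites()
  first <- sites$site_id[match(str_sub(seq, 1L, SITE_LEN), sites$sequence)]
  last <- sites$site_id[match(str_sub(seq, -SITE_LEN, -1L), sites$sequence)]
  if (is.na(first) || is.na(last) || last >= first) return(NULL)
  new_backbone(seq, chain_start = last, chain_end = first, name = name)
}
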