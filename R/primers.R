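#' Primer design parameters
#'
#' Defaults mirror the platform's PCR regime: a 62 degC annealing
#' temperature (homology portions are grown until their melting temperature
#' reaches this target), 18-35 nt homology, and a 1 min/kb extension rate.
#' Melting temperatures use unified nearest-neighbor thermodynamics at
#' 50 mM monovalent salt and 500 nM primer by default; the Wallace rule is
#' available as an explicit fallback for short oligos.
#'
#' @param tm_target Target homology melting temperature, degC.
#' @param homology_min,homology_max Bounds on the homology length, nt.
#' @param tm_method `"nearest_neighbor"` or `"wallace"`.
#' @param extension_rate Extension time per kb of amplicon, minutes.
#' @param annealing_temp PCR annealing temperature, degC (recorded for the
#'   ordering sheet; not used in simulation).
#' @param monovalent_mM Monovalent cation concentration for the
#'   nearest-neighbor model, mM.
#' @param primer_nM Total primer concentration, nM.
#' @return A `primer_params` list.
#' @export
primer_params <- function(tm_target = 62, homology_min = 18,
                          homology_max = 35,
                          tm_method = c("nearest_neighbor", "wallace"),
                          extension_rate = 1, annealing_temp = 62,
                          monovalent_mM = 50, primer_nM = 500) {
  tm_method <- match.arg(tm_method)
  if (homology_min > homology_max) {
    abort("`homology_min` must be <= `homology_max`.",
          class = "gibsim_error_input")
  }
  if (extension_rate <= 0) {
    abort("`extension_rate` must be > 0.", class = "gibsim_error_input")
  }
  structure(list(tm_target = tm_target, homology_min = as.integer(homology_min),
                 homology_max = as.integer(homology_max),
                 tm_method = tm_method, extension_rate = extension_rate,
                 annealing_temp = annealing_temp,
                 monovalent_mM = monovalent_mM, primer_nM = primer_nM),
            class = "gibsim_primer_params")
}

# Unified nearest-neighbor parameters (kcal/mol, cal/(K mol)) for the ten
# distinct DNA dimer duplexes, plus terminal initiation terms.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT <- list(AT = c(dh = 2.3, ds = 4.1), GC = c(dh = 0.1, ds = -2.8))

#' Melting temperature of an oligonucleotide
#'
#' Two models are provided. `"wallace"` is the rule-of-thumb
#' `2(A+T) + 4(G+C)` degC. `"nearest_neighbor"` evaluates unified
#' nearest-neighbor thermodynamics: dimer enthalpies/entropies are summed
#' with terminal initiation terms, the entropy is salt-corrected by
#' `0.368 (N-1) ln[Mon+]`, and
#' `Tm = 1000 dH / (dS + R ln(C_T/4)) - 273.15` with the primer in excess
#' over template.
#'
#' @param seq Oligo sequence(s), 5'->3' (vectorized).
#' @param method `"nearest_neighbor"` (needs length >= 8) or `"wallace"`
#'   (needs length >= 2).
#' @param monovalent_mM Monovalent cation concentration, mM.
#' @param primer_nM Total primer concentration, nM.
#' @return Melting temperature(s) in degC.
#' @examples
#' melting_temperature("AAAAATTTTTAAAAATTTTT", method = "wallace")  # 40
#' melting_temperature("AGCTTGCATGCCTGCAGGTC")
#' @export
melting_temperature <- function(seq,
                                method = c("nearest_neighbor", "wallace"),
                                monovalent_mM = 50, primer_nM = 500) {
  method <- match.arg(method)
  vapply(seq, function(s) {
    s <- dna_clean(s)
    n <- nchar(s)
    if (method == "wallace") {
      if (n < 2L) {
        abort("Wallace rule needs a sequence of length >= 2.",
              class = "gibsim_error_input")
      }
      counts <- table(factor(strsplit(s, "")[[1]],
                             levels = c("A", "C", "G", "T")))
      return(2 * (counts[["A"]] + counts[["T"]]) +
               4 * (counts[["G"]] + counts[["C"]]))
    }
    if (n < 8L) {
      abort("Nearest-neighbor model needs a sequence of length >= 8.",
            class = "gibsim_error_input")
    }
    chars <- strsplit(s, "")[[1]]
    dimers <- paste0(chars[-n], chars[-1])
    dh <- sum(NN_DH[dimers])
    ds <- sum(NN_DS[dimers])
    for (end in chars[c(1L, n)]) {
      init <- if (end %in% c("A", "T")) NN_INIT$AT else NN_INIT$GC
      dh <- dh + init[["dh"]]
      ds <- ds + init[["ds"]]
    }
    ds <- ds + 0.368 * (n - 1) * log(monovalent_mM * 1e-3)
    ct <- primer_nM * 1e-9
    1000 * dh / (ds + 1.987 * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Design the overhang primer pair for a slot
#'
#' Implements the platform's F/R scheme: the forward primer is the slot's
#' left overlap site followed by the shortest template prefix whose melting
#' temperature reaches the target; the reverse primer is the reverse
#' complement of the right site followed by the reverse complement of the
#' shortest template suffix reaching the target. Homology lengths are
#' clamped to `[homology_min, homology_max]`; if the target is unreachable
#' within `homology_max` the pair is returned with a below-target warning.
#'
#' Primer names follow the F/R site convention (e.g. gB, flanked by sites 4
#' and 5, is amplified with F4/R5).
#'
#' @param template Template (core) sequence to amplify.
#' @param slot Slot label.
#' @param params A [primer_params()] object.
#' @return A one-row tibble with columns `slot`, `forward_name`,
#'   `reverse_name`, `forward`, `reverse`, `overhang_len_fwd`,
#'   `overhang_len_rev`, `homology_len_fwd`, `homology_len_rev`,
#'   `homology_tm_fwd`, `homology_tm_rev`, `warnings` (list column).
#' @examples
#' tpl <- make_flanked_part(strrep("GATC", 50), "gB")$core_sequence
#' design_part_primers(tpl, "gB")
#' @export
design_part_primers <- function(template, slot, params = primer_params()) {
  template <- dna_clean(template, arg = "template")
  stopifnot(inherits(params, "gibsim_primer_params"))
  if (nchar(template) < 2L * params$homology_min) {
    abort(sprintf(
      "Template of %d nt cannot host two homology regions of >= %d nt.",
      nchar(template), params$homology_min), class = "gibsim_error_input")
  }
  flanks <- flanks_for_slot(slot)
  fwd <- grow_homology(template, params, from_start = TRUE)
  rev <- grow_homology(template, params, from_start = FALSE)
  warnings <- character(0)
  if (fwd$tm < params$tm_target) {
    warnings <- c(warnings, sprintf(
      "forward homology Tm %.1f degC below target %.1f at homology_max",
      fwd$tm, params$tm_target))
  }
  if (rev$tm < params$tm_target) {
    warnings <- c(warnings, sprintf(
      "reverse homology Tm %.1f degC below target %.1f at homology_max",
      rev$tm, params$tm_target))
  }
  tibble(
    slot = slot,
    forward_name = paste0("F", flanks$site_id[1]),
    reverse_name = paste0("R", flanks$site_id[2]),
    forward = paste0(flanks$sequence[1], fwd$homology),
    reverse = paste0(revcomp(flanks$sequence[2]), revcomp(rev$homology)),
    overhang_len_fwd = SITE_LEN,
    overhang_len_rev = SITE_LEN,
    homology_len_fwd = nchar(fwd$homology),
    homology_len_rev = nchar(rev$homology),
    homology_tm_fwd = fwd$tm,
    homology_tm_rev = rev$tm,
    warnings = list(warnings)
  )
}

# Grow a homology region 3'-ward one base at a time until Tm >= target,
# clamped to [homology_min, homology_max]. from_start = TRUE grows a
# template prefix (forward primer); FALSE grows a suffix (reverse primer,
# whose own 3' growth walks leftward along the template top strand).
grow_homology <- function(template, params, from_start = TRUE) {
  n <- nchar(template)
  max_len <- min(params$homology_max, n)
  len <- min(params$homology_min, max_len)
  repeat {
    hom <- if (from_start) str_sub(template, 1L, len) else
      str_sub(template, n - len + 1L, n)
    tm <- melting_temperature(hom, method = params$tm_method,
                              monovalent_mM = params$monovalent_mM,
                              primer_nM = params$primer_nM)
    if (tm >= params$tm_target || len >= max_len) {
      return(list(homology = hom, tm = tm, length = len))
    }
    len <- len + 1L
  }
}

#' Simulate PCR with an overhang primer pair
#'
#' Amplifies the template segment delimited by the two primer homologies and
#' appends the primer overhangs, reproducing what the designed PCR would
#' yield. Homology matching is exact (no mismatch tolerance): the forward
#' homology must occur on the top strand and the reverse homology's reverse
#' complement on the top strand, exactly once each and in amplifiable
#' orientation.
#'
#' @param template Template sequence.
#' @param pair A primer pair row from [design_part_primers()].
#' @param template_name Optional template identifier.
#' @return A one-row tibble with columns `template_name`, `slot`, `sequence`
#'   and `length`. When the primers came from [design_part_primers()] on the
#'   full template, the amplicon equals the corresponding
#'   [make_flanked_part()] sequence.
#' @export
simulate_pcr <- function(template, pair, template_name = "template") {
  template <- dna_clean(template, arg = "template")
  stopifnot(is.data.frame(pair), nrow(pair) == 1L)
  fwd_overhang <- str_sub(pair$forward, 1L, pair$overhang_len_fwd)
  fwd_hom <- str_sub(pair$forward, pair$overhang_len_fwd + 1L, -1L)
  rev_overhang <- str_sub(pair$reverse, 1L, pair$overhang_len_rev)
  rev_hom <- str_sub(pair$reverse, pair$overhang_len_rev + 1L, -1L)
  rev_hom_top <- revcomp(rev_hom)
  fwd_hits <- iupac_match_starts(fwd_hom, template)
  rev_hits <- iupac_match_starts(rev_hom_top, template)
  if (length(fwd_hits) > 1L || length(rev_hits) > 1L) {
    abort(sprintf(
      "Ambiguous priming: forward homology at 0-based position(s) %s; reverse homology at %s.",
      paste(fwd_hits - 1L, collapse = ", "),
      paste(rev_hits - 1L, collapse = ", ")),
      class = "gibsim_error_ambiguous_priming")
  }
  if (length(fwd_hits) == 0L || length(rev_hits) == 0L) {
    abort("No amplification: a primer homology is absent from the template.",
          class = "gibsim_error_no_amplification")
  }
  seg_start <- fwd_hits[1]
  seg_end <- rev_hits[1] + nchar(rev_hom_top) - 1L
  if (seg_end < seg_start + nchar(fwd_hom) - 1L) {
    abort("No amplification: primer homologies are not in amplifiable orientation.",
          class = "gibsim_error_no_amplification")
  }
  seq <- paste0(fwd_overhang, str_sub(template, seg_start, seg_end),
                revcomp(rev_overhang))
  tibble(template_name = template_name, slot = pair$slot, sequence = seq,
         length = nchar(seq))
}

#' Extension time for an amplicon
#'
#' @param amplicon_length Amplicon length(s), bp (>= 1).
#' @param params A [primer_params()] object (uses `extension_rate`, default
#'   1 min/kb).
#' @return Extension time(s) in minutes.
#' @examples
#' extension_time(1000)  # 1 min
#' extension_time(2500)  # 2.5 min
#' @export
extension_time <- function(amplicon_length, params = primer_params()) {
  if (any(amplicon_length < 1)) {
    abort("`amplicon_length` must be >= 1 bp.", class = "gibsim_error_input")
  }
  amplicon_length / 1000 * params$extension_rate
}

#' Export primer pairs as an ordering sheet
#'
#' @param pairs A tibble of primer pair rows ([design_part_primers()]).
#' @param path Output path.
#' @param format `"tsv"` (name, sequence, overhang length, homology Tm) or
#'   `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_primer_sheet <- function(pairs, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  long <- bind_rows(
    tibble(name = paste0(pairs$slot, "_", pairs$forward_name),
           sequence = pairs$forward, overhang_len = pairs$overhang_len_fwd,
           homology_tm = pairs$homology_tm_fwd),
    tibble(name = paste0(pairs$slot, "_", pairs$reverse_name),
           sequence = pairs$reverse, overhang_len = pairs$overhang_len_rev,
           homology_tm = pairs$homology_tm_rev)
  )
  if (format == "tsv") {
    readr::write_tsv(long, path)
  } else {
    writeLines(paste0(">", long$name, "\n", long$sequence), path)
  }
  invisible(path)
}
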