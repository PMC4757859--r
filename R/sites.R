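#' The five canonical overlap sites
#'
#' The platform positions every promoter and gene in a construct using five
#' fixed 30-nucleotide "overlap sites" (#1-#5). Each part is amplified with
#' these sites appended as primer overhangs, so that in a one-pot isothermal
#' (Gibson) reaction consecutive fragments share a 30 bp terminal homology
#' and fuse seamlessly in a defined order. Sites #2, #3 and #4 each carry a
#' restriction recognition sequence (NheI, AvrII, AfeI) used for diagnostic
#' digestion of assembled clones; no screening-panel recognition lies inside
#' the printed #1 and #5 sequences, so their `encoded_enzyme` is `NA`.
#'
#' @return A tibble with columns `site_id` (integer 1..5), `sequence`
#'   (30-mer) and `encoded_enzyme` (character, `NA` when none of the shipped
#'   screening panel cuts within the site).
#' @examples
#' overlap_sites()
#' @seealso [slot_grammar()], [flanks_for_slot()]
#' @export
overlap_sites <- function() {
  tibble(
    site_id = 1:5,
    sequence = c(
      "GATCAGTGTGAGGGAGTGTAAAGCTGGTTT",
      "CTAACTCGAACGCTAGCTGTGCGATCGTTT",
      "AAACCGCTGTTCCTAGGAATCCCGAGGCCT",
      "GACCCGACATTAGCGCTACAGCTTAAGCGG",
      "AAACGTTGTTGTTTGGGGTTGAATTACTCT"
    ),
    encoded_enzyme = c(NA, "NheI", "AvrII", "AfeI", NA)
  )
}

# Fast lookup: site sequence by id (integer vector in 1..5).
site_sequence <- function(id) {
  sites <- overlap_sites()
  if (!all(id %in% sites$site_id)) {
    abort(sprintf("Unknown overlap site id: %s (must be 1..5).",
                  paste(setdiff(id, sites$site_id), collapse = ", ")),
          class = "gibsim_error_input")
  }
  sites$sequence[match(id, sites$site_id)]
}

SITE_LEN <- 30L

#' The slot grammar
#'
#' Six slots position parts between pairs of overlap sites: promoters occupy
#' pA (sites 1-2), pB (3-4) and pC (1-4); genes occupy gA (2-3), gB (4-5)
#' and gC (2-5). A construct design is any chain of slots whose site pairs
#' tile consecutively from a backbone's start site to its end site, e.g. the
#' four-fragment design pA:gA-pB:gB or the two-fragment designs pC:gB and
#' pA:gC on a (1,5) backbone.
#'
#' The pC slot spans sites 1 and 4: it is produced with the F1/R4 primer
#' pair, and only the (1,4) pairing tiles against gB (4,5) to complete the
#' two-fragment pC:gB design.
#'
#' @return A tibble with columns `slot`, `role` (`"promoter"` or `"gene"`),
#'   `left_site` and `right_site` (integer site ids, left < right).
#' @examples
#' slot_grammar()
#' @export
slot_grammar <- function() {
  tibble(
    slot = c("pA", "gA", "pB", "gB", "pC", "gC"),
    role = c("promoter", "gene", "promoter", "gene", "promoter", "gene"),
    left_site = c(1L, 2L, 3L, 4L, 1L, 2L),
    right_site = c(2L, 3L, 4L, 5L, 4L, 5L)
  )
}

#' Flanking overlap sites for a slot
#'
#' @param slot One of the six canonical slot labels (`"pA"`, `"gA"`, `"pB"`,
#'   `"gB"`, `"pC"`, `"gC"`; case-sensitive).
#' @return A two-row tibble (the left then the right flank) with columns
#'   `side`, `site_id`, `sequence` and `encoded_enzyme`.
#' @examples
#' flanks_for_slot("gB")
#' @export
flanks_for_slot <- function(slot) {
  grammar <- slot_grammar()
  if (length(slot) != 1L || !slot %in% grammar$slot) {
    abort(sprintf(
      "Unknown slot label '%s'. Valid slots: %s.",
      as.character(slot)[1], paste(grammar$slot, collapse = ", ")),
      class = "gibsim_error_slot")
  }
  edge <- grammar[grammar$slot == slot, ]
  sites <- overlap_sites()
  out <- sites[match(c(edge$left_site, edge$right_site), sites$site_id), ]
  out$side <- c("left", "right")
  out[, c("side", "site_id", "sequence", "encoded_enzyme")]
}
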