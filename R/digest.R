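#' Restriction enzyme definitions
#'
#' Loads the packaged enzyme table (or a user-supplied one in the same
#' tab-delimited layout). `cut_top` and `cut_bottom` are offsets, in
#' top-strand coordinates, from the recognition start to the cut on the top
#' and bottom strand respectively; blunt cutters have `cut_top == cut_bottom`
#' (e.g. PmeI `GTTT^AAAC`), 5' overhang cutters have `cut_top < cut_bottom`
#' (e.g. NheI `G^CTAGC`).
#'
#' @param path Optional path to a tab-delimited file with columns `enzyme`,
#'   `recognition`, `cut_top`, `cut_bottom`; defaults to the packaged panel.
#' @return A tibble of enzyme definitions.
#' @examples
#' restriction_enzymes()
#' @export
restriction_enzymes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "enzymes.tsv", package = "gibsim",
                                mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    enzyme = readr::col_character(), recognition = readr::col_character(),
    cut_top = readr::col_integer(), cut_bottom = readr::col_integer()),
    progress = FALSE, show_col_types = FALSE)
  for (i in seq_len(nrow(tab))) {
    check_iupac(tab$recognition[i], tab$enzyme[i])
  }
  tab
}

# The five enzymes used for diagnostic screening of assembled clones.
screening_panel <- function() {
  panel <- c("XmaI", "NheI", "AvrII", "AfeI", "AscI")
  enz <- restriction_enzymes()
  enz[match(panel, enz$enzyme), ]
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (IUPAC codes allowed).
#' @param cut_top,cut_bottom Cut offsets from the recognition start, in
#'   top-strand coordinates.
#' @return A one-row enzyme tibble.
#' @export
enzyme_spec <- function(name, recognition, cut_top, cut_bottom) {
  recognition <- str_to_upper(recognition)
  check_iupac(recognition, name)
  tibble(enzyme = name, recognition = recognition,
         cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom))
}

check_iupac <- function(recognition, name) {
  if (is.na(recognition) || nchar(recognition) == 0L ||
      grepl("[^ACGTRYSWKMBDHVN]", recognition)) {
    abort(sprintf("Enzyme %s has an invalid IUPAC recognition sequence '%s'.",
                  name, recognition), class = "gibsim_error_enzyme")
  }
  invisible(recognition)
}

# Resolve enzymes given as names (looked up in the packaged panel) or as
# enzyme tibbles into a single tibble.
resolve_enzymes <- function(enzymes) {
  if (is.character(enzymes)) {
    panel <- restriction_enzymes()
    missing <- setdiff(enzymes, panel$enzyme)
    if (length(missing) > 0L) {
      abort(sprintf("Unknown enzyme(s): %s. Supply an enzyme_spec() or a custom table.",
                    paste(missing, collapse = ", ")),
            class = "gibsim_error_enzyme")
    }
    panel[match(enzymes, panel$enzyme), ]
  } else if (is.data.frame(enzymes)) {
    for (i in seq_len(nrow(enzymes))) {
      check_iupac(enzymes$recognition[i], enzymes$enzyme[i])
    }
    as_tibble(enzymes)
  } else {
    abort("`enzymes` must be a character vector of names or an enzyme tibble.",
          class = "gibsim_error_input")
  }
}

#' Find restriction recognition sites
#'
#' Locates all matches of an enzyme's (possibly IUPAC-degenerate)
#' recognition sequence in a substrate, on both strands. Palindromic
#' recognitions are reported once per duplex site. On circular substrates,
#' matches spanning the origin are included.
#'
#' @param seq Substrate sequence.
#' @param enzyme An enzyme name (looked up in the packaged panel) or a
#'   one-row enzyme tibble.
#' @param circular Is the substrate circular?
#' @return A tibble with 0-based `position` (top-strand start of the
#'   recognition) and `strand` (`"+"`/`"-"`).
#' @examples
#' find_recognition_sites(overlap_sites()$sequence[2], "NheI")
#' @export
find_recognition_sites <- function(seq, enzyme, circular = FALSE) {
  seq <- dna_clean(seq)
  enzyme <- resolve_enzymes(enzyme)
  stopifnot(nrow(enzyme) == 1L)
  pat <- enzyme$recognition
  n <- nchar(seq)
  m <- nchar(pat)
  subject <- if (circular && n > 1L) {
    paste0(seq, str_sub(seq, 1L, min(m - 1L, n)))
  } else {
    seq
  }
  hits_plus <- iupac_match_starts(pat, subject)
  pat_rc <- revcomp(pat)
  palindromic <- identical(pat, pat_rc)
  hits_minus <- if (palindromic) integer(0) else
    iupac_match_starts(pat_rc, subject)
  out <- tibble(
    position = c(hits_plus, hits_minus) - 1L,
    strand = rep(c("+", "-"), c(length(hits_plus), length(hits_minus)))
  )
  if (circular) {
    out$position <- out$position %% n
    out <- distinct(out)
  }
  arrange(out, .data$position, .data$strand)
}

# 1-based start positions of IUPAC-pattern matches in an ACGT subject.
iupac_match_starts <- function(pattern, subject) {
  if (nchar(pattern) > nchar(subject)) return(integer(0))
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                   fixed = FALSE)
  as.integer(Biostrings::start(hits))
}

#' Simulate a restriction digest
#'
#' Computes cut positions and fragment lengths for a (co-)digestion of a
#' linear or circular substrate. Cut bookkeeping uses the top-strand cut
#' coordinate; fragment lengths are duplex lengths between successive top
#' cuts (sticky-end identity is not tracked -- screening needs sizes, not
#' ends). Fragment lengths always sum to the substrate length.
#'
#' @param seq Substrate sequence.
#' @param enzymes Enzyme names and/or an enzyme tibble; co-digestion pools
#'   all cuts.
#' @param circular Is the substrate circular?
#' @return A `gibsim_digest` object; `tidy()` gives the fragment table,
#'   `glance()` a one-row summary.
#' @examples
#' d <- digest(paste0(strrep("A", 50), "GTTTAAAC", strrep("C", 42)),
#'             "PmeI", circular = TRUE)
#' d$fragment_lengths
#' @export
digest <- function(seq, enzymes, circular = FALSE) {
  seq <- dna_clean(seq)
  enzymes <- resolve_enzymes(enzymes)
  n <- nchar(seq)
  cut_rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    e <- enzymes[i, ]
    sites <- find_recognition_sites(seq, e, circular = circular)
    if (nrow(sites) == 0L) next
    m <- nchar(e$recognition)
    cut <- ifelse(sites$strand == "+",
                  sites$position + e$cut_top,
                  sites$position + m - e$cut_bottom)
    if (circular) {
      cut <- cut %% n
    } else {
      keep <- cut >= 0L & cut <= n
      sites <- sites[keep, ]
      cut <- cut[keep]
    }
    cut_rows[[length(cut_rows) + 1L]] <- tibble(
      enzyme = e$enzyme, recognition_position = sites$position,
      strand = sites$strand, cut_position = as.integer(cut))
  }
  cuts <- if (length(cut_rows)) bind_rows(cut_rows) else
    tibble(enzyme = character(0), recognition_position = integer(0),
           strand = character(0), cut_position = integer(0))
  uniq <- sort(unique(cuts$cut_position))
  if (circular) {
    fragment_lengths <- if (length(uniq) == 0L) {
      n
    } else if (length(uniq) == 1L) {
      n
    } else {
      as.integer(diff(c(uniq, uniq[1] + n)))
    }
  } else {
    bounds <- unique(c(0L, uniq, n))
    fragment_lengths <- as.integer(diff(sort(bounds)))
  }
  structure(
    list(cuts = arrange(cuts, .data$cut_position),
         fragment_lengths = sort(as.integer(fragment_lengths),
                                 decreasing = TRUE),
         circular = circular, substrate_length = n,
         enzymes = enzymes$enzyme),
    class = "gibsim_digest")
}

#' @export
print.gibsim_digest <- function(x, ...) {
  cat(sprintf("<digest> %s substrate of %d bp with %s\n",
              if (x$circular) "circular" else "linear",
              x$substrate_length, paste(x$enzymes, collapse = " + ")))
  cat(sprintf("  %d cut(s); fragments (bp): %s\n", nrow(x$cuts),
              paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.gibsim_digest <- function(x, ...) {
  tibble(fragment = seq_along(x$fragment_lengths),
         length = x$fragment_lengths)
}

#' @export
glance.gibsim_digest <- function(x, ...) {
  tibble(substrate_length = x$substrate_length, circular = x$circular,
         n_cuts = length(unique(x$cuts$cut_position)),
         n_fragments = length(x$fragment_lengths),
         enzymes = paste(x$enzymes, collapse = "+"))
}

#' Gel schematic for one or more digests
#'
#' Draws a schematic agarose gel: one lane per digest, bands placed on a
#' log10 length scale as on a real gel.
#'
#' @param digests A named list of `gibsim_digest` objects (or a single one).
#' @return A ggplot object.
#' @export
plot_gel <- function(digests) {
  if (inherits(digests, "gibsim_digest")) digests <- list(digest = digests)
  stopifnot(length(digests) > 0L)
  nms <- names(digests) %||% paste0("lane", seq_along(digests))
  bands <- bind_rows(lapply(seq_along(digests), function(i) {
    tibble(lane = nms[i], length = digests[[i]]$fragment_lengths)
  }))
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$lane, y = .data$length)) +
    ggplot2::geom_point(shape = 95, size = 12) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "fragment length (bp)",
                  title = "Predicted digest") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gibsim_digest <- function(object, ...) {
  plot_gel(list(digest = object))
}

# Text rendering of a digest band table (used by the CLI).
gel_text <- function(digests) {
  if (inherits(digests, "gibsim_digest")) digests <- list(digest = digests)
  nms <- names(digests) %||% paste0("lane", seq_along(digests))
  lines <- character(0)
  for (i in seq_along(digests)) {
    lines <- c(lines, sprintf("%s: %s bp", nms[i],
                              paste(digests[[i]]$fragment_lengths,
                                    collapse = " / ")))
  }
  lines
}
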