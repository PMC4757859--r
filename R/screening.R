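#' Rank screening enzymes by how well they discriminate clones
#'
#' For each enzyme in a panel, the predicted band pattern of the correct
#' assembly is compared with that of each alternative (misassembly)
#' candidate. Fragment sizes that a gel cannot resolve are merged first:
#' pooled lengths are clustered so that sizes differing by less than the
#' fractional `tolerance` fall in one class (default 0.10, typical agarose
#' discrimination). The pattern distance is the symmetric difference of the
#' merged size-class multisets, weighted by log10 length, so it is monotone
#' in the number of visibly different bands. An enzyme's score is its
#' minimum distance over the alternatives (worst case); enzymes are ranked
#' by descending score, ties broken alphabetically. A score of 0 means the
#' enzyme cannot distinguish the correct clone from some alternative.
#'
#' @param correct The intended `gibson_assembly` (or a plain circular
#'   sequence).
#' @param alternatives A list of alternative products (or sequences);
#'   at least one.
#' @param panel Enzyme tibble, default the packaged screening panel
#'   (XmaI, NheI, AvrII, AfeI, AscI).
#' @param tolerance Fractional length difference below which two bands are
#'   considered indistinguishable.
#' @return A tibble with columns `enzyme`, `score`, `n_fragments_correct`,
#'   ranked best first.
#' @export
discriminating_enzymes <- function(correct, alternatives,
                                   panel = screening_panel(),
                                   tolerance = 0.10) {
  if (is.null(panel) || nrow(panel) == 0L) {
    abort("Enzyme panel must be non-empty.", class = "gibsim_error_input")
  }
  if (length(alternatives) == 0L) {
    abort("At least one alternative product is required.",
          class = "gibsim_error_input")
  }
  correct_seq <- product_sequence(correct)
  alt_seqs <- vapply(alternatives, product_sequence, character(1))
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    e <- panel[i, ]
    frag_correct <- digest(correct_seq, e, circular = TRUE)$fragment_lengths
    dists <- vapply(alt_seqs, function(a) {
      frag_alt <- digest(a, e, circular = TRUE)$fragment_lengths
      band_pattern_distance(frag_correct, frag_alt, tolerance)
    }, numeric(1))
    tibble(enzyme = e$enzyme, score = min(dists),
           n_fragments_correct = length(frag_correct))
  })
  out <- bind_rows(rows)
  out <- arrange(out, desc(.data$score), .data$enzyme)
  attr(out, "tolerance") <- tolerance
  out
}

product_sequence <- function(x) {
  if (inherits(x, "gibson_assembly")) return(x$sequence)
  dna_clean(x, arg = "product")
}

# Symmetric difference of tolerance-merged size classes, weighted by log10
# of the class's geometric-mean length.
band_pattern_distance <- function(a, b, tolerance) {
  pooled <- sort(c(a, b))
  if (length(pooled) == 0L) return(0)
  class_id <- integer(length(pooled))
  cls <- 1L
  class_id[1] <- cls
  if (length(pooled) > 1L) {
    for (i in 2:length(pooled)) {
      if ((pooled[i] - pooled[i - 1L]) / pooled[i - 1L] < tolerance) {
        class_id[i] <- cls
      } else {
        cls <- cls + 1L
        class_id[i] <- cls
      }
    }
  }
  dist <- 0
  for (k in unique(class_id)) {
    members <- pooled[class_id == k]
    na <- count_in(a, members)
    nb <- count_in(b, members)
    w <- log10(exp(mean(log(members))))
    dist <- dist + abs(na - nb) * w
  }
  dist
}

# How many elements of x (a multiset) fall in the class `members`
# (values drawn from the pooled multiset).
count_in <- function(x, members) {
  rng <- range(members)
  sum(x >= rng[1] & x <= rng[2])
}

#' Find sequencing-primer annealing sites
#'
#' Locates every position (both strands) where a primer matches the
#' substrate with at most `max_mismatch` substitutions. On circular
#' substrates, binding sites spanning the origin are found.
#'
#' @param seq Substrate sequence.
#' @param primer Primer sequence, 5'->3' (length >= 15).
#' @param circular Is the substrate circular?
#' @param max_mismatch Maximum number of substitutions tolerated.
#' @return A tibble with 0-based `position` (top-strand start of the
#'   matched region), `strand` and `mismatches`.
#' @export
primer_annealing_sites <- function(seq, primer, circular = FALSE,
                                   max_mismatch = 0L) {
  seq <- dna_clean(seq)
  primer <- dna_clean(primer, arg = "primer")
  if (nchar(primer) < 15L) {
    abort("Sequencing primers must be >= 15 nt.",
          class = "gibsim_error_input")
  }
  n <- nchar(seq)
  m <- nchar(primer)
  subject_str <- if (circular && n > 1L) {
    paste0(seq, str_sub(seq, 1L, min(m - 1L, n)))
  } else {
    seq
  }
  subject <- Biostrings::DNAString(subject_str)
  hit_tbl <- function(pat, strand) {
    hits <- Biostrings::matchPattern(pat, subject,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE)
    if (length(hits) == 0L) {
      return(tibble(position = integer(0), strand = character(0),
                    mismatches = integer(0)))
    }
    starts <- as.integer(Biostrings::start(hits))
    seqs_chr <- as.character(hits)
    keep <- starts >= 1L & nchar(seqs_chr) == m
    pat_chars <- strsplit(pat, "")[[1]]
    mm <- vapply(seqs_chr[keep], function(s) {
      sum(strsplit(s, "")[[1]] != pat_chars)
    }, integer(1), USE.NAMES = FALSE)
    tibble(position = starts[keep] - 1L, strand = strand,
           mismatches = mm)
  }
  out <- bind_rows(hit_tbl(primer, "+"), hit_tbl(revcomp(primer), "-"))
  if (circular && nrow(out) > 0L) {
    out$position <- out$position %% n
    out <- distinct(out)
  }
  arrange(out, .data$position, .data$strand)
}

#' Junction coverage by sequencing primers
#'
#' Verifies that every junction of an assembled product can be read by
#' Sanger sequencing: each junction must lie within `read_length` bases
#' downstream of some primer annealing site (reading 5'->3' from the
#' primer's 3' end, on either strand). The default primer panel is the five
#' overlap-site 30-mers themselves, which anneal to every junction's
#' overlap; a custom panel (e.g. junction-specific primers) can be supplied.
#'
#' @param product A `gibson_assembly`.
#' @param primers Character vector of primer sequences (named if desired).
#' @param read_length Usable Sanger read length, nt.
#' @param max_mismatch Mismatches tolerated when locating primer sites.
#' @return A tibble with one row per junction: `position`, `site_id`,
#'   `covered`, `primer`, `distance` (bases from the primer's 3' end to the
#'   junction start along the reading direction).
#' @export
junction_coverage <- function(product, primers = NULL, read_length = 700L,
                              max_mismatch = 0L) {
  stopifnot(inherits(product, "gibson_assembly"))
  if (is.null(primers)) {
    primers <- setNames(overlap_sites()$sequence,
                        paste0("site", overlap_sites()$site_id))
  }
  if (is.null(names(primers))) {
    names(primers) <- paste0("primer", seq_along(primers))
  }
  n <- product$total_length
  sites <- bind_rows(lapply(names(primers), function(nm) {
    hits <- primer_annealing_sites(product$sequence, primers[[nm]],
                                   circular = TRUE,
                                   max_mismatch = max_mismatch)
    if (nrow(hits) == 0L) return(NULL)
    hits$primer <- nm
    hits$primer_len <- nchar(primers[[nm]])
    hits
  }))
  rows <- lapply(seq_len(nrow(product$junctions)), function(i) {
    jpos <- product$junctions$position[i]
    best <- NULL
    if (!is.null(sites) && nrow(sites) > 0L) {
      jlen <- product$junctions$overlap_length[i]
      for (k in seq_len(nrow(sites))) {
        # distance from the start of the annealed primer footprint to the
        # junction start, measured along the reading direction; a primer
        # annealing on the junction itself has distance 0
        if (sites$strand[k] == "+") {
          d <- (jpos - sites$position[k]) %% n
        } else {
          d <- ((sites$position[k] + sites$primer_len[k]) - (jpos + jlen)) %% n
        }
        if (d <= read_length && (is.null(best) || d < best$distance)) {
          best <- list(primer = sites$primer[k], distance = d)
        }
      }
    }
    tibble(junction = i, position = jpos,
           site_id = product$junctions$site_id[i],
           covered = !is.null(best),
           primer = if (is.null(best)) NA_character_ else best$primer,
           distance = if (is.null(best)) NA_integer_ else
             as.integer(best$distance))
  })
  bind_rows(rows)
}
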