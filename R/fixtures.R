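#' Specification for the synthetic fixture generator
#'
#' The generator emulates the platform's real resources entirely offline:
#' a promoter/gene collection (random cores flanked per slot) and a
#' backbone plasmid that carries the two chain sites separated by a
#' releasable spacer, so that digestion with the declared enzymes excises
#' the spacer and leaves a linear backbone with the sites terminal. Random
#' cores are rejection-sampled so that they contain none of the forbidden
#' substrings (by default the five overlap sites and the packaged enzyme
#' recognitions, so fixture assemblies and digests are free of stray
#' homology and stray cut sites).
#'
#' Identical `seed` and spec fields give byte-identical fixtures.
#'
#' @param seed Integer seed.
#' @param n_promoters,n_genes Number of promoter and gene parts (slots are
#'   assigned cycling pA, pB, pC and gA, gB, gC).
#' @param core_length_range Core length interval, bp. Promoter and gene
#'   bodies in routine constructs run a few hundred bp to a few kb; the
#'   default keeps fixtures in that range while staying desk-sized.
#' @param gc_fraction GC content of random cores and stuffer.
#' @param backbone_arch List with `chain_start`, `chain_end`,
#'   `spacer_length` (the released fragment length, bp) and `enzymes`
#'   (character, the releasing enzymes).
#' @param forbid_internal Substrings excluded from random cores/stuffer.
#' @param stuffer_length Length of the random vector body, bp.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_promoters = 3L, n_genes = 3L,
                         core_length_range = c(200L, 1200L),
                         gc_fraction = 0.5,
                         backbone_arch = list(chain_start = 1L,
                                              chain_end = 5L,
                                              spacer_length = 469L,
                                              enzymes = c("PmeI", "BsrGI")),
                         forbid_internal = NULL,
                         stuffer_length = 2000L) {
  if (is.null(forbid_internal)) {
    forbid_internal <- default_forbidden()
  }
  stopifnot(length(core_length_range) == 2L,
            core_length_range[1] >= 1L,
            core_length_range[1] <= core_length_range[2],
            gc_fraction > 0, gc_fraction < 1)
  structure(list(seed = as.integer(seed),
                 n_promoters = as.integer(n_promoters),
                 n_genes = as.integer(n_genes),
                 core_length_range = as.integer(core_length_range),
                 gc_fraction = gc_fraction,
                 backbone_arch = backbone_arch,
                 forbid_internal = forbid_internal,
                 stuffer_length = as.integer(stuffer_length)),
            class = "gibsim_fixture_spec")
}

# Sites, their reverse complements, and all packaged recognitions: cores
# free of these assemble and screen without surprises.
default_forbidden <- function() {
  sites <- overlap_sites()$sequence
  unique(c(sites, revcomp(sites), restriction_enzymes()$recognition))
}

MAX_SAMPLING_ATTEMPTS <- 1e5

# Rejection-sample one random sequence free of forbidden substrings.
sample_clean_dna <- function(n, gc, forbidden) {
  if (any(nchar(forbidden) == 1L)) {
    abort("Unsatisfiable forbid list: single-base substrings are forbidden.",
          class = "gibsim_error_fixture")
  }
  for (attempt in seq_len(MAX_SAMPLING_ATTEMPTS)) {
    s <- random_dna(n, gc)
    if (!any(vapply(forbidden, function(f) str_detect(s, fixed(f)),
                    logical(1)))) {
      return(s)
    }
  }
  abort(sprintf(
    "Could not sample a %d bp sequence free of forbidden substrings in %d attempts.",
    n, MAX_SAMPLING_ATTEMPTS), class = "gibsim_error_fixture")
}

#' Generate a synthetic part collection
#'
#' @param spec A [fixture_spec()].
#' @return A parts tibble ([make_flanked_part()] rows), deterministic under
#'   the seed in `spec`; promoter slots cycle pA, pB, pC and gene slots cycle
#'   gA, gB, gC.
#' @export
generate_fixture_parts <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "gibsim_fixture_spec"))
  withr::local_seed(spec$seed)
  promoter_slots <- rep(c("pA", "pB", "pC"),
                        length.out = spec$n_promoters)
  gene_slots <- rep(c("gA", "gB", "gC"), length.out = spec$n_genes)
  rows <- list()
  for (i in seq_along(promoter_slots)) {
    len <- sample(spec$core_length_range[1]:spec$core_length_range[2], 1L)
    core <- sample_clean_dna(len, spec$gc_fraction, spec$forbid_internal)
    rows[[length(rows) + 1L]] <- make_flanked_part(
      core, promoter_slots[i],
      name = sprintf("syn_promoter_%02d_%s", i, promoter_slots[i]))
  }
  for (i in seq_along(gene_slots)) {
    len <- sample(spec$core_length_range[1]:spec$core_length_range[2], 1L)
    core <- sample_clean_dna(len, spec$gc_fraction, spec$forbid_internal)
    rows[[length(rows) + 1L]] <- make_flanked_part(
      core, gene_slots[i],
      name = sprintf("syn_gene_%02d_%s", i, gene_slots[i]))
  }
  bind_rows(rows)
}

# Can `enzyme` cut flush at a site/spacer boundary? Returns the required
# spacer-side bases, or NULL when no straddle works.
# side = "after_site": boundary is site end -> spacer start; the spacer
#   must begin with the recognition tail.
# side = "before_site": boundary is spacer end -> site start; the spacer
#   must end with the recognition head.
flush_straddle <- function(enzyme, site_seq, side) {
  rec <- enzyme$recognition
  m <- nchar(rec)
  if (side == "after_site") {
    for (j in seq_len(m - 1L)) {
      if (enzyme$cut_top == j &&
          str_sub(site_seq, -j, -1L) == str_sub(rec, 1L, j)) {
        return(str_sub(rec, j + 1L, m))
      }
    }
  } else {
    for (j in seq_len(m - 1L)) {
      if (enzyme$cut_top == m - j &&
          str_sub(site_seq, 1L, j) == str_sub(rec, m - j + 1L, m)) {
        return(str_sub(rec, 1L, m - j))
      }
    }
  }
  NULL
}

#' Generate a synthetic backbone plasmid with a releasable spacer
#'
#' Builds a circular plasmid whose insert-facing region reads
#' (chain start site)(spacer)(chain end site) around the circle, embedded
#' in a random vector body. Spacer termini are engineered so the declared
#' releasing enzymes cut flush to the sites where their geometry permits
#' (e.g. PmeI's blunt `GTTT^AAAC` straddling a site ending in ...GTTT, or
#' BsrGI's `T^GTACA` straddling site #1's terminal T): digestion then
#' releases a fragment of exactly `spacer_length` bp and the linearized
#' backbone carries the two site 30-mers intact at its termini. An enzyme
#' whose recognition cannot straddle a boundary (its recognition conflicts
#' with the fixed site bases) is placed flush against the boundary inside
#' the spacer; the released fragment still measures `spacer_length`, and
#' the few residual bases left on the backbone terminus are reported in
#' `remnant` (with a warning), since an exact-homology assembly would need
#' a remnant-free terminus.
#'
#' @param spec A [fixture_spec()]; `spec$backbone_arch` declares the
#'   architecture.
#' @return A list with elements `plasmid` (tibble row: `name`, `sequence`,
#'   `topology`), `backbone` (a [new_backbone()] row when remnant-free,
#'   otherwise a plain tibble row), `expected_release` (bp), `remnant`
#'   (named character of residual bases per terminus, possibly empty) and
#'   `enzymes`.
#' @export
generate_fixture_backbone <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "gibsim_fixture_spec"))
  arch <- spec$backbone_arch
  enzymes <- resolve_enzymes(arch$enzymes)
  start_site <- site_sequence(arch$chain_start)
  end_site <- site_sequence(arch$chain_end)
  spacer_len <- as.integer(arch$spacer_length)

  pick <- function(side, site_seq, prefer_not = character(0)) {
    ord <- order(enzymes$enzyme %in% prefer_not)
    for (i in ord) {
      tail <- flush_straddle(enzymes[i, ], site_seq, side)
      if (!is.null(tail)) {
        return(list(enzyme = enzymes$enzyme[i], bases = tail, flush = TRUE))
      }
    }
    # fallback: whole recognition just inside the spacer; the cut leaves
    # (m - cut_top) residual bases on the site side of the boundary
    e <- enzymes[nrow(enzymes), ]
    list(enzyme = e$enzyme,
         bases = e$recognition,
         flush = FALSE,
         remnant = str_sub(e$recognition, e$cut_top + 1L, -1L))
  }
  right <- pick("before_site", end_site)    # spacer -> chain end site
  left <- pick("after_site", start_site,    # chain start site -> spacer
               prefer_not = right$enzyme)
  remnant <- character(0)
  right_rem <- 0L
  if (!right$flush) {
    right_rem <- nchar(right$remnant)
    remnant <- c(remnant, setNames(right$remnant, "chain_end_terminus"))
    warn(sprintf(
      "%s cannot cut flush at the site #%d boundary; the linearized backbone keeps a %d nt remnant (%s).",
      right$enzyme, arch$chain_end, right_rem, right$remnant))
  }
  if (!left$flush) {
    abort(sprintf(
      "No declared enzyme can release the spacer at the site #%d boundary.",
      arch$chain_start), class = "gibsim_error_fixture")
  }
  fixed_len <- nchar(left$bases) + nchar(right$bases)
  filler_len <- spacer_len + right_rem - fixed_len
  if (filler_len < 0L) {
    abort(sprintf(
      "Spacer of %d bp is too short to host the cut-site geometry (%d bp needed).",
      spacer_len, fixed_len - right_rem), class = "gibsim_error_fixture")
  }

  withr::local_seed(spec$seed + 104729L)  # distinct stream from the parts
  forbidden <- unique(c(spec$forbid_internal, enzymes$recognition))
  for (attempt in 1:50) {
    filler <- if (filler_len > 0L) {
      sample_clean_dna(filler_len, spec$gc_fraction, forbidden)
    } else ""
    stuffer <- sample_clean_dna(spec$stuffer_length, spec$gc_fraction,
                                forbidden)
    spacer_region <- paste0(left$bases, filler, right$bases)
    # circular plasmid, written from the chain end site
    plasmid_seq <- paste0(end_site, stuffer, start_site, spacer_region)
    d <- digest(plasmid_seq, enzymes, circular = TRUE)
    ok <- length(d$fragment_lengths) == 2L &&
      (spacer_len %in% d$fragment_lengths)
    if (ok) break
    if (attempt == 50L) {
      abort("Could not realize the requested backbone architecture.",
            class = "gibsim_error_fixture")
    }
  }
  backbone_seq <- paste0(
    if (right_rem > 0L) right$remnant else "",
    end_site, stuffer, start_site)
  backbone <- if (right_rem == 0L) {
    new_backbone(backbone_seq, arch$chain_start, arch$chain_end,
                 name = sprintf("syn_backbone_%d_%d", arch$chain_start,
                                arch$chain_end),
                 source_note = sprintf(
                   "synthetic fixture; spacer %d bp released by %s",
                   spacer_len, paste(unique(c(left$enzyme, right$enzyme)),
                                     collapse = "+")))
  } else {
    tibble(name = sprintf("syn_backbone_%d_%d", arch$chain_start,
                          arch$chain_end),
           role = "backbone", sequence = backbone_seq,
           length = nchar(backbone_seq),
           chain_start_site = as.integer(arch$chain_start),
           chain_end_site = as.integer(arch$chain_end),
           source_note = sprintf(
             "synthetic fixture; %d nt remnant at the chain end terminus",
             right_rem))
  }
  list(
    plasmid = tibble(
      name = sprintf("syn_plasmid_%d_%d", arch$chain_start, arch$chain_end),
      sequence = plasmid_seq, topology = "circular",
      length = nchar(plasmid_seq)),
    backbone = backbone,
    expected_release = spacer_len,
    remnant = remnant,
    enzymes = enzymes$enzyme)
}
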