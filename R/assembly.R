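#' @title One-pot isothermal assembly simulation
#' @description Gibson assembly joins fragments that share terminal
#'   homology: an exonuclease chews back 5' ends, complementary single
#'   strands anneal, and polymerase/ligase seal the joints. The simulation
#'   reduces this to exact terminal homology: fragment B can follow
#'   fragment A when a suffix of A equals a prefix of B (each fragment
#'   optionally reverse-complemented), with the shared region at least
#'   `min_overlap` long. Designed junctions in this platform are 30 bp
#'   overlap sites, so the default minimum is 30 (configurable down to 15
#'   and up to 40 to mirror typical Gibson practice).
#' @name assembly-engine
NULL

# Longest terminal overlap: max L in [min_overlap, min(nchar)] with
# suffix(a, L) == prefix(b, L); 0 when none.
terminal_overlap <- function(a, b, min_overlap) {
  na <- nchar(a); nb <- nchar(b)
  top <- min(na, nb)
  if (top < min_overlap) return(0L)
  ls <- seq.int(top, min_overlap)
  hit <- which(substring(a, na - ls + 1L, na) == substring(b, 1L, ls))
  if (length(hit) == 0L) 0L else as.integer(ls[hit[1]])
}

oriented_seq <- function(seq, orientation) {
  if (orientation == "reverse") revcomp(seq) else seq
}

site_id_of <- function(overlap_seq) {
  sites <- overlap_sites()
  id <- sites$site_id[match(overlap_seq, sites$sequence)]
  if (length(id) == 0L) NA_integer_ else id
}

#' Find candidate junctions among fragments
#'
#' For every ordered fragment pair and every orientation combination,
#' records the longest suffix-of-upstream = prefix-of-downstream match of at
#' least `min_overlap` bases. A fragment used in reverse contributes the
#' termini of its reverse complement.
#'
#' @param fragments A tibble with columns `name` and `sequence` (>= 2 rows).
#' @param min_overlap Minimum homology length, nt (>= 15).
#' @return A tibble with columns `upstream`, `upstream_orientation`,
#'   `downstream`, `downstream_orientation`, `overlap_length`,
#'   `overlap_sequence` and `site_id` (set when the overlap is exactly a
#'   canonical 30 bp site).
#' @export
find_junctions <- function(fragments, min_overlap = 30) {
  check_fragments(fragments)
  if (nrow(fragments) < 2L) {
    abort("At least 2 fragments are required.", class = "gibsim_error_input")
  }
  if (min_overlap < 15) {
    abort("`min_overlap` must be >= 15 nt.", class = "gibsim_error_input")
  }
  orientations <- c("forward", "reverse")
  rows <- list()
  for (i in seq_len(nrow(fragments))) {
    for (j in seq_len(nrow(fragments))) {
      if (i == j) next
      for (uo in orientations) {
        up <- oriented_seq(fragments$sequence[i], uo)
        for (do in orientations) {
          down <- oriented_seq(fragments$sequence[j], do)
          L <- terminal_overlap(up, down, min_overlap)
          if (L > 0L) {
            ov <- str_sub(down, 1L, L)
            rows[[length(rows) + 1L]] <- tibble(
              upstream = fragments$name[i], upstream_orientation = uo,
              downstream = fragments$name[j], downstream_orientation = do,
              overlap_length = L, overlap_sequence = ov,
              site_id = if (L == SITE_LEN) site_id_of(ov) else NA_integer_)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(upstream = character(0), upstream_orientation = character(0),
                  downstream = character(0),
                  downstream_orientation = character(0),
                  overlap_length = integer(0), overlap_sequence = character(0),
                  site_id = integer(0)))
  }
  bind_rows(rows)
}

check_fragments <- function(fragments) {
  if (!is.data.frame(fragments) ||
      !all(c("name", "sequence") %in% names(fragments))) {
    abort("`fragments` must be a data frame with columns `name` and `sequence`.",
          class = "gibsim_error_input")
  }
  if (anyDuplicated(fragments$name)) {
    abort("Fragment names must be unique.", class = "gibsim_error_input")
  }
  invisible(fragments)
}

# Depth-first search for circular orderings. `oriented` is a named list of
# list(forward=, reverse=) sequences; start_name is fixed forward. With
# allow_subset = TRUE every closable cycle through the start fragment is
# reported, not only those visiting every fragment (used by assemble() to
# diagnose ambiguity when a fragment pool admits several circles).
find_cycles <- function(oriented, start_name, min_overlap,
                        max_cycles = Inf, allow_subset = FALSE) {
  names_all <- names(oriented)
  memo <- new.env(parent = emptyenv())
  ov <- function(an, ao, bn, bo) {
    key <- paste(an, ao, bn, bo, sep = "\r")
    val <- memo[[key]]
    if (is.null(val)) {
      val <- terminal_overlap(oriented[[an]][[ao]], oriented[[bn]][[bo]],
                              min_overlap)
      memo[[key]] <- val
    }
    val
  }
  cycles <- list()
  record <- function(path_names, path_orients) {
    k <- length(path_names)
    closing <- ov(path_names[k], path_orients[k], start_name, "forward")
    if (closing > 0L && k >= 2L) {
      cycles[[length(cycles) + 1L]] <<- list(
        names = path_names, orientations = path_orients,
        overlaps = c(vapply(seq_len(k - 1L), function(i) {
          ov(path_names[i], path_orients[i], path_names[i + 1L],
             path_orients[i + 1L])
        }, integer(1)), closing))
    }
  }
  dfs <- function(path_names, path_orients, used) {
    if (length(cycles) >= max_cycles) return(invisible())
    k <- length(path_names)
    if (k == length(names_all) || (allow_subset && k >= 2L)) {
      record(path_names, path_orients)
      if (k == length(names_all)) return(invisible())
    }
    for (nxt in setdiff(names_all, used)) {
      for (o in c("forward", "reverse")) {
        if (ov(path_names[k], path_orients[k], nxt, o) > 0L) {
          dfs(c(path_names, nxt), c(path_orients, o), c(used, nxt))
        }
      }
    }
  }
  dfs(start_name, "forward", start_name)
  cycles
}

# Build a gibson_assembly object from a cycle (fragments given as a named
# list of forward sequences).
build_product <- function(cycle, seqs, backbone_name = NA_character_) {
  k <- length(cycle$names)
  oriented <- vapply(seq_len(k), function(i) {
    oriented_seq(seqs[[cycle$names[i]]], cycle$orientations[i])
  }, character(1))
  lens <- nchar(oriented)
  pieces <- character(k)
  pieces[1] <- oriented[1]
  if (k > 1L) {
    for (i in 2:k) {
      pieces[i] <- str_sub(oriented[i], cycle$overlaps[i - 1L] + 1L, -1L)
    }
  }
  seq <- paste(pieces, collapse = "")
  closing <- cycle$overlaps[k]
  seq <- str_sub(seq, 1L, nchar(seq) - closing)
  total <- nchar(seq)
  starts <- integer(k)
  starts[1] <- 0L
  if (k > 1L) {
    for (i in 2:k) {
      starts[i] <- starts[i - 1L] + lens[i - 1L] - cycle$overlaps[i - 1L]
    }
  }
  fragment_order <- tibble(
    position = seq_len(k), name = cycle$names,
    orientation = cycle$orientations, length = lens, start = starts)
  nxt <- if (k == 1L) 1L else c(2:k, 1L)
  junctions <- tibble(
    upstream = cycle$names,
    downstream = cycle$names[nxt],
    downstream_orientation = cycle$orientations[nxt],
    overlap_length = cycle$overlaps,
    position = c(starts[-1L], 0L)[seq_len(k)]
  )
  junctions$overlap_sequence <- vapply(seq_len(k), function(i) {
    p <- junctions$position[i]
    str_sub(seq, p + 1L, p + junctions$overlap_length[i])
  }, character(1))
  junctions$site_id <- vapply(seq_len(k), function(i) {
    if (junctions$overlap_length[i] == SITE_LEN) {
      site_id_of(junctions$overlap_sequence[i])
    } else NA_integer_
  }, integer(1))
  warnings <- character(0)
  doubled <- paste0(seq, str_sub(seq, 1L, max(junctions$overlap_length)))
  for (i in seq_len(k)) {
    starts <- iupac_match_starts(junctions$overlap_sequence[i], doubled)
    hits <- sum(starts <= total)  # matches beginning within one full turn
    if (hits > 1L) {
      warnings <- c(warnings, sprintf(
        "junction homology %s occurs %d times in the product (potential misassembly)",
        if (!is.na(junctions$site_id[i]))
          sprintf("site #%d", junctions$site_id[i]) else
            sprintf("at position %d", junctions$position[i]),
        hits))
    }
  }
  structure(
    list(sequence = seq, total_length = total,
         canonical_sequence = canonical_circular(seq),
         fragment_order = fragment_order, junctions = junctions,
         backbone = backbone_name, circular = TRUE,
         warnings = unique(warnings)),
    class = "gibson_assembly")
}

#' Assemble fragments into a circular construct
#'
#' Searches for a circular ordering in which every fragment is used exactly
#' once and consecutive fragments share terminal homology of at least
#' `min_overlap` bases. Exactly one distinct circular product must exist:
#' zero products raise an incomplete-assembly error naming the unmatched
#' termini (the "gap"), and more than one raises an ambiguity error.
#'
#' The product is rotated to start at the backbone's first base with the
#' backbone in forward orientation. Junctions whose overlap is exactly a
#' canonical 30 bp overlap site are annotated with the site id.
#'
#' @param fragments A tibble of parts with columns `name` and `sequence`.
#' @param backbone A backbone row (columns `name`, `sequence`), or `NULL`
#'   to assemble the fragments alone (the product is then reported in its
#'   canonical rotation).
#' @param min_overlap Minimum homology, nt.
#' @return A `gibson_assembly` object; see [tidy.gibson_assembly()] and
#'   [glance.gibson_assembly()].
#' @examples
#' parts <- dplyr::bind_rows(
#'   make_flanked_part(strrep("ACGGT", 30), "pA", "promoter"),
#'   make_flanked_part(strrep("TTGCA", 30), "gC", "gene"))
#' sites <- overlap_sites()$sequence
#' backbone <- new_backbone(paste0(sites[5], strrep("CAGTA", 60), sites[1]),
#'                          1, 5, "vector")
#' assemble(parts, backbone)
#' @export
assemble <- function(fragments, backbone = NULL, min_overlap = 30) {
  check_fragments(fragments)
  all_frags <- fragments[, c("name", "sequence")]
  backbone_name <- NA_character_
  if (!is.null(backbone)) {
    stopifnot(is.data.frame(backbone), nrow(backbone) == 1L)
    backbone_name <- backbone$name[1]
    if (backbone_name %in% all_frags$name) {
      abort("Backbone name collides with a fragment name.",
            class = "gibsim_error_input")
    }
    all_frags <- bind_rows(
      tibble(name = backbone_name, sequence = backbone$sequence[1]),
      all_frags)
  }
  if (nrow(all_frags) < 2L) {
    abort("At least 2 fragments (including the backbone) are required.",
          class = "gibsim_error_input")
  }
  seqs <- as.list(setNames(all_frags$sequence, all_frags$name))
  oriented <- lapply(seqs, function(s) {
    list(forward = s, reverse = revcomp(s))
  })
  start_name <- if (!is.na(backbone_name)) backbone_name else
    all_frags$name[1]
  cycles <- find_cycles(oriented, start_name, min_overlap,
                        allow_subset = TRUE)
  if (length(cycles) == 0L) {
    gap <- describe_gaps(all_frags, min_overlap)
    abort(sprintf("Incomplete assembly: no circular product. Unmatched termini: %s.",
                  gap),
          class = "gibsim_error_incomplete_assembly", gap = gap)
  }
  products <- lapply(cycles, build_product, seqs = seqs,
                     backbone_name = backbone_name)
  canon <- vapply(products, function(p) p$canonical_sequence, character(1))
  products <- products[!duplicated(canon)]
  if (length(products) > 1L) {
    alts <- vapply(products, function(p) {
      paste(p$fragment_order$name, collapse = "-")
    }, character(1))
    abort(sprintf("Ambiguous assembly: %d distinct circular products (%s).",
                  length(products), paste(alts, collapse = "; ")),
          class = "gibsim_error_ambiguous_assembly",
          alternatives = products)
  }
  product <- products[[1]]
  unused <- setdiff(all_frags$name, product$fragment_order$name)
  if (length(unused) > 0L) {
    product$warnings <- c(product$warnings, sprintf(
      "fragment(s) not incorporated in the product: %s",
      paste(unused, collapse = ", ")))
  }
  product
}

# Human-readable description of unmatched forward-orientation termini.
describe_gaps <- function(fragments, min_overlap) {
  msgs <- character(0)
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$sequence[i]
    has_out <- FALSE
    has_in <- FALSE
    for (j in seq_len(nrow(fragments))) {
      if (i == j) next
      for (o in c("forward", "reverse")) {
        other <- oriented_seq(fragments$sequence[j], o)
        if (terminal_overlap(s, other, min_overlap) > 0L) has_out <- TRUE
        if (terminal_overlap(other, s, min_overlap) > 0L) has_in <- TRUE
      }
    }
    if (!has_in) {
      id <- site_id_of(str_sub(s, 1L, SITE_LEN))
      msgs <- c(msgs, sprintf("left end of %s%s", fragments$name[i],
                              if (!is.na(id)) sprintf(" (site #%d)", id)
                              else ""))
    }
    if (!has_out) {
      id <- site_id_of(str_sub(s, -SITE_LEN, -1L))
      msgs <- c(msgs, sprintf("right end of %s%s", fragments$name[i],
                              if (!is.na(id)) sprintf(" (site #%d)", id)
                              else ""))
    }
  }
  if (length(msgs) == 0L) "none at fragment level (no full cycle exists)"
  else paste(msgs, collapse = ", ")
}

#' Enumerate all circular products formable from a fragment pool
#'
#' Considers every sub-multiset of the fragments (each used at most once),
#' every ordering and every orientation, and returns the distinct circular
#' products, deduplicated up to rotation and reverse complement.
#'
#' @param fragments A tibble with columns `name` and `sequence`.
#' @param min_overlap Minimum homology, nt.
#' @param max_products Cap on the number of distinct products; when reached,
#'   the result carries `attr(, "truncated") = TRUE`.
#' @return A list of `gibson_assembly` objects (possibly empty).
#' @export
enumerate_products <- function(fragments, min_overlap = 30,
                               max_products = 100L) {
  if (max_products < 1L) {
    abort("`max_products` must be >= 1.", class = "gibsim_error_input")
  }
  if (is.null(fragments) || nrow(fragments) == 0L) {
    out <- list()
    attr(out, "truncated") <- FALSE
    return(out)
  }
  check_fragments(fragments)
  n <- nrow(fragments)
  if (n > 12L) {
    abort("Exhaustive product enumeration supports at most 12 fragments.",
          class = "gibsim_error_input")
  }
  seen <- character(0)
  products <- list()
  truncated <- FALSE
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    sub <- fragments[idx, ]
    if (nrow(sub) == 1L) {
      s <- sub$sequence[1]
      L <- terminal_overlap(s, s, min_overlap)
      if (L > 0L && L < nchar(s)) {
        cyc <- list(names = sub$name[1], orientations = "forward",
                    overlaps = L)
        p <- build_product(cyc, setNames(as.list(sub$sequence), sub$name))
        if (!p$canonical_sequence %in% seen) {
          if (length(products) >= max_products) { truncated <- TRUE; break }
          seen <- c(seen, p$canonical_sequence)
          products[[length(products) + 1L]] <- p
        }
      }
      next
    }
    seqs <- as.list(setNames(sub$sequence, sub$name))
    oriented <- lapply(seqs, function(s) {
      list(forward = s, reverse = revcomp(s))
    })
    cycles <- find_cycles(oriented, sub$name[1], min_overlap)
    for (cyc in cycles) {
      p <- build_product(cyc, seqs)
      if (!p$canonical_sequence %in% seen) {
        if (length(products) >= max_products) { truncated <- TRUE; break }
        seen <- c(seen, p$canonical_sequence)
        products[[length(products) + 1L]] <- p
      }
    }
    if (truncated) break
  }
  attr(products, "truncated") <- truncated
  products
}

#' @export
print.gibson_assembly <- function(x, ...) {
  cat(sprintf("<gibson_assembly> circular, %d bp, %d fragments\n",
              x$total_length, nrow(x$fragment_order)))
  cat(sprintf("  order: %s\n",
              paste0(x$fragment_order$name,
                     ifelse(x$fragment_order$orientation == "reverse",
                            "(-)", ""), collapse = " -> ")))
  sites <- x$junctions$site_id
  if (any(!is.na(sites))) {
    cat(sprintf("  junction sites: %s\n",
                paste(ifelse(is.na(sites), "?", paste0("#", sites)),
                      collapse = ", ")))
  }
  if (length(x$warnings)) {
    cat(sprintf("  warnings: %s\n", paste(x$warnings, collapse = "; ")))
  }
  invisible(x)
}

#' Tidy the junction table of an assembly
#'
#' @param x A `gibson_assembly`.
#' @param ... Unused.
#' @return A tibble with one row per junction.
#' @export
tidy.gibson_assembly <- function(x, ...) {
  as_tibble(x$junctions)
}

#' One-row summary of an assembly
#'
#' @param x A `gibson_assembly`.
#' @param ... Unused.
#' @return A tibble with total length, fragment and junction counts, and
#'   the backbone name.
#' @export
glance.gibson_assembly <- function(x, ...) {
  tibble(total_length = x$total_length,
         n_fragments = nrow(x$fragment_order),
         n_junctions = nrow(x$junctions),
         n_site_junctions = sum(!is.na(x$junctions$site_id)),
         backbone = x$backbone,
         n_warnings = length(x$warnings))
}

#' Plot a linearized map of an assembly
#'
#' Fragments are drawn as tiles along the linearized circle (opened at the
#' product start), junction overlap sites marked and labelled.
#'
#' @param object A `gibson_assembly`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gibson_assembly <- function(object, ...) {
  fo <- object$fragment_order
  fo$end <- pmin(fo$start + fo$length, object$total_length)
  jx <- object$junctions
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = fo,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = 1, fill = .data$name),
      color = "grey20") +
    ggplot2::geom_vline(data = jx,
                        ggplot2::aes(xintercept = .data$position),
                        linetype = 2) +
    ggplot2::geom_text(
      data = jx[!is.na(jx$site_id), ],
      ggplot2::aes(x = .data$position, y = 1.15,
                   label = paste0("#", .data$site_id)), size = 3) +
    ggplot2::scale_y_continuous(limits = c(-0.1, 1.3), breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "fragment",
                  title = sprintf("Assembled construct (%d bp, circular)",
                                  object$total_length)) +
    ggplot2::theme_minimal()
}
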