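#' Reaction defaults for one-pot isothermal assembly
#'
#' The shipped defaults reproduce the platform's bench protocol: part
#' stocks normalized to 57 nM, 5.7e-2 pmol of each insert in a 5 uL insert
#' pool, 200 ng of backbone, 15 uL of isothermal master mix, incubation at
#' 50 degC for 20 min, and a 99% target confidence for colony screening.
#'
#' @param stock_conc Part stock concentration, nM.
#' @param insert_amount Amount of each insert, pmol.
#' @param backbone_mass Backbone mass, ng.
#' @param master_mix_volume Master mix volume per reaction, uL.
#' @param insert_volume_total Total insert-pool volume (topped up with
#'   buffer), uL.
#' @param incubation_temp Incubation temperature, degC.
#' @param incubation_min Incubation time, minutes.
#' @param confidence Target probability of at least one correct colony.
#' @return A `reaction_defaults` list.
#' @export
reaction_defaults <- function(stock_conc = 57, insert_amount = 5.7e-2,
                              backbone_mass = 200, master_mix_volume = 15,
                              insert_volume_total = 5, incubation_temp = 50,
                              incubation_min = 20, confidence = 0.99) {
  vals <- c(stock_conc, insert_amount, backbone_mass, master_mix_volume,
            insert_volume_total, incubation_temp, incubation_min)
  if (any(vals <= 0)) {
    abort("All reaction quantities must be strictly positive.",
          class = "gibsim_error_input")
  }
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must lie in (0, 1).", class = "gibsim_error_input")
  }
  structure(list(stock_conc = stock_conc, insert_amount = insert_amount,
                 backbone_mass = backbone_mass,
                 master_mix_volume = master_mix_volume,
                 insert_volume_total = insert_volume_total,
                 incubation_temp = incubation_temp,
                 incubation_min = incubation_min, confidence = confidence),
            class = "gibsim_reaction_defaults")
}

# Average molar mass of double-stranded DNA, g/mol, anhydrous salt-free
# convention: 617.96 per bp plus 36.04 for the two terminal hydroxyls.
ds_dna_molar_mass <- function(length) 617.96 * length + 36.04

#' Mass of a given molar amount of dsDNA
#'
#' @param length Fragment length, bp (>= 1).
#' @param amount Amount, pmol (> 0).
#' @return Mass in ng.
#' @examples
#' ds_dna_mass_for_amount(1000, 0.057)  # ~35.2 ng
#' @export
ds_dna_mass_for_amount <- function(length, amount) {
  if (any(length < 1) || any(amount <= 0)) {
    abort("`length` must be >= 1 bp and `amount` > 0 pmol.",
          class = "gibsim_error_input")
  }
  amount * ds_dna_molar_mass(length) * 1e-3
}

#' Molar amount contained in a volume of stock
#'
#' @param conc Stock concentration, nM (> 0).
#' @param volume Volume, uL (> 0).
#' @return Amount in pmol.
#' @examples
#' amount_in_volume(57, 1)  # 0.057 pmol
#' @export
amount_in_volume <- function(conc, volume) {
  if (any(conc <= 0) || any(volume <= 0)) {
    abort("`conc` and `volume` must be > 0.", class = "gibsim_error_input")
  }
  conc * volume * 1e-3
}

#' Colonies to screen for a target confidence
#'
#' With per-colony probability `p` of a correct assembly, the number of
#' colonies needed so that the probability of at least one correct clone
#' strictly exceeds `confidence` is the smallest integer n with
#' `1 - (1-p)^n > confidence`. The inequality is strict: when
#' `1 - (1-p)^n` equals the confidence exactly, one more colony is
#' required.
#'
#' @param p Per-colony probability of a correct assembly. Values >= 1
#'   return 1.
#' @param confidence Target confidence in (0, 1).
#' @return The smallest sufficient integer number of colonies.
#' @examples
#' colonies_to_screen(0.80, 0.99)  # 3 (two-fragment reactions)
#' colonies_to_screen(0.65, 0.99)  # 5 (four-fragment reactions)
#' @export
colonies_to_screen <- function(p, confidence = 0.99) {
  if (length(p) > 1L || length(confidence) > 1L) {
    return(mapply(colonies_to_screen, p, confidence))
  }
  if (is.na(p) || p <= 0) {
    abort("`p` must be > 0.", class = "gibsim_error_input")
  }
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must lie in (0, 1).", class = "gibsim_error_input")
  }
  if (p >= 1) return(1L)
  n <- floor(log(1 - confidence) / log(1 - p)) + 1
  # guard the floating-point boundary: enforce the strict inequality
  while (n > 1 && 1 - (1 - p)^(n - 1) > confidence) n <- n - 1
  while (1 - (1 - p)^n <= confidence) n <- n + 1
  as.integer(n)
}

#' Probability of at least one correct colony among n
#'
#' @param p Per-colony probability of a correct assembly, in `[0, 1]`.
#' @param n Number of colonies screened (>= 0).
#' @return `1 - (1-p)^n`.
#' @examples
#' success_probability(0.5, 2)  # 0.75
#' @export
success_probability <- function(p, n) {
  if (any(n < 0)) {
    abort("`n` must be >= 0.", class = "gibsim_error_input")
  }
  if (any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].", class = "gibsim_error_input")
  }
  1 - (1 - p)^n
}

#' Per-colony efficiency by fragment count
#'
#' Assembly efficiency decreases as the number of fragments (excluding the
#' backbone) grows. The package ships no authoritative per-count values:
#' supply measured efficiencies for your own reaction conditions, or use
#' [example_efficiency_table()] for an explicitly illustrative default.
#'
#' @param fragment_count Integer vector of insert counts.
#' @param p Per-colony correct-assembly probabilities in (0, 1], same
#'   length; must be non-increasing in `fragment_count`.
#' @return A tibble with columns `fragment_count` and `p`.
#' @export
efficiency_table <- function(fragment_count, p) {
  fragment_count <- as.integer(fragment_count)
  if (length(fragment_count) != length(p) || any(p <= 0) || any(p > 1)) {
    abort("`p` must match `fragment_count` and lie in (0, 1].",
          class = "gibsim_error_input")
  }
  ord <- order(fragment_count)
  if (is.unsorted(-p[ord])) {
    abort("Efficiencies must be non-increasing in fragment count.",
          class = "gibsim_error_input")
  }
  tibble(fragment_count = fragment_count[ord], p = p[ord])
}

#' Illustrative efficiency table
#'
#' An explicitly illustrative (not experimentally measured) efficiency
#' curve, chosen so that the standard colony guidance is reproduced at 99%
#' confidence: 0.80 for two inserts (3 colonies) and 0.65 for four inserts
#' (5 colonies), with a smooth decrease in between.
#'
#' @return An [efficiency_table()] tibble.
#' @export
example_efficiency_table <- function() {
  efficiency_table(1:4, c(0.90, 0.80, 0.72, 0.65))
}

#' Plan a one-pot assembly reaction
#'
#' Produces a pipetting sheet for one reaction: each insert is dispensed at
#' `insert_amount` pmol from its 57 nM stock, the insert pool is topped up
#' to `insert_volume_total` uL with buffer, the backbone is added at
#' `backbone_mass` ng, and `master_mix_volume` uL of isothermal master mix
#' completes the reaction. The plan also carries the 5X buffer and master
#' mix batch recipes (scaled to the requested number of reactions), the
#' incubation parameters, and - when an efficiency table covers the insert
#' count - the number of colonies to screen at the target confidence.
#'
#' @param parts A parts tibble (rows from [make_flanked_part()] or any
#'   tibble with `name` and `sequence`/`length`).
#' @param backbone A backbone row with `name` and `sequence`/`length`.
#' @param defaults A [reaction_defaults()] object.
#' @param efficiency An [efficiency_table()] or `NULL`.
#' @param n_reactions Number of reactions for the batch recipes.
#' @return A `gibsim_reaction_plan` object; `tidy()` returns the component
#'   table.
#' @export
reaction_plan <- function(parts, backbone, defaults = reaction_defaults(),
                          efficiency = NULL, n_reactions = 1L) {
  if (is.null(parts) || nrow(parts) == 0L) {
    abort("At least one insert is required.", class = "gibsim_error_input")
  }
  stopifnot(inherits(defaults, "gibsim_reaction_defaults"))
  part_len <- part_lengths(parts)
  insert_volume <- defaults$insert_amount / (defaults$stock_conc * 1e-3)
  components <- tibble(
    name = parts$name, role = "insert", length = part_len,
    stock_nM = defaults$stock_conc,
    volume_uL = insert_volume,
    amount_pmol = defaults$insert_amount,
    mass_ng = ds_dna_mass_for_amount(part_len, defaults$insert_amount))
  buffer_fill <- defaults$insert_volume_total - sum(components$volume_uL)
  if (buffer_fill < 0) {
    warn(sprintf(
      "Insert volumes (%.2f uL) exceed the %g uL insert pool; no buffer fill.",
      sum(components$volume_uL), defaults$insert_volume_total))
    buffer_fill <- 0
  }
  bb_len <- part_lengths(backbone)
  bb_pmol <- defaults$backbone_mass / (ds_dna_molar_mass(bb_len) * 1e-3)
  components <- bind_rows(
    components,
    tibble(name = "TE buffer", role = "buffer", length = NA_integer_,
           stock_nM = NA_real_, volume_uL = buffer_fill,
           amount_pmol = NA_real_, mass_ng = NA_real_),
    tibble(name = backbone$name[1], role = "backbone", length = bb_len,
           stock_nM = defaults$stock_conc,
           volume_uL = bb_pmol / (defaults$stock_conc * 1e-3),
           amount_pmol = bb_pmol, mass_ng = defaults$backbone_mass),
    tibble(name = "isothermal master mix", role = "master_mix",
           length = NA_integer_, stock_nM = NA_real_,
           volume_uL = defaults$master_mix_volume, amount_pmol = NA_real_,
           mass_ng = NA_real_))
  n_inserts <- nrow(parts)
  colonies <- NA_integer_
  colony_note <- "no efficiency table supplied; colonies_to_screen omitted"
  if (!is.null(efficiency)) {
    hit <- efficiency$p[match(n_inserts, efficiency$fragment_count)]
    if (!is.na(hit)) {
      colonies <- colonies_to_screen(hit, defaults$confidence)
      colony_note <- sprintf(
        "p = %.2f per colony at %d insert(s); > %.0f%% confidence",
        hit, n_inserts, 100 * defaults$confidence)
    } else {
      colony_note <- sprintf(
        "efficiency table has no entry for %d insert(s)", n_inserts)
    }
  }
  structure(
    list(components = components,
         incubation = list(temp_C = defaults$incubation_temp,
                           minutes = defaults$incubation_min),
         n_inserts = n_inserts,
         colonies_to_screen = colonies, colony_note = colony_note,
         buffer_recipe = isothermal_buffer_recipe(),
         master_mix = master_mix_recipe(n_reactions, defaults),
         n_reactions = n_reactions),
    class = "gibsim_reaction_plan")
}

part_lengths <- function(x) {
  if ("length" %in% names(x) && !all(is.na(x$length))) {
    as.integer(x$length)
  } else if ("sequence" %in% names(x)) {
    nchar(x$sequence)
  } else {
    abort("Parts need a `length` or `sequence` column.",
          class = "gibsim_error_input")
  }
}

#' 5X isothermal assembly buffer recipe
#'
#' One 6 mL batch: 3 mL of 1 M Tris-HCl (pH 7.5), 300 uL of 1 M MgCl2,
#' 600 uL of 10 mM dNTPs, 300 uL of 1 M DTT, 1.5 g PEG-8000, 20 mg NAD,
#' water to 6 mL. Final concentrations are derived from the batch volume
#' (Tris-HCl 500 mM, MgCl2 50 mM, and so on).
#'
#' @return A tibble with columns `component`, `stock`, `amount`, `unit`,
#'   `final_conc`, `final_unit`.
#' @export
isothermal_buffer_recipe <- function() {
  batch_mL <- 6
  tibble(
    component = c("Tris-HCl pH 7.5", "MgCl2", "dNTPs", "DTT", "PEG-8000",
                  "NAD", "water"),
    stock = c("1 M", "1 M", "10 mM", "1 M", "powder", "powder", ""),
    amount = c(3000, 300, 600, 300, 1.5, 20, NA),
    unit = c("uL", "uL", "uL", "uL", "g", "mg", "to 6 mL"),
    final_conc = c(3 / batch_mL * 1000, 0.3 / batch_mL * 1000,
                   0.6 * 10 / batch_mL, 0.3 / batch_mL * 1000,
                   1.5 / batch_mL * 100, 20 / batch_mL, NA),
    final_unit = c("mM", "mM", "mM", "mM", "% w/v", "mg/mL", "")
  )
}

#' Isothermal master mix recipe, scaled to a reaction count
#'
#' The stock batch combines 320 uL of 5X isothermal buffer, 1.2 uL of T5
#' exonuclease, 20 uL of Phusion polymerase, 160 uL of Taq ligase and
#' 700 uL of water (1201.2 uL, 80 reactions at 15 uL); the returned volumes
#' are scaled to `n_reactions`.
#'
#' @param n_reactions Number of 15 uL reactions to prepare for.
#' @param defaults A [reaction_defaults()] object.
#' @return A tibble with columns `component`, `batch_uL`, `scaled_uL`.
#' @export
master_mix_recipe <- function(n_reactions = 1L,
                              defaults = reaction_defaults()) {
  batch <- tibble(
    component = c("5X isothermal buffer", "T5 exonuclease",
                  "Phusion polymerase", "Taq ligase", "water"),
    batch_uL = c(320, 1.2, 20, 160, 700))
  total <- sum(batch$batch_uL)
  scale <- n_reactions * defaults$master_mix_volume / total
  batch$scaled_uL <- batch$batch_uL * scale
  batch
}

#' @export
print.gibsim_reaction_plan <- function(x, ...) {
  cat(sprintf("<reaction plan> %d insert(s) + backbone, incubate %g degC / %g min\n",
              x$n_inserts, x$incubation$temp_C, x$incubation$minutes))
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %-24s %7.2f uL%s\n", comp$name[i], comp$volume_uL[i],
                if (!is.na(comp$amount_pmol[i]))
                  sprintf("  (%.3f pmol, %.1f ng)", comp$amount_pmol[i],
                          comp$mass_ng[i]) else ""))
  }
  if (!is.na(x$colonies_to_screen)) {
    cat(sprintf("  screen %d colonies (%s)\n", x$colonies_to_screen,
                x$colony_note))
  } else {
    cat(sprintf("  colonies to screen: %s\n", x$colony_note))
  }
  invisible(x)
}

#' @export
tidy.gibsim_reaction_plan <- function(x, ...) {
  x$components
}

#' @export
glance.gibsim_reaction_plan <- function(x, ...) {
  tibble(n_inserts = x$n_inserts,
         total_volume_uL = sum(x$components$volume_uL, na.rm = TRUE),
         incubation_temp_C = x$incubation$temp_C,
         incubation_min = x$incubation$minutes,
         colonies_to_screen = x$colonies_to_screen)
}
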