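test_that("fixture generation is byte-identical under a fixed seed", {
  spec <- fixture_spec(seed = 7, core_length_range = c(80L, 200L),
                       stuffer_length = 500L)
  a <- generate_fixture_parts(spec)
  b <- generate_fixture_parts(spec)
  expect_identical(a, b)
  ba <- generate_fixture_backbone(spec)
  bb <- generate_fixture_backbone(spec)
  expect_identical(ba$plasmid$sequence, bb$plasmid$sequence)
  # a different seed changes the sequences
  other <- generate_fixture_parts(fixture_spec(seed = 8,
                                               core_length_range = c(80L, 200L),
                                               stuffer_length = 500L))
  expect_false(identical(a$sequence, other$sequence))
})

test_that("fixture cores are clean and classify to their declared slots", {
  fx <- small_fixture()
  expect_identical(nrow(fx$parts), 6L)
  for (i in seq_len(nrow(fx$parts))) {
    expect_length(fx$parts$warnings[[i]], 0L)
    expect_identical(classify_fragment(fx$parts$sequence[i]),
                     fx$parts$slot[i])
    report <- validate_part(fx$parts[i, ])
    expect_true(all(report$pass))
  }
  expect_setequal(fx$parts$slot, slot_grammar()$slot)
})

test_that("an unsatisfiable forbid list fails loudly", {
  spec <- fixture_spec(seed = 1, forbid_internal = c("A", "C", "G", "T"))
  expect_error(generate_fixture_parts(spec), class = "gibsim_error_fixture")
})

test_that("the (1,5) architecture releases its spacer with PmeI + BsrGI", {
  fx <- small_fixture()
  bb <- fx$backbone
  expect_identical(bb$expected_release, 469L)
  d <- digest(bb$plasmid$sequence, c("PmeI", "BsrGI"), circular = TRUE)
  expect_identical(length(d$fragment_lengths), 2L)
  expect_true(469L %in% d$fragment_lengths)
  expect_identical(sum(d$fragment_lengths), bb$plasmid$length)
  # the linear backbone carries sites #5 and #1 terminal, intact
  classified <- classify_backbone(bb$backbone$sequence)
  expect_identical(classified$chain_start_site, 1L)
  expect_identical(classified$chain_end_site, 5L)
  expect_length(bb$remnant, 0L)
})

test_that("the (2,5) architecture releases a 389 bp spacer with PmeI alone", {
  spec <- fixture_spec(seed = 13,
                       backbone_arch = list(chain_start = 2L, chain_end = 5L,
                                            spacer_length = 389L,
                                            enzymes = "PmeI"),
                       core_length_range = c(80L, 200L),
                       stuffer_length = 500L)
  bb <- generate_fixture_backbone(spec)
  d <- digest(bb$plasmid$sequence, "PmeI", circular = TRUE)
  expect_true(389L %in% d$fragment_lengths)
  expect_identical(length(d$fragment_lengths), 2L)
  classified <- classify_backbone(bb$backbone$sequence)
  expect_identical(classified$chain_start_site, 2L)
  expect_identical(classified$chain_end_site, 5L)
})

test_that("the (1,4) architecture releases 361 bp with PmeI + NheI, noting the remnant", {
  spec <- fixture_spec(seed = 13,
                       backbone_arch = list(chain_start = 1L, chain_end = 4L,
                                            spacer_length = 361L,
                                            enzymes = c("PmeI", "NheI")),
                       core_length_range = c(80L, 200L),
                       stuffer_length = 500L)
  expect_warning(bb <- generate_fixture_backbone(spec), "remnant")
  d <- digest(bb$plasmid$sequence, c("PmeI", "NheI"), circular = TRUE)
  expect_true(361L %in% d$fragment_lengths)
  expect_identical(sum(d$fragment_lengths), bb$plasmid$length)
  # NheI's sticky geometry cannot cut flush against site #4, so the
  # linearized backbone keeps the residual recognition bases
  expect_identical(unname(bb$remnant), "CTAGC")
  expect_true(startsWith(bb$backbone$sequence, "CTAGC"))
})

test_that("sites ending in GTTT joined to an AAAC spacer form the PmeI recognition", {
  site1 <- overlap_sites()$sequence[1]
  expect_true(endsWith(site1, "GGTTT"))
  # string concatenation check on the printed terminus
  expect_identical(paste0(substr(site1, 27, 30), "AAAC"), "GTTTAAAC")
  # realized in the (2,5) fixture: site #2 also ends ...GTTT
  spec <- fixture_spec(seed = 13,
                       backbone_arch = list(chain_start = 2L, chain_end = 5L,
                                            spacer_length = 389L,
                                            enzymes = "PmeI"),
                       stuffer_length = 500L)
  bb <- generate_fixture_backbone(spec)
  site2 <- overlap_sites()$sequence[2]
  idx <- regexpr(site2, bb$plasmid$sequence, fixed = TRUE)
  junction <- substr(bb$plasmid$sequence, idx + 30 - 4, idx + 30 + 3)
  expect_identical(junction, "GTTTAAAC")
  # in the (1,5) fixture BsrGI straddles site #1's terminal T instead
  fx <- small_fixture()
  plasmid <- fx$backbone$plasmid$sequence
  idx1 <- regexpr(overlap_sites()$sequence[1], plasmid, fixed = TRUE)
  expect_identical(substr(plasmid, idx1 + 30 - 1, idx1 + 30 + 4), "TGTACA")
})

test_that("a too-short spacer is rejected", {
  spec <- fixture_spec(seed = 1,
                       backbone_arch = list(chain_start = 2L, chain_end = 5L,
                                            spacer_length = 5L,
                                            enzymes = "PmeI"),
                       stuffer_length = 500L)
  expect_error(generate_fixture_backbone(spec),
               class = "gibsim_error_fixture")
})

test_that("the full offline pipeline holds over multiple seeds", {
  for (seed in c(101, 202, 303)) {
    spec <- fixture_spec(seed = seed, core_length_range = c(80L, 200L),
                         stuffer_length = 500L)
    parts <- generate_fixture_parts(spec)
    bb <- generate_fixture_backbone(spec)
    # redesign primers from the cores, re-amplify, re-classify
    redone <- lapply(seq_len(nrow(parts)), function(i) {
      pair <- design_part_primers(parts$core_sequence[i], parts$slot[i])
      simulate_pcr(parts$core_sequence[i], pair)
    })
    amplified <- dplyr::bind_rows(redone)
    expect_identical(amplified$sequence, parts$sequence)
    sel <- parts[parts$slot %in% c("pA", "gA", "pB", "gB"), ]
    product <- assemble(sel, bb$backbone)
    expect_identical(product$total_length,
                     sum(sel$length) + bb$backbone$length - 150L)
    expect_identical(product$junctions$site_id, 1:5)
    d <- digest(product$sequence, screening_panel(), circular = TRUE)
    expect_identical(sum(d$fragment_lengths), product$total_length)
  }
})
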