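test_that("make_flanked_part sandwiches the core between the slot's sites", {
  part <- make_flanked_part(strrep("ACGT", 10), "gB", "test_gene")
  expect_identical(part$length, 100L)  # 30 + 40 + 30
  sites <- overlap_sites()$sequence
  expect_true(startsWith(part$sequence, sites[4]))
  expect_true(endsWith(part$sequence, sites[5]))
  expect_identical(part$role, "gene")
  expect_length(part$warnings[[1]], 0L)
  # lowercase input is upcased
  lower <- make_flanked_part("acgtacgt", "pA")
  expect_identical(lower$core_sequence, "ACGTACGT")
})

test_that("make_flanked_part rejects bad cores and flags internal sites", {
  expect_error(make_flanked_part("", "gB"), class = "gibsim_error_input")
  err <- expect_error(make_flanked_part("ACGTXACGT", "gB"),
                      class = "gibsim_error_alphabet")
  expect_match(conditionMessage(err), "position 5")
  expect_error(make_flanked_part("ACGUACGU", "gB"),
               class = "gibsim_error_alphabet")
  # internal site #3 inside a gB core is a warning, not an error
  core <- paste0("ACGTACGTAC", overlap_sites()$sequence[3], "ACGTACGTAC")
  part <- make_flanked_part(core, "gB")
  expect_match(part$warnings[[1]], "site #3", all = FALSE)
  # internal screening recognition is flagged too
  part2 <- make_flanked_part("ACGTACCCGGGACGTA", "pA")
  expect_match(part2$warnings[[1]], "XmaI", all = FALSE)
})

test_that("classify_fragment recovers the slot from the terminal 30-mers", {
  sites <- overlap_sites()$sequence
  expect_identical(classify_fragment(paste0(sites[2], strrep("AC", 10),
                                            sites[5])), "gC")
  expect_identical(classify_fragment(paste0(sites[4], strrep("AC", 10),
                                            sites[5])), "gB")
  expect_identical(classify_fragment(paste0(sites[1], strrep("AC", 10),
                                            sites[4])), "pC")
  set.seed(5)
  expect_identical(classify_fragment(random_acgt(70)), NA_character_)
  expect_error(classify_fragment(random_acgt(59)),
               class = "gibsim_error_input")
})

test_that("classify_fragment inverts make_flanked_part for random cores", {
  set.seed(99)
  slots <- slot_grammar()$slot
  for (i in 1:30) {
    slot <- sample(slots, 1)
    core <- random_acgt(sample(1:500, 1))
    part <- make_flanked_part(core, slot)
    expect_identical(classify_fragment(part$sequence), slot)
  }
})

test_that("enumerate_fills reproduces the three canonical (1,5) designs", {
  fills <- enumerate_fills(chain_start = 1, chain_end = 5)
  expect_identical(fills$design, c("pA:gC", "pC:gB", "pA:gA:pB:gB"))
  expect_identical(fills$n_fragments, c(2L, 2L, 4L))
})

test_that("enumerate_fills matches exhaustive edge-subset search for every terminal pair", {
  for (i in 1:4) {
    for (j in (i + 1):5) {
      got <- enumerate_fills(chain_start = i, chain_end = j)$slots
      want <- oracle_enumerate_paths(i, j)
      expect_identical(length(got), length(want),
                       info = sprintf("termini (%d,%d)", i, j))
      got_str <- sort(vapply(got, paste, "", collapse = ":"))
      want_str <- sort(vapply(want, paste, "", collapse = ":"))
      expect_identical(got_str, want_str,
                       info = sprintf("termini (%d,%d)", i, j))
    }
  }
  # spot values derived from the oracle
  expect_identical(enumerate_fills(chain_start = 2, chain_end = 5)$design,
                   c("gC", "gA:pB:gB"))
  expect_identical(enumerate_fills(chain_start = 4, chain_end = 5)$design,
                   "gB")
})

test_that("validate_part passes builder output and fails mislabelled parts", {
  part <- make_flanked_part("ACGTACGTACGT", "pA")
  report <- validate_part(part)
  expect_true(all(report$pass[report$severity == "error"]))
  # relabel as pB: flanks no longer match
  bad <- part
  bad$slot <- "pB"
  rep2 <- validate_part(bad)
  fails <- rep2[rep2$severity == "error" & !rep2$pass, ]
  expect_true(any(grepl("flank", fails$check)))
  # internal-site warnings do not fail validation
  warned <- make_flanked_part(
    paste0("AAAA", overlap_sites()$sequence[2], "TTTT"), "gB")
  rep3 <- validate_part(warned)
  expect_true(all(rep3$pass[rep3$severity == "error"]))
  expect_false(rep3$pass[rep3$check == "no_internal_sites"])
})

test_that("backbone construction enforces terminal sites and ordering", {
  sites <- overlap_sites()$sequence
  bb <- new_backbone(paste0(sites[5], strrep("TTGACA", 30), sites[1]), 1, 5)
  expect_identical(bb$chain_start_site, 1L)
  expect_identical(bb$chain_end_site, 5L)
  expect_error(
    new_backbone(paste0(sites[5], strrep("TTGACA", 30), sites[2]), 1, 5),
    class = "gibsim_error_input")
  expect_error(new_backbone(paste0(sites[5], strrep("TTGACA", 30),
                                   sites[1]), 5, 1),
               class = "gibsim_error_input")
  classified <- classify_backbone(bb$sequence)
  expect_identical(classified$chain_start_site, 1L)
  expect_identical(classified$chain_end_site, 5L)
  set.seed(3)
  expect_null(classify_backbone(random_acgt(200)))
})
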