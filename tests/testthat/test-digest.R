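test_that("the packaged panel carries the standard recognitions", {
  enz <- restriction_enzymes()
  need <- c(XmaI = "CCCGGG", NheI = "GCTAGC", AvrII = "CCTAGG",
            AfeI = "AGCGCT", AscI = "GGCGCGCC", PmeI = "GTTTAAAC",
            BsrGI = "TGTACA")
  for (nm in names(need)) {
    expect_identical(enz$recognition[enz$enzyme == nm], unname(need[nm]))
  }
  expect_error(enzyme_spec("bad", "ACGQ", 1, 3),
               class = "gibsim_error_enzyme")
})

test_that("screening enzymes sit at offset 11 of their overlap sites", {
  sites <- overlap_sites()$sequence
  for (case in list(list(site = 2, enzyme = "NheI"),
                    list(site = 3, enzyme = "AvrII"),
                    list(site = 4, enzyme = "AfeI"))) {
    hits <- find_recognition_sites(sites[case$site], case$enzyme)
    expect_identical(hits$position, 11L)
    # independent string-search confirmation
    enz <- restriction_enzymes()
    rec <- enz$recognition[enz$enzyme == case$enzyme]
    expect_identical(as.integer(regexpr(rec, sites[case$site],
                                        fixed = TRUE)) - 1L, 11L)
  }
})

test_that("circular search finds origin-spanning sites exactly once", {
  # rotate a PmeI site across the origin
  base <- paste0("GTTTAAAC", strrep("ACGGT", 20))
  for (shift in c(0, 3, 5, 7)) {
    rotated <- paste0(substr(base, shift + 1, nchar(base)),
                      substr(base, 1, shift))
    hits <- find_recognition_sites(rotated, "PmeI", circular = TRUE)
    expect_identical(nrow(hits), 1L)
    oracle <- oracle_find_sites(rotated, "GTTTAAAC", circular = TRUE)
    expect_identical(hits$position[hits$strand == "+"], oracle$plus)
  }
  # linear search must not find the split site
  split <- paste0("AAAC", strrep("ACGGT", 20), "GTTT")
  expect_identical(nrow(find_recognition_sites(split, "PmeI")), 0L)
  expect_identical(nrow(find_recognition_sites(split, "PmeI",
                                               circular = TRUE)), 1L)
})

test_that("find_recognition_sites agrees with a rotate-and-scan oracle", {
  set.seed(101)
  panel <- restriction_enzymes()
  for (i in 1:6) {
    n <- sample(500:5000, 1)
    seq <- random_acgt(n)
    for (j in seq_len(nrow(panel))) {
      e <- panel[j, ]
      hits <- find_recognition_sites(seq, e, circular = TRUE)
      oracle <- oracle_find_sites(seq, e$recognition, circular = TRUE)
      expect_identical(sort(hits$position[hits$strand == "+"]),
                       sort(oracle$plus),
                       info = sprintf("%s on substrate %d", e$enzyme, i))
      expect_identical(sort(hits$position[hits$strand == "-"]),
                       sort(oracle$minus),
                       info = sprintf("%s minus strand, substrate %d",
                                      e$enzyme, i))
    }
  }
})

test_that("degenerate IUPAC recognitions match on both strands", {
  # XcmI-like degenerate pattern (symmetric as IUPAC: reported once per site)
  e <- enzyme_spec("degen", "CCANNNNNNNNNTGG", 8, 7)
  s <- paste0("TTTT", "CCA", "GATCGATCG", "TGG", "TTTT")
  hits <- find_recognition_sites(s, e)
  expect_identical(hits$position, 4L)
  expect_identical(hits$strand, "+")
  oracle <- oracle_find_sites(s, "CCANNNNNNNNNTGG")
  expect_identical(sort(hits$position[hits$strand == "+"]),
                   sort(oracle$plus))
  # a genuinely asymmetric pattern is searched on both strands
  e2 <- enzyme_spec("asym", "GGTCTC", 1, 5)  # BsaI-like
  s2 <- paste0("AAAA", "GGTCTC", "AAAA", revcomp("GGTCTC"), "AAAA")
  hits2 <- find_recognition_sites(s2, e2)
  expect_identical(nrow(hits2), 2L)
  expect_setequal(hits2$strand, c("+", "-"))
})

test_that("digest conserves length on circular and linear substrates", {
  # single-cut circle: one full-length fragment
  circ <- paste0(strrep("A", 50), "GTTTAAAC", strrep("C", 42))
  d1 <- digest(circ, "PmeI", circular = TRUE)
  expect_identical(d1$fragment_lengths, 100L)
  # two cuts: two fragments summing to the length
  two <- paste0("GTTTAAAC", strrep("A", 30), "GCTAGC", strrep("C", 26))
  d2 <- digest(two, c("PmeI", "NheI"), circular = TRUE)
  expect_identical(length(d2$fragment_lengths), 2L)
  expect_identical(sum(d2$fragment_lengths), 70L)
  # uncut circle
  d3 <- digest(strrep("ACGGT", 30), "PmeI", circular = TRUE)
  expect_identical(d3$fragment_lengths, 150L)
  expect_identical(nrow(d3$cuts), 0L)
  # linear substrate keeps end fragments
  lin <- paste0(strrep("A", 20), "GCTAGC", strrep("C", 24))
  d4 <- digest(lin, "NheI", circular = FALSE)
  expect_identical(length(d4$fragment_lengths), 2L)
  expect_identical(sum(d4$fragment_lengths), 50L)
  # random substrates, every panel enzyme, co-digestion
  set.seed(111)
  panel <- restriction_enzymes()
  for (i in 1:8) {
    n <- sample(300:5000, 1)
    s <- random_acgt(n)
    dc <- digest(s, panel, circular = TRUE)
    expect_identical(sum(dc$fragment_lengths), n)
    dl <- digest(s, panel, circular = FALSE)
    expect_identical(sum(dl$fragment_lengths), n)
  }
})

test_that("blunt and sticky cut offsets place the top-strand cut correctly", {
  s <- paste0(strrep("T", 10), "GCTAGC", strrep("T", 10))
  d <- digest(s, "NheI")
  expect_identical(d$cuts$cut_position, 11L)  # G^CTAGC
  s2 <- paste0(strrep("T", 10), "GTTTAAAC", strrep("T", 10))
  expect_identical(digest(s2, "PmeI")$cuts$cut_position, 14L)  # GTTT^AAAC
})

test_that("every site-2/3/4 junction of a four-insert product is cut", {
  fx <- small_fixture()
  product <- assemble(four_fragment_parts(fx), fx$backbone$backbone)
  for (enzyme in c("NheI", "AvrII", "AfeI")) {
    d <- digest(product$sequence, enzyme, circular = TRUE)
    expect_gte(nrow(d$cuts), 1L)
  }
})

test_that("digest tidiers and gel plot work", {
  d <- digest(paste0("GTTTAAAC", strrep("A", 30), "GCTAGC",
                     strrep("C", 26)),
              c("PmeI", "NheI"), circular = TRUE)
  td <- tidy(d)
  expect_identical(td$length, d$fragment_lengths)
  expect_identical(glance(d)$n_fragments, 2L)
  expect_s3_class(plot_gel(list(lane1 = d)), "ggplot")
  expect_match(gel_text(list(x = d))[1], "bp")
})
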