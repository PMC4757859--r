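test_that("find_junctions detects shared terminal 30-mers in both orientations", {
  sites <- overlap_sites()$sequence
  set.seed(71)
  a <- paste0(random_acgt(60), sites[2])
  b <- paste0(sites[2], random_acgt(60))
  frags <- tibble::tibble(name = c("A", "B"), sequence = c(a, b))
  g <- find_junctions(frags)
  fwd <- g[g$upstream == "A" & g$downstream == "B" &
             g$upstream_orientation == "forward" &
             g$downstream_orientation == "forward", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$overlap_length, 30L)
  expect_identical(fwd$site_id, 2L)
  # reverse-complemented downstream is found with orientation = reverse
  frags_rc <- tibble::tibble(name = c("A", "B"),
                             sequence = c(a, revcomp(b)))
  g2 <- find_junctions(frags_rc)
  hit <- g2[g2$upstream == "A" & g2$downstream == "B" &
              g2$upstream_orientation == "forward", ]
  expect_identical(hit$downstream_orientation, "reverse")
  # no shared 30-mer: empty graph
  set.seed(72)
  g3 <- find_junctions(tibble::tibble(name = c("x", "y"),
                                      sequence = c(random_acgt(60),
                                                   random_acgt(60))))
  expect_identical(nrow(g3), 0L)
  expect_error(find_junctions(frags[1, ]), class = "gibsim_error_input")
  expect_error(find_junctions(frags, min_overlap = 10),
               class = "gibsim_error_input")
})

test_that("terminal overlaps agree with a brute-force oracle", {
  set.seed(73)
  for (i in 1:25) {
    a <- random_acgt(sample(40:120, 1))
    ov_len <- sample(15:35, 1)
    b <- paste0(substr(a, nchar(a) - ov_len + 1, nchar(a)),
                random_acgt(sample(40:120, 1)))
    g <- find_junctions(tibble::tibble(name = c("a", "b"),
                                       sequence = c(a, b)),
                        min_overlap = 15)
    fwd <- g[g$upstream == "a" & g$downstream == "b" &
               g$upstream_orientation == "forward" &
               g$downstream_orientation == "forward", ]
    expect_identical(fwd$overlap_length[1],
                     as.integer(oracle_overlap(a, b, 15)))
  }
})

test_that("a four-insert assembly conserves length and orders sites 1..5", {
  fx <- small_fixture()
  parts <- four_fragment_parts(fx)
  bb <- fx$backbone$backbone
  product <- assemble(parts, bb)
  expect_s3_class(product, "gibson_assembly")
  expect_identical(product$total_length,
                   sum(parts$length) + bb$length - 5L * 30L)
  expect_identical(product$junctions$site_id, c(1L, 2L, 3L, 4L, 5L))
  expect_identical(product$backbone, bb$name)
  # rotation convention: product starts at the backbone's first base
  expect_true(startsWith(product$sequence, substr(bb$sequence, 1, 60)))
  expect_identical(sum(product$junctions$overlap_length), 150L)
  expect_length(product$warnings, 0L)
})

test_that("a missing part yields an incomplete error naming the gap sites", {
  fx <- small_fixture()
  parts <- fx$parts[fx$parts$slot %in% c("pA", "gA", "gB"), ]
  err <- expect_error(assemble(parts, fx$backbone$backbone),
                      class = "gibsim_error_incomplete_assembly")
  expect_match(conditionMessage(err), "site #3")
  expect_match(conditionMessage(err), "site #4")
})

test_that("competing parts yield an ambiguity error enumerating products", {
  fx <- small_fixture()
  parts <- fx$parts[fx$parts$slot %in% c("pC", "gB"), ]
  dup <- make_flanked_part(strrep("CAGTT", 40), "gB", "second_gB")
  err <- expect_error(
    assemble(dplyr::bind_rows(parts, dup), fx$backbone$backbone),
    class = "gibsim_error_ambiguous_assembly")
  expect_match(conditionMessage(err), "2 distinct circular products")
})

test_that("assembly is invariant under fragment shuffling and strand flipping", {
  fx <- small_fixture()
  parts <- four_fragment_parts(fx)
  bb <- fx$backbone$backbone
  reference <- assemble(parts, bb)$sequence
  set.seed(81)
  for (rep in 1:8) {
    shuffled <- parts[sample(nrow(parts)), ]
    flip <- runif(nrow(shuffled)) < 0.5
    shuffled$sequence[flip] <- revcomp(shuffled$sequence[flip])
    product <- assemble(shuffled, bb)
    expect_identical(product$sequence, reference)
  }
})

test_that("enumerate_products matches exhaustive expectations on small pools", {
  fx <- small_fixture()
  bb <- fx$backbone$backbone
  pool2 <- dplyr::bind_rows(
    fx$parts[fx$parts$slot %in% c("pC", "gB"), ],
    tibble::tibble(name = bb$name, sequence = bb$sequence))
  prods <- enumerate_products(pool2)
  expect_length(prods, 1L)
  expect_false(attr(prods, "truncated"))
  # pC:gB and pA:gC both close the same backbone: two distinct circles
  pool4 <- dplyr::bind_rows(
    fx$parts[fx$parts$slot %in% c("pC", "gB", "pA", "gC"), ],
    tibble::tibble(name = bb$name, sequence = bb$sequence))
  prods4 <- enumerate_products(pool4)
  expect_length(prods4, 2L)
  lens <- sort(vapply(prods4, function(p) p$total_length, integer(1)))
  p_pcgb <- assemble(fx$parts[fx$parts$slot %in% c("pC", "gB"), ], bb)
  p_pagc <- assemble(fx$parts[fx$parts$slot %in% c("pA", "gC"), ], bb)
  expect_identical(lens, sort(c(p_pcgb$total_length, p_pagc$total_length)))
  # the cap sets the truncation flag
  capped <- enumerate_products(pool4, max_products = 1)
  expect_length(capped, 1L)
  expect_true(attr(capped, "truncated"))
  # empty pool
  empty <- enumerate_products(tibble::tibble(name = character(0),
                                             sequence = character(0)))
  expect_length(empty, 0L)
})

test_that("products deduplicate up to rotation and reverse complement", {
  fx <- small_fixture()
  parts <- fx$parts[fx$parts$slot %in% c("pA", "gC"), ]
  bb <- fx$backbone$backbone
  pool <- dplyr::bind_rows(parts,
                           tibble::tibble(name = bb$name,
                                          sequence = bb$sequence))
  pool_rc <- pool
  pool_rc$sequence <- revcomp(pool_rc$sequence)
  p1 <- enumerate_products(pool)
  p2 <- enumerate_products(pool_rc)
  expect_identical(p1[[1]]$canonical_sequence, p2[[1]]$canonical_sequence)
})

test_that("tidy/glance/autoplot summarize an assembly", {
  fx <- small_fixture()
  product <- assemble(four_fragment_parts(fx), fx$backbone$backbone)
  td <- tidy(product)
  expect_identical(nrow(td), 5L)
  expect_true(all(c("upstream", "downstream", "overlap_length", "site_id",
                    "position") %in% names(td)))
  gl <- glance(product)
  expect_identical(gl$n_fragments, 5L)
  expect_identical(gl$total_length, product$total_length)
  p <- autoplot(product)
  expect_s3_class(p, "ggplot")
})

test_that("stray internal homology to a junction raises a product warning", {
  sites <- overlap_sites()$sequence
  set.seed(91)
  bb <- new_backbone(paste0(sites[5], random_acgt(200), sites[1]), 1, 5)
  # gC part whose core carries an internal copy of site #1
  core <- paste0(random_acgt(50), sites[1], random_acgt(50))
  parts <- dplyr::bind_rows(
    make_flanked_part(random_acgt(120), "pA", "pA1"),
    make_flanked_part(core, "gC", "gC_hot"))
  product <- assemble(parts, bb)
  expect_match(product$warnings, "site #1", all = FALSE)
})
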