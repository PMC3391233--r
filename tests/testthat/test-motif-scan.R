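# CCCH motif scanner: consensus matching, overlap resolution, tallies,
# histograms and logo profiles.

test_that("minimal and degenerate inputs scan correctly", {
  hit <- find_motifs("CAAAACAAAACAAAH")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1)
  expect_equal(hit$end, 15)
  expect_equal(c(hit$a, hit$b, hit$c), c(4, 4, 3))
  expect_equal(hit$signature, "C-X4-C-X4-C-X3-H")

  expect_equal(nrow(find_motifs("AAAAAAAAAA")), 0)
  expect_equal(nrow(find_motifs("")), 0)
  expect_error(find_motifs("CAAB1"), "position 4")
})

test_that("X matches spacers but never anchors", {
  expect_equal(nrow(find_motifs("CXXXXCXXXXCXXXH")), 1)
  # X in place of the first anchor C
  expect_equal(nrow(find_motifs("XAAAACAAAACAAAH")), 0)
  # X in place of the H
  expect_equal(nrow(find_motifs("CAAAACAAAACAAAX")), 0)
})

test_that("signatures render deterministically", {
  expect_equal(motif_signature(8, 5), "C-X8-C-X5-C-X3-H")
  expect_equal(motif_signature(4, 4), "C-X4-C-X4-C-X3-H")
  expect_equal(motif_signature(17, 6), "C-X17-C-X6-C-X3-H")
})

test_that("ambiguous parses follow the shortest-span policy and match the oracle", {
  # two valid parses share the second C: C-X4-C-X4-C-X3-H starting at 1 and
  # an alternative using a later H; the compact leftmost parse wins
  seq <- "CAAAACAAAACAAAHAAACAAAH"
  got <- find_motifs(seq)
  ora <- oracle_find_motifs(seq)
  expect_equal(as.data.frame(got[, c("start", "end", "a", "b")]),
               ora, ignore_attr = TRUE)
  expect_equal(got$start[1], 1)
})

test_that("scanner equals exhaustive enumeration on random short sequences", {
  withr::with_seed(42, {
    for (i in 1:40) {
      seq <- random_protein(sample(20:80, 1))
      got <- as.data.frame(find_motifs(seq)[, c("start", "end", "a", "b")])
      ora <- oracle_find_motifs(seq)
      expect_equal(got, ora, ignore_attr = TRUE)
    }
  })
})

test_that("hits are non-overlapping and re-match the consensus", {
  withr::with_seed(7, {
    for (i in 1:15) {
      seq <- random_protein(120)
      hits <- find_motifs(seq)
      if (nrow(hits) > 1) {
        expect_true(all(hits$start[-1] > hits$end[-nrow(hits)]))
      }
      for (r in seq_len(nrow(hits))) {
        ch <- strsplit(seq, "")[[1]]
        s <- hits$start[r]; a <- hits$a[r]; b <- hits$b[r]
        expect_equal(ch[s], "C")
        expect_equal(ch[s + a + 1], "C")
        expect_equal(ch[s + a + b + 2], "C")
        expect_equal(ch[hits$end[r]], "H")
        expect_equal(hits$end[r] - s, a + b + 3 + 3)
      }
    }
  })
})

test_that("widening spacer bounds never loses candidate parses", {
  withr::with_seed(11, {
    for (i in 1:10) {
      seq <- random_protein(100)
      ch <- strsplit(seq, "")[[1]]
      narrow <- ccchsurvey:::ccch_candidates(ch, ccch_bounds(a_max = 15))
      wide <- ccchsurvey:::ccch_candidates(ch, ccch_bounds(a_max = 17))
      expect_gte(nrow(wide), nrow(narrow))
    }
  })
})

test_that("class tallies report half-up one-decimal percentages", {
  hits <- tibble::tibble(
    signature = rep(c("C-X8-C-X5-C-X3-H", "C-X7-C-X5-C-X3-H", "other"),
                    c(98, 45, 37))
  )
  tal <- tally_classes(hits)
  expect_equal(attr(tal, "total"), 180)
  expect_equal(tal$percentage[tal$signature == "C-X8-C-X5-C-X3-H"], 54.4)
  expect_equal(tal$percentage[tal$signature == "C-X7-C-X5-C-X3-H"], 25.0)
  expect_equal(sum(tal$count), 180)
  expect_lt(abs(sum(tal$percentage) - 100), 0.2)

  single <- tally_classes(tibble::tibble(signature = "C-X8-C-X5-C-X3-H"))
  expect_equal(single$percentage, 100)
  empty <- tally_classes(tibble::tibble(signature = character()))
  expect_equal(attr(empty, "total"), 0L)
})

test_that("per-protein histograms cover 1..max and report zero-hit proteins", {
  hits <- tibble::tibble(protein_id = rep(c("p1", "p2", "p3"), c(7, 1, 1)))
  h <- count_histogram(hits, protein_ids = c("p1", "p2", "p3", "p4"))
  expect_equal(h$n_motifs, 1:7)
  expect_equal(h$n_proteins[h$n_motifs == 7], 1)
  expect_equal(h$n_proteins[h$n_motifs == 1], 2)
  expect_equal(sum(h$n_proteins[h$n_motifs %in% 2:6]), 0)
  expect_equal(attr(h, "zero_hit_proteins"), "p4")
})

test_that("logo profiles have unit columns, anchored C/H, and correct entropy", {
  hits <- find_motifs("CAAAACAAAACAAAH")
  hits <- hits[rep(1, 10), ]
  logo <- build_logo(hits)
  expect_equal(colSums(logo$freq), rep(1, logo$width), ignore_attr = TRUE)
  expect_equal(logo$ic, rep(log2(20), logo$width), tolerance = 1e-12)
  for (col in logo$anchor_cols[c("first_C", "second_C", "third_C")]) {
    expect_equal(unname(logo$freq["C", col]), 1)
  }
  expect_equal(unname(logo$freq["H", logo$anchor_cols["H"]]), 1)

  # a column uniform over the 20 residues carries 0 bits
  subs <- paste0("C", AA_LETTERS, "AAAC", "AAAA", "C", "AAA", "H")
  hits20 <- tibble::tibble(start = 1, end = nchar(subs[1]), a = 4, b = 4,
                           c = 3, signature = "C-X4-C-X4-C-X3-H",
                           subsequence = subs)
  logo20 <- build_logo(hits20)
  expect_equal(logo20$ic[2], 0, tolerance = 1e-12)
  expect_equal(logo20$freq[, 2], rep(1 / 20, 20), ignore_attr = TRUE)
})

test_that("planted column biases are recovered in logo frequencies", {
  # 98 motifs with F at 60% and Y at 40% in the first spacer position
  res <- c(rep("F", 59), rep("Y", 39), rep("F", 0))
  subs <- vapply(res, function(r) {
    paste0("C", r, "AAAAAAAC", "AAAAA", "C", "AAA", "H")
  }, character(1))
  hits <- tibble::tibble(start = 1, end = nchar(subs[1]), a = 8, b = 5,
                         c = 3, signature = "C-X8-C-X5-C-X3-H",
                         subsequence = unname(subs))
  logo <- build_logo(hits)
  expect_equal(unname(logo$freq["F", 2]), 59 / 98, tolerance = 1e-12)
  expect_equal(unname(logo$freq["Y", 2]), 39 / 98, tolerance = 1e-12)
})

test_that("combined logos right-justify on the second C", {
  h7 <- find_motifs(paste0("C", strrep("A", 7), "C", strrep("A", 5),
                           "C", "AAA", "H"))
  h8 <- find_motifs(paste0("C", strrep("G", 8), "C", strrep("G", 5),
                           "C", "GGG", "H"))
  logo <- build_logo(dplyr::bind_rows(h7, h8))
  expect_equal(logo$width, 8 + 5 + 3 + 4)
  # anchors beyond the variable spacer align exactly
  expect_equal(unname(logo$freq["C", logo$anchor_cols["second_C"]]), 1)
  expect_equal(unname(logo$freq["C", logo$anchor_cols["third_C"]]), 1)
  expect_equal(unname(logo$freq["H", logo$anchor_cols["H"]]), 1)
  # first column only covered by the longer class
  expect_equal(logo$n[1], 1)
  expect_error(build_logo(h7[0, ]), "empty")
})

test_that("tidy and glance expose the logo profile", {
  logo <- build_logo(find_motifs("CAAAACAAAACAAAH"))
  td <- generics::tidy(logo)
  expect_equal(nrow(td), 20 * logo$width)
  expect_equal(sum(td$freq), logo$width)
  gl <- generics::glance(logo)
  expect_equal(gl$n_motifs, 1)
  expect_s3_class(ggplot2::autoplot(logo), "ggplot")
})
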