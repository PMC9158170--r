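test_that("transcript enumeration is the product of event cardinalities", {
  g <- fixture_gene()
  # brute-force oracle: product of event outcome counts
  card <- function(events) {
    n_skip <- vapply(events$skip, function(i) 2L, integer(1))
    n_site <- vapply(events$site, function(i) {
      length(baitquant:::exon_sites(baitquant:::get_exon(g, i)))
    }, integer(1))
    prod(c(n_skip, n_site, 1L))
  }
  cases <- list(
    list(skip = integer(), site = integer()),          # constitutive only
    list(skip = c(12L, 14L), site = 15L),              # the 12 variable forms
    list(skip = c(12L, 14L), site = c(15L, 17L)),      # + exon-17 site: 24
    list(skip = 14L, site = integer())
  )
  for (ev in cases) {
    specs <- enumerate_transcripts(g, ev)
    expect_length(specs, card(ev))
    labs <- vapply(specs, baitquant:::spec_label, character(1))
    expect_false(anyDuplicated(labs) > 0)
  }
  expect_length(enumerate_transcripts(g, list(skip = c(12, 14), site = 15)), 12L)
  expect_error(enumerate_transcripts(g, list(skip = 99L)), "optional exons")
  expect_error(enumerate_transcripts(g, list(site = 13L)), "multi-acceptor")
})

test_that("splicing concatenates retained exons and records junctions", {
  g <- toy_gene()
  # no events: all five exons at default sites
  full <- splice_transcript(g, transcript_spec(c(`3` = TRUE), c(`4` = "A")))
  expect_identical(nchar(full$sequence), 60L + 40L + 66L + 55L + 90L)
  expect_identical(full$junctions, c(60L, 100L, 166L, 221L))
  expect_identical(substr(full$sequence, 1, 60), g$exons[["exon1"]]$sequence)
  # skipping the middle optional exon joins its flanks
  skip <- splice_transcript(g, transcript_spec(c(`3` = FALSE), c(`4` = "A")))
  expect_identical(nchar(skip$sequence), 60L + 40L + 55L + 90L)
  expect_identical(skip$junctions, c(60L, 100L, 155L))
  # acceptor site B trims 21 nt from the exon's 5' end
  b <- splice_transcript(g, transcript_spec(c(`3` = TRUE), c(`4` = "B")))
  expect_identical(nchar(b$sequence), nchar(full$sequence) - 21L)
  expect_identical(substr(b$sequence, 167, 167 + 33),
                   substr(g$exons[["exon4"]]$sequence, 22, 22 + 33))
  expect_error(splice_transcript(g, transcript_spec(c(`9` = TRUE))),
               "not optional")
})

test_that("spliced length equals included exon lengths minus site offsets", {
  g <- fixture_gene()
  exlen <- vapply(g$exons, function(e) nchar(e$sequence), integer(1))
  names(exlen) <- as.character(baitquant:::exon_indices(g))
  for (sp in enumerate_transcripts(g)) {
    seg <- splice_transcript(g, sp)$segments
    expect_identical(nchar(splice_transcript(g, sp)$sequence),
                     as.integer(sum(exlen[as.character(seg$exon)]) -
                                  sum(seg$offset)))
  }
})

test_that("junction baits are substrings of exactly the transcripts using them", {
  g <- fixture_gene()
  baits <- fixture_baits()
  specs <- enumerate_transcripts(g)
  for (b in baits) {
    if (is.na(b$junction_offset)) next
    for (sp in specs) {
      tx <- splice_transcript(g, sp)
      carries <- baitquant:::junction_in_segments(tx$segments, b$donor,
                                                  b$acceptor, b$site)
      expect_identical(grepl(b$sequence, tx$sequence, fixed = TRUE), carries,
                       info = paste(b$bait_id, baitquant:::spec_label(sp)))
    }
  }
})
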