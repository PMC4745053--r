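count_matches <- function(svg, pattern) {
  lengths(regmatches(svg, gregexpr(pattern, svg, fixed = TRUE)))
}

demo_primers <- function() {
  data.frame(source_id = c("r1", "r1", "r1"), name = c("83", "120", "554"),
             orientation = c("forward", "forward", "reverse"),
             start = c(83L, 120L, 554L), length = c(19L, 20L, 20L),
             sequence = c(strrep("A", 19), strrep("C", 20), strrep("G", 20)),
             tm = c(55, 56, 57), gc_percent = c(40, 100, 100),
             selfcomp = c(0L, 0L, 0L), hairpin_dg = c(0, 0, 0),
             stringsAsFactors = FALSE)
}

test_that("positional records apply the naming-coordinate arithmetic", {
  pos <- positional_records(demo_primers())
  expect_equal(pos$start, c(83L, 120L, 535L))
  expect_equal(pos$end, c(101L, 139L, 554L))
  expect_equal(pos$strand, c("+", "+", "-"))
  expect_equal(pos$end - pos$start + 1L, demo_primers()$length)
  expect_equal(nrow(pos), nrow(demo_primers()))
})

test_that("positional TSV round-trips byte-identically", {
  pos <- positional_records(demo_primers())
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_positions_tsv(pos, f1)
  write_positions_tsv(read_positions_tsv(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_positions_tsv(f1), pos)
})

test_that("per-sequence map draws one glyph per primer plus ruler and SNP marker", {
  set.seed(97)
  rec <- data.frame(id = "r1", description = "demo record",
                    residues = random_dna(1, 600), stringsAsFactors = FALSE)
  pos <- positional_records(demo_primers())
  svg <- render_sequence_map(rec, pos, pixels_per_base = 1)
  expect_equal(count_matches(svg, 'class="primer"'), 3L)
  expect_equal(count_matches(svg, 'class="ruler"'), 1L)
  expect_equal(count_matches(svg, 'class="snp"'), 0L)
  # 1 px/base: glyph for (83, 101) spans margin+82 .. margin+101 user units
  expect_match(svg, 'points="112,')
  svg_snp <- render_sequence_map(rec, pos, snp_position = 300,
                                 pixels_per_base = 1)
  expect_equal(count_matches(svg_snp, 'class="snp"'), 1L)
  # pure function
  expect_identical(svg, render_sequence_map(rec, pos, pixels_per_base = 1))
  out_of_range <- pos
  out_of_range$end[1] <- 9999L
  expect_error(render_sequence_map(rec, out_of_range), "out of range")
})

test_that("concatenated map lays records end-to-end at cumulative offsets", {
  set.seed(101)
  recs <- data.frame(id = c("a", "b"), description = "",
                     residues = c(random_dna(1, 100), random_dna(1, 200)),
                     stringsAsFactors = FALSE)
  expect_equal(unname(global_offsets(recs)), c(0L, 100L))
  pos <- data.frame(source_id = c("a", "b"), name = c("5", "10"),
                    start = c(5L, 10L), end = c(24L, 29L),
                    strand = c("+", "+"),
                    sequence = c(strrep("A", 20), strrep("A", 20)),
                    stringsAsFactors = FALSE)
  svg <- render_concatenated_map(recs, pos, pixels_per_base = 1)
  # local start 10 of record 2 -> global 110 -> x = margin + 109
  expect_match(svg, 'points="139,')
  expect_equal(count_matches(svg, 'class="primer"'),
               sum(vapply(c("a", "b"), function(id) {
                 count_matches(render_sequence_map(recs[recs$id == id, ],
                                                   pos[pos$source_id == id, ]),
                               'class="primer"')
               }, 1L)))
  expect_equal(count_matches(svg, 'class="boundary"'), 2L)
  expect_identical(svg, render_concatenated_map(recs, pos,
                                                pixels_per_base = 1))
})

test_that("coordinate drawing returns forward or reverse primers by direction", {
  rec <- data.frame(id = "r", residues = "ATGCATGCCC",
                    stringsAsFactors = FALSE)
  fwd <- primer_from_coordinates(rec, 1, 8)
  expect_equal(fwd$sequence, "ATGCATGC")
  expect_equal(fwd$orientation, "forward")
  rev <- primer_from_coordinates(rec, 8, 1)
  expect_equal(rev$sequence, "GCATGCAT")
  expect_equal(rev$orientation, "reverse")
  expect_equal(rev$sequence, reverse_complement(fwd$sequence))
  expect_equal(fwd$gc_percent, 50)
  expect_error(primer_from_coordinates(rec, 3, 3), "differ")
  expect_error(primer_from_coordinates(rec, 1, 11), "out of range")
  expect_error(primer_from_coordinates(rec, 1, 5), "shorter than 8")
})

test_that("JSON export writes one parseable object per primer", {
  pos <- positional_records(demo_primers())
  path <- tempfile(fileext = ".json")
  write_primers_json(pos, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(pos))
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_equal(vapply(parsed, `[[`, character(1), "name"), pos$name)
  expect_equal(vapply(parsed, `[[`, 1L, "start"), pos$start)
  expect_equal(vapply(parsed, `[[`, character(1), "strand"), pos$strand)
})
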