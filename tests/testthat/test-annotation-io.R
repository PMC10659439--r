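test_that("branch notation parses canonical and bare forms", {
  a <- parse_branch_notation("starts(1;13);secs(25)")
  expect_equal(a$starts, c(1L, 13L))
  expect_equal(a$secs, 25L)

  a <- parse_branch_notation("starts(1);shifts(100,99)")
  expect_equal(a$starts, 1L)
  expect_equal(a$shifts, data.frame(i = 100L, s = 99L))

  ## the bare parenthesis-free legacy form
  a <- parse_branch_notation("starts1;13;shifts100,99")
  expect_equal(a$starts, c(1L, 13L))
  expect_equal(a$shifts$s, 99L)

  ## whitespace is ignored
  a <- parse_branch_notation(" starts( 1 ; 13 ) ; secs(25) ")
  expect_equal(a$starts, c(1L, 13L))
})

test_that("unknown clauses warn and are ignored (forward compatibility)", {
  expect_warning(a <- parse_branch_notation("starts(1);wobble(7)"),
                 "unknown clause 'wobble'")
  expect_equal(a$starts, 1L)
  expect_equal(a$secs, integer())
})

test_that("malformed notation fails with an offset", {
  expect_error(parse_branch_notation("starts(1;x)"), "offset",
               class = "rdg_parse_error")
  expect_error(parse_branch_notation("starts(1"), "unclosed",
               class = "rdg_parse_error")
  expect_error(parse_branch_notation("starts(1);shifts(100)"),
               class = "rdg_parse_error")
})

test_that("formatting is canonical and round-trips", {
  expect_equal(format_branch_notation(branch_annotation(starts = c(5, 20))),
               "starts(5;20)")
  expect_equal(
    format_branch_notation(branch_annotation(starts = 1,
                                             shifts = list(c(100, 101)))),
    "starts(1);shifts(100,101)")
})

test_that("parse(format(a)) is the identity on random annotations", {
  set.seed(99)
  for (k in 1:500) {
    starts <- sort(sample(1:5000, sample(1:6, 1)))
    secs <- if (runif(1) < 0.4) sort(sample(5001:6000, sample(1:2, 1))) else integer()
    shifts <- if (runif(1) < 0.4) {
      i <- sample(6001:7000, 1)
      list(c(i, i + sample(c(-1L, 1L, 50L), 1)))
    } else NULL
    a <- branch_annotation(starts = starts, secs = secs, shifts = shifts)
    b <- parse_branch_notation(format_branch_notation(a))
    expect_equal(b$starts, a$starts)
    expect_equal(b$secs, a$secs)
    expect_equal(b$shifts, a$shifts)
  }
})

test_that("annotation validation enforces bounds and codon identity", {
  tx <- transcript("t", "ccAUGgccUAAgcgcc")
  expect_silent(validate_annotation(branch_annotation(starts = 3), tx))
  expect_error(validate_annotation(branch_annotation(starts = 4), tx),
               "not in start set", class = "rdg_validation_error")
  expect_error(validate_annotation(branch_annotation(starts = 100), tx),
               class = "rdg_validation_error")
  expect_error(validate_annotation(branch_annotation(starts = 3, secs = 5), tx),
               "not a stop", class = "rdg_validation_error")
  expect_silent(validate_annotation(branch_annotation(starts = 3, secs = 9), tx))
  expect_error(branch_annotation(starts = c(10, 5)), class = "rdg_validation_error")
  expect_error(branch_annotation(starts = 3, shifts = list(c(7, 7))),
               class = "rdg_validation_error")
})

test_that("RDG JSON export/import reconstructs an equivalent graph", {
  r <- fixture_rdg("fig3")
  f <- withr::local_tempfile(fileext = ".json")
  export_rdg_json(r$g, f)
  g2 <- import_rdg_json(f)
  expect_equal(sort(g2$nodes$id), sort(r$g$nodes$id))
  ord <- function(e) e[order(e$from, e$to), c("from", "to", "kind")]
  expect_equal(ord(g2$edges), ord(r$g$edges), ignore_attr = TRUE)
  expect_equal(names(g2$translons), names(r$g$translons))
  expect_equal(format_branch_notation(g2$annotation),
               format_branch_notation(r$g$annotation))
})

test_that("empty-annotation RDG exports are empty but well-formed", {
  tx <- transcript("t", strrep("GCA", 30))
  g <- build_rdg(tx, branch_annotation())
  expect_equal(nrow(branch_points(g)), 0L)
  f <- withr::local_tempfile(fileext = ".gff3")
  export_translons_gff(g, f)
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), 0L)
  j <- withr::local_tempfile(fileext = ".json")
  export_rdg_json(g, j)
  doc <- jsonlite::read_json(j)
  expect_equal(length(doc$translons), 0L)
})

test_that("fig3 GFF3 carries nested translon intervals; BED and GFF agree", {
  r <- fixture_rdg("fig3")
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  export_translons_gff(r$g, gff)
  export_translons_bed(r$g, bed)
  g <- rtracklayer::import(gff)
  tr <- g[g$type == "translon"]
  expect_equal(length(tr), 3L)
  t2 <- tr[tr$ID == "T2"]; t3 <- tr[tr$ID == "T3"]
  ## the CUG-extended translon strictly contains the AUG translon
  expect_true(GenomicRanges::start(t3) < GenomicRanges::start(t2))
  expect_true(GenomicRanges::end(t3) >= GenomicRanges::end(t2))
  b <- rtracklayer::import(bed)
  expect_equal(sort(b$name), sort(tr$ID))
  ## BED (0-based half-open on disk) and GFF3 (1-based) describe the same spans
  m <- match(b$name, tr$ID)
  expect_equal(GenomicRanges::start(b), GenomicRanges::start(tr)[m])
  expect_equal(GenomicRanges::end(b), GenomicRanges::end(tr)[m])
})

test_that("a frameshift translon exports as a multi-block BED record", {
  r <- fixture_rdg("peg10_like")
  bed <- withr::local_tempfile(fileext = ".bed")
  export_translons_bed(r$g, bed)
  b <- rtracklayer::import(bed)
  expect_equal(length(b$blocks[[1]]), 2L)
  segs <- r$g$translons$T1$segments
  ## block spans match the decoded segments (the -1 re-read nt clipped)
  bl <- b$blocks[[1]]
  expect_equal(GenomicRanges::start(b) + GenomicRanges::start(bl) - 1L,
               c(segs$begin[1], segs$begin[2] + 1L))
})

test_that("footprint tracks round-trip through bedGraph and TSV", {
  tx <- transcript("t", strrep("GCA", 40))
  set.seed(1)
  tr <- footprint_track(tx, rpois(120, 2))
  for (fmt in c("bedgraph", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_track(tr, f, fmt)
    back <- read_track(f, tx, if (fmt == "tsv") "tsv" else "bedgraph")
    expect_equal(back$counts, tr$counts)
  }
})
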