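leader_tx <- function() {
  ## 30 nt leader, CDS at 31
  transcript("t", paste0(strrep("GCA", 10), "AUG", strrep("GCU", 8), "UAA",
                         strrep("GCA", 4)), cds_start = 31L)
}

test_that("HGVS-like strings parse into transcript coordinates", {
  tx <- leader_tx()
  v <- parse_variant("c.-10_-9insU", tx)
  expect_equal(v$type, "ins")
  expect_equal(v$pos, 21L)           # c.-10 == position 21
  expect_equal(v$alt, "U")

  v <- parse_variant("c.2U>C", tx)   # second nt of the start codon
  expect_equal(v$pos, 32L)
  expect_equal(v$ref, "U")

  v <- parse_variant("5C>G", tx)     # plain transcript coordinate
  expect_equal(v$pos, 5L)

  v <- parse_variant("c.-3_-1del", tx)
  expect_equal(v$type, "del")
  expect_equal(v$pos, 28L)
  expect_equal(nchar(v$ref), 3L)

  expect_error(parse_variant("c.5dup", tx), class = "rdg_unsupported_form_error")
  expect_error(parse_variant("c.-10_-8insU", tx),
               class = "rdg_unsupported_form_error")
})

test_that("reference mismatches are reported with expected vs found", {
  tx <- leader_tx()
  err <- tryCatch(parse_variant("5A>G", tx), error = identity)
  expect_s3_class(err, "rdg_ref_mismatch_error")
  expect_match(conditionMessage(err), "expected 'A', found 'C'")
})

test_that("c. coordinates require an annotated CDS start", {
  tx <- transcript("t", strrep("GCA", 20))
  expect_error(parse_variant("c.-5A>G", tx), class = "rdg_validation_error")
})

test_that("applying a 5' leader insertion shifts downstream coordinates", {
  tx <- leader_tx()
  v <- parse_variant("c.-10_-9insU", tx)
  tx2 <- apply_variant(tx, v)
  expect_equal(tx_len_for_test(tx2), tx_len_for_test(tx) + 1L)
  expect_equal(tx2$cds_start, 32L)
  ## downstream sequence letter-for-letter unchanged, positions +1
  expect_equal(substr(tx2$seq, 23, tx_len_for_test(tx2)),
               substr(tx$seq, 22, tx_len_for_test(tx)))
  expect_equal(substr(tx2$seq, 1, 21), substr(tx$seq, 1, 21))
})

test_that("a deletion spanning the CDS anchor is refused", {
  tx <- leader_tx()
  v <- variant(30, substr(tx$seq, 30, 32), "")
  expect_error(apply_variant(tx, v), "CDS anchor",
               class = "rdg_validation_error")
})

test_that("applying the inverse edit restores the original sequence", {
  tx <- leader_tx()
  cases <- list(parse_variant("5C>G", tx),
                parse_variant("c.-10_-9insUUG", tx),
                parse_variant("c.-6_-4del", tx))
  for (v in cases) {
    tx2 <- apply_variant(tx, v)
    tx3 <- apply_variant(tx2, invert_variant(v))
    expect_equal(tx3$seq, tx$seq)
  }
})

test_that("position mapping through an edit is consistent with the sequences", {
  tx <- leader_tx()
  v <- parse_variant("c.-10_-9insU", tx)
  tx2 <- apply_variant(tx, v)
  for (p in c(1L, 10L, 21L, 22L, 40L)) {
    m <- map_position(v, p)
    expect_equal(substr(tx2$seq, m, m), substr(tx$seq, p, p))
  }
  vd <- parse_variant("c.-6_-4del", tx)
  expect_true(is.na(map_position(vd, 26L)))
  expect_equal(map_position(vd, 30L), 27L)
})

test_that("an identity substitution yields an empty diff", {
  tx <- leader_tx()
  d <- rdg_diff(tx, "5C>C")
  expect_true(is_empty_diff(d))
})

test_that("the leader insertion abrogates the CDS translon (NF2-like)", {
  fx <- make_fixture("nf2_like")
  d <- rdg_diff(fx$transcript, fx$meta$variant, fx$meta$policy)
  ## the CDS translon is no longer in the matched set
  cds_lost <- d$translons_lost$start == fx$transcript$cds_start
  expect_true(any(cds_lost))
  ## both upstream translons are extended past the (mapped) CDS start
  expect_gte(nrow(d$translons_modified), 2L)
  expect_true(all(d$translons_modified$change == "extended"))
  expect_true(all(d$translons_modified$new_end >
                    map_position(d$variant, fx$transcript$cds_start)))
  ## the insertion introduces one new uAUG branch point
  expect_equal(length(d$branch_points_gained), 1L)
  expect_equal(length(d$branch_points_lost), 0L)
})

test_that("SNVs that touch no start or stop codon leave the diff empty", {
  fx <- make_fixture("nf2_like")
  tx <- fx$transcript
  codons <- scan_codons(tx, "AUG")
  protected <- unique(unlist(lapply(codons$pos, function(p) p + 0:2)))
  set.seed(17)
  tested <- 0L
  for (k in 1:60) {
    p <- sample(setdiff(seq_len(tx_len_for_test(tx)), protected), 1)
    old <- substr(tx$seq, p, p)
    new <- sample(setdiff(c("A", "C", "G", "U"), old), 1)
    v <- variant(p, old, new)
    tx2 <- apply_variant(tx, v)
    ## oracle: recompute codon sites on both alleles; skip edits that create
    ## or destroy any start or stop anywhere
    s1 <- scan_codons(tx, "AUG"); s2 <- scan_codons(tx2, "AUG")
    if (!identical(s1, s2)) next
    d <- rdg_diff(tx, v, fx$meta$policy)
    expect_true(is_empty_diff(d))
    tested <- tested + 1L
  }
  expect_gte(tested, 20L)
})

test_that("leader frameshifts that remove the uORF stop lose or modify the CDS translon", {
  ## property over the NF2-like family: insert any single base inside the
  ## uORF body; whenever the uORF loses its in-frame stop 5' of the CDS
  ## start, the CDS translon disappears or changes
  fx <- make_fixture("nf2_like")
  tx <- fx$transcript
  set.seed(23)
  hits <- 0L
  for (k in 1:25) {
    pos <- sample(21:43, 1)          # strictly inside the uORF body
    base <- sample(c("A", "C", "G", "U"), 1)
    v <- variant(pos, "", base)
    tx2 <- apply_variant(tx, v)
    ## does the (frameshifted) uORF still stop 5' of the CDS start?
    ann2 <- branch_annotation(starts = scan_codons(tx2, "AUG")$pos[
      scan_codons(tx2, "AUG")$kind == "start"])
    g2 <- build_rdg(tx2, ann2)
    d <- rdg_diff(tx, v, fx$meta$policy)
    uorf_alt <- Filter(function(t) t$start_pos == 6L, g2$translons)[[1]]
    if (uorf_alt$end_pos >= map_position(v, tx$cds_start)) {
      expect_true(any(d$translons_lost$start == tx$cds_start) ||
                    any(d$translons_modified$old_start == tx$cds_start))
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 10L)
})
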