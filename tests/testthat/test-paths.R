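test_that("the worked three-start example has five RiboPaths, one unproductive", {
  r <- fixture_rdg("fig3")
  paths <- enumerate_paths(r$g)
  expect_equal(length(paths), 5L)
  expect_equal(count_paths(r$g), 5)
  unprod <- Filter(function(p) !p$productive, paths)
  expect_equal(length(unprod), 1L)
  sets <- lapply(paths, function(p) p$translons)
  expect_true(list(c("T1", "T2")) %in% sets ||
                any(vapply(sets, identical, logical(1), c("T1", "T2"))))
  expect_true(mutually_exclusive(r$g, "T1", "T3"))
  expect_false(mutually_exclusive(r$g, "T1", "T2"))
  expect_false(mutually_exclusive(r$g, "T1", "T1"))
  expect_error(mutually_exclusive(r$g, "T1", "T9"),
               class = "rdg_validation_error")
})

test_that("enumeration and counting agree with the decision-vector oracle", {
  tested <- 0L
  for (seed in 1:260) {
    case <- random_start_annotation(seed)
    if (is.null(case)) next
    g <- build_rdg(case$tx, case$ann)
    want <- oracle_ribopaths(case$tx, case$ann)
    got <- enumerate_paths(g, limit = 100000L)
    expect_equal(count_paths(g), length(got))
    expect_equal(length(got), length(want))
    canon <- function(xs) sort(vapply(xs, paste, character(1), collapse = ","))
    got_sets <- lapply(got, function(p) {
      vapply(p$translons, function(id) g$translons[[id]]$start_pos, integer(1))
    })
    expect_equal(canon(got_sets), canon(want))
    tested <- tested + 1L
  }
  expect_gte(tested, 200L)
})

test_that("count_paths matches igraph's path enumeration on fixtures", {
  for (name in c("fig3", "delayed_reinit", "gpx4_like", "peg10_like")) {
    r <- fixture_rdg(name)
    ig <- igraph::graph_from_data_frame(r$g$edges[, c("from", "to")],
                                        vertices = r$g$nodes$id)
    sinks <- r$g$nodes$id[!r$g$nodes$id %in% r$g$edges$from]
    n <- sum(vapply(sinks, function(s)
      length(igraph::all_simple_paths(ig, "cap", s, mode = "out")),
      integer(1)))
    expect_equal(count_paths(r$g), n)
  }
})

test_that("k exclusive leaky starts give k+1 paths", {
  ## all starts leaky (none deterministic): k productive paths + runoff
  for (k in c(1L, 3L, 5L)) {
    xs <- 6L + 120L * (seq_len(k) - 1L)
    s <- strrep("GCA", 40L * k + 20L)
    for (x in xs) {
      substr(s, x, x + 2L) <- "AUG"
      substr(s, x + 102L, x + 104L) <- "UAA"
    }
    tx <- transcript("chain", s)
    g <- build_rdg(tx, branch_annotation(starts = xs))
    expect_equal(count_paths(g), k + 1)
  }
})

test_that("path enumeration refuses to materialize an exploded graph", {
  s <- strrep("GCA", 120)
  for (x in 6L + 21L * (0:9)) {
    substr(s, x, x + 2L) <- "AUG"      # short uORF: 4 codons, competent,
    substr(s, x + 9L, x + 11L) <- "UAA"  # so every start re-feeds scanning
  }
  g <- build_rdg(transcript("t", s), branch_annotation(starts = 6L + 21L * (0:9)))
  expect_gt(count_paths(g), 20)
  err <- tryCatch(enumerate_paths(g, limit = 5L), error = identity)
  expect_s3_class(err, "rdg_explosion_error")
  expect_match(conditionMessage(err), sprintf("%.0f", count_paths(g)),
               fixed = TRUE)
})

test_that("path probabilities multiply to a normalized distribution", {
  set.seed(123)
  checked <- 0L
  for (seed in 1:40) {
    case <- random_start_annotation(seed)
    if (is.null(case)) next
    g <- build_rdg(case$tx, case$ann)
    bp <- branch_points(g)
    if (!nrow(bp)) next
    p <- stats::setNames(runif(nrow(bp)), bp$id)
    tab <- path_table(g, p = p, limit = 100000L)
    expect_equal(sum(tab$probability), 1, tolerance = 1e-12)
    checked <- checked + 1L
  }
  expect_gte(checked, 20L)
})

test_that("every translon appears in at least one path; runoff path in exactly one", {
  for (name in c("fig3", "delayed_reinit", "peg10_like")) {
    r <- fixture_rdg(name)
    paths <- enumerate_paths(r$g)
    seen <- unique(unlist(lapply(paths, function(p) p$translons)))
    expect_setequal(seen, names(r$g$translons))
  }
})

test_that("proteoforms translate with the standard code", {
  tx <- transcript("t", "AUGAAAUAA")
  g <- build_rdg(tx, branch_annotation(starts = 1, deterministic = 1))
  pf <- proteoform_sequences(g)
  expect_equal(pf$protein, "MK")
})

test_that("in-frame alternative starts give suffix-nested proteoforms (PANTs)", {
  set.seed(31)
  for (k in 1:8) {
    tx <- transcript("r", random_rna(240))
    orfs <- find_start_stop_orfs(tx)
    if (nrow(orfs) < 2) next
    ## pick any two ORFs sharing a stop
    shared <- split(seq_len(nrow(orfs)), orfs$last)
    shared <- Filter(function(ix) length(ix) >= 2, shared)
    if (!length(shared)) next
    ix <- shared[[1]][1:2]
    ann <- branch_annotation(starts = sort(orfs$first[ix]))
    g <- build_rdg(tx, ann)
    pf <- proteoform_sequences(g)
    long <- pf$protein[which.max(nchar(pf$protein))]
    short <- pf$protein[which.min(nchar(pf$protein))]
    expect_true(endsWith(long, short))
  }
})

test_that("selenocysteine readthrough renders as U in the proteoform", {
  r <- fixture_rdg("gpx4_like")
  pf <- proteoform_sequences(r$g)
  expect_equal(nrow(pf), 1L)
  aa_at_sec <- substr(pf$protein, (123 - 6) / 3 + 1, (123 - 6) / 3 + 1)
  expect_equal(aa_at_sec, "U")
  expect_false(grepl("[*]", pf$protein))
})

test_that("proteoform FASTA carries transcript, translon and event ids", {
  r <- fixture_rdg("gpx4_like")
  f <- withr::local_tempfile(fileext = ".fa")
  write_proteoform_fasta(r$g, f)
  hdr <- readLines(f)[1]
  expect_match(hdr, "gpx4_like\\|T1\\|readthrough@123")
})
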