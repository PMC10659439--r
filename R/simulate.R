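#' Simulation configuration
#'
#' @param depth Expected footprints per codon at unit ribosome flux (> 0).
#' @param seed RNG seed; combined with a transcript-id offset so that
#'   multi-fixture runs are reproducible regardless of generation order.
#' @param start_peak_fold Multiplier applied to the first 5 codons of every
#'   translon, emulating the high initiation peak of real ribosome profiling
#'   (>= 1; default 1 = no peak).
#' @param noise `"poisson"` (counts drawn from Poisson with the per-codon
#'   expectation) or `"none"` (the exact expectation, possibly non-integer).
#' @return A list of class `rdg_sim_config`.
#' @export
sim_config <- function(depth = 10, seed = 1L, start_peak_fold = 1,
                       noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(depth > 0, start_peak_fold >= 1)
  structure(list(depth = depth, seed = as.integer(seed),
                 start_peak_fold = start_peak_fold, noise = noise),
            class = "rdg_sim_config")
}

## run fn under a deterministic per-transcript RNG stream, restoring the
## caller's RNG state afterwards
with_track_seed <- function(seed, id, fn) {
  offset <- sum(utf8ToInt(id)) %% 10000L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  fn()
}

#' Simulate a ribosome footprint track from an RDG
#'
#' Propagates unit flux through the graph under the given branch
#' probabilities and deposits the expected footprint count of every decoded
#' codon at the codon's first nucleotide (A-site assignment):
#' `flux x depth`, multiplied by `start_peak_fold` for the first five codons
#' after each initiation. Codons on elongation chunks downstream of a
#' readthrough or shift branch carry only the flux that takes that branch.
#' Elongation is uniform: no codon dwell-time model.
#'
#' @param rdg An RDG.
#' @param p Branch probability map (see [propagate_flux()]).
#' @param cfg A [sim_config()].
#' @return A [footprint_track()]; with `noise = "poisson"` the same seed
#'   reproduces the same track.
#' @export
simulate_track <- function(rdg, p, cfg = sim_config()) {
  stopifnot(inherits(cfg, "rdg_sim_config"))
  fl <- flux_map(rdg, p)
  n <- tx_len(rdg$transcript)
  lambda <- numeric(n)
  el <- rdg$nodes[rdg$nodes$type == "elong", , drop = FALSE]
  for (k in seq_len(nrow(el))) {
    b <- el$pos[k]; e <- el$end[k]
    if (is.na(e) || e < b + 2L) next
    cps <- seq.int(b, e - 2L, by = 3L)
    codon_index <- el$codons_before[k] + seq_along(cps)
    fold <- ifelse(codon_index <= 5L, cfg$start_peak_fold, 1)
    lambda[cps] <- lambda[cps] + fl$node[[el$id[k]]] * cfg$depth * fold
  }
  counts <- if (cfg$noise == "poisson") {
    with_track_seed(cfg$seed, rdg$transcript$id,
                    function() stats::rpois(n, lambda))
  } else lambda
  footprint_track(rdg$transcript, counts)
}

#' Built-in synthetic fixtures
#'
#' Deterministic synthetic transcripts realizing the canonical branch-point
#' topologies used throughout the package's tests and documentation. The
#' sequences are constructed from a neutral codon filler (no stops or starts
#' in any frame) with the relevant codons spliced in, so every fixture
#' validates against its own annotation. Available fixtures:
#'
#' * `fig3`: three leaky starts in two reading frames -- a short uORF (AUG),
#'   then a CUG and an in-frame AUG sharing a stop; only the uORF is
#'   re-initiation-competent. 3 branch points, 3 translons, 5 RiboPaths.
#' * `nf2_like`: uAUG, a downstream in-frame strong (deterministic) AUG
#'   sharing the uORF stop, and a CDS fed by re-initiation; `meta$variant`
#'   documents a 5' leader single-base insertion that frameshifts the uORF
#'   (extending both uORF translons past the CDS start, creating a new uAUG)
#'   and thereby abrogates CDS translation.
#' * `gpx4_like`: one start and one selenocysteine (UGA readthrough) stop.
#' * `peg10_like`: one start and one -1 programmed frameshift site.
#' * `delayed_reinit`: short uORF, long inhibitory uORF and CDS -- the
#'   minimal architecture for delayed re-initiation; which downstream start
#'   is re-initiation-eligible depends on the recharge distance.
#' * `leaky_chain`: `k` sequential long translons on one strand, every start
#'   leaky except the last (deterministic), for probability inference.
#'
#' @param name Fixture name.
#' @param seed Accepted for interface uniformity; the fixtures are fully
#'   deterministic.
#' @param k Number of starts for `leaky_chain`.
#' @return A list with `transcript`, `annotation` and `meta` (fixture-specific
#'   extras such as the documented variant for `nf2_like`).
#' @export
make_fixture <- function(name = c("fig3", "nf2_like", "gpx4_like",
                                  "peg10_like", "delayed_reinit",
                                  "leaky_chain"),
                         seed = 1L, k = 2L) {
  name <- match.arg(name)
  switch(name,
         fig3 = fixture_fig3(),
         nf2_like = fixture_nf2(),
         gpx4_like = fixture_gpx4(),
         peg10_like = fixture_peg10(),
         delayed_reinit = fixture_delayed_reinit(),
         leaky_chain = fixture_leaky_chain(k))
}

## neutral filler: GCAGCA... contains no stop, AUG or CUG in any frame
filler_seq <- function(n) {
  paste(rep_len(c("G", "C", "A"), n), collapse = "")
}

splice_in <- function(seq, pos, what) {
  substr(seq, pos, pos + nchar(what) - 1L) <- what
  seq
}

fixture_fig3 <- function() {
  s <- filler_seq(174)
  s <- splice_in(s, 6, "AUG")     # uORF start (frame class 2)
  s <- splice_in(s, 33, "UAA")    # uORF stop: T1 = 6..35, 10 codons
  s <- splice_in(s, 16, "CUG")    # extended proteoform start (frame class 0)
  s <- splice_in(s, 40, "AUG")    # short proteoform start, in frame with 16
  s <- splice_in(s, 166, "UAG")   # shared stop of the CUG/AUG frame
  tx <- transcript("fig3", s)
  ann <- branch_annotation(starts = c(6L, 16L, 40L),
                           start_set = c("AUG", "CUG"))
  list(transcript = tx, annotation = ann, meta = list())
}

fixture_nf2 <- function() {
  s <- filler_seq(189)
  s <- splice_in(s, 6, "AUG")     # uAUG (leaky)
  s <- splice_in(s, 18, "AUG")    # strong in-frame AUG (deterministic)
  s <- splice_in(s, 45, "UGA")    # shared uORF stop: 6..47 / 18..47
  s <- splice_in(s, 61, "AUG")    # CDS start, fed by re-initiation
  s <- splice_in(s, 163, "UAA")   # CDS stop: 35 codons
  tx <- transcript("nf2_like", s, cds_start = 61L)
  ann <- branch_annotation(starts = c(6L, 18L, 61L),
                           deterministic = c(18L, 61L))
  list(transcript = tx, annotation = ann,
       meta = list(
         ## documented pathogenic-style 5' leader insertion: a U inserted
         ## inside the uORF body creates a new uAUG and shifts the uORF
         ## frame so that both uORF translons extend past the CDS start
         variant = "c.-31_-30insU",
         policy = list(start_set = "AUG", deterministic = c(18L, 61L))))
}

fixture_gpx4 <- function() {
  s <- filler_seq(189)
  s <- splice_in(s, 6, "AUG")
  s <- splice_in(s, 123, "UGA")   # selenocysteine-permissive stop (codon 40)
  s <- splice_in(s, 183, "UAA")   # final stop of the readthrough extension
  tx <- transcript("gpx4_like", s)
  ann <- branch_annotation(starts = 6L, secs = 123L, sec_symbol = "U")
  list(transcript = tx, annotation = ann, meta = list())
}

fixture_peg10 <- function() {
  s <- filler_seq(178)
  s <- splice_in(s, 6, "AUG")
  s <- splice_in(s, 96, "UAA")    # zero-frame stop (continue branch, 31 codons)
  s <- splice_in(s, 170, "UAG")   # stop of the -1 frame (shifted product)
  tx <- transcript("peg10_like", s)
  ann <- branch_annotation(starts = 6L, shifts = list(c(63L, 62L)))
  list(transcript = tx, annotation = ann, meta = list())
}

fixture_delayed_reinit <- function() {
  s <- filler_seq(270)
  s <- splice_in(s, 6, "AUG")     # short uORF start
  s <- splice_in(s, 12, "UAA")    # short uORF stop: 3 codons, competent
  s <- splice_in(s, 27, "AUG")    # long uORF start, 13 nt past the stop
  s <- splice_in(s, 120, "UAG")   # long uORF stop: 32 codons, not competent
  s <- splice_in(s, 166, "AUG")   # CDS start, 152 nt past the short uORF stop
  s <- splice_in(s, 262, "UAA")   # CDS stop
  tx <- transcript("delayed_reinit", s, cds_start = 166L)
  ann <- branch_annotation(starts = c(6L, 27L, 166L))
  list(transcript = tx, annotation = ann,
       meta = list(uorf_short_end = 14L,
                   dist_long_uorf = 27L - 14L, dist_cds = 166L - 14L))
}

fixture_leaky_chain <- function(k = 2L) {
  stopifnot(k >= 1L)
  xs <- 6L + 120L * (seq_len(k) - 1L)
  s <- filler_seq(120L * k + 60L)
  for (x in xs) {
    s <- splice_in(s, x, "AUG")
    s <- splice_in(s, x + 102L, "UAA")  # 35 codons, never reinit-competent
  }
  tx <- transcript(sprintf("leaky_chain%d", k), s)
  ann <- branch_annotation(starts = xs, deterministic = xs[length(xs)])
  list(transcript = tx, annotation = ann, meta = list())
}

#' Write a fixture to disk
#'
#' Emits the fixture as FASTA plus a notation text file so that every module
#' is exercisable from the command line without any download.
#'
#' @param fx A [make_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(fx$transcript$id, ".fa"))
  nota <- file.path(dir, paste0(fx$transcript$id, ".notation.txt"))
  write_transcripts_fasta(fx$transcript, fasta)
  writeLines(format_branch_notation(fx$annotation), nota)
  c(fasta = fasta, notation = nota)
}
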