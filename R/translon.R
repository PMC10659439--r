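#' Classify a frameshift branch point
#'
#' A shift site is encoded by two coordinates: `i`, the first nucleotide of
#' the last codon decoded in the incoming frame, and `s`, the re-pairing
#' coordinate of the first codon in the shifted frame. The signed offset is
#' the direct difference `s - i`: +1 is +1 frameshifting, -1 is -1
#' frameshifting, and large positive offsets encode translational bypassing
#' (the T4 gene 60 hop is `s - i = 50`).
#'
#' @param i Take-off coordinate (1-based).
#' @param s Resume coordinate (1-based).
#' @return A list with `offset` (integer `s - i`), `frame_offset`
#'   (`offset %% 3`), and `label` (e.g. `"+1 frameshifting"`,
#'   `"bypass(50)"`).
#' @examples
#' classify_shift(100, 101)$offset   # +1 frameshifting
#' classify_shift(100, 150)$label    # bypass(50)
#' @export
classify_shift <- function(i, s) {
  i <- as.integer(i); s <- as.integer(s)
  offset <- s - i
  if (offset == 0L) {
    stop_rdg("rdg_validation_error", "shift with s == i is not a branch point")
  }
  if (offset <= -4L) {
    stop_rdg("rdg_validation_error",
             "unsupported backward jump: s - i = %d (at most -3 supported)",
             offset)
  }
  label <- if (offset > 3L) {
    sprintf("bypass(%d)", offset)
  } else {
    sprintf("%+d frameshifting", offset)
  }
  list(offset = offset, frame_offset = ((offset %% 3L) + 3L) %% 3L,
       label = label)
}

## Position where decoding resumes after a shift (i, s): the first newly
## decoded codon lies 3 nt past the re-pairing coordinate. This one rule
## gives resume = i + 2 for -1 PRF (re-pairing re-reads the last nt),
## i + 4 for +1 frameshifting, and s + 3 for a bypass that skips s - i nt.
shift_resume_pos <- function(i, s) s + 3L

#' Derive the translon initiated at a start position
#'
#' Walks codon-by-codon from the initiation codon. An in-frame stop listed in
#' the annotation's `secs` is decoded (readthrough/selenocysteine event) and
#' elongation continues; an annotated shift site reached in frame re-routes
#' decoding into the shifted frame; otherwise the walk ends at the first
#' in-frame stop. The *maximal* translon is returned -- the one in which every
#' readthrough and shift event fires -- with the events recorded; the
#' alternatives (early termination, no shift) appear as branches in the RDG,
#' not as extra translons.
#'
#' @param tx A [transcript()].
#' @param start 1-based position of the initiation codon; must be listed in
#'   `ann$starts`.
#' @param ann An [branch_annotation()].
#' @return An object of class `rdg_translon`: `start_pos`, `end_pos` (last nt
#'   of the terminating stop, or transcript end if unbounded), `segments`
#'   (data.frame begin/end/frame, each a whole number of codons, ordered by
#'   ribosome traversal), `events` (data.frame kind/pos/detail), `n_codons`
#'   (terminating stop included), `stopped`, `unbounded` and
#'   `reinit_competent` (codon count at most `reinit_max_codons` and
#'   stop-terminated; unbounded translons are never competent).
#' @export
derive_translon <- function(tx, start, ann) {
  stopifnot(inherits(tx, "rdg_transcript"), inherits(ann, "rdg_annotation"))
  if (!start %in% ann$starts) {
    stop_rdg("rdg_validation_error", "position %d is not an annotated start", start)
  }
  cod <- codon_at(tx, start)
  if (!cod %in% ann$start_set) {
    stop_rdg("rdg_validation_error",
             "start at %d is '%s', not in start set", start, cod)
  }
  walk_translon(tx, start, ann)
}

## core elongation walk shared by derive_translon and the graph builder.
## Returns the maximal translon; `stop_events = FALSE` limits the walk to the
## first termination (used nowhere currently but kept simple).
walk_translon <- function(tx, start, ann) {
  n <- tx_len(tx)
  segs <- list()
  events <- list()
  anchor <- as.integer(start)
  pos <- anchor
  n_codons <- 0L
  stopped <- FALSE
  sec_symbol <- stats::setNames(ann$sec_symbol, ann$secs)
  repeat {
    if (pos + 2L > n) {
      ## ran off the 3' end: close at the last complete codon
      last_full <- pos - 1L
      if (last_full >= anchor) {
        segs[[length(segs) + 1L]] <- c(anchor, last_full)
      }
      end_pos <- n
      break
    }
    hit_shift <- which(ann$shifts$i == pos)
    if (length(hit_shift)) {
      i <- ann$shifts$i[hit_shift[1L]]
      s <- ann$shifts$s[hit_shift[1L]]
      n_codons <- n_codons + 1L  # codon at i is decoded in the incoming frame
      segs[[length(segs) + 1L]] <- c(anchor, i + 2L)
      events[[length(events) + 1L]] <- list(
        kind = "shift", pos = i,
        detail = classify_shift(i, s)$label)
      anchor <- shift_resume_pos(i, s)
      pos <- anchor
      if (anchor > n - 2L) { end_pos <- n; break }
      next
    }
    cod <- codon_at(tx, pos)
    if (cod %in% STOP_CODONS) {
      n_codons <- n_codons + 1L
      if (pos %in% ann$secs) {
        segs[[length(segs) + 1L]] <- c(anchor, pos + 2L)
        events[[length(events) + 1L]] <- list(
          kind = "readthrough", pos = pos,
          detail = unname(sec_symbol[as.character(pos)]))
        anchor <- pos + 3L
        pos <- anchor
        if (anchor > n - 2L) { end_pos <- n; break }
        next
      }
      segs[[length(segs) + 1L]] <- c(anchor, pos + 2L)
      end_pos <- pos + 2L
      stopped <- TRUE
      break
    }
    n_codons <- n_codons + 1L
    pos <- pos + 3L
  }
  segments <- if (length(segs)) {
    data.frame(begin = vapply(segs, `[`, integer(1), 1L),
               end = vapply(segs, `[`, integer(1), 2L))
  } else data.frame(begin = integer(), end = integer())
  segments$frame <- (segments$begin - 1L) %% 3L
  ev <- if (length(events)) {
    data.frame(kind = vapply(events, `[[`, character(1), "kind"),
               pos = vapply(events, `[[`, integer(1), "pos"),
               detail = vapply(events, function(e)
                 as.character(e$detail %||% NA_character_), character(1)),
               stringsAsFactors = FALSE)
  } else data.frame(kind = character(), pos = integer(), detail = character(),
                    stringsAsFactors = FALSE)
  unbounded <- !stopped
  structure(list(
    id = NA_character_,
    start_pos = as.integer(start),
    end_pos = as.integer(end_pos),
    segments = segments,
    events = ev,
    n_codons = n_codons,
    stopped = stopped,
    unbounded = unbounded,
    reinit_competent = stopped && n_codons <= ann$reinit_max_codons
  ), class = "rdg_translon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rdg_translon <- function(x, ...) {
  cat(sprintf("<translon %s> start %d, end %d, %d codons%s%s\n",
              if (is.na(x$id)) "?" else x$id, x$start_pos, x$end_pos,
              x$n_codons,
              if (x$unbounded) ", unbounded" else "",
              if (x$reinit_competent) ", reinit-competent" else ""))
  if (nrow(x$segments) > 1L) {
    cat(sprintf("  segments: %s\n", paste(
      sprintf("[%d,%d]/f%d", x$segments$begin, x$segments$end,
              x$segments$frame), collapse = " -> ")))
  }
  invisible(x)
}
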