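#' Construct a transcript variant
#'
#' Variants live in transcript coordinates. A substitution or deletion starts
#' at `pos` (1-based, `ref` non-empty); a pure insertion has empty `ref` and
#' inserts `alt` immediately *after* `pos` (`pos = 0` inserts before the
#' first nucleotide). The reference allele is always checked against the
#' transcript before use.
#'
#' @param pos 1-based position (left flank for insertions).
#' @param ref Reference allele ("" for insertion).
#' @param alt Alternate allele ("" for deletion).
#' @param source Optional source notation (e.g. the HGVS-like string).
#' @return An object of class `rdg_variant`.
#' @export
variant <- function(pos, ref, alt, source = NULL) {
  pos <- as.integer(pos)
  ref <- if (nzchar(ref)) normalize_rna(ref) else ""
  alt <- if (nzchar(alt)) normalize_rna(alt) else ""
  if (!nzchar(ref) && !nzchar(alt)) {
    stop_rdg("rdg_validation_error", "variant with empty ref and alt")
  }
  if (nzchar(ref) && pos < 1L) {
    stop_rdg("rdg_validation_error", "ref-anchored variant needs pos >= 1")
  }
  if (!nzchar(ref) && pos < 0L) {
    stop_rdg("rdg_validation_error", "insertion flank must be >= 0")
  }
  type <- if (!nzchar(ref)) "ins" else if (!nzchar(alt)) "del"
          else if (nchar(ref) == nchar(alt)) "snv" else "indel"
  structure(list(pos = pos, ref = ref, alt = alt, type = type,
                 source = source), class = "rdg_variant")
}

#' @export
print.rdg_variant <- function(x, ...) {
  cat(sprintf("<variant> %s at %d: '%s' -> '%s'%s\n", x$type, x$pos,
              x$ref, x$alt,
              if (!is.null(x$source)) sprintf("  (%s)", x$source) else ""))
  invisible(x)
}

## map a c.-style coordinate to a transcript coordinate; c.1 is the A of the
## CDS start codon and c.-1 the nucleotide immediately 5' of it (there is no
## c.0)
c_to_tx <- function(cpos, tx) {
  if (is.null(tx$cds_start)) {
    stop_rdg("rdg_validation_error",
             "transcript %s has no annotated CDS start; cannot resolve c. coordinates",
             tx$id)
  }
  ifelse(cpos > 0, tx$cds_start + cpos - 1L, tx$cds_start + cpos)
}

#' Parse a variant from an HGVS-like string
#'
#' Supported minimal forms (optionally prefixed `c.`): substitutions
#' `123A>G`, insertions `30_31insACG`, deletions `10_12delAAA` / `10_12del`
#' and single-base `10delA`. Positions with a leading `-` (or any `c.` form)
#' are CDS-anchored: `c.-1` is the nucleotide 5' of the annotated CDS start,
#' which must then be set on the transcript. Plain positive positions
#' without the `c.` prefix are transcript coordinates. A `pos/ref/alt`
#' triple can be given directly to [variant()].
#'
#' @param text The variant string.
#' @param tx The [transcript()] the variant applies to.
#' @return A ref-checked [variant()].
#' @examples
#' tx <- transcript("t", strrep("GCA", 20), cds_start = 31)
#' parse_variant("c.-10_-9insU", tx)
#' @export
parse_variant <- function(text, tx) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- gsub("[[:space:]]", "", text)
  body <- sub("^c\\.", "", raw)
  anchored <- startsWith(raw, "c.") || startsWith(body, "-")
  conv <- function(p) {
    p <- as.integer(p)
    if (anchored) c_to_tx(p, tx) else p
  }
  num <- "(-?[0-9]+)"
  nt <- "([ACGTUacgtu]+)"
  if (grepl(sprintf("^%s%s>%s$", num, nt, nt), body)) {
    m <- regmatches(body, regexec(sprintf("^%s%s>%s$", num, nt, nt), body))[[1]]
    v <- variant(conv(m[2]), m[3], m[4], source = raw)
  } else if (grepl(sprintf("^%s_%sins%s$", num, num, nt), body)) {
    m <- regmatches(body, regexec(sprintf("^%s_%sins%s$", num, num, nt), body))[[1]]
    left <- conv(m[2]); right <- conv(m[3])
    if (right != left + 1L) {
      stop_rdg("rdg_unsupported_form_error",
               "insertion flanks %s_%s are not adjacent", m[2], m[3])
    }
    v <- variant(left, "", m[4], source = raw)
  } else if (grepl(sprintf("^%s(_%s)?del%s?$", num, num, nt), body)) {
    m <- regmatches(body, regexec(sprintf("^%s(_%s)?del%s?$", num, num, nt),
                                  body))[[1]]
    from <- conv(m[2])
    to <- if (nzchar(m[3])) conv(m[4]) else from
    ref <- if (nzchar(m[5])) m[5] else substr(tx$seq, from, to)
    if (nchar(ref) != to - from + 1L) {
      stop_rdg("rdg_validation_error",
               "deleted sequence length %d does not match range %d_%d",
               nchar(ref), from, to)
    }
    v <- variant(from, ref, "", source = raw)
  } else {
    stop_rdg("rdg_unsupported_form_error",
             "unsupported variant form '%s'", raw)
  }
  check_ref(v, tx)
  v
}

check_ref <- function(v, tx) {
  if (!nzchar(v$ref)) {
    if (v$pos > tx_len(tx)) {
      stop_rdg("rdg_validation_error", "insertion flank %d beyond transcript end", v$pos)
    }
    return(invisible(v))
  }
  found <- substr(tx$seq, v$pos, v$pos + nchar(v$ref) - 1L)
  if (v$pos + nchar(v$ref) - 1L > tx_len(tx)) {
    stop_rdg("rdg_validation_error", "variant at %d runs past transcript end", v$pos)
  }
  if (!identical(found, v$ref)) {
    stop_rdg("rdg_ref_mismatch_error",
             "reference mismatch at %d: expected '%s', found '%s'",
             v$pos, v$ref, found)
  }
  invisible(v)
}

#' Apply a variant to a transcript
#'
#' Returns the edited transcript; length changes by
#' `nchar(alt) - nchar(ref)` and the annotated CDS start shifts when the
#' edit lies entirely 5' of it. An edit overlapping the CDS anchor itself is
#' refused (the coordinate anchor would be destroyed).
#'
#' @param tx A [transcript()].
#' @param v An [variant()] (ref-checked against `tx`).
#' @return A new [transcript()] with id `<id>:<variant>`.
#' @export
apply_variant <- function(tx, v) {
  stopifnot(inherits(tx, "rdg_transcript"), inherits(v, "rdg_variant"))
  check_ref(v, tx)
  n <- tx_len(tx)
  if (v$type == "ins") {
    newseq <- paste0(substr(tx$seq, 1, v$pos), v$alt,
                     substr(tx$seq, v$pos + 1L, n))
  } else {
    newseq <- paste0(substr(tx$seq, 1, v$pos - 1L), v$alt,
                     substr(tx$seq, v$pos + nchar(v$ref), n))
  }
  cds <- tx$cds_start
  if (!is.null(cds)) {
    last_ref <- if (v$type == "ins") v$pos else v$pos + nchar(v$ref) - 1L
    first_ref <- if (v$type == "ins") v$pos + 1L else v$pos
    if (v$type != "ins" && first_ref <= cds && last_ref >= cds &&
        nchar(v$ref) != nchar(v$alt)) {
      stop_rdg("rdg_validation_error",
               "edit overlaps CDS anchor at %d", cds)
    }
    if (last_ref < cds) cds <- cds + nchar(v$alt) - nchar(v$ref)
  }
  label <- v$source %||% sprintf("%d%s>%s", v$pos, v$ref, v$alt)
  transcript(paste0(tx$id, ":", label), newseq, cds)
}

#' Map a reference-allele position through a variant
#'
#' @param v An [variant()].
#' @param pos Positions in reference-transcript coordinates.
#' @return Positions in the edited transcript; `NA` for deleted positions.
#' @export
map_position <- function(v, pos) {
  delta <- nchar(v$alt) - nchar(v$ref)
  vapply(as.integer(pos), function(p) {
    if (v$type == "ins") {
      if (p <= v$pos) p else p + delta
    } else {
      last_ref <- v$pos + nchar(v$ref) - 1L
      if (p < v$pos) p
      else if (p <= last_ref) {
        if (nchar(v$ref) == nchar(v$alt)) p else NA_integer_
      } else p + delta
    }
  }, integer(1))
}

#' Invert a variant
#'
#' The returned variant, applied to the edited transcript, restores the
#' original sequence.
#'
#' @param v An [variant()].
#' @return An [variant()] in edited-transcript coordinates.
#' @export
invert_variant <- function(v) {
  switch(v$type,
         snv = , indel = variant(v$pos, v$alt, v$ref),
         ins = variant(v$pos + 1L, v$alt, ""),
         del = variant(v$pos - 1L, "", v$ref))
}

#' Compare RDG topology between a reference and a variant allele
#'
#' Start codons and the resulting graph are re-derived independently on each
#' allele (variants create and destroy codons, so lifting the reference
#' annotation would miss the point); the re-initiation policy and the set of
#' deterministic (non-leaky) starts are carried across through the
#' coordinate mapping. Translons are matched across alleles by their mapped
#' start position; a matched translon whose end moved is reported as
#' extended or truncated. `branch_points_gained/lost` compare the candidate
#' start codons themselves (including starts that are not reachable in the
#' graph, e.g. a new AUG inside a non-leaky upstream ORF).
#'
#' @param tx Reference [transcript()].
#' @param v An [variant()] or HGVS-like string.
#' @param policy List: `start_set` (default `"AUG"`), `reinit_max_codons`,
#'   `recharge_distance`, `deterministic` (reference coordinates), `secs`,
#'   `shifts` (lifted, for branch points of non-sequence origin).
#' @return An object of class `rdg_diff` with data.frames
#'   `translons_lost`, `translons_gained`, `translons_modified`,
#'   `branch_points_lost`, `branch_points_gained`, plus both RDGs.
#' @export
rdg_diff <- function(tx, v, policy = list()) {
  if (is.character(v)) v <- parse_variant(v, tx)
  pol <- utils::modifyList(list(start_set = "AUG", reinit_max_codons = 30L,
                                recharge_distance = 0L,
                                deterministic = integer(),
                                secs = integer(), shifts = NULL), policy)
  tx_alt <- apply_variant(tx, v)

  scan_starts <- function(t) {
    sc <- scan_codons(t, pol$start_set)
    sc$pos[sc$kind == "start"]
  }
  ref_starts <- scan_starts(tx)
  alt_starts <- scan_starts(tx_alt)
  lift <- function(p) {
    m <- map_position(v, p)
    m[!is.na(m)]
  }
  ann_ref <- branch_annotation(
    starts = ref_starts, secs = pol$secs, shifts = pol$shifts,
    reinit_max_codons = pol$reinit_max_codons,
    recharge_distance = pol$recharge_distance,
    deterministic = intersect(pol$deterministic, ref_starts),
    start_set = pol$start_set)
  ann_alt <- branch_annotation(
    starts = alt_starts, secs = lift(pol$secs),
    shifts = if (!is.null(pol$shifts))
      normalize_shifts(data.frame(i = lift(pol$shifts$i),
                                  s = lift(pol$shifts$s))) else NULL,
    reinit_max_codons = pol$reinit_max_codons,
    recharge_distance = pol$recharge_distance,
    deterministic = intersect(lift(pol$deterministic), alt_starts),
    start_set = pol$start_set)
  g_ref <- build_rdg(tx, ann_ref)
  g_alt <- build_rdg(tx_alt, ann_alt)

  ref_tr <- g_ref$translons
  alt_tr <- g_alt$translons
  alt_by_start <- stats::setNames(alt_tr,
    vapply(alt_tr, function(t) t$start_pos, integer(1)))

  lost <- list(); modified <- list(); matched_alt <- character()
  for (t in ref_tr) {
    mstart <- map_position(v, t$start_pos)
    mt <- if (!is.na(mstart)) alt_by_start[[as.character(mstart)]] else NULL
    if (is.null(mt)) {
      lost[[length(lost) + 1L]] <- data.frame(
        id = t$id, start = t$start_pos, end = t$end_pos,
        stringsAsFactors = FALSE)
      next
    }
    matched_alt <- c(matched_alt, mt$id)
    mend <- map_position(v, t$end_pos)
    if (is.na(mend) || mt$end_pos != mend || mt$unbounded != t$unbounded) {
      change <- if (!is.na(mend) && mt$end_pos < mend) "truncated" else "extended"
      modified[[length(modified) + 1L]] <- data.frame(
        id = t$id, alt_id = mt$id, change = change,
        old_start = t$start_pos, old_end = t$end_pos,
        new_start = mt$start_pos, new_end = mt$end_pos,
        stringsAsFactors = FALSE)
    }
  }
  gained <- lapply(alt_tr[!names(alt_tr) %in% matched_alt], function(t) {
    data.frame(id = t$id, start = t$start_pos, end = t$end_pos,
               stringsAsFactors = FALSE)
  })

  mapped_ref_starts <- map_position(v, ref_starts)
  bp_lost <- ref_starts[is.na(mapped_ref_starts) |
                          !mapped_ref_starts %in% alt_starts]
  bp_gained <- setdiff(alt_starts, mapped_ref_starts[!is.na(mapped_ref_starts)])

  empty_tr <- data.frame(id = character(), start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
  structure(list(
    variant = v,
    translons_lost = do.call(rbind, c(lost, list(empty_tr))),
    translons_gained = do.call(rbind, c(gained, list(empty_tr))),
    translons_modified = do.call(rbind, c(modified, list(data.frame(
      id = character(), alt_id = character(), change = character(),
      old_start = integer(), old_end = integer(), new_start = integer(),
      new_end = integer(), stringsAsFactors = FALSE)))),
    branch_points_lost = bp_lost,
    branch_points_gained = bp_gained,
    rdg_ref = g_ref, rdg_alt = g_alt
  ), class = "rdg_diff")
}

#' @export
print.rdg_diff <- function(x, ...) {
  cat("<RDG diff>", x$variant$source %||%
        sprintf("%d%s>%s", x$variant$pos, x$variant$ref, x$variant$alt), "\n")
  if (is_empty_diff(x)) {
    cat("  no topology change\n")
    return(invisible(x))
  }
  if (nrow(x$translons_lost)) {
    cat(sprintf("  translons lost: %s\n", paste(
      sprintf("%s(%d..%d)", x$translons_lost$id, x$translons_lost$start,
              x$translons_lost$end), collapse = ", ")))
  }
  if (nrow(x$translons_gained)) {
    cat(sprintf("  translons gained: %s\n", paste(
      sprintf("%s(%d..%d)", x$translons_gained$id, x$translons_gained$start,
              x$translons_gained$end), collapse = ", ")))
  }
  if (nrow(x$translons_modified)) {
    cat(sprintf("  translons modified: %s\n", paste(
      sprintf("%s %s (%d..%d -> %d..%d)", x$translons_modified$id,
              x$translons_modified$change, x$translons_modified$old_start,
              x$translons_modified$old_end, x$translons_modified$new_start,
              x$translons_modified$new_end), collapse = ", ")))
  }
  if (length(x$branch_points_lost)) {
    cat("  branch points lost at:", paste(x$branch_points_lost, collapse = ", "), "\n")
  }
  if (length(x$branch_points_gained)) {
    cat("  branch points gained at:", paste(x$branch_points_gained, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Is a topology diff empty?
#'
#' @param x An [rdg_diff()] result.
#' @return TRUE when no translon or branch point changed.
#' @export
is_empty_diff <- function(x) {
  nrow(x$translons_lost) == 0 && nrow(x$translons_gained) == 0 &&
    nrow(x$translons_modified) == 0 && length(x$branch_points_lost) == 0 &&
    length(x$branch_points_gained) == 0
}
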