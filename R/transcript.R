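#' @importFrom stats optim runif rpois setNames
#' @importFrom utils modifyList read.table write.table
NULL

## Stop codons are fixed by the standard genetic code; start sets are
## configurable because initiation is not (near-cognate starts are common).
STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Start-codon sets
#'
#' `start_codons("AUG")` is the default strict set; `start_codons("near_cognate")`
#' additionally contains the common near-cognate initiators (single-mismatch
#' AUG variants such as CUG, GUG, UUG, ACG) that support initiation in many
#' transcripts, e.g. the non-AUG starts producing N-terminally extended
#' proteoforms.
#'
#' @param set `"AUG"` or `"near_cognate"`.
#' @return Character vector of 3-letter RNA codons.
#' @export
start_codons <- function(set = c("AUG", "near_cognate")) {
  set <- match.arg(set)
  if (set == "AUG") return("AUG")
  c("AUG", "CUG", "GUG", "UUG", "ACG", "AUA", "AUU", "AUC", "AGG", "AAG")
}

stop_rdg <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rdg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

normalize_rna <- function(seq) {
  s <- chartr("tT", "uU", toupper(seq))
  s <- chartr("T", "U", s)
  bad <- gsub("[ACGU]", "", s)
  if (nzchar(bad)) {
    stop_rdg("rdg_alphabet_error",
             "sequence contains non-ACGU characters after normalization: '%s'",
             substr(bad, 1, 10))
  }
  s
}

#' Create a transcript
#'
#' A transcript is a mature mRNA sequence with 1-based coordinates. `T` is
#' accepted and normalized to `U`; mixed case is uppercased. An optional
#' annotated CDS start anchors HGVS-like `c.` coordinates (negative offsets
#' address the 5' leader).
#'
#' @param id Transcript identifier.
#' @param seq Nucleotide sequence (A, C, G, U/T).
#' @param cds_start Optional 1-based position of the A of the annotated CDS AUG.
#' @return An object of class `rdg_transcript` with elements `id`, `seq`
#'   (normalized RNA string) and `cds_start`.
#' @examples
#' tx <- transcript("tx1", "augaaauaa")
#' nchar(tx$seq)
#' @export
transcript <- function(id, seq, cds_start = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_rna(as.character(seq))
  if (!nzchar(seq)) stop_rdg("rdg_validation_error", "empty transcript sequence")
  if (!is.null(cds_start)) {
    cds_start <- as.integer(cds_start)
    if (cds_start < 1L || cds_start > nchar(seq) - 2L) {
      stop_rdg("rdg_validation_error",
               "cds_start %d outside [1, %d]", cds_start, nchar(seq) - 2L)
    }
  }
  structure(list(id = id, seq = seq, cds_start = cds_start),
            class = "rdg_transcript")
}

#' @export
print.rdg_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> %d nt%s\n", x$id, nchar(x$seq),
              if (!is.null(x$cds_start)) sprintf(", CDS start %d", x$cds_start) else ""))
  invisible(x)
}

tx_len <- function(tx) nchar(tx$seq)

## 3-mer at a 1-based position (NA-safe at the 3' boundary)
codon_at <- function(tx, pos) substr(tx$seq, pos, pos + 2L)

#' Read transcripts from a FASTA file
#'
#' Multi-record FASTA; the first whitespace-delimited token of each header is
#' the transcript id. DNA input is normalized to RNA.
#'
#' @param path FASTA file path.
#' @param cds_start Optional named integer vector of CDS starts keyed by id.
#' @return A named list of [transcript()] objects.
#' @export
read_transcripts_fasta <- function(path, cds_start = NULL) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(set), function(i) {
    cs <- if (!is.null(cds_start) && ids[i] %in% names(cds_start))
      cds_start[[ids[i]]] else NULL
    transcript(ids[i], as.character(set[[i]]), cs)
  })
  names(out) <- ids
  out
}

#' Write transcripts to FASTA
#'
#' @param txs A list of transcripts (or one transcript).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(txs, path) {
  if (inherits(txs, "rdg_transcript")) txs <- list(txs)
  set <- Biostrings::BStringSet(vapply(txs, function(t) t$seq, character(1)))
  names(set) <- vapply(txs, function(t) t$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Locate start and stop codons in all three reading frames
#'
#' Scans every position of the transcript and reports codon sites for the
#' configured start set and the three stop codons. Frame is defined relative
#' to transcript position 1: `frame = (pos - 1) %% 3`. When `cds_start` is
#' annotated, a CDS-relative frame is reported additionally.
#'
#' @param tx A [transcript()].
#' @param start_set Character vector of start codons (see [start_codons()]).
#' @return A data.frame with columns `pos`, `frame`, `kind` ("start"/"stop"),
#'   `codon`, and `cds_frame` (NA without an annotated CDS start), ordered by
#'   `pos`.
#' @examples
#' scan_codons(transcript("t", "AUGUAA"))
#' @export
scan_codons <- function(tx, start_set = start_codons()) {
  stopifnot(inherits(tx, "rdg_transcript"), length(start_set) >= 1L)
  start_set <- vapply(start_set, normalize_rna, character(1), USE.NAMES = FALSE)
  stopifnot(all(nchar(start_set) == 3L))
  n <- tx_len(tx)
  if (n < 3L) {
    return(data.frame(pos = integer(), frame = integer(), kind = character(),
                      codon = character(), cds_frame = integer()))
  }
  pos <- seq_len(n - 2L)
  codons <- substring(tx$seq, pos, pos + 2L)
  is_start <- codons %in% start_set
  is_stop <- codons %in% STOP_CODONS
  keep <- is_start | is_stop
  pos <- pos[keep]
  out <- data.frame(
    pos = pos,
    frame = (pos - 1L) %% 3L,
    kind = ifelse(is_stop[keep], "stop", "start"),
    codon = codons[keep],
    cds_frame = if (is.null(tx$cds_start)) rep(NA_integer_, length(pos))
                else ((pos - tx$cds_start) %% 3L),
    stringsAsFactors = FALSE
  )
  out[order(out$pos), , drop = FALSE]
}

#' Find Start-Stop ORFs
#'
#' One ORF per start codon that has a downstream in-frame stop: the span runs
#' from the first nucleotide of the start codon to the last nucleotide of the
#' nearest in-frame stop (the stop codon is included in the span). Nested
#' in-frame starts yield nested ORFs sharing a stop.
#'
#' @inheritParams scan_codons
#' @return data.frame with columns `mode`, `first`, `last`, `frame`,
#'   `unbounded` (always FALSE here: start codons with no downstream in-frame
#'   stop are omitted, they do not form a Start-Stop ORF).
#' @examples
#' find_start_stop_orfs(transcript("t", "AUGAUGUAA"))
#' @export
find_start_stop_orfs <- function(tx, start_set = start_codons()) {
  sites <- scan_codons(tx, start_set)
  starts <- sites[sites$kind == "start", , drop = FALSE]
  stops <- sites[sites$kind == "stop", , drop = FALSE]
  res <- lapply(seq_len(nrow(starts)), function(i) {
    s <- starts$pos[i]
    f <- starts$frame[i]
    cand <- stops$pos[stops$frame == f & stops$pos > s]
    ## the nearest in-frame stop terminates the ORF; an in-frame start/stop
    ## distance is always a codon multiple
    cand <- cand[(cand - s) %% 3L == 0L]
    if (!length(cand)) return(NULL)
    data.frame(mode = "start_stop", first = s, last = min(cand) + 2L,
               frame = f, unbounded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(data.frame(
    mode = character(), first = integer(), last = integer(),
    frame = integer(), unbounded = logical(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out[order(out$first, out$last), , drop = FALSE]
}

#' Find Stop-Stop ORFs
#'
#' Per reading frame, the maximal stop-free codon runs bounded by stop codons.
#' The span excludes the bounding stops themselves. Runs truncated by a
#' transcript boundary (no bounding stop on one side) are returned flagged
#' `unbounded = TRUE` rather than silently clipped.
#'
#' @inheritParams scan_codons
#' @return data.frame with columns `mode`, `first`, `last`, `frame`,
#'   `unbounded`.
#' @export
find_stop_stop_orfs <- function(tx) {
  sites <- scan_codons(tx, start_set = "AUG")
  stops <- sites[sites$kind == "stop", , drop = FALSE]
  n <- tx_len(tx)
  res <- list()
  for (f in 0:2) {
    first_codon <- f + 1L
    if (first_codon + 2L > n) next
    last_codon <- first_codon + 3L * ((n - first_codon - 2L) %/% 3L)
    sp <- sort(stops$pos[stops$frame == f])
    ## candidate run starts: frame's first codon, and the codon after each stop;
    ## run ends: the nt before each stop, and the frame's last full codon
    run_first <- c(first_codon, sp + 3L)
    run_last <- c(sp - 1L, last_codon + 2L)
    trunc5 <- c(TRUE, rep(FALSE, length(sp)))
    trunc3 <- c(rep(FALSE, length(sp)), TRUE)
    for (k in seq_along(run_first)) {
      if (run_last[k] - run_first[k] + 1L < 3L) next  # empty codon run
      res[[length(res) + 1L]] <- data.frame(
        mode = "stop_stop", first = run_first[k], last = run_last[k],
        frame = f, unbounded = trunc5[k] || trunc3[k], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(res, list(data.frame(
    mode = character(), first = integer(), last = integer(),
    frame = integer(), unbounded = logical(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out[order(out$frame, out$first), , drop = FALSE]
}

#' Export an ORF table as GFF3 or BED
#'
#' GFF3 is written 1-based inclusive, BED 0-based half-open; the conversion is
#' handled by `rtracklayer`. Frame and mode are carried as attributes (GFF3)
#' or encoded in the name field (BED).
#'
#' @param orfs A data.frame from [find_start_stop_orfs()] or
#'   [find_stop_stop_orfs()].
#' @param tx The transcript the ORFs were computed on.
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
export_orfs <- function(orfs, tx, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = tx$id,
    ranges = IRanges::IRanges(start = orfs$first, end = orfs$last),
    strand = "+")
  if (format == "gff3") {
    S4Vectors::mcols(gr)$type <- "ORF"
    S4Vectors::mcols(gr)$ID <- sprintf("%s_orf%02d", orfs$mode, seq_len(nrow(orfs)))
    S4Vectors::mcols(gr)$mode <- orfs$mode
    S4Vectors::mcols(gr)$frame <- orfs$frame
    S4Vectors::mcols(gr)$unbounded <- tolower(as.character(orfs$unbounded))
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    S4Vectors::mcols(gr)$name <- sprintf("%s_f%d", orfs$mode, orfs$frame)
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}
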