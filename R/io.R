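RDG_SCHEMA <- "rdg/1.0"

#' Export an RDG as JSON
#'
#' Versioned schema carrying the transcript (id, length, sequence, CDS
#' start), the annotation echo (including its canonical notation string),
#' nodes, edges and translons. [import_rdg_json()] reconstructs an
#' equivalent graph from the document.
#'
#' @param rdg An RDG.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_rdg_json <- function(rdg, path) {
  ann <- rdg$annotation
  doc <- list(
    schema = RDG_SCHEMA,
    transcript = list(id = rdg$transcript$id,
                      length = tx_len(rdg$transcript),
                      seq = rdg$transcript$seq,
                      cds_start = rdg$transcript$cds_start),
    annotation = list(
      notation = format_branch_notation(ann),
      starts = ann$starts, secs = ann$secs, shifts = ann$shifts,
      reinit_max_codons = ann$reinit_max_codons,
      recharge_distance = ann$recharge_distance,
      deterministic = ann$deterministic,
      sec_symbol = ann$sec_symbol,
      start_set = ann$start_set),
    nodes = rdg$nodes,
    edges = rdg$edges,
    translons = lapply(unname(rdg$translons), function(t) list(
      id = t$id, start_pos = t$start_pos, end_pos = t$end_pos,
      segments = t$segments, events = t$events, n_codons = t$n_codons,
      stopped = t$stopped, unbounded = t$unbounded,
      reinit_competent = t$reinit_competent))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Import an RDG from JSON
#'
#' Rebuilds the graph from the transcript sequence and annotation echoed in
#' the document; the result is structurally equivalent to the exported graph
#' (same nodes, edges and translons up to row order).
#'
#' @param path JSON path written by [export_rdg_json()].
#' @return An RDG.
#' @export
import_rdg_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !startsWith(doc$schema, "rdg/")) {
    stop_rdg("rdg_validation_error", "not an RDG JSON document: %s", path)
  }
  tx <- transcript(doc$transcript$id, doc$transcript$seq,
                   doc$transcript$cds_start)
  a <- doc$annotation
  shifts <- if (!is.null(a$shifts) && length(a$shifts)) a$shifts else NULL
  ann <- branch_annotation(
    starts = unlist(a$starts), secs = unlist(a$secs) %||% integer(),
    shifts = shifts,
    reinit_max_codons = a$reinit_max_codons,
    recharge_distance = a$recharge_distance,
    deterministic = unlist(a$deterministic) %||% integer(),
    sec_symbol = unlist(a$sec_symbol) %||% "X",
    start_set = unlist(a$start_set))
  build_rdg(tx, ann)
}

#' Export an RDG as Graphviz DOT
#'
#' Branch nodes render as diamonds, elongation segments as boxes,
#' terminations and sinks as ellipses. When probabilities (and optionally a
#' quantification) are given, branch edges are labelled with their
#' probability and translon initiate edges with relative synthesis
#' percentages, mirroring the heatmap-style figures of RDG quantification.
#'
#' @param rdg An RDG.
#' @param path Output path.
#' @param p Optional branch probability map.
#' @param quant Optional [propagate_flux()] result.
#' @return `path`, invisibly.
#' @export
export_rdg_dot <- function(rdg, path, p = NULL, quant = NULL) {
  esc <- function(x) gsub('"', '\\"', x, fixed = TRUE)
  shape <- c(source = "circle", branch_start = "diamond",
             branch_sec = "diamond", branch_shift = "diamond",
             start_det = "rarrow", elong = "box", term = "ellipse",
             sink = "doublecircle")
  lines <- c("digraph RDG {", "  rankdir=LR;",
             sprintf('  label="%s";', esc(rdg$transcript$id)))
  for (k in seq_len(nrow(rdg$nodes))) {
    nd <- rdg$nodes[k, ]
    lab <- if (nd$type == "elong" && !is.na(nd$end)) {
      sprintf("%s\\n%d..%d", nd$id, nd$pos, nd$end)
    } else if (!is.na(nd$pos)) sprintf("%s\\n@%d", nd$id, nd$pos) else nd$id
    lines <- c(lines, sprintf('  "%s" [shape=%s, label="%s"];',
                              esc(nd$id), shape[[nd$type]], esc(lab)))
  }
  for (k in seq_len(nrow(rdg$edges))) {
    e <- rdg$edges[k, ]
    lab <- e$kind
    if (!is.null(p) && !is.na(e$choice) && e$from %in% names(p)) {
      pe <- branch_prob(p, e$from)
      pr <- if (e$choice %in% c("initiate", "readthrough", "shift")) pe else 1 - pe
      lab <- sprintf("%s p=%.3g", lab, pr)
    }
    if (!is.null(quant) && e$kind == "initiate" && !is.na(e$translon) &&
        e$translon %in% names(quant$rel_synthesis)) {
      lab <- sprintf("%s (%.3g%%)", lab, quant$rel_synthesis[[e$translon]])
    }
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                              esc(e$from), esc(e$to), esc(lab)))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

translon_granges <- function(rdg) {
  grl <- lapply(rdg$translons, function(t) {
    ## a -1 shift re-reads one nucleotide; clip the overlap so the block
    ## representation stays sorted and disjoint (one block per segment)
    b <- t$segments$begin; e <- t$segments$end
    for (k in seq_along(b)[-1]) b[k] <- max(b[k], e[k - 1L] + 1L)
    GenomicRanges::GRanges(
      seqnames = rdg$transcript$id,
      ranges = IRanges::IRanges(start = b, end = e),
      strand = "+")
  })
  GenomicRanges::GRangesList(grl)
}

#' Export translon segments as GFF3
#'
#' One `translon` parent feature per translon (span = start to end) with one
#' `translon_segment` child per decoded segment; frames and re-initiation
#' competence travel as attributes. 1-based inclusive coordinates.
#'
#' @param rdg An RDG.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_translons_gff <- function(rdg, path) {
  rows <- list()
  for (t in rdg$translons) {
    parent <- GenomicRanges::GRanges(
      rdg$transcript$id,
      IRanges::IRanges(t$start_pos, max(t$segments$end, t$start_pos)), "+")
    S4Vectors::mcols(parent) <- S4Vectors::DataFrame(
      type = "translon", ID = t$id,
      reinit_competent = tolower(as.character(t$reinit_competent)),
      unbounded = tolower(as.character(t$unbounded)))
    rows[[length(rows) + 1L]] <- parent
    for (k in seq_len(nrow(t$segments))) {
      seg <- GenomicRanges::GRanges(
        rdg$transcript$id,
        IRanges::IRanges(t$segments$begin[k], t$segments$end[k]), "+")
      S4Vectors::mcols(seg) <- S4Vectors::DataFrame(
        type = "translon_segment", ID = sprintf("%s.seg%d", t$id, k),
        reinit_competent = NA_character_, unbounded = NA_character_)
      S4Vectors::mcols(seg)$Parent <- t$id
      rows[[length(rows) + 1L]] <- seg
    }
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges()
  } else {
    for (k in seq_along(rows)) {
      if (!"Parent" %in% names(S4Vectors::mcols(rows[[k]]))) {
        S4Vectors::mcols(rows[[k]])$Parent <- NA_character_
      }
    }
    gr <- do.call(c, unname(rows))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export translons as BED12
#'
#' 0-based half-open coordinates via `rtracklayer`; a multi-segment
#' (frameshift) translon becomes a multi-block record.
#'
#' @param rdg An RDG.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_translons_bed <- function(rdg, path) {
  if (!length(rdg$translons)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  grl <- translon_granges(rdg)
  bed <- rtracklayer::asBED(grl)
  bed$name <- names(rdg$translons)
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

#' Read a footprint track
#'
#' Accepts bedGraph (0-based half-open intervals, expanded to per-nucleotide
#' values) or two-column TSV (`pos`, `count`; 1-based). Positions without a
#' record are zero.
#'
#' @param path Input path.
#' @param tx The [transcript()] the track belongs to.
#' @param format `"auto"` (by extension), `"bedgraph"` or `"tsv"`.
#' @return A [footprint_track()].
#' @export
read_track <- function(path, tx, format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  }
  counts <- numeric(tx_len(tx))
  if (format == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == tx$id]
    for (k in seq_along(gr)) {
      idx <- GenomicRanges::start(gr)[k]:GenomicRanges::end(gr)[k]
      idx <- idx[idx >= 1 & idx <= length(counts)]
      counts[idx] <- counts[idx] + gr$score[k]
    }
  } else {
    df <- utils::read.table(path, header = FALSE, col.names = c("pos", "count"))
    keep <- df$pos >= 1 & df$pos <= length(counts)
    counts[df$pos[keep]] <- df$count[keep]
  }
  footprint_track(tx, counts)
}

#' Write a footprint track
#'
#' @param track A [footprint_track()].
#' @param path Output path.
#' @param format `"bedgraph"` (runs of equal value collapsed to intervals)
#'   or `"tsv"` (one line per non-zero position).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "bedgraph") {
    r <- rle(track$counts)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    gr <- GenomicRanges::GRanges(
      track$id, IRanges::IRanges(starts[keep], ends[keep]))
    gr$score <- r$values[keep]
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    nz <- which(track$counts != 0)
    utils::write.table(data.frame(pos = nz, count = track$counts[nz]),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a quantification result
#'
#' Emits a TSV of per-translon relative synthesis and a JSON document with
#' branch probabilities, path probabilities and metadata (the inference
#' assumes no unproductive leakage past the terminal start of a scanning
#' chain).
#'
#' @param quant An [propagate_flux()] result.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Character vector of written paths, invisibly.
#' @export
write_quant <- function(quant, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(
    data.frame(translon = names(quant$rel_synthesis),
               flux = as.numeric(quant$translon_flux),
               rel_synthesis_pct = as.numeric(quant$rel_synthesis)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(p = as.list(quant$p),
         translon_flux = as.list(quant$translon_flux),
         rel_synthesis_pct = as.list(quant$rel_synthesis),
         path_prob = as.list(quant$path_prob),
         metadata = list(
           terminal_start_probability = 1,
           unproductive_leakage_past_last_start = 0)),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = json))
}
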