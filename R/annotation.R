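#' Create a branch-point annotation
#'
#' A branch annotation lists the non-deterministic translation events on one
#' transcript: initiation sites (`starts`), readthrough-permissive stop codons
#' (`secs`, selenocysteine insertion or generic readthrough), and programmed
#' frameshift sites (`shifts`, pairs (i, s) giving the first nucleotide of the
#' last codon decoded in the incoming frame and the re-pairing coordinate in
#' the shifted frame). It also carries the re-initiation policy: translons of
#' at most `reinit_max_codons` codons (stop included) that terminate at a stop
#' leave behind a scanning-competent small subunit, which may re-initiate at
#' downstream starts at least `recharge_distance` nucleotides past the stop
#' (the distance needed to re-acquire the ternary complex; under stress this
#' distance grows, shifting re-initiation to more distal starts).
#'
#' @param starts Integer vector of 1-based initiation-codon positions,
#'   strictly increasing.
#' @param secs Integer vector of readthrough-permissive stop positions.
#' @param shifts Two-column matrix or data.frame of (i, s) pairs, or a list of
#'   length-2 vectors.
#' @param reinit_max_codons Re-initiation competence threshold (codons,
#'   terminating stop included). Default 30: re-initiation is common after
#'   short upstream ORFs and excluded after long translons.
#' @param recharge_distance Minimum scanning distance (nt, measured from the
#'   last nucleotide of the terminating stop) before a post-termination
#'   subunit can initiate again. Default 0.
#' @param deterministic Positions among `starts` treated as non-leaky
#'   (initiation probability 1, no branch node) -- the usual convention for
#'   strong-context CDS starts.
#' @param sec_symbol Single-letter amino acid inserted at readthrough stops in
#'   proteoform output, recycled along `secs`: `"U"` for selenocysteine,
#'   `"X"` for unspecified readthrough (default).
#' @param start_set Codons accepted as starts when validating against a
#'   sequence.
#' @return An object of class `rdg_annotation`.
#' @seealso [parse_branch_notation()], [validate_annotation()]
#' @export
branch_annotation <- function(starts = integer(), secs = integer(),
                              shifts = NULL, reinit_max_codons = 30L,
                              recharge_distance = 0L,
                              deterministic = integer(),
                              sec_symbol = "X",
                              start_set = start_codons()) {
  starts <- as.integer(starts)
  if (is.unsorted(starts, strictly = TRUE)) {
    stop_rdg("rdg_validation_error", "starts must be strictly increasing")
  }
  secs <- sort(as.integer(secs))
  shifts <- normalize_shifts(shifts)
  if (nrow(shifts) && any(shifts$s == shifts$i)) {
    stop_rdg("rdg_validation_error", "shift with s == i is not a branch point")
  }
  deterministic <- as.integer(deterministic)
  if (length(setdiff(deterministic, starts))) {
    stop_rdg("rdg_validation_error",
             "deterministic positions must be a subset of starts")
  }
  if (length(secs)) sec_symbol <- rep_len(sec_symbol, length(secs))
  structure(list(
    starts = starts, secs = secs, shifts = shifts,
    reinit_max_codons = as.integer(reinit_max_codons),
    recharge_distance = as.integer(recharge_distance),
    deterministic = deterministic,
    sec_symbol = if (length(secs)) sec_symbol else character(),
    start_set = toupper(chartr("T", "U", start_set))
  ), class = "rdg_annotation")
}

normalize_shifts <- function(shifts) {
  if (is.null(shifts) || (is.data.frame(shifts) && !nrow(shifts))) {
    return(data.frame(i = integer(), s = integer()))
  }
  if (is.list(shifts) && !is.data.frame(shifts)) {
    shifts <- do.call(rbind, lapply(shifts, function(p) data.frame(i = p[[1]], s = p[[2]])))
  }
  if (is.matrix(shifts)) shifts <- data.frame(i = shifts[, 1], s = shifts[, 2])
  stopifnot(is.data.frame(shifts), ncol(shifts) >= 2)
  names(shifts)[1:2] <- c("i", "s")
  shifts$i <- as.integer(shifts$i); shifts$s <- as.integer(shifts$s)
  shifts[order(shifts$i), c("i", "s"), drop = FALSE]
}

#' @export
print.rdg_annotation <- function(x, ...) {
  cat("<branch annotation>", format_branch_notation(x), "\n")
  cat(sprintf("  reinit_max_codons=%d recharge_distance=%d%s\n",
              x$reinit_max_codons, x$recharge_distance,
              if (length(x$deterministic))
                paste0(" deterministic=", paste(x$deterministic, collapse = ","))
              else ""))
  invisible(x)
}

#' Validate an annotation against a transcript
#'
#' Checks that all positions are in bounds, each start begins a codon in the
#' annotation's start set, each secs position is a stop codon, and shift
#' coordinates are addressable.
#'
#' @param ann An [branch_annotation()].
#' @param tx A [transcript()].
#' @return `ann`, invisibly, or an error of class `rdg_validation_error`.
#' @export
validate_annotation <- function(ann, tx) {
  stopifnot(inherits(ann, "rdg_annotation"), inherits(tx, "rdg_transcript"))
  n <- tx_len(tx)
  all_pos <- c(ann$starts, ann$secs, ann$shifts$i, ann$shifts$s)
  if (length(all_pos) && (min(all_pos) < 1L || max(all_pos) > n - 2L)) {
    stop_rdg("rdg_validation_error",
             "annotation position outside [1, %d]", n - 2L)
  }
  for (x in ann$starts) {
    cod <- codon_at(tx, x)
    if (!cod %in% ann$start_set) {
      stop_rdg("rdg_validation_error",
               "annotated start at %d is '%s', not in start set {%s}",
               x, cod, paste(ann$start_set, collapse = ","))
    }
  }
  for (y in ann$secs) {
    cod <- codon_at(tx, y)
    if (!cod %in% STOP_CODONS) {
      stop_rdg("rdg_validation_error",
               "annotated readthrough site at %d is '%s', not a stop codon",
               y, cod)
    }
  }
  invisible(ann)
}

#' Parse the compact branch-point notation
#'
#' The canonical grammar is `starts(x1;x2;...)` optionally followed by
#' `;secs(y1;...)` and/or `;shifts(i1,s1;...)`; whitespace is ignored and the
#' bare parenthesis-free form (`startsx1;x2`) is accepted on input. Unknown
#' clause names are preserved for forward compatibility: they produce a
#' warning and are otherwise ignored, so notations written by newer tools
#' still parse.
#'
#' @param s Notation string.
#' @param tx Optional [transcript()]; when supplied the parsed annotation is
#'   validated against its sequence.
#' @param ... Passed to [branch_annotation()] (re-initiation policy, start
#'   set, ...).
#' @return An [branch_annotation()].
#' @examples
#' parse_branch_notation("starts(1;13);secs(25)")
#' @export
parse_branch_notation <- function(s, tx = NULL, ...) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  raw <- gsub("[[:space:]]+", "", s)
  clauses <- tokenize_notation(raw)
  starts <- integer(); secs <- integer(); shifts <- NULL
  for (cl in clauses) {
    args <- cl$args
    switch(cl$name,
      starts = {
        starts <- parse_int_args(args, cl$offset)
      },
      secs = {
        secs <- parse_int_args(args, cl$offset)
      },
      shifts = {
        pairs <- strsplit(args, ";", fixed = TRUE)[[1]]
        shifts <- lapply(pairs, function(p) {
          xy <- strsplit(p, ",", fixed = TRUE)[[1]]
          if (length(xy) != 2L || anyNA(suppressWarnings(as.integer(xy)))) {
            stop_rdg("rdg_parse_error",
                     "malformed shift pair '%s' near offset %d", p, cl$offset)
          }
          as.integer(xy)
        })
      },
      {
        warning(sprintf("unknown clause '%s' ignored", cl$name),
                call. = FALSE)
      }
    )
  }
  ann <- branch_annotation(starts = sort(starts), secs = secs,
                           shifts = shifts, ...)
  if (!is.null(tx)) validate_annotation(ann, tx)
  ann
}

## split "name(args);name(args)..." (or the bare legacy form) into clauses
tokenize_notation <- function(raw) {
  clauses <- list()
  pos <- 1L
  n <- nchar(raw)
  while (pos <= n) {
    rest <- substr(raw, pos, n)
    m <- regexpr("^([A-Za-z_]+)", rest)
    if (m == -1L) {
      stop_rdg("rdg_parse_error", "expected clause name at offset %d", pos)
    }
    name <- regmatches(rest, m)
    after <- pos + nchar(name)
    if (after <= n && substr(raw, after, after) == "(") {
      close <- find_close_paren(raw, after)
      args <- substr(raw, after + 1L, close - 1L)
      pos2 <- close + 1L
    } else {
      ## bare form: arguments run until the next clause name
      tail_str <- substr(raw, after, n)
      nm <- regexpr("(starts|secs|shifts)", tail_str)
      ## bare args run up to (not including) the ';' before the next clause
      end <- if (nm == -1L) n else after + nm - 3L
      args <- substr(raw, after, end)
      pos2 <- end + 1L
    }
    clauses[[length(clauses) + 1L]] <- list(name = name, args = args,
                                            offset = pos)
    if (pos2 <= n) {
      if (substr(raw, pos2, pos2) != ";") {
        stop_rdg("rdg_parse_error", "expected ';' at offset %d", pos2)
      }
      pos2 <- pos2 + 1L
    }
    pos <- pos2
  }
  clauses
}

find_close_paren <- function(raw, open) {
  close <- regexpr(")", substr(raw, open, nchar(raw)), fixed = TRUE)
  if (close == -1L) {
    stop_rdg("rdg_parse_error", "unclosed '(' at offset %d", open)
  }
  open + close - 1L
}

parse_int_args <- function(args, offset) {
  if (!nzchar(args)) return(integer())
  vals <- suppressWarnings(as.integer(strsplit(args, ";", fixed = TRUE)[[1]]))
  if (anyNA(vals)) {
    stop_rdg("rdg_parse_error", "malformed integer list near offset %d", offset)
  }
  vals
}

#' Format an annotation in canonical branch-point notation
#'
#' Clauses are emitted in the order starts, secs, shifts with ascending
#' positions and explicit parentheses; `parse_branch_notation(format_branch_notation(a))`
#' reproduces `a`'s event positions exactly.
#'
#' @param ann An [branch_annotation()].
#' @return A single notation string.
#' @examples
#' format_branch_notation(branch_annotation(starts = c(5, 20)))
#' @export
format_branch_notation <- function(ann) {
  stopifnot(inherits(ann, "rdg_annotation"))
  parts <- character()
  if (length(ann$starts)) {
    parts <- c(parts, sprintf("starts(%s)", paste(ann$starts, collapse = ";")))
  }
  if (length(ann$secs)) {
    parts <- c(parts, sprintf("secs(%s)", paste(ann$secs, collapse = ";")))
  }
  if (nrow(ann$shifts)) {
    parts <- c(parts, sprintf("shifts(%s)", paste(
      sprintf("%d,%d", ann$shifts$i, ann$shifts$s), collapse = ";")))
  }
  if (!length(parts)) "starts()" else paste(parts, collapse = ";")
}
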