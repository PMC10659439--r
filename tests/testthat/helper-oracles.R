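# Independent oracles used by the property-style tests. These work directly
# on sequences and annotations (no graph construction) so they provide a
# second route to the same answers.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# brute-force codon-site scan: compare every position against the sets
oracle_scan_codons <- function(seq, start_set) {
  n <- nchar(seq)
  stops <- c("UAA", "UAG", "UGA")
  out <- list()
  for (p in seq_len(max(0L, n - 2L))) {
    cod <- substr(seq, p, p + 2L)
    kind <- if (cod %in% start_set) "start" else if (cod %in% stops) "stop" else NA
    if (!is.na(kind)) {
      out[[length(out) + 1L]] <- data.frame(
        pos = p, frame = (p - 1L) %% 3L, kind = kind, codon = cod,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(data.frame(pos = integer(), frame = integer(),
                                        kind = character(), codon = character(),
                                        stringsAsFactors = FALSE))))
}

# exhaustive (start, stop) pair enumeration for Start-Stop ORFs
oracle_start_stop <- function(seq, start_set) {
  sites <- oracle_scan_codons(seq, start_set)
  out <- list()
  starts <- sites[sites$kind == "start", ]
  stops <- sites[sites$kind == "stop", ]
  for (i in seq_len(nrow(starts))) {
    best <- Inf
    for (j in seq_len(nrow(stops))) {
      d <- stops$pos[j] - starts$pos[i]
      if (d > 0 && d %% 3 == 0 && stops$pos[j] < best) best <- stops$pos[j]
    }
    if (is.finite(best)) {
      out[[length(out) + 1L]] <- c(starts$pos[i], best + 2L)
    }
  }
  out
}

# recursive ribosome simulator: enumerates every decision vector directly on
# the sequence/annotation, without building a graph. Returns a list of
# character vectors: sorted-by-traversal translon start positions per path.
oracle_ribopaths <- function(tx, ann) {
  n <- nchar(tx$seq)
  stops <- c("UAA", "UAG", "UGA")
  paths <- list()
  elongate_end <- function(start) {
    pos <- start
    repeat {
      if (pos + 2L > n) return(list(end = n, stopped = FALSE,
                                    codons = (pos - start) %/% 3))
      cod <- substr(tx$seq, pos, pos + 2L)
      if (cod %in% stops) {
        return(list(end = pos + 2L, stopped = TRUE,
                    codons = (pos + 2L - start + 1L) %/% 3))
      }
      pos <- pos + 3L
    }
  }
  walk <- function(pos, eligible_from, translated) {
    xs <- ann$starts[ann$starts >= max(pos, eligible_from)]
    if (!length(xs)) {
      paths[[length(paths) + 1L]] <<- translated
      return(invisible())
    }
    x <- xs[1L]
    det <- x %in% ann$deterministic
    if (!det) walk(x + 1L, 0L, translated)        # scan through
    tr <- elongate_end(x)                         # initiate
    if (tr$stopped && tr$codons <= ann$reinit_max_codons) {
      walk(tr$end + 1L, tr$end + max(1L, ann$recharge_distance),
           c(translated, x))
    } else {
      paths[[length(paths) + 1L]] <<- c(translated, x)
    }
  }
  walk(1L, 0L, integer())
  paths
}

# random starts-only annotation on a random transcript
random_start_annotation <- function(seed) {
  set.seed(seed)
  tx <- transcript(sprintf("rnd%d", seed), random_rna(sample(120:240, 1)))
  sc <- scan_codons(tx, "AUG")
  starts <- sc$pos[sc$kind == "start"]
  if (!length(starts)) return(NULL)
  k <- sample.int(min(5L, length(starts)), 1)
  use <- sort(starts[sample.int(length(starts), k)])
  ann <- branch_annotation(
    starts = use,
    reinit_max_codons = sample(c(0L, 5L, 30L, 10000L), 1),
    recharge_distance = sample(c(0L, 10L, 60L), 1))
  list(tx = tx, ann = ann)
}

tx_len_for_test <- function(tx) nchar(tx$seq)

fixture_rdg <- function(name, ...) {
  fx <- make_fixture(name, ...)
  list(fx = fx, g = build_rdg(fx$transcript, fx$annotation))
}
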