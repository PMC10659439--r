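## deterministic topological order (DFS postorder from the cap, reversed)
topo_sort <- function(g) {
  adj <- split(g$edges$to, g$edges$from)
  seen <- new.env(parent = emptyenv())
  out <- character(nrow(g$nodes)); k <- nrow(g$nodes)
  visit <- function(v) {
    if (!is.null(seen[[v]])) return(invisible())
    seen[[v]] <- TRUE
    for (w in sort(adj[[v]])) visit(w)
    out[k] <<- v; k <<- k - 1L
  }
  visit("cap")
  out[out != ""]
}

#' Count RiboPaths without enumerating them
#'
#' Dynamic programming over a topological order: the number of cap-to-sink
#' paths, linear in the number of edges. Safe on conceptual RDGs whose path
#' count explodes combinatorially.
#'
#' @param rdg An [build_rdg()] result.
#' @return Integer path count (as a double to tolerate large graphs).
#' @export
count_paths <- function(rdg) {
  ord <- topo_sort(rdg)
  adj <- split(rdg$edges$to, rdg$edges$from)
  np <- stats::setNames(numeric(length(ord)), ord)
  for (v in rev(ord)) {
    ch <- adj[[v]]
    np[v] <- if (is.null(ch) || !length(ch)) 1 else sum(np[ch])
  }
  unname(np["cap"])
}

## paths between two nodes (DP); from == to counts the empty path
count_paths_between <- function(rdg, from, to) {
  ord <- topo_sort(rdg)
  adj <- split(rdg$edges$to, rdg$edges$from)
  np <- stats::setNames(numeric(length(ord)), ord)
  for (v in rev(ord)) {
    np[v] <- if (v == to) 1 else {
      ch <- adj[[v]]
      if (is.null(ch)) 0 else sum(np[ch])
    }
  }
  unname(np[from])
}

#' Enumerate RiboPaths
#'
#' Lists every source-to-sink path of the graph in a deterministic
#' lexicographic order on the decision sequence (at each branch the
#' non-event decision -- scan-through, terminate, continue in frame -- sorts
#' before the event decision). The all-scan-through unproductive path is
#' always present.
#'
#' @param rdg An RDG.
#' @param limit Maximum number of paths to materialize; if [count_paths()]
#'   exceeds it, an error of class `rdg_explosion_error` names the count.
#'   Default 10000: conceptual RDGs are not meant for exhaustive listing.
#' @return A list of `rdg_path` objects: `id`, `nodes`, `events` (data.frame
#'   node/choice for every branch decision), `translons` (ordered ids),
#'   `productive`.
#' @export
enumerate_paths <- function(rdg, limit = 10000L) {
  stopifnot(limit >= 1L)
  total <- count_paths(rdg)
  if (total > limit) {
    stop_rdg("rdg_explosion_error",
             "RDG has %.0f RiboPaths, more than the limit %d", total, limit)
  }
  by_from <- edges_by_from(rdg)
  paths <- list()
  walk <- function(v, nodes, events, translons) {
    out <- by_from[[v]]
    if (is.null(out) || !nrow(out)) {
      p <- structure(list(
        id = length(paths) + 1L, nodes = c(nodes, v),
        events = do.call(rbind, c(events, list(empty_events()))),
        translons = translons, productive = length(translons) > 0L),
        class = "rdg_path")
      paths[[length(paths) + 1L]] <<- p
      return(invisible())
    }
    is_branch <- nrow(out) > 1L
    ## non-event < event so the unproductive all-scan-through path comes first
    rank <- ifelse(out$choice %in% c("initiate", "readthrough", "shift"), 1L, 0L)
    out <- out[order(rank), , drop = FALSE]
    for (k in seq_len(nrow(out))) {
      ev <- events
      if (is_branch) {
        ev <- c(ev, list(data.frame(node = v, choice = out$choice[k],
                                    stringsAsFactors = FALSE)))
      }
      tr <- translons
      if (out$kind[k] == "initiate") tr <- c(tr, out$translon[k])
      walk(out$to[k], c(nodes, v), ev, tr)
    }
  }
  walk("cap", character(), list(), character())
  paths
}

empty_events <- function() {
  data.frame(node = character(), choice = character(), stringsAsFactors = FALSE)
}

#' @export
print.rdg_path <- function(x, ...) {
  cat(sprintf("<RiboPath %d> %s%s\n", x$id,
              if (x$productive) paste(x$translons, collapse = "+")
              else "(unproductive)",
              if (nrow(x$events))
                paste0("  [", paste(sprintf("%s=%s", x$events$node,
                                            x$events$choice), collapse = ", "),
                       "]")
              else ""))
  invisible(x)
}

#' Are two translons mutually exclusive?
#'
#' TRUE iff no RiboPath contains both translons, i.e. no single ribosome can
#' translate both. Computed by path counting through the two initiate edges
#' (no enumeration), so it is safe on large graphs. A translon always
#' co-occurs with itself.
#'
#' @param rdg An RDG.
#' @param a,b Translon ids.
#' @return Logical scalar.
#' @export
mutually_exclusive <- function(rdg, a, b) {
  for (id in c(a, b)) {
    if (!id %in% names(rdg$translons)) {
      stop_rdg("rdg_validation_error", "unknown translon id '%s'", id)
    }
  }
  if (a == b) return(FALSE)
  ea <- rdg$edges[rdg$edges$kind == "initiate" & rdg$edges$translon == a, ]
  eb <- rdg$edges[rdg$edges$kind == "initiate" & rdg$edges$translon == b, ]
  both <- count_paths_between(rdg, ea$to[1], eb$from[1]) +
          count_paths_between(rdg, eb$to[1], ea$from[1])
  both == 0
}

#' Translate every translon into its proteoform
#'
#' One record per translon (the unproductive path encodes nothing and is not
#' reported). Readthrough stops are rendered as the annotation's configured
#' symbol (`U` for selenocysteine sites, `X` for unspecified readthrough);
#' frameshift translons concatenate their segment translations into the
#' trans-frame product. The terminating stop is not included. Two in-frame
#' starts sharing a stop yield proteoforms with alternative N-termini: the
#' shorter is an exact suffix of the longer.
#'
#' @param rdg An RDG.
#' @return data.frame with columns `translon`, `start_pos`, `protein`,
#'   `unbounded` (translated to the 3' end without a stop), `events`.
#' @export
proteoform_sequences <- function(rdg) {
  code <- Biostrings::GENETIC_CODE
  rows <- lapply(rdg$translons, function(t) {
    aa <- character()
    nseg <- nrow(t$segments)
    for (si in seq_len(nseg)) {
      b <- t$segments$begin[si]; e <- t$segments$end[si]
      if (e < b + 2L) next
      cps <- seq.int(b, e - 2L, by = 3L)
      codons <- substring(rdg$transcript$seq, cps, cps + 2L)
      tr <- unname(code[chartr("U", "T", codons)])
      for (k in seq_along(tr)) {
        if (tr[k] == "*") {
          rt <- t$events[t$events$kind == "readthrough" &
                         t$events$pos == cps[k], , drop = FALSE]
          if (nrow(rt)) {
            tr[k] <- rt$detail[1]
          } else if (si == nseg && k == length(tr) && t$stopped) {
            tr[k] <- ""  # terminating stop: not part of the product
          }
        }
      }
      aa <- c(aa, tr)
    }
    data.frame(translon = t$id, start_pos = t$start_pos,
               protein = paste(aa, collapse = ""),
               unbounded = t$unbounded,
               events = if (nrow(t$events))
                 paste(sprintf("%s@%d", t$events$kind, t$events$pos),
                       collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write proteoforms as protein FASTA
#'
#' Record ids have the form `transcript|translon|events` (events empty for
#' plain translons); unbounded translons carry `unbounded` in the
#' description.
#'
#' @param rdg An RDG.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteoform_fasta <- function(rdg, path) {
  pf <- proteoform_sequences(rdg)
  if (!nrow(pf)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ids <- sprintf("%s|%s|%s%s", rdg$transcript$id, pf$translon, pf$events,
                 ifelse(pf$unbounded, " unbounded", ""))
  set <- Biostrings::AAStringSet(pf$protein)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Tabulate RiboPaths
#'
#' @param rdg An RDG.
#' @param p Optional branch probability map (see [propagate_flux()]); when
#'   given, a `probability` column is added.
#' @param limit Passed to [enumerate_paths()].
#' @return data.frame with one row per path: `path`, `decisions`,
#'   `translons`, `productive` and optionally `probability`.
#' @export
path_table <- function(rdg, p = NULL, limit = 10000L) {
  paths <- enumerate_paths(rdg, limit)
  out <- do.call(rbind, lapply(paths, function(pt) data.frame(
    path = pt$id,
    decisions = if (nrow(pt$events))
      paste(sprintf("%s=%s", pt$events$node, pt$events$choice), collapse = ";")
    else "",
    translons = paste(pt$translons, collapse = ","),
    productive = pt$productive,
    stringsAsFactors = FALSE)))
  if (!is.null(p)) {
    out$probability <- vapply(paths, function(pt) path_probability(rdg, pt, p),
                              numeric(1))
  }
  rownames(out) <- NULL
  out
}

## probability of one path = product of its branch decisions under p
path_probability <- function(rdg, path, p) {
  if (!nrow(path$events)) return(prob_of_no_branch(rdg, p))
  pr <- 1
  for (k in seq_len(nrow(path$events))) {
    node <- path$events$node[k]
    choice <- path$events$choice[k]
    pe <- branch_prob(p, node)
    pr <- pr * if (choice %in% c("initiate", "readthrough", "shift")) pe else 1 - pe
  }
  pr
}

prob_of_no_branch <- function(rdg, p) 1

branch_prob <- function(p, node) {
  if (!node %in% names(p)) {
    stop_rdg("rdg_validation_error", "no probability set for branch '%s'", node)
  }
  v <- p[[node]]
  if (v < 0 || v > 1) {
    stop_rdg("rdg_validation_error", "probability %g for '%s' outside [0,1]", v, node)
  }
  v
}
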