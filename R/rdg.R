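#' Build a Ribosome Decision Graph
#'
#' Constructs the directed acyclic graph of scanning/elongation states implied
#' by a transcript and its branch annotation. Scanning complexes enter at the
#' 5' cap and move 3'-ward; each leaky start is a branch node
#' (initiate / scan-through), each annotated readthrough stop a branch node
#' (readthrough / terminate), each shift site a branch node (shift / continue
#' in frame). Ordinary stop codons end translons deterministically: a
#' re-initiation-competent termination resumes scanning strictly 3' of the
#' stop (subject to the annotation's `recharge_distance`), any other
#' termination dissociates. A scanning complex that passes every start runs
#' off the 3' end: the all-scan-through path is the unproductive RiboPath.
#'
#' Starts listed in `ann$deterministic` initiate with probability 1 and are
#' not branch nodes (the usual convention for strong-context CDS starts).
#'
#' @param tx A [transcript()].
#' @param ann An [branch_annotation()]; validated against `tx`.
#' @return An object of class `rdg` with elements `transcript`, `annotation`,
#'   `nodes` (data.frame: id, type, pos, origin, competent), `edges`
#'   (data.frame: from, to, kind, choice, translon), `translons` (named list
#'   of [derive_translon()] results keyed by id T1, T2, ...; only starts
#'   reachable from the cap produce translons).
#' @examples
#' tx <- transcript("t", "ccAUGgccUAAccccc")
#' g <- build_rdg(tx, branch_annotation(starts = 3))
#' g
#' @export
build_rdg <- function(tx, ann) {
  validate_annotation(ann, tx)
  for (k in seq_len(nrow(ann$shifts))) {
    classify_shift(ann$shifts$i[k], ann$shifts$s[k])  # rejects s - i <= -4
  }
  n <- tx_len(tx)
  st <- new.env(parent = emptyenv())
  st$nodes <- list()
  st$edges <- list()
  st$edge_keys <- character()
  st$expanded <- character()

  add_node <- function(id, type, pos = NA_integer_, origin = NA_integer_,
                       competent = NA, end = NA_integer_,
                       codons_before = NA_integer_) {
    if (is.null(st$nodes[[id]])) {
      st$nodes[[id]] <- list(id = id, type = type, pos = pos, origin = origin,
                             competent = competent, end = end,
                             codons_before = codons_before)
    }
    id
  }
  add_edge <- function(from, to, kind, choice = NA_character_,
                       translon_origin = NA_integer_) {
    key <- paste(from, to, kind, sep = "|")
    if (!key %in% st$edge_keys) {
      st$edge_keys <- c(st$edge_keys, key)
      st$edges[[length(st$edges) + 1L]] <-
        list(from = from, to = to, kind = kind, choice = choice,
             translon_origin = translon_origin)
    }
  }
  add_node("cap", "source", pos = 0L)
  add_node("sink:runoff", "sink", pos = n + 1L)

  starts <- ann$starts
  is_det <- starts %in% ann$deterministic
  sec_symbol <- stats::setNames(ann$sec_symbol, ann$secs)

  scan_target <- function(pos, eligible_from = 0L) {
    xs <- starts[starts >= max(pos, eligible_from)]
    if (!length(xs)) return("sink:runoff")
    expand_start(xs[1L])
  }

  expand_start <- function(x) {
    id <- sprintf("start:%d", x)
    det <- x %in% ann$deterministic
    add_node(id, if (det) "start_det" else "branch_start", pos = x, origin = x)
    if (id %in% st$expanded) return(id)
    st$expanded <- c(st$expanded, id)
    entry <- elongate(x, x, 0L)
    add_edge(id, entry, "initiate", choice = "initiate", translon_origin = x)
    if (!det) {
      nxt <- scan_target(x + 1L)
      add_edge(id, nxt, "scan_through", choice = "scan_through")
    }
    id
  }

  terminate_at <- function(origin, stop_end, count, stopped = TRUE) {
    competent <- stopped && count <= ann$reinit_max_codons
    id <- sprintf("term:%d:%d:%s", stop_end, origin,
                  if (competent) "c" else "nc")
    add_node(id, "term", pos = stop_end, origin = origin,
             competent = competent)
    if (id %in% st$expanded) return(id)
    st$expanded <- c(st$expanded, id)
    if (competent) {
      eligible_from <- stop_end + max(1L, ann$recharge_distance)
      nxt <- scan_target(stop_end + 1L, eligible_from)
      add_edge(id, nxt, "terminate_reinitiate")
    } else {
      add_node("sink:dissoc", "sink", pos = NA_integer_)
      add_edge(id, "sink:dissoc", "terminate_dissociate")
    }
    id
  }

  ## elongation chunk starting at `anchor` for the translon initiated at
  ## `origin`, having already decoded `count` codons; returns the entry node
  elongate <- function(origin, anchor, count) {
    if (anchor + 2L > n) return("sink:runoff")
    id <- sprintf("elong:%d:%d", origin, anchor)
    if (!is.null(st$nodes[[id]])) return(id)
    add_node(id, "elong", pos = anchor, origin = origin,
             codons_before = count)
    chunk_end <- NA_integer_
    pos <- anchor
    repeat {
      if (pos + 2L > n) {
        chunk_end <- pos - 1L
        add_edge(id, "sink:runoff", "elongate")
        break
      }
      hit <- which(ann$shifts$i == pos)
      if (length(hit)) {
        i <- ann$shifts$i[hit[1L]]; s <- ann$shifts$s[hit[1L]]
        count <- count + 1L
        chunk_end <- i + 2L
        bid <- sprintf("shift:%d:%d", i, origin)
        add_node(bid, "branch_shift", pos = i, origin = origin)
        add_edge(id, bid, "elongate")
        cont <- elongate(origin, i + 3L, count)
        add_edge(bid, cont, "elongate", choice = "continue")
        shifted <- elongate(origin, shift_resume_pos(i, s), count)
        add_edge(bid, shifted, "shift", choice = "shift")
        break
      }
      cod <- codon_at(tx, pos)
      if (cod %in% STOP_CODONS) {
        count <- count + 1L
        chunk_end <- pos + 2L
        if (pos %in% ann$secs) {
          bid <- sprintf("sec:%d:%d", pos, origin)
          add_node(bid, "branch_sec", pos = pos, origin = origin)
          add_edge(id, bid, "elongate")
          term <- terminate_at(origin, pos + 2L, count)
          add_edge(bid, term, "terminate", choice = "terminate")
          rt <- elongate(origin, pos + 3L, count)
          add_edge(bid, rt, "readthrough", choice = "readthrough")
        } else {
          term <- terminate_at(origin, pos + 2L, count)
          add_edge(id, term, "terminate")
        }
        break
      }
      count <- count + 1L
      pos <- pos + 3L
    }
    st$nodes[[id]]$end <- chunk_end
    id
  }

  first <- scan_target(1L)
  add_edge("cap", first, "scan")

  nodes <- do.call(rbind, lapply(st$nodes, function(nd) data.frame(
    id = nd$id, type = nd$type, pos = nd$pos, origin = nd$origin,
    competent = nd$competent, end = nd$end, codons_before = nd$codons_before,
    stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(st$edges, function(e) data.frame(
    from = e$from, to = e$to, kind = e$kind, choice = e$choice,
    translon_origin = e$translon_origin, stringsAsFactors = FALSE)))
  rownames(nodes) <- rownames(edges) <- NULL

  g <- structure(list(transcript = tx, annotation = ann,
                      nodes = nodes, edges = edges),
                 class = "rdg")
  g <- prune_unreachable(g)
  g$translons <- name_translons(g)
  ## attach ids to initiate edges for convenience
  o2id <- stats::setNames(
    vapply(g$translons, function(t) t$id, character(1)),
    vapply(g$translons, function(t) t$start_pos, integer(1)))
  g$edges$translon <- ifelse(
    g$edges$kind == "initiate",
    unname(o2id[as.character(g$edges$translon_origin)]), NA_character_)
  stopifnot(is_acyclic(g))
  g
}

## drop nodes not reachable from the cap (lazy construction makes this a
## no-op in practice; kept as a guard for hand-edited graphs)
prune_unreachable <- function(g) {
  adj <- split(g$edges$to, g$edges$from)
  seen <- character(); stack <- "cap"
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, adj[[v]])
  }
  g$nodes <- g$nodes[g$nodes$id %in% seen, , drop = FALSE]
  g$edges <- g$edges[g$edges$from %in% seen, , drop = FALSE]
  g
}

## Translon ids (T1, T2, ...) follow first discovery along a deterministic
## initiate-first depth-first traversal from the cap. For plain leaky
## scanning this is start-position order; with re-initiation it reproduces
## the conventional numbering in which the re-initiation target downstream of
## a uORF is numbered before starts that are only reachable by leaky
## scanning past the uORF.
name_translons <- function(g) {
  adj <- edges_by_from(g)
  order_codes <- c(initiate = 0, shift = 0, readthrough = 0)
  seen <- character(); origins <- integer()
  visit <- function(v) {
    if (v %in% seen) return(invisible())
    seen <<- c(seen, v)
    out <- adj[[v]]
    if (is.null(out) || !nrow(out)) return(invisible())
    rank <- ifelse(out$kind %in% names(order_codes), 0L, 1L)
    out <- out[order(rank), , drop = FALSE]
    for (k in seq_len(nrow(out))) {
      if (out$kind[k] == "initiate") {
        o <- out$translon_origin[k]
        if (!o %in% origins) origins <<- c(origins, o)
      }
      visit(out$to[k])
    }
  }
  visit("cap")
  translons <- lapply(seq_along(origins), function(k) {
    t <- walk_translon(g$transcript, origins[k], g$annotation)
    t$id <- sprintf("T%d", k)
    t
  })
  names(translons) <- vapply(translons, function(t) t$id, character(1))
  translons
}

edges_by_from <- function(g) {
  split(g$edges, g$edges$from)
}

is_acyclic <- function(g) {
  ## Kahn's algorithm
  indeg <- table(factor(g$edges$to, levels = g$nodes$id))
  queue <- g$nodes$id[indeg[g$nodes$id] == 0]
  adj <- split(g$edges$to, g$edges$from)
  removed <- 0L
  indeg <- as.list(indeg)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    removed <- removed + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  removed == nrow(g$nodes)
}

#' @export
print.rdg <- function(x, ...) {
  nb <- sum(startsWith(x$nodes$type, "branch"))
  cat(sprintf("<RDG %s> %d nt, %d nodes (%d branch points), %d edges, %d translons\n",
              x$transcript$id, tx_len(x$transcript), nrow(x$nodes), nb,
              nrow(x$edges), length(x$translons)))
  for (t in x$translons) {
    cat(sprintf("  %s: %d..%d (%d codons%s%s)\n", t$id, t$start_pos, t$end_pos,
                t$n_codons,
                if (t$unbounded) ", unbounded" else "",
                if (t$reinit_competent) ", reinit-competent" else ""))
  }
  invisible(x)
}

#' Branch nodes of an RDG
#'
#' @param rdg An [build_rdg()] result.
#' @return data.frame of branch nodes (two or more outgoing decisions),
#'   ordered by position then kind.
#' @export
branch_points <- function(rdg) {
  b <- rdg$nodes[startsWith(rdg$nodes$type, "branch"), , drop = FALSE]
  b <- b[order(b$pos, b$type), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Starts eligible for re-initiation after a termination event
#'
#' After a re-initiation-competent translon terminates, the small subunit
#' resumes scanning 3' of the stop and can initiate only once it has scanned
#' far enough to re-acquire the ternary complex. This query returns the
#' annotated starts at distance at least `recharge_distance` downstream of
#' the termination. Under stress the recharge distance grows, so proximal
#' starts (e.g. the long inhibitory uORF of a delayed re-initiation
#' architecture) drop out of the eligible set while distal starts (the CDS)
#' remain.
#'
#' @param rdg An RDG.
#' @param termination A translon id (e.g. `"T1"`) or a termination node id;
#'   the translon must be re-initiation-competent.
#' @param recharge_distance Scanning distance in nt measured from the last
#'   nucleotide of the terminating stop.
#' @return data.frame with columns `pos` (start position), `node` (branch
#'   node id), `distance` (nt past the stop).
#' @export
reinitiation_eligible_starts <- function(rdg, termination,
                                         recharge_distance = rdg$annotation$recharge_distance) {
  if (termination %in% names(rdg$translons)) {
    t <- rdg$translons[[termination]]
    if (!t$reinit_competent) {
      stop_rdg("rdg_policy_error",
               "translon %s is not re-initiation-competent", termination)
    }
    end_pos <- t$end_pos
  } else {
    nd <- rdg$nodes[rdg$nodes$id == termination, , drop = FALSE]
    if (!nrow(nd) || nd$type != "term") {
      stop_rdg("rdg_validation_error", "unknown termination '%s'", termination)
    }
    if (!isTRUE(nd$competent)) {
      stop_rdg("rdg_policy_error",
               "termination %s is not re-initiation-competent", termination)
    }
    end_pos <- nd$pos
  }
  xs <- rdg$annotation$starts
  dist <- xs - end_pos
  keep <- dist >= max(1L, recharge_distance)
  data.frame(pos = xs[keep], node = sprintf("start:%d", xs[keep]),
             distance = dist[keep])
}
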