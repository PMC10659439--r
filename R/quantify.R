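#' Create a per-nucleotide footprint track
#'
#' Ribosome-profiling A-site counts for one transcript, one value per
#' nucleotide position (1-based). The track is the substrate of
#' quantification and the output of simulation.
#'
#' @param tx A [transcript()] (or a transcript id as character).
#' @param counts Numeric vector of non-negative counts, length equal to the
#'   transcript length.
#' @return An object of class `rdg_track` with `id` and `counts`.
#' @export
footprint_track <- function(tx, counts) {
  id <- if (inherits(tx, "rdg_transcript")) tx$id else as.character(tx)
  counts <- as.numeric(counts)
  if (inherits(tx, "rdg_transcript") && length(counts) != tx_len(tx)) {
    stop_rdg("rdg_validation_error",
             "track length %d != transcript length %d",
             length(counts), tx_len(tx))
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop_rdg("rdg_validation_error", "footprint counts must be non-negative")
  }
  structure(list(id = id, counts = counts), class = "rdg_track")
}

## 1-based first positions of every codon of a translon, in traversal order
translon_codon_starts <- function(t) {
  unlist(lapply(seq_len(nrow(t$segments)), function(si) {
    b <- t$segments$begin[si]; e <- t$segments$end[si]
    if (e < b + 2L) integer() else seq.int(b, e - 2L, by = 3L)
  }), use.names = FALSE)
}

## nt positions of a translon after removing its first `trim` codons
trimmed_span <- function(t, trim) {
  cps <- translon_codon_starts(t)
  if (length(cps) <= trim) return(integer())
  if (trim > 0L) cps <- cps[-seq_len(trim)]
  as.integer(outer(0:2, cps, `+`))
}

#' Translation efficiency of a translon
#'
#' Footprints per codon: the footprint counts mapped to the translon, divided
#' by the number of codons used for the mapping. The first `trim_codons`
#' codons are excluded to avoid the distortion introduced by the high
#' initiation peak (default 5). With `exclusive_only` (the default), only
#' positions lying in exactly one translon's trimmed span are counted --
#' footprints in regions shared between overlapping or nested translons
#' cannot be assigned uniquely and are discarded, and so are the codons
#' carrying them. `frame_aware` additionally restricts counting to positions
#' on the translon's own codon grid (A-site first-nucleotide assignment).
#'
#' @param track A [footprint_track()].
#' @param translon A translon (id or object) of `rdg`.
#' @param rdg The RDG the translon belongs to; needed for exclusivity
#'   filtering (may be NULL when `exclusive_only = FALSE`).
#' @param trim_codons Leading codons to exclude (default 5).
#' @param exclusive_only Count only positions unique to this translon.
#' @param frame_aware Count only in-frame (codon-start) positions.
#' @return Footprints per codon (double).
#' @export
translation_efficiency <- function(track, translon, rdg = NULL,
                                   trim_codons = 5L, exclusive_only = TRUE,
                                   frame_aware = FALSE) {
  stopifnot(inherits(track, "rdg_track"))
  if (is.character(translon)) {
    stopifnot(!is.null(rdg))
    translon <- rdg$translons[[translon]]
  }
  stopifnot(inherits(translon, "rdg_translon"))
  cps <- translon_codon_starts(translon)
  if (length(cps) <= trim_codons) {
    stop_rdg("rdg_validation_error",
             "translon has %d codons, needs more than trim_codons = %d",
             length(cps), trim_codons)
  }
  if (trim_codons > 0L) cps <- cps[-seq_len(trim_codons)]
  if (exclusive_only && !is.null(rdg)) {
    others <- Filter(function(t) !identical(t$start_pos, translon$start_pos)
                     || !identical(t$segments, translon$segments),
                     rdg$translons)
    ## positions anywhere inside another translon are ambiguous, whether or
    ## not they fall in that translon's own trimmed region
    shared <- unique(unlist(lapply(others, trimmed_span, trim = 0L)))
    keep <- vapply(cps, function(cp) !any((cp + 0:2) %in% shared), logical(1))
    cps <- cps[keep]
  }
  if (!length(cps)) return(NaN)
  counts <- if (frame_aware) {
    track$counts[cps]
  } else {
    track$counts[as.integer(outer(0:2, cps, `+`))]
  }
  sum(counts) / length(cps)
}

#' Initiation probability from two translation efficiencies
#'
#' For a leaky-scanning branch feeding an upstream and a downstream translon,
#' the probability of initiating at the upstream start is
#' `p = Ru / (Ru + Rd)`, the upstream share of the observed flux.
#'
#' @param te_upstream,te_downstream Translation efficiencies (footprints per
#'   codon), both non-negative and not both zero.
#' @return Probability in `[0, 1]`.
#' @examples
#' infer_initiation_probability(3, 1)  # 0.75
#' @export
infer_initiation_probability <- function(te_upstream, te_downstream) {
  if (te_upstream < 0 || te_downstream < 0) {
    stop_rdg("rdg_validation_error", "translation efficiencies must be >= 0")
  }
  if (te_upstream + te_downstream == 0) {
    stop_rdg("rdg_undefined_probability_error",
             "both translation efficiencies are zero: no flux observed")
  }
  te_upstream / (te_upstream + te_downstream)
}

## flux through every node and edge under branch probabilities p.
## Unit flux enters at the cap; a branch node splits it p (event edge) /
## 1 - p (non-event edge); all other nodes pass it through.
flux_map <- function(rdg, p) {
  ord <- topo_sort(rdg)
  by_from <- edges_by_from(rdg)
  nodeflux <- stats::setNames(numeric(length(ord)), ord)
  nodeflux["cap"] <- 1
  edgeflux <- numeric(nrow(rdg$edges))
  edge_index <- stats::setNames(seq_len(nrow(rdg$edges)),
                                paste(rdg$edges$from, rdg$edges$to,
                                      rdg$edges$kind, sep = "|"))
  for (v in ord) {
    out <- by_from[[v]]
    if (is.null(out) || !nrow(out)) next
    fl <- nodeflux[v]
    if (nrow(out) == 1L) {
      sh <- fl
    } else {
      pe <- branch_prob(p, v)
      ev <- out$choice %in% c("initiate", "readthrough", "shift")
      sh <- ifelse(ev, fl * pe, fl * (1 - pe))
    }
    for (k in seq_len(nrow(out))) {
      idx <- edge_index[[paste(out$from[k], out$to[k], out$kind[k], sep = "|")]]
      edgeflux[idx] <- edgeflux[idx] + sh[k]
      nodeflux[out$to[k]] <- nodeflux[out$to[k]] + sh[k]
    }
  }
  list(node = nodeflux, edge = edgeflux)
}

#' Propagate branch probabilities to path probabilities and synthesis rates
#'
#' Unit scanning flux enters at the 5' cap and splits at every branch node
#' according to `p`. A translon's synthesis rate is the flux through its
#' initiate edge; path probabilities are the products of branch decisions
#' along each path and sum to 1.
#'
#' @param rdg An RDG.
#' @param p Named numeric: probability of the *event* decision (initiate,
#'   readthrough, shift) for every branch node id (see [branch_points()]).
#' @param limit Path-enumeration cap for the per-path table; path
#'   probabilities are omitted (with a message) when the count exceeds it.
#' @return An object of class `rdg_quant`: `p`, `translon_flux` (named),
#'   `rel_synthesis` (percentages over translons, summing to 100),
#'   `path_prob` (named by path id, sums to 1), `paths` (the path table).
#' @export
propagate_flux <- function(rdg, p, limit = 10000L) {
  bp <- branch_points(rdg)
  missing_p <- setdiff(bp$id, names(p))
  if (length(missing_p)) {
    stop_rdg("rdg_validation_error", "missing probability for branch(es): %s",
             paste(missing_p, collapse = ", "))
  }
  fl <- flux_map(rdg, p)
  init <- rdg$edges$kind == "initiate"
  translon_flux <- stats::setNames(fl$edge[init], rdg$edges$translon[init])
  translon_flux <- translon_flux[names(rdg$translons)]
  rel <- if (sum(translon_flux) > 0) 100 * translon_flux / sum(translon_flux)
         else translon_flux * 0
  path_prob <- NULL; ptab <- NULL
  if (count_paths(rdg) <= limit) {
    ptab <- path_table(rdg, p = p, limit = limit)
    path_prob <- stats::setNames(ptab$probability, ptab$path)
  } else {
    message("path count exceeds limit; per-path probabilities omitted")
  }
  structure(list(p = p, translon_flux = translon_flux,
                 rel_synthesis = rel, path_prob = path_prob, paths = ptab),
            class = "rdg_quant")
}

#' @export
print.rdg_quant <- function(x, ...) {
  cat("<RDG quantification>\n")
  if (length(x$p)) {
    cat("  branch probabilities:\n")
    for (nm in names(x$p)) cat(sprintf("    %s: %.4g\n", nm, x$p[[nm]]))
  }
  if (length(x$rel_synthesis)) {
    cat("  relative synthesis (%):\n")
    for (nm in names(x$rel_synthesis)) {
      cat(sprintf("    %s: %.3g%%\n", nm, x$rel_synthesis[[nm]]))
    }
  }
  invisible(x)
}

is_leaky_chain <- function(rdg) {
  bp <- branch_points(rdg)
  all(bp$type == "branch_start") &&
    !any(rdg$edges$kind == "terminate_reinitiate")
}

#' Fit branch probabilities from translation efficiencies
#'
#' For a pure leaky-scanning chain (start branches only, no re-initiation)
#' the closed form applies: walking 5' to 3', each start takes its share of
#' the remaining flux, `p_k = TE_k / sum(TE_j, j >= k)`; the terminal start
#' gets probability 1 (unproductive leakage past the last start is assumed
#' zero -- it is not identifiable from translation efficiencies alone). For
#' graphs with re-initiation or readthrough/shift branches, probabilities are
#' fit by bounded least squares between the flux predicted by
#' [propagate_flux()] and the observed efficiencies, which are then treated
#' as absolute per-unit-flux densities (footprints per codon divided by
#' sequencing depth); with an unknown scale such graphs are generally not
#' identifiable.
#'
#' @param rdg An RDG.
#' @param te Named numeric of translation efficiencies keyed by translon id;
#'   non-negative, at least one positive.
#' @return Named numeric of event probabilities for every branch node.
#' @export
fit_branch_probabilities <- function(rdg, te) {
  if (!all(names(rdg$translons) %in% names(te))) {
    stop_rdg("rdg_validation_error",
             "missing translation efficiency for translon(s): %s",
             paste(setdiff(names(rdg$translons), names(te)), collapse = ", "))
  }
  te <- te[names(rdg$translons)]
  if (anyNA(te)) {
    stop_rdg("rdg_validation_error",
             "efficiency is NA/NaN for translon(s) %s (no uniquely assignable positions?)",
             paste(names(te)[is.na(te)], collapse = ", "))
  }
  if (any(te < 0) || !any(te > 0)) {
    stop_rdg("rdg_validation_error",
             "translation efficiencies must be >= 0 with at least one positive")
  }
  bp <- branch_points(rdg)
  if (!nrow(bp)) return(stats::setNames(numeric(), character()))
  if (nrow(bp) > length(te)) {
    stop_rdg("rdg_identifiability_error",
             "%d free branch probabilities but only %d translon efficiencies: %s",
             nrow(bp), length(te), paste(bp$id, collapse = ", "))
  }
  if (is_leaky_chain(rdg)) {
    ## closed form, scale-free
    starts_order <- order(vapply(rdg$translons, function(t) t$start_pos,
                                 integer(1)))
    ids <- names(rdg$translons)[starts_order]
    pos <- vapply(rdg$translons[ids], function(t) t$start_pos, integer(1))
    p <- numeric(0)
    for (k in seq_along(ids)) {
      node <- sprintf("start:%d", pos[k])
      if (!node %in% bp$id) next  # deterministic start, p = 1 by convention
      denom <- sum(te[ids[k:length(ids)]])
      if (denom == 0) {
        stop_rdg("rdg_undefined_probability_error",
                 "no flux at or downstream of start %d", pos[k])
      }
      p[node] <- unname(te[ids[k]] / denom)
    }
    return(p)
  }
  ## general graphs: bounded least squares against predicted flux
  objective <- function(par) {
    pm <- stats::setNames(as.list(par), bp$id)
    fl <- flux_map(rdg, pm)
    init <- rdg$edges$kind == "initiate"
    pred <- stats::setNames(fl$edge[init], rdg$edges$translon[init])
    sum((pred[names(te)] - te)^2)
  }
  best <- NULL
  for (p0 in list(rep(0.5, nrow(bp)), rep(0.2, nrow(bp)), rep(0.8, nrow(bp)))) {
    fit <- stats::optim(p0, objective, method = "L-BFGS-B",
                        lower = rep(0, nrow(bp)), upper = rep(1, nrow(bp)),
                        control = list(factr = 10, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## polish from the best optimum
  best <- stats::optim(best$par, objective, method = "L-BFGS-B",
                       lower = rep(0, nrow(bp)), upper = rep(1, nrow(bp)),
                       control = list(factr = 1, maxit = 1000))
  stats::setNames(best$par, bp$id)
}
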