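make_uniform_case <- function(n_codons = 100L) {
  ## one deterministic start, n_codons translon (stop included)
  s <- paste0("gcgcg", "AUG", strrep("GCU", n_codons - 2L), "UAA",
              strrep("GCA", 4L))
  tx <- transcript("u", s)
  g <- build_rdg(tx, branch_annotation(starts = 6, deterministic = 6,
                                       reinit_max_codons = 0L))
  list(tx = tx, g = g, t = g$translons$T1)
}

test_that("TE is footprints per codon after excluding the first five codons", {
  case <- make_uniform_case(100L)
  cps <- rdgraph:::translon_codon_starts(case$t)
  counts <- numeric(tx_len_for_test(case$tx))
  counts[cps[6:100]] <- 1          # one footprint on each codon 6..100
  tr <- footprint_track(case$tx, counts)
  expect_equal(translation_efficiency(tr, case$t, case$g), 1.0)

  ## footprints only in the trimmed region contribute nothing
  counts2 <- numeric(tx_len_for_test(case$tx))
  counts2[cps[1:5]] <- 50
  tr2 <- footprint_track(case$tx, counts2)
  expect_equal(translation_efficiency(tr2, case$t, case$g), 0)

  ## counts outside the translon are ignored too
  counts3 <- counts
  counts3[1:5] <- 99
  expect_equal(translation_efficiency(footprint_track(case$tx, counts3),
                                      case$t, case$g), 1.0)
})

test_that("too-short translons are refused", {
  case <- make_uniform_case(6L)
  tr <- footprint_track(case$tx, numeric(tx_len_for_test(case$tx)))
  expect_error(translation_efficiency(tr, case$t, case$g, trim_codons = 6L),
               class = "rdg_validation_error")
})

test_that("TE equals a direct position-sum oracle on simulated data", {
  r <- fixture_rdg("leaky_chain", k = 2)
  p <- c("start:6" = 0.35)
  tr <- simulate_track(r$g, p, sim_config(depth = 20, seed = 11,
                                          start_peak_fold = 8))
  for (id in names(r$g$translons)) {
    t <- r$g$translons[[id]]
    cps <- rdgraph:::translon_codon_starts(t)[-(1:5)]
    oracle <- sum(tr$counts[as.integer(outer(0:2, cps, `+`))]) / length(cps)
    expect_equal(translation_efficiency(tr, id, r$g), oracle)
  }
})

test_that("the initiation probability formula is Ru/(Ru+Rd)", {
  expect_equal(infer_initiation_probability(2, 2), 0.5)
  expect_equal(infer_initiation_probability(5, 0), 1.0)
  expect_equal(infer_initiation_probability(3, 1), 0.75)
  expect_error(infer_initiation_probability(0, 0),
               class = "rdg_undefined_probability_error")
  expect_error(infer_initiation_probability(-1, 1),
               class = "rdg_validation_error")
})

test_that("flux propagation splits a leaky start p / 1-p", {
  r <- fixture_rdg("leaky_chain", k = 2)
  q <- propagate_flux(r$g, c("start:6" = 0.3))
  expect_equal(unname(q$translon_flux["T1"]), 0.3)
  expect_equal(unname(q$translon_flux["T2"]), 0.7)
  expect_equal(sum(q$path_prob), 1)
  expect_equal(sum(q$rel_synthesis), 100)

  ## all flux to the upstream start: no CDS translation at all
  q1 <- propagate_flux(r$g, c("start:6" = 1))
  expect_equal(unname(q1$translon_flux["T2"]), 0)
})

test_that("flux is conserved at every node", {
  r <- fixture_rdg("fig3")
  p <- c("start:6" = 0.6, "start:16" = 0.2, "start:40" = 0.9)
  fl <- rdgraph:::flux_map(r$g, p)
  for (v in r$g$nodes$id) {
    outflow <- sum(fl$edge[r$g$edges$from == v])
    inflow <- sum(fl$edge[r$g$edges$to == v])
    if (v == "cap") {
      expect_equal(outflow, 1)
    } else if (v %in% r$g$edges$from) {
      expect_equal(outflow, inflow)
    }
  }
  sinks <- setdiff(r$g$nodes$id, r$g$edges$from)
  expect_equal(sum(fl$node[sinks]), 1)
})

test_that("missing branch probabilities are refused", {
  r <- fixture_rdg("fig3")
  expect_error(propagate_flux(r$g, c("start:6" = 0.5)),
               class = "rdg_validation_error")
})

test_that("path probabilities match per-path products from enumeration", {
  r <- fixture_rdg("fig3")
  set.seed(5)
  for (k in 1:10) {
    p <- stats::setNames(runif(3), branch_points(r$g)$id)
    q <- propagate_flux(r$g, p)
    paths <- enumerate_paths(r$g)
    manual <- vapply(paths, function(pt) {
      pr <- 1
      for (j in seq_len(nrow(pt$events))) {
        pe <- p[[pt$events$node[j]]]
        ev <- pt$events$choice[j] %in% c("initiate", "readthrough", "shift")
        pr <- pr * if (ev) pe else 1 - pe
      }
      pr
    }, numeric(1))
    expect_equal(unname(q$path_prob), manual)
    expect_equal(sum(manual), 1, tolerance = 1e-12)
  }
})

test_that("chain inference reduces to the closed form", {
  ## two translons: identical to the Ru/(Ru+Rd) formula
  r <- fixture_rdg("leaky_chain", k = 2)
  te <- c(T1 = 3, T2 = 1)
  p <- fit_branch_probabilities(r$g, te)
  expect_equal(unname(p["start:6"]), infer_initiation_probability(3, 1))

  ## equal efficiencies on a 3-start chain: p = (1/3, 1/2, [1])
  r3 <- fixture_rdg("leaky_chain", k = 3)
  te3 <- c(T1 = 2, T2 = 2, T3 = 2)
  p3 <- fit_branch_probabilities(r3$g, te3)
  expect_equal(unname(p3[c("start:6", "start:126")]), c(1 / 3, 1 / 2))
})

test_that("inferred probability is monotone in the upstream efficiency", {
  r <- fixture_rdg("leaky_chain", k = 2)
  ps <- vapply(seq(0.5, 5, by = 0.5), function(ru)
    unname(fit_branch_probabilities(r$g, c(T1 = ru, T2 = 2))["start:6"]),
    numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("fit then propagate is the identity on noiseless graph fluxes", {
  r <- fixture_rdg("fig3")
  truth <- c("start:6" = 0.45, "start:16" = 0.3, "start:40" = 0.8)
  q <- propagate_flux(r$g, truth)
  fit <- fit_branch_probabilities(r$g, q$translon_flux)
  expect_equal(fit[names(truth)], truth, tolerance = 1e-6)
})

test_that("under-determined graphs raise an identifiability error", {
  ## the readthrough fixture has two branch nodes but a single translon
  r <- fixture_rdg("gpx4_like")
  err <- tryCatch(fit_branch_probabilities(r$g, c(T1 = 1)), error = identity)
  expect_s3_class(err, "rdg_identifiability_error")
  expect_match(conditionMessage(err), "start:6")
})
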