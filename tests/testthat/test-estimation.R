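test_that("a compound with all-zero scores leaves the network unchanged", {
  net <- generate_cascade(synthetic_spec(n_nodes = 8, seed = 3))
  sc <- suppressMessages(docking_scores(data.frame(
    compound = c("null", "hit"),
    target = rep(net$nodes[1:2], each = 2),
    binding_energy = c(0, -8, 0, -8))))
  est <- estimate_compounds(net, sc)
  e <- est$estimates
  expect_equal(e$ne_decrease[e$compound == "null"], 0)
  expect_gt(e$ne_decrease[e$compound == "hit"], 0)
  expect_equal(e$compound[1L], "hit")
})

test_that("NE decrease on a 4-node chain equals hand-computed arithmetic", {
  net <- pathway_network(data.frame(source = c("a", "b", "c"),
                                    target = c("b", "c", "d")))
  # baseline: 3 edges at 1/10, 2 two-hop at 1/20, 1 three-hop at 1/30
  base <- 3 / 10 + 2 / 20 + 1 / 30
  expect_equal(network_efficiency(net), base)
  sc <- docking_scores(data.frame(compound = "c1", target = "b",
                                  binding_energy = -9))
  # b's only out-edge becomes 10^2.3; paths through it lengthen accordingly
  lv <- 10^2.3
  after <- 2 / 10 + 1 / lv + 1 / (10 + lv) + 1 / (lv + 10) + 1 / (10 + lv + 10)
  est <- estimate_compounds(net, sc)
  expect_equal(est$estimates$ne_after, after, tolerance = 1e-12)
  expect_equal(est$estimates$ne_decrease, base - after, tolerance = 1e-12)
})

test_that("compound with no scored target in the network warns, decrease 0", {
  net <- pathway_network(data.frame(source = "a", target = "b"))
  sc <- docking_scores(data.frame(compound = "c1", target = "elsewhere",
                                  binding_energy = -5))
  expect_warning(est <- estimate_compounds(net, sc), "no scored target")
  expect_equal(est$estimates$ne_decrease, 0)
})

test_that("estimate ranking is invariant to adding compounds under fixed refs", {
  spec <- synthetic_spec(n_nodes = 12, n_targets = 4, n_compounds = 6,
                         potency_gradient = seq(-11, -6, length.out = 6),
                         noise_sd = 1, seed = 11)
  net <- generate_cascade(spec)
  sc <- generate_scores(spec, net)
  refs <- reference_energies(sc)
  est_all <- estimate_compounds(net, sc, refs = refs)
  sub <- sc[sc$compound != "cmpd06", ]
  class(sub) <- class(sc)
  est_sub <- estimate_compounds(net, sub, refs = refs)
  common <- est_sub$estimates$compound
  ord_all <- est_all$estimates$compound[est_all$estimates$compound %in% common]
  expect_equal(est_sub$estimates$compound, ord_all)
})

test_that("ne_decrease is monotone in a single binding energy", {
  net <- generate_cascade(synthetic_spec(n_nodes = 10, seed = 5))
  tg <- net$edges$source[1L]
  decs <- vapply(c(-2, -5, -8, -10), function(be) {
    sc <- docking_scores(data.frame(
      compound = c("probe", "anchor"), target = tg,
      binding_energy = c(be, -10)))
    est <- estimate_compounds(net, sc)
    e <- est$estimates
    e$ne_decrease[e$compound == "probe"]
  }, numeric(1))
  expect_true(all(diff(decs) >= -1e-12))
})

test_that("ne_estimate methods print, summarize and expose coefficients", {
  net <- generate_cascade(synthetic_spec(n_nodes = 10, seed = 5))
  spec <- synthetic_spec(n_nodes = 10, n_targets = 3, n_compounds = 4,
                         potency_gradient = seq(-10, -4, length.out = 4),
                         noise_sd = 0, seed = 5)
  sc <- generate_scores(spec, net)
  est <- estimate_compounds(net, sc)
  expect_output(print(est), "baseline NE")
  expect_output(summary(est), "Top compound")
  cf <- coef(est)
  expect_named(cf)
  expect_equal(unname(cf), est$estimates$ne_decrease)
})

test_that("hierarchical screen keeps ceiling(fraction * n) compounds", {
  spec <- synthetic_spec(n_nodes = 15, n_targets = 5, n_compounds = 20,
                         potency_gradient = seq(-12, -4, length.out = 20),
                         noise_sd = 0.3, seed = 21)
  net <- generate_cascade(spec)
  s1 <- generate_scores(spec, net)
  spec2 <- spec; spec2$seed <- 22L
  s2 <- generate_scores(spec2, net)
  scr <- hierarchical_screen(net, s1, s2, keep_fraction = 0.10)
  expect_length(scr$survivors, 2L)   # ceil(0.1 * 20)
  expect_equal(nrow(scr$stage2$estimates), 2L)
  # keep_fraction 1 ranks everything under stage 2
  scr_all <- hierarchical_screen(net, s1, s2, keep_fraction = 1)
  expect_equal(nrow(scr_all$stage2$estimates), 20L)
  # ceiling guarantees at least one survivor
  scr_min <- hierarchical_screen(net, s1, s2, keep_fraction = 0.01)
  expect_length(scr_min$survivors, 1L)
})

test_that("hierarchical screen errors when stage 2 misses survivors", {
  spec <- synthetic_spec(n_nodes = 12, n_targets = 4, n_compounds = 10,
                         potency_gradient = seq(-12, -4, length.out = 10),
                         noise_sd = 0, seed = 31)
  net <- generate_cascade(spec)
  s1 <- generate_scores(spec, net)
  s2 <- s1[s1$compound != "cmpd01", ]
  class(s2) <- class(s1)
  expect_error(hierarchical_screen(net, s1, s2, keep_fraction = 0.10),
               "cmpd01")
})

test_that("drug-target network thresholds and degrees", {
  sc <- docking_scores(data.frame(
    compound = rep(c("rutin", "weak"), c(3, 2)),
    target = c("t1", "t2", "t3", "t1", "t2"),
    binding_energy = c(-9, -8, -7, -2, -1)))
  dtn <- drug_target_network(sc, threshold = 5)
  expect_equal(nrow(dtn), 3L)
  deg <- attr(dtn, "degree")
  expect_equal(unname(deg[c("rutin", "weak")]), c(3L, 0L))
  # degree equals the brute-force row count above threshold
  expect_equal(unname(deg["rutin"]),
               sum(sc$compound == "rutin" & abs(sc$binding_energy) >= 5))
  # threshold above all energies: empty network
  expect_equal(nrow(drug_target_network(sc, threshold = 99)), 0L)
  expect_error(drug_target_network(sc), "threshold")
})

test_that("a compound binding all 14 targets gets degree 14", {
  sc <- docking_scores(data.frame(
    compound = "rutin", target = sprintf("t%02d", 1:14),
    binding_energy = rep(-8, 14)))
  dtn <- drug_target_network(sc, threshold = 6)
  expect_equal(unname(attr(dtn, "degree")["rutin"]), 14L)
})
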