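toy_scores <- function() {
  docking_scores(data.frame(
    compound = c("c1", "c1", "c2", "c2", "c3"),
    target = c("tx", "ty", "tx", "ty", "tx"),
    binding_energy = c(-9, -3, -4.5, 0, -1)))
}

test_that("positive energies are clamped to zero with a message", {
  expect_message(
    sc <- docking_scores(data.frame(compound = "c1", target = "t",
                                    binding_energy = 1.2)),
    "clamped")
  expect_equal(sc$binding_energy, 0)
  sc2 <- docking_scores(data.frame(compound = "c1", target = "t",
                                   binding_energy = -7.5))
  expect_equal(sc2$binding_energy, -7.5)
  expect_error(docking_scores(data.frame(compound = "c1", target = "t",
                                         binding_energy = 1),
                              clamp_positive = FALSE),
               "positive")
})

test_that("duplicate and malformed rows are rejected", {
  expect_error(docking_scores(data.frame(
    compound = c("c1", "c1"), target = c("thrombin", "thrombin"),
    binding_energy = c(-1, -2))), "duplicate")
  expect_error(docking_scores(data.frame(compound = "c1", target = "t")),
               "missing column")
  expect_error(docking_scores(data.frame(compound = "c1", target = "t",
                                         binding_energy = "strong")),
               "row 1")
})

test_that("score files load with delimiter auto-detection", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,target,binding_energy", "c1,tx,-9", "c1,ty,2"), f)
  expect_message(sc <- load_scores(f), "clamped")
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$binding_energy, c(-9, 0))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\ttarget\tbinding_energy\tstage",
               "c1\ttx\t-5\tautodock"), f2)
  sc2 <- load_scores(f2)
  expect_equal(sc2$stage, "autodock")
})

test_that("reference energies are per-target minima with degenerate flags", {
  sc <- docking_scores(data.frame(
    compound = c("a", "b", "c", "a", "b"),
    target = c("tx", "tx", "tx", "ty", "ty"),
    binding_energy = c(-3, -9, 0, 0, 0)))
  refs <- reference_energies(sc)
  expect_equal(refs$bes[refs$target == "tx"], -9)
  expect_false(refs$degenerate[refs$target == "tx"])
  expect_true(refs$degenerate[refs$target == "ty"])
  # brute-force per-group minimum agrees
  expect_equal(refs$bes,
               as.numeric(tapply(sc$binding_energy, sc$target, min)[refs$target]))
  expect_error(reference_energies(docking_scores(
    data.frame(compound = character(), target = character(),
               binding_energy = numeric()))), "empty")
})

test_that("line value calibration: reference binder maps to 10^2.3", {
  expect_equal(line_value(-9, -9), 10^2.3)
  expect_equal(signif(line_value(-9, -9), 3), 200)
  expect_equal(line_value(-4.5, -9), 10^1.15)
  # non-binder floored at the baseline
  expect_equal(line_value(0, -9), 10)
  # floor disabled: raw value 1
  expect_equal(line_value(0, -9, lv_floor = NULL), 1)
  expect_error(line_value(-1, 0), "degenerate")
  expect_error(line_value(2, -9), "<= 0")
})

test_that("line value is bounded and monotone in |be|", {
  bes <- -10
  be <- seq(0, -10, by = -0.5)
  lv <- line_value(be, bes)
  expect_true(all(lv >= 10))
  expect_true(all(lv <= 10^2.3 + 1e-9))
  raw <- line_value(be, bes, lv_floor = NULL)
  expect_true(all(diff(raw) > 0))       # strictly increasing in |be|
  expect_true(all(diff(lv) >= 0))       # nondecreasing with the floor
})

test_that("reweighting touches exactly the out-edges of scored targets", {
  net <- pathway_network(data.frame(
    source = c("tx", "tx", "ty", "a", "b"),
    target = c("a", "b", "b", "ty", "c")))
  sc <- toy_scores()
  rw <- reweight_network(net, sc, "c1")
  key <- paste0(rw$edges$source, "->", rw$edges$target)
  lv <- setNames(rw$edges$line_value, key)
  expect_equal(unname(lv[c("tx->a", "tx->b")]), rep(10^2.3, 2))  # be = bes
  expect_equal(unname(lv["ty->a"]), NA_real_)  # no such edge
  expect_equal(unname(lv["ty->b"]), 10^(2.3 * 3 / 3))
  expect_equal(unname(lv[c("a->ty", "b->c")]), c(10, 10))
  # original untouched
  expect_true(all(net$edges$line_value == 10))
})

test_that("reference-strength compound reweights only its target's out-edges", {
  net <- clotting_cascade()
  sc <- docking_scores(data.frame(compound = c("ref", "weak"),
                                  target = c("thrombin", "thrombin"),
                                  binding_energy = c(-9, -3)))
  rw <- reweight_network(net, sc, "ref")
  out <- rw$edges$source == "thrombin"
  expect_true(all(rw$edges$line_value[out] == 10^2.3))
  expect_true(all(rw$edges$line_value[!out] == 10))
})

test_that("unknown targets are skipped with a warning", {
  net <- pathway_network(data.frame(source = "a", target = "b"))
  sc <- docking_scores(data.frame(compound = "c1", target = "nowhere",
                                  binding_energy = -5))
  expect_warning(rw <- reweight_network(net, sc, "c1"), "nowhere")
  expect_equal(rw$edges$line_value, 10)
})

test_that("reweighted NE never exceeds the baseline (floor rule)", {
  set.seed(404)
  for (i in 1:25) {
    net <- random_digraph(6, 10, weights = 10)
    sc <- docking_scores(data.frame(
      compound = "c",
      target = sample(net$nodes, 3),
      binding_energy = -runif(3, 0, 12)))
    rw <- suppressWarnings(reweight_network(net, sc, "c"))
    expect_lte(network_efficiency(rw), network_efficiency(net) + 1e-12)
  }
})
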