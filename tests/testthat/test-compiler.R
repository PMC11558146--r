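test_that("recipe_concentrations evaluates the gate formulas", {
  rec <- recipe_concentrations(10, matrix(4))
  expect_equal(as.numeric(rec$sg), 4.8)
  expect_equal(as.numeric(rec$sumx), 7.2)
  expect_equal(as.numeric(rec$fuel), 2 * (10 + 4))
  # negative weight: subtraction gate clamps to zero, |a - b| = a + |b|
  rec <- recipe_concentrations(10, matrix(-4))
  expect_equal(as.numeric(rec$sg), 0)
  expect_equal(as.numeric(rec$sumx), 16.8)
  # closed forms for the competitive-layer gates from d = (2, 4, 6):
  # single feature a = 0 against prototype weights 2, 4, 6
  rec <- recipe_concentrations(0, matrix(c(2, 4, 6), 1, 3))
  expect_equal(rec$d, c(2, 4, 6))
  expect_equal(rec$s, c(5, 4, 3))
  expect_equal(rec$srg, 6)
  expect_equal(rec$rsg, 6)
  expect_equal(rec$anh, 6)
  expect_equal(rec$re, 5)
  expect_equal(rec$r, 7.5)
})

test_that("input activation is catalytic and converts all substrates", {
  # a_i = 0: nothing moves
  net0 <- build_input_activation(0, matrix(5))
  sim0 <- simulate(net0, t_end = 1000, n_points = 50)
  expect_equal(unname(sim0$final["X[i=1,j=1]"]), 0)
  # substrate totals are the turnover oracle: X -> a, W -> |b|
  net <- build_input_activation(10, matrix(5))
  sim <- simulate(net, t_end = 30000)
  expect_equal(unname(sim$final["X[i=1,j=1]"]), 10, tolerance = 0.01)
  expect_equal(unname(sim$final["W[i=1,j=1]"]), 5, tolerance = 0.01)
  # negative weight emits the NW strand instead of W
  netn <- build_input_activation(10, matrix(-5))
  expect_true("NW[i=1,j=1]" %in% netn$species$name)
  expect_false("W[i=1,j=1]" %in% netn$species$name)
  expect_error(build_input_activation(-1, matrix(1)), "negative input")
})

test_that("subtraction annihilation consumes the minority strand", {
  # X = W: both decay toward zero (summation gates absent)
  net <- distance_crn(10, 10, sg = 12, sumx = 0, sumw = 0, sum_gate = 0)
  sim <- simulate(net, t_end = 30000)
  x_tot <- sum(sim$final[c("X[i=1,j=1]", "SGIX[i=1,j=1]")])
  w_tot <- sum(sim$final[c("W[i=1,j=1]", "SGIW[i=1,j=1]")])
  expect_lt(max(x_tot, w_tot), 0.5)
  # X = 8, W = 2: W exhausted, 6 nM of X material survives
  net <- distance_crn(8, 2, sg = 12, sumx = 0, sumw = 0, sum_gate = 0)
  sim <- simulate(net, t_end = 30000)
  x_tot <- sum(sim$final[c("X[i=1,j=1]", "SGIX[i=1,j=1]")])
  w_tot <- sum(sim$final[c("W[i=1,j=1]", "SGIW[i=1,j=1]")])
  expect_equal(x_tot, 6, tolerance = 0.01)
  expect_lt(w_tot, 0.05)
  # negative weight: no subtraction gate is emitted, X stays untouched
  net <- distance_crn(10, -5, sumx = 0, sumw = 0, sum_gate = 0)
  expect_false(any(grepl("^SG", net$species$name)))
  sim <- simulate(net, t_end = 1000, n_points = 50)
  expect_equal(unname(sim$final["X[i=1,j=1]"]), 10)
})

test_that("absolute-value summation funnels residues into D", {
  # nothing in, nothing out
  net <- distance_crn(0, 0, sumx = 12, sumw = 12, sum_gate = 12, sg = 12)
  sim <- simulate(net, t_end = 1000, n_points = 50)
  expect_equal(unname(sim$final["D[j=1]"]), 0)
  # 6 nM of leftover X converts to D within 1% given ample gates
  net <- build_abs_summation(6, matrix(0), sumx = 12, sumw = 12,
                             sum_gate = 12)
  net$species$initial[net$species$name == "X[i=1,j=1]"] <- 6
  sim <- simulate(net, t_end = 30000)
  expect_equal(unname(sim$final["D[j=1]"]), 6, tolerance = 0.01)
  # signed weight: D approaches a + |b| with recipe gates
  net <- distance_crn(10, -5)
  sim <- simulate(net, t_end = 30000)
  expect_equal(unname(sim$final["D[j=1]"]), 15, tolerance = 0.01)
})

test_that("loser-take-all reverses and selects the minimum", {
  # ideal algebra: s_k = (sum d - d_k) / (n - 1)
  frag <- build_loser_take_all(c(2, 4, 6))
  expect_equal(frag$metadata$s_ideal, c(5, 4, 3))
  expect_error(build_loser_take_all(5), "at least two")
  # symmetric inputs give identical trajectories
  net <- lta_crn(c(30, 30, 30))
  sim <- simulate(net, t_end = 2000, n_points = 100)
  s_cols <- paste0("S[k=", 1:3, "]")
  expect_equal(sim$conc[, s_cols[1]], sim$conc[, s_cols[2]],
               tolerance = 1e-8)
  expect_equal(sim$conc[, s_cols[1]], sim$conc[, s_cols[3]],
               tolerance = 1e-8)
  # kinetic run: minimum input survives with normalized output ~ 1
  res <- run_lta_fixture(c(20, 40, 60))
  expect_identical(res$winner, 1L)
  expect_equal(max(res$normalized), 1)
  expect_lt(res$normalized[2], 0.5)
})

test_that("reporting wires competitive neurons to their class outputs", {
  # no surviving reverse signal: all outputs stay zero
  net <- build_reporting(c(1, 2), c(5, 5))
  sim <- simulate(net, t_end = 1000, n_points = 50)
  expect_equal(unname(sim$final[c("FLUOR[l=1]", "FLUOR[l=2]")]), c(0, 0))
  # survivor S_2 mapped to output 1 lights Y_1 only
  net <- build_reporting(c(2, 1, 2), c(5, 5, 5))
  net$species$initial[net$species$name == "S[k=2]"] <- 5
  sim <- simulate(net, t_end = 30000)
  expect_gt(sim$final["FLUOR[l=1]"], 4.5)
  expect_lt(sim$final["FLUOR[l=2]"], 1e-6)
  # two prototypes on the same output: either survivor lights it
  for (k in c(1, 3)) {
    net <- build_reporting(c(2, 1, 2), c(5, 5, 5))
    net$species$initial[net$species$name == sprintf("S[k=%d]", k)] <- 5
    sim <- simulate(net, t_end = 30000)
    expect_gt(sim$final["FLUOR[l=2]"], 4.5)
  }
  expect_error(build_reporting(c(1, NA), c(5, 5)), "unmapped")
})

test_that("compiled network recovers the nearest-prototype decision", {
  # (1, 2, 2): input exactly on prototype 1
  d <- data.frame(id = 1:8, label = factor(rep(c("a", "b"), each = 4)),
                  f1 = c(100, 120, 110, 130, 800, 820, 810, 830))
  fit <- lvq(d["f1"], d$label, n_prototypes = 2, seed = 1, epochs = 20)
  x_on_proto <- unscale_features(fit$weights[1, , drop = FALSE],
                                 fit$scaling)
  net <- compile_network(fit, as.numeric(x_on_proto))
  sim <- simulate(net, t_end = 30000)
  dg <- call_diagnosis(sim)
  expect_identical(dg$predicted, fit$prototype_class[1])
  # degenerate tie: a mirror-symmetric input is equidistant from both
  # prototypes, annihilation suppresses both outputs symmetrically
  tie_fit <- fit
  tie_fit$weights <- matrix(c(400, 600, 600, 400), 2, 2)
  tie_fit$shape <- c(i = 2L, j = 2L, l = 2L)
  net <- compile_network(tie_fit, c(500, 500), scaled = TRUE)
  sim <- simulate(net, t_end = 30000)
  expect_true(call_diagnosis(sim)$undetermined)
})

test_that("(10, 3, 2) network compiles, validates, simulates cleanly", {
  mk <- make_fit(n_prototypes = 3, seed = 7, n = c(60, 60))
  net <- compile_network(mk$fit, mk$x[5, ])
  expect_true(validate_crn(net)$ok)
  sim <- simulate(net, t_end = 30000)
  expect_gt(min(sim$conc), -1e-9)
})

test_that("census counts reagent strands per module", {
  # (1, 2, 2) network: hand enumeration
  d <- data.frame(id = 1:8, label = factor(rep(c("a", "b"), each = 4)),
                  f1 = c(100, 120, 110, 130, 800, 820, 810, 830))
  fit <- lvq(d["f1"], d$label, n_prototypes = 2, seed = 1, epochs = 20)
  net <- compile_network(fit, 150)
  cen <- census(net)
  # XSUB 2, WSUB 2, XFUEL 1, SG 2, SUMX 2, SUMW 2, SUM 2,
  # SRG 2, RSG 2, ANH 1, RE 2, R 2  = 22
  expect_identical(attr(cen, "total"), 22L)
  by_mod <- stats::setNames(cen$strands, cen$module)
  expect_identical(by_mod[["input_activation"]], 5L)
  expect_identical(by_mod[["subtraction_annihilation"]], 2L)
  expect_identical(by_mod[["abs_summation"]], 6L)
  expect_identical(by_mod[["annihilation"]], 1L)
  # census depends on shape and weight signs only, not the sample
  mk <- make_fit(n_prototypes = 3, seed = 7, n = c(60, 60))
  c1 <- census(compile_network(mk$fit, mk$x[1, ]))
  c2 <- census(compile_network(mk$fit, mk$x[33, ]))
  expect_identical(attr(c1, "total"), attr(c2, "total"))
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("leak mode adds a parallel channel per bimolecular reaction", {
  net <- distance_crn(4, 6)
  leaky <- molvq:::add_leak_channels(net)
  n_bi <- sum(!is.na(net$reactions$r2))
  expect_identical(nrow(leaky$reactions), nrow(net$reactions) + n_bi)
  expect_true(all(leaky$reactions$rate[leaky$reactions$module == "leak"] ==
                    1e-9))
})
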