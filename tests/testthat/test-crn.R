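test_that("validate_crn reports structural findings", {
  expect_true(validate_crn(crn())$ok)
  bad <- abc_crn()
  bad$reactions$p1 <- "GHOST"
  v <- validate_crn(bad)
  expect_false(v$ok)
  expect_match(v$findings, "GHOST", all = FALSE)
  # compiled network is valid by construction
  mk <- make_fit(n_prototypes = 2, seed = 2, n = c(25, 25))
  net <- compile_network(mk$fit, mk$x[1, ])
  expect_true(validate_crn(net)$ok)
})

test_that("conservation_laws returns the left null space", {
  laws <- conservation_laws(abc_crn())
  expect_identical(ncol(laws), 2L)
  # A - B and A + C are conserved: both lie in the span of the returned basis
  for (target in list(c(A = 1, B = -1, C = 0), c(A = 1, B = 0, C = 1))) {
    aug <- cbind(laws, target[rownames(laws)])
    expect_identical(qr(aug)$rank, 2L)
  }
  # annihilation subsystem vs a numeric null-space oracle
  net <- anh_crn()
  laws <- conservation_laws(net)
  S <- molvq:::stoich_matrix(net)
  expect_identical(ncol(laws), nrow(S) - qr(S)$rank)
  expect_lt(max(abs(t(laws) %*% S)), 1e-8)
  # every law of a compiled network annihilates every stoichiometry vector
  mk <- make_fit(n_prototypes = 2, seed = 2, n = c(25, 25))
  net <- compile_network(mk$fit, mk$x[2, ])
  S <- molvq:::stoich_matrix(net)
  laws <- conservation_laws(net)
  expect_gt(ncol(laws), 0L)
  expect_lt(max(abs(t(laws) %*% S)), 1e-6)
})

test_that("merge_crns unifies shared species and is associative", {
  a <- build_loser_take_all(c(2, 4, 6), d_init = c(2, 4, 6))
  empty <- crn()
  m <- merge_crns(list(a, empty))
  expect_identical(m$species, a$species)
  expect_identical(m$reactions, a$reactions)
  # input layer and competitive layer share D[j]
  x <- c(5, 7)
  b <- matrix(c(3, 9, 2, 2), 2, 2)
  up <- merge_crns(list(build_subtraction_annihilation(x, b),
                        build_abs_summation(x, b)))
  down <- build_loser_take_all(colSums(abs(x - b)))
  both <- merge_crns(list(up, down))
  expect_identical(sum(both$species$name == "D[j=1]"), 1L)
  expect_identical(nrow(both$reactions),
                   nrow(up$reactions) + nrow(down$reactions))
  # associativity on three parts
  rep_part <- build_reporting(c(1, 2), c(4, 4))
  m1 <- merge_crns(list(merge_crns(list(up, down)), rep_part))
  m2 <- merge_crns(list(up, merge_crns(list(down, rep_part))))
  o1 <- m1$species[order(m1$species$name), ]
  o2 <- m2$species[order(m2$species$name), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(m1$reactions[order(m1$reactions$r1, m1$reactions$rate), ],
               m2$reactions[order(m2$reactions$r1, m2$reactions$rate), ],
               ignore_attr = TRUE)
})

test_that("merge_crns sums doubly-declared nonzero initials and rejects
           conflicting metadata", {
  a <- crn(data.frame(name = "X", role = "X", initial = 3, module = "m"),
           metadata = list(tag = 1))
  b <- crn(data.frame(name = "X", role = "X", initial = 4, module = "m"))
  expect_equal(merge_crns(list(a, b))$species$initial, 7)
  c2 <- crn(metadata = list(tag = 2))
  expect_error(merge_crns(list(a, c2)), "conflicting metadata")
})

test_that("reaction-list export round-trips losslessly", {
  one <- abc_crn(k = 0.0123, a0 = 1.5, b0 = 2.25)
  path <- tempfile(fileext = ".txt")
  export_crn(one, path, "reactions")
  expect_identical(sum(grepl("^reaction ", readLines(path))), 1L)
  back <- read_crn(path, "reactions")
  expect_identical(back$species$name, one$species$name)
  expect_equal(back$species$initial, one$species$initial, tolerance = 1e-12)
  expect_equal(back$reactions$rate, one$reactions$rate)
  expect_identical(unclass(back$rates), unclass(one$rates))
  # a compiled network round-trips too
  mk <- make_fit(n_prototypes = 2, seed = 2, n = c(25, 25))
  net <- compile_network(mk$fit, mk$x[1, ])
  export_crn(net, path, "reactions")
  back <- read_crn(path, "reactions")
  expect_setequal(back$species$name, net$species$name)
  expect_equal(back$species$initial[match(net$species$name,
                                          back$species$name)],
               net$species$initial, tolerance = 1e-12)
  key <- function(z) paste(z$r1, z$r2, z$p1, z$p2, z$p3, z$rate)
  expect_setequal(key(back$reactions), key(net$reactions))
})

test_that("SBML export parses back with identical network content", {
  mk <- make_fit(n_prototypes = 2, seed = 2, n = c(25, 25))
  net <- compile_network(mk$fit, mk$x[1, ])
  path <- tempfile(fileext = ".xml")
  export_crn(net, path, "sbml")
  doc <- xml2::read_xml(path)           # well-formed XML
  expect_identical(xml2::xml_name(doc), "sbml")
  expect_identical(xml2::xml_attr(doc, "level"), "3")
  back <- read_crn(path, "sbml")
  expect_setequal(back$species$name, net$species$name)
  expect_equal(back$species$initial[match(net$species$name,
                                          back$species$name)],
               net$species$initial, tolerance = 1e-12)
  key <- function(z) paste(z$r1, z$r2, z$p1, z$p2, z$p3,
                           signif(z$rate, 15))
  expect_setequal(key(back$reactions), key(net$reactions))
})

test_that("species_table parses the naming grammar", {
  net <- distance_crn(4, 6)
  tab <- species_table(net)
  d_row <- tab[tab$name == "D[j=1]", ]
  expect_identical(d_row$j, 1L)
  expect_true(is.na(d_row$i))
  sg <- tab[tab$name == "SG[i=1,j=1]", ]
  expect_identical(c(sg$i, sg$j), c(1L, 1L))
})
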