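test_that("Koopmans inversion and the descriptor identities hold exactly", {
  ia <- koopmans_ia(-5.0, -1.0)
  expect_equal(ia$I, 5.0)
  expect_equal(ia$A, 1.0)
  expect_equal(koopmans_ia(0, 0), list(I = 0, A = 0))

  g <- global_descriptors(2, 0)
  expect_equal(g, list(mu = -1, chi = 1, eta = 2, softness = 0.5,
                       omega = 0.25))
  expect_error(global_descriptors(1, 1), "zero")

  # identity chain on random frontier pairs
  set.seed(6)
  for (k in 1:25) {
    eh <- runif(1, -9, -2); el <- runif(1, eh + 0.1, 0)
    ia <- koopmans_ia(eh, el)
    g <- global_descriptors(ia$I, ia$A)
    expect_equal(g$softness * g$eta, 1, tolerance = 1e-12)
    expect_equal(g$omega * 2 * g$eta, g$mu^2, tolerance = 1e-12)
    expect_equal(g$chi, -g$mu, tolerance = 1e-15)
    # round trip through the frontier energies
    fr <- frontier_from_mu_eta(g$mu, g$eta)
    expect_equal(fr$e_homo, eh, tolerance = 1e-12)
    expect_equal(fr$e_lumo, el, tolerance = 1e-12)
  }

  # widening the gap at fixed midpoint raises hardness, lowers softness
  gaps <- c(1, 2, 4)
  etas <- vapply(gaps, function(d) {
    fr <- frontier_from_mu_eta(-4, d)
    g <- global_descriptors(-fr$e_homo, -fr$e_lumo)
    g$eta
  }, 0)
  expect_true(all(diff(etas) > 0))
  expect_true(all(diff(1 / etas) < 0))
})

test_that("the most active compound's descriptors come out as published", {
  # frontier energies implied by mu = -3.5320, eta = 3.5277
  fr <- frontier_from_mu_eta(-3.5320, 3.5277)
  expect_equal(fr$e_homo, -5.29585, tolerance = 1e-10)
  expect_equal(fr$e_lumo, -1.76815, tolerance = 1e-10)
  ia <- koopmans_ia(fr$e_homo, fr$e_lumo)
  expect_equal(ia$I, 5.29585, tolerance = 1e-10)
  g <- global_descriptors(ia$I, ia$A)
  expect_equal(round(g$softness, 4), 0.2835)
  expect_equal(round(g$omega, 4), 1.7682)
})

test_that("condensed Fukui functions are population finite differences", {
  d <- orbital_data("x", -5, -1,
                    populations = list(N = 6, N_plus_1 = 7, N_minus_1 = 5))
  fk <- fukui_functions(d)
  expect_equal(fk$f_plus, 1)
  expect_equal(fk$f_minus, 1)

  d2 <- orbital_data("y", -5, -1,
                     populations = list(N = c(5.9, 4.1, 1.0),
                                        N_plus_1 = c(6.5, 4.3, 1.2),
                                        N_minus_1 = c(5.5, 3.9, 0.6)))
  fk2 <- fukui_functions(d2)
  expect_equal(fk2$f_plus, c(0.6, 0.2, 0.2), tolerance = 1e-12)
  expect_identical(attr(fk2, "site_nucleophilic"), "atom1")
  # conservation: each set of differences sums to the electron added/removed
  expect_equal(sum(fk2$f_plus), 1, tolerance = 1e-12)
  expect_equal(sum(fk2$f_minus), 1, tolerance = 1e-12)

  # equal N and N+1 populations give identically zero f+
  d3 <- orbital_data("z", -5, -1,
                     populations = list(N = c(1, 2), N_plus_1 = c(1, 2),
                                        N_minus_1 = c(0.5, 1.5)))
  expect_equal(fukui_functions(d3)$f_plus, c(0, 0))

  # charge convention flips the sign
  fkq <- fukui_functions(d2, convention = "charge")
  expect_equal(fkq$f_plus, -fk2$f_plus)

  d4 <- orbital_data("w", -5, -1)
  expect_error(fukui_functions(d4), "population")
  d5 <- orbital_data("v", -5, -1,
                     populations = list(N = c(1, 2), N_plus_1 = c(1, 2)))
  expect_error(fukui_functions(d5), "N_minus_1")
})

test_that("orbital files parse with unit normalisation", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(compound_id = "t1", e_homo_hartree = -0.2,
                            e_lumo_hartree = -0.05),
                       f, auto_unbox = TRUE, digits = NA)
  d <- parse_orbital_file(f, "native-json")
  expect_equal(d$e_homo, -5.4423, tolerance = 1e-4)
  expect_null(d$populations)  # still valid for global descriptors
  expect_silent(descriptor_table(list(d)))

  jsonlite::write_json(list(compound_id = "t2", e_lumo_eV = -1), f,
                       auto_unbox = TRUE)
  expect_error(parse_orbital_file(f, "native-json"), "e_homo")

  writeLines("not json {", f)
  expect_error(parse_orbital_file(f, "native-json"))

  # Gaussian-style eigenvalue lines
  g <- tempfile(fileext = ".log")
  writeLines(c(" Alpha  occ. eigenvalues --  -10.2  -0.35  -0.19",
               " Alpha virt. eigenvalues --   -0.06  0.10  0.50"), g)
  dg <- parse_orbital_file(g, "qm-log")
  expect_equal(dg$e_homo, -0.19 * 27.211386, tolerance = 1e-9)
  expect_equal(dg$e_lumo, -0.06 * 27.211386, tolerance = 1e-9)
})

test_that("descriptor table mirrors the published ten-compound report", {
  ref <- reactivity_reference()
  fr <- frontier_from_mu_eta(ref$mu_eV, ref$eta_eV)
  data <- lapply(seq_len(nrow(ref)), function(i)
    orbital_data(as.character(ref$compound_id[i]), fr$e_homo[i],
                 fr$e_lumo[i]))
  tab <- descriptor_table(data)
  expect_equal(nrow(tab), 10)
  expect_identical(names(tab),
                   c("compound_id", "mu", "eta", "softness", "omega",
                     "max_omega"))
  expect_equal(tab$mu, ref$mu_eV, tolerance = 1e-12)
  # compound 39 has the highest electrophilicity
  expect_identical(tab$compound_id[tab$max_omega], "39")
  # single record degenerates to a single row
  expect_equal(nrow(descriptor_table(data[1])), 1)
  expect_error(descriptor_table(list()), "no orbital data")
})

test_that("published softness/omega values are checked for self-consistency", {
  cc <- reactivity_consistency()
  # the seven self-consistent published (value, compound) pairs reproduce
  expect_true(all(cc$omega_consistent[cc$compound_id %in%
                                        c(44, 28, 37, 43, 46)]))
  expect_true(all(cc$softness_consistent[cc$compound_id %in% c(39, 4, 44)]))
  # rounding mismatches in the published table are flagged, not corrected
  expect_false(any(cc$omega_consistent[cc$compound_id %in% c(9, 29, 32, 39)]))
  expect_equal(cc$omega_computed[cc$compound_id == 44], 1.7682)
  expect_equal(cc$softness_computed[cc$compound_id == 44], 0.2835)
})
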