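inulin_poly <- fiber_polytope("inulin")
pectin_poly <- fiber_polytope("pectin")

test_that("null space basis is orthonormal with the right dimension", {
  B <- null_space_basis(inulin_poly$balance)
  expect_equal(ncol(B), 5L) # 9 species - rank 4
  expect_equal(crossprod(B), diag(5), tolerance = 1e-10)
  expect_lt(max(abs(inulin_poly$balance$M %*% B)), 1e-10)

  B2 <- null_space_basis(matrix(c(1, -1), 1, 2))
  expect_equal(abs(as.numeric(B2)), rep(1 / sqrt(2), 2), tolerance = 1e-12)

  expect_equal(ncol(null_space_basis(diag(3))), 0L)
})

test_that("the closed polytope has the documented constraint structure", {
  expect_equal(.affine_dim(inulin_poly), 4L) # 9 coords - 4 balances - substrate pin
  lb <- inulin_poly$lb
  expect_equal(sum(is.finite(lb) & names(lb) != "inulin"), 7L) # 7 sign constraints
  expect_true(is.infinite(lb[["H2O"]])) # water free by default
  expect_true(inulin_poly$bounded)
})

test_that("vertex enumeration finds the closed-form extreme fermentations", {
  V <- enumerate_vertices(inulin_poly)
  has_vertex <- function(V, want) {
    any(apply(V, 1, function(v) max(abs(v[names(want)] - want)) < 1e-7))
  }
  # C6H10O5 + 7 H2O -> 6 CO2 + 12 H2
  expect_true(has_vertex(V, c(H2 = 12, CO2 = 6, acetate = 0, butyrate = 0, CH4 = 0, H2O = -7)))
  # C6H10O5 + H2O -> 3 C2H4O2
  expect_true(has_vertex(V, c(acetate = 3, H2 = 0, CO2 = 0, CH4 = 0, H2O = -1)))
  # every vertex satisfies Ms = 0 and is distinct
  expect_lt(max(abs(inulin_poly$balance$M %*% t(V))), 1e-9)
  if (nrow(V) > 1) {
    dmin <- min(as.matrix(dist(V, method = "maximum"))[upper.tri(diag(nrow(V)))])
    expect_gt(dmin, 1e-8)
  }
})

test_that("per-product maxima match the carbon/electron closed forms", {
  # degree of reduction budgets: inulin 24, pectin 20 electrons per monomer
  expect_equal(max_product(inulin_poly, "H2"), 12, tolerance = 1e-9)
  expect_equal(max_product(pectin_poly, "H2"), 10, tolerance = 1e-9)
  expect_equal(max_product(inulin_poly, "CH4"), 3, tolerance = 1e-9)
  expect_equal(max_product(pectin_poly, "CH4"), 2.5, tolerance = 1e-9)
  expect_equal(max_product(inulin_poly, "butyrate"), 1.2, tolerance = 1e-9)
  expect_equal(max_product(pectin_poly, "butyrate"), 1.0, tolerance = 1e-9)
  expect_error(max_product(inulin_poly, "ethanol"), "unknown product")
})

test_that("LP maxima coincide with vertex maxima on both fibers", {
  for (poly in list(inulin_poly, pectin_poly)) {
    V <- enumerate_vertices(poly)
    for (p in c("acetate", "propionate", "butyrate", "H2", "CH4", "CO2")) {
      expect_equal(max_product(poly, p), max(V[, p]), tolerance = 1e-8)
    }
  }
})

test_that("2D projections reproduce the fiber contrast in CO2 coproduction", {
  h <- project_2d(inulin_poly, "H2", "CO2")
  expect_false(h$degenerate)
  on_hull <- function(h, pt) any(apply(h$hull, 1, function(v) max(abs(v - pt)) < 1e-7))
  expect_true(on_hull(h, c(12, 6)))
  expect_true(on_hull(h, c(0, 0))) # the 3-acetate solution projects here
  # minimum CO2 coproduced at maximum acetate: pectin 1, inulin 0
  expect_equal(max_product(pectin_poly, "CO2", maximize = FALSE,
                           fixed = c(acetate = max_product(pectin_poly, "acetate"))),
               1, tolerance = 1e-8)
  expect_equal(max_product(inulin_poly, "CO2", maximize = FALSE,
                           fixed = c(acetate = max_product(inulin_poly, "acetate"))),
               0, tolerance = 1e-8)
  # degenerate projection onto (p, p): the diagonal segment
  hd <- project_2d(inulin_poly, "H2", "H2")
  expect_true(hd$degenerate)
  expect_equal(sort(hd$hull[, 1]), c(0, 12), tolerance = 1e-8)
})

test_that("feasibility checks accept balanced profiles and reject excess", {
  r <- check_feasibility(inulin_poly,
                         c(acetate = 3, propionate = 0, butyrate = 0,
                           H2 = 0, CH4 = 0, CO2 = 0))
  expect_true(r$feasible)
  expect_equal(r$witness[["H2O"]], -1, tolerance = 1e-7) # hydrolysis water consumed

  r2 <- check_feasibility(inulin_poly, c(H2 = 13))
  expect_false(r2$feasible)
  expect_equal(r2$slack, 1, tolerance = 1e-7) # electron bound is 12

  expect_error(check_feasibility(inulin_poly, c(H2 = 1), tolerance = -1), ">= 0")
  expect_error(check_feasibility(inulin_poly, c(ethanol = 1)), "named by species")
})

test_that("input relaxation admits reducing-agent uptake and only that", {
  relaxed <- relax_input(pectin_poly, "H2", 1 / 3)
  expect_equal(relaxed$lb[["H2"]], -10 / 3, tolerance = 1e-9)
  # extra electron budget 2 x 10/3 raises the butyrate ceiling to 4/3
  expect_equal(max_product(relaxed, "butyrate"), 4 / 3, tolerance = 1e-8)

  # a measured butyrate of 7/6 needs reducing-agent uptake: infeasible closed
  prof <- c(acetate = 0, propionate = 0, butyrate = 7 / 6, CH4 = 0)
  expect_false(check_feasibility(pectin_poly, prof)$feasible)
  expect_true(check_feasibility(relaxed, prof)$feasible)

  # vanishing relaxation: identical vertex set
  tiny <- relax_input(pectin_poly, "H2", 1e-12)
  V0 <- enumerate_vertices(pectin_poly)
  V1 <- enumerate_vertices(tiny)
  expect_equal(nrow(V0), nrow(V1))
  for (i in seq_len(nrow(V0))) {
    expect_true(any(apply(V1, 1, function(v) max(abs(v - V0[i, ])) < 1e-7)))
  }
})

test_that("biomass yield pins biomass carbon and lowers the H2 ceiling", {
  pb <- apply_biomass_yield(inulin_poly, 0.15)
  # 15% of 6 C = 0.9 C into biomass at 1 C per unit
  expect_true("NH3" %in% names(pb$lb)) # ammonia exchange added for N balance
  V <- enumerate_vertices(pb)
  expect_true(all(abs(V[, "biomass"] - 0.9) < 1e-8))
  # (24 - 0.9 * 4.2) / 2
  expect_equal(max_product(pb, "H2"), 10.11, tolerance = 1e-8)

  expect_identical(apply_biomass_yield(inulin_poly, 0)$config$biomass_yield, NULL)

  val <- build_balance_matrix(c(list(monomer_species("inulin")), default_product_panel()),
                              "total_valence")
  expect_error(build_polytope(val, polytope_config(biomass_yield = 0.15)),
               "total_valence")
})

test_that("feasible sets nest under relaxation and biomass restriction", {
  # every closed vertex lies in the relaxed polytope
  relaxed <- relax_input(pectin_poly, "H2", 1 / 3)
  V0 <- enumerate_vertices(pectin_poly)
  for (i in seq_len(nrow(V0))) {
    expect_true(satisfies_polytope(relaxed, V0[i, ]))
  }
  # every biomass-constrained vertex lies in the unconstrained polytope
  # (same panel including the NH3 exchange column, no biomass pin)
  pb <- apply_biomass_yield(inulin_poly, 0.15)
  free <- build_polytope(pb$balance, polytope_config())
  Vb <- enumerate_vertices(pb)
  for (i in seq_len(nrow(Vb))) {
    expect_true(satisfies_polytope(free, Vb[i, ]))
  }
})

test_that("strictly closed water changes the attainable SCFA range", {
  closed <- fiber_polytope("inulin", water_mode = "nonnegative")
  # hand-verified: 1 inulin -> 0.5 acetate + 1 butyrate + 1 CO2 uses no water,
  # so the water-nonnegative maximum is 0.5 (not 3)
  expect_equal(max_product(closed, "acetate"), 0.5, tolerance = 1e-8)
  expect_true(check_feasibility(
    closed, c(acetate = 0.5, butyrate = 1, CO2 = 1, propionate = 0,
              H2 = 0, CH4 = 0))$feasible)
})

test_that("known glucose fermentations are feasible in the monosaccharide convention", {
  glc <- fiber_polytope("inulin", "monosaccharide") # substrate C6H12O6
  expect_true(check_feasibility(
    glc, c(acetate = 3, propionate = 0, butyrate = 0, H2 = 0, CH4 = 0, CO2 = 0))$feasible)
  expect_true(check_feasibility(
    glc, c(acetate = 0, propionate = 0, butyrate = 1, H2 = 2, CH4 = 0, CO2 = 2))$feasible)
})

test_that("an exchange cycle is detected as unbounded with a certificate ray", {
  species <- c(list(monomer_species("inulin")), default_product_panel(),
               list(chemical_species("acetate_alt", "C2H4O2", "exchange")))
  poly <- build_polytope(build_balance_matrix(species))
  expect_false(poly$bounded)
  expect_error(enumerate_vertices(poly), "unbounded")
  ray <- poly$ray
  expect_lt(max(abs(poly$balance$M %*% ray)), 1e-8) # ray stays in the cone
})

test_that("infeasible configurations fail loudly at build time", {
  cfg <- polytope_config(relaxed_inputs = c(H2 = -1))
  expect_error(polytope_config(relaxed_inputs = c(H2 = 1)), "<= 0")
  expect_error(polytope_config(biomass_yield = 1.2), "biomass_yield")
})
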