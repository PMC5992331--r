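# Design specifications, generator partitioning, constrained minimal cut
# sets and knockout evaluation.

toy_design <- function() {
  design_spec(data.frame(
    quantity = c("yield:R3/R1", "rate:R4"),
    op = c("<", ">"),
    value = c(0.5, 0),
    region = c("target", "desired")
  ), notes = "minimum product yield 0.5 for every substrate-consuming flux")
}

test_that("generators partition into target, desired and neutral", {
  sc <- scenario("S1")
  gen <- partition_generators(enumerate_efms(sc$model), toy_design(),
                              sc$model)
  tab <- tidy(gen)
  supp <- apply(gen$fluxes, 1, function(x) {
    paste(which(abs(x) > 1e-9), collapse = ",")
  })
  # the substrate-to-Q mode (zero product yield) must be eliminated
  expect_equal(tab$region[supp == "1,2,8"], "target")
  # both pure-biomass pathways have product yield 0 < 0.5: targets
  expect_equal(sum(tab$region == "target"), 3)
  # the mixed biomass+product mode (yields 0.5/0.5) is worth keeping
  expect_equal(tab$region[supp == "1,3,4,6,10"], "desired")
  # the cycle has undefined yields and zero growth: neutral
  expect_equal(tab$region[supp == "7,10,11"], "neutral")
})

test_that("yield constraints do not apply to undefined-yield generators", {
  s2 <- scenario("S2")
  gen <- partition_generators(enumerate_efvs(s2$poly), toy_design(),
                              s2$model)
  tab <- tidy(gen)
  zero_or_cycle <- rowSums(abs(gen$fluxes[, 1, drop = FALSE])) < 1e-9
  expect_true(all(tab$region[zero_or_cycle] == "neutral"))
})

test_that("empty designs label everything neutral and refuse cutting", {
  sc <- scenario("S1")
  empty <- design_spec(data.frame(quantity = character(0), op = character(0),
                                  value = numeric(0), region = character(0)))
  gen <- partition_generators(enumerate_efms(sc$model), empty, sc$model)
  expect_true(all(tidy(gen)$region == "neutral"))
  expect_error(compute_mcs(gen), "empty")
})

test_that("the toy design yields {R5, R8} among the smallest cut sets", {
  sc <- scenario("S1")
  gen <- partition_generators(enumerate_efms(sc$model), toy_design(),
                              sc$model)
  mcs <- compute_mcs(gen, max_size = 3)
  keys <- vapply(mcs$reactions, function(r) paste(sort(r), collapse = "+"),
                 character(1))
  expect_true("R5+R8" %in% keys[mcs$size == min(mcs$size)])
  # every returned set is verified by re-enumeration of the mutant
  for (k in seq_len(nrow(mcs))) {
    mut <- apply_knockouts(sc$model, mcs$reactions[[k]])
    ev <- evaluate_design(mut, toy_design(), ub = c(R1 = 10))
    expect_true(ev$pass, label = paste("cut set", keys[k]))
  }
  # minimality: dropping any reaction from a returned set breaks the design
  for (k in seq_len(nrow(mcs))) {
    for (drop in mcs$reactions[[k]]) {
      sub <- setdiff(mcs$reactions[[k]], drop)
      if (length(sub) == 0L) next
      mut <- apply_knockouts(sc$model, sub)
      ev <- evaluate_design(mut, toy_design(), ub = c(R1 = 10))
      expect_false(ev$pass, label = paste(keys[k], "minus", drop))
    }
  }
})

test_that("cut sets can be restricted to an allowed reaction list", {
  sc <- scenario("S1")
  gen <- partition_generators(enumerate_efms(sc$model), toy_design(),
                              sc$model)
  mcs <- compute_mcs(gen, max_size = 3,
                     allowed = c("R5", "R7", "R8", "R9", "R11"))
  for (r in unlist(mcs$reactions)) {
    expect_true(r %in% c("R5", "R7", "R8", "R9", "R11"))
  }
})

test_that("compute_mcs equals the exhaustive oracle on random instances", {
  set.seed(77)
  for (rep in 1:8) {
    n <- 6
    targets <- lapply(1:sample(2:4, 1),
                      function(i) sort(sample.int(n, sample(1:3, 1))))
    desired <- lapply(1:sample(1:2, 1),
                      function(i) sort(sample.int(n, sample(1:3, 1))))
    mine <- compute_mcs(targets = targets, desired = desired, max_size = 4)
    ref <- oracle_mcs(targets, desired, n, max_size = 4)
    mine_sets <- lapply(mine$reactions, function(r) {
      as.integer(sub("R", "", r))
    })
    expect_equal(canon_set(mine_sets), canon_set(ref),
                 label = paste("instance", rep))
  }
})

test_that("knockouts zero out fluxes and enable the engineered scenarios", {
  base <- example_network()
  s4 <- scenario("S4")
  # growth without product co-synthesis is impossible after removing R5:
  # on the r3 = 0 slice the maximal growth rate collapses to 0
  pp <- sample_phase_plane(s4$poly, "R3", "R4", n = 2, model = s4$model)
  slice0 <- pp$points[pp$points$slice == 0 & pp$points$branch == "upper", ]
  expect_equal(slice0$value, 0)
  # but zero-yield fluxes (substrate to Q) still exist in S4
  expect_gt(flux_variability(s4$poly, "R8")["max"], 0)

  # S5 removes them; S6 additionally guarantees production
  s5 <- scenario("S5")
  expect_equal(unname(flux_variability(s5$poly, "R8")), c(0, 0))
  s6 <- scenario("S6")
  expect_gte(flux_variability(s6$poly, "R3")["min"], 3)

  # knocking out everything leaves only the zero flux
  dead <- apply_knockouts(base, base$reaction_ids)
  pdead <- build_polyhedron(dead)
  for (j in 1:11) {
    expect_equal(unname(flux_variability(pdead, j)), c(0, 0))
  }
  expect_error(apply_knockouts(base, "R99"), "unknown reaction")
})

test_that("S4 passes growth coupling but retains low-yield fluxes", {
  d1 <- design_spec(data.frame(
    quantity = c("rate:R3-0.0001*R4", "rate:R4"),
    op = c("<", ">"), value = c(0, 0),
    region = c("target", "desired")
  ))
  s4 <- scenario("S4")
  ev <- evaluate_design(s4$model, d1, ub = c(R1 = 10))
  expect_true(ev$pass)
  # yet the yield-based design is violated by the substrate-to-Q route
  ev2 <- evaluate_design(s4$model, toy_design(), ub = c(R1 = 10))
  expect_false(ev2$pass)
})

test_that("the wild type passes an empty design trivially", {
  sc <- scenario("S2")
  empty <- design_spec(data.frame(quantity = "rate:R4", op = ">",
                                  value = 0, region = "desired"))
  ev <- evaluate_design(sc$model, empty, ub = c(R1 = 10))
  expect_true(ev$pass)
})

test_that("knockouts cannot enforce nonzero production when 0 is feasible", {
  # the S5 mutant satisfies the yield design, yet its minimal production
  # rate is still zero: the zero flux vector survives any knockout
  s5 <- scenario("S5")
  expect_true(feasible(s5$poly, rep(0, 11)))
  expect_equal(unname(flux_variability(s5$poly, "R3")["min"]), 0)
  # only the enforced lower bound of S6 guarantees production
  s6 <- scenario("S6")
  expect_gte(unname(flux_variability(s6$poly, "R3")["min"]), 3)
})

test_that("design files round-trip through JSON", {
  d <- toy_design()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(d$constraints, path, auto_unbox = TRUE, digits = NA)
  back <- read_design(path)
  expect_equal(back$constraints, d$constraints)
})
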