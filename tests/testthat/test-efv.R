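# Elementary flux mode/vector enumeration and the generator-based
# characterization of rate- and yield-optimal solution sets.

test_that("the example flux cone has exactly six elementary modes", {
  mod <- example_network()
  efms <- enumerate_efms(mod)
  expect_equal(nrow(efms$fluxes), 6)
  expect_true(all(efms$kind == "unbounded"))
  # exactly one internal cycle: R7, R10 forward, R11 backward
  supports <- apply(efms$fluxes, 1, function(x) {
    paste(which(abs(x) > 1e-9), collapse = ",")
  })
  cyc <- which(supports == "7,10,11")
  expect_length(cyc, 1)
  expect_lt(efms$fluxes[cyc, 11], 0)
  # the substrate-to-Q mode uses R1, R8, R2
  expect_true("1,2,8" %in% supports)
  # yield pairs (biomass, product) of the six modes
  sB <- yield_spec("R4", "R1", model = mod)
  sP <- yield_spec("R3", "R1", model = mod)
  yB <- generator_yields(efms, sB)
  yP <- generator_yields(efms, sP)
  pairs <- sort(vapply(seq_len(6), function(i) {
    if (is.character(yB[[i]])) "undefined" else
      paste0(yB[[i]], "/", yP[[i]])
  }, character(1)))
  expect_equal(pairs,
               sort(c("0/0", "0.5/0.5", "0/1", "1/0", "1/0", "undefined")))
})

test_that("the bounded scenario has seven generators including zero and cycle", {
  s2 <- scenario("S2")
  efvs <- enumerate_efvs(s2$poly)
  expect_equal(nrow(efvs$fluxes), 7)
  expect_equal(sum(efvs$kind == "bounded"), 6)
  # zero vector present as a bounded generator
  zero_row <- which(rowSums(abs(efvs$fluxes)) < 1e-9)
  expect_length(zero_row, 1)
  expect_equal(efvs$kind[zero_row], "bounded")
  # the cycle is the only unbounded generator
  unb <- which(efvs$kind == "unbounded")
  expect_length(unb, 1)
  expect_equal(which(abs(efvs$fluxes[unb, ]) > 1e-9), c(7, 10, 11),
               ignore_attr = TRUE)
  # nonzero bounded generators are the five pathways scaled to r1 = 10
  nonzero_bounded <- efvs$kind == "bounded" & rowSums(abs(efvs$fluxes)) > 1e-9
  expect_true(all(abs(efvs$fluxes[nonzero_bounded, 1] - 10) < 1e-9))
})

test_that("simple chains and symmetry behave as expected", {
  chain <- metabolic_model(matrix(c(1, -1), 1, 2), c(FALSE, FALSE))
  efms <- enumerate_efms(chain)
  expect_equal(nrow(efms$fluxes), 1)
  expect_equal(efms$fluxes[1, ], c(1, 1), ignore_attr = TRUE)

  # reversing all reactions of a cycle-free network flips every mode
  mod <- random_network(4, 6, seed = 99, p_rev = 0)
  fwd <- enumerate_efms(mod)
  revmod <- metabolic_model(-mod$S, mod$reversible)
  bwd <- enumerate_efms(revmod)
  canon <- function(M) {
    sort(apply(M, 1, function(x) {
      x <- x / max(abs(x))
      paste(signif(x, 8), collapse = ",")
    }))
  }
  expect_equal(canon(fwd$fluxes), canon(-bwd$fluxes))
})

test_that("enumerated modes match the exhaustive nullspace oracle", {
  skip_if_not_installed("MASS")
  for (seed in c(3, 17, 31, 58)) {
    mod <- random_network(5, 8, seed = seed, p_rev = 0.25)
    mine <- enumerate_efms(mod)
    ref <- oracle_efms(mod)
    canon <- function(xs) {
      sort(vapply(xs, function(x) {
        x <- x / max(abs(x))
        paste(signif(x, 6), collapse = ",")
      }, character(1)))
    }
    mine_list <- lapply(seq_len(nrow(mine$fluxes)),
                        function(i) mine$fluxes[i, ])
    expect_equal(canon(mine_list), canon(ref), label = paste("seed", seed))
    # every mode satisfies steady state exactly
    for (x in mine_list) expect_lt(max(abs(mod$S %*% x)), 1e-9)
  }
})

test_that("generator supports are minimal (no strictly contained support)", {
  s2 <- scenario("S2")
  efvs <- enumerate_efvs(s2$poly)
  # signed support in the lifted homogenized coordinates (x, t, slacks)
  A <- efvs$poly$ineq
  b <- efvs$poly$ineq_rhs
  hsupp <- lapply(seq_len(nrow(efvs$fluxes)), function(i) {
    x <- efvs$fluxes[i, ]
    tt <- as.integer(efvs$kind[i] == "bounded")
    slack <- tt * b - as.vector(A %*% x)
    s <- c(which(x > 1e-9), -which(x < -1e-9))
    if (tt > 0) s <- c(s, 99L)
    c(s, 100L + which(slack > 1e-9))
  })
  for (i in seq_along(hsupp)) {
    for (j in seq_along(hsupp)) {
      if (i == j) next
      expect_false(length(hsupp[[j]]) < length(hsupp[[i]]) &&
                     all(hsupp[[j]] %in% hsupp[[i]]),
                   label = paste("support", j, "inside", i))
    }
  }
})

test_that("every feasible point decomposes over the generators", {
  for (id in c("S1", "S2", "S3")) {
    sc <- scenario(id)
    gen <- enumerate_efvs(sc$poly)
    set.seed(5)
    for (rep in 1:25) {
      x <- random_generator_point(gen)
      expect_true(feasible(sc$poly, x))
      expect_true(decomposable(gen, x), label = paste(id, "rep", rep))
    }
    # and a point outside the polyhedron does not
    if (id == "S2") {
      expect_false(decomposable(gen, c(20, rep(0, 9), 20)))
    }
  }
})

test_that("annotation mirrors the generator-table layout", {
  s2 <- scenario("S2")
  spec <- yield_spec("R4", "R1", model = s2$model)
  gen <- annotate_generators(enumerate_efvs(s2$poly), rate = "R4",
                             spec = spec, model = s2$model)
  tab <- tidy(gen)
  cycle <- tab[tab$kind == "unbounded", ]
  expect_equal(cycle$yield_status, "undefined")
  zero <- tab[abs(tab$R1) < 1e-9 & tab$kind == "bounded", ]
  expect_equal(zero$yield_status, "undefined")
  expect_equal(zero$rate, 0)
  best <- tab[!is.na(tab$yield) & abs(tab$yield - 1) < 1e-9, ]
  expect_equal(nrow(best), 2)
  expect_equal(best$rate, c(10, 10))
})

test_that("attainment via the generator criterion matches the LFP", {
  s1 <- scenario("S1")
  s3 <- scenario("S3")
  spec <- yield_spec("R4", "R1", model = s1$model)

  att <- yield_attained(enumerate_efvs(s3$poly), spec)
  expect_true(att$attained)
  expect_equal(att$supremum, 1)

  pna <- add_constraints(s1$poly, -unit_vec(11, 2), -1)
  attna <- yield_attained(enumerate_efvs(pna), spec)
  expect_false(attna$attained)
  expect_equal(attna$supremum, 1)
  expect_equal(maximize_yield(pna, spec)$status, "optimal_not_attained")

  # a pure polytope always attains its optimum
  box <- flux_polyhedron(2, ineq = rbind(diag(2)), ineq_rhs = c(1, 1),
                         nonneg = c(TRUE, TRUE))
  gb <- enumerate_efvs(box)
  expect_true(all(gb$kind == "bounded"))
  expect_true(yield_attained(gb, yield_spec(c(1, 0), c(1, 1)))$attained)

  # unbounded yield is refused with an explanation
  expect_error(yield_attained(enumerate_efvs(s1$poly),
                              yield_spec("R7", "R1", model = s1$model)),
               "unbounded")
})

test_that("optimality classes reproduce the known solution-set structure", {
  s1 <- scenario("S1")
  s2 <- scenario("S2")
  spec <- yield_spec("R4", "R1", model = s2$model)

  g2 <- enumerate_efvs(s2$poly)
  cls <- classify_optimal(g2, spec)
  expect_equal(cls$Y_star, 1)
  expect_length(cls$I_star, 2)        # the two yield-one pathways
  zero_row <- which(rowSums(abs(g2$fluxes)) < 1e-9)
  expect_equal(cls$I_u, unname(zero_row))     # the zero vector
  expect_length(cls$J_star, 0)
  expect_length(cls$J_u, 1)           # the cycle

  g1 <- enumerate_efvs(s1$poly)
  cls1 <- classify_optimal(g1, spec)
  expect_length(cls1$J_star, 2)
  expect_length(cls1$J_u, 1)
  expect_length(cls1$I_star, 0)

  # c = d makes the yield identically one on its domain
  gs <- classify_optimal(g2, yield_spec(unit_vec(11, 1), unit_vec(11, 1)))
  expect_equal(gs$Y_star, 1)
  expect_length(gs$other, 0)
})

test_that("rate-optimal generator sets match the scenarios", {
  s2 <- scenario("S2")
  s3 <- scenario("S3")
  g2 <- enumerate_efvs(s2$poly)
  ro2 <- rate_optimal_set(g2, "R4", model = s2$model)
  expect_equal(ro2$max_rate, 10)
  expect_length(ro2$optimal, 2)
  # in this scenario the rate-optimal generators are the yield-optimal ones
  cls <- classify_optimal(g2, yield_spec("R4", "R1", model = s2$model))
  expect_setequal(ro2$optimal, cls$I_star)

  g3 <- enumerate_efvs(s3$poly)
  ro3 <- rate_optimal_set(g3, "R4", model = s3$model)
  expect_equal(ro3$max_rate, 7.5)
  expect_length(ro3$optimal, 2)      # newly arising vertices at r5 = 5
  expect_true(all(abs(g3$fluxes[ro3$optimal, 5] - 5) < 1e-9))
  # the cycle can be added to any optimum
  expect_length(ro3$recession, 1)

  expect_error(rate_optimal_set(enumerate_efvs(scenario("S1")$poly), "R4",
                                model = s2$model),
               "unbounded|no bounded")
  # zero objective: every bounded generator is optimal
  ro0 <- rate_optimal_set(g2, numeric(11))
  expect_length(ro0$optimal, sum(g2$kind == "bounded"))
})

test_that("constraints never increase the optimal rate or yield", {
  spec <- yield_spec("R4", "R1", model = example_network())
  vals <- lapply(c("S1", "S2", "S3"), function(id) {
    sc <- scenario(id)
    r <- maximize_rate(sc$poly, "R4", sc$model)
    y <- maximize_yield(sc$poly, spec)
    c(rate = r$objective_value, yield = y$optimal_yield)
  })
  tol <- 1e-9
  expect_true(vals[[1]]["rate"] >= vals[[2]]["rate"] - tol)
  expect_true(vals[[2]]["rate"] >= vals[[3]]["rate"] - tol)
  expect_true(vals[[1]]["yield"] >= vals[[2]]["yield"] - tol)
  expect_true(vals[[2]]["yield"] >= vals[[3]]["yield"] - tol)
})

test_that("enumeration guard refuses oversized problems", {
  mod <- random_network(4, 6, seed = 1)
  poly <- build_polyhedron(mod)
  expect_error(enumerate_efvs(poly, max_dim = 3), "refused")
})
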