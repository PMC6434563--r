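# a small hand-wired web reused across dynamics tests:
# nodes 1-2 autotrophs, 3-4 invertebrates, 5 fish
small_web <- function() {
  A <- matrix(0L, 5, 5)
  A[3, 1] <- A[3, 2] <- 1L
  A[4, 2] <- A[4, 3] <- 1L
  A[5, 3] <- A[5, 4] <- 1L
  make_annotated_web(
    A, guild = c("autotroph", "autotroph", "invertebrate", "invertebrate",
                 "fish"),
    M = c(1, 1, 100, 100, 1e4))
}

test_that("resource overlap fractions match hand counts", {
  A <- matrix(0L, 4, 4)
  A[2, 1] <- 1L                 # prey(2) = {1}
  A[3, 1] <- A[3, 4] <- 1L      # prey(3) = {1, 4}
  p <- resource_overlap(A)
  expect_equal(p[2, 2], 1)      # identical diet with itself
  expect_equal(p[2, 3], 1)      # prey(2) is contained in prey(3)
  expect_equal(p[3, 2], 0.5)    # 3 shares 1 of its 2 resources with 2
  expect_equal(p[4, 2], 0)      # no prey: zero row

  # the half-overlap pair {1,2} vs {2,3}, and a fully disjoint pair
  A2 <- matrix(0L, 5, 5)
  A2[4, 1] <- A2[4, 2] <- 1L    # prey(4) = {1, 2}
  A2[5, 2] <- A2[5, 3] <- 1L    # prey(5) = {2, 3}
  p2 <- resource_overlap(A2)
  expect_equal(p2[4, 5], 0.5)
  expect_equal(p2[5, 4], 0.5)
  A2[5, ] <- 0L; A2[5, 3] <- 1L
  expect_equal(resource_overlap(A2)[4, 5], 0)
})

test_that("functional response matches its closed forms and the oracle", {
  params <- atn_params()
  # single prey at the half-saturation density: F = 1/2
  A <- matrix(0L, 2, 2); A[2, 1] <- 1L
  w <- make_annotated_web(A, c("autotroph", "invertebrate"))
  B <- c(params$B0, 10)
  expect_equal(functional_response(B, 2, 1, w, params), 0.5)
  expect_equal(functional_response(c(0, 10), 2, 1, w, params), 0)

  # two prey at equal biomass B0 and no interference: F = 0.25
  A3 <- matrix(0L, 3, 3); A3[3, 1] <- A3[3, 2] <- 1L
  w3 <- make_annotated_web(A3, c("autotroph", "autotroph", "invertebrate"))
  B3 <- c(params$B0, params$B0, 5)
  expect_equal(functional_response(B3, 3, 1, w3, params), 0.25)

  # random states on the 5-node web against the literal transcription,
  # with and without predator interference
  web <- small_web()
  set.seed(71)
  for (pars in list(atn_params(), atn_params(c_interference = 0.8))) {
    B0m <- matrix(pars$B0, 5, 5)
    cm <- matrix(pars$c_interference, 5, 5)
    for (rep in 1:10) {
      B <- runif(5, 0, 400)
      for (ij in list(c(3, 1), c(4, 3), c(5, 4))) {
        expect_equal(
          functional_response(B, ij[1], ij[2], web, pars),
          oracle_F(B, ij[1], ij[2], web$A, B0m, cm, pars$h),
          tolerance = 1e-12)
      }
    }
  }
  expect_true(all(replicate(5, {
    B <- runif(5, 0, 1e4)
    f <- functional_response(B, 5, 3, web, params)
    f >= 0 && f < 1
  })))
})

test_that("functional response is monotone in prey and interferers", {
  web <- small_web()
  pars <- atn_params(c_interference = 0.6)
  B <- c(100, 150, 80, 60, 40)
  eps <- 1e-4
  # non-decreasing in the focal prey's biomass
  for (d in c(1, 10, 50)) {
    B2 <- B; B2[3] <- B[3] + d
    expect_gte(functional_response(B2, 5, 3, web, pars),
               functional_response(B, 5, 3, web, pars))
  }
  # non-increasing in an interfering consumer's biomass (4 also eats 3)
  B3 <- B; B3[4] <- B[4] + 50
  expect_lte(functional_response(B3, 5, 3, web, pars) - eps,
             functional_response(B, 5, 3, web, pars))
})

test_that("compiled derivatives equal the literal growth-equation oracle", {
  web <- small_web()
  set.seed(72)
  for (pars in list(atn_params(), atn_params(c_interference = 0.5))) {
    sys <- atn_system(web, pars, r = c(0.8, 1.0))
    for (rep in 1:8) {
      B <- runif(5, 0, 500)
      expect_equal(atn_derivatives(B, sys),
                   oracle_deriv(B, web, pars, r = c(0.8, 1.0)),
                   tolerance = 1e-10)
    }
  }
  # the "divide" toggle rescales the loss-to-predation term by 1/e^2
  # relative to the multiplicative default, leaving everything else alone
  B <- c(200, 200, 50, 40, 30)
  pm <- atn_params(); pd <- atn_params(loss_efficiency = "divide")
  d_mult <- atn_derivatives(B, atn_system(web, pm, r = c(0.9, 0.9)))
  d_div <- atn_derivatives(B, atn_system(web, pd, r = c(0.9, 0.9)))
  ref <- oracle_deriv(B, web, pm, c(0.9, 0.9))
  loss1 <- 0.9 * (1 - sum(B[1:2]) / pm$K) * B[1] - ref[1]   # e-scaled loss on prey 1
  expect_equal(d_div[1] - d_mult[1], loss1 - loss1 / pm$e_autotroph^2,
               tolerance = 1e-8)
})

test_that("logistic autotroph limits and starvation decay", {
  pars <- atn_params()
  # lone autotroph: zero growth at carrying capacity, hand value at K/2
  A1 <- matrix(0L, 1, 1)
  w1 <- make_annotated_web(A1, "autotroph")
  sys1 <- atn_system(w1, pars, r = 0.9)
  expect_equal(atn_derivatives(540, sys1), 0)
  expect_equal(atn_derivatives(270, sys1), 0.9 * 0.5 * 270)  # 121.5

  # consumer with all prey extinct: pure maintenance decay
  web <- small_web()
  sys <- atn_system(web, pars, r = c(0.9, 0.9))
  B <- c(0, 0, 0, 0, 25)
  x5 <- web$trophic$x[5]
  expect_equal(atn_derivatives(B, sys)[5], -pars$fm * x5 * 25)

  # with feeding off (y = 0) consumers decay exponentially at fm * x
  pars0 <- atn_params(y = 0, extinction_threshold = 0)
  sys0 <- atn_system(web, pars0, r = c(0.9, 0.9))
  out <- integrate_season(c(0, 0, 10, 10, 10), sys0)
  expect_true(out$ok)
  t_end <- pars0$season_days
  for (i in 3:5) {
    expect_equal(out$B_end[i], 10 * exp(-pars0$fm * web$trophic$x[i] * t_end),
                 tolerance = 1e-5)
  }
})

test_that("a lone autotroph equilibrates at the carrying capacity", {
  w1 <- make_annotated_web(matrix(0L, 1, 1), "autotroph")
  pars <- atn_params()
  sys <- atn_system(w1, pars, r = 0.9)
  B <- 5
  for (yr in 1:3) B <- integrate_season(B, sys)$B_end
  expect_equal(as.numeric(B), 540, tolerance = 1e-4)

  # several autotrophs share one carrying capacity: totals settle at K
  A3 <- matrix(0L, 3, 3)
  w3 <- make_annotated_web(A3, rep("autotroph", 3))
  set.seed(73)
  sys3 <- atn_system(w3, pars, r = draw_growth_rates(3, pars))
  B3 <- c(5, 100, 300)
  for (yr in 1:3) B3 <- integrate_season(B3, sys3)$B_end
  expect_equal(sum(B3), 540, tolerance = 1e-3)
  expect_equal(as.numeric(integrate_season(rep(0, 3), sys3)$B_end), rep(0, 3))
})

test_that("season integration clamps, thresholds and reports failures", {
  fx <- std_fixture()
  pars <- atn_params()
  set.seed(74)
  sys <- atn_system(fx$staged, pars)
  B <- initial_biomass(fx$staged, pars)
  out <- integrate_season(B, sys)
  expect_true(out$ok)
  expect_true(all(out$traj[, -1] >= 0))
  expect_true(all(out$B_end == 0 | out$B_end >= pars$extinction_threshold))

  # halving the solver tolerances moves year-end biomass by < 0.1%
  pars2 <- atn_params(rtol = pars$rtol / 2, atol = pars$atol / 2)
  sys2 <- atn_system(fx$staged, pars2, r = sys$r)
  out2 <- integrate_season(B, sys2)
  live <- out$B_end > 0
  expect_lt(max(abs(out2$B_end[live] - out$B_end[live]) / out$B_end[live]),
            1e-3)
})

test_that("multi-year runs honour the annual pause and Leslie linkage", {
  fx <- std_fixture()
  sw <- fx$staged
  pars <- atn_params()
  set.seed(75)
  r <- draw_growth_rates(sum(sw$guild == "autotroph"), pars)
  B0v <- initial_biomass(sw, pars)

  # one year of the linked model equals one season plus one Leslie step
  season <- integrate_season(B0v, atn_system(sw, pars, r))
  expected <- apply_annual_transition(season$B_end, sw)
  tr <- run_simulation(sw, "linked", years = 1, params = pars, r = r,
                       B_init = B0v)
  expect_equal(tr$annual_end[1, ], expected, tolerance = 1e-12)
  # the unlinked model skips the Leslie step
  tru <- run_simulation(sw, "unlinked", years = 1, params = pars, r = r,
                        B_init = B0v)
  expect_equal(tru$annual_end[1, ], as.numeric(season$B_end),
               tolerance = 1e-12)

  # a fish species populated only in stage 0 moves 90% of its post-season
  # stage-0 biomass into stage 1 at the year-end transition
  sp <- sw$fish_species[1]
  ids <- sw$stage_nodes[[as.character(sp)]]
  B1 <- B0v
  B1[ids] <- 0
  B1[ids[1]] <- 20
  season1 <- integrate_season(B1, atn_system(sw, pars, r))
  tr1 <- run_simulation(sw, "linked", years = 1, params = pars, r = r,
                        B_init = B1)
  expect_equal(tr1$annual_end[1, ids[2]],
               0.9 * season1$B_end[ids[1]] + 0.1 * season1$B_end[ids[2]],
               tolerance = 1e-12)

  # determinism: identical seeds give identical trajectories
  set.seed(321)
  a <- run_simulation(sw, "linked", years = 3, params = pars)
  set.seed(321)
  b <- run_simulation(sw, "linked", years = 3, params = pars)
  expect_identical(a$annual_mean, b$annual_mean)
  expect_identical(a$annual_end, b$annual_end)
  # non-negativity of all reported biomasses
  expect_true(all(a$annual_mean >= 0, na.rm = TRUE))
  expect_true(all(a$annual_end >= 0, na.rm = TRUE))
})

test_that("model-variant guards reject mismatched webs", {
  fx <- std_fixture()
  expect_error(run_simulation(fx$web, "linked", years = 1), "staged_web")
  expect_error(run_simulation(fx$staged, "original", years = 1), "unstaged")
  expect_error(integrate_season(rep(-1, fx$staged$N),
                                atn_system(fx$staged, atn_params(),
                                           r = rep(0.9, sum(fx$staged$guild == "autotroph")))),
               "non-negative")
})
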