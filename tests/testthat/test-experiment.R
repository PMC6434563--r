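test_that("model variants share structure, draws and initial conditions", {
  fx <- std_fixture()
  set.seed(81)
  v <- build_model_variants(fx$web, stage_seed = 1000L + fx$seed)
  expect_s3_class(v$staged, "staged_web")
  expect_equal(v$original$S, 30)
  expect_equal(v$staged$N, 39)
  # species-level initial totals are matched between variants
  expect_equal(sum(v$init_original), sum(v$init_staged), tolerance = 1e-12)
  for (sp in v$staged$fish_species) {
    ids <- v$staged$stage_nodes[[as.character(sp)]]
    expect_equal(sum(v$init_staged[ids]), v$init_original[sp])
    expect_equal(v$init_staged[ids], rep(v$init_original[sp] / 4, 4))
  }
  nonfish <- which(is.na(v$staged$node_stage))
  expect_equal(v$init_staged[nonfish], v$init_original[nonfish])
  expect_equal(length(v$r), sum(fx$web$trophic$guild == "autotroph"))
  expect_true(all(v$r >= 0.6 & v$r <= 1.2))
})

test_that("fish survival matches a brute-force scan of the final state", {
  fx <- std_fixture()
  sw <- fx$staged
  pars <- atn_params()
  set.seed(82)
  tr <- run_simulation(sw, "linked", years = 5, params = pars)
  s <- fish_survival(tr)
  final <- tr$annual_end[5, ]
  for (sp in sw$fish_species) {
    alive <- FALSE
    for (node in which(sw$node_species == sp))
      if (final[node] >= pars$extinction_threshold) alive <- TRUE
    expect_identical(unname(s$survived[as.character(sp)]), alive)
  }
  expect_equal(s$count, sum(s$survived))

  # a species with any single live stage counts as surviving
  tr2 <- tr
  sp1 <- sw$fish_species[1]
  ids <- which(sw$node_species == sp1)
  tr2$annual_end[5, ids] <- 0
  tr2$annual_end[5, ids[2]] <- 10 * pars$extinction_threshold
  expect_true(fish_survival(tr2)$survived[as.character(sp1)])
  tr2$annual_end[5, ids] <- 0
  expect_false(fish_survival(tr2)$survived[as.character(sp1)])
})

test_that("stabilization requires completion, boundedness and live fish", {
  fx <- std_fixture()
  set.seed(83)
  tr <- run_simulation(fx$staged, "linked", years = 12, params = atn_params())
  burn <- 10L
  base <- stabilization_check(tr, burn_in = burn)
  expect_type(base, "logical")

  # solver failure during burn-in fails the check
  trf <- tr; trf$status <- "solver_error"; trf$failed_year <- 4L
  trf$annual_mean[4:12, ] <- NA; trf$annual_end[4:12, ] <- NA
  trf$annual_max[4:12] <- NA
  expect_false(stabilization_check(trf, burn_in = burn))

  # all-fish-extinct at the end of burn-in fails the check
  trx <- tr
  fish_nodes <- trx$node_species %in% trx$fish_species
  trx$annual_end[burn, fish_nodes] <- 0
  expect_false(stabilization_check(trx, burn_in = burn))

  # a biomass excursion above the ceiling during burn-in fails the check
  trb <- tr; trb$annual_max[3] <- 1e12
  expect_false(stabilization_check(trb, burn_in = burn))
})

test_that("coefficient of variation follows the sample-sd convention", {
  expect_equal(biomass_cv(rep(7, 10)), 0)
  expect_equal(biomass_cv(c(1, 3)), sqrt(2) / 2)
  expect_true(is.na(biomass_cv(c(0, 0, 0))))
  expect_true(is.na(biomass_cv(c(3))))
  set.seed(84)
  x <- rlnorm(50)
  expect_equal(biomass_cv(x), sd(x) / mean(x))
})

test_that("stage-size ordering fraction follows the vB arithmetic", {
  # with K = 1 and adults at 90% of W_inf, the youngest stage sits at
  # ~2.895% of W_inf, so the ordering holds iff the mass ratio is < ~31
  mk <- function(run, W_adults) {
    do.call(rbind, lapply(seq_along(W_adults), function(i) {
      st <- vb_stage_weights(W_adults[i])
      data.frame(run = run, species = i, survived = TRUE,
                 W_adult = st$W[4], W_inf = st$W_inf, W_min = st$W[1])
    }))
  }
  tab10 <- mk("a", c(100, 1000))        # ratio 10  -> ordering holds
  tab1e4 <- mk("b", c(100, 1e6))        # ratio 1e4 -> ordering fails
  expect_equal(size_ordering_fraction(tab10)$fraction, 1)
  expect_equal(size_ordering_fraction(tab1e4)$fraction, 0)
  both <- rbind(tab10, tab1e4)
  res <- size_ordering_fraction(both)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$n_eligible, 2L)
  # single-survivor runs drop out of the denominator
  single <- mk("c", 500)
  expect_equal(size_ordering_fraction(rbind(both, single))$n_eligible, 2L)
  # threshold check: ratio just below ~31 holds, just above fails
  expect_equal(size_ordering_fraction(mk("d", c(100, 3000)))$fraction, 1)
  expect_equal(size_ordering_fraction(mk("e", c(100, 3200)))$fraction, 0)
})

test_that("size-stability regressions recover synthetic slopes and filters", {
  set.seed(85)
  n <- 120
  mass <- 10^runif(n, 2, 8)
  mk_tab <- function(cv_eco) data.frame(
    run = seq_len(n), survived = TRUE, W_inf = mass,
    mean_eco = rnorm(n, 500, 1), mean_species = rnorm(n, 50, 1),
    cv_eco = cv_eco, cv_species = cv_eco / 2,
    mean_fish = NA_real_, cv_fish = NA_real_)

  # perfectly collinear response: enormous t, essentially zero p
  tab <- mk_tab(cv_eco = 0.01 * log10(mass))
  reg <- suppressWarnings(size_stability_regression(tab))  # exact fit warns
  row <- reg[reg$response == "cv_eco", ]
  expect_gt(row$t, 1e6)
  expect_lt(row$p, 1e-10)
  expect_equal(row$df, n - 2L)
  expect_equal(row$slope, 0.01, tolerance = 1e-6)

  # null response: slope near zero, |t| small on average
  tab0 <- mk_tab(cv_eco = abs(rnorm(n, 0.5, 0.05)))
  reg0 <- size_stability_regression(tab0)
  expect_lt(abs(reg0[reg0$response == "cv_eco", "slope"]), 0.05)

  # outlier filters remove heavy masses and runaway CVs
  tab2 <- mk_tab(cv_eco = rep(0.5, n))
  tab2$W_inf[1] <- 1e12
  tab2$cv_eco[2] <- 9        # 900% > the 800% cutoff
  reg2 <- suppressWarnings(size_stability_regression(tab2))  # flat response warns
  expect_equal(unique(reg2$n), n - 2L)
})

test_that("a small ensemble runs end to end with consistent bookkeeping", {
  pars <- atn_params()
  ens <- run_ensemble(n_webs = 2, burn_in = 4L, analysis = 4L,
                      params = pars, seed = 42)
  expect_s3_class(ens, "atn_ensemble")
  expect_equal(nrow(ens$runs), 6)
  expect_true(all(ens$runs$model_type %in%
                    c("original", "unlinked", "linked")))
  # survivor-frequency rows sum to the number of accepted runs per type
  freq <- ens$survivor_freq
  counted <- ens$runs[!is.na(ens$runs$n_survived), ]
  prelim_webs <- unique(counted$web[counted$n_survived >= 1])
  for (mt in rownames(freq)) {
    expect_equal(sum(freq[mt, ]),
                 sum(counted$model_type == mt & counted$web %in% prelim_webs))
  }
  # filters are monotone: stringent webs are preliminary webs
  expect_lte(ens$fractions$stringent, ens$fractions$preliminary)
  expect_true(all(unlist(ens$fractions[c("stabilized_any", "stringent",
                                         "preliminary")]) >= 0))
  # survivor counts are integers in 0..3
  expect_true(all(counted$n_survived %in% 0:3))

  # determinism: the same master seed reproduces every summary
  ens2 <- run_ensemble(n_webs = 2, burn_in = 4L, analysis = 4L,
                       params = pars, seed = 42)
  expect_identical(ens$runs, ens2$runs)
  expect_identical(ens$fractions, ens2$fractions)
  expect_equal(ens$species, ens2$species)
})
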