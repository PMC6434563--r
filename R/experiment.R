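#' Build the three model variants sharing one web and one set of draws
#'
#' From a validated, annotated web this prepares the ensemble's three model
#' types: `original` (one node per species), `unlinked` (fish split into
#' life-history stages, stages independent) and `linked` (staged plus the
#' annual Leslie step). All three share the web, the autotroph growth-rate
#' draws and the species-level initial-biomass draws, so differences in
#' outcome are attributable to the life-history structure alone.
#'
#' @param web an `annotated_web` with (by default) three fish species.
#' @param params an [atn_params()] object.
#' @param t_max terminal stage index for the staged variants.
#' @param stage_seed passed to [insert_stages()].
#' @param on_empty_diet passed to [insert_stages()].
#' @return A list of class `atn_variants` with `original`, `staged` (the
#'   shared staged web used by both `unlinked` and `linked`), `r`
#'   (autotroph growth rates), `species_init` (per-species initial
#'   draws) and ready per-variant initial vectors `init_original`,
#'   `init_staged`.
#' @export
build_model_variants <- function(web, params = atn_params(), t_max = 3L,
                                 stage_seed = NULL,
                                 on_empty_diet = c("reject", "flag")) {
  sweb <- insert_stages(web, t_max = t_max, stage_seed = stage_seed,
                        on_empty_diet = match.arg(on_empty_diet))
  n_aut <- sum(web$trophic$guild == "autotroph")
  r <- draw_growth_rates(n_aut, params)
  species_init <- stats::runif(web$S, params$init_min, params$init_max)
  structure(list(
    original = web, staged = sweb, r = r, species_init = species_init,
    init_original = initial_biomass(web, params, species_init),
    init_staged = initial_biomass(sweb, params, species_init)),
    class = "atn_variants")
}

#' Fish survival at the end of a run
#'
#' A fish species survives when any of its nodes (its single node in the
#' original variant, any life-history stage in the staged variants) holds
#' at least the extinction threshold of biomass in the final recorded
#' year-end state.
#'
#' @param traj an `atn_trajectory` from [run_simulation()].
#' @param threshold biomass threshold (µgC/L); defaults to the run's
#'   extinction threshold.
#' @return List with logical `survived` (named by fish species id) and
#'   integer `count`; both `NA` when the run recorded no complete year.
#' @export
fish_survival <- function(traj, threshold = traj$params$extinction_threshold) {
  fs <- traj$fish_species
  done <- which(stats::complete.cases(traj$annual_end))
  if (length(done) == 0L) {
    survived <- rep(NA, length(fs))
    names(survived) <- fs
    return(list(survived = survived, count = NA_integer_))
  }
  final <- traj$annual_end[max(done), ]
  survived <- vapply(fs, function(sp)
    any(final[traj$node_species == sp] >= threshold), logical(1))
  names(survived) <- fs
  list(survived = survived, count = sum(survived))
}

#' Did fish biomass stabilize over the burn-in period?
#'
#' Operational definition (the underlying notion is not given a formula in
#' the source tradition, so this is explicit and configurable): the run
#' completed the burn-in without solver failure, no node exceeded the
#' blow-up ceiling during burn-in, and total fish biomass at the end of
#' burn-in is at least the extinction threshold.
#'
#' @param traj an `atn_trajectory`.
#' @param burn_in number of burn-in years.
#' @param ceiling blow-up ceiling (µgC/L).
#' @export
stabilization_check <- function(traj, burn_in = 200L,
                                ceiling = traj$params$blowup_ceiling) {
  if (traj$status == "solver_error" &&
      !is.na(traj$failed_year) && traj$failed_year <= burn_in) return(FALSE)
  amax <- traj$annual_max[seq_len(min(burn_in, traj$years))]
  if (anyNA(amax) || any(amax > ceiling)) return(FALSE)
  fish_nodes <- traj$node_species %in% traj$fish_species
  end <- traj$annual_end[burn_in, ]
  if (anyNA(end)) return(FALSE)
  sum(end[fish_nodes]) >= traj$params$extinction_threshold
}

#' Coefficient of variation of a biomass series
#'
#' Sample standard deviation divided by the mean; the stability metric of
#' the ensemble analyses (unitless ratio; multiply by 100 for percent).
#'
#' @param series numeric vector with at least two non-missing values.
#' @return CV as a ratio, or `NA` for degenerate input (zero/NA mean).
#' @export
biomass_cv <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) < 2L) return(NA_real_)
  m <- mean(series)
  if (!is.finite(m) || m == 0) return(NA_real_)
  stats::sd(series) / m
}

# per-run summary over the analysis window (years burn_in+1 .. years)
analyse_run <- function(traj, sweb_or_web, burn_in) {
  yrs <- seq(burn_in + 1L, traj$years)
  mean_mat <- traj$annual_mean[yrs, , drop = FALSE]
  complete <- stats::complete.cases(mean_mat)
  surv <- fish_survival(traj)
  fish_nodes <- traj$node_species %in% traj$fish_species
  eco <- rowSums(mean_mat)
  fish_tot <- rowSums(mean_mat[, fish_nodes, drop = FALSE])
  analysed <- all(complete) && traj$status == "ok"
  species <- NULL
  if (analysed) {
    vb <- if (inherits(sweb_or_web, "staged_web")) sweb_or_web$vb else NULL
    M_adult <- if (inherits(sweb_or_web, "staged_web"))
      sweb_or_web$base$trophic$M else sweb_or_web$trophic$M
    rows <- lapply(traj$fish_species, function(sp) {
      sp_series <- rowSums(mean_mat[, traj$node_species == sp, drop = FALSE])
      st <- if (!is.null(vb)) vb[[as.character(sp)]]
            else vb_stage_weights(M_adult[sp])
      data.frame(species = sp,
                 survived = unname(surv$survived[as.character(sp)]),
                 W_adult = st$W[st$t_max + 1L],
                 W_inf = st$W_inf, W_min = st$W[1L],
                 mean_species = mean(sp_series),
                 cv_species = biomass_cv(sp_series),
                 mean_eco = mean(eco), cv_eco = biomass_cv(eco),
                 mean_fish = mean(fish_tot), cv_fish = biomass_cv(fish_tot))
    })
    species <- do.call(rbind, rows)
  }
  list(analysed = analysed,
       survived = surv$survived, n_survived = surv$count,
       cv_eco = if (analysed) biomass_cv(eco) else NA_real_,
       cv_fish = if (analysed) biomass_cv(fish_tot) else NA_real_,
       mean_eco = if (analysed) mean(eco) else NA_real_,
       mean_fish = if (analysed) mean(fish_tot) else NA_real_,
       species = species)
}

#' Stage-size ordering across surviving fish species
#'
#' For runs with at least two surviving fish species: is the youngest life
#' stage of the largest surviving species lighter than the oldest life
#' stage of the smallest surviving species? Runs with fewer than two
#' survivors are excluded from the denominator.
#'
#' @param species_table data frame with one row per surviving fish species
#'   and columns `run` (run identifier), `W_inf`, `W_min`, `W_adult` (as
#'   produced by [run_ensemble()]).
#' @return List with `fraction`, `n_true` and `n_eligible`.
#' @export
size_ordering_fraction <- function(species_table) {
  if (is.null(species_table) || nrow(species_table) == 0L)
    return(list(fraction = NA_real_, n_true = 0L, n_eligible = 0L))
  runs <- split(species_table, species_table$run)
  verdicts <- vapply(runs, function(df) {
    df <- df[df$survived, , drop = FALSE]
    if (nrow(df) < 2L) return(NA)
    largest <- df[which.max(df$W_inf), ]
    smallest <- df[which.min(df$W_inf), ]
    largest$W_min < smallest$W_adult
  }, logical(1))
  verdicts <- verdicts[!is.na(verdicts)]
  list(fraction = if (length(verdicts)) mean(verdicts) else NA_real_,
       n_true = sum(verdicts), n_eligible = length(verdicts))
}

#' Ordinary least-squares size-stability regressions
#'
#' Fits the four pooled regressions of the ensemble analysis -- mean
#' ecosystem biomass, mean fish biomass, CV of ecosystem biomass and CV of
#' fish biomass, each against (by default log10 of) the asymptotic adult
#' body mass of surviving fish species -- after removing outlier rows with
#' mass above `mass_cut` or a CV above `cv_cut` percent.
#'
#' @param species_table one row per surviving fish species with columns
#'   `W_inf`, `mean_eco`, `mean_species` (or `mean_fish`), `cv_eco`,
#'   `cv_species` (or `cv_fish`).
#' @param mass_cut mass outlier cutoff (default `1e10`).
#' @param cv_cut CV outlier cutoff in percent (default 800).
#' @param log_mass regress on `log10(W_inf)` (default) rather than raw mass.
#' @param fish_scope `"species"` (default) analyses each species' own
#'   biomass in the fish columns; `"total"` uses the run's total fish
#'   biomass.
#' @return Data frame with one row per response: slope, standard error,
#'   `t`, `df` (`n - 2`) and two-sided `p`.
#' @export
size_stability_regression <- function(species_table, mass_cut = 1e10,
                                      cv_cut = 800, log_mass = TRUE,
                                      fish_scope = c("species", "total")) {
  fish_scope <- match.arg(fish_scope)
  df <- species_table[species_table$survived, , drop = FALSE]
  mean_fish_col <- if (fish_scope == "species") df$mean_species else df$mean_fish
  cv_fish_col <- if (fish_scope == "species") df$cv_species else df$cv_fish
  keep <- df$W_inf <= mass_cut &
    100 * df$cv_eco <= cv_cut & 100 * cv_fish_col <= cv_cut &
    is.finite(df$cv_eco) & is.finite(cv_fish_col)
  df <- df[keep, , drop = FALSE]
  mean_fish_col <- mean_fish_col[keep]
  cv_fish_col <- cv_fish_col[keep]
  predictor <- if (log_mass) log10(df$W_inf) else df$W_inf
  responses <- list(mean_eco = df$mean_eco, mean_fish = mean_fish_col,
                    cv_eco = df$cv_eco, cv_fish = cv_fish_col)
  out <- lapply(names(responses), function(nm) {
    yv <- responses[[nm]]
    if (length(yv) < 3L || stats::sd(predictor) == 0)
      return(data.frame(response = nm, slope = NA_real_, se = NA_real_,
                        t = NA_real_, df = NA_integer_, p = NA_real_,
                        n = length(yv)))
    fit <- stats::lm(yv ~ predictor)
    sm <- summary(fit)$coefficients
    data.frame(response = nm, slope = sm[2L, 1L], se = sm[2L, 2L],
               t = sm[2L, 3L], df = stats::df.residual(fit),
               p = sm[2L, 4L], n = length(yv))
  })
  do.call(rbind, out)
}

#' Run the three-model-type ensemble experiment
#'
#' For each replicate: generate a validated niche web (regenerating when a
#' juvenile stage would have an empty diet), build the three matched model
#' variants, simulate `burn_in + analysis` years of seasonal dynamics for
#' each, and summarise fish survival and biomass stability. Two acceptance
#' filters are applied when tabulating: the preliminary filter discards
#' webs in which every fish died in every variant; the stringent filter
#' additionally requires at least one surviving fish species in every
#' variant of the web. The headline fractions reported are the fraction of
#' webs whose fish biomass stabilized in at least one variant, the
#' fraction meeting the stringent per-variant criterion, and the
#' stage-size ordering fraction among runs with two or more surviving fish.
#'
#' @param n_webs number of replicate webs.
#' @param S,C,Z web richness, target connectance and allometric ratio.
#' @param burn_in,analysis years of burn-in and of analysis.
#' @param params an [atn_params()] object.
#' @param seed master seed; per-web sub-seeds are drawn from it so the
#'   ensemble is reproducible and runs are independent given their seeds.
#' @param model_types subset of `c("original", "unlinked", "linked")`.
#' @param tol connectance tolerance for web validation.
#' @param max_web_attempts rejection-sampling budget per web (including
#'   empty-diet staging rejections).
#' @param progress print one line per web.
#' @return An object of class `atn_ensemble`: `runs` (one row per web and
#'   model type), `species` (one row per fish species per analysed run),
#'   `survivor_freq` (counts of 0-3 surviving species by model type over
#'   preliminary-accepted webs), `fractions`, `regression` (pooled linked-
#'   variant fits), and the configuration echo.
#' @export
run_ensemble <- function(n_webs, S = 30L, C = 0.15, Z = 100,
                         burn_in = 200L, analysis = 100L,
                         params = atn_params(), seed = 1L,
                         model_types = c("original", "unlinked", "linked"),
                         tol = 0.05, max_web_attempts = 200L,
                         progress = FALSE) {
  model_types <- match.arg(model_types, several.ok = TRUE)
  years <- burn_in + analysis
  set.seed(seed)
  web_seeds <- sample.int(.Machine$integer.max - 1L, n_webs)

  run_rows <- list()
  species_rows <- list()
  for (w in seq_len(n_webs)) {
    set.seed(web_seeds[w])
    variants <- NULL
    for (att in seq_len(max_web_attempts)) {
      web <- try(generate_valid_web(S, C, tol = tol, max_attempts = 2000L),
                 silent = TRUE)
      if (inherits(web, "try-error")) next
      web <- annotate_web(web, Z = Z)
      stage_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      variants <- tryCatch(
        build_model_variants(web, params, stage_seed = stage_seed),
        atn_empty_diet = function(e) NULL)
      if (!is.null(variants)) break
    }
    if (is.null(variants)) {
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        web = w, model_type = NA_character_, status = "web_generation_failed",
        analysed = FALSE, stabilized = FALSE, n_survived = NA_integer_,
        cv_eco = NA_real_, cv_fish = NA_real_,
        mean_eco = NA_real_, mean_fish = NA_real_)
      next
    }
    for (mt in model_types) {
      traj <- run_simulation(
        web = if (mt == "original") variants$original else variants$staged,
        model_type = mt, years = years, params = params,
        r = variants$r,
        B_init = if (mt == "original") variants$init_original
                 else variants$init_staged)
      res <- analyse_run(
        traj, if (mt == "original") variants$original else variants$staged,
        burn_in)
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        web = w, model_type = mt, status = traj$status,
        analysed = res$analysed,
        stabilized = stabilization_check(traj, burn_in),
        n_survived = res$n_survived,
        cv_eco = res$cv_eco, cv_fish = res$cv_fish,
        mean_eco = res$mean_eco, mean_fish = res$mean_fish)
      if (!is.null(res$species)) {
        res$species$web <- w
        res$species$model_type <- mt
        res$species$run <- paste(w, mt, sep = ":")
        species_rows[[length(species_rows) + 1L]] <- res$species
      }
    }
    if (progress)
      message(sprintf("web %d/%d done (seed %d)", w, n_webs, web_seeds[w]))
  }
  runs <- do.call(rbind, run_rows)
  species <- if (length(species_rows)) do.call(rbind, species_rows) else NULL

  ok <- runs[!is.na(runs$model_type), , drop = FALSE]
  by_web <- split(ok, ok$web)
  stab_any <- vapply(by_web, function(df) any(df$stabilized), logical(1))
  stringent <- vapply(by_web, function(df) {
    all(df$stabilized) && all(!is.na(df$n_survived) & df$n_survived >= 1L)
  }, logical(1))
  preliminary <- vapply(by_web, function(df)
    any(!is.na(df$n_survived) & df$n_survived >= 1L), logical(1))

  prelim_webs <- as.integer(names(by_web))[preliminary]
  freq_src <- ok[ok$web %in% prelim_webs & !is.na(ok$n_survived), ]
  survivor_freq <- table(
    factor(freq_src$model_type, levels = model_types),
    factor(freq_src$n_survived, levels = 0:3))

  surv_species <- if (!is.null(species))
    species[species$survived, , drop = FALSE] else NULL
  staged_species <- if (!is.null(surv_species))
    surv_species[surv_species$model_type != "original", , drop = FALSE]
    else NULL
  ordering <- size_ordering_fraction(staged_species)

  linked_species <- if (!is.null(species))
    species[species$model_type == "linked", , drop = FALSE] else NULL
  regression <- if (!is.null(linked_species) && nrow(linked_species) >= 10L)
    size_stability_regression(linked_species) else NULL

  fractions <- list(
    stabilized_any = mean(stab_any),
    stringent = mean(stringent),
    preliminary = mean(preliminary),
    size_ordering = ordering$fraction,
    size_ordering_n = ordering$n_eligible,
    n_webs = n_webs)

  structure(list(runs = runs, species = species,
                 survivor_freq = survivor_freq,
                 fractions = fractions, regression = regression,
                 config = list(n_webs = n_webs, S = S, C = C, Z = Z,
                               burn_in = burn_in, analysis = analysis,
                               seed = seed, model_types = model_types,
                               tol = tol, params = params)),
            class = "atn_ensemble")
}

#' @export
print.atn_ensemble <- function(x, ...) {
  f <- x$fractions
  cat(sprintf("ATN ensemble: %d webs x {%s}\n", f$n_webs,
              paste(x$config$model_types, collapse = ", ")))
  cat(sprintf("  stabilized in >= 1 variant : %.1f%%\n", 100 * f$stabilized_any))
  cat(sprintf("  stringent (all variants)   : %.1f%%\n", 100 * f$stringent))
  cat(sprintf("  stage-size ordering        : %.1f%% (n = %d)\n",
              100 * f$size_ordering, f$size_ordering_n))
  cat("  survivor frequencies (rows sum to accepted runs):\n")
  print(x$survivor_freq)
  if (!is.null(x$regression)) {
    cat("  pooled linked-variant regressions on log10 asymptotic mass:\n")
    print(x$regression, row.names = FALSE)
  }
  invisible(x)
}
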