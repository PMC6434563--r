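#' Bioenergetic model parameters
#'
#' Container for every constant of the seasonal consumer-resource ODEs and
#' the simulation harness, with defaults at the standard values for an
#' allometrically scaled aquatic web: shared autotroph carrying capacity
#' `K = 540` µgC/L; autotroph intrinsic growth rates drawn from
#' `N(0.9, 0.2^2)` truncated to `[0.6, 1.2]` per day; maximum consumption
#' rate `y = 10` per day; assimilation efficiency 0.45 on autotroph prey
#' and 0.85 otherwise; Hill exponent `h = 1.2`; growth fraction
#' `fa = 0.4`; maintenance fraction `fm = 0.1`; extinction threshold
#' `1e-6` µgC/L; 100-day growing season. The half-saturation density `B0`
#' (default 80 µgC/L, uniform) and predator-interference coefficients `c`
#' (default 0) are the least constrained inputs and accept either scalars
#' or full node-by-node matrices.
#'
#' @param K autotroph shared carrying capacity (µgC/L).
#' @param r_mean,r_sd,r_min,r_max truncated-normal law for autotroph
#'   intrinsic growth rates (per day).
#' @param y maximum consumption rate (per day).
#' @param e_autotroph,e_consumer assimilation efficiencies by prey type.
#' @param h Hill exponent (>= 1).
#' @param fa fraction of assimilated carbon contributing to growth.
#' @param fm fraction of assimilated carbon lost to maintenance.
#' @param B0 half-saturation density (µgC/L), scalar or matrix.
#' @param c_interference predator-interference coefficient, scalar or matrix.
#' @param extinction_threshold biomass below which a node is set extinct at
#'   season end (µgC/L).
#' @param season_days length of the growing season (days).
#' @param rtol,atol solver tolerances passed to [deSolve::ode()].
#' @param loss_efficiency `"multiply"` applies the assimilation efficiency
#'   as a multiplier on the loss-to-predation term (the form used here);
#'   `"divide"` selects the conventional bioenergetic form dividing by it.
#' @param blowup_ceiling biomass above which a run is declared numerically
#'   blown up (µgC/L).
#' @param init_min,init_max uniform law for per-species initial biomass.
#' @return A validated list of class `atn_params`.
#' @export
atn_params <- function(K = 540, r_mean = 0.9, r_sd = 0.2,
                       r_min = 0.6, r_max = 1.2,
                       y = 10, e_autotroph = 0.45, e_consumer = 0.85,
                       h = 1.2, fa = 0.4, fm = 0.1,
                       B0 = 80, c_interference = 0,
                       extinction_threshold = 1e-6,
                       season_days = 100, rtol = 1e-6, atol = 1e-9,
                       loss_efficiency = c("multiply", "divide"),
                       blowup_ceiling = 1e10,
                       init_min = 5, init_max = 500) {
  loss_efficiency <- match.arg(loss_efficiency)
  p <- list(K = K, r_mean = r_mean, r_sd = r_sd, r_min = r_min, r_max = r_max,
            y = y, e_autotroph = e_autotroph, e_consumer = e_consumer,
            h = h, fa = fa, fm = fm, B0 = B0, c_interference = c_interference,
            extinction_threshold = extinction_threshold,
            season_days = season_days, rtol = rtol, atol = atol,
            loss_efficiency = loss_efficiency,
            blowup_ceiling = blowup_ceiling,
            init_min = init_min, init_max = init_max)
  with(p, {
    stopifnot(K > 0, y >= 0, h >= 1, fa >= 0, fm >= 0,
              e_autotroph > 0, e_autotroph <= 1,
              e_consumer > 0, e_consumer <= 1,
              all(B0 > 0), all(c_interference >= 0),
              extinction_threshold >= 0, season_days > 0,
              r_min <= r_max, init_min <= init_max)
  })
  class(p) <- "atn_params"
  p
}

#' Draw truncated-normal autotroph growth rates
#'
#' `r ~ N(r_mean, r_sd^2)` truncated to `[r_min, r_max]`, drawn by inverse
#' transform so one uniform is consumed per rate.
#'
#' @param n number of rates.
#' @param params an [atn_params()] object.
#' @export
draw_growth_rates <- function(n, params = atn_params()) {
  lo <- stats::pnorm(params$r_min, params$r_mean, params$r_sd)
  hi <- stats::pnorm(params$r_max, params$r_mean, params$r_sd)
  stats::qnorm(stats::runif(n, lo, hi), params$r_mean, params$r_sd)
}

#' Diet-overlap fractions
#'
#' `p[i, k]` is the fraction of consumer `i`'s resources shared with
#' consumer `k`: `|prey(i) intersect prey(k)| / |prey(i)|`. Rows of nodes
#' without prey are zero.
#'
#' @param A binary adjacency matrix (consumers in rows).
#' @return Numeric matrix of overlap fractions in `[0, 1]`.
#' @export
resource_overlap <- function(A) {
  P <- rowSums(A)
  shared <- A %*% t(A)
  p <- shared / ifelse(P > 0, P, 1)
  p[P == 0, ] <- 0
  p
}

# uniform view of an (annotated or staged) web for the dynamic model
dyn_nodes <- function(web) {
  if (inherits(web, "staged_web")) {
    list(N = web$N, A = web$A, guild = web$guild, M = web$M, x = web$x,
         node_species = web$node_species, node_stage = web$node_stage,
         fish_species = web$fish_species, staged = TRUE, sweb = web)
  } else if (inherits(web, "annotated_web")) {
    tr <- web$trophic
    list(N = web$S, A = web$A, guild = tr$guild, M = tr$M, x = tr$x,
         node_species = seq_len(web$S), node_stage = rep(NA_integer_, web$S),
         fish_species = which(tr$guild == "fish"), staged = FALSE, sweb = NULL)
  } else {
    stop("`web` must be an annotated_web or staged_web", call. = FALSE)
  }
}

as_full_matrix <- function(v, N, what) {
  if (is.matrix(v)) {
    if (!all(dim(v) == N))
      stop(sprintf("`%s` matrix must be %d x %d", what, N, N), call. = FALSE)
    v
  } else matrix(v, N, N)
}

# pack the node-resolved model into the flat parameter vector read by the
# compiled derivative (layout documented in src/atn.c)
pack_atn_parms <- function(nodes, params, r) {
  N <- nodes$N
  guild_code <- match(nodes$guild, c("autotroph", "invertebrate", "fish")) - 1L
  if (anyNA(guild_code)) stop("unknown guild in web", call. = FALSE)
  rvec <- numeric(N)
  rvec[guild_code == 0L] <- r
  A <- nodes$A
  P <- rowSums(A)
  w <- A / ifelse(P > 0, P, 1)
  w[P == 0, ] <- 0
  B0 <- as_full_matrix(params$B0, N, "B0")
  cM <- as_full_matrix(params$c_interference, N, "c_interference")
  B0h <- B0^params$h
  cB0h <- A * cM * B0h
  e_prey <- ifelse(guild_code == 0L, params$e_autotroph, params$e_consumer)
  eloss <- if (params$loss_efficiency == "multiply") e_prey else 1 / e_prey
  pov <- resource_overlap(A)
  head <- c(NA_real_, N, params$K, params$y, params$h, params$fa, params$fm,
            as.numeric(any(cB0h > 0)))
  parms <- c(head, guild_code, rvec, nodes$x, eloss,
             as.numeric(w), as.numeric(B0h), as.numeric(cB0h), as.numeric(pov))
  parms[1L] <- length(parms)
  parms
}

#' Build a ready-to-integrate dynamic system from a web
#'
#' Resolves guilds, metabolic rates, feeding preferences, overlap and
#' efficiency terms into the packed parameter block used by the compiled
#' derivative, drawing autotroph growth rates if none are supplied.
#'
#' @param web an `annotated_web` or `staged_web`.
#' @param params an [atn_params()] object.
#' @param r autotroph intrinsic growth rates (one per autotroph, in node
#'   order); drawn with [draw_growth_rates()] from the current RNG stream
#'   when `NULL`.
#' @return A list of class `atn_system` with `nodes`, `params`, `r` and the
#'   packed `parms` vector.
#' @export
atn_system <- function(web, params = atn_params(), r = NULL) {
  nodes <- dyn_nodes(web)
  n_aut <- sum(nodes$guild == "autotroph")
  if (is.null(r)) r <- draw_growth_rates(n_aut, params)
  if (length(r) != n_aut)
    stop(sprintf("`r` must have one rate per autotroph (%d)", n_aut),
         call. = FALSE)
  structure(list(nodes = nodes, params = params, r = r,
                 parms = pack_atn_parms(nodes, params, r)),
            class = "atn_system")
}

#' Evaluate the bioenergetic derivative at a state
#'
#' Autotrophs follow shared-capacity logistic growth minus losses to
#' grazing; consumers balance maintenance loss `-fm * x_i * B_i`, dietary
#' intake `sum_j fa * x_i * y * B_i * F_ij`, and losses to their own
#' predators. `F_ij` is the normalized functional response (see
#' [functional_response()]).
#'
#' @param B biomass state vector (µgC/L).
#' @param system an [atn_system()] (or a web, from which one is built with
#'   default parameters and freshly drawn growth rates).
#' @param ... passed to [atn_system()] when `system` is a web.
#' @return `dB/dt` vector (µgC/L per day).
#' @export
atn_derivatives <- function(B, system, ...) {
  if (!inherits(system, "atn_system")) system <- atn_system(system, ...)
  if (length(B) != system$nodes$N)
    stop("state length does not match the web", call. = FALSE)
  if (any(!is.finite(B)))
    stop("non-finite biomass state", call. = FALSE)
  .Call(C_atn_deriv, as.numeric(B), system$parms)
}

#' Normalized functional response
#'
#' `F_ij = w_ij B_j^h / (B0_ij^h + sum_k c_kj p_ik B_k B0_kj^h +
#' sum_l w_il B_l^h)` with uniform preferences `w_ij = 1 / P_i` over the
#' `P_i` prey of `i`; the interference sum runs over the consumers `k` of
#' `j` and the final sum over the prey `l` of `i`. Values lie in `[0, 1)`.
#'
#' @param B biomass state vector.
#' @param i consumer node id.
#' @param j resource node id (must be prey of `i`).
#' @param web an `annotated_web` or `staged_web`.
#' @param params an [atn_params()] object.
#' @export
functional_response <- function(B, i, j, web, params = atn_params()) {
  nodes <- dyn_nodes(web)
  A <- nodes$A
  if (A[i, j] != 1L) stop("`j` is not prey of `i`", call. = FALSE)
  N <- nodes$N
  h <- params$h
  B0 <- as_full_matrix(params$B0, N, "B0")
  if (any(B0 <= 0)) stop("B0 must be positive", call. = FALSE)
  cM <- as_full_matrix(params$c_interference, N, "c_interference")
  w_i <- A[i, ] / sum(A[i, ])
  pov <- resource_overlap(A)
  cons_j <- which(A[, j] == 1L)
  interf <- sum(cM[cons_j, j] * pov[i, cons_j] * B[cons_j] * B0[cons_j, j]^h)
  prey_sum <- sum(w_i * B^h * (A[i, ] == 1L))
  as.numeric(w_i[j] * B[j]^h / (B0[i, j]^h + interf + prey_sum))
}

#' Integrate one growing season
#'
#' Adaptive integration (lsoda via [deSolve::ode()], compiled derivative)
#' of the bioenergetic ODEs over the growing season, sampled daily.
#' Negative excursions are clamped to zero in the reported trajectory, and
#' nodes below the extinction threshold at season end are set to zero.
#'
#' @param B_start non-negative biomass vector at season start.
#' @param system an [atn_system()] (or a web; see [atn_derivatives()]).
#' @param ... passed to [atn_system()] when `system` is a web.
#' @return A list with `traj` (time-by-node matrix of daily samples, first
#'   column `time`), `B_end` (thresholded season-end state), and `ok`
#'   (FALSE when the solver failed or returned non-finite values).
#' @export
integrate_season <- function(B_start, system, ...) {
  if (!inherits(system, "atn_system")) system <- atn_system(system, ...)
  p <- system$params
  if (any(B_start < 0)) stop("`B_start` must be non-negative", call. = FALSE)
  times <- seq(0, p$season_days, by = 1)
  .Call(C_atn_set_parms, system$parms)
  out <- try(deSolve::ode(
    y = as.numeric(B_start), times = times,
    func = "atn_derivs", parms = NULL,
    dllname = "atnfish",
    method = "lsoda", rtol = p$rtol, atol = p$atol, maxsteps = 50000),
    silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times) ||
      any(!is.finite(out[, -1L]))) {
    return(list(traj = NULL, B_end = NULL, ok = FALSE))
  }
  traj <- unclass(out)
  dimnames(traj) <- list(NULL, c("time", seq_len(ncol(traj) - 1L)))
  traj[, -1L][traj[, -1L] < 0] <- 0
  B_end <- unname(traj[nrow(traj), -1L])
  B_end[B_end < p$extinction_threshold] <- 0
  list(traj = traj, B_end = B_end, ok = TRUE)
}

#' Draw matched initial biomasses for a web
#'
#' One `Uniform(init_min, init_max)` draw per original species; in staged
#' webs a fish species' draw is split equally across its stages so that
#' structured and unstructured model variants start from identical
#' species-level totals.
#'
#' @param web an `annotated_web` or `staged_web`.
#' @param params an [atn_params()] object.
#' @param species_draws optional pre-drawn per-species values (recycled
#'   across variants); drawn from the current RNG stream when `NULL`.
#' @return Per-node biomass vector.
#' @export
initial_biomass <- function(web, params = atn_params(), species_draws = NULL) {
  nodes <- dyn_nodes(web)
  S <- max(nodes$node_species)
  if (is.null(species_draws))
    species_draws <- stats::runif(S, params$init_min, params$init_max)
  B <- species_draws[nodes$node_species]
  if (nodes$staged) {
    n_stage <- nodes$sweb$t_max + 1L
    staged_nodes <- !is.na(nodes$node_stage)
    B[staged_nodes] <- B[staged_nodes] / n_stage
  }
  B
}

#' Run a multi-year seasonal simulation
#'
#' Integrates the bioenergetic ODEs season by season. At the end of every
#' 100-day growing season the ODEs pause: biomasses below the extinction
#' threshold are zeroed, and in the `"linked"` model variant each fish
#' species' stage biomasses are redistributed through its Leslie matrix
#' (growth and reproduction). The `"original"` (unstaged web) and
#' `"unlinked"` (staged web, stages independent) variants skip the Leslie
#' step. A run stops early when the solver fails or any biomass exceeds
#' the blow-up ceiling; remaining years are recorded as `NA`.
#'
#' @param web `annotated_web` for `"original"`, `staged_web` for
#'   `"unlinked"`/`"linked"`.
#' @param model_type one of `"original"`, `"unlinked"`, `"linked"`.
#' @param years number of simulated years.
#' @param params an [atn_params()] object.
#' @param r autotroph growth rates (see [atn_system()]).
#' @param B_init initial per-node biomass; drawn with [initial_biomass()]
#'   when `NULL`.
#' @param store_daily keep the full daily trajectory of every season
#'   (memory-hungry; meant for small fixtures).
#' @return An object of class `atn_trajectory`: annual per-node summaries
#'   (`annual_mean` = season means, `annual_end` = post-transition year-end
#'   states, both years-by-nodes with `NA` rows after a failure),
#'   `annual_max`, `status` (`"ok"`, `"solver_error"` or `"blowup"`),
#'   `failed_year`, node metadata, and the inputs needed to reproduce the
#'   run.
#' @export
run_simulation <- function(web, model_type = c("original", "unlinked", "linked"),
                           years, params = atn_params(), r = NULL,
                           B_init = NULL, store_daily = FALSE) {
  model_type <- match.arg(model_type)
  nodes <- dyn_nodes(web)
  if (model_type == "original" && nodes$staged)
    stop("the original model variant runs on the unstaged web", call. = FALSE)
  if (model_type != "original" && !nodes$staged)
    stop(sprintf("the %s model variant needs a staged_web", model_type),
         call. = FALSE)
  system <- atn_system(web, params, r)
  if (is.null(B_init)) B_init <- initial_biomass(web, params)
  N <- nodes$N

  annual_mean <- matrix(NA_real_, years, N)
  annual_end <- matrix(NA_real_, years, N)
  annual_max <- rep(NA_real_, years)
  daily <- if (store_daily) vector("list", years) else NULL
  status <- "ok"
  failed_year <- NA_integer_
  B <- B_init
  for (yr in seq_len(years)) {
    season <- integrate_season(B, system)
    if (!season$ok) {
      status <- "solver_error"
      failed_year <- yr
      break
    }
    annual_mean[yr, ] <- colMeans(season$traj[, -1L, drop = FALSE])
    annual_max[yr] <- max(season$traj[, -1L])
    if (store_daily) daily[[yr]] <- season$traj
    B <- season$B_end
    if (model_type == "linked")
      B <- apply_annual_transition(B, nodes$sweb)
    annual_end[yr, ] <- B
    if (annual_max[yr] > params$blowup_ceiling) {
      status <- "blowup"
      failed_year <- yr
      break
    }
  }
  structure(list(
    model_type = model_type, years = years, N = N,
    node_species = nodes$node_species, node_stage = nodes$node_stage,
    guild = nodes$guild, fish_species = nodes$fish_species,
    annual_mean = annual_mean, annual_end = annual_end,
    annual_max = annual_max,
    status = status, failed_year = failed_year,
    completed_years = if (status == "ok") years else failed_year - 1L,
    params = params, r = system$r, B_init = B_init,
    daily = daily), class = "atn_trajectory")
}

#' @export
print.atn_trajectory <- function(x, ...) {
  cat(sprintf("ATN trajectory: %s model, %d node(s), %d year(s), status %s\n",
              x$model_type, x$N, x$years, x$status))
  if (x$status != "ok")
    cat(sprintf("  failed at year %d\n", x$failed_year))
  invisible(x)
}
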