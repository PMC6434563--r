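#' Von Bertalanffy stage weights for a fish species
#'
#' Sizes `t_max + 1` life-history stages (ages `t = 0, ..., t_max`) along
#' an isometric von Bertalanffy growth curve
#' `W(t) = W_inf * (1 - exp(-K * (t - t0)))^3`.
#' The curvature is tied to the terminal stage, `K = 3 / t_max`, and adults
#' (stage `t_max`) retain the species' original mass `W_max`, assumed to be
#' `adult_fraction = 0.9` of the asymptotic weight `W_inf`. Those two
#' constraints pin the age offset:
#' `t0 = t_max + log(1 - adult_fraction^(1/3)) / K`.
#'
#' @param W_max adult (species) relative body mass, > 0.
#' @param t_max terminal stage index (default 3, i.e. four stages).
#' @param adult_fraction `W_max / W_inf`, default 0.9.
#' @return A list of class `stage_structure` with `K_vb`, `t0`, `W_inf`,
#'   `W` (stage weights, youngest first), `t_max` and `adult_fraction`.
#' @export
vb_stage_weights <- function(W_max, t_max = 3L, adult_fraction = 0.9) {
  if (!is.numeric(W_max) || W_max <= 0) stop("`W_max` must be > 0", call. = FALSE)
  if (!is.numeric(t_max) || t_max <= 0 || t_max != round(t_max))
    stop("`t_max` must be a positive integer", call. = FALSE)
  if (adult_fraction <= 0 || adult_fraction >= 1)
    stop("`adult_fraction` must lie in (0, 1)", call. = FALSE)
  K <- 3 / t_max
  W_inf <- W_max / adult_fraction
  t0 <- t_max + log(1 - adult_fraction^(1 / 3)) / K
  t <- 0:t_max
  W <- W_inf * (1 - exp(-K * (t - t0)))^3
  W[t_max + 1L] <- W_max  # exact by construction; remove rounding residue
  structure(list(K_vb = K, t0 = t0, W_inf = W_inf, W = W,
                 t_max = as.integer(t_max), adult_fraction = adult_fraction),
            class = "stage_structure")
}

# least-squares map from short-weighted trophic position to niche value,
# fitted across the original nodes of an annotated web
stage_niche_map <- function(web) {
  T <- web$trophic$T
  if (stats::sd(T) == 0)
    stop("degenerate niche map: all trophic positions equal; web rejected",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, T), web$n)
  coef <- fit$coefficients
  names(coef) <- c("intercept", "slope")
  coef
}

#' Approximate the niche value of a life-history stage from its mass
#'
#' Inverts the allometric mass rule to a trophic position,
#' `T_stage = 1 + log_Z(M_stage)`, then maps it to the niche axis through
#' the web's empirical (least-squares linear) relation between
#' short-weighted trophic position and niche value, clamped to (0, 1).
#'
#' @param M_stage stage relative body mass (vectorized).
#' @param web an `annotated_web` (see [annotate_web()]).
#' @return Numeric niche values in (0, 1).
#' @export
stage_niche_value <- function(M_stage, web) {
  Z <- web$trophic$Z
  coef <- stage_niche_map(web)
  T_stage <- 1 + log(M_stage) / log(Z)
  eps <- 1e-9
  pmin(pmax(coef[["intercept"]] + coef[["slope"]] * T_stage, eps), 1 - eps)
}

#' Leslie biomass-transition matrix for the annual growth/reproduction step
#'
#' Each year `advance` (default 90%) of a stage's biomass moves to the next
#' life-history stage while `stay` (10%) remains; the terminal stage
#' reproduces, transferring `advance` of its biomass to the first stage as
#' newborns. Columns are source stages (youngest first), rows destination
#' stages; every column sums to 1, so the transition conserves biomass.
#'
#' @param stay fraction remaining in its stage, default 0.1.
#' @param advance fraction moving on (or reproducing), default 0.9;
#'   `stay + advance` must equal 1.
#' @param stages number of life-history stages, default 4.
#' @return A `stages x stages` matrix.
#' @export
leslie_matrix <- function(stay = 0.1, advance = 0.9, stages = 4L) {
  if (stay < 0 || stay > 1 || advance < 0 || advance > 1 ||
      abs(stay + advance - 1) > 1e-12)
    stop("`stay` and `advance` must lie in [0, 1] and sum to 1", call. = FALSE)
  L <- diag(stay, stages)
  for (s in seq_len(stages - 1L)) L[s + 1L, s] <- advance
  L[1L, stages] <- advance
  L
}

#' Split fish species of an annotated web into life-history stages
#'
#' Every fish species is expanded into `t_max + 1` stage nodes sized by
#' [vb_stage_weights()]. The adult stage keeps the species' original node
#' (niche triple, diet and mass unchanged). Each younger stage receives a
#' niche value from its mass through [stage_niche_value()], reuses the
#' species' diet-range fraction `x = r / n`, and draws its range center
#' `Uniform(r_stage / 2, n_stage)` from a species-deterministic sub-seed,
#' so staging is reproducible given the web and seed. The full adjacency is
#' then rebuilt from the niche triples: stages prey on every node
#' (including other stages) inside their range and are eaten by every
#' consumer whose range contains their niche value. Stage metabolic rates
#' use the fish allometry on stage mass.
#'
#' @param web an `annotated_web` with at least one fish species.
#' @param t_max terminal stage index (default 3).
#' @param stay,advance annual Leslie fractions, see [leslie_matrix()].
#' @param stage_seed integer seed from which per-species sub-seeds are
#'   derived; default `web$seed` (or 0 when the web records none).
#' @param on_empty_diet `"reject"` (default) errors with class
#'   `atn_empty_diet` when a juvenile stage ends up with an empty diet, so
#'   callers can regenerate the web; `"flag"` keeps the web and records the
#'   starving nodes (they simply decay dynamically).
#' @return An object of class `staged_web`: list with niche triples `n`,
#'   `r`, `c` over all nodes, adjacency `A`, `node_species`, `node_stage`
#'   (NA for unstaged nodes), `M`, `x`, `guild`, `fish_species`,
#'   `stage_nodes` (per fish species, node ids youngest stage first),
#'   `vb` (per-species `stage_structure`), `leslie`, `empty_diet_nodes`,
#'   and the original web as `base`.
#' @export
insert_stages <- function(web, t_max = 3L, stay = 0.1, advance = 0.9,
                          stage_seed = NULL,
                          on_empty_diet = c("reject", "flag")) {
  on_empty_diet <- match.arg(on_empty_diet)
  tr <- web$trophic
  if (is.null(tr)) stop("web must be annotated first", call. = FALSE)
  fish <- which(tr$guild == "fish")
  if (length(fish) < 1L) stop("web has no fish species", call. = FALSE)
  if (is.null(stage_seed)) stage_seed <- if (is.null(web$seed)) 0L else web$seed

  S <- web$S
  n_new <- t_max * length(fish)
  N <- S + n_new

  n <- c(web$n, numeric(n_new))
  r <- c(web$r, numeric(n_new))
  cc <- c(web$c, numeric(n_new))
  M <- c(tr$M, numeric(n_new))
  guild <- c(tr$guild, rep("fish", n_new))
  node_species <- c(seq_len(S), integer(n_new))
  node_stage <- c(ifelse(seq_len(S) %in% fish, t_max, NA_integer_),
                  integer(n_new))

  vb <- list()
  stage_nodes <- list()
  # keep the caller's RNG stream untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  nxt <- S
  for (sp in fish) {
    st <- vb_stage_weights(tr$M[sp], t_max = t_max)
    vb[[as.character(sp)]] <- st
    ids <- integer(t_max + 1L)
    ids[t_max + 1L] <- sp
    x_sp <- web$r[sp] / web$n[sp]
    set.seed((stage_seed + 7919L * sp) %% .Machine$integer.max)
    for (t in seq_len(t_max)) {      # stages 0 .. t_max-1
      nxt <- nxt + 1L
      ids[t] <- nxt
      n[nxt] <- stage_niche_value(st$W[t], web)
      r[nxt] <- x_sp * n[nxt]
      cc[nxt] <- stats::runif(1, min = r[nxt] / 2, max = n[nxt])
      M[nxt] <- st$W[t]
      node_species[nxt] <- sp
      node_stage[nxt] <- t - 1L
    }
    stage_nodes[[as.character(sp)]] <- ids
  }
  M[fish] <- vapply(vb, function(s) s$W[t_max + 1L], numeric(1))[
    as.character(fish)]

  A <- niche_adjacency(n, r, cc)
  x <- numeric(N)
  x[guild == "invertebrate"] <- 0.314 * M[guild == "invertebrate"]^(-0.15)
  x[guild == "fish"] <- 0.88 * M[guild == "fish"]^(-0.11)

  Ans <- A
  diag(Ans) <- 0L
  staged <- which(!is.na(node_stage) & node_stage < t_max)
  empty <- staged[rowSums(Ans[staged, , drop = FALSE]) == 0L]
  if (length(empty) && on_empty_diet == "reject") {
    cond <- structure(
      class = c("atn_empty_diet", "error", "condition"),
      list(message = sprintf(
        "juvenile stage(s) with empty diet (node %s); web rejected",
        paste(empty, collapse = ", ")), call = NULL))
    stop(cond)
  }

  structure(list(
    S_base = S, N = N, n = n, r = r, c = cc, A = A,
    node_species = node_species, node_stage = node_stage,
    M = M, x = x, guild = guild,
    fish_species = fish, stage_nodes = stage_nodes, vb = vb,
    t_max = as.integer(t_max),
    leslie = leslie_matrix(stay, advance, stages = t_max + 1L),
    stage_seed = stage_seed,
    empty_diet_nodes = empty,
    base = web), class = "staged_web")
}

#' Apply the annual Leslie growth/reproduction step
#'
#' Pauses between growing seasons: for each fish species the stage biomass
#' vector (youngest first) is multiplied by the species' Leslie matrix;
#' all other nodes are untouched. Because every Leslie column sums to 1
#' the species (and total) biomass is conserved exactly.
#'
#' @param B biomass vector over the nodes of `sweb` (µgC/L, >= 0).
#' @param sweb a `staged_web`.
#' @return Updated biomass vector.
#' @export
apply_annual_transition <- function(B, sweb) {
  if (any(B < 0)) stop("negative biomass input", call. = FALSE)
  for (ids in sweb$stage_nodes)
    B[ids] <- as.numeric(sweb$leslie %*% B[ids])
  B
}

#' Serialize a staged web to JSON
#'
#' Extends the plain web record with the node-to-(species, stage) map,
#' per-node mass and niche triple, and the Leslie matrix, for audit.
#'
#' @param sweb a `staged_web`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @export
staged_web_to_json <- function(sweb, path = NULL) {
  links <- which(sweb$A == 1L, arr.ind = TRUE)
  obj <- list(
    S_base = sweb$S_base, N = sweb$N, t_max = sweb$t_max,
    stage_seed = sweb$stage_seed,
    leslie = sweb$leslie,
    nodes = data.frame(id = seq_len(sweb$N),
                       species = sweb$node_species,
                       stage = sweb$node_stage,
                       guild = sweb$guild,
                       mass = sweb$M, x = sweb$x,
                       n = sweb$n, r = sweb$r, c = sweb$c),
    links = unname(links[order(links[, 1L], links[, 2L]), , drop = FALSE]))
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @export
print.staged_web <- function(x, ...) {
  cat(sprintf("staged web: %d nodes (%d base species, %d fish x %d stages)\n",
              x$N, x$S_base, length(x$fish_species), x$t_max + 1L))
  if (length(x$empty_diet_nodes))
    cat("  flagged empty-diet stages:",
        paste(x$empty_diet_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.stage_structure <- function(x, ...) {
  cat(sprintf("von Bertalanffy stages: K = %.3f, t0 = %.4f, W_inf = %.4g\n",
              x$K_vb, x$t0, x$W_inf))
  cat("  stage weights:", format(x$W, digits = 4), "\n")
  invisible(x)
}
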