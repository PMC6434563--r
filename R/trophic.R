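#' Shortest trophic level
#'
#' `T1_i = 1` for basal species (no prey other than themselves) and
#' `1 + min(T1_j)` over the prey `j` of `i` otherwise, computed by
#' breadth-first relaxation from the basal set. Cannibalistic self-links
#' are ignored: a shortest chain through a self-loop is never shortest.
#'
#' @param A binary adjacency matrix, `A[i, j] = 1` iff `i` eats `j`.
#' @return Integer vector of shortest trophic levels (basal = 1).
#' @export
shortest_trophic_level <- function(A) {
  S <- nrow(A)
  Ans <- A
  diag(Ans) <- 0L
  T1 <- rep(NA_integer_, S)
  frontier <- basal_nodes(A)
  if (length(frontier) == 0L)
    stop("web has no basal species; no node has a path to an autotroph",
         call. = FALSE)
  level <- 1L
  T1[frontier] <- level
  while (length(frontier)) {
    level <- level + 1L
    # consumers having at least one prey in the frontier, not yet levelled
    cand <- which(is.na(T1) & (Ans[, frontier, drop = FALSE] %*%
                                 rep(1L, length(frontier)) > 0))
    T1[cand] <- level
    frontier <- cand
  }
  if (anyNA(T1))
    stop("node(s) without a basal food chain: ",
         paste(which(is.na(T1)), collapse = ", "), call. = FALSE)
  T1
}

#' Prey-averaged trophic position
#'
#' `T2_i = 1 + mean(T2_j over prey j of i)`, with `T2 = 1` fixed for basal
#' species. Feeding loops (including cannibalism) are handled exactly by
#' solving the linear system `(I - W) T2 = 1`, where `W[i, j] = A[i, j] /
#' P_i` for non-basal `i` (`P_i` = number of prey, self-links retained:
#' they are links) and `W` is zero on basal rows.
#'
#' @inheritParams shortest_trophic_level
#' @return Numeric vector of prey-averaged trophic positions (>= 1).
#' @export
prey_averaged_position <- function(A) {
  S <- nrow(A)
  basal <- basal_nodes(A)
  P <- rowSums(A)
  W <- A / ifelse(P > 0, P, 1)
  W[basal, ] <- 0
  M <- diag(S) - W
  T2 <- tryCatch(solve(M, rep(1, S)),
                 error = function(e)
                   stop("singular prey-average system; web rejected (",
                        conditionMessage(e), ")", call. = FALSE))
  as.numeric(T2)
}

#' Short-weighted trophic position
#'
#' The average `(T1 + T2) / 2` of the shortest trophic level and the
#' prey-averaged trophic position; basal species sit at exactly 1 in every
#' metric.
#'
#' @param T1,T2 numeric vectors of equal length.
#' @export
short_weighted_position <- function(T1, T2) {
  if (length(T1) != length(T2))
    stop("`T1` and `T2` must have equal length", call. = FALSE)
  (T1 + T2) / 2
}

#' Assign autotroph / invertebrate / fish guilds
#'
#' Basal species (no prey) are autotrophs. Among the remaining consumers,
#' the three most apex nodes -- highest short-weighted trophic position `T`
#' -- are fish; everything else is an invertebrate. Ties at the fish cutoff
#' are broken deterministically by higher niche value, then lower node id.
#'
#' @param A binary adjacency matrix.
#' @param T short-weighted trophic positions.
#' @param n niche values (used only to break ties); may be `NULL`.
#' @param n_fish number of apex consumers classed as fish (default 3).
#' @return Character vector over `{"autotroph", "invertebrate", "fish"}`.
#' @export
assign_guilds <- function(A, T, n = NULL, n_fish = 3L) {
  S <- nrow(A)
  basal <- basal_nodes(A)
  consumers <- setdiff(seq_len(S), basal)
  if (length(consumers) < n_fish)
    stop(sprintf("web rejected: only %d consumer(s), need >= %d for fish guild",
                 length(consumers), n_fish), call. = FALSE)
  if (is.null(n)) n <- rep(0, S)
  ord <- consumers[order(-T[consumers], -n[consumers], consumers)]
  guild <- rep("invertebrate", S)
  guild[basal] <- "autotroph"
  guild[ord[seq_len(n_fish)]] <- "fish"
  guild
}

#' Allometric body mass from trophic position
#'
#' Relative body mass `M = Z^(T - 1)`: basal species have mass 1 and each
#' step up the food chain multiplies mass by the consumer-resource
#' allometric ratio `Z` (default 100).
#'
#' @param T trophic positions.
#' @param Z allometric consumer-resource mass ratio (> 0).
#' @export
body_mass <- function(T, Z = 100) {
  if (!is.numeric(Z) || Z <= 0) stop("`Z` must be > 0", call. = FALSE)
  Z^(T - 1)
}

#' Mass-specific metabolic rate
#'
#' Allometric (Kleiber-type) scaling of metabolic rate per unit biomass:
#' 0 for autotrophs, `0.314 * M^-0.15` for invertebrates and
#' `0.88 * M^-0.11` for fish.
#'
#' @param M relative body mass (must be > 0 for consumers).
#' @param guild character vector over
#'   `{"autotroph", "invertebrate", "fish"}`, recycled against `M`.
#' @return Numeric vector of mass-specific metabolic rates (per day).
#' @export
metabolic_rate <- function(M, guild) {
  res <- rep(NA_real_, max(length(M), length(guild)))
  M <- rep_len(M, length(res))
  guild <- rep_len(guild, length(res))
  bad <- guild != "autotroph" & !(is.finite(M) & M > 0)
  if (any(bad))
    stop("consumer body mass must be > 0 (node ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  res[guild == "autotroph"] <- 0
  inv <- guild == "invertebrate"
  res[inv] <- 0.314 * M[inv]^(-0.15)
  fsh <- guild == "fish"
  res[fsh] <- 0.88 * M[fsh]^(-0.11)
  unknown <- is.na(res)
  if (any(unknown))
    stop("unknown guild: ", paste(unique(guild[unknown]), collapse = ", "),
         call. = FALSE)
  res
}

#' Annotate a niche web with trophic positions, guilds, masses and rates
#'
#' Convenience wrapper running [shortest_trophic_level()],
#' [prey_averaged_position()], [short_weighted_position()],
#' [assign_guilds()], [body_mass()] and [metabolic_rate()] on a validated
#' web.
#'
#' @param web a `niche_web`.
#' @param Z allometric mass ratio.
#' @param n_fish number of apex consumers classed as fish.
#' @return The web with an added `trophic` element (list with `T1`, `T2`,
#'   `T`, `guild`, `M`, `x`, `Z`) and class `annotated_web`.
#' @export
annotate_web <- function(web, Z = 100, n_fish = 3L) {
  A <- web$A
  T1 <- shortest_trophic_level(A)
  T2 <- prey_averaged_position(A)
  Tm <- short_weighted_position(T1, T2)
  guild <- assign_guilds(A, Tm, n = web$n, n_fish = n_fish)
  M <- body_mass(Tm, Z)
  M[guild == "autotroph"] <- 1
  x <- metabolic_rate(M, guild)
  web$trophic <- list(T1 = T1, T2 = T2, T = Tm, guild = guild,
                      M = M, x = x, Z = Z)
  class(web) <- unique(c("annotated_web", class(web)))
  web
}

#' Export a per-node trophic annotation table
#'
#' @param web an `annotated_web`.
#' @param path optional TSV path; when given the table is written with
#'   [utils::write.table()].
#' @return A data frame with columns id, n, guild, T1, T2, T, M, x.
#' @export
annotation_table <- function(web, path = NULL) {
  tr <- web$trophic
  if (is.null(tr)) stop("web is not annotated; run annotate_web()", call. = FALSE)
  df <- data.frame(id = seq_len(web$S), n = web$n, guild = tr$guild,
                   T1 = tr$T1, T2 = tr$T2, T = tr$T, M = tr$M, x = tr$x)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
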