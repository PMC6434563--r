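#' atnfish: life-history-structured allometric trophic network simulations
#'
#' Tools to generate niche-model food webs, annotate them with trophic
#' positions and allometric body masses, split fish species into von
#' Bertalanffy life-history stages, integrate seasonal bioenergetic
#' consumer-resource dynamics with an annual Leslie-matrix step, and run
#' replicated ensembles contrasting unstructured, stage-added and
#' stage-linked model variants.
#'
#' @useDynLib atnfish, .registration = TRUE
#' @keywords internal
"_PACKAGE"

#' Draw a (possibly invalid) niche-model food web
#'
#' Implements the classic niche model: each of the `S` species receives a
#' niche value `n_i ~ Uniform(0, 1)`, a diet-range fraction
#' `x_i ~ Beta(1, (1 - 2C) / (2C))` so that the expected realized
#' connectance matches `C`, a range width `r_i = x_i * n_i`, and a range
#' center `c_i ~ Uniform(r_i / 2, n_i)`. Species `i` consumes every species
#' whose niche value falls inside `[c_i - r_i/2, c_i + r_i/2]` and nothing
#' else; cannibalistic self-links are permitted by range membership. The
#' returned web is not validated (see [validate_web()]).
#'
#' @param S integer number of species (>= 2).
#' @param C target connectance in (0, 0.5); the Beta shape parameter
#'   `(1 - 2C) / (2C)` must be positive.
#' @param seed optional integer seed applied before drawing; `NULL` uses the
#'   current RNG state.
#' @return An object of class `niche_web`: a list with elements `S`,
#'   `C_target`, `n`, `r`, `c`, `A` (binary `S x S` adjacency, `A[i, j] = 1`
#'   iff `i` eats `j`) and `seed`.
#' @seealso [generate_valid_web()], [realized_connectance()]
#' @export
draw_niche_web <- function(S, C, seed = NULL) {
  if (!is.numeric(S) || length(S) != 1L || S < 2 || S != round(S))
    stop("`S` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || C <= 0 || C >= 0.5)
    stop("`C` must lie in (0, 0.5) so that the Beta shape (1-2C)/(2C) is positive",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  S <- as.integer(S)
  beta_shape <- (1 - 2 * C) / (2 * C)
  n <- stats::runif(S)
  x <- stats::rbeta(S, shape1 = 1, shape2 = beta_shape)
  r <- x * n
  cc <- stats::runif(S, min = r / 2, max = n)
  web <- structure(
    list(S = S, C_target = C, n = n, r = r, c = cc,
         A = niche_adjacency(n, r, cc), seed = seed),
    class = "niche_web")
  web
}

#' Rebuild the adjacency matrix implied by niche triples
#'
#' The adjacency of a niche-model web is a pure function of the niche
#' values and diet ranges: `A[i, j] = 1` iff
#' `n_j` is in `[c_i - r_i/2, c_i + r_i/2]`.
#'
#' @param n,r,c numeric vectors of niche values, range widths and range
#'   centers (equal length).
#' @return Binary integer matrix with consumers in rows, resources in columns.
#' @export
niche_adjacency <- function(n, r, c) {
  stopifnot(length(n) == length(r), length(n) == length(c))
  lo <- c - r / 2
  hi <- c + r / 2
  A <- outer(seq_along(n), seq_along(n),
             function(i, j) as.integer(n[j] >= lo[i] & n[j] <= hi[i]))
  storage.mode(A) <- "integer"
  A
}

#' Realized connectance of a web
#'
#' Directed links divided by `S^2` (ordered species pairs, self-links
#' counted in both numerator and denominator).
#'
#' @param web a `niche_web`, or a plain binary adjacency matrix.
#' @return Scalar fraction in `[0, 1]`.
#' @export
realized_connectance <- function(web) {
  A <- if (is.matrix(web)) web else web$A
  sum(A) / (nrow(A)^2)
}

# prey index sets with self-links dropped; basal = no non-self prey
basal_nodes <- function(A) {
  Ans <- A
  diag(Ans) <- 0L
  which(rowSums(Ans) == 0L)
}

# breadth-first search over a directed adjacency (rows = from), self-links
# ignored; returns logical reachability of `targets` from each node
reaches_targets <- function(A, targets) {
  S <- nrow(A)
  Ans <- A
  diag(Ans) <- 0L
  ok <- logical(S)
  ok[targets] <- TRUE
  # relax until fixed point: i is ok if any prey j of i is ok
  repeat {
    nxt <- ok | (Ans %*% ok > 0)
    if (all(nxt == ok)) break
    ok <- nxt
  }
  as.logical(ok)
}

#' Validate a niche-model web against the biological-realism rules
#'
#' Checks the four rejection rules used when generating webs:
#' (a) every species is connected to the web by eating or being eaten
#' (self-links ignored); (b) every species has an autotroph (basal species)
#' somewhere down its food chain; (c) the web is a single connected
#' component when regarded as an undirected graph, i.e. not several
#' distinct smaller webs; (d) the realized connectance is within a relative
#' tolerance of the target.
#'
#' @param web a `niche_web`.
#' @param tol relative connectance tolerance for rule (d); default 0.05.
#' @return A list of class `web_validation` with logical elements
#'   `no_isolated`, `basal_reachable`, `connected`, `connectance_ok`, and
#'   `pass` (all four), plus the realized connectance.
#' @export
validate_web <- function(web, tol = 0.05) {
  A <- if (is.matrix(web)) web else web$A
  C_target <- if (is.matrix(web)) NA_real_ else web$C_target
  S <- nrow(A)
  Ans <- A
  diag(Ans) <- 0L

  no_isolated <- all(rowSums(Ans) + colSums(Ans) > 0L)

  # rule (b) uses the strict basal set (no prey at all): a node whose only
  # prey is itself is not an autotroph and has no basal food chain
  basal <- which(rowSums(A) == 0L)
  basal_reachable <- length(basal) > 0L && all(reaches_targets(A, basal))

  # undirected connectivity by BFS from node 1
  U <- (Ans + t(Ans)) > 0L
  seen <- logical(S)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(U[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  connected <- all(seen)

  Creal <- realized_connectance(A)
  connectance_ok <- if (is.na(C_target)) NA
                    else abs(Creal - C_target) / C_target <= tol

  out <- list(no_isolated = no_isolated,
              basal_reachable = basal_reachable,
              connected = connected,
              connectance_ok = connectance_ok,
              realized_connectance = Creal)
  out$pass <- no_isolated && basal_reachable && connected &&
    isTRUE(connectance_ok)
  class(out) <- "web_validation"
  out
}

#' @export
print.web_validation <- function(x, ...) {
  cat("niche web validation:",
      if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  (a) no isolated node      : %s\n", x$no_isolated))
  cat(sprintf("  (b) basal chain for all   : %s\n", x$basal_reachable))
  cat(sprintf("  (c) single component      : %s\n", x$connected))
  cat(sprintf("  (d) connectance %.4f ok   : %s\n",
              x$realized_connectance, x$connectance_ok))
  invisible(x)
}

#' Generate a validated niche-model web by rejection sampling
#'
#' Repeatedly draws webs with [draw_niche_web()] and keeps the first one
#' passing [validate_web()]. Webs failing any of rules (a)-(d) are
#' discarded, mirroring the rejection step used to impose biological
#' realism on the niche model.
#'
#' @inheritParams draw_niche_web
#' @param tol relative connectance tolerance passed to [validate_web()].
#' @param max_attempts attempts before giving up with an error naming the
#'   most frequently failing rule.
#' @param seed optional integer seed; attempts consume the RNG stream
#'   sequentially so a given seed identifies a unique accepted web.
#' @return A validated `niche_web` with an `attempts` element recording the
#'   number of draws used.
#' @export
generate_valid_web <- function(S, C, seed = NULL, tol = 0.05,
                               max_attempts = 10000L) {
  if (max_attempts < 1L) stop("`max_attempts` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fails <- c(no_isolated = 0L, basal_reachable = 0L,
             connected = 0L, connectance_ok = 0L)
  for (k in seq_len(max_attempts)) {
    web <- draw_niche_web(S, C, seed = NULL)
    v <- validate_web(web, tol = tol)
    if (v$pass) {
      web$attempts <- k
      web$seed <- seed
      web$tol <- tol
      return(web)
    }
    for (rule in names(fails))
      if (!isTRUE(v[[rule]])) fails[rule] <- fails[rule] + 1L
  }
  worst <- names(which.max(fails))
  stop(sprintf(
    "no valid web in %d attempts (most common failure: rule '%s', %d times)",
    max_attempts, worst, fails[worst]), call. = FALSE)
}

#' Serialize a niche web to JSON
#'
#' Writes `{S, C_target, seed, nodes:[{id, n, r, c}], links:[[consumer,
#' resource], ...]}` with 1-based node ids. [web_from_json()] inverts it.
#'
#' @param web a `niche_web`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @export
web_to_json <- function(web, path = NULL) {
  links <- which(web$A == 1L, arr.ind = TRUE)
  obj <- list(
    S = web$S, C_target = web$C_target,
    seed = if (is.null(web$seed)) NA else web$seed,
    nodes = data.frame(id = seq_len(web$S), n = web$n, r = web$r, c = web$c),
    links = unname(links[order(links[, 1L], links[, 2L]), , drop = FALSE]))
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname web_to_json
#' @param json a JSON string or file path produced by [web_to_json()].
#' @export
web_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  n <- obj$nodes$n[order(obj$nodes$id)]
  r <- obj$nodes$r[order(obj$nodes$id)]
  cc <- obj$nodes$c[order(obj$nodes$id)]
  web <- structure(
    list(S = as.integer(obj$S), C_target = obj$C_target,
         n = n, r = r, c = cc, A = niche_adjacency(n, r, cc),
         seed = if (is.null(obj$seed) || is.na(obj$seed)) NULL else obj$seed),
    class = "niche_web")
  web
}

#' @export
print.niche_web <- function(x, ...) {
  cat(sprintf("niche web: S = %d, target C = %.3f, realized C = %.4f\n",
              x$S, x$C_target, realized_connectance(x)))
  cat(sprintf("  basal species: %d, links: %d\n",
              length(basal_nodes(x$A)), sum(x$A)))
  invisible(x)
}
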