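# shared fixtures, built in code

# wrap an arbitrary adjacency matrix as a web object (n values optional);
# used for hand-constructed topologies where the niche triples are irrelevant
web_from_A <- function(A, n = NULL, C_target = NA_real_) {
  S <- nrow(A)
  storage.mode(A) <- "integer"
  structure(list(S = S, C_target = C_target,
                 n = if (is.null(n)) seq_len(S) / (S + 1) else n,
                 r = rep(0.1, S), c = rep(0.5, S), A = A, seed = NULL),
            class = "niche_web")
}

# food chain 1 <- 2 <- 3 <- ... (node 1 basal, i eats i-1)
chain_web <- function(S) {
  A <- matrix(0L, S, S)
  for (i in 2:S) A[i, i - 1L] <- 1L
  web_from_A(A, C_target = (S - 1) / S^2)
}

# a standard annotated + staged 30-species web, cached across tests
std_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    for (s in 1:50) {
      set.seed(s)
      web <- annotate_web(generate_valid_web(30, 0.15))
      sw <- tryCatch(insert_stages(web, stage_seed = 1000L + s),
                     atn_empty_diet = function(e) NULL)
      if (!is.null(sw)) {
        cache <<- list(web = web, staged = sw, seed = s)
        return(cache)
      }
    }
    stop("no stageable fixture web found")
  }
})

# independent T1 oracle: shortest path to a basal node through igraph
oracle_T1 <- function(A) {
  Ans <- A; diag(Ans) <- 0L
  basal <- which(rowSums(Ans) == 0L)
  g <- igraph::graph_from_adjacency_matrix(Ans, mode = "directed")
  d <- igraph::distances(g, to = basal, mode = "out")
  1 + apply(d, 1L, min)
}

oracle_T2_acyclic <- function(A) {
  # topological-order recursion; valid only for acyclic adjacency
  S <- nrow(A)
  T2 <- rep(NA_real_, S)
  basal <- which(rowSums(A) == 0L)
  T2[basal] <- 1
  repeat {
    progressed <- FALSE
    for (i in which(is.na(T2))) {
      prey <- which(A[i, ] == 1L)
      if (all(!is.na(T2[prey]))) {
        T2[i] <- 1 + mean(T2[prey])
        progressed <- TRUE
      }
    }
    if (!anyNA(T2) || !progressed) break
  }
  T2
}

# hand-build an annotated web with explicit guilds/masses for dynamics tests
make_annotated_web <- function(A, guild, M = NULL, n = NULL, Z = 100) {
  S <- nrow(A)
  storage.mode(A) <- "integer"
  if (is.null(M)) M <- rep(1, S)
  w <- web_from_A(A, n = n)
  w$trophic <- list(T1 = rep(1L, S), T2 = rep(1, S), T = rep(1, S),
                    guild = guild, M = M,
                    x = metabolic_rate(M, guild), Z = Z)
  class(w) <- c("annotated_web", class(w))
  w
}

# literal transcription of the normalized functional response, used as the
# independent oracle for the compiled dynamics
oracle_F <- function(B, i, j, A, B0, cmat, h) {
  P <- rowSums(A)
  w_ij <- 1 / P[i]
  prey_i <- which(A[i, ] == 1L)
  cons_j <- which(A[, j] == 1L)
  overlap <- function(i, k) {
    if (P[i] == 0) return(0)
    length(intersect(which(A[i, ] == 1L), which(A[k, ] == 1L))) / P[i]
  }
  interf <- 0
  for (k in cons_j)
    interf <- interf + cmat[k, j] * overlap(i, k) * B[k] * B0[k, j]^h
  denom <- B0[i, j]^h + interf + sum(w_ij * B[prey_i]^h)
  w_ij * B[j]^h / denom
}

# literal transcription of the autotroph/consumer growth equations
oracle_deriv <- function(B, web, params, r) {
  tr <- web$trophic
  A <- web$A
  S <- nrow(A)
  B0 <- matrix(params$B0, S, S)
  cmat <- matrix(params$c_interference, S, S)
  e_prey <- ifelse(tr$guild == "autotroph", params$e_autotroph,
                   params$e_consumer)
  rfull <- numeric(S)
  rfull[tr$guild == "autotroph"] <- r
  dB <- numeric(S)
  Sauto <- sum(B[tr$guild == "autotroph"])
  for (i in seq_len(S)) {
    cons_i <- which(A[, i] == 1L)
    loss <- 0
    for (jj in cons_i)
      loss <- loss + tr$x[jj] * params$y * B[jj] *
        oracle_F(B, jj, i, A, B0, cmat, params$h) * e_prey[i]
    if (tr$guild[i] == "autotroph") {
      dB[i] <- rfull[i] * (1 - Sauto / params$K) * B[i] - loss
    } else {
      gain <- 0
      for (jj in which(A[i, ] == 1L))
        gain <- gain + params$fa * tr$x[i] * params$y * B[i] *
          oracle_F(B, i, jj, A, B0, cmat, params$h)
      dB[i] <- -params$fm * tr$x[i] * B[i] + gain - loss
    }
  }
  dB
}

# draw a small random acyclic web (each node may eat only lower-indexed
# nodes) with at least one basal species
random_acyclic_A <- function(S, p = 0.5) {
  A <- matrix(0L, S, S)
  for (i in 2:S)
    for (j in 1:(i - 1L))
      if (stats::runif(1) < p) A[i, j] <- 1L
  A
}
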