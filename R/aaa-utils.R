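# Internal helpers shared across modules.

DEG <- pi / 180

#' @noRd
ff_stop <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("ff_", class), "ff_error")))
}

#' @noRd
ff_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("ff_", class), "ff_warning")))
}

## Normalize an angle in degrees to [0, 360).
norm360 <- function(a) {
  a <- a %% 360
  a[a < 0] <- a[a < 0] + 360
  a
}

## Normalize an angle in degrees to (-180, 180].
norm180 <- function(a) {
  a <- norm360(a)
  a[a > 180] <- a[a > 180] - 360
  a
}

## Run `expr` with a temporary RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package route through this so the same
## seed always reproduces the same result without clobbering the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Rotation matrix for a right-handed rotation by `theta` radians about unit
## axis `u` (Rodrigues form).
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Adjacency list (list of integer vectors) from an n-atom bond table.
adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, sort)
}

## Breadth-first bond-path distances from atom `from` (Inf if disconnected).
bond_distances <- function(adj, from) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (a in frontier) {
      for (b in adj[[a]]) {
        if (is.infinite(d[b])) {
          d[b] <- d[a] + 1
          nxt <- c(nxt, b)
        }
      }
    }
    frontier <- nxt
  }
  d
}

## Optimal rigid superposition (Kabsch, SVD, proper rotation only) taking
## `src` onto `dst` (both m x 3). Returns list(R, t) with fit = src %*% R + t.
kabsch_superpose <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t_vec <- cd - as.numeric(cs %*% R)
  list(R = R, t = t_vec)
}

## Connected component of `start`, never expanding through atoms in `blocked`.
component_excluding <- function(adj, start, blocked) {
  seen <- rep(FALSE, length(adj))
  seen[blocked] <- TRUE
  seen[start] <- TRUE
  frontier <- start
  out <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (a in frontier) {
      for (b in adj[[a]]) {
        if (!seen[b]) {
          seen[b] <- TRUE
          nxt <- c(nxt, b)
          out <- c(out, b)
        }
      }
    }
    frontier <- nxt
  }
  sort(out)
}
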