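# Shared fixtures, built in code. The small scheme/cohort are cached per
# test run since several files reuse them.

small_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_parcel_scheme(c(8, 8, 8), 8L, seed = 1)
    cache
  }
})

default_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_parcel_scheme(c(16, 16, 16), 64L, seed = 1)
    cache
  }
})

# a deterministic layered graph with arbitrary weights, for SBM tests
random_graph <- function(N, p = 0.5, seed = 1, n_patients = 20L) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  e <- pairs[keep, , drop = FALSE]
  structure(list(
    nodes = as.character(seq_len(N)),
    edges = data.frame(
      from = as.character(e[, 1]), to = as.character(e[, 2]),
      w_les = stats::runif(nrow(e)), w_def = stats::rnorm(nrow(e)),
      support = sample(2:9, nrow(e), replace = TRUE),
      stringsAsFactors = FALSE),
    n_patients = n_patients), class = "layered_graph")
}

# graph from an explicit edge list matrix: rows (from, to, w_les, w_def, sup)
edge_graph <- function(nodes, edges, n_patients = 10L) {
  structure(list(
    nodes = as.character(nodes),
    edges = data.frame(
      from = as.character(edges[, 1]), to = as.character(edges[, 2]),
      w_les = as.numeric(edges[, 3]), w_def = as.numeric(edges[, 4]),
      support = as.integer(edges[, 5]), stringsAsFactors = FALSE),
    n_patients = n_patients), class = "layered_graph")
}

# longhand description-length oracle: direct nested-loop evaluation of the
# objective, independent of the package's vectorized implementation
dl_longhand <- function(graph, partition, n_bins = 8) {
  b <- as.integer(partition)
  N <- length(graph$nodes)
  E <- nrow(graph$edges)
  B <- max(b)
  n_r <- sapply(seq_len(B), function(r) sum(b == r))
  ei <- match(graph$edges$from, graph$nodes)
  ej <- match(graph$edges$to, graph$nodes)
  qs <- seq(0, 1, length.out = n_bins + 1)
  bin_of <- function(w) {
    ub <- unique(quantile(w, qs, names = FALSE))
    if (length(ub) < 2) return(list(v = rep(1, length(w)), K = 1))
    list(v = findInterval(w, ub, all.inside = TRUE), K = length(ub) - 1)
  }
  bins <- list(bin_of(graph$edges$w_les), bin_of(graph$edges$w_def))
  # m_rs as a symmetric matrix, diagonal counted twice
  m <- matrix(0, B, B)
  for (k in seq_along(ei)) {
    r <- b[ei[k]]; s <- b[ej[k]]
    m[r, s] <- m[r, s] + 1
    m[s, r] <- m[s, r] + 1
  }
  s_adj <- lchoose(B * (B + 1) / 2 + E - 1, E)
  for (r in seq_len(B)) for (s in seq_len(B)) {
    if (m[r, s] > 0)
      s_adj <- s_adj - 0.5 * m[r, s] * log(m[r, s] / (n_r[r] * n_r[s]))
  }
  s_w <- c(0, 0)
  for (ch in 1:2) {
    v <- bins[[ch]]$v
    K <- bins[[ch]]$K
    if (K < 2) next
    for (r in seq_len(B)) for (s in seq(r, B)) {
      sel <- (b[ei] == r & b[ej] == s) | (b[ei] == s & b[ej] == r)
      mrs <- sum(sel)
      if (mrs == 0) next
      cnt <- table(v[sel])
      arrange <- lfactorial(mrs) - sum(lfactorial(cnt))
      s_w[ch] <- s_w[ch] + arrange + lchoose(mrs + K - 1, K - 1)
    }
  }
  s_adj + sum(s_w) + N * log(B)
}

# brute-force least-squares oracle for the age-adjusted group F test:
# residual sums of squares of full vs reduced model via normal equations
ancova_oracle_f <- function(scores, group, age) {
  g <- factor(group)
  Xr <- cbind(1, age)
  Xf <- cbind(Xr, stats::model.matrix(~ g)[, -1, drop = FALSE])
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% scores)
    sum((scores - X %*% beta)^2)
  }
  rss_r <- rss(Xr); rss_f <- rss(Xf)
  df1 <- ncol(Xf) - ncol(Xr)
  df2 <- length(scores) - ncol(Xf)
  ((rss_r - rss_f) / df1) / (rss_f / df2)
}

sim_age_groups <- function(n_per, k, effect = 0, seed) {
  set.seed(seed)
  g <- rep(letters[1:k], each = n_per)
  age <- runif(n_per * k, 20, 75)
  y <- 70 + effect * (as.integer(factor(g)) - 1) - 0.15 * age +
    rnorm(n_per * k, 0, 6)
  list(y = y, g = g, age = age)
}
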