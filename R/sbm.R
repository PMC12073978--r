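#' Quantile bin edges for the graph's weight channels
#'
#' Global quantile bin edges for the lesion and deficit weight channels.
#' Each graph is binned by its own quantiles: quantile binning makes the
#' marginal bin distribution (near-)uniform for the graph it is computed
#' on, so a test graph and its behaviour-permuted null pay the same
#' marginal encoding cost and differ only through block-conditional
#' structure. (Reusing one graph's bin edges on another systematically
#' favours whichever graph the edges came from.)
#'
#' @param graph a \code{layered_graph}.
#' @param n_bins number of bins per channel (>= 2).
#' @return list with numeric break vectors \code{w_les} and \code{w_def}.
#' @export
sbm_bins <- function(graph, n_bins = 8L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  qs <- seq(0, 1, length.out = n_bins + 1L)
  list(w_les = stats::quantile(graph$edges$w_les, qs, names = FALSE),
       w_def = stats::quantile(graph$edges$w_def, qs, names = FALSE))
}

# internal: edge arrays + per-edge weight bins for fast DL evaluation.
# Duplicate quantile break points (ties in the weights) are collapsed, so
# each channel carries its effective alphabet size K (occupied bins); a
# constant channel has K = 1 and costs nothing.
.sbm_prep <- function(graph, n_bins = 8L, bin_breaks = NULL) {
  if (is.null(bin_breaks)) bin_breaks <- sbm_bins(graph, n_bins)
  e <- graph$edges
  bin_of <- function(w, breaks) {
    ub <- unique(breaks)
    if (length(ub) < 2L) return(list(v = rep(1L, length(w)), K = 1L))
    list(v = findInterval(w, ub, all.inside = TRUE),
         K = length(ub) - 1L)
  }
  bl <- bin_of(e$w_les, bin_breaks$w_les)
  bd <- bin_of(e$w_def, bin_breaks$w_def)
  list(N = length(graph$nodes), E = nrow(e),
       ei = match(e$from, graph$nodes), ej = match(e$to, graph$nodes),
       bl = bl$v, Kl = bl$K, bd = bd$v, Kd = bd$K,
       n_bins = as.integer(n_bins), breaks = bin_breaks)
}

# internal: description length of partition b (integers 1..B, none empty)
# components: adjacency, lesion-weight, deficit-weight, partition prior
.dl_eval <- function(prep, b, B) {
  n_r <- tabulate(b, B)
  r <- b[prep$ei]; s <- b[prep$ej]
  lo <- pmin(r, s); hi <- pmax(r, s)
  tri <- lo + (hi * (hi - 1L)) %/% 2L      # triangular pair index, lo <= hi
  ntri <- (B * (B + 1L)) %/% 2L
  m <- tabulate(tri, ntri)
  pos <- which(m > 0L)
  mp <- m[pos]
  hi_p <- ceiling((sqrt(8 * pos + 1) - 1) / 2)
  lo_p <- pos - (hi_p * (hi_p - 1L)) %/% 2L
  msym <- mp * (1L + (lo_p == hi_p))       # symmetric-count diagonal doubling
  s_adj <- -sum(mp * log(msym / (n_r[lo_p] * n_r[hi_p]))) +
    lchoose(ntri + prep$E - 1, prep$E)     # cost of the edge-count matrix
  w_channel <- function(v, K) {
    if (K < 2L) return(0)
    cc <- tabulate((tri - 1L) * K + v, ntri * K)
    cc <- cc[cc > 0L]
    (sum(lfactorial(mp)) - sum(lfactorial(cc))) +   # exact multinomial count
      sum(lchoose(mp + K - 1, K - 1))               # composition prior
  }
  s_les <- w_channel(prep$bl, prep$Kl)
  s_def <- w_channel(prep$bd, prep$Kd)
  s_part <- prep$N * log(B)
  list(total = s_adj + s_les + s_def + s_part,
       adjacency = s_adj, weights_lesion = s_les,
       weights_deficit = s_def, partition_prior = s_part)
}

.block_state <- function(prep, b, B, graph = NULL, extra = list()) {
  comp <- .dl_eval(prep, b, B)
  structure(c(list(partition = b, B = B, dl_total = comp$total,
                   dl_components = c(adjacency = comp$adjacency,
                                     weights_lesion = comp$weights_lesion,
                                     weights_deficit = comp$weights_deficit,
                                     partition_prior = comp$partition_prior),
                   nodes = if (!is.null(graph)) graph$nodes else NULL),
              extra),
            class = "block_state")
}

#' Description length of a graph partition, in nats
#'
#' Evaluates the minimum-description-length objective of the layered
#' stochastic block model for a fixed partition. The adjacency channel
#' costs
#' \deqn{S_{adj} = -\tfrac12 \sum_{r,s} m_{rs} \ln\frac{m_{rs}}{n_r n_s}
#'   + \ln\binom{B(B+1)/2 + E - 1}{E}}
#' (with \eqn{m_{rs}} counted twice on the diagonal of the symmetric sum,
#' \eqn{0 \ln 0 = 0}, and the second term the cost of transmitting the
#' block-pair edge-count matrix itself — without it a partition into
#' singletons encodes any graph for free and noise graphs shatter into
#' spurious blocks). For each weight channel, edge weights are discretized
#' into \code{n_bins} global quantile bins (duplicate break points from
#' tied weights are collapsed, giving an effective alphabet of K occupied
#' bins) and each block pair pays the exact multinomial arrangement count
#' \eqn{\ln(m_{rs}!/\prod_q c_q!)} plus the composition cost
#' \eqn{\ln\binom{m_{rs}+K-1}{K-1}}; the exact count, rather than its
#' entropy approximation \eqn{m H}, keeps large blocks from being
#' over-charged for their weight heterogeneity. A uniform partition prior
#' adds \eqn{N \ln B}. Lower is better; differences between models act as
#' log posterior odds.
#'
#' @param graph a \code{layered_graph}.
#' @param partition block id per node, integers with every block 1..B
#'   non-empty.
#' @param n_bins quantile bins per weight channel.
#' @param bin_breaks optional precomputed \code{\link{sbm_bins}} (used to
#'   score a null graph with the test graph's bins).
#' @return object of class \code{block_state}: \code{partition}, \code{B},
#'   \code{dl_total} and the four \code{dl_components}, all in nats.
#' @export
description_length <- function(graph, partition, n_bins = 8L,
                               bin_breaks = NULL) {
  b <- as.integer(partition)
  if (length(b) != length(graph$nodes))
    stop("partition must cover all ", length(graph$nodes), " nodes")
  B <- max(b)
  if (min(b) < 1L || any(tabulate(b, B) == 0L))
    stop("partition error: empty block (labels must be 1..B, all present)")
  prep <- .sbm_prep(graph, n_bins, bin_breaks)
  .block_state(prep, b, B, graph)
}

#' @export
print.block_state <- function(x, ...) {
  cat("SBM block state: B =", x$B, "blocks,",
      "description length", format(round(x$dl_total, 2)), "nats\n")
  comp <- round(x$dl_components, 2)
  cat("  components:", paste(names(comp), comp, sep = " = ",
                             collapse = ", "), "\n")
  invisible(x)
}

# single-node reassignment sweeps; accepts only strictly DL-decreasing moves
.sweep_nodes <- function(prep, b, B, cur_dl, n_sweeps) {
  trace <- numeric(0)
  if (B > 1L) for (sw in seq_len(n_sweeps)) {
    improved <- FALSE
    for (i in sample.int(prep$N)) {
      r <- b[i]
      if (sum(b == r) == 1L) next          # a move would empty the block
      best_dl <- cur_dl; best_s <- r
      for (s in seq_len(B)) {
        if (s == r) next
        b[i] <- s
        d <- .dl_eval(prep, b, B)$total
        if (d < best_dl) { best_dl <- d; best_s <- s }
      }
      b[i] <- best_s
      if (best_s != r) {
        cur_dl <- best_dl
        trace <- c(trace, cur_dl)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(b = b, dl = cur_dl, trace = trace)
}

# greedy best merge of two blocks; ties broken by the smallest (r, s) pair
.best_merge <- function(prep, b, B) {
  best <- NULL
  for (r in seq_len(B - 1L)) for (s in seq(r + 1L, B)) {
    b2 <- b
    b2[b2 == s] <- r
    b2[b2 > s] <- b2[b2 > s] - 1L
    d <- .dl_eval(prep, b2, B - 1L)$total
    if (is.null(best) || d < best$dl)
      best <- list(b = b2, dl = d, pair = c(r, s))
  }
  best
}

#' Fit the stochastic block model by agglomerative MDL descent
#'
#' Starting from \code{B = min(b_max, N)} blocks (singletons when
#' \code{b_max >= N}, otherwise a seeded random balanced assignment), the
#' fitter alternates greedy best merges of block pairs with up to
#' \code{n_sweeps} sweeps of single-node reassignment, accepting only
#' strictly description-length-decreasing moves, down to B = 1. The visited
#' state of minimal description length is returned. Deterministic for a
#' fixed seed (the seed controls the initial assignment and sweep order;
#' merge ties break on the smallest block-id pair).
#'
#' @inheritParams description_length
#' @param b_max largest number of blocks considered.
#' @param n_sweeps reassignment sweeps per agglomeration level.
#' @param seed integer seed.
#' @return a \code{block_state} with additional fields \code{seed},
#'   \code{merges} (the agglomerative merge record) and \code{trace}
#'   (accepted-move DL trajectories per level, strictly decreasing within a
#'   level).
#' @export
fit_sbm <- function(graph, b_max = 16L, n_sweeps = 3L, seed = 1L,
                    n_bins = 8L, bin_breaks = NULL) {
  prep <- .sbm_prep(graph, n_bins, bin_breaks)
  N <- prep$N
  if (prep$E < 1L) stop("input error: graph has no edges")
  set.seed(seed)
  B <- min(as.integer(b_max), N)
  b <- if (B == N) seq_len(N) else rep_len(seq_len(B), N)[sample.int(N)]
  cur <- .dl_eval(prep, b, B)$total
  best <- list(b = b, B = B, dl = cur)
  trace <- list()
  merges <- NULL
  repeat {
    sw <- .sweep_nodes(prep, b, B, cur, n_sweeps)
    b <- sw$b; cur <- sw$dl
    trace[[length(trace) + 1L]] <- sw$trace
    if (cur < best$dl) best <- list(b = b, B = B, dl = cur)
    if (B == 1L) break
    mg <- .best_merge(prep, b, B)
    merges <- rbind(merges,
                    data.frame(B_before = B, block_a = mg$pair[1L],
                               block_b = mg$pair[2L], dl_after = mg$dl))
    b <- mg$b; B <- B - 1L; cur <- mg$dl
    if (cur < best$dl) best <- list(b = b, B = B, dl = cur)
  }
  names(trace) <- NULL
  st <- .block_state(prep, best$b, best$B, graph,
                     extra = list(seed = seed, merges = merges,
                                  trace = trace, n_bins = prep$n_bins,
                                  bin_breaks = prep$breaks))
  st
}

#' Exhaustive search over all partitions (test oracle)
#'
#' Evaluates \code{\link{description_length}} on every set partition of the
#' nodes (Bell-number enumeration via restricted growth strings) and returns
#' the global minimum. Intended as an independent oracle for small graphs.
#'
#' @inheritParams description_length
#' @param n_max guard: refuse graphs with more than this many nodes
#'   (Bell(8) = 4140 partitions).
#' @return the globally optimal \code{block_state}.
#' @export
exhaustive_oracle <- function(graph, n_max = 8L, n_bins = 8L,
                              bin_breaks = NULL) {
  N <- length(graph$nodes)
  if (N > n_max)
    stop("size guard: exhaustive enumeration limited to ", n_max, " nodes")
  prep <- .sbm_prep(graph, n_bins, bin_breaks)
  best <- NULL
  for (b in all_set_partitions(N)) {
    B <- max(b)
    d <- .dl_eval(prep, b, B)$total
    if (is.null(best) || d < best$dl) best <- list(b = b, B = B, dl = d)
  }
  .block_state(prep, best$b, best$B, graph)
}

#' All set partitions of n elements as restricted growth strings
#'
#' @param n number of elements.
#' @return list of integer vectors; element i holds the block label of item
#'   i, labels in canonical first-appearance order.
#' @export
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(b, mx) {
    i <- length(b) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- b; return(invisible()) }
    for (v in seq_len(mx + 1L)) rec(c(b, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

#' Compare test and null block models
#'
#' The description-length difference \code{delta = s_null - s_test} (nats)
#' acts as the log posterior odds in favour of the test model; the odds are
#' reported as \code{e} raised to the rounded delta (e.g. a test model at
#' 476362 nats against a null at 725748 nats gives delta 249386 and odds
#' label "e249386").
#'
#' @param s_test,s_null description lengths in nats, as bare numbers or
#'   \code{block_state} objects (their \code{dl_total} is used). Fitted
#'   states being compared must come from graphs sharing one edge set.
#' @return object of class \code{model_comparison}: \code{s_test},
#'   \code{s_null}, \code{delta}, \code{log_odds} (= delta) and
#'   \code{odds_label}.
#' @export
compare_models <- function(s_test, s_null) {
  take <- function(x, which) {
    if (inherits(x, "block_state")) x$dl_total
    else if (is.numeric(x) && length(x) == 1L) as.numeric(x)
    else stop(which, " must be a number or a block_state")
  }
  if (inherits(s_test, "block_state") && inherits(s_null, "block_state") &&
      !is.null(s_test$nodes) && !is.null(s_null$nodes) &&
      !identical(s_test$nodes, s_null$nodes))
    stop("comparability error: states were fitted on different node sets")
  st <- take(s_test, "s_test"); sn <- take(s_null, "s_null")
  delta <- sn - st
  structure(list(s_test = st, s_null = sn, delta = delta, log_odds = delta,
                 odds_label = paste0("e", format(round(delta),
                                                 scientific = FALSE,
                                                 trim = TRUE))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(paste0("Model comparison: test %s vs null %s nats\n",
                     "  delta = %s nats; posterior odds %s in favour of test\n"),
              format(round(x$s_test), scientific = FALSE),
              format(round(x$s_null), scientific = FALSE),
              format(round(x$delta), scientific = FALSE), x$odds_label))
  invisible(x)
}

#' Newick string of the agglomerative merge tree
#'
#' Renders the merge record of \code{\link{fit_sbm}} as a Newick tree whose
#' leaves are the blocks at the start of the agglomeration; one level of
#' this tree corresponds to the first agglomerative grouping of
#' communities.
#'
#' @param fit a \code{block_state} returned by \code{\link{fit_sbm}}.
#' @return a Newick format string.
#' @export
merge_newick <- function(fit) {
  if (is.null(fit$merges) || nrow(fit$merges) == 0L) return("(B1);")
  B0 <- fit$merges$B_before[1L]
  lab <- paste0("B", seq_len(B0))
  for (k in seq_len(nrow(fit$merges))) {
    a <- fit$merges$block_a[k]; bb <- fit$merges$block_b[k]
    lab[a] <- paste0("(", lab[a], ",", lab[bb], ")")
    lab <- lab[-bb]
  }
  paste0(lab[1L], ";")
}
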