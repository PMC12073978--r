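#' Graph lesion-deficit mapping
#'
#' The package's central fitting function: from a patients x parcels damage
#' matrix and a cohort table it (i) anchors patient deficit z-scores to the
#' healthy controls and regresses out age, (ii) builds the layered
#' lesion/deficit graph and its behaviour-permuted null, (iii) infers block
#' structure in both by minimum-description-length stochastic block
#' modelling and compares them in nats, and (iv) backprojects edge weights
#' to parcel strengths with bootstrap confidence intervals and applies the
#' CI-disjointness retention rule.
#'
#' @param damage patients x parcels damage-fraction matrix (rows aligned
#'   with the cohort's patients, in order).
#' @param cohort cohort data frame (see \code{\link{simulate_cohort}} for
#'   the layout); controls provide the z-score reference.
#' @param score_column score column used as the behavioural variable.
#' @param tau damage binarization threshold.
#' @param m_min minimum co-damage support for an edge.
#' @param n_bins quantile bins per SBM weight channel.
#' @param b_max,n_sweeps SBM fitter controls (see \code{\link{fit_sbm}}).
#' @param n_boot,alpha bootstrap controls (see \code{\link{bootstrap_cis}}).
#' @param seed master seed; stage seeds (fit, permutation, bootstrap) are
#'   derived from it deterministically.
#' @param fit_blocks set FALSE to skip the SBM stage (graph + map only).
#' @return object of class \code{gldm} with components \code{graph},
#'   \code{null_graph}, \code{fit}, \code{null_fit}, \code{comparison},
#'   \code{map}, \code{z}, plus the call and configuration.
#' @examples
#' \donttest{
#' sch <- make_parcel_scheme(c(8, 8, 8), n_parcels = 16, seed = 1)
#' tr <- ground_truth(sch, effect_beta = 30, noise_sd = 5)
#' sim <- simulate_cohort(sch, tr, n_patients = 80, n_controls = 30, seed = 1)
#' dm <- damage_matrix(sim$masks, sch)
#' fit <- gldm(dm, sim$cohort, n_boot = 200, b_max = 8, seed = 1)
#' print(fit)
#' }
#' @export
gldm <- function(damage, cohort, score_column = "score", tau = 0.1,
                 m_min = 2L, n_bins = 8L, b_max = 16L, n_sweeps = 3L,
                 n_boot = 1000L, alpha = 0.05, seed = 1L,
                 fit_blocks = TRUE) {
  pat <- cohort$role == "patient"
  if (nrow(damage) != sum(pat))
    stop("damage matrix rows must match the cohort's patients")
  z <- deficit_scores(cohort, score_column)
  dbin <- binarize_damage(damage, tau)
  seeds <- derive_seeds(seed, c("fit", "permutation", "bootstrap"))
  graph <- build_graph(dbin, z, m_min = m_min)
  null_graph <- permute_null(dbin, z, seed = seeds["permutation"],
                             m_min = m_min)
  fit <- null_fit <- comparison <- NULL
  community <- NULL
  if (fit_blocks) {
    fit <- fit_sbm(graph, b_max = b_max, n_sweeps = n_sweeps,
                   seed = seeds["fit"], n_bins = n_bins)
    null_fit <- fit_sbm(null_graph, b_max = b_max, n_sweeps = n_sweeps,
                        seed = seeds["fit"], n_bins = n_bins)
    comparison <- compare_models(fit, null_fit)
    community <- fit$partition
  }
  strengths <- node_strengths(graph)
  cis <- bootstrap_cis(dbin, z, n_boot = n_boot, alpha = alpha,
                       seed = seeds["bootstrap"], m_min = m_min,
                       cohort = cohort, score_column = score_column)
  map <- retention_rule(strengths, cis, community = community)
  structure(list(graph = graph, null_graph = null_graph, fit = fit,
                 null_fit = null_fit, comparison = comparison, map = map,
                 z = z,
                 config = list(score_column = score_column, tau = tau,
                               m_min = m_min, n_bins = n_bins,
                               b_max = b_max, n_sweeps = n_sweeps,
                               n_boot = n_boot, alpha = alpha, seed = seed),
                 call = match.call()),
            class = "gldm")
}

#' Derive named stage seeds from a master seed
#'
#' Deterministic, collision-avoiding seeds for each random stage, so
#' reordering or skipping stages cannot silently change another stage's
#' stream.
#'
#' @param seed master integer seed.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds, each below 2^31.
#' @export
derive_seeds <- function(seed, stages) {
  out <- vapply(seq_along(stages), function(k)
    as.integer((as.double(seed) * 48271 + k * 100003) %% 2147483629), 1L)
  names(out) <- stages
  out
}

#' @export
print.gldm <- function(x, ...) {
  cat("Graph lesion-deficit map\n")
  print(x$graph)
  if (!is.null(x$comparison)) {
    cat(sprintf("  blocks: B = %d (test), B = %d (null)\n",
                x$fit$B, x$null_fit$B))
    print(x$comparison)
  }
  cat("  retained parcels:", sum(x$map$retained), "of", nrow(x$map), "\n")
  invisible(x)
}

#' @export
summary.gldm <- function(object, ...) {
  out <- list(
    n_nodes = length(object$graph$nodes),
    n_edges = nrow(object$graph$edges),
    n_patients = object$graph$n_patients,
    delta = if (!is.null(object$comparison)) object$comparison$delta else NA,
    odds_label = if (!is.null(object$comparison))
      object$comparison$odds_label else NA,
    retained = object$map$node[object$map$retained],
    map = object$map
  )
  class(out) <- "summary.gldm"
  out
}

#' @export
print.summary.gldm <- function(x, ...) {
  cat("Graph lesion-deficit mapping summary\n")
  cat(sprintf("  graph: %d nodes, %d edges over %d patients\n",
              x$n_nodes, x$n_edges, x$n_patients))
  if (!is.na(x$delta))
    cat(sprintf("  model comparison: delta = %s nats (odds %s)\n",
                format(round(x$delta)), x$odds_label))
  cat("  retained parcels:", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' @export
coef.gldm <- function(object, ...) {
  m <- object$map
  stats::setNames(m$deficit_strength, m$node)
}

#' Plot method: deficit versus lesion strength with intervals
#'
#' Scatter of per-parcel deficit strength against lesion strength with the
#' bootstrap intervals drawn as segments; retained parcels are filled.
#'
#' @param x a \code{gldm} object.
#' @param ... passed to \code{plot}.
#' @export
plot.gldm <- function(x, ...) {
  m <- x$map
  ok <- stats::complete.cases(m[, c("deficit_strength", "lesion_strength")])
  m <- m[ok, ]
  plot(m$lesion_strength, m$deficit_strength,
       xlab = "lesion strength (co-occurrence)",
       ylab = "deficit strength (z units)",
       pch = ifelse(m$retained, 19, 1),
       col = ifelse(m$retained, "firebrick", "grey40"), ...)
  graphics::segments(m$lesion_strength, m$def_ci_low,
                     m$lesion_strength, m$def_ci_high,
                     col = "grey70")
  graphics::legend("topleft", pch = c(19, 1),
                   col = c("firebrick", "grey40"),
                   legend = c("retained", "not retained"), bty = "n")
  invisible(x)
}
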