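# node strengths straight from the damage matrix and z, bypassing the edge
# data frame; used by the bootstrap where thousands of rebuilds are needed
.node_strengths_mat <- function(damage_bin, z, m_min = 2L) {
  D <- damage_bin
  storage.mode(D) <- "double"
  S <- crossprod(D)
  Zs <- crossprod(D * as.numeric(z), D)
  keep <- S >= m_min
  diag(keep) <- FALSE
  sup_tot <- rowSums(S * keep)
  deficit <- ifelse(sup_tot > 0, rowSums(Zs * keep) / sup_tot, NA_real_)
  deg <- rowSums(keep)
  lesion <- ifelse(deg > 0, rowSums((S / nrow(D)) * keep) / deg, NA_real_)
  cbind(deficit_strength = deficit, lesion_strength = lesion, degree = deg)
}

#' Backproject edge weights onto nodes
#'
#' For each parcel, the deficit strength is the support-weighted mean of the
#' deficit weights of its incident edges, and the lesion strength is the
#' plain mean of their lesion co-occurrence weights. Isolated nodes (no
#' retained edge) get undefined strengths and are flagged.
#'
#' @param graph a \code{layered_graph}.
#' @return data frame with \code{node}, \code{deficit_strength},
#'   \code{lesion_strength}, \code{degree}, \code{isolated}.
#' @export
node_strengths <- function(graph) {
  e <- graph$edges
  nodes <- graph$nodes
  idx_f <- match(e$from, nodes)
  idx_t <- match(e$to, nodes)
  i <- c(idx_f, idx_t)
  sup <- rep(e$support, 2L)
  wd <- rep(e$w_def, 2L)
  wl <- rep(e$w_les, 2L)
  sup_tot <- as.numeric(tapply_fill(sup, i, length(nodes), sum))
  def_num <- as.numeric(tapply_fill(sup * wd, i, length(nodes), sum))
  deg <- as.numeric(tapply_fill(rep(1, length(i)), i, length(nodes), sum))
  les_sum <- as.numeric(tapply_fill(wl, i, length(nodes), sum))
  data.frame(
    node = nodes,
    deficit_strength = ifelse(sup_tot > 0, def_num / sup_tot, NA_real_),
    lesion_strength = ifelse(deg > 0, les_sum / deg, NA_real_),
    degree = as.integer(deg),
    isolated = deg == 0,
    stringsAsFactors = FALSE
  )
}

# sum `x` into `n` groups given by integer index `i` (dense, zero-filled)
tapply_fill <- function(x, i, n, fun) {
  out <- numeric(n)
  agg <- rowsum(x, i)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Bootstrap confidence intervals for node strengths
#'
#' Resamples patients with replacement, rebuilds the graph and recomputes
#' both node strengths per replicate, and returns percentile intervals at
#' levels alpha/2 and 1 - alpha/2. A parcel that is never co-damaged in a
#' replicate contributes no value to that replicate; its interval is formed
#' from the available replicates and the count is reported.
#'
#' When a \code{cohort} is supplied, each replicate also resamples the
#' healthy controls and recomputes the deficit z-scores against the
#' resampled reference, so the intervals propagate the sampling
#' uncertainty of the control anchoring (a shared shift of all z that
#' patient-only resampling cannot see) as well as of the patients.
#'
#' @param damage_bin 0/1 patients x parcels matrix.
#' @param z per-patient deficit scores.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param alpha 1 - confidence level.
#' @param seed integer seed.
#' @param m_min minimum edge support, as in \code{\link{build_graph}}.
#' @param cohort optional cohort data frame; when present, controls are
#'   resampled per replicate and z is recomputed via
#'   \code{\link{deficit_scores}}.
#' @param score_column score column used when \code{cohort} is given.
#' @return data frame per parcel: \code{def_ci_low/high},
#'   \code{les_ci_low/high}, \code{n_replicates}.
#' @export
bootstrap_cis <- function(damage_bin, z, n_boot = 1000L, alpha = 0.05,
                          seed = 1L, m_min = 2L, cohort = NULL,
                          score_column = "score") {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  set.seed(seed)
  n <- nrow(damage_bin)
  P <- ncol(damage_bin)
  def <- matrix(NA_real_, n_boot, P)
  les <- matrix(NA_real_, n_boot, P)
  z <- as.numeric(z)
  if (!is.null(cohort)) {
    pat <- cohort[cohort$role == "patient", , drop = FALSE]
    ctl <- cohort[cohort$role == "control", , drop = FALSE]
    if (nrow(pat) != n) stop("cohort patients must match damage_bin rows")
  }
  for (bi in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (is.null(cohort)) {
      zb <- z[idx]
    } else {
      cidx <- sample.int(nrow(ctl), nrow(ctl), replace = TRUE)
      boot_cohort <- rbind(pat[idx, , drop = FALSE],
                           ctl[cidx, , drop = FALSE])
      zb <- deficit_scores(boot_cohort, score_column)
    }
    st <- .node_strengths_mat(damage_bin[idx, , drop = FALSE], zb, m_min)
    def[bi, ] <- st[, "deficit_strength"]
    les[bi, ] <- st[, "lesion_strength"]
  }
  qs <- c(alpha / 2, 1 - alpha / 2)
  qfun <- function(mat) t(apply(mat, 2L, stats::quantile, probs = qs,
                                na.rm = TRUE, names = FALSE))
  dq <- qfun(def); lq <- qfun(les)
  data.frame(
    node = if (!is.null(colnames(damage_bin))) colnames(damage_bin)
           else as.character(seq_len(P)),
    def_ci_low = dq[, 1L], def_ci_high = dq[, 2L],
    les_ci_low = lq[, 1L], les_ci_high = lq[, 2L],
    n_replicates = colSums(!is.na(def)),
    stringsAsFactors = FALSE
  )
}

#' Assemble a network map and apply the CI-disjointness retention rule
#'
#' A parcel is retained when its 95% (more generally 1 - alpha) deficit
#' strength interval does not cross the same parcel's lesion-weight
#' interval, and lies above it: \code{def_ci_low > les_ci_high}. The
#' directional rule reflects that deficit z is signed (higher = worse), so
#' only parcels whose deficit weight exceeds what lesion co-occurrence
#' alone would explain are kept.
#'
#' @param strengths output of \code{\link{node_strengths}}.
#' @param cis output of \code{\link{bootstrap_cis}} on matching parcels.
#' @param community optional per-parcel block id from a fitted
#'   \code{block_state}.
#' @return object of class \code{network_map}: data frame with strengths,
#'   intervals, \code{retained} and \code{retain_reason}.
#' @export
retention_rule <- function(strengths, cis, community = NULL) {
  stopifnot(identical(strengths$node, cis$node))
  m <- cbind(strengths, cis[, setdiff(names(cis), "node")])
  has_ci <- stats::complete.cases(m[, c("def_ci_low", "def_ci_high",
                                        "les_ci_low", "les_ci_high")])
  m$retained <- has_ci & m$def_ci_low > m$les_ci_high
  m$retain_reason <- ifelse(!has_ci, "missing CI",
                       ifelse(m$retained, "deficit CI above lesion CI",
                              "CIs overlap or deficit below lesion"))
  if (!is.null(community)) m$community <- community
  class(m) <- c("network_map", "data.frame")
  m
}

#' @export
print.network_map <- function(x, ...) {
  cat("Network map:", nrow(x), "parcels,", sum(x$retained), "retained\n")
  if (any(x$retained)) {
    kept <- x[x$retained, c("node", "deficit_strength", "lesion_strength",
                            "def_ci_low", "def_ci_high")]
    print(format(kept, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Overlap between retained parcels and a known substrate
#'
#' @param map a \code{network_map}.
#' @param truth a \code{ground_truth} on the same parcel scheme.
#' @return list with \code{jaccard}, \code{sensitivity},
#'   \code{specificity}.
#' @export
substrate_recovery <- function(map, truth) {
  retained <- map$node[map$retained]
  substrate <- as.character(truth$substrate_parcels)
  all_p <- map$node
  tp <- length(intersect(retained, substrate))
  un <- length(union(retained, substrate))
  neg <- setdiff(all_p, substrate)
  tn <- length(setdiff(neg, retained))
  list(jaccard = if (un == 0) 1 else tp / un,
       sensitivity = if (length(substrate)) tp / length(substrate) else NA_real_,
       specificity = if (length(neg)) tn / length(neg) else NA_real_)
}

#' Export a network map as a parcel-constant volume
#'
#' Writes a volumetric NIfTI image in which every voxel of a retained
#' parcel holds that parcel's deficit strength (zero elsewhere), plus a
#' side-car TSV with all per-parcel fields.
#'
#' @param map a \code{network_map}.
#' @param scheme the \code{parcel_scheme} the map was computed on.
#' @param path output NIfTI path; the table goes next to it as \code{.tsv}.
#' @export
export_parcel_map <- function(map, scheme, path) {
  vol <- array(0, dim = dim(scheme$labels))
  pid <- as.character(scheme$parcels$parcel_id)
  for (k in which(map$retained)) {
    p <- match(map$node[k], pid)
    if (is.na(p)) stop("map node ", map$node[k], " not in scheme")
    vol[scheme$labels == scheme$parcels$parcel_id[p]] <-
      map$deficit_strength[k]
  }
  ok <- try(write_map(vol, path, scheme$voxel_size_mm), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed writing parcel map to ", path, ": ",
         attr(ok, "condition")$message)
  utils::write.table(as.data.frame(map), .sidecar_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
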