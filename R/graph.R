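#' Healthy-control-anchored deficit scores
#'
#' Expresses each patient's score in control units: \code{z = (hc_mean -
#' score) / hc_sd}, so positive z means impairment and a score one control
#' standard deviation below the control mean gives z = 1. The reference
#' moments come from the cohort's controls unless supplied. Age, a nuisance
#' factor, is by default regressed out of z across patients (the age slope
#' is removed while the control-anchored level is kept).
#'
#' @param cohort cohort data frame with \code{role} and the score column;
#'   patients are rows with \code{role == "patient"}.
#' @param score_column name of the score column.
#' @param hc_mean,hc_sd optional reference moments; defaults are the mean
#'   and SD of the controls' scores. \code{hc_sd} must be positive.
#' @param adjust_age if TRUE and the cohort has an \code{age} column, the
#'   age slope is removed from the patients' z.
#' @return numeric vector of z scores over patients (named by participant
#'   id), attribute \code{direction = "higher = worse"}.
#' @export
deficit_scores <- function(cohort, score_column = "score", hc_mean = NULL,
                           hc_sd = NULL, adjust_age = TRUE) {
  if (is.null(hc_mean) || is.null(hc_sd)) {
    hc <- cohort[[score_column]][cohort$role == "control"]
    if (length(hc) < 2L)
      stop("reference error: need controls or explicit reference moments")
    if (is.null(hc_mean)) hc_mean <- mean(hc)
    if (is.null(hc_sd)) hc_sd <- stats::sd(hc)
  }
  if (!is.finite(hc_sd) || hc_sd <= 0)
    stop("reference error: hc_sd must be positive")
  pat <- cohort[cohort$role == "patient", , drop = FALSE]
  z <- (hc_mean - pat[[score_column]]) / hc_sd
  if (adjust_age && !is.null(pat$age)) {
    b <- stats::cov(z, pat$age) / stats::var(pat$age)
    z <- z - b * (pat$age - mean(pat$age))
  }
  names(z) <- pat$participant_id
  attr(z, "direction") <- "higher = worse"
  z
}

#' Build the layered lesion-deficit graph
#'
#' Nodes are parcels. For every parcel pair (j, k), \code{support} is the
#' number of patients in whom both parcels are damaged; an edge is kept when
#' \code{support >= m_min}. Each retained edge carries two weight channels:
#' the lesion co-occurrence weight \code{w_les = support / n_patients} and
#' the deficit weight \code{w_def}, the mean deficit z over the co-damaged
#' patients. The mean (rather than sum) decouples the deficit channel from
#' lesion frequency, which the lesion channel already encodes.
#'
#' @param damage_bin 0/1 patients x parcels matrix (see
#'   \code{\link{binarize_damage}}).
#' @param z per-patient deficit scores aligned with the rows of
#'   \code{damage_bin}.
#' @param m_min minimum co-damage support for an edge (default 2;
#'   single-patient edges carry no co-occurrence information).
#' @return object of class \code{layered_graph}: list with \code{nodes}
#'   (parcel ids), \code{edges} (data frame \code{from}, \code{to},
#'   \code{w_les}, \code{w_def}, \code{support}; \code{from < to}) and
#'   \code{n_patients}.
#' @export
build_graph <- function(damage_bin, z, m_min = 2L) {
  if (nrow(damage_bin) != length(z))
    stop("rows of damage_bin must align with z")
  n <- nrow(damage_bin)
  P <- ncol(damage_bin)
  D <- damage_bin
  storage.mode(D) <- "double"
  S <- crossprod(D)                      # co-damage counts
  Zs <- crossprod(D * as.numeric(z), D)  # summed z over co-damaged
  keep <- upper.tri(S) & S >= m_min
  if (!any(keep)) {
    stop("coverage error: no parcel pair reaches support >= ", m_min,
         " (damaged parcels per patient: median ",
         stats::median(rowSums(damage_bin)), ")")
  }
  idx <- which(keep, arr.ind = TRUE)
  nodes <- if (!is.null(colnames(damage_bin))) colnames(damage_bin)
           else as.character(seq_len(P))
  edges <- data.frame(
    from = nodes[idx[, 1L]],
    to = nodes[idx[, 2L]],
    w_les = S[keep] / n,
    w_def = Zs[keep] / S[keep],
    support = as.integer(S[keep]),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges, n_patients = n),
            class = "layered_graph")
}

#' @export
print.layered_graph <- function(x, ...) {
  cat("Layered lesion-deficit graph: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", x$n_patients, " patients)\n", sep = "")
  cat(sprintf("  w_les in [%.3f, %.3f]; w_def in [%.3f, %.3f]\n",
              min(x$edges$w_les), max(x$edges$w_les),
              min(x$edges$w_def), max(x$edges$w_def)))
  invisible(x)
}

#' Behaviour-permuted null graph
#'
#' Rebuilds the layered graph after permuting the deficit scores across
#' patients: lesion anatomy (edge set, support, \code{w_les}) is preserved
#' exactly, while any lesion-behaviour coupling in \code{w_def} is
#' destroyed. This is the null model against which the test model's
#' description length is compared.
#'
#' @inheritParams build_graph
#' @param seed integer seed for the permutation; \code{NULL} applies the
#'   identity permutation.
#' @return a \code{layered_graph}.
#' @export
permute_null <- function(damage_bin, z, seed = 1L, m_min = 2L) {
  perm <- if (is.null(seed)) seq_along(z)
          else { set.seed(seed); sample.int(length(z)) }
  build_graph(damage_bin, as.numeric(z)[perm], m_min = m_min)
}

#' Serialize / read a layered graph as delimited text
#'
#' Writes the edge list (from, to, w_les, w_def, support) and the node
#' table; \code{read_graph} round-trips the object.
#'
#' @param graph a \code{layered_graph}.
#' @param path path of the edge-list TSV; the node table goes to the same
#'   path with suffix \code{_nodes.tsv}.
#' @export
write_graph <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  nodes <- data.frame(node = graph$nodes,
                      n_patients = graph$n_patients,
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, .nodes_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(from = "character",
                                            to = "character"))
  nodes <- utils::read.delim(.nodes_path(path), stringsAsFactors = FALSE,
                             colClasses = c(node = "character"))
  structure(list(nodes = nodes$node, edges = edges,
                 n_patients = nodes$n_patients[1L]),
            class = "layered_graph")
}

.nodes_path <- function(path) sub("(\\.[^.]+)?$", "_nodes.tsv",
                                  sub("\\.tsv$", "", path))
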