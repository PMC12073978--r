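#' Ground-truth deficit substrate
#'
#' Defines the hidden substrate used by the cohort simulator: the set of
#' parcels whose damage depresses the behavioural score. The default
#' substrate is the full set of right frontal parcels, emulating a cohort in
#' which a right frontal network is critical for the task. The deficit acts
#' through the mean damage fraction over the substrate (a smooth
#' dose-response), not through a binary hit.
#'
#' @param scheme a \code{parcel_scheme}.
#' @param substrate_parcels parcel ids forming the substrate; defaults to all
#'   right frontal parcels of the scheme.
#' @param effect_beta score points lost at full substrate damage (load 1).
#' @param age_gamma score points lost per year of age above the age-range
#'   midpoint.
#' @param noise_sd standard deviation of the additive score noise, >= 0.
#' @param seed integer recorded for provenance.
#' @return object of class \code{ground_truth}.
#' @export
ground_truth <- function(scheme, substrate_parcels = NULL, effect_beta = 30,
                         age_gamma = 0.2, noise_sd = 5, seed = NA_integer_) {
  if (is.null(substrate_parcels))
    substrate_parcels <- scheme$parcels$parcel_id[
      scheme$parcels$hemisphere == "right" & scheme$parcels$lobe == "frontal"]
  if (!all(substrate_parcels %in% scheme$parcels$parcel_id))
    stop("substrate_parcels must be parcel ids of the scheme")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(substrate_parcels = as.integer(substrate_parcels),
                 effect_beta = effect_beta, age_gamma = age_gamma,
                 noise_sd = noise_sd, seed = seed),
            class = "ground_truth")
}

#' Simulate a lesion cohort with a known deficit substrate
#'
#' Generates \code{n_patients} unilateral focal lesions (side Bernoulli(1/2);
#' volume log-uniform between the configured fractions of the hemisphere
#' voxel count) and \code{n_controls} lesion-free controls. Each
#' participant's score is
#' \deqn{s_i = clamp(\mu_0 - \beta \cdot load_i - \gamma (age_i - \bar a)
#'   + \epsilon_i,\ 0,\ ceiling)}
#' where \eqn{load_i} is the mean damage fraction over the substrate parcels
#' (0 for controls), \eqn{\bar a} is the midpoint of the age range, and
#' \eqn{\epsilon_i \sim N(0, noise\_sd)}. The noise draw \eqn{\epsilon_i} is
#' stored in the emitted table so the generator can be checked independently
#' against the noise-free formula. Ages are uniform on \code{age_range}.
#' All draws are governed by \code{seed}.
#'
#' @param scheme a \code{parcel_scheme}.
#' @param truth a \code{ground_truth} defined on the scheme.
#' @param n_patients,n_controls cohort sizes; the defaults mirror a cohort of
#'   247 patients with unilateral focal lesions and 81 healthy controls.
#' @param score_ceiling upper clamp of the (percentage-like) score.
#' @param mu0 control-level mean score at the age midpoint.
#' @param age_range uniform age range in years.
#' @param lesion_frac_range lesion volume bounds as fractions of the
#'   hemisphere voxel count (log-uniform draw).
#' @param seed integer seed for all draws.
#' @return list with \code{masks} (patients' \code{lesion_mask}s) and
#'   \code{cohort}, a data frame with columns \code{participant_id},
#'   \code{role}, \code{age}, \code{side}, \code{lesion_volume_vox},
#'   \code{substrate_load}, \code{epsilon} and \code{score}.
#' @export
simulate_cohort <- function(scheme, truth, n_patients = 247L,
                            n_controls = 81L, score_ceiling = 100,
                            mu0 = 80, age_range = c(20, 75),
                            lesion_frac_range = c(0.01, 0.15), seed = 1L) {
  stopifnot(inherits(scheme, "parcel_scheme"), inherits(truth, "ground_truth"))
  if (!all(truth$substrate_parcels %in% scheme$parcels$parcel_id))
    stop("ground truth is not defined on this scheme")
  set.seed(seed)
  n <- n_patients + n_controls
  hemi_vox <- sum(voxel_hemisphere(scheme) == "left")

  sides <- sample(c("left", "right"), n_patients, replace = TRUE)
  lo <- max(1, round(lesion_frac_range[1] * hemi_vox))
  hi <- max(lo, round(lesion_frac_range[2] * hemi_vox))
  sizes <- round(exp(stats::runif(n_patients, log(lo), log(hi))))
  sizes <- pmin(pmax(sizes, 1L), hemi_vox)
  ages <- stats::runif(n, age_range[1], age_range[2])
  eps <- stats::rnorm(n, 0, truth$noise_sd)
  mask_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)

  ids <- c(sprintf("P%03d", seq_len(n_patients)),
           sprintf("C%03d", seq_len(n_controls)))
  masks <- vector("list", n_patients)
  load <- numeric(n)
  vol <- integer(n)
  sub_idx <- match(truth$substrate_parcels, scheme$parcels$parcel_id)
  for (i in seq_len(n_patients)) {
    masks[[i]] <- sample_lesion(scheme, sides[i], sizes[i],
                                seed = mask_seeds[i], patient_id = ids[i])
    fr <- damage_fractions(masks[[i]], scheme)
    load[i] <- mean(fr[sub_idx])
    vol[i] <- sum(masks[[i]]$volume)
  }
  age_mid <- mean(age_range)
  score <- mu0 - truth$effect_beta * load -
    truth$age_gamma * (ages - age_mid) + eps
  score <- pmin(pmax(score, 0), score_ceiling)

  cohort <- data.frame(
    participant_id = ids,
    role = rep(c("patient", "control"), c(n_patients, n_controls)),
    age = ages,
    side = c(sides, rep(NA_character_, n_controls)),
    lesion_volume_vox = vol,
    substrate_load = load,
    epsilon = eps,
    score = score,
    stringsAsFactors = FALSE
  )
  list(masks = masks, cohort = cohort)
}

#' Simulate item-level responses from summary scores
#'
#' For participant i and item q the response is correct with probability
#' \code{plogis(ability_scale * (score_i/100 - difficulty_q))}: a logistic
#' item-response stand-in linking the 0-100 summary score to per-item
#' accuracy. The emitted log keeps the generating probability per row so the
#' mean percent-correct can be checked against its analytic expectation.
#'
#' @param cohort cohort data frame with \code{participant_id} and a score
#'   column in [0, 100].
#' @param item_bank an \code{\link{item_bank}}.
#' @param ability_scale slope of the logistic link (larger = more
#'   deterministic responding).
#' @param seed integer seed.
#' @param score_column name of the score column used as ability.
#' @return a response log: data frame with \code{participant_id},
#'   \code{item_id}, \code{correct} (0/1) and \code{prob} (the generating
#'   probability).
#' @export
simulate_responses <- function(cohort, item_bank, ability_scale = 6,
                               seed = 1L, score_column = "score") {
  if (nrow(item_bank) == 0L) stop("input error: empty item bank")
  sc <- cohort[[score_column]]
  if (any(sc < 0 | sc > 100)) stop("scores must lie in [0, 100]")
  set.seed(seed)
  grid <- expand.grid(i = seq_len(nrow(cohort)), q = seq_len(nrow(item_bank)))
  p <- stats::plogis(ability_scale *
                       (sc[grid$i] / 100 - item_bank$difficulty_q[grid$q]))
  data.frame(
    participant_id = cohort$participant_id[grid$i],
    item_id = item_bank$item_id[grid$q],
    correct = as.integer(stats::runif(nrow(grid)) < p),
    prob = p,
    stringsAsFactors = FALSE
  )
}
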