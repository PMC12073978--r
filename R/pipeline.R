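#' Default pipeline configuration
#'
#' A single nested list (YAML-serializable) holding every knob of the
#' analysis. The cohort defaults emulate the study conditions the package
#' targets: 247 patients with unilateral focal lesions and 81 healthy
#' controls on a 64-parcel scheme, a right frontal substrate costing 30
#' score points at full damage, additive noise of 5 points, ages uniform on
#' 20-75. Every random stage has an explicit seed derived from
#' \code{seeds$master}.
#'
#' @param output output directory for \code{\link{run_pipeline}}.
#' @param master_seed master integer seed.
#' @param ... named overrides applied on top of the defaults, e.g.
#'   \code{cohort = list(n_patients = 80)} (lists merge recursively).
#' @return object of class \code{gldmap_config}.
#' @export
default_config <- function(output = tempfile("gldmap_run_"),
                           master_seed = 1L, ...) {
  cfg <- list(
    paths = list(output = output),
    scheme = list(grid_shape = c(16L, 16L, 16L), n_parcels = 64L),
    cohort = list(n_patients = 247L, n_controls = 81L, effect_beta = 30,
                  age_gamma = 0.2, noise_sd = 5, mu0 = 80,
                  score_ceiling = 100, age_range = c(20, 75),
                  lesion_frac_range = c(0.01, 0.15)),
    tasks = list(ability_scale = 6),
    analysis = list(tau = 0.1, m_min = 2L, n_bins = 8L, b_max = 16L,
                    n_sweeps = 3L, n_boot = 1000L, alpha = 0.05,
                    lobe_threshold = 0.70),
    seeds = list(master = as.integer(master_seed))
  )
  cfg <- .merge_config(cfg, list(...))
  validate_config(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults; missing keys keep their
#' default values.
#'
#' @param path YAML file.
#' @param ... further overrides, highest precedence.
#' @return a validated \code{gldmap_config}.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path))
    stop(.cfg_err("config file not found: ", path))
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(unclass(default_config()), user)
  cfg <- .merge_config(cfg, list(...))
  validate_config(cfg)
}

.merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]]))
      base[[k]] <- .merge_config(base[[k]], over[[k]])
    else base[[k]] <- over[[k]]
  }
  base
}

.cfg_err <- function(...) {
  structure(class = c("gldmap_config_error", "error", "condition"),
            list(message = paste0(...), call = NULL))
}

.dep_err <- function(stage, missing) {
  structure(class = c("gldmap_dependency_error", "error", "condition"),
            list(message = paste0("stage '", stage, "' needs artifacts ",
                                  "from an earlier stage; missing: ",
                                  paste(missing, collapse = ", "),
                                  ". Run the producing stage first."),
                 call = NULL))
}

#' @rdname default_config
#' @param cfg configuration list to validate.
#' @export
validate_config <- function(cfg) {
  a <- cfg$analysis
  chk <- function(ok, msg) if (!ok) stop(.cfg_err("config error: ", msg))
  chk(is.character(cfg$paths$output), "paths$output must be a path")
  chk(cfg$scheme$n_parcels >= 4, "scheme$n_parcels must be >= 4")
  chk(a$tau > 0 && a$tau <= 1, "analysis$tau must lie in (0,1]")
  chk(a$m_min >= 1, "analysis$m_min must be >= 1")
  chk(a$n_bins >= 2, "analysis$n_bins must be >= 2")
  chk(a$n_boot >= 100, "analysis$n_boot must be >= 100")
  chk(a$alpha > 0 && a$alpha < 1, "analysis$alpha must lie in (0,1)")
  chk(cfg$cohort$n_patients >= 1, "cohort$n_patients must be >= 1")
  chk(is.numeric(cfg$seeds$master), "seeds$master must be an integer")
  structure(cfg, class = "gldmap_config")
}

.stage_seeds <- function(cfg) {
  derive_seeds(cfg$seeds$master,
               c("simulate", "score", "permutation", "fit", "bootstrap"))
}

.art <- function(out, ...) file.path(out, ...)

.need <- function(stage, out, files) {
  missing <- files[!file.exists(.art(out, files))]
  if (length(missing)) stop(.dep_err(stage, missing))
}

.manifest <- function(out, stage, cfg, seed, inputs = character(0)) {
  man <- list(stage = stage, seed = seed,
              config = unclass(cfg),
              inputs = as.list(tools::md5sum(.art(out, inputs))),
              package_version = as.character(utils::packageVersion("gldmap")))
  jsonlite::write_json(man, .art(out, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.log_line <- function(out, stage, seed, t0) {
  line <- sprintf("stage=%s seed=%s wall_time_s=%.2f", stage, seed,
                  as.numeric(proc.time()["elapsed"] - t0))
  cat(line, "\n", file = .art(out, "run.log"), append = TRUE)
}

#' Run the lesion-deficit mapping pipeline
#'
#' Executes the requested stages in canonical order, each writing its
#' artifacts (delimited text, NIfTI, JSON) plus a manifest (config echo,
#' seed, input digests) into the run directory. Stage seeds are derived
#' from the master seed by name, so rerunning with the same configuration
#' reproduces every deterministic artifact bit-for-bit. A stage whose
#' upstream artifacts are absent raises a dependency error naming the stage
#' to run first.
#'
#' Stages: \code{simulate} (scheme, masks, cohort, ground truth),
#' \code{score} (item-level responses and percent-correct columns),
#' \code{stats} (age-adjusted group comparison with Bonferroni post hocs),
#' \code{graph} (damage matrix, test and null edge lists), \code{fit} (SBM
#' block states and model comparison), \code{map} (bootstrap intervals,
#' retention, exported volume), \code{report} (plain-text summary).
#'
#' @param config a \code{gldmap_config}.
#' @param stages character subset of
#'   \code{c("simulate","score","stats","graph","fit","map","report")} or
#'   \code{"all"}.
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (!inherits(config, "gldmap_config")) config <- validate_config(config)
  all_stages <- c("simulate", "score", "stats", "graph", "fit", "map",
                  "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop(.cfg_err("unknown stage(s): ",
                                 paste(bad, collapse = ", ")))
  stages <- all_stages[all_stages %in% stages]
  out <- config$paths$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stage_seeds(config)
  for (st in stages) {
    t0 <- proc.time()["elapsed"]
    seed <- if (st %in% names(seeds)) seeds[[st]] else config$seeds$master
    switch(st,
      simulate = .stage_simulate(config, out, seed),
      score = .stage_score(config, out, seed),
      stats = .stage_stats(config, out),
      graph = .stage_graph(config, out, seeds),
      fit = .stage_fit(config, out, seeds),
      map = .stage_map(config, out, seeds),
      report = .stage_report(config, out))
    .log_line(out, st, as.integer(seed), t0)
  }
  invisible(out)
}

.stage_simulate <- function(cfg, out, seed) {
  sch <- make_parcel_scheme(cfg$scheme$grid_shape, cfg$scheme$n_parcels,
                            seed = seed)
  truth <- ground_truth(sch, effect_beta = cfg$cohort$effect_beta,
                        age_gamma = cfg$cohort$age_gamma,
                        noise_sd = cfg$cohort$noise_sd, seed = seed)
  sim <- simulate_cohort(sch, truth, n_patients = cfg$cohort$n_patients,
                         n_controls = cfg$cohort$n_controls,
                         score_ceiling = cfg$cohort$score_ceiling,
                         mu0 = cfg$cohort$mu0,
                         age_range = cfg$cohort$age_range,
                         lesion_frac_range = cfg$cohort$lesion_frac_range,
                         seed = seed)
  write_parcel_scheme(sch, .art(out, "scheme.nii.gz"))
  dir.create(.art(out, "masks"), showWarnings = FALSE)
  for (m in sim$masks)
    write_mask(m, .art(out, "masks", paste0(m$patient_id, ".nii.gz")),
               sch$voxel_size_mm)
  utils::write.table(sim$cohort, .art(out, "cohort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(truth), .art(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  .manifest(out, "simulate", cfg, seed)
}

.read_cohort <- function(out) {
  utils::read.delim(.art(out, "cohort.tsv"), stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character"))
}

.read_scheme_masks <- function(out, cohort) {
  sch <- read_parcel_scheme(.art(out, "scheme.nii.gz"))
  pids <- cohort$participant_id[cohort$role == "patient"]
  masks <- lapply(pids, function(id)
    read_mask(.art(out, "masks", paste0(id, ".nii.gz")), sch,
              patient_id = id))
  list(scheme = sch, masks = masks)
}

.stage_score <- function(cfg, out, seed) {
  .need("score", out, "cohort.tsv")
  cohort <- .read_cohort(out)
  banks <- list(ART = art_item_bank(), DRT = drt_item_bank(),
                baseline = baseline_item_bank())
  sseeds <- derive_seeds(seed, names(banks))
  scored <- cohort
  for (tk in names(banks)) {
    log <- simulate_responses(cohort, banks[[tk]],
                              ability_scale = cfg$tasks$ability_scale,
                              seed = sseeds[[tk]])
    utils::write.table(log, .art(out, paste0("responses_", tk, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    pc <- percent_correct(log, banks[[tk]])
    scored[[paste0(tolower(tk), "_pct")]] <-
      as.numeric(pc[match(cohort$participant_id, names(pc))])
  }
  drt_log <- utils::read.delim(.art(out, "responses_DRT.tsv"),
                               stringsAsFactors = FALSE)
  for (det in c("determinate", "indeterminate")) {
    pc <- percent_correct(drt_log, banks$DRT,
                          function(it) it$determinacy == det)
    scored[[paste0("drt_", substr(det, 1, 5), "_pct")]] <-
      as.numeric(pc[match(cohort$participant_id, names(pc))])
  }
  utils::write.table(scored, .art(out, "scored.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  .manifest(out, "score", cfg, seed, "cohort.tsv")
}

.group_labels <- function(cfg, out, cohort) {
  sm <- .read_scheme_masks(out, cohort)
  pat <- which(cohort$role == "patient")
  grp <- rep("HC", nrow(cohort))
  for (k in seq_along(pat)) {
    fr <- damage_fractions(sm$masks[[k]], sm$scheme)
    cl <- classify_patient(fr, sm$scheme,
                           threshold = cfg$analysis$lobe_threshold)
    grp[pat[k]] <- cl$lobe_group
  }
  grp
}

.stage_stats <- function(cfg, out) {
  .need("stats", out, c("cohort.tsv", "scheme.nii.gz"))
  cohort <- .read_cohort(out)
  grp <- .group_labels(cfg, out, cohort)
  keep <- grp %in% c("frontal", "posterior", "HC")
  fit <- ancova(cohort$score[keep], grp[keep], cohort$age[keep])
  ph <- bonferroni_posthoc(ancova_posthoc(fit), n_comparisons = 3L)
  desc <- do.call(rbind, lapply(split(cohort$score[keep], grp[keep]),
    function(s) data.frame(mean = mean(s), sd = stats::sd(s), n = length(s))))
  desc$group <- rownames(desc)
  tab <- data.frame(
    group = desc$group,
    mean_sd = sprintf("%.2f (%.2f)", desc$mean, desc$sd),
    n = desc$n,
    f_statistic = fit$f_statistic,
    df = sprintf("(%d,%d)", fit$df_between, fit$df_residual),
    p_value = fit$p_value)
  utils::write.table(tab, .art(out, "stats_groups.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ph$marker <- ifelse(ph$significant, "*", "")
  utils::write.table(ph, .art(out, "stats_posthoc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  .manifest(out, "stats", cfg, NA_integer_,
            c("cohort.tsv", "scheme.nii.gz"))
}

.stage_graph <- function(cfg, out, seeds) {
  .need("graph", out, c("cohort.tsv", "scheme.nii.gz"))
  cohort <- .read_cohort(out)
  sm <- .read_scheme_masks(out, cohort)
  dm <- damage_matrix(sm$masks, sm$scheme)
  utils::write.table(data.frame(patient_id = rownames(dm), dm,
                                check.names = FALSE),
                     .art(out, "damage_matrix.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  z <- deficit_scores(cohort)
  dbin <- binarize_damage(dm, cfg$analysis$tau)
  graph <- build_graph(dbin, z, m_min = cfg$analysis$m_min)
  null_graph <- permute_null(dbin, z, seed = seeds[["permutation"]],
                             m_min = cfg$analysis$m_min)
  write_graph(graph, .art(out, "graph_test.tsv"))
  write_graph(null_graph, .art(out, "graph_null.tsv"))
  .manifest(out, "graph", cfg, seeds[["permutation"]],
            c("cohort.tsv", "scheme.nii.gz"))
}

.stage_fit <- function(cfg, out, seeds) {
  .need("fit", out, c("graph_test.tsv", "graph_null.tsv"))
  graph <- read_graph(.art(out, "graph_test.tsv"))
  null_graph <- read_graph(.art(out, "graph_null.tsv"))
  fit <- fit_sbm(graph, b_max = cfg$analysis$b_max,
                 n_sweeps = cfg$analysis$n_sweeps, seed = seeds[["fit"]],
                 n_bins = cfg$analysis$n_bins)
  nfit <- fit_sbm(null_graph, b_max = cfg$analysis$b_max,
                  n_sweeps = cfg$analysis$n_sweeps, seed = seeds[["fit"]],
                  n_bins = cfg$analysis$n_bins)
  cmp <- compare_models(fit, nfit)
  utils::write.table(data.frame(node = graph$nodes, block = fit$partition),
                     .art(out, "blocks.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(merge_newick(fit), .art(out, "merge_tree.nwk"))
  jsonlite::write_json(
    list(s_test = fit$dl_total, s_null = nfit$dl_total,
         delta = cmp$delta, odds_label = cmp$odds_label,
         B_test = fit$B, B_null = nfit$B,
         dl_components_test = as.list(fit$dl_components),
         dl_components_null = as.list(nfit$dl_components),
         seed = seeds[["fit"]]),
    .art(out, "comparison.json"), auto_unbox = TRUE, digits = NA)
  .manifest(out, "fit", cfg, seeds[["fit"]],
            c("graph_test.tsv", "graph_null.tsv"))
}

.stage_map <- function(cfg, out, seeds) {
  .need("map", out, c("damage_matrix.tsv", "graph_test.tsv", "cohort.tsv",
                      "scheme.nii.gz"))
  cohort <- .read_cohort(out)
  dm_tab <- utils::read.delim(.art(out, "damage_matrix.tsv"),
                              check.names = FALSE)
  dm <- as.matrix(dm_tab[, -1L, drop = FALSE])
  rownames(dm) <- dm_tab$patient_id
  z <- deficit_scores(cohort)
  dbin <- binarize_damage(dm, cfg$analysis$tau)
  graph <- read_graph(.art(out, "graph_test.tsv"))
  strengths <- node_strengths(graph)
  cis <- bootstrap_cis(dbin, z, n_boot = cfg$analysis$n_boot,
                       alpha = cfg$analysis$alpha,
                       seed = seeds[["bootstrap"]],
                       m_min = cfg$analysis$m_min)
  community <- NULL
  if (file.exists(.art(out, "blocks.tsv"))) {
    bl <- utils::read.delim(.art(out, "blocks.tsv"))
    community <- bl$block[match(strengths$node, as.character(bl$node))]
  }
  map <- retention_rule(strengths, cis, community = community)
  sch <- read_parcel_scheme(.art(out, "scheme.nii.gz"))
  export_parcel_map(map, sch, .art(out, "deficit_map.nii.gz"))
  if (file.exists(.art(out, "ground_truth.json"))) {
    tr <- jsonlite::read_json(.art(out, "ground_truth.json"),
                              simplifyVector = TRUE)
    rec <- substrate_recovery(map, structure(tr, class = "ground_truth"))
    jsonlite::write_json(rec, .art(out, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  .manifest(out, "map", cfg, seeds[["bootstrap"]],
            c("damage_matrix.tsv", "graph_test.tsv"))
}

#' Assemble the run report
#'
#' Gathers the behavioural table, the test/null description lengths with
#' their odds label, the retained-parcel table and (when ground truth is
#' present) the recovery metrics into a plain-text summary. Sections whose
#' artifacts are missing are marked unavailable.
#'
#' @param run_dir a pipeline run directory.
#' @return the report lines, invisibly; also written to
#'   \code{report.txt}.
#' @export
report <- function(run_dir) {
  out <- run_dir
  lines <- c("Graph lesion-deficit mapping run report", "")
  if (file.exists(.art(out, "stats_groups.tsv"))) {
    tab <- utils::read.delim(.art(out, "stats_groups.tsv"))
    lines <- c(lines, "Group comparison (age-adjusted):",
               utils::capture.output(print(tab, row.names = FALSE)), "")
    if (file.exists(.art(out, "stats_posthoc.tsv"))) {
      ph <- utils::read.delim(.art(out, "stats_posthoc.tsv"))
      lines <- c(lines, "Bonferroni post hocs:",
                 utils::capture.output(print(ph, row.names = FALSE)), "")
    }
  } else lines <- c(lines, "[behavioural section unavailable]", "")
  if (file.exists(.art(out, "comparison.json"))) {
    cmp <- jsonlite::read_json(.art(out, "comparison.json"),
                               simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "Model comparison: s_test = %.0f nats, s_null = %.0f nats, delta = %.0f nats (odds %s in favour of test)",
      cmp$s_test, cmp$s_null, cmp$delta, cmp$odds_label), "")
  } else lines <- c(lines, "[model comparison unavailable]", "")
  map_path <- .sidecar_path(.art(out, "deficit_map.nii.gz"))
  if (file.exists(map_path)) {
    map <- utils::read.delim(map_path)
    kept <- map[map$retained == "TRUE" | map$retained == TRUE, , drop = FALSE]
    lines <- c(lines, sprintf("Retained parcels: %d of %d", nrow(kept),
                              nrow(map)))
    if (nrow(kept))
      lines <- c(lines, utils::capture.output(print(
        kept[, c("node", "deficit_strength", "lesion_strength")],
        row.names = FALSE)))
    lines <- c(lines, "")
  } else lines <- c(lines, "[network map unavailable]", "")
  if (file.exists(.art(out, "recovery.json"))) {
    rec <- jsonlite::read_json(.art(out, "recovery.json"),
                               simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "Substrate recovery: Jaccard %.3f, sensitivity %.3f, specificity %.3f",
      rec$jaccard, rec$sensitivity, rec$specificity))
  }
  writeLines(lines, .art(out, "report.txt"))
  invisible(lines)
}

.stage_report <- function(cfg, out) {
  .need("report", out, "comparison.json")
  report(out)
}
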