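# End-to-end study: networks in, five attack conditions, outcome matrices,
# robust descriptives, omnibus and post hoc tables out.

ALL_CONDITIONS <- c("random", "degree", "strength", "bridgeness", "overlap")
OUTCOME_MEASURES <- c("components_magnitude", "pathlength_magnitude",
                      "components_extent", "pathlength_extent",
                      "connectivity_extent")

#' Study configuration
#'
#' @param networks List of `symptom_network` objects, or `NULL` to
#'   generate them from `spec`.
#' @param spec An [ensemble_spec()] used when `networks` is `NULL`.
#' @param conditions Attack conditions to run (default all five).
#' @param mode Attack mode, `"initial"` (default) or `"recalculated"`.
#' @param n_sims Random-attack replicates per network (default 2000).
#' @param weighted Connectivity as summed absolute weight.
#' @param distance Path-length mode (`"hops"` or `"inverse_weight"`).
#' @param robust A [robust_config()] for the condition comparisons.
#' @param output_dir Optional directory for CSV/JSON artifacts.
#' @param seed Integer master seed for the random attacks.
#' @return A `study_config` list.
#' @export
study_config <- function(networks = NULL, spec = NULL,
                         conditions = ALL_CONDITIONS,
                         mode = c("initial", "recalculated"),
                         n_sims = 2000, weighted = FALSE,
                         distance = c("hops", "inverse_weight"),
                         robust = robust_config(),
                         output_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  conditions <- match.arg(conditions, ALL_CONDITIONS, several.ok = TRUE)
  if (length(conditions) < 2) stop("need at least 2 conditions to compare")
  if (is.null(networks) && is.null(spec))
    stop("supply `networks` or an ensemble `spec`")
  structure(list(networks = networks, spec = spec, conditions = conditions,
                 mode = mode, n_sims = as.integer(n_sims),
                 weighted = weighted, distance = distance,
                 robust = robust, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "study_config")
}

attack_one_network <- function(network, id, config, net_index = 1L) {
  targeted <- setdiff(config$conditions, "random")
  needs_modules <- any(targeted %in% c("bridgeness", "overlap"))
  assignment <- if (needs_modules) detect_modules(network) else NULL
  rows <- list()
  for (cond in targeted) {
    tr <- if (config$mode == "initial") {
      targeted_attack(network, rank_nodes(network, cond, assignment = assignment),
                      mode = "initial", weighted = config$weighted,
                      distance = config$distance)
    } else {
      targeted_attack(network, cond, mode = "recalculated",
                      weighted = config$weighted, distance = config$distance)
    }
    rows[[cond]] <- trajectory_outcome(tr, network_id = id)
  }
  if ("random" %in% config$conditions) {
    net_seed <- as.integer((config$seed + net_index * 100003) %% 2147483647)
    reps <- random_attack(network, n_sims = config$n_sims, seed = net_seed,
                          weighted = config$weighted, distance = config$distance)
    rows[["random"]] <- aggregate_random(reps, network_id = id)
  }
  do.call(rbind, rows)
}

#' Run the full attack study
#'
#' For every network: compute the ranking measures, simulate the targeted
#' conditions and the random condition, and reduce each to the five
#' outcome measures. Across networks: robust descriptives per condition,
#' then an omnibus and post hoc trimmed-mean bootstrap-t comparison per
#' outcome measure. Networks that fail a stage (no edges, too few nodes)
#' are skipped with a logged reason; the study aborts if fewer than 5
#' networks survive.
#'
#' @param config A [study_config()].
#' @return A `study_report`: `outcomes` (network x condition rows),
#'   `descriptives`, `omnibus` (one result per outcome measure), `posthoc`
#'   (one comparison table per outcome measure), `skipped`, `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  networks <- config$networks
  if (is.null(networks)) networks <- gen_network_ensemble(config$spec)
  ids <- sprintf("net%03d", seq_along(networks))
  skipped <- data.frame(network = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_along(networks)) {
    res <- tryCatch(attack_one_network(networks[[i]], ids[i], config, net_index = i),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message("skipping ", ids[i], ": ", res)
      skipped <- rbind(skipped, data.frame(network = ids[i], reason = res,
                                           stringsAsFactors = FALSE))
    } else rows[[ids[i]]] <- res
  }
  if (length(rows) < 5)
    stop("fewer than 5 networks survived the attack stage")
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL

  descriptives <- do.call(rbind, lapply(OUTCOME_MEASURES, function(m) {
    do.call(rbind, lapply(config$conditions, function(cond) {
      v <- outcomes[outcomes$condition == cond, m]
      d <- tryCatch(describe_outcomes(v, trim = config$robust$trim),
                    error = function(e) NULL)
      if (is.null(d)) return(NULL)
      cbind(data.frame(measure = m, condition = cond,
                       stringsAsFactors = FALSE), d)
    }))
  }))
  rownames(descriptives) <- NULL

  omnibus <- list(); posthoc <- list()
  for (mi in seq_along(OUTCOME_MEASURES)) {
    m <- OUTCOME_MEASURES[mi]
    X <- do.call(cbind, lapply(config$conditions, function(cond)
      outcomes[outcomes$condition == cond, m]))
    colnames(X) <- config$conditions
    cfg <- config$robust
    cfg$seed <- as.integer((cfg$seed + 7919L * mi) %% 2147483647L)
    omnibus[[m]] <- tryCatch(omnibus_bootstrap_t(X, cfg),
                             error = function(e) conditionMessage(e))
    posthoc[[m]] <- tryCatch(posthoc_bootstrap_t(X, cfg),
                             error = function(e) conditionMessage(e))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("netattack")),
    seed = config$seed,
    n_networks = length(networks),
    n_survived = length(rows),
    conditions = config$conditions,
    attack_mode = config$mode,
    n_sims = config$n_sims,
    connectivity = if (config$weighted) "weighted" else "count",
    distance = config$distance,
    random_aggregation = "per_replicate",
    extent_denominator = "initial node count",
    stopping_rule = "remove N-1 nodes",
    robust = list(trim = config$robust$trim, B = config$robust$B,
                  alpha = config$robust$alpha, seed = config$robust$seed),
    skipped = skipped$network
  )

  report <- structure(list(outcomes = outcomes, descriptives = descriptives,
                           omnibus = omnibus, posthoc = posthoc,
                           skipped = skipped, manifest = manifest),
                      class = "study_report")
  if (!is.null(config$output_dir)) write_study_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report: ", length(unique(x$outcomes$network)), " networks x ",
      length(unique(x$outcomes$condition)), " conditions\n", sep = "")
  sig <- vapply(x$omnibus, function(o)
    if (inherits(o, "omnibus_result")) o$significant else NA, logical(1))
  cat("  omnibus significant: ",
      paste(names(sig)[which(sig)], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write study artifacts
#'
#' Writes `outcomes.csv`, `descriptives.csv`, one post hoc CSV per outcome
#' measure, `omnibus.json` and a reproducibility `manifest.json`.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  for (m in names(report$posthoc)) {
    if (is.data.frame(report$posthoc[[m]]))
      utils::write.csv(report$posthoc[[m]],
                       file.path(dir, paste0("posthoc_", m, ".csv")),
                       row.names = FALSE)
  }
  omni <- lapply(report$omnibus, function(o) {
    if (inherits(o, "omnibus_result"))
      list(F_t = o$F_t, F_crit = o$F_crit, significant = o$significant, n = o$n)
    else list(error = o)
  })
  jsonlite::write_json(omni, file.path(dir, "omnibus.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
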