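# Reduction of attack trajectories to the five outcome measures: impact
# magnitude and attack extent for components and average path length, and
# the extent to a 50% connectivity drop.

trajectory_column <- function(trajectory, metric) {
  switch(metric,
         components = trajectory$states$n_components,
         path_length = trajectory$states$avg_path_length,
         stop("unknown metric: ", metric))
}

#' Impact magnitude of an attack
#'
#' Difference between the peak value of the metric over the whole
#' trajectory (steps where the metric is undefined are skipped) and its
#' initial value.
#'
#' @param trajectory An `attack_trajectory`.
#' @param metric `"components"` or `"path_length"`.
#' @return Nonnegative scalar (the initial step participates in the peak
#'   search, so the difference cannot be negative).
#' @export
impact_magnitude <- function(trajectory, metric = c("components", "path_length")) {
  metric <- match.arg(metric)
  v <- trajectory_column(trajectory, metric)
  if (all(is.na(v))) stop("metric '", metric, "' is undefined at every step")
  if (is.na(v[1]))
    stop("metric '", metric, "' is undefined at step 0 (no initial edges)")
  max(v, na.rm = TRUE) - v[1]
}

#' Attack extent to peak
#'
#' Proportion of the network's symptoms that had to be removed to first
#' attain the metric's peak: (first step index attaining the peak) divided
#' by the initial node count. A peak already present at step 0 gives 0.
#'
#' @inheritParams impact_magnitude
#' @return Proportion in \[0, 1\].
#' @export
attack_extent <- function(trajectory, metric = c("components", "path_length")) {
  metric <- match.arg(metric)
  v <- trajectory_column(trajectory, metric)
  if (all(is.na(v))) stop("metric '", metric, "' is undefined at every step")
  if (is.na(v[1]))
    stop("metric '", metric, "' is undefined at step 0 (no initial edges)")
  peak <- max(v, na.rm = TRUE)
  first <- which(!is.na(v) & v == peak)[1] - 1L
  first / trajectory$n_initial
}

#' Attack extent to a 50% connectivity drop
#'
#' Proportion of symptoms that had to be removed for connectivity to fall
#' to half its initial value or less.
#'
#' @param trajectory An `attack_trajectory` whose initial connectivity is
#'   positive.
#' @return Proportion in \[0, 1\].
#' @export
connectivity_extent <- function(trajectory) {
  v <- trajectory$states$connectivity
  if (v[1] <= 0) stop("initial connectivity is 0; extent undefined")
  first <- which(v <= 0.5 * v[1])[1] - 1L
  first / trajectory$n_initial
}

# fast path shared by trajectory_outcome and aggregate_random: the five
# outcomes of one trajectory as a named numeric vector (NA where undefined)
outcome_vector <- function(trajectory) {
  st <- trajectory$states
  N <- trajectory$n_initial
  cmp <- st$n_components
  pl <- st$avg_path_length
  cn <- st$connectivity
  cpeak <- max(cmp)
  out <- c(components_magnitude = cpeak - cmp[1],
           components_extent = (which(cmp == cpeak)[1] - 1L) / N,
           pathlength_magnitude = NA_real_, pathlength_extent = NA_real_,
           connectivity_extent = NA_real_)
  if (!is.na(pl[1])) {
    ppeak <- max(pl, na.rm = TRUE)
    out["pathlength_magnitude"] <- ppeak - pl[1]
    out["pathlength_extent"] <- (which(!is.na(pl) & pl == ppeak)[1] - 1L) / N
  }
  if (cn[1] > 0)
    out["connectivity_extent"] <- (which(cn <= 0.5 * cn[1])[1] - 1L) / N
  out
}

#' Outcome measures of one trajectory
#'
#' The five per-network, per-condition outcomes. Path-length outcomes are
#' `NA` (rather than an error) when the initial network has no edges so
#' ensemble runs can skip them listwise.
#'
#' @param trajectory An `attack_trajectory`.
#' @param network_id Identifier carried into the output row.
#' @return One-row data frame with columns `network`, `condition`,
#'   `components_magnitude`, `components_extent`, `pathlength_magnitude`,
#'   `pathlength_extent`, `connectivity_extent`.
#' @export
trajectory_outcome <- function(trajectory, network_id = NA_character_) {
  v <- outcome_vector(trajectory)
  cbind(data.frame(network = network_id, condition = trajectory$condition,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(v)))
}

#' Aggregate random-attack replicates into one outcome row
#'
#' Default: compute the five outcomes for every replicate, then average
#' them across replicates. The alternative (`"mean_trajectory"`) averages
#' the state trajectories step-wise first and reduces the averaged
#' trajectory; it is kept for sensitivity analysis.
#'
#' @param trajectories List of `attack_trajectory` replicates on the same
#'   network.
#' @param network_id Identifier carried into the output row.
#' @param method `"per_replicate"` (default) or `"mean_trajectory"`.
#' @return One-row data frame as in [trajectory_outcome()], condition
#'   `"random"`.
#' @export
aggregate_random <- function(trajectories, network_id = NA_character_,
                             method = c("per_replicate", "mean_trajectory")) {
  method <- match.arg(method)
  stopifnot(length(trajectories) >= 1)
  if (method == "per_replicate") {
    vals <- vapply(trajectories, outcome_vector, numeric(5))
    return(cbind(data.frame(network = network_id, condition = "random",
                            stringsAsFactors = FALSE),
                 as.data.frame(as.list(rowMeans(vals)))))
  }
  mean_states <- Reduce(`+`, lapply(trajectories, function(tr)
    as.matrix(tr$states[, c("connectivity", "n_components", "avg_path_length")]))) /
    length(trajectories)
  proto <- trajectories[[1]]
  proto$states <- data.frame(step = proto$states$step,
                             connectivity = mean_states[, 1],
                             n_components = mean_states[, 2],
                             avg_path_length = mean_states[, 3])
  proto$condition <- "random"
  trajectory_outcome(proto, network_id = network_id)
}

#' Robust descriptive summary of an outcome
#'
#' Mean, SD (n-1 divisor), 20%-trimmed mean, trimmed-mean standard error
#' (Winsorized SD divided by `(1 - 2 trim) * sqrt(n)`), minimum and
#' maximum — the descriptive layout used for skewed attack outcomes.
#'
#' @param values Numeric vector with at least 5 non-missing values.
#' @param trim Trimming proportion per tail.
#' @return One-row data frame with columns `n`, `mean`, `sd`,
#'   `trimmed_mean`, `trimmed_se`, `min`, `max`.
#' @export
describe_outcomes <- function(values, trim = 0.2) {
  values <- values[!is.na(values)]
  if (length(values) < 5)
    stop("need at least 5 non-missing values for trimmed statistics")
  n <- length(values)
  w <- winsorize(values, trim)
  data.frame(n = n,
             mean = mean(values),
             sd = stats::sd(values),
             trimmed_mean = mean(values, trim = trim),
             trimmed_se = stats::sd(w) / ((1 - 2 * trim) * sqrt(n)),
             min = min(values),
             max = max(values))
}
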