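#' Optimal propensity-score cohort matching
#'
#' Matches each case (trait = 1) to exactly `ratio` distinct controls
#' (trait = 0) so that the total propensity-score distance over all pairs is
#' globally minimal. The propensity score is the linear predictor of a
#' logistic regression of the trait on the matching covariates (categorical
#' covariates one-hot encoded); the pairwise distance is the absolute
#' difference of linear predictors, and the `ratio`-to-one assignment is
#' solved exactly by replicating each case `ratio` times and solving the
#' rectangular linear sum assignment problem. Exact distance ties are broken
#' toward the lexicographically smaller control id so the result is
#' deterministic.
#'
#' @param metadata data frame with columns `sample_id`, `trait` (0/1) and the
#'   matching covariates.
#' @param ratio controls per case (default 2).
#' @param match_covariates covariate column names used in the propensity
#'   model; constant covariates are dropped with a warning.
#' @return An object of class `match_result`: a list with
#'   `retained_sample_ids`, `case_ids`, `control_ids`, `match_map` (tibble
#'   `case_id`, `control_id`, `distance`), `balance` (tibble of per-covariate
#'   standardized mean differences before/after matching) and
#'   `total_distance`. `tidy()` returns the match map, `glance()` a one-row
#'   summary.
#' @examples
#' md <- simulate_dataset(simulation_config(n_genes = 40, n_cases = 6,
#'   n_controls = 20, module_sizes = c(10, 8, 6), seed = 3))$metadata
#' m <- match_cohort(md, ratio = 2)
#' glance(m)
#' @export
match_cohort <- function(metadata, ratio = 2,
                         match_covariates = c("sex", "age", "race")) {
  check_metadata(metadata)
  stopifnot(length(ratio) == 1, ratio >= 1, ratio == round(ratio))
  miss <- setdiff(match_covariates, names(metadata))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(metadata[match_covariates])) stop("covariates contain missing values", call. = FALSE)

  cases <- metadata$sample_id[metadata$trait == 1]
  controls <- metadata$sample_id[metadata$trait == 0]
  if (ratio * length(cases) > length(controls)) {
    stop(sprintf("insufficient controls: need %d, have %d",
                 ratio * length(cases), length(controls)), call. = FALSE)
  }

  keep <- vapply(match_covariates, function(v) {
    ok <- length(unique(metadata[[v]])) > 1
    if (!ok) warning("dropping constant covariate: ", v, call. = FALSE)
    ok
  }, logical(1))
  covs <- match_covariates[keep]
  if (!length(covs)) stop("no usable (non-constant) matching covariates", call. = FALSE)

  fml <- stats::reformulate(covs, response = "trait")
  fit <- suppressWarnings(glm(fml, family = binomial(), data = metadata))
  lp <- predict(fit, type = "link")
  names(lp) <- metadata$sample_id

  # rows = cases replicated `ratio` times, cols = controls; Hungarian solve
  cost <- abs(outer(rep(lp[cases], each = ratio), lp[controls], "-"))
  # deterministic tie-break: nudge toward lexicographically smaller controls
  eps <- 1e-9 * max(cost, 1)
  nudge <- (rank(controls) - 1) / max(length(controls) - 1, 1) * eps
  cost <- sweep(cost, 2, nudge, "+")
  sol <- clue::solve_LSAP(cost)
  picked <- controls[as.integer(sol)]

  match_map <- tibble::tibble(
    case_id = rep(cases, each = ratio),
    control_id = picked,
    distance = abs(lp[rep(cases, each = ratio)] - lp[picked])
  ) |>
    dplyr::arrange(.data$case_id, .data$control_id)

  retained <- c(cases, sort(unique(picked)))

  smd <- function(ids1, ids0) {
    mm <- model.matrix(stats::reformulate(covs, intercept = FALSE), data = metadata)
    rownames(mm) <- metadata$sample_id
    purrr::map_dfr(colnames(mm), function(v) {
      x1 <- mm[ids1, v]; x0 <- mm[ids0, v]
      pooled <- sqrt((var(x1) + var(x0)) / 2)
      tibble::tibble(covariate = v,
                     smd = if (pooled == 0) 0 else (mean(x1) - mean(x0)) / pooled)
    })
  }
  balance <- dplyr::full_join(
    dplyr::rename(smd(cases, controls), smd_before = "smd"),
    dplyr::rename(smd(cases, sort(unique(picked))), smd_after = "smd"),
    by = "covariate"
  )

  structure(list(
    retained_sample_ids = retained,
    case_ids = cases,
    control_ids = sort(unique(picked)),
    match_map = match_map,
    balance = balance,
    total_distance = sum(match_map$distance),
    ratio = ratio,
    covariates = covs
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Optimal %d:1 match: %d cases, %d controls retained (of %s candidates)\n",
              x$ratio, length(x$case_ids), length(x$control_ids),
              "the control pool"))
  cat(sprintf("  total propensity distance: %.4g\n", x$total_distance))
  print(x$balance)
  invisible(x)
}

#' @export
tidy.match_result <- function(x, ...) x$match_map

#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    n_cases = length(x$case_ids),
    n_controls_matched = length(x$control_ids),
    n_retained = length(x$retained_sample_ids),
    ratio = x$ratio,
    total_distance = x$total_distance,
    max_abs_smd_after = max(abs(x$balance$smd_after))
  )
}
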