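# Case-based survival estimation: an alive patient's survival percent is
# derived from cosine similarity to the most similar deceased registry
# members. The default ("deceased-distance") estimator is
#   percent = 100 * (1 - mean similarity to the k nearest deceased),
# searched within the patient's own risk stratum when it holds at least k
# deceased members, else registry-wide. The alternative "outcome-weighted"
# estimator looks at the k most similar patients of known vital status and
# returns the similarity-weighted alive fraction.

clamp01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# stratum label: the high-risk subgroup, or the risk tier for unassigned
stratum_of <- function(assignments) {
  ifelse(assignments$subgroup == "none", assignments$group,
         assignments$subgroup)
}

estimate_one <- function(qid, E, ids, alive, stratum, k, mode, book,
                         policy, sim_mode) {
  qi <- match(qid, ids)
  q <- E[qi, ]
  if (mode == "deceased-distance") {
    ref <- which(!alive & ids != qid)
    scope <- "global"
    in_stratum <- ref[stratum[ref] == stratum[qi]]
    if (length(in_stratum) >= k) {
      ref <- in_stratum
      scope <- "subgroup"
    }
  } else {
    ref <- which(!is.na(alive) & ids != qid)
    scope <- "global"
  }
  if (length(ref) == 0) {
    stop("insufficient-reference error (mode ", mode,
         "): no reference patients available", call. = FALSE)
  }
  sims <- sim_query_to_matrix(q, E[ref, , drop = FALSE], book,
                              policy = policy, mode = sim_mode)
  ok <- !is.na(sims)
  ref <- ref[ok]
  sims <- sims[ok]
  if (length(ref) == 0) {
    stop("insufficient-reference error (mode ", mode,
         "): no comparable reference patients for ", qid, call. = FALSE)
  }
  ord <- order(-sims, ids[ref])
  take <- ord[seq_len(min(k, length(ord)))]
  nb_ids <- ids[ref][take]
  nb_sims <- sims[take]
  percent <- if (mode == "deceased-distance") {
    clamp01(100 * (1 - mean(nb_sims)))
  } else {
    w <- sum(nb_sims)
    a <- as.numeric(alive[ref][take])
    if (w > 0) clamp01(100 * sum(nb_sims * a) / w) else 100 * mean(a)
  }
  tibble::tibble(
    patient_id = qid,
    percent = percent,
    k_used = length(nb_ids),
    mode = mode,
    scope = scope,
    neighbors = list(tibble::tibble(neighbor_id = nb_ids,
                                    similarity = nb_sims))
  )
}

#' Estimate survival percent from similarity to deceased patients
#'
#' Computes a [0, 100] survival percent for alive registry members. In
#' `"deceased-distance"` mode (default) the estimate is
#' `100 * (1 - mean cosine similarity)` over the `k` deceased patients most
#' similar to the query, taken within the query's risk stratum when that
#' stratum holds at least `k` deceased members and registry-wide otherwise
#' (`scope` records which). In `"outcome-weighted"` mode the `k` most similar
#' patients of known vital status contribute their similarity-weighted alive
#' indicator. Neighbor ties are broken by patient id, ascending; similarities
#' follow the registry's configured rounding contract, and by default each
#' feature slot is scaled by its maximum code first (see
#' [registry_config()]'s `scale_features`).
#'
#' @param reg A `crc_registry` (see [build_registry()]).
#' @param ids Patient ids to estimate; default all alive patients.
#' @param k Number of neighbors (default from the registry config).
#' @param mode `"deceased-distance"` or `"outcome-weighted"`.
#' @return A tibble: `patient_id`, `percent`, `k_used`, `mode`, `scope`,
#'   `stratum`, and a `neighbors` list column of
#'   `(neighbor_id, similarity)` tibbles sorted by similarity descending.
#' @export
estimate_survival <- function(reg, ids = NULL, k = NULL, mode = NULL) {
  stopifnot(inherits(reg, "crc_registry"))
  k <- k %||% reg$config$k
  mode <- mode %||% reg$config$mode
  mode <- match.arg(mode, c("deceased-distance", "outcome-weighted"))
  stopifnot(k >= 1)
  all_ids <- as.character(reg$patients$patient_id)
  alive <- tolower(as.character(reg$patients$vital_status)) == "alive"
  if (is.null(ids)) ids <- all_ids[which(alive)]
  if (length(ids) == 0) return(empty_estimates(mode))
  if (!all(ids %in% all_ids)) {
    stop("lookup error: unknown patient id(s): ",
         paste(setdiff(ids, all_ids), collapse = ", "), call. = FALSE)
  }
  book <- reg$codebook
  features <- reg$config$feature_set %||% setdiff(book$fields,
                                                  outcome_fields)
  E <- as.matrix(reg$encoded[, features, drop = FALSE])
  storage.mode(E) <- "numeric"
  if (isTRUE(reg$config$scale_features)) {
    maxcode <- vapply(features, function(f) max(book$specs[[f]], 1),
                      numeric(1))
    E <- sweep(E, 2, maxcode, "/")
  }
  stratum <- stratum_of(reg$assignments)
  out <- purrr::map_dfr(ids, function(qid) {
    estimate_one(qid, E, all_ids, alive, stratum, k, mode, book,
                 policy = reg$config$policy,
                 sim_mode = reg$config$similarity_mode)
  })
  out$stratum <- stratum[match(out$patient_id, all_ids)]
  out
}

empty_estimates <- function(mode = "deceased-distance") {
  tibble::tibble(patient_id = character(0), percent = numeric(0),
                 k_used = integer(0), mode = character(0),
                 scope = character(0),
                 neighbors = list(), stratum = character(0))
}

compute_group_stats <- function(estimates, revision, prev = NULL) {
  stats <- estimates |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(mean_percent = mean(.data$percent),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$stratum)
  if (is.null(prev) || nrow(prev) == 0) {
    stats$last_updated <- rep(as.integer(revision), nrow(stats))
    return(stats)
  }
  old <- prev[match(stats$stratum, prev$stratum), , drop = FALSE]
  unchanged <- !is.na(old$stratum) & old$n == stats$n &
    abs(old$mean_percent - stats$mean_percent) < 1e-12
  stats$last_updated <- ifelse(unchanged, old$last_updated,
                               as.integer(revision))
  stats
}

#' Per-stratum mean survival statistics
#'
#' Arithmetic mean of the current member estimates for each risk stratum
#' (high-risk subgroup, or risk tier for unassigned patients), with member
#' count and a monotone revision stamp that advances whenever the group's
#' statistics are recomputed to a new value. An empty or unknown stratum
#' yields zero rows, not an error.
#'
#' @param reg A `crc_registry`.
#' @param subgroup Optional stratum filter (e.g. `"HNPCC"`, `"average"`).
#' @return A tibble: `stratum`, `mean_percent`, `n`, `last_updated`.
#' @export
group_mean_survival <- function(reg, subgroup = NULL) {
  stopifnot(inherits(reg, "crc_registry"))
  stats <- reg$stats
  if (!is.null(subgroup)) {
    stats <- stats[stats$stratum %in% subgroup, , drop = FALSE]
  }
  stats
}
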