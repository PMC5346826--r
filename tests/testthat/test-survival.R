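# The estimator's arithmetic on hand-built registries, plus its agreement
# with an independent recomputation of "100 * (1 - mean top-k similarity)".

small_registry <- function(patients, families = NULL, k = 1,
                           mode = "deceased-distance", ...) {
  build_registry(patients, families,
                 config = registry_config(k = k, mode = mode, ...))
}

test_that("an identical deceased reference gives a 0% estimate at k = 1", {
  patients <- dplyr::bind_rows(
    make_patient("alive-1"),
    make_patient("dead-1", vital_status = "Dead",
                 survival_quality = "Dead", survival_time = 24)
  )
  reg <- small_registry(patients, k = 1)
  est <- reg$estimates
  expect_equal(nrow(est), 1)
  expect_equal(est$patient_id, "alive-1")
  expect_equal(est$percent, 0)
  expect_equal(est$k_used, 1L)
  expect_equal(est$neighbors[[1]]$neighbor_id, "dead-1")
  expect_equal(est$neighbors[[1]]$similarity, 1)
})

test_that("estimate equals 100*(1 - mean top-k similarity), ties by id", {
  set.seed(31)
  sim <- simulate_registry(n_patients = 40, seed = 31)
  reg <- build_registry(sim$patients, sim$families)
  book <- reg$codebook
  features <- setdiff(book$fields, c("vital_status", "survival_quality"))
  maxcode <- vapply(features, function(f) max(book$specs[[f]], 1),
                    numeric(1))
  dead_ids <- reg$patients$patient_id[
    tolower(reg$patients$vital_status) == "dead"]

  for (row in sample(nrow(reg$estimates), 5)) {
    est <- reg$estimates[row, ]
    q <- as.numeric(reg$encoded[
      match(est$patient_id, reg$encoded$patient_id), features]) / maxcode
    strat_all <- ifelse(reg$assignments$subgroup == "none",
                        reg$assignments$group, reg$assignments$subgroup)
    refs <- if (est$scope == "subgroup") {
      dead_ids[strat_all[match(dead_ids,
                               reg$assignments$patient_id)] == est$stratum]
    } else {
      dead_ids
    }
    sims <- vapply(refs, function(d) {
      v <- as.numeric(reg$encoded[match(d, reg$encoded$patient_id),
                                  features]) / maxcode
      keep <- !is.na(q) & !is.na(v)
      cosine_similarity(q[keep], v[keep])
    }, numeric(1))
    ord <- order(-sims, refs)
    topk <- sims[ord][seq_len(min(5, length(ord)))]
    expect_equal(est$percent, max(0, min(100, 100 * (1 - mean(topk)))),
                 info = est$patient_id)
    expect_equal(est$neighbors[[1]]$neighbor_id, refs[ord][seq_along(topk)])
  }
})

test_that("outcome-weighted mode returns 100% for an all-alive neighborhood", {
  patients <- dplyr::bind_rows(
    make_patient("q"),
    make_patient("n1"), make_patient("n2"), make_patient("n3")
  )
  reg <- small_registry(patients, k = 3, mode = "outcome-weighted")
  expect_equal(reg$estimates$percent, rep(100, 4))
  expect_equal(unique(reg$estimates$k_used), 3L)
})

test_that("estimates stay in [0,100] on synthetic registries", {
  for (s in c(2, 13)) {
    sim <- simulate_registry(n_patients = 80, seed = s)
    reg <- build_registry(sim$patients, sim$families)
    expect_true(all(reg$estimates$percent >= 0 &
                      reg$estimates$percent <= 100))
    expect_true(all(reg$estimates$k_used >= 1))
    ow <- estimate_survival(reg, mode = "outcome-weighted")
    expect_true(all(ow$percent >= 0 & ow$percent <= 100))
  }
})

test_that("higher similarity to the nearest deceased never raises the estimate", {
  # make the deceased reference progressively more similar to the query
  query <- make_patient("q", pt = "T4", pn = "N2", pm = "M1",
                        anemia = "Yes", weight_loss = "Yes")
  steps <- list(
    make_patient("d", vital_status = "Dead", survival_quality = "Dead"),
    make_patient("d", vital_status = "Dead", survival_quality = "Dead",
                 pt = "T4", pn = "N2"),
    make_patient("d", vital_status = "Dead", survival_quality = "Dead",
                 pt = "T4", pn = "N2", pm = "M1", anemia = "Yes",
                 weight_loss = "Yes")
  )
  prev_sim <- -Inf
  prev_pct <- Inf
  for (d in steps) {
    reg <- small_registry(dplyr::bind_rows(query, d), k = 1)
    est <- reg$estimates
    expect_gte(est$neighbors[[1]]$similarity, prev_sim)
    expect_lte(est$percent, prev_pct)
    prev_sim <- est$neighbors[[1]]$similarity
    prev_pct <- est$percent
  }
  expect_equal(prev_pct, 0) # final step is an exact clone
})

test_that("reference scope falls back registry-wide when the stratum is thin", {
  patients <- dplyr::bind_rows(
    make_patient("q", ibd = "Yes"), # IBD stratum, no IBD deceased
    make_patient("d1", vital_status = "Dead", survival_quality = "Dead"),
    make_patient("d2", vital_status = "Dead", survival_quality = "Dead",
                 ibd = "Yes")
  )
  reg <- small_registry(patients, k = 2)
  est <- reg$estimates[reg$estimates$patient_id == "q", ]
  expect_equal(est$scope, "global")
  expect_equal(est$k_used, 2L)

  reg1 <- small_registry(patients, k = 1)
  est1 <- reg1$estimates[reg1$estimates$patient_id == "q", ]
  expect_equal(est1$scope, "subgroup")
  expect_equal(est1$neighbors[[1]]$neighbor_id, "d2")
})

test_that("an all-alive registry has no estimates until a death is recorded", {
  patients <- dplyr::bind_rows(make_patient("a"), make_patient("b"))
  expect_message(reg <- build_registry(patients,
                                       config = registry_config(k = 1)),
                 "no survival estimates")
  expect_equal(nrow(reg$estimates), 0)
  expect_error(estimate_survival(reg, ids = "a"), "insufficient-reference")
})

test_that("group means are arithmetic means of member estimates", {
  sim <- simulate_registry(n_patients = 60, seed = 17)
  reg <- build_registry(sim$patients, sim$families)
  manual <- reg$estimates |>
    dplyr::group_by(stratum) |>
    dplyr::summarise(mean_percent = mean(percent), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(stratum)
  expect_equal(reg$stats$stratum, manual$stratum)
  expect_equal(reg$stats$mean_percent, manual$mean_percent)
  expect_equal(reg$stats$n, manual$n)

  one <- group_mean_survival(reg, "average")
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_percent,
               mean(reg$estimates$percent[reg$estimates$stratum ==
                                            "average"]))
  expect_equal(nrow(group_mean_survival(reg, "no-such-group")), 0)
})
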