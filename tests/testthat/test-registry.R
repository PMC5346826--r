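write_fixture_files <- function(patients, families, dir) {
  mol_cols <- c("germline_mutation", "ihc_result", "msi_status",
                "mutyh_biallelic")
  readr::write_csv(patients[, setdiff(names(patients), mol_cols)],
                   file.path(dir, "patients.csv"), na = "")
  sim_like <- structure(list(patients = patients, families = families,
                             truth = tibble::tibble()),
                        class = "crc_simulation")
  # reuse the exchange-format writer for the companion JSON
  tmp <- file.path(dir, "sim")
  write_simulation(sim_like, tmp)
  file.copy(file.path(tmp, "families.json"), file.path(dir, "families.json"),
            overwrite = TRUE)
  list(csv = file.path(dir, "patients.csv"),
       json = file.path(dir, "families.json"))
}

ten_patients <- function() {
  dplyr::bind_rows(lapply(1:10, function(i) {
    make_patient(sprintf("R%03d", i),
                 vital_status = ifelse(i > 7, "Dead", "Alive"),
                 survival_quality = ifelse(i > 7, "Dead",
                                           "Normal activity"),
                 diagnosis_age = 40 + i,
                 pt = c("T0", "T1", "T2", "T3", "T4")[(i %% 5) + 1],
                 pn = c("N0", "N1", "N2")[(i %% 3) + 1],
                 pm = ifelse(i %% 2 == 0, "M1", "M0"),
                 anemia = ifelse(i %% 2 == 0, "Yes", "No"),
                 tumor_topology = c("Cecum", "Rectum", "Sigmoid colon",
                                    "Colon", "Descending colon")[(i %% 5) + 1])
  }))
}

test_that("a clean fixture ingests completely", {
  dir <- withr::local_tempdir()
  fams <- amsterdam_pedigree("R001")
  paths <- write_fixture_files(ten_patients(), fams, dir)
  reg <- ingest_registry(paths$csv, paths$json)
  expect_equal(nrow(reg$patients), 10)
  expect_equal(sum(reg$ingest_report$status == "accepted"), 10)
  expect_equal(sum(reg$ingest_report$status == "rejected"), 0)
  expect_equal(nrow(reg$families), 3) # pedigree arrived via the JSON
  expect_equal(reg$assignments$subgroup[reg$assignments$patient_id == "R001"],
               "Suspected HNPCC")
})

test_that("malformed and duplicate rows are rejected with reasons", {
  dir <- withr::local_tempdir()
  bad <- ten_patients()
  bad$weight[3] <- -10
  bad <- dplyr::bind_rows(bad, make_patient("R001")) # duplicate id
  paths <- write_fixture_files(bad, tibble::tibble(patient_id = character(0)),
                               dir)
  reg <- ingest_registry(paths$csv, paths$json)
  rep <- reg$ingest_report
  expect_equal(nrow(reg$patients), 9)
  expect_equal(sum(rep$status == "rejected"), 2)
  expect_match(rep$reason[rep$row == 3], "weight")
  expect_match(rep$reason[rep$row == 11], "duplicate")

  unknown <- ten_patients()
  unknown$sex[5] <- "Martian"
  paths2 <- write_fixture_files(unknown,
                                tibble::tibble(patient_id = character(0)),
                                withr::local_tempdir())
  reg2 <- ingest_registry(paths2$csv)
  expect_match(reg2$ingest_report$reason[5], "sex.*Martian")
})

test_that("global search matches decoded labels case-insensitively", {
  reg <- build_registry(dplyr::bind_rows(
    make_patient("A1", hnpcc = "Yes"),
    make_patient("A2", tumor_topology = "Sigmoid colon"),
    make_patient("A3", vital_status = "Dead", survival_quality = "Dead")
  ))
  expect_equal(global_search(reg, "hnpcc"), "A1")
  expect_equal(global_search(reg, "sigmoid"), "A2")
  expect_equal(global_search(reg, ""), c("A1", "A2", "A3"))
  expect_equal(global_search(reg, "zzz-no-match"), character(0))
  expect_true("A3" %in% global_search(reg, "dead"))
})

test_that("special search is an exact-match conjunction", {
  sim <- simulate_registry(n_patients = 80, seed = 23)
  reg <- build_registry(sim$patients, sim$families)
  fap_ids <- reg$assignments$patient_id[reg$assignments$subgroup == "FAP"]
  expect_setequal(special_search(reg, subgroup = "FAP"), fap_ids)

  both <- special_search(reg, survival_status = "alive",
                         risk_group = "high")
  alive <- reg$patients$patient_id[
    tolower(reg$patients$vital_status) == "alive"]
  high <- reg$assignments$patient_id[reg$assignments$group == "high"]
  expect_setequal(both, intersect(alive, high))

  expect_equal(special_search(reg, id = "absent-id"), character(0))
  rng <- special_search(reg, survival_percent_range = c(0, 10))
  expect_true(all(reg$estimates$percent[
    match(rng, reg$estimates$patient_id)] <= 10))

  expect_error(special_search(reg), "at least one criterion")
  expect_error(special_search(reg, vital = "alive"), "unknown criterion")
})

test_that("search results survive an export/ingest round trip", {
  sim <- simulate_registry(n_patients = 50, seed = 29)
  reg <- build_registry(sim$patients, sim$families)
  dir <- withr::local_tempdir()
  export_registry(reg, dir)
  reg2 <- ingest_registry(file.path(dir, "patients.csv"),
                          file.path(dir, "families.json"))
  expect_equal(sum(reg2$ingest_report$status == "rejected"), 0)
  for (q in c("", "hnpcc", "sigmoid", "colonoscopy")) {
    expect_equal(global_search(reg2, q), global_search(reg, q), info = q)
  }
  expect_equal(special_search(reg2, risk_group = "high"),
               special_search(reg, risk_group = "high"))
  expect_equal(registry_state(reg2)$estimates,
               registry_state(reg)$estimates)
})

test_that("inserting an alive patient changes no existing estimate", {
  reg <- build_registry(ten_patients(),
                        config = registry_config(k = 2))
  before <- registry_state(reg)$estimates
  reg2 <- upsert_patient(reg, make_patient("NEW", diagnosis_age = 44))
  after <- registry_state(reg2)$estimates
  expect_equal(dplyr::filter(after, patient_id != "NEW"), before)
  expect_true("NEW" %in% after$patient_id)
  expect_equal(reg2$revision, reg$revision + 1L)
})

test_that("inserting a deceased clone zeroes the twin's estimate and its group mean", {
  reg <- build_registry(ten_patients(), config = registry_config(k = 1))
  est_before <- reg$estimates[reg$estimates$patient_id == "R001", ]
  expect_gt(est_before$percent, 0)
  mean_before <- group_mean_survival(reg, "average")$mean_percent

  clone <- reg$patients[reg$patients$patient_id == "R001", ]
  clone$patient_id <- "Z-clone"
  clone$vital_status <- "Dead"
  clone$survival_quality <- "Dead"
  reg2 <- upsert_patient(reg, clone)
  est_after <- reg2$estimates[reg2$estimates$patient_id == "R001", ]
  expect_equal(est_after$percent, 0)
  expect_equal(est_after$neighbors[[1]]$neighbor_id, "Z-clone")
  expect_lt(group_mean_survival(reg2, "average")$mean_percent, mean_before)
  expect_gt(group_mean_survival(reg2, "average")$last_updated,
            group_mean_survival(reg, "average")$last_updated)
})

test_that("editing molecular findings moves a suspected HNPCC patient's stratum", {
  patients <- dplyr::bind_rows(
    make_patient("S", diagnosis_age = 45),
    make_patient("H2", hnpcc = "Yes"),
    ten_patients()
  )
  reg <- build_registry(patients, amsterdam_pedigree("S"),
                        config = registry_config(k = 2))
  expect_equal(reg$assignments$subgroup[reg$assignments$patient_id == "S"],
               "Suspected HNPCC")
  rec <- reg$patients[reg$patients$patient_id == "S", ]
  rec$germline_mutation <- "yes"
  reg2 <- upsert_patient(reg, rec)
  expect_equal(reg2$assignments$subgroup[reg2$assignments$patient_id == "S"],
               "HNPCC")
  expect_false("Suspected HNPCC" %in% reg2$stats$stratum)
  expect_equal(reg2$stats$n[reg2$stats$stratum == "HNPCC"], 2L)
  # the moved patient's estimate now lives in the HNPCC stratum
  expect_equal(
    reg2$estimates$stratum[reg2$estimates$patient_id == "S"], "HNPCC")
})

test_that("incremental updates equal a full rebuild over random edit mixes", {
  sim <- simulate_registry(n_patients = 60, seed = 37)
  reg <- build_registry(sim$patients, sim$families)
  set.seed(373)
  for (step in 1:8) {
    pid <- sample(reg$patients$patient_id, 1)
    rec <- reg$patients[reg$patients$patient_id == pid, ]
    switch(sample(4, 1),
           {
             rec$vital_status <- ifelse(tolower(rec$vital_status) == "alive",
                                        "Dead", "Alive")
             rec$survival_quality <- ifelse(rec$vital_status == "Dead",
                                            "Dead", "Normal activity")
           },
           rec$germline_mutation <- "yes",
           rec$pm <- sample(c("M0", "M1"), 1),
           rec$ibd <- sample(c("Yes", "No"), 1))
    reg <- upsert_patient(reg, rec)
    full <- build_registry(reg$patients, reg$families, config = reg$config)
    expect_equal(registry_state(reg), registry_state(full),
                 info = paste("step", step, "pid", pid))
  }
  expect_equal(reg$revision, 1L + 8L)
  expect_equal(nrow(reg$log), 9)
  expect_true(all(diff(reg$log$revision) > 0))
})

test_that("update_on_change rejects unknown ids and upsert validates", {
  reg <- build_registry(ten_patients())
  expect_error(update_on_change(reg, "nope"), "lookup error")
  expect_error(upsert_patient(reg, make_patient("bad", weight = -1)),
               "invalid record")
})
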