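test_that("Amsterdam II clauses evaluate a qualifying pedigree", {
  ped <- amsterdam_pedigree("X")
  res <- meets_amsterdam_ii(ped, fap_excluded = TRUE)
  expect_true(res$met)
  expect_true(all(unlist(res[grepl("^clause_", names(res))])))

  empty <- meets_amsterdam_ii(tibble::tibble(), fap_excluded = TRUE)
  expect_false(empty$met)
  expect_false(empty$clause_three_affected)
  expect_false(empty$clause_fdr)
  expect_false(empty$clause_age_under_50)

  old <- dplyr::mutate(ped, age_at_diagnosis = c(55, 62, 58))
  res_old <- meets_amsterdam_ii(old, fap_excluded = TRUE)
  expect_false(res_old$met)
  expect_false(res_old$clause_age_under_50)
  expect_true(res_old$clause_three_affected) # only the age clause flipped

  expect_false(meets_amsterdam_ii(ped, fap_excluded = FALSE)$met)
  # non-successive generations do not count as two generations
  gap <- dplyr::mutate(ped, generation = c(1L, 1L, 3L))
  expect_false(meets_amsterdam_ii(gap, fap_excluded = TRUE)$clause_generations)
})

test_that("Bethesda clauses fire individually", {
  young <- meets_bethesda(make_patient(diagnosis_age = 42), NULL)
  expect_true(young$met)
  expect_true(young$clause_age50)

  neg <- meets_bethesda(make_patient(diagnosis_age = 70, msi_status = "MSS"),
                        NULL)
  expect_false(neg$met)

  msi <- meets_bethesda(make_patient(diagnosis_age = 55,
                                     msi_status = "MSI-high"), NULL)
  expect_true(msi$met)
  expect_true(msi$clause_msi_young)
  expect_false(msi$clause_age50)

  # clause set is configurable
  cfg <- risk_config(bethesda_clauses = c("metachronous"))
  expect_false(meets_bethesda(make_patient(diagnosis_age = 42), NULL,
                              cfg)$met)
})

test_that("the cascade assigns subgroups by priority with a rule trace", {
  susp <- make_patient("S", diagnosis_age = 45)
  asg <- classify_risk(susp, amsterdam_pedigree("S"))
  expect_equal(asg$subgroup, "Suspected HNPCC")
  expect_equal(asg$group, "high")
  expect_equal(asg$fired_rules[[1]][1], "suspected_hnpcc")

  ibd <- classify_risk(make_patient("I", ibd = "Yes"))
  expect_equal(ibd$subgroup, "IBD")
  expect_equal(ibd$group, "high")

  clean <- classify_risk(make_patient("C"))
  expect_equal(clean$subgroup, "none")
  expect_equal(clean$group, "average")
  expect_length(clean$fired_rules[[1]], 0)

  fam <- classify_risk(make_patient("M", family_crc_history = "Yes"))
  expect_equal(fam$group, "moderate")

  # confirmed beats suspected: HNPCC flag wins over the pedigree rule
  conf <- classify_risk(make_patient("H", hnpcc = "Yes", diagnosis_age = 45),
                        amsterdam_pedigree("H"))
  expect_equal(conf$subgroup, "HNPCC")
  expect_true(all(c("hnpcc", "suspected_hnpcc") %in% conf$fired_rules[[1]]))

  pol <- classify_risk(make_patient("P", polyp_count = 30))
  expect_equal(pol$subgroup, "Suspected FAP")
  afap <- classify_risk(make_patient("A", polyp_count = 30,
                                     germline_mutation = "yes"))
  expect_equal(afap$subgroup, "AFAP")
  fap <- classify_risk(make_patient("F", fap = "Yes", polyp_count = 500))
  expect_equal(fap$subgroup, "FAP")
  myh <- classify_risk(make_patient("Y", mutyh_biallelic = "yes"))
  expect_equal(myh$subgroup, "MYH")
})

test_that("molecular evidence promotes suspected HNPCC and is idempotent", {
  base <- make_patient("S", diagnosis_age = 45)
  ped <- amsterdam_pedigree("S")

  mut <- dplyr::mutate(base, germline_mutation = "yes")
  a1 <- apply_molecular_update(classify_risk(base, ped), mut)
  expect_equal(a1$subgroup, "HNPCC")
  expect_true(any(grepl("molecular_update", a1$fired_rules[[1]])))

  ihc <- dplyr::mutate(base, ihc_result = "abnormal",
                       msi_status = "MSI-high")
  a2 <- apply_molecular_update(classify_risk(base, ped), ihc)
  expect_equal(a2$subgroup, "HNPCC")

  untested <- dplyr::mutate(base, ihc_result = "normal")
  a3 <- apply_molecular_update(classify_risk(base, ped), untested)
  expect_equal(a3$subgroup, "Suspected HNPCC")

  # idempotence: a second application changes nothing
  a1_again <- apply_molecular_update(a1, mut)
  expect_equal(a1_again$subgroup, a1$subgroup)
  expect_equal(a1_again$fired_rules, a1$fired_rules)
})

test_that("screening recommendations come from the table, or fail loudly", {
  asg <- classify_risk(dplyr::bind_rows(
    make_patient("H", hnpcc = "Yes"),
    make_patient("C")
  ))
  rec <- recommend_screening(asg)
  expect_equal(rec$method[rec$patient_id == "H"], "colonoscopy")
  expect_equal(rec$method[rec$patient_id == "C"], "FIT")
  expect_equal(rec$start_age[rec$patient_id == "C"], 50L)

  crippled <- dplyr::filter(default_screening_table(), subgroup != "MYH")
  myh <- classify_risk(make_patient("Y", mutyh_biallelic = "yes"))
  expect_error(recommend_screening(myh, crippled),
               "configuration error.*MYH")
  expect_error(
    recommend_screening(asg, dplyr::mutate(default_screening_table(),
                                           start_age = 0L)),
    "configuration error")
})

test_that("classification is pure and total over a combinatorial grid", {
  grid <- tidyr::expand_grid(
    hnpcc = c("Yes", "No"),
    fap = c("Yes", "No"),
    ibd = c("Yes", "No"),
    family_crc_history = c("Yes", "No"),
    polyp_count = c(0, 15, 150),
    germline_mutation = c("yes", "untested"),
    diagnosis_age = c(42, 70)
  )
  grid$patient_id <- sprintf("G%04d", seq_len(nrow(grid)))
  patients <- dplyr::bind_rows(
    lapply(seq_len(nrow(grid)),
           function(i) do.call(make_patient, as.list(grid[i, ]))))
  fams <- dplyr::bind_rows(
    lapply(patients$patient_id[seq(1, nrow(grid), 3)], amsterdam_pedigree))
  asg1 <- classify_risk(patients, fams)
  asg2 <- classify_risk(patients, fams)
  expect_identical(asg1$subgroup, asg2$subgroup) # pure

  expect_true(all(asg1$subgroup %in% c("FAP", "AFAP", "Suspected FAP",
                                       "HNPCC", "Suspected HNPCC", "MYH",
                                       "IBD", "none")))
  high <- asg1$subgroup != "none"
  expect_true(all(asg1$group[high] == "high"))
  expect_true(all(lengths(asg1$fired_rules[high]) > 0))
  expect_true(all(asg1$group[!high] %in% c("average", "moderate")))
})
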