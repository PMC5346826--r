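# Fixture builders: one complete valid record with overridable fields, small
# cohorts, and a deterministic Amsterdam-II-positive pedigree.

make_patient <- function(id = "PT001", ...) {
  rec <- tibble::tibble(
    patient_id = id, weight = 70, height = 175,
    birthdate_persian = "1350-01-01", diagnosis_age = 55,
    sex = "Male", education = "High school", marital_status = "Married",
    ethnicity = "Fars", religion = "Muslim", location = "City",
    chemical_exposure = "No", tobacco = "No", alcohol = "No",
    oral_narcotic = "No", iv_drug = "No", nsaids = "No",
    tumor_size_mm = 25, tumor_topology = "Cecum",
    tumor_morphology = "Adenocarcinoma",
    histological_grade = "Well differentiated",
    pt = "T2", pn = "N0", pm = "M0", pathologic_grade = "II",
    advancing_grade = "Primary grade", treatment = "Surgery",
    hnpcc = "No", fap = "No", diabetes = "No", hypertension = "No",
    ibd = "No", personal_crc_history = "No", family_crc_history = "No",
    perforation = "No", fuo = "No", obstruction = "No",
    abdominal_pain = "No", anemia = "No", rectal_bleeding = "No",
    bowel_habit_change = "No", weakness = "No", weight_loss = "No",
    polyp_count = 0, survival_quality = "Normal activity",
    vital_status = "Alive", survival_time = NA_real_,
    referral_type = "screening program",
    germline_mutation = "untested", ihc_result = "untested",
    msi_status = "untested", mutyh_biallelic = "untested")
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

make_cohort <- function(specs) {
  dplyr::bind_rows(lapply(names(specs), function(id) {
    do.call(make_patient, c(list(id = id), specs[[id]]))
  }))
}

# deterministic pedigree satisfying every Amsterdam II clause
amsterdam_pedigree <- function(id) {
  tibble::tibble(
    patient_id = id,
    relation_degree = c("first", "first", "second"),
    generation = c(1L, 1L, 2L),
    cancer_site = c("CRC", "CRC", "endometrial"),
    age_at_diagnosis = c(45, 62, 58),
    pathology_verified = c(TRUE, FALSE, TRUE)
  )
}

# the shipped codebook's expected content, frozen independently:
# every field's label -> code map in slot order (with the two documented
# collision remaps: ethnicity Other -> 5, topology renumbered 1..10)
expected_codebook_pairs <- function() {
  list(
    age_category = c("<45" = 1, "45-64" = 2, ">=65" = 3),
    sex = c(Female = 1, Male = 2, Transsexual = 3),
    education = c(Illiterate = 1, "Primary school" = 2, "High school" = 3,
                  University = 4),
    marital_status = c(Married = 1, Single = 2, Divorced = 3, Widowed = 4),
    ethnicity = c(Fars = 1, Turk = 2, Kord = 3, Lor = 4, Other = 5),
    religion = c(Muslim = 1, Christian = 2, Jewish = 3, Zoroastrian = 4,
                 Other = 5),
    location = c(City = 1, Village = 2),
    bmi_category = c("<18.5" = 1, "18.5-24.9" = 2, "25-29.9" = 3,
                     ">=30" = 4),
    chemical_exposure = c(Yes = 1, No = 0, Unknown = 3),
    tobacco = c(Yes = 1, No = 0, Unknown = 3),
    alcohol = c(Yes = 1, No = 0, Unknown = 3),
    oral_narcotic = c(Yes = 1, No = 0, Unknown = 3),
    iv_drug = c(Yes = 1, No = 0, Unknown = 3),
    nsaids = c(Yes = 1, No = 0, Unknown = 3),
    tumor_size_class = c("Below threshold" = 1, "Above threshold" = 2),
    tumor_topology = c(Cecum = 1, "Ascending colon" = 2,
                       "Hepatic flexure" = 3, "Transverse colon" = 4,
                       "Splenic flexure" = 5, "Descending colon" = 6,
                       "Sigmoid colon" = 7, Colon = 8,
                       "Rectosigmoid junction" = 9, Rectum = 10),
    tumor_morphology = c(Adenocarcinoma = 1, "Mucinous adenocarcinoma" = 2,
                         "Signet ring cell carcinoma" = 3,
                         "Squamous cell carcinoma" = 4,
                         "Squamous-cell adenocarcinoma" = 5,
                         "Medullary carcinoma" = 6),
    histological_grade = c("Undetermined grade" = 1,
                           "Well differentiated" = 2,
                           "Moderately differentiated" = 3,
                           "Poorly differentiated" = 4,
                           Undifferentiated = 5),
    pt = c(T0 = 0, T1 = 1, T2 = 2, T3 = 3, T4 = 4),
    pn = c(N0 = 0, N1 = 1, N2 = 2),
    pm = c(M0 = 0, M1 = 1),
    pathologic_grade = c(I = 1, II = 2, III = 3, IV = 4),
    advancing_grade = c("Primary grade" = 1, "Advanced grade" = 2),
    treatment = c(Surgery = 1, "Chemotherapy/Radiotherapy" = 2, Biopsy = 3),
    hnpcc = c(Yes = 1, No = 0),
    fap = c(Yes = 1, No = 0),
    diabetes = c(Yes = 1, No = 0, Unknown = 3),
    hypertension = c(Yes = 1, No = 0, Unknown = 3),
    ibd = c(Yes = 1, No = 0, Unknown = 3),
    personal_crc_history = c(Yes = 1, No = 0, Unknown = 3),
    family_crc_history = c(Yes = 1, No = 0, Unknown = 3),
    perforation = c(Yes = 1, No = 0),
    fuo = c(Yes = 1, No = 0),
    obstruction = c(Yes = 1, No = 0),
    abdominal_pain = c(Yes = 1, No = 0),
    anemia = c(Yes = 1, No = 0),
    rectal_bleeding = c(Yes = 1, No = 0),
    bowel_habit_change = c(Yes = 1, No = 0),
    weakness = c(Yes = 1, No = 0),
    weight_loss = c(Yes = 1, No = 0),
    survival_quality = c("Normal activity" = 1, "Non-normal activity" = 2,
                         Dead = 3),
    vital_status = c(Alive = 1, Dead = 0)
  )
}

# registry state stripped to the value-bearing parts (log timestamps and the
# stats revision stamps are process metadata, not derived values)
registry_state <- function(reg) {
  list(
    estimates = dplyr::arrange(dplyr::select(reg$estimates, -"neighbors"),
                               patient_id),
    assignments = dplyr::arrange(
      dplyr::select(reg$assignments, -"fired_rules"), patient_id),
    stats = dplyr::select(reg$stats, -"last_updated")
  )
}
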