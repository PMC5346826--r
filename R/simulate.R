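# Synthetic registry generator. Emulates a CRC screening registry with
# hereditary high-risk subgroups, a deceased reference pool and *planted*
# prognosis structure: each patient's true survival probability is a
# logistic function of a few encoded tumor-burden features, and vital status
# is drawn from it. The generator never uses the estimator's mechanics, so
# recovery of the planted ranking by the similarity estimator is an honest
# calibration check rather than a self-fulfilling one. Identical seeds give
# identical output.

default_subgroup_mix <- function() {
  c(FAP = 0.05, AFAP = 0.03, "Suspected FAP" = 0.04, HNPCC = 0.08,
    "Suspected HNPCC" = 0.10, MYH = 0.03, IBD = 0.07, average = 0.60)
}

default_risk_weights <- function() {
  c(pt = -0.45, pn = -0.6, pm = -1.4, pathologic_grade = -0.5,
    advancing_grade = -0.7, histological_grade = -0.25,
    age_category = -0.35, anemia = -0.3, weight_loss = -0.3,
    obstruction = -0.25)
}

sample_from <- function(book, field, n, prob = NULL) {
  labels <- names(book$specs[[field]])
  sample(labels, n, replace = TRUE, prob = prob)
}

# ordinal sample tied to a latent severity z, preserving the target marginal:
# u = Phi((z + noise)/sd_total) is uniform, cut at the cumulative marginals
sample_severity_ordinal <- function(labels, z, probs, noise_sd) {
  u <- stats::pnorm((z + stats::rnorm(length(z), 0, noise_sd)) /
                      sqrt(1 + noise_sd^2))
  labels[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
}

# yes/no flag whose log-odds shift with latent severity
sample_severity_flag <- function(z, base_rate, slope = 0.8) {
  p <- stats::plogis(stats::qlogis(base_rate) + slope * z)
  ifelse(stats::runif(length(z)) < p, "Yes", "No")
}

#' Generate a pedigree that provably meets (or fails) Amsterdam II
#'
#' Builds a relatives table that satisfies every Amsterdam II clause, or —
#' for `meets_amsterdam = FALSE` — violates exactly one randomly chosen
#' clause. The result is verified against [meets_amsterdam_ii()] at
#' generation time; the broken clause (if any) is recorded in the
#' `"failed_clause"` attribute.
#'
#' @param meets_amsterdam Should the pedigree satisfy the criteria?
#' @param seed Optional integer seed (omit when an outer generator already
#'   controls the random state).
#' @param config [risk_config()].
#' @return A tibble of relatives (`relation_degree`, `generation`,
#'   `cancer_site`, `age_at_diagnosis`, `pathology_verified`) with attribute
#'   `"failed_clause"` (`NA` when the criteria are met).
#' @export
generate_pedigree <- function(meets_amsterdam = TRUE, seed = NULL,
                              config = risk_config()) {
  if (!is.null(seed)) set.seed(seed)
  base <- tibble::tibble(
    relation_degree = c("first", "first", "second"),
    generation = c(1L, 1L, 2L),
    cancer_site = c("CRC", "CRC",
                    sample(c("CRC", "endometrial", "small bowel"), 1)),
    age_at_diagnosis = c(sample(35:49, 1), sample(50:75, 1),
                         sample(45:75, 1)),
    pathology_verified = c(TRUE, sample(c(TRUE, FALSE), 1),
                           sample(c(TRUE, FALSE), 1))
  )
  failed <- NA_character_
  ped <- base
  if (!meets_amsterdam) {
    failed <- sample(c("three_affected", "fdr", "generations",
                       "age_under_50", "pathology"), 1)
    ped <- switch(
      failed,
      three_affected = base[1:2, ],
      fdr = dplyr::mutate(base, relation_degree = "second"),
      generations = dplyr::mutate(base, generation = 1L),
      age_under_50 = dplyr::mutate(
        base, age_at_diagnosis = sample(50:80, 3, replace = TRUE)),
      pathology = dplyr::mutate(base, pathology_verified = FALSE)
    )
    res <- meets_amsterdam_ii(ped, fap_excluded = TRUE, config = config)
    stopifnot(!res$met, !res[[paste0("clause_", failed)]])
  } else {
    res <- meets_amsterdam_ii(ped, fap_excluded = TRUE, config = config)
    stopifnot(res$met)
  }
  attr(ped, "failed_clause") <- failed
  ped
}

#' Generate a synthetic screening registry with planted prognosis structure
#'
#' Samples `n_patients` complete, valid minimum-data-set records. Each
#' patient is drawn into a target risk stratum (`subgroup_mix`), and the
#' stratum's determining fields are set accordingly: FAP/AFAP flags, adenoma
#' counts and germline findings for the polyposis groups, an
#' Amsterdam-II-satisfying pedigree with an early-onset proband for suspected
#' HNPCC, the HNPCC/IBD/MUTYH flags for their groups. A share of average-risk
#' patients carries a family CRC history (the moderate tier).
#'
#' A latent per-patient disease severity drives the tumor-burden fields
#' jointly (pT/pN/pM, grades, tumor size, stage-linked symptoms), emulating
#' the strong correlation of stage components in real tumours; the remaining
#' fields are sampled independently from the codebook label sets.
#'
#' The planted truth is a logistic survival probability
#' `p_i = plogis(c + w . x_i)` over the *complete* encoded features `x_i`
#' (missing entries contribute zero), with weights `planted_risk_weights` on
#' tumor-burden slots and the intercept `c` calibrated so the expected
#' deceased share equals `deceased_fraction`; vital status is then drawn as
#' `Bernoulli(1 - p_i)`. Missingness (rate `missingness_rate` per maskable
#' field) is applied *after* the truth is fixed, as an observation process.
#'
#' @param n_patients Number of patients.
#' @param seed Mandatory integer seed; identical seeds give identical output.
#' @param subgroup_mix Named proportions over the seven high-risk subgroups
#'   plus `average`; must sum to 1.
#' @param deceased_fraction Expected share of deceased patients, in (0, 1).
#' @param planted_risk_weights Named numeric vector of per-code weights over
#'   encoded slots.
#' @param missingness_rate Per-field masking probability for the
#'   non-determining fields, in [0, 1).
#' @param reference_year Gregorian census year used to encode ages.
#' @return A list of class `crc_simulation`: `patients`, `families`, and the
#'   never-ingested `truth` table (`patient_id`, `risk_score`,
#'   `survival_prob`, `target_subgroup`, `dead`).
#' @export
simulate_registry <- function(n_patients = 500, seed,
                              subgroup_mix = default_subgroup_mix(),
                              deceased_fraction = 0.3,
                              planted_risk_weights = default_risk_weights(),
                              missingness_rate = 0.02,
                              reference_year = 2017) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for simulate_registry", call. = FALSE)
  }
  stopifnot(abs(sum(subgroup_mix) - 1) < 1e-8,
            deceased_fraction > 0, deceased_fraction < 1,
            missingness_rate >= 0, missingness_rate < 1)
  set.seed(as.integer(seed))
  book <- crc_codebook()
  n <- as.integer(n_patients)
  id <- sprintf("P%05d", seq_len(n))
  target <- sample(names(subgroup_mix), n, replace = TRUE,
                   prob = subgroup_mix)

  # one latent disease severity per patient drives the tumor-burden fields
  # jointly (stage components of real tumours are strongly correlated)
  z <- stats::rnorm(n)

  age <- pmin(pmax(round(stats::rnorm(n, 58, 13)), 25), 90)
  jy <- reference_year - 621 - age
  jm <- sample(1:12, n, replace = TRUE)
  jd <- vapply(seq_len(n),
               function(i) sample(seq_len(jalali_month_length(jy[i], jm[i])),
                                  1),
               integer(1))
  diagnosis_age <- pmax(25, age - sample(0:10, n, replace = TRUE))

  yn <- function(p_yes) {
    sample(c("Yes", "No"), n, replace = TRUE, prob = c(p_yes, 1 - p_yes))
  }
  ynu <- function(p_yes, p_unknown = 0.05) {
    sample(c("Yes", "No", "Unknown"), n, replace = TRUE,
           prob = c(p_yes, 1 - p_yes - p_unknown, p_unknown))
  }

  patients <- tibble::tibble(
    patient_id = id,
    weight = round(pmin(pmax(stats::rnorm(n, 72, 12), 40), 130), 1),
    height = round(pmin(pmax(stats::rnorm(n, 168, 9), 140), 200), 1),
    birthdate_persian = sprintf("%04d-%02d-%02d", jy, jm, jd),
    diagnosis_age = diagnosis_age,
    sex = sample_from(book, "sex", n, prob = c(0.47, 0.52, 0.01)),
    education = sample_from(book, "education", n,
                            prob = c(0.2, 0.35, 0.3, 0.15)),
    marital_status = sample_from(book, "marital_status", n,
                                 prob = c(0.7, 0.15, 0.05, 0.1)),
    ethnicity = sample_from(book, "ethnicity", n,
                            prob = c(0.5, 0.25, 0.1, 0.1, 0.05)),
    religion = sample_from(book, "religion", n,
                           prob = c(0.94, 0.02, 0.01, 0.01, 0.02)),
    location = sample_from(book, "location", n, prob = c(0.7, 0.3)),
    chemical_exposure = ynu(0.08),
    tobacco = ynu(0.25),
    alcohol = ynu(0.08),
    oral_narcotic = ynu(0.06),
    iv_drug = ynu(0.02),
    nsaids = ynu(0.2),
    tumor_size_mm = round(stats::rlnorm(n, log(25) + 0.25 * z, 0.4)),
    tumor_topology = sample_from(book, "tumor_topology", n),
    tumor_morphology = sample_from(book, "tumor_morphology", n,
                                   prob = c(0.6, 0.15, 0.08, 0.07, 0.05,
                                            0.05)),
    histological_grade = sample_severity_ordinal(
      names(book$specs$histological_grade), z,
      c(0.08, 0.3, 0.35, 0.2, 0.07), noise_sd = 1.0),
    pt = sample_severity_ordinal(names(book$specs$pt), z,
                                 c(0.04, 0.16, 0.25, 0.35, 0.2),
                                 noise_sd = 0.6),
    pn = sample_severity_ordinal(names(book$specs$pn), z,
                                 c(0.5, 0.3, 0.2), noise_sd = 0.8),
    pm = sample_severity_ordinal(names(book$specs$pm), z,
                                 c(0.75, 0.25), noise_sd = 0.9),
    pathologic_grade = sample_severity_ordinal(
      names(book$specs$pathologic_grade), z,
      c(0.25, 0.35, 0.25, 0.15), noise_sd = 0.8),
    advancing_grade = sample_severity_ordinal(
      names(book$specs$advancing_grade), z,
      c(0.6, 0.4), noise_sd = 0.8),
    treatment = sample_from(book, "treatment", n, prob = c(0.5, 0.35, 0.15)),
    hnpcc = "No", fap = "No",
    diabetes = ynu(0.15), hypertension = ynu(0.25),
    ibd = "No",
    personal_crc_history = ynu(0.06),
    family_crc_history = ynu(0.1),
    perforation = yn(0.04), fuo = yn(0.05),
    obstruction = sample_severity_flag(z, 0.15),
    abdominal_pain = yn(0.5),
    anemia = sample_severity_flag(z, 0.35),
    rectal_bleeding = yn(0.45),
    bowel_habit_change = yn(0.4),
    weakness = sample_severity_flag(z, 0.3, slope = 0.5),
    weight_loss = sample_severity_flag(z, 0.35),
    polyp_count = sample(0:5, n, replace = TRUE),
    survival_quality = NA_character_, vital_status = NA_character_,
    survival_time = NA_real_,
    referral_type = sample(c("screening program", "physician referral",
                             "self-referral"), n, replace = TRUE),
    germline_mutation = "untested",
    ihc_result = "untested",
    msi_status = sample(c("untested", "MSS", "MSI-low"), n, replace = TRUE,
                        prob = c(0.7, 0.25, 0.05)),
    mutyh_biallelic = "untested"
  )

  # stratum-determining fields
  fam_rows <- list()
  for (i in seq_len(n)) {
    tg <- target[i]
    if (tg == "FAP") {
      patients$fap[i] <- "Yes"
      patients$polyp_count[i] <- sample(100:1000, 1)
      patients$germline_mutation[i] <- "yes"
    } else if (tg == "AFAP") {
      patients$polyp_count[i] <- sample(10:99, 1)
      patients$germline_mutation[i] <- "yes"
    } else if (tg == "Suspected FAP") {
      patients$polyp_count[i] <- sample(10:150, 1)
    } else if (tg == "HNPCC") {
      patients$hnpcc[i] <- "Yes"
    } else if (tg == "Suspected HNPCC") {
      patients$diagnosis_age[i] <- sample(30:49, 1)
      patients$family_crc_history[i] <- "Yes"
      ped <- generate_pedigree(TRUE)
      ped$patient_id <- patients$patient_id[i]
      fam_rows[[length(fam_rows) + 1]] <- ped
    } else if (tg == "MYH") {
      patients$mutyh_biallelic[i] <- "yes"
    } else if (tg == "IBD") {
      patients$ibd[i] <- "Yes"
    } else if (stats::runif(1) < 0.15) {
      # moderate tier: family history without hereditary criteria
      patients$family_crc_history[i] <- "Yes"
      ped <- generate_pedigree(FALSE)
      ped$patient_id <- patients$patient_id[i]
      fam_rows[[length(fam_rows) + 1]] <- ped
    }
  }
  families <- if (length(fam_rows) > 0) {
    dplyr::bind_rows(fam_rows)[, c("patient_id", "relation_degree",
                                   "generation", "cancer_site",
                                   "age_at_diagnosis",
                                   "pathology_verified")]
  } else {
    tibble::tibble(patient_id = character(0))
  }

  # planted truth from the complete encoding
  patients$vital_status <- "Alive"
  patients$survival_quality <- "Normal activity"
  enc <- encode_patients(patients, book = book,
                         reference_year = reference_year)
  w_fields <- names(planted_risk_weights)
  missing_fields <- setdiff(w_fields, book$fields)
  if (length(missing_fields) > 0) {
    stop("planted_risk_weights name unknown slot(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(enc[, w_fields, drop = FALSE])
  storage.mode(X) <- "numeric"
  X[is.na(X)] <- 0
  score <- as.vector(X %*% planted_risk_weights)
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(c0 + score)) - (1 - deceased_fraction),
    interval = c(-30, 30), tol = 1e-10)$root
  p <- stats::plogis(intercept + score)
  dead <- stats::rbinom(n, 1, 1 - p) == 1

  patients$vital_status <- ifelse(dead, "Dead", "Alive")
  patients$survival_quality <- ifelse(
    dead, "Dead",
    sample(c("Normal activity", "Non-normal activity"), n, replace = TRUE,
           prob = c(0.8, 0.2)))
  patients$survival_time <- ifelse(
    dead, pmax(1, round(120 * p + stats::rnorm(n, 0, 6))), NA_real_)

  # observation-process missingness, never on stratum determinants/outcomes
  if (missingness_rate > 0) {
    maskable <- c("weight", "height", "education", "marital_status",
                  "ethnicity", "religion", "location", "chemical_exposure",
                  "tobacco", "alcohol", "oral_narcotic", "iv_drug", "nsaids",
                  "tumor_size_mm", "tumor_topology", "tumor_morphology",
                  "histological_grade", "treatment", "diabetes",
                  "hypertension")
    for (f in maskable) {
      mask <- stats::runif(n) < missingness_rate
      patients[[f]][mask] <- NA
    }
  }

  structure(list(
    patients = patients,
    families = families,
    truth = tibble::tibble(patient_id = id, risk_score = score,
                           survival_prob = p, target_subgroup = target,
                           dead = dead),
    seed = as.integer(seed),
    reference_year = reference_year
  ), class = "crc_simulation")
}

#' @export
print.crc_simulation <- function(x, ...) {
  cat("<crc_simulation>", nrow(x$patients), "patients, seed", x$seed, "\n")
  cat("  deceased:", sum(x$truth$dead), "\n")
  print(table(x$truth$target_subgroup))
  invisible(x)
}

#' Write a simulation to the registry exchange format
#'
#' Emits the same `patients.csv` + companion `families.json` pair that
#' [ingest_registry()] reads, plus `truth.csv` (the planted truth — kept
#' separate and never ingested).
#'
#' @param sim A `crc_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "crc_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mol_cols <- c("germline_mutation", "ihc_result", "msi_status",
                "mutyh_biallelic")
  readr::write_csv(
    sim$patients[, setdiff(names(sim$patients), mol_cols), drop = FALSE],
    file.path(dir, "patients.csv"), na = "")
  doc <- companion_json_doc(sim$patients, sim$families)
  jsonlite::write_json(doc, file.path(dir, "families.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
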