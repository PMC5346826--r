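# Guideline rule engine: Amsterdam II and revised-Bethesda evaluation,
# priority-ordered assignment into the hereditary high-risk subgroups,
# molecular-evidence status transitions, and screening recommendations.
#
# The clause sets and thresholds live in a single config object
# (risk_config()) because the guideline versions admit local variation; the
# shipped defaults are the widely published criteria, documented clause by
# clause in the methods vignette.

#' Rule-engine configuration
#'
#' All tunable thresholds and clause toggles of the risk rule engine.
#'
#' @param hnpcc_sites Cancer sites counted as HNPCC-associated (Lynch
#'   spectrum) in pedigree clauses.
#' @param amsterdam_age Diagnosis-age cut (years) for the Amsterdam II
#'   early-onset clause; default 50.
#' @param bethesda_age Proband diagnosis-age cut for the first Bethesda
#'   clause; default 50.
#' @param bethesda_msi_age Diagnosis-age cut for the MSI-high Bethesda
#'   clause; default 60.
#' @param bethesda_clauses Which Bethesda clauses are active; any nonempty
#'   subset of `"age50"`, `"metachronous"`, `"msi_young"`, `"fdr_young"`,
#'   `"two_relatives"`.
#' @param fap_polyp_min Adenoma count at or above which a confirmed polyposis
#'   is classical FAP; default 100.
#' @param afap_polyp_min Lower adenoma bound of the attenuated (AFAP)
#'   phenotype; default 10.
#' @param moderate_tier Whether family CRC history without hereditary
#'   criteria assigns the moderate tier (else such patients stay average).
#' @return A list of class `crc_risk_config`.
#' @export
risk_config <- function(hnpcc_sites = c("CRC", "endometrial", "small bowel",
                                        "ureter/renal pelvis"),
                        amsterdam_age = 50,
                        bethesda_age = 50,
                        bethesda_msi_age = 60,
                        bethesda_clauses = c("age50", "metachronous",
                                             "msi_young", "fdr_young",
                                             "two_relatives"),
                        fap_polyp_min = 100,
                        afap_polyp_min = 10,
                        moderate_tier = TRUE) {
  bethesda_clauses <- match.arg(bethesda_clauses, several.ok = TRUE)
  structure(list(hnpcc_sites = tolower(hnpcc_sites),
                 amsterdam_age = amsterdam_age,
                 bethesda_age = bethesda_age,
                 bethesda_msi_age = bethesda_msi_age,
                 bethesda_clauses = bethesda_clauses,
                 fap_polyp_min = fap_polyp_min,
                 afap_polyp_min = afap_polyp_min,
                 moderate_tier = moderate_tier),
            class = "crc_risk_config")
}

# normalise a yes/no/unknown-ish column to lowercase character
lc <- function(x) tolower(as.character(x))

is_yes <- function(x) !is.na(x) & lc(x) == "yes"

#' Evaluate the Amsterdam II criteria on one pedigree
#'
#' A pedigree satisfies Amsterdam II when all of the following hold: at least
#' three relatives with an HNPCC-associated cancer; at least one of them a
#' first-degree relative; the affected relatives span at least two successive
#' generations; at least one diagnosis before age 50; FAP excluded in any CRC
#' case; and at least one tumour verified by pathology. The "one is a
#' first-degree relative of the other two" clause is operationalised as "at
#' least one affected first-degree relative", since the relatives table
#' records degree relative to the proband rather than pairwise kinship;
#' generations come from the `generation` (lineage) identifier, which must
#' contain two adjacent integer values among the affected.
#'
#' @param history Data frame of relatives for one proband, with columns
#'   `relation_degree` (`"first"`/`"second"`), `generation` (integer
#'   generation index, e.g. 0 = proband's, 1 = parents'), `cancer_site`,
#'   `age_at_diagnosis`, `pathology_verified` (logical). May be empty.
#' @param fap_excluded Has FAP been excluded in the CRC cases?
#' @param config [risk_config()].
#' @return One-row tibble: `met` plus one logical column per clause
#'   (`clause_three_affected`, `clause_fdr`, `clause_generations`,
#'   `clause_age_under_50`, `clause_fap_excluded`, `clause_pathology`) and
#'   `n_affected`.
#' @export
meets_amsterdam_ii <- function(history, fap_excluded = TRUE,
                               config = risk_config()) {
  history <- if (is.null(history)) {
    tibble::tibble()
  } else {
    tibble::as_tibble(history)
  }
  if (nrow(history) > 0) {
    affected <- history[lc(history$cancer_site) %in% config$hnpcc_sites, ,
                        drop = FALSE]
  } else {
    affected <- history
  }
  n_aff <- nrow(affected)
  gen <- if (n_aff > 0) sort(unique(as.integer(affected$generation))) else integer(0)
  clauses <- tibble::tibble(
    clause_three_affected = n_aff >= 3,
    clause_fdr = n_aff > 0 && any(lc(affected$relation_degree) == "first"),
    clause_generations = length(gen) >= 2 && any(diff(gen) == 1),
    clause_age_under_50 = n_aff > 0 &&
      any(affected$age_at_diagnosis < config$amsterdam_age, na.rm = TRUE),
    clause_fap_excluded = isTRUE(fap_excluded),
    clause_pathology = n_aff > 0 &&
      any(as.logical(affected$pathology_verified), na.rm = TRUE)
  )
  dplyr::bind_cols(
    tibble::tibble(met = all(unlist(clauses)), n_affected = n_aff),
    clauses
  )
}

#' Evaluate the revised Bethesda guidelines for one proband
#'
#' True when any active clause fires: CRC diagnosed before 50
#' (`age50`); synchronous or metachronous HNPCC-associated tumours,
#' operationalised as a personal CRC history in a CRC proband
#' (`metachronous`); MSI-high tumour diagnosed before 60 (`msi_young`); a
#' first-degree relative with an HNPCC-related tumour diagnosed before 50
#' (`fdr_young`); two or more first- or second-degree relatives with
#' HNPCC-related tumours at any age (`two_relatives`). The active clause set
#' is configurable.
#'
#' @param patient One-row data frame with (at least) `diagnosis_age`,
#'   `msi_status`, `personal_crc_history`.
#' @param history Relatives table for this proband (may be empty or `NULL`).
#' @param config [risk_config()].
#' @return One-row tibble: `met` plus one logical column per clause.
#' @export
meets_bethesda <- function(patient, history = NULL, config = risk_config()) {
  patient <- tibble::as_tibble(patient)
  stopifnot(nrow(patient) == 1)
  history <- if (is.null(history)) tibble::tibble() else tibble::as_tibble(history)
  getf <- function(nm) if (nm %in% names(patient)) patient[[nm]] else NA
  dx_age <- suppressWarnings(as.numeric(getf("diagnosis_age")))
  msi <- lc(getf("msi_status"))

  if (nrow(history) > 0) {
    aff <- history[lc(history$cancer_site) %in% config$hnpcc_sites, ,
                   drop = FALSE]
  } else {
    aff <- history
  }
  clauses <- tibble::tibble(
    clause_age50 = !is.na(dx_age) && dx_age < config$bethesda_age,
    clause_metachronous = is_yes(getf("personal_crc_history")),
    clause_msi_young = !is.na(msi) && msi == "msi-high" &&
      !is.na(dx_age) && dx_age < config$bethesda_msi_age,
    clause_fdr_young = nrow(aff) > 0 &&
      any(lc(aff$relation_degree) == "first" &
            aff$age_at_diagnosis < config$bethesda_age, na.rm = TRUE),
    clause_two_relatives = nrow(aff) >= 2
  )
  active <- paste0("clause_", config$bethesda_clauses)
  dplyr::bind_cols(
    tibble::tibble(met = any(unlist(clauses[, active]))),
    clauses
  )
}

subgroup_levels <- function() {
  c("FAP", "AFAP", "Suspected FAP", "HNPCC", "Suspected HNPCC", "MYH",
    "IBD", "none")
}

#' Classify screening risk for every patient
#'
#' Priority-ordered rule cascade over the high-risk hereditary subgroups:
#' confirmed subgroups first (`FAP`, `AFAP`, `MYH`, `HNPCC`), then suspected
#' ones (`Suspected HNPCC` from Amsterdam II + Bethesda, `Suspected FAP` from
#' adenoma counts without molecular confirmation), then `IBD`; a family CRC
#' history without hereditary criteria gives the `moderate` tier, anything
#' else `average`. Exactly one subgroup per patient, decided by the fixed
#' priority order; every rule that fired is recorded in `fired_rules` (the
#' first entry decides).
#'
#' Shipped rule definitions (all thresholds from [risk_config()]):
#' * `FAP`: FAP flag set (unless the adenoma count is in the attenuated
#'   range), or an identified germline mutation with >= `fap_polyp_min`
#'   adenomas.
#' * `AFAP`: FAP flag or germline mutation with an attenuated adenoma count
#'   in `[afap_polyp_min, fap_polyp_min)`.
#' * `MYH`: biallelic MUTYH mutation.
#' * `HNPCC`: HNPCC flag set, or germline mutation in a patient meeting
#'   Amsterdam II or Bethesda.
#' * `Suspected HNPCC`: Amsterdam II and Bethesda both met, no molecular
#'   confirmation.
#' * `Suspected FAP`: adenoma count >= `afap_polyp_min` without
#'   confirmation.
#' * `IBD`: inflammatory bowel disease flag.
#'
#' @param patients Raw-record tibble (see [encode_patients()]); molecular
#'   columns `germline_mutation`, `ihc_result`, `msi_status`,
#'   `mutyh_biallelic` are read when present.
#' @param families Relatives table with a `patient_id` column joining it to
#'   `patients`, or `NULL`.
#' @param config [risk_config()].
#' @return A tibble: `patient_id`, `group` (`average`/`moderate`/`high`),
#'   `subgroup`, `amsterdam`, `bethesda` (logicals) and `fired_rules` (list
#'   column of character vectors, priority order, empty for average risk with
#'   no history).
#' @export
classify_risk <- function(patients, families = NULL,
                          config = risk_config()) {
  patients <- tibble::as_tibble(patients)
  n <- nrow(patients)
  id <- as.character(patients$patient_id)
  getf <- function(nm, default = NA) {
    if (nm %in% names(patients)) patients[[nm]] else rep(default, n)
  }

  fam_split <- if (is.null(families) || nrow(tibble::as_tibble(families)) == 0) {
    list()
  } else {
    split(tibble::as_tibble(families), as.character(families$patient_id))
  }

  fap_flag <- is_yes(getf("fap"))

  # Amsterdam II can only hold with >= 3 pedigree rows, so only probands with
  # a family history are evaluated; Bethesda's proband clauses are vectorised
  # and its pedigree clauses evaluated on the same subset.
  amst <- logical(n)
  dx_age <- suppressWarnings(as.numeric(getf("diagnosis_age")))
  msi <- lc(getf("msi_status"))
  beth_cl <- list(
    age50 = !is.na(dx_age) & dx_age < config$bethesda_age,
    metachronous = is_yes(getf("personal_crc_history")),
    msi_young = !is.na(msi) & msi == "msi-high" & !is.na(dx_age) &
      dx_age < config$bethesda_msi_age,
    fdr_young = logical(n),
    two_relatives = logical(n)
  )
  for (pid in names(fam_split)) {
    i <- which(id == pid)
    if (length(i) == 0) next
    hist <- fam_split[[pid]]
    amst[i] <- meets_amsterdam_ii(hist, fap_excluded = !any(fap_flag[i]),
                                  config = config)$met
    aff <- hist[lc(hist$cancer_site) %in% config$hnpcc_sites, , drop = FALSE]
    beth_cl$fdr_young[i] <- nrow(aff) > 0 &&
      any(lc(aff$relation_degree) == "first" &
            aff$age_at_diagnosis < config$bethesda_age, na.rm = TRUE)
    beth_cl$two_relatives[i] <- nrow(aff) >= 2
  }
  beth <- Reduce(`|`, beth_cl[config$bethesda_clauses])

  polyps <- suppressWarnings(as.numeric(getf("polyp_count")))
  germline <- is_yes(getf("germline_mutation"))
  mutyh <- is_yes(getf("mutyh_biallelic"))
  hnpcc_flag <- is_yes(getf("hnpcc"))
  ibd_flag <- is_yes(getf("ibd"))
  famhx <- is_yes(getf("family_crc_history"))

  many_polyps <- !is.na(polyps) & polyps >= config$fap_polyp_min
  att_polyps <- !is.na(polyps) & polyps >= config$afap_polyp_min &
    polyps < config$fap_polyp_min
  any_polyposis <- !is.na(polyps) & polyps >= config$afap_polyp_min

  rules <- list(
    fap = (fap_flag & !att_polyps) | (germline & many_polyps),
    afap = (fap_flag | germline) & att_polyps,
    myh = mutyh,
    hnpcc = hnpcc_flag | (germline & (amst | beth)),
    suspected_hnpcc = amst & beth,
    suspected_fap = any_polyposis,
    ibd = ibd_flag,
    moderate = if (config$moderate_tier) famhx else rep(FALSE, n)
  )
  subgroup_of <- c(fap = "FAP", afap = "AFAP", myh = "MYH", hnpcc = "HNPCC",
                   suspected_hnpcc = "Suspected HNPCC",
                   suspected_fap = "Suspected FAP", ibd = "IBD",
                   moderate = "none")
  group_of <- c(fap = "high", afap = "high", myh = "high", hnpcc = "high",
                suspected_hnpcc = "high", suspected_fap = "high",
                ibd = "high", moderate = "moderate")

  fired <- lapply(seq_len(n), function(i) {
    names(rules)[vapply(rules, `[`, logical(1), i)]
  })
  first <- vapply(fired, function(f) {
    if (length(f) == 0) NA_character_ else f[1]
  }, character(1))

  tibble::tibble(
    patient_id = id,
    group = ifelse(is.na(first), "average", unname(group_of[first])),
    subgroup = ifelse(is.na(first), "none", unname(subgroup_of[first])),
    amsterdam = amst,
    bethesda = beth,
    fired_rules = fired
  )
}

#' Promote suspected HNPCC on molecular evidence
#'
#' A patient classified `Suspected HNPCC` becomes `HNPCC` when molecular
#' genetic testing identifies a germline mutation, or when
#' immunohistochemistry is abnormal together with MSI-high status. All other
#' assignments pass through unchanged; the transition is appended to
#' `fired_rules`. The operation is idempotent.
#'
#' @param assignments Tibble from [classify_risk()].
#' @param patients Raw-record tibble carrying the molecular columns
#'   `germline_mutation`, `ihc_result`, `msi_status` (untested or missing is
#'   distinct from negative and never triggers the transition).
#' @return The updated assignments tibble.
#' @export
apply_molecular_update <- function(assignments, patients) {
  patients <- tibble::as_tibble(patients)
  getf <- function(nm) {
    if (nm %in% names(patients)) patients[[nm]] else rep(NA, nrow(patients))
  }
  mol <- tibble::tibble(
    patient_id = as.character(patients$patient_id),
    trigger = is_yes(getf("germline_mutation")) |
      (!is.na(getf("ihc_result")) & lc(getf("ihc_result")) == "abnormal" &
         !is.na(getf("msi_status")) & lc(getf("msi_status")) == "msi-high")
  )
  out <- dplyr::left_join(assignments, mol, by = "patient_id")
  promote <- out$subgroup == "Suspected HNPCC" & !is.na(out$trigger) &
    out$trigger
  out$subgroup[promote] <- "HNPCC"
  out$fired_rules[promote] <- lapply(out$fired_rules[promote], function(f) {
    c(f, "molecular_update:suspected_hnpcc->hnpcc")
  })
  out$trigger <- NULL
  out
}

#' Shipped screening recommendation table
#'
#' Default surveillance schedule per risk stratum, encoding widely published
#' intervals (annual colonoscopy from childhood for FAP, 1--2-yearly
#' colonoscopy from age 20 for Lynch-spectrum groups, and so on). Purely a
#' default: supply your own table of the same shape to
#' [recommend_screening()] to override any row.
#'
#' @return A tibble with columns `group`, `subgroup`, `method`, `start_age`,
#'   `interval_months`.
#' @export
default_screening_table <- function() {
  tibble::tribble(
    ~group,     ~subgroup,         ~method,       ~start_age, ~interval_months,
    "high",     "FAP",             "colonoscopy", 12L,        12L,
    "high",     "AFAP",            "colonoscopy", 20L,        24L,
    "high",     "Suspected FAP",   "colonoscopy", 20L,        24L,
    "high",     "HNPCC",           "colonoscopy", 20L,        12L,
    "high",     "Suspected HNPCC", "colonoscopy", 20L,        24L,
    "high",     "MYH",             "colonoscopy", 18L,        24L,
    "high",     "IBD",             "colonoscopy", 30L,        24L,
    "moderate", "none",            "colonoscopy", 40L,        60L,
    "average",  "none",            "FIT",         50L,        12L
  )
}

#' Attach a screening recommendation to each risk assignment
#'
#' Deterministic lookup of `(group, subgroup)` in the recommendation table.
#' Every assignment must be covered; an uncovered stratum is a configuration
#' error.
#'
#' @param assignments Tibble from [classify_risk()] /
#'   [apply_molecular_update()].
#' @param table Recommendation table, default [default_screening_table()].
#' @return `assignments` with `method`, `start_age`, `interval_months`
#'   columns added.
#' @export
recommend_screening <- function(assignments,
                                table = default_screening_table()) {
  table <- tibble::as_tibble(table)
  need <- c("group", "subgroup", "method", "start_age", "interval_months")
  if (!all(need %in% names(table))) {
    stop("configuration error: recommendation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(table$start_age <= 0) || any(table$interval_months <= 0)) {
    stop("configuration error: start_age and interval_months must be positive",
         call. = FALSE)
  }
  out <- dplyr::left_join(assignments, table,
                          by = c("group", "subgroup"))
  uncovered <- is.na(out$method)
  if (any(uncovered)) {
    miss <- unique(paste0(out$group[uncovered], "/", out$subgroup[uncovered]))
    stop("configuration error: recommendation table has no row for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out
}
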