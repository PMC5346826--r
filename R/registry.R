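# The registry object: raw records + relatives, their encoded vectors, risk
# assignments, screening recommendations, survival estimates and per-stratum
# statistics, kept mutually consistent. Every mutating operation appends to a
# structured log and bumps a monotone revision counter; after any sequence of
# inserts and edits the registry state equals a full recomputation from the
# raw records (the consistency contract update_on_change() enforces).

#' Registry configuration
#'
#' @param k Neighbor count for the survival estimator.
#' @param mode Estimator mode, `"deceased-distance"` or `"outcome-weighted"`.
#' @param reference_year Gregorian year ages are computed against (explicit
#'   for reproducibility; the default is the registry census year used
#'   throughout the package's examples).
#' @param bmi_mode `"strict"` or `"faithful"`, see [compute_bmi()].
#' @param policy Similarity missing-data policy, see [prepare_pair()].
#' @param similarity_mode `"faithful"` (two-stage 3-decimal rounding) or
#'   `"unrounded"`.
#' @param feature_set Codebook slots entering the estimator's similarity
#'   queries; `NULL` (default) means every coded slot except the two outcome
#'   slots (`vital_status`, `survival_quality`), which would leak the label
#'   being estimated.
#' @param scale_features If `TRUE` (default) the estimator divides each slot
#'   by its field's maximum code before computing similarity, so that no
#'   single wide-coded field dominates the distance — feature values must be
#'   comparable in scale for similarity analysis to be meaningful. Raw codes
#'   are used when `FALSE` (and always in [similarity_matrix()]).
#' @param risk [risk_config()] for the rule engine.
#' @param screening_table Recommendation table, see [recommend_screening()].
#' @param size_thresholds Tumor-size cuts (mm) for pathologic grades I / II.
#' @return A list of class `crc_registry_config`.
#' @export
registry_config <- function(k = 5,
                            mode = c("deceased-distance", "outcome-weighted"),
                            reference_year = 2017,
                            bmi_mode = c("strict", "faithful"),
                            policy = c("pairwise-complete",
                                       "unknown-as-coded"),
                            similarity_mode = c("faithful", "unrounded"),
                            feature_set = NULL,
                            scale_features = TRUE,
                            risk = risk_config(),
                            screening_table = default_screening_table(),
                            size_thresholds = c(20, 35)) {
  structure(list(k = k, mode = match.arg(mode),
                 reference_year = reference_year,
                 bmi_mode = match.arg(bmi_mode),
                 policy = match.arg(policy),
                 similarity_mode = match.arg(similarity_mode),
                 feature_set = feature_set,
                 scale_features = isTRUE(scale_features), risk = risk,
                 screening_table = screening_table,
                 size_thresholds = size_thresholds),
            class = "crc_registry_config")
}

log_entry <- function(revision, op, patient_id) {
  tibble::tibble(revision = as.integer(revision), op = op,
                 patient_id = as.character(patient_id),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
}

derive_all <- function(patients, families, codebook, config) {
  encoded <- encode_patients(patients, book = codebook,
                             reference_year = config$reference_year,
                             bmi_mode = config$bmi_mode,
                             size_thresholds = config$size_thresholds)
  assignments <- classify_risk(patients, families, config = config$risk) |>
    apply_molecular_update(patients)
  recommendations <- recommend_screening(assignments,
                                         table = config$screening_table)
  list(encoded = encoded, assignments = assignments,
       recommendations = recommendations)
}

#' Build a registry from raw records
#'
#' Validates, encodes, classifies, recommends and estimates in one pass and
#' returns the consistent registry object. Records with error-severity
#' validation findings abort the build (use [ingest_registry()] for
#' row-level accept/reject behaviour). If the registry holds no deceased
#' member, survival estimates are empty (with a message) — they appear as
#' soon as a deceased reference exists.
#'
#' @param patients Raw-record tibble (see [encode_patients()]).
#' @param families Relatives table with a `patient_id` column, or `NULL`.
#' @param config [registry_config()].
#' @param codebook [crc_codebook()].
#' @return A `crc_registry` object.
#' @export
build_registry <- function(patients, families = NULL,
                           config = registry_config(),
                           codebook = crc_codebook()) {
  patients <- tibble::as_tibble(patients)
  patients$patient_id <- as.character(patients$patient_id)
  families <- if (is.null(families)) {
    tibble::tibble(patient_id = character(0))
  } else {
    tibble::as_tibble(families)
  }
  parts <- derive_all(patients, families, codebook, config)
  reg <- structure(list(patients = patients, families = families,
                        codebook = codebook, config = config,
                        encoded = parts$encoded,
                        assignments = parts$assignments,
                        recommendations = parts$recommendations,
                        estimates = empty_estimates(config$mode),
                        stats = compute_group_stats(empty_estimates(), 1L),
                        revision = 1L,
                        log = log_entry(1L, "build", NA_character_),
                        last_refresh = character(0)),
                   class = "crc_registry")
  reg$estimates <- tryCatch(estimate_survival(reg),
                            error = function(e) {
                              message("no survival estimates yet: ",
                                      conditionMessage(e))
                              empty_estimates(config$mode)
                            })
  reg$stats <- compute_group_stats(reg$estimates, 1L)
  reg
}

#' @export
print.crc_registry <- function(x, ...) {
  alive <- tolower(as.character(x$patients$vital_status)) == "alive"
  cat("<crc_registry> revision", x$revision, "\n")
  cat("  patients:", nrow(x$patients), "(",
      sum(alive, na.rm = TRUE), "alive /", sum(!alive, na.rm = TRUE),
      "deceased )\n")
  cat("  high risk:", sum(x$assignments$group == "high"), "\n")
  cat("  estimates:", nrow(x$estimates), " mode:", x$config$mode,
      " k:", x$config$k, "\n")
  invisible(x)
}

#' Insert or update one patient
#'
#' Adds a new patient (or replaces an existing one, matched by
#' `patient_id`), optionally replaces that patient's relatives, and then
#' refreshes every derived quantity whose inputs could have changed via
#' [update_on_change()].
#'
#' @param reg A `crc_registry`.
#' @param record One-row raw-record data frame.
#' @param family Optional relatives rows for this patient (replaces any
#'   existing ones; must carry the same `patient_id`).
#' @return The updated registry.
#' @export
upsert_patient <- function(reg, record, family = NULL) {
  stopifnot(inherits(reg, "crc_registry"))
  record <- tibble::as_tibble(record)
  stopifnot(nrow(record) == 1)
  record$patient_id <- as.character(record$patient_id)
  id <- record$patient_id
  existing <- match(id, reg$patients$patient_id)
  op <- if (is.na(existing)) "insert" else "update"

  patients <- reg$patients
  if (is.na(existing)) {
    patients <- dplyr::bind_rows(patients, record)
  } else {
    patients <- dplyr::rows_upsert(
      patients,
      record[, intersect(names(record), names(patients)), drop = FALSE],
      by = "patient_id")
    extra <- setdiff(names(record), names(patients))
    for (nm in extra) {
      patients[[nm]] <- NA
      patients[[nm]][existing] <- record[[nm]]
    }
  }
  findings <- validate_patients(patients)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("invalid record: ",
         paste(unique(paste0(errs$patient_id, " (", errs$field, ")")),
               collapse = ", "), call. = FALSE)
  }
  reg$patients <- patients
  if (!is.null(family)) {
    family <- tibble::as_tibble(family)
    if (nrow(family) > 0 &&
        !all(as.character(family$patient_id) == id)) {
      stop("family rows must carry the upserted patient_id", call. = FALSE)
    }
    reg$families <- dplyr::bind_rows(
      reg$families[reg$families$patient_id != id, , drop = FALSE],
      family)
  }
  update_on_change(reg, id, op = op)
}

#' Refresh derived state after a patient changed
#'
#' Recomputes the changed patient's encoded vector, risk assignment and
#' recommendation, then every survival estimate whose reference set could
#' include the changed patient, and finally the per-stratum statistics. The
#' post-state is identical (estimates, assignments, statistics) to a full
#' recomputation from the raw records. In `"deceased-distance"` mode the
#' affected estimates are those of alive patients in the changed patient's
#' old or new stratum plus all estimates with registry-wide scope; an edit
#' that never touches a deceased record only refreshes the patient itself. In
#' `"outcome-weighted"` mode every estimate is refreshed (any patient with
#' known vital status is a potential reference).
#'
#' @param reg A `crc_registry`.
#' @param patient_id Id of the changed patient (must exist).
#' @param op Log label, default `"update"`.
#' @return The updated registry; the ids whose estimates were recomputed are
#'   in `reg$last_refresh`.
#' @export
update_on_change <- function(reg, patient_id, op = "update") {
  stopifnot(inherits(reg, "crc_registry"))
  id <- as.character(patient_id)
  pi <- match(id, reg$patients$patient_id)
  if (is.na(pi)) {
    stop("lookup error: unknown patient_id: ", id, call. = FALSE)
  }

  old_idx <- match(id, reg$encoded$patient_id)
  old_dead <- !is.na(old_idx) &&
    identical(reg$encoded$vital_status[old_idx], 0L)
  old_stratum <- if (!is.na(old_idx)) {
    stratum_of(reg$assignments)[match(id, reg$assignments$patient_id)]
  } else {
    NA_character_
  }

  fam <- reg$families[reg$families$patient_id == id, , drop = FALSE]
  parts <- derive_all(reg$patients[pi, , drop = FALSE], fam,
                      reg$codebook, reg$config)
  replace_row <- function(tab, row) {
    dplyr::bind_rows(tab[tab$patient_id != id, , drop = FALSE], row) |>
      dplyr::arrange(match(.data$patient_id, reg$patients$patient_id))
  }
  reg$encoded <- replace_row(reg$encoded, parts$encoded)
  attr(reg$encoded, "codebook") <- reg$codebook
  reg$assignments <- replace_row(reg$assignments, parts$assignments)
  reg$recommendations <- replace_row(reg$recommendations,
                                     parts$recommendations)

  new_dead <- tolower(as.character(reg$patients$vital_status[pi])) == "dead"
  new_stratum <- stratum_of(parts$assignments)[1]
  alive <- tolower(as.character(reg$patients$vital_status)) == "alive"
  alive_ids <- reg$patients$patient_id[which(alive)]

  if (reg$config$mode == "outcome-weighted") {
    affected <- alive_ids
  } else if (isTRUE(old_dead) || isTRUE(new_dead)) {
    stratum <- stratum_of(reg$assignments)
    in_strata <- alive_ids[stratum[match(alive_ids,
                                         reg$assignments$patient_id)] %in%
                             stats::na.omit(c(old_stratum, new_stratum))]
    global_scope <- reg$estimates$patient_id[reg$estimates$scope == "global"]
    affected <- union(union(in_strata, intersect(global_scope, alive_ids)),
                      intersect(id, alive_ids))
  } else {
    affected <- intersect(id, alive_ids)
  }

  reg$revision <- reg$revision + 1L
  keep <- reg$estimates[!(reg$estimates$patient_id %in% c(affected, id)), ,
                        drop = FALSE]
  refreshed <- if (length(affected) > 0) {
    estimate_survival(reg, ids = affected)
  } else {
    empty_estimates(reg$config$mode)
  }
  reg$estimates <- dplyr::bind_rows(keep, refreshed) |>
    dplyr::arrange(match(.data$patient_id, reg$patients$patient_id))
  reg$stats <- compute_group_stats(reg$estimates, reg$revision, reg$stats)
  reg$log <- dplyr::bind_rows(reg$log, log_entry(reg$revision, op, id))
  reg$last_refresh <- affected
  reg
}

#' Ingest a registry from CSV (+ companion JSON)
#'
#' Reads raw records from a one-header-row UTF-8 CSV (one column per scalar
#' field) and, when given, a companion JSON keyed by `patient_id` holding
#' each patient's `family_history` array and `molecular` object. Every row is
#' validated and encoded; malformed rows (validation errors, unknown labels,
#' duplicate ids) are rejected individually with a reason, and the registry
#' is built from the accepted rows. The ingest report is available as
#' `reg$ingest_report` (columns `row`, `patient_id`, `status`, `reason`).
#'
#' @param csv Path to the patients CSV.
#' @param families_json Optional path to the companion JSON.
#' @param config [registry_config()].
#' @param codebook [crc_codebook()].
#' @return A `crc_registry` with an `ingest_report` element.
#' @export
ingest_registry <- function(csv, families_json = NULL,
                            config = registry_config(),
                            codebook = crc_codebook()) {
  patients <- readr::read_csv(csv, show_col_types = FALSE,
                              col_types = readr::cols(
                                patient_id = readr::col_character(),
                                .default = readr::col_guess()))
  patients <- tibble::as_tibble(patients)

  families <- tibble::tibble(patient_id = character(0))
  if (!is.null(families_json)) {
    doc <- jsonlite::fromJSON(families_json, simplifyVector = FALSE)
    fam_rows <- list()
    for (pid in names(doc)) {
      entry <- doc[[pid]]
      fh <- entry$family_history
      if (!is.null(fh) && length(fh) > 0) {
        fam_rows[[pid]] <- purrr::map_dfr(fh, function(r) {
          tibble::tibble(patient_id = pid,
                         relation_degree = r$relation_degree %||% NA,
                         generation = as.integer(r$generation %||% NA),
                         cancer_site = r$cancer_site %||% NA,
                         age_at_diagnosis = as.numeric(r$age_at_diagnosis %||% NA),
                         pathology_verified = isTRUE(r$pathology_verified))
        })
      }
      mol <- entry$molecular
      if (!is.null(mol)) {
        ri <- which(patients$patient_id == pid)
        for (nm in c("germline_mutation", "ihc_result", "msi_status",
                     "mutyh_biallelic")) {
          if (!is.null(mol[[nm]])) {
            if (!nm %in% names(patients)) patients[[nm]] <- NA_character_
            patients[[nm]][ri] <- as.character(mol[[nm]])
          }
        }
      }
    }
    if (length(fam_rows) > 0) families <- dplyr::bind_rows(fam_rows)
  }

  report <- list()
  seen <- character(0)
  accept <- logical(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    row <- patients[i, , drop = FALSE]
    pid <- as.character(row$patient_id)
    reason <- NA_character_
    if (!is.na(pid) && pid %in% seen) {
      reason <- "duplicate patient_id"
    } else {
      f <- validate_patients(row)
      errs <- f[f$severity == "error", , drop = FALSE]
      if (nrow(errs) > 0) {
        reason <- paste(unique(paste0(errs$field, ": ", errs$message)),
                        collapse = "; ")
      } else {
        enc_try <- tryCatch({
          encode_patients(row, book = codebook,
                          reference_year = config$reference_year,
                          bmi_mode = config$bmi_mode,
                          size_thresholds = config$size_thresholds)
          NA_character_
        }, error = function(e) conditionMessage(e))
        reason <- enc_try
      }
    }
    accept[i] <- is.na(reason)
    if (accept[i]) seen <- c(seen, pid)
    report[[i]] <- tibble::tibble(
      row = i, patient_id = pid,
      status = if (accept[i]) "accepted" else "rejected",
      reason = reason)
  }
  report <- dplyr::bind_rows(report)

  kept <- patients[accept, , drop = FALSE]
  fam_kept <- families[families$patient_id %in% kept$patient_id, ,
                       drop = FALSE]
  reg <- build_registry(kept, fam_kept, config = config,
                        codebook = codebook)
  reg$ingest_report <- report
  reg
}

#' Export a registry as a plain-text directory store
#'
#' Writes `patients.csv` (scalar fields, molecular columns excluded),
#' `families.json` (family history + molecular findings keyed by
#' `patient_id`), `estimates.csv` and `stats.json`. The CSV/JSON pair round-
#' trips through [ingest_registry()] to an equivalent registry.
#'
#' @param reg A `crc_registry`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_registry <- function(reg, dir) {
  stopifnot(inherits(reg, "crc_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mol_cols <- c("germline_mutation", "ihc_result", "msi_status",
                "mutyh_biallelic")
  readr::write_csv(
    reg$patients[, setdiff(names(reg$patients), mol_cols), drop = FALSE],
    file.path(dir, "patients.csv"), na = "")

  doc <- companion_json_doc(reg$patients, reg$families)
  jsonlite::write_json(doc, file.path(dir, "families.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  est <- reg$estimates
  est$neighbors <- NULL
  readr::write_csv(est, file.path(dir, "estimates.csv"), na = "")
  jsonlite::write_json(reg$stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# companion-JSON document: family history + molecular findings per patient
companion_json_doc <- function(patients, families) {
  mol_cols <- c("germline_mutation", "ihc_result", "msi_status",
                "mutyh_biallelic")
  doc <- list()
  for (pid in as.character(patients$patient_id)) {
    fam <- families[families$patient_id == pid, , drop = FALSE]
    entry <- list()
    if (nrow(fam) > 0) {
      entry$family_history <- purrr::pmap(
        fam[, c("relation_degree", "generation", "cancer_site",
                "age_at_diagnosis", "pathology_verified")],
        function(relation_degree, generation, cancer_site, age_at_diagnosis,
                 pathology_verified) {
          list(relation_degree = relation_degree, generation = generation,
               cancer_site = cancer_site,
               age_at_diagnosis = age_at_diagnosis,
               pathology_verified = pathology_verified)
        })
    }
    pi <- match(pid, patients$patient_id)
    mol <- list()
    for (nm in mol_cols) {
      if (nm %in% names(patients) && !is.na(patients[[nm]][pi])) {
        mol[[nm]] <- as.character(patients[[nm]][pi])
      }
    }
    if (length(mol) > 0) entry$molecular <- mol
    if (length(entry) > 0) doc[[pid]] <- entry
  }
  doc
}

search_corpus <- function(reg) {
  decoded <- decode_patients(reg$encoded, reg$codebook)
  passthrough <- intersect(c("referral_type", "germline_mutation",
                             "ihc_result", "msi_status", "mutyh_biallelic"),
                           names(reg$patients))
  extra <- reg$patients[, passthrough, drop = FALSE]
  asg <- reg$assignments[match(decoded$patient_id,
                               reg$assignments$patient_id), , drop = FALSE]
  rec <- reg$recommendations[match(decoded$patient_id,
                                   reg$recommendations$patient_id), ,
                             drop = FALSE]
  mat <- cbind(as.matrix(decoded),
               as.matrix(extra),
               group = asg$group, subgroup = asg$subgroup,
               method = rec$method)
  apply(mat, 1, function(r) paste(stats::na.omit(r), collapse = " | "))
}

#' Global substring search over a registry
#'
#' Case-insensitive substring match across every decoded label field, the
#' uncoded passthrough fields (referral type, molecular findings), risk
#' group/subgroup, recommendation method and the patient id itself. An empty
#' query matches everyone.
#'
#' @param reg A `crc_registry`.
#' @param query Search string.
#' @return Character vector of matching patient ids, ascending.
#' @export
global_search <- function(reg, query) {
  stopifnot(inherits(reg, "crc_registry"))
  if (nrow(reg$patients) == 0) return(character(0))
  if (is.na(query) || query == "") {
    return(sort(as.character(reg$patients$patient_id)))
  }
  corpus <- search_corpus(reg)
  hit <- stringr::str_detect(corpus,
                             stringr::fixed(query, ignore_case = TRUE))
  sort(as.character(reg$patients$patient_id)[hit])
}

#' Field-specific ("special") registry search
#'
#' Conjunction of exact-match criteria over id, the screening recommendation
#' (method, start age, interval), risk group and subgroup, vital status, and
#' an inclusive survival-percent range. At least one criterion must be given;
#' an unknown criterion name is a query error.
#'
#' @param reg A `crc_registry`.
#' @param id Exact patient id.
#' @param screening_method,screening_start_age,screening_interval Exact
#'   matches on the recommendation fields.
#' @param risk_group `"average"`, `"moderate"` or `"high"`.
#' @param subgroup High-risk subgroup label.
#' @param survival_status `"alive"` or `"dead"` (case-insensitive).
#' @param survival_percent_range Length-2 numeric `c(lo, hi)`, inclusive;
#'   only patients holding an estimate can match.
#' @param ... Trap for misspelled criteria (raises a query error).
#' @return Character vector of matching patient ids, ascending.
#' @export
special_search <- function(reg, id = NULL, screening_method = NULL,
                           screening_start_age = NULL,
                           screening_interval = NULL, risk_group = NULL,
                           subgroup = NULL, survival_status = NULL,
                           survival_percent_range = NULL, ...) {
  stopifnot(inherits(reg, "crc_registry"))
  dots <- list(...)
  if (length(dots) > 0) {
    stop("query error: unknown criterion name(s): ",
         paste(names(dots), collapse = ", "), call. = FALSE)
  }
  crit <- list(id = id, screening_method = screening_method,
               screening_start_age = screening_start_age,
               screening_interval = screening_interval,
               risk_group = risk_group, subgroup = subgroup,
               survival_status = survival_status,
               survival_percent_range = survival_percent_range)
  if (all(vapply(crit, is.null, logical(1)))) {
    stop("query error: at least one criterion must be set", call. = FALSE)
  }
  ids <- as.character(reg$patients$patient_id)
  keep <- rep(TRUE, length(ids))
  rec <- reg$recommendations[match(ids, reg$recommendations$patient_id), ,
                             drop = FALSE]
  if (!is.null(id)) keep <- keep & ids %in% as.character(id)
  if (!is.null(screening_method)) {
    keep <- keep & tolower(rec$method) %in% tolower(screening_method)
  }
  if (!is.null(screening_start_age)) {
    keep <- keep & rec$start_age %in% screening_start_age
  }
  if (!is.null(screening_interval)) {
    keep <- keep & rec$interval_months %in% screening_interval
  }
  if (!is.null(risk_group)) {
    keep <- keep & tolower(rec$group) %in% tolower(risk_group)
  }
  if (!is.null(subgroup)) {
    keep <- keep & tolower(rec$subgroup) %in% tolower(subgroup)
  }
  if (!is.null(survival_status)) {
    keep <- keep & tolower(as.character(reg$patients$vital_status)) %in%
      tolower(survival_status)
  }
  if (!is.null(survival_percent_range)) {
    stopifnot(length(survival_percent_range) == 2)
    pct <- reg$estimates$percent[match(ids, reg$estimates$patient_id)]
    keep <- keep & !is.na(pct) & pct >= survival_percent_range[1] &
      pct <= survival_percent_range[2]
  }
  sort(ids[keep])
}
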