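# The minimum-data-set codebook: every categorical field of a registry
# record, its label -> integer-code map, and the frozen slot order of the
# encoded vector. Slot order is a contract: cosine similarity compares
# vectors position by position, so the order ships with the codebook and a
# serialized codebook reloads with identical behaviour.

yn_labels <- function() c(Yes = 1L, No = 0L)
ynu_labels <- function() c(Yes = 1L, No = 0L, Unknown = 3L)

# Fields whose codes are computed from raw measurements rather than looked up
derived_fields <- c("age_category", "bmi_category", "tumor_size_class")

# Fields that record the outcome itself (excluded from the survival
# estimator's default feature set)
outcome_fields <- c("survival_quality", "vital_status")

default_field_specs <- function() {
  list(
    age_category = c("<45" = 1L, "45-64" = 2L, ">=65" = 3L),
    sex = c(Female = 1L, Male = 2L, Transsexual = 3L),
    education = c(Illiterate = 1L, "Primary school" = 2L,
                  "High school" = 3L, University = 4L),
    marital_status = c(Married = 1L, Single = 2L, Divorced = 3L,
                       Widowed = 4L),
    # "Other" remapped from a colliding 1 to 5 so the encoder is injective
    ethnicity = c(Fars = 1L, Turk = 2L, Kord = 3L, Lor = 4L, Other = 5L),
    religion = c(Muslim = 1L, Christian = 2L, Jewish = 3L,
                 Zoroastrian = 4L, Other = 5L),
    location = c(City = 1L, Village = 2L),
    bmi_category = c("<18.5" = 1L, "18.5-24.9" = 2L, "25-29.9" = 3L,
                     ">=30" = 4L),
    chemical_exposure = ynu_labels(),
    tobacco = ynu_labels(),
    alcohol = ynu_labels(),
    oral_narcotic = ynu_labels(),
    iv_drug = ynu_labels(),
    nsaids = ynu_labels(),
    tumor_size_class = c("Below threshold" = 1L, "Above threshold" = 2L),
    # colliding/duplicated site codes remapped to sequential 1..10
    tumor_topology = c(Cecum = 1L, "Ascending colon" = 2L,
                       "Hepatic flexure" = 3L, "Transverse colon" = 4L,
                       "Splenic flexure" = 5L, "Descending colon" = 6L,
                       "Sigmoid colon" = 7L, Colon = 8L,
                       "Rectosigmoid junction" = 9L, Rectum = 10L),
    tumor_morphology = c(Adenocarcinoma = 1L,
                         "Mucinous adenocarcinoma" = 2L,
                         "Signet ring cell carcinoma" = 3L,
                         "Squamous cell carcinoma" = 4L,
                         "Squamous-cell adenocarcinoma" = 5L,
                         "Medullary carcinoma" = 6L),
    histological_grade = c("Undetermined grade" = 1L,
                           "Well differentiated" = 2L,
                           "Moderately differentiated" = 3L,
                           "Poorly differentiated" = 4L,
                           Undifferentiated = 5L),
    pt = c(T0 = 0L, T1 = 1L, T2 = 2L, T3 = 3L, T4 = 4L),
    pn = c(N0 = 0L, N1 = 1L, N2 = 2L),
    pm = c(M0 = 0L, M1 = 1L),
    pathologic_grade = c(I = 1L, II = 2L, III = 3L, IV = 4L),
    advancing_grade = c("Primary grade" = 1L, "Advanced grade" = 2L),
    treatment = c(Surgery = 1L, "Chemotherapy/Radiotherapy" = 2L,
                  Biopsy = 3L),
    hnpcc = yn_labels(),
    fap = yn_labels(),
    diabetes = ynu_labels(),
    hypertension = ynu_labels(),
    ibd = ynu_labels(),
    personal_crc_history = ynu_labels(),
    family_crc_history = ynu_labels(),
    perforation = yn_labels(),
    fuo = yn_labels(),
    obstruction = yn_labels(),
    abdominal_pain = yn_labels(),
    anemia = yn_labels(),
    rectal_bleeding = yn_labels(),
    bowel_habit_change = yn_labels(),
    weakness = yn_labels(),
    weight_loss = yn_labels(),
    survival_quality = c("Normal activity" = 1L, "Non-normal activity" = 2L,
                         Dead = 3L),
    vital_status = c(Alive = 1L, Dead = 0L)
  )
}

new_codebook <- function(specs) {
  if (anyDuplicated(names(specs))) {
    stop("codebook schema error: duplicate field names: ",
         paste(unique(names(specs)[duplicated(names(specs))]), collapse = ", "),
         call. = FALSE)
  }
  for (f in names(specs)) {
    codes <- specs[[f]]
    if (length(codes) < 1) {
      stop("codebook schema error: field '", f, "' has no labels",
           call. = FALSE)
    }
    if (anyDuplicated(codes)) {
      stop("codebook collision error in field '", f, "': code(s) ",
           paste(unique(codes[duplicated(codes)]), collapse = ", "),
           " assigned to more than one label", call. = FALSE)
    }
    if (anyDuplicated(tolower(names(codes)))) {
      stop("codebook schema error: field '", f,
           "' has case-colliding labels", call. = FALSE)
    }
  }
  structure(list(specs = specs, fields = names(specs)),
            class = "crc_codebook")
}

#' The default minimum-data-set codebook
#'
#' Builds the shipped codebook: one field spec per categorical element of the
#' registry minimum data set (socio-demographics, lifestyle, tumor
#' classification, past medical history, symptoms, vital quality), in the
#' frozen top-to-bottom slot order that encoded vectors follow. Three slots
#' are derived rather than looked up: `age_category` (from the Persian
#' birthdate), `bmi_category` (from weight and height) and `tumor_size_class`
#' (from tumor size in mm with a grade-dependent threshold).
#'
#' Two documented remaps resolve code collisions in the source coding sheet:
#' `ethnicity` "Other" moves from 1 (colliding with "Fars") to 5, and the
#' tumor topology sites are renumbered sequentially 1--10 after collapsing a
#' case-duplicated "Sigmoid colon" entry.
#'
#' @param extra_morphology Optional named integer vector of additional tumor
#'   morphology labels (the shipped list is extensible).
#' @return A `crc_codebook` object.
#' @export
#' @examples
#' book <- crc_codebook()
#' codebook_codes(book, "sex")
crc_codebook <- function(extra_morphology = NULL) {
  specs <- default_field_specs()
  if (!is.null(extra_morphology)) {
    specs$tumor_morphology <- c(specs$tumor_morphology,
                                vapply(extra_morphology, as.integer,
                                       integer(1)))
  }
  new_codebook(specs)
}

#' @export
print.crc_codebook <- function(x, ...) {
  cat("<crc_codebook>", length(x$fields), "fields\n")
  for (f in x$fields) {
    codes <- x$specs[[f]]
    cat(sprintf("  %-22s %s\n", f,
                paste0(names(codes), "=", codes, collapse = " / ")))
  }
  invisible(x)
}

#' Look up the label/code map of one codebook field
#'
#' @param book A `crc_codebook`.
#' @param field Field name.
#' @return Named integer vector (labels to codes).
#' @export
codebook_codes <- function(book, field) {
  stopifnot(inherits(book, "crc_codebook"))
  if (!field %in% book$fields) {
    stop("unknown codebook field: ", field, call. = FALSE)
  }
  book$specs[[field]]
}

#' Codebook as a tidy table
#'
#' @param book A `crc_codebook`.
#' @return A tibble with columns `field`, `label`, `code`, in slot order.
#' @export
codebook_table <- function(book) {
  stopifnot(inherits(book, "crc_codebook"))
  purrr::map_dfr(book$fields, function(f) {
    tibble::tibble(field = f, label = names(book$specs[[f]]),
                   code = unname(book$specs[[f]]))
  })
}

#' Serialize / load a codebook as JSON
#'
#' The JSON document is an ordered array of field specs
#' (`{"field": ..., "labels": [{"label": ..., "code": ...}], "missing": "na"}`);
#' a reloaded codebook behaves identically to the original. Loading applies
#' the same schema checks as construction: duplicate field names are a schema
#' error, duplicate codes within a field a collision error naming the field.
#'
#' @param book A `crc_codebook`.
#' @param path File path; for `write_codebook` where the JSON is written, for
#'   `read_codebook` a path or a literal JSON string.
#' @return `write_codebook` returns `path` invisibly; `read_codebook` returns
#'   a `crc_codebook`.
#' @export
write_codebook <- function(book, path) {
  stopifnot(inherits(book, "crc_codebook"))
  doc <- purrr::map(book$fields, function(f) {
    list(field = f,
         labels = purrr::imap(as.list(book$specs[[f]]),
                              function(code, label) {
                                list(label = label, code = code)
                              }) |> unname(),
         missing = "na")
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- list()
  fields <- character(0)
  for (entry in doc) {
    f <- entry$field
    if (f %in% fields) {
      stop("codebook schema error: duplicate field names: ", f,
           call. = FALSE)
    }
    fields <- c(fields, f)
    codes <- vapply(entry$labels, function(l) as.integer(l$code), integer(1))
    names(codes) <- vapply(entry$labels, function(l) as.character(l$label),
                           character(1))
    specs[[f]] <- codes
  }
  new_codebook(specs)
}

# case-insensitive, whitespace-trimmed label -> code lookup for one field
match_labels <- function(labels, field, book) {
  codes <- book$specs[[field]]
  idx <- match(tolower(stringr::str_trim(as.character(labels))),
               tolower(names(codes)))
  unknown <- !is.na(labels) & is.na(idx)
  if (any(unknown)) {
    stop("encoding error: field '", field, "' has no code for label(s): ",
         paste(unique(labels[unknown]), collapse = ", "), call. = FALSE)
  }
  unname(codes[idx])
}

#' Encode raw patient records as integer minimum-data-set vectors
#'
#' Maps every categorical field of `patients` through the codebook and
#' computes the three derived slots: `age_category` via
#' [compute_age()] from `birthdate_persian` and `reference_year`,
#' `bmi_category` via [compute_bmi()] from `weight`/`height`, and
#' `tumor_size_class` from `tumor_size_mm` with a threshold that depends on
#' pathologic grade (grade I uses the lower cut, grade II the higher; other
#' or missing grades use the higher cut). Label matching is case-insensitive.
#' Missing raw values encode as `NA`, the dedicated missing marker — never 0,
#' which is a live code for yes/no fields.
#'
#' @param patients Data frame of raw records, one row per patient, with a
#'   `patient_id` column plus the raw fields the codebook covers (see
#'   [crc_codebook()]; raw column names equal field names except the derived
#'   slots).
#' @param book Codebook, default [crc_codebook()].
#' @param reference_year Gregorian year for age derivation (explicit, never
#'   the wall clock).
#' @param bmi_mode `"strict"` or `"faithful"`, see [compute_bmi()].
#' @param size_thresholds Numeric length-2 vector: tumor-size cut (mm) for
#'   pathologic grades I and II.
#' @return A tibble: `patient_id` plus one integer column per codebook slot,
#'   in slot order. The codebook travels with the result as attribute
#'   `"codebook"`.
#' @export
encode_patients <- function(patients, book = crc_codebook(),
                            reference_year,
                            bmi_mode = c("strict", "faithful"),
                            size_thresholds = c(20, 35)) {
  stopifnot(inherits(book, "crc_codebook"))
  bmi_mode <- match.arg(bmi_mode)
  patients <- tibble::as_tibble(patients)
  if (!"patient_id" %in% names(patients)) {
    stop("patients must have a patient_id column", call. = FALSE)
  }
  findings <- validate_patients(patients)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("invalid records: ",
         paste(unique(paste0(errs$patient_id, " (", errs$field, ")")),
               collapse = ", "), call. = FALSE)
  }

  n <- nrow(patients)
  get_col <- function(nm) {
    if (nm %in% names(patients)) patients[[nm]] else rep(NA, n)
  }

  out <- tibble::tibble(patient_id = as.character(patients$patient_id))
  for (f in book$fields) {
    if (f == "age_category") {
      bd <- as.character(get_col("birthdate_persian"))
      code <- rep(NA_integer_, n)
      ok <- !is.na(bd)
      if (any(ok)) {
        code[ok] <- compute_age(bd[ok], reference_year)$category
      }
    } else if (f == "bmi_category") {
      code <- compute_bmi(as.numeric(get_col("weight")),
                          as.numeric(get_col("height")),
                          mode = bmi_mode)$category
    } else if (f == "tumor_size_class") {
      size <- as.numeric(get_col("tumor_size_mm"))
      grade <- match_labels(get_col("pathologic_grade"), "pathologic_grade",
                            book)
      cut <- ifelse(!is.na(grade) & grade == 1L, size_thresholds[1],
                    size_thresholds[2])
      code <- dplyr::case_when(
        is.na(size) ~ NA_integer_,
        size < cut ~ 1L,
        .default = 2L
      )
    } else {
      code <- match_labels(get_col(f), f, book)
    }
    out[[f]] <- as.integer(code)
  }
  attr(out, "codebook") <- book
  out
}

#' Decode encoded vectors back to categorical labels
#'
#' Inverse of [encode_patients()] on the categorical fields: every code maps
#' back to its canonical codebook label. Derived slots decode to their bin
#' labels (e.g. `bmi_category` 2 decodes to `"18.5-24.9"`), not to raw weight
#' or height. `NA` codes decode to `NA`. Encoding a decoded table again
#' reproduces the original codes on all non-derived slots.
#'
#' @param encoded Tibble from [encode_patients()] (or of the same shape).
#' @param book Codebook; defaults to the one attached to `encoded`.
#' @return A tibble of `patient_id` plus one character (label) column per
#'   slot.
#' @export
decode_patients <- function(encoded, book = attr(encoded, "codebook")) {
  if (is.null(book)) book <- crc_codebook()
  stopifnot(inherits(book, "crc_codebook"))
  out <- tibble::tibble(patient_id = as.character(encoded$patient_id))
  for (f in book$fields) {
    codes <- book$specs[[f]]
    x <- encoded[[f]]
    bad <- !is.na(x) & !(x %in% codes)
    if (any(bad)) {
      stop("decoding error: field '", f, "' has code(s) outside its spec: ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    out[[f]] <- names(codes)[match(x, codes)]
  }
  out
}

#' Validate raw patient records
#'
#' Structural checks on a raw-record table. Returns findings rather than
#' throwing: each row of the result names the patient, the field, a severity
#' (`"error"` or `"warning"`) and a message. An empty result means every
#' invariant holds.
#'
#' Errors: empty or duplicated `patient_id`; negative `weight`, `height`,
#' `survival_time`, `tumor_size_mm` or `polyp_count`. Warnings: vital status
#' dead while survival quality is not `"Dead"` (and vice versa).
#'
#' @param patients Data frame of raw records.
#' @param families Optional relatives table (see [classify_risk()]); when
#'   given, nonpositive `age_at_diagnosis` and unknown `cancer_site` or
#'   `relation_degree` values are reported as errors.
#' @return A tibble with columns `patient_id`, `field`, `severity`,
#'   `message`.
#' @export
validate_patients <- function(patients, families = NULL) {
  patients <- tibble::as_tibble(patients)
  findings <- list()
  add <- function(id, field, severity, message) {
    findings[[length(findings) + 1]] <<-
      tibble::tibble(patient_id = as.character(id), field = field,
                     severity = severity, message = message)
  }

  id <- as.character(patients$patient_id)
  empty <- is.na(id) | id == ""
  for (i in which(empty)) {
    add(id[i], "patient_id", "error", "patient_id is empty")
  }
  for (d in unique(id[duplicated(id) & !empty])) {
    add(d, "patient_id", "error", "duplicate patient_id")
  }

  for (f in c("weight", "height", "survival_time", "tumor_size_mm",
              "polyp_count")) {
    if (f %in% names(patients)) {
      neg <- !is.na(patients[[f]]) & patients[[f]] < 0
      for (i in which(neg)) {
        add(id[i], f, "error", paste0(f, " is negative"))
      }
    }
  }

  if (all(c("vital_status", "survival_quality") %in% names(patients))) {
    vs <- tolower(as.character(patients$vital_status))
    sq <- tolower(as.character(patients$survival_quality))
    mism <- (!is.na(vs) & !is.na(sq)) &
      ((vs == "dead" & sq != "dead") | (vs == "alive" & sq == "dead"))
    for (i in which(mism)) {
      add(id[i], "survival_quality", "warning",
          "vital_status and survival_quality disagree")
    }
  }

  if (!is.null(families) && nrow(families) > 0) {
    fam <- tibble::as_tibble(families)
    sites <- c("crc", "endometrial", "small bowel", "ureter/renal pelvis",
               "other")
    if ("age_at_diagnosis" %in% names(fam)) {
      bad <- !is.na(fam$age_at_diagnosis) & fam$age_at_diagnosis <= 0
      for (i in which(bad)) {
        add(fam$patient_id[i], "age_at_diagnosis", "error",
            "relative age_at_diagnosis must be positive")
      }
    }
    if ("cancer_site" %in% names(fam)) {
      bad <- !is.na(fam$cancer_site) &
        !(tolower(as.character(fam$cancer_site)) %in% sites)
      for (i in which(bad)) {
        add(fam$patient_id[i], "cancer_site", "error",
            paste0("cancer_site not in controlled vocabulary: ",
                   fam$cancer_site[i]))
      }
    }
    if ("relation_degree" %in% names(fam)) {
      bad <- !is.na(fam$relation_degree) &
        !(tolower(as.character(fam$relation_degree)) %in%
            c("first", "second"))
      for (i in which(bad)) {
        add(fam$patient_id[i], "relation_degree", "error",
            "relation_degree must be 'first' or 'second'")
      }
    }
  }

  if (length(findings) == 0) {
    return(tibble::tibble(patient_id = character(0), field = character(0),
                          severity = character(0), message = character(0)))
  }
  dplyr::bind_rows(findings)
}
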