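# Cosine similarity with the registry system's exact rounding semantics:
# each Euclidean norm is rounded to 3 decimals (round-half-even) BEFORE the
# product, and the quotient is rounded to 3 decimals again. The two-stage
# rounding is a contract, not an implementation detail: the system's worked
# example (0.972 for [3,45,7,2] vs [2,54,13,15]) is only reproducible with
# this order of operations. An "unrounded" mode gives the plain
# high-precision cosine.

#' Euclidean norm rounded to three decimals
#'
#' `round(sqrt(sum(x^2)), 3)` with round-half-even, exactly as the registry
#' system's helper computes it.
#'
#' @param x Nonempty numeric vector, all values finite.
#' @return A single number.
#' @export
#' @examples
#' rounded_norm(c(3, 45, 7, 2)) # 45.684
rounded_norm <- function(x) {
  if (length(x) == 0) {
    stop("rounded_norm: empty vector", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("rounded_norm: values must be finite", call. = FALSE)
  }
  round(sqrt(sum(x^2)), 3)
}

#' Cosine similarity between two feature vectors
#'
#' In `"faithful"` mode (default) the denominator is the product of the two
#' norms *after* each has been rounded to 3 decimals, and the quotient is
#' rounded to 3 decimals again. `"unrounded"` mode returns the plain cosine.
#' For nonnegative inputs the result lies in `[0, 1]` up to the documented
#' rounding (faithful values can exceed an unrounded cosine by at most
#' 0.002).
#'
#' @param x,y Numeric vectors of equal length, built over the same feature
#'   mask (see [prepare_pair()]).
#' @param mode `"faithful"` or `"unrounded"`.
#' @return A single number.
#' @export
#' @examples
#' cosine_similarity(c(3, 45, 7, 2), c(2, 54, 13, 15)) # 0.972
cosine_similarity <- function(x, y, mode = c("faithful", "unrounded")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) {
    stop("alignment error: vectors have lengths ", length(x), " and ",
         length(y), call. = FALSE)
  }
  numerator <- sum(x * y)
  if (mode == "faithful") {
    denominator <- rounded_norm(x) * rounded_norm(y)
    if (denominator == 0) {
      stop("undefined similarity: both norms round to zero", call. = FALSE)
    }
    round(numerator / denominator, 3)
  } else {
    denominator <- sqrt(sum(x^2)) * sqrt(sum(y^2))
    if (denominator == 0) {
      stop("undefined similarity: zero-norm vector", call. = FALSE)
    }
    numerator / denominator
  }
}

# codes that mean "Unknown" per field, as a named vector aligned to the
# codebook slot order (NA where the field has no Unknown label)
unknown_code_by_field <- function(book) {
  vapply(book$fields, function(f) {
    codes <- book$specs[[f]]
    i <- match("unknown", tolower(names(codes)))
    if (is.na(i)) NA_integer_ else unname(codes[i])
  }, integer(1))
}

#' Align two encoded vectors for a similarity query
#'
#' Builds the pair of comparable feature vectors from two encoded records of
#' the same codebook. Under the default `"pairwise-complete"` policy a slot
#' is kept only when both records carry an informative code there: slots
#' missing (`NA`) in either vector are dropped, as are slots holding an
#' `Unknown` code. Under `"unknown-as-coded"` the Unknown codes are retained
#' as their literal value (3), and only `NA` slots are dropped.
#'
#' @param a,b Named integer vectors (one encoded record each, names = slot
#'   names) or one-row tibbles from [encode_patients()].
#' @param policy `"pairwise-complete"` or `"unknown-as-coded"`.
#' @param book The codebook the vectors were encoded with (used to identify
#'   Unknown codes); defaults to an attached `"codebook"` attribute, else the
#'   shipped default.
#' @return A list with numeric vectors `x`, `y` and the logical `mask` of
#'   retained slots (aligned to the codebook slot order).
#' @export
prepare_pair <- function(a, b, policy = c("pairwise-complete",
                                          "unknown-as-coded"),
                         book = NULL) {
  policy <- match.arg(policy)
  if (is.null(book)) {
    book <- attr(a, "codebook") %||% attr(b, "codebook") %||% crc_codebook()
  }
  as_slots <- function(v) {
    if (is.data.frame(v)) {
      stopifnot(nrow(v) == 1)
      v <- unlist(v[, setdiff(names(v), "patient_id"), drop = FALSE])
    }
    if (!is.null(names(v))) {
      miss <- setdiff(book$fields, names(v))
      if (length(miss) > 0) {
        stop("vector is missing codebook slot(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      v <- v[book$fields]
    } else if (length(v) != length(book$fields)) {
      stop("alignment error: unnamed vector length ", length(v),
           " does not match the codebook (", length(book$fields), " slots)",
           call. = FALSE)
    }
    as.numeric(v)
  }
  x <- as_slots(a)
  y <- as_slots(b)
  mask <- !is.na(x) & !is.na(y)
  if (policy == "pairwise-complete") {
    unk <- unknown_code_by_field(book)
    mask <- mask & !(!is.na(unk) & (x == unk | y == unk))
  }
  if (!any(mask)) {
    stop("empty-overlap error: no shared non-missing slots", call. = FALSE)
  }
  list(x = x[mask], y = y[mask], mask = stats::setNames(mask, book$fields))
}

# similarity of one query vector against the rows of a reference code
# matrix, vectorised; NA entries handled per policy. Returns NA where a pair
# has no overlap or a zero denominator.
sim_query_to_matrix <- function(q, M, book,
                                policy = "pairwise-complete",
                                mode = "faithful") {
  if (nrow(M) == 0) return(numeric(0))
  q <- as.numeric(q)
  keep <- matrix(!is.na(q), nrow(M), ncol(M), byrow = TRUE) & !is.na(M)
  if (policy == "pairwise-complete") {
    unk <- unknown_code_by_field(book)
    unk <- unk[match(colnames(M), book$fields)]
    has_unk <- !is.na(unk)
    if (any(has_unk)) {
      U <- matrix(unk, nrow(M), ncol(M), byrow = TRUE)
      qU <- matrix(!is.na(q) & !is.na(unk) & q == unk,
                   nrow(M), ncol(M), byrow = TRUE)
      mU <- !is.na(M) & has_unk[col(M)] & M == U
      mU[is.na(mU)] <- FALSE
      keep <- keep & !qU & !mU
    }
  }
  Q <- matrix(q, nrow(M), ncol(M), byrow = TRUE)
  Q[!keep] <- 0
  R <- M
  R[!keep] <- 0
  num <- rowSums(Q * R)
  if (mode == "faithful") {
    nx <- round(sqrt(rowSums(Q^2)), 3)
    ny <- round(sqrt(rowSums(R^2)), 3)
  } else {
    nx <- sqrt(rowSums(Q^2))
    ny <- sqrt(rowSums(R^2))
  }
  den <- nx * ny
  sim <- ifelse(rowSums(keep) == 0 | den == 0, NA_real_, num / den)
  if (mode == "faithful") round(sim, 3) else sim
}

#' Pairwise similarity matrix of encoded records
#'
#' Symmetric matrix of pairwise cosine similarities ([cosine_similarity()]
#' applied to [prepare_pair()] of every pair), with unit diagonal and
#' `patient_id` dimnames. Pairs with no shared informative slots or an
#' undefined quotient get `NA` with a warning naming the pair.
#'
#' @param encoded Tibble from [encode_patients()] with at least two rows.
#' @param policy Missing-handling policy, see [prepare_pair()].
#' @param mode Rounding mode, see [cosine_similarity()].
#' @param book Codebook; defaults to the attribute on `encoded`.
#' @return A numeric matrix.
#' @export
similarity_matrix <- function(encoded,
                              policy = c("pairwise-complete",
                                         "unknown-as-coded"),
                              mode = c("faithful", "unrounded"),
                              book = attr(encoded, "codebook")) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  if (is.null(book)) book <- crc_codebook()
  if (nrow(encoded) < 2) {
    stop("similarity_matrix needs at least two encoded records",
         call. = FALSE)
  }
  ids <- as.character(encoded$patient_id)
  M <- as.matrix(encoded[, book$fields, drop = FALSE])
  storage.mode(M) <- "numeric"
  n <- nrow(M)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    s <- sim_query_to_matrix(M[i, ], M[(i + 1):n, , drop = FALSE], book,
                             policy = policy, mode = mode)
    S[i, (i + 1):n] <- s
    S[(i + 1):n, i] <- s
  }
  if (anyNA(S)) {
    bad <- which(is.na(S), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    warning("similarity undefined for ", nrow(bad), " pair(s), e.g. ",
            ids[bad[1, 1]], " vs ", ids[bad[1, 2]], call. = FALSE)
  }
  S
}

#' Export a similarity matrix as CSV
#'
#' Writes the matrix with patient ids as the first column and as column
#' headers.
#'
#' @param sim Matrix from [similarity_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(sim, path) {
  df <- tibble::as_tibble(sim, rownames = "patient_id")
  readr::write_csv(df, path)
  invisible(path)
}
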