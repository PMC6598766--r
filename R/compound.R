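#' Assemble a compound library table
#'
#' Builds the canonical per-compound table used by every downstream stage:
#' standardised SMILES and the InChIKey identity hash are attached to the
#' vendor metadata. Structures that fail to parse keep their row but carry
#' `NA` for `smiles_std` and `identity_key`.
#'
#' @param df A data.frame with columns `library_id`, `plate`, `well`,
#'   `name`, `smiles`. A `compound_id` column is honoured if present,
#'   otherwise ids are derived as `<library_id>_<plate>_<well>`.
#' @param standardize Standardise structures (default `TRUE`).
#' @return A data.frame of class `"zf_compounds"` with added columns
#'   `compound_id`, `smiles_std`, `identity_key`.
#' @export
compound_library <- function(df, standardize = TRUE) {
  req <- c("library_id", "plate", "well", "name", "smiles")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("compound table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad_well <- !grepl("^[A-H][0-9]{2}$", df$well)
  if (any(bad_well)) {
    stop("malformed well ids (expect letter + 2-digit column): ",
         paste(utils::head(df$well[bad_well], 5), collapse = ", "))
  }
  if (!"compound_id" %in% names(df)) {
    df$compound_id <- paste(df$library_id, df$plate, df$well, sep = "_")
  }
  if (anyDuplicated(df$compound_id)) {
    stop("duplicate compound_id values in library table")
  }
  std <- if (standardize) {
    vapply(df$smiles, function(s) {
      tryCatch(standardize_structure(s),
               zfscreen_parse_error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
  } else {
    ob_canonical(df$smiles)
  }
  df$smiles_std <- std
  df$identity_key <- ifelse(is.na(std), NA_character_, ob_inchikey(std))
  class(df) <- c("zf_compounds", "data.frame")
  df
}

#' Cross-library duplicate detection by InChIKey
#'
#' Flags compound pairs across two libraries whose standardised structures
#' hash to the same InChIKey (all three blocks, so stereoisomers differ).
#' Compounds with no identity key (unparseable structures) are skipped with
#' a warning.
#'
#' @param lib_a,lib_b Compound tables carrying `compound_id` and
#'   `identity_key` columns (see [compound_library()]).
#' @return A data.frame with columns `id_a`, `id_b`, `identity_key`, ordered
#'   by key then ids.
#' @export
find_duplicates <- function(lib_a, lib_b) {
  for (lib in list(lib_a, lib_b)) {
    stopifnot(all(c("compound_id", "identity_key") %in% names(lib)))
  }
  skip <- sum(is.na(lib_a$identity_key)) + sum(is.na(lib_b$identity_key))
  if (skip > 0) {
    warning(sprintf("%d compounds without identity_key skipped", skip))
  }
  a <- lib_a[!is.na(lib_a$identity_key), c("compound_id", "identity_key")]
  b <- lib_b[!is.na(lib_b$identity_key), c("compound_id", "identity_key")]
  hit <- merge(a, b, by = "identity_key", suffixes = c("_a", "_b"))
  out <- data.frame(id_a = hit$compound_id_a, id_b = hit$compound_id_b,
                    identity_key = hit$identity_key,
                    stringsAsFactors = FALSE)
  out[order(out$identity_key, out$id_a, out$id_b), , drop = FALSE]
}
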