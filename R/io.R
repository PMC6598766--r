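# CSV schemas and run configuration binding the pipeline stages. All tables
# are UTF-8 CSV with a header row; per-embryo scores travel as
# semicolon-packed lists so a well is one row.

#' Read a compound library CSV
#'
#' Expects columns `library_id`, `plate`, `well`, `name`, `smiles`
#' (`compound_id` optional). Structures are standardised and identity keys
#' attached via [compound_library()].
#'
#' @param path CSV file.
#' @param standardize Passed to [compound_library()].
#' @return A `"zf_compounds"` data.frame.
#' @export
read_library <- function(path, standardize = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  compound_library(df, standardize = standardize)
}

#' Write a compound library CSV
#'
#' @param compounds Compound table.
#' @param path Output CSV.
#' @export
write_library <- function(compounds, path) {
  utils::write.csv(as.data.frame(compounds), path, row.names = FALSE)
  invisible(path)
}

#' Standard 96-well screening plate map
#'
#' Columns 1 and 12 hold the controls (positive control at two doses,
#' vehicle, and untreated wild type, two rows each); columns 2-11 hold
#' compounds.
#'
#' @param plate_id Plate identifier.
#' @return A data.frame of class `"zf_plate_map"`: `plate`, `well`, `role`.
#' @export
standard_plate_map <- function(plate_id) {
  rows <- LETTERS[1:8]
  ctrl_roles <- rep(c("positive_control_IBMX_50", "positive_control_IBMX_100",
                      "negative_control_DMSO", "untreated_wt"), each = 2)
  ctrl <- data.frame(
    plate = plate_id,
    well = c(paste0(rows, "01"), paste0(rows, "12")),
    role = rep(ctrl_roles, 2),
    stringsAsFactors = FALSE)
  cmp <- expand.grid(r = rows, c = sprintf("%02d", 2:11),
                     stringsAsFactors = FALSE)
  cmp <- data.frame(plate = plate_id, well = paste0(cmp$r, cmp$c),
                    role = "compound", stringsAsFactors = FALSE)
  out <- rbind(ctrl, cmp)
  out <- out[order(out$well), ]
  rownames(out) <- NULL
  class(out) <- c("zf_plate_map", "data.frame")
  out
}

validate_plate_map <- function(map) {
  col <- substr(map$well, 2, 3)
  bad <- col %in% c("01", "12") & map$role == "compound"
  if (any(bad)) {
    stop("plate map invalid: compound wells in control columns 1/12: ",
         paste(utils::head(paste0(map$plate[bad], ":", map$well[bad]), 5),
               collapse = ", "))
  }
  invisible(map)
}

#' Read a well-results CSV
#'
#' Expects columns `compound_id`, `assay`, `replicate`, `concentration_uM`,
#' `embryo_scores` (semicolon-packed), `n_embryos_found`,
#' `n_dead_or_abnormal`, and optionally `plate`/`well`. When a plate map is
#' given, any result claiming a compound in a control column is rejected.
#'
#' @param path CSV file.
#' @param plate_map Optional `"zf_plate_map"` (or rbind of several).
#' @return A well-results data.frame as accepted by [triage_screen()].
#' @export
read_wells <- function(path, plate_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(embryo_scores = "character"))
  req <- c("compound_id", "assay", "replicate", "embryo_scores",
           "n_embryos_found", "n_dead_or_abnormal")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  bad_assay <- !df$assay %in% c("vcanb_tb233c", "mbp_tb233c", "vcanb_fr24")
  if (any(bad_assay)) {
    stop(sprintf("%s: row %d: unknown assay '%s'", path,
                 which(bad_assay)[1], df$assay[which(bad_assay)[1]]))
  }
  scores <- unpack_scores(df$embryo_scores)
  bad <- vapply(scores, function(s) any(is.na(s)) || any(!s %in% 0:3),
                logical(1))
  if (any(bad)) {
    stop(sprintf("%s: row %d: column embryo_scores: scores must be 0-3",
                 path, which(bad)[1]))
  }
  if (!is.null(plate_map) && "well" %in% names(df)) {
    validate_plate_map(plate_map)
    key <- paste(df$plate, df$well)
    mkey <- paste(plate_map$plate, plate_map$well)
    role <- plate_map$role[match(key, mkey)]
    bad <- !is.na(role) & role != "compound"
    if (any(bad)) {
      stop(sprintf("%s: row %d: compound result in control well %s",
                   path, which(bad)[1], df$well[which(bad)[1]]))
    }
  }
  df
}

#' Write a well-results CSV
#'
#' @param wells Well-results data.frame.
#' @param path Output CSV.
#' @export
write_wells <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a triage table
#'
#' The triage CSV mirrors the published hit-table layout (plate, well, name,
#' the three score averages and the class calls) plus the pipeline columns.
#' `read_triage(write_triage(x))` restores the records.
#'
#' @param records A `"zf_triage"` data.frame.
#' @param path CSV path.
#' @export
write_triage <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_triage
#' @export
read_triage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fr24_score = "character",
                                       retest_sums = "character"),
                        na.strings = "")
  df$is_hit <- as.logical(df$is_hit)
  class(df) <- c("zf_triage", "data.frame")
  df
}

#' Assemble and validate a run configuration
#'
#' Collects the tunable constants of the pipeline into one validated list
#' whose hash can be stamped into outputs, so a run is reproducible from its
#' report.
#'
#' @param category_bins See [default_category_bins()].
#' @param mbp_rescue_min,mbp_downregulated_max Counter-screen bin edges
#'   (exclusive lower edge of `rescue`, inclusive upper edge of
#'   `downregulated`).
#' @param fr24_downstream_max,fr24_receptor_min Mechanism rule constants.
#' @param fingerprint_radius,fingerprint_bits Fingerprint parameters.
#' @param network_threshold Similarity network edge threshold.
#' @param jitter_seed Polar layout jitter seed.
#' @param toxicity_rule `"any"` or `"majority"`.
#' @return A list of class `"zf_run_config"` with a `hash` attribute.
#' @export
run_config <- function(category_bins = default_category_bins(),
                       mbp_rescue_min = 3.5, mbp_downregulated_max = 1.5,
                       fr24_downstream_max = 7, fr24_receptor_min = 9,
                       fingerprint_radius = 2L, fingerprint_bits = 2048L,
                       network_threshold = 0.5, jitter_seed = 1L,
                       toxicity_rule = "any") {
  validate_category_bins(category_bins)
  stopifnot(mbp_downregulated_max < mbp_rescue_min,
            fr24_downstream_max < fr24_receptor_min,
            network_threshold >= 0, network_threshold <= 1,
            toxicity_rule %in% c("any", "majority"))
  cfg <- list(category_bins = category_bins,
              mbp_rescue_min = mbp_rescue_min,
              mbp_downregulated_max = mbp_downregulated_max,
              fr24_downstream_max = fr24_downstream_max,
              fr24_receptor_min = fr24_receptor_min,
              fingerprint_radius = fingerprint_radius,
              fingerprint_bits = fingerprint_bits,
              network_threshold = network_threshold,
              jitter_seed = jitter_seed,
              toxicity_rule = toxicity_rule)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "zf_run_config"
  cfg
}

# Polynomial rolling hash (mod 2^31 - 1) of the JSON serialisation; enough
# to detect config drift in run reports without a cryptographic dependency.
config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                     digits = NA))
  h <- 17
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a JSON run report
#'
#' Bundles category histograms per library and the configuration (with its
#' hash) into a JSON report alongside the triage CSV.
#'
#' @param records A `"zf_triage"`.
#' @param cfg A `"zf_run_config"`.
#' @param path Output JSON path.
#' @export
write_run_report <- function(records, cfg, path) {
  stopifnot(inherits(cfg, "zf_run_config"))
  lib <- substr(as.character(records$plate), 1, 1)
  hist <- lapply(split(records$primary_category, lib), function(x) {
    as.list(table(factor(x, levels = LETTERS[1:7])))
  })
  jsonlite::write_json(list(
    n_compounds = nrow(records),
    n_hits = sum(records$is_hit, na.rm = TRUE),
    category_histograms = hist,
    config = unclass(cfg),
    config_hash = attr(cfg, "hash")
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
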