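# Screen decision logic: per-well scoring, A-G categorisation, hit selection
# across retests, counter-screen classes, allele-comparison mechanism classes
# and duplicate reconciliation.
#
# Scoring convention (in situ hybridisation readout): each live embryo gets
# an ordinal score 0-3, with 0 = marker expression suppressed back to
# wild-type levels (a strong rescue) and 3 = no effect. Three embryos per
# well give a well sum of 0-9.

#' Default category bins for the primary screen
#'
#' The A-E bins partition the integer well sums 0-9. Only the A boundary
#' (sum no greater than 2) is fixed by the screen design; the remaining
#' edges follow the convention that E (sum 9) is "no effect" and D is
#' "partial suppression". F (toxic) and G (no embryos found) are flag
#' categories, not sum bins.
#'
#' @return A named list of `c(lower, upper)` integer pairs.
#' @export
default_category_bins <- function() {
  list(A = c(0L, 2L), B = c(3L, 4L), C = c(5L, 6L), D = c(7L, 8L), E = c(9L, 9L))
}

validate_category_bins <- function(bins) {
  covered <- as.integer(unlist(lapply(bins, function(b) seq(b[1], b[2])),
                               use.names = FALSE))
  if (!identical(sort(covered), 0:9)) {
    stop("category bins must partition the sums 0-9 exactly once")
  }
  invisible(bins)
}

#' Score a single screen well
#'
#' Sums the per-embryo ordinal scores of a well, or raises a flag instead:
#' `"toxic"` when dead or grossly abnormal embryos are present (under the
#' default `"any"` rule; `"majority"` requires more than half), and
#' `"empty"` when no embryos were found in the well (potentially corrosive
#' compound, or loss of the embryos).
#'
#' @param embryo_scores Integer scores in `{0,1,2,3}` for the live,
#'   scoreable embryos (length 0-3).
#' @param n_embryos_found Number of embryos found in the well (0-3).
#' @param n_dead_or_abnormal Number of dead or severely abnormal embryos.
#' @param toxicity_rule `"any"` (default) or `"majority"`.
#' @return A list of class `"zf_well_score"`: `sum` (integer or `NA`) and
#'   `flag` (`"ok"`, `"toxic"` or `"empty"`).
#' @export
#' @examples
#' score_well(c(0, 1, 1))             # sum 2
#' score_well(integer(0), 3, 3)       # toxic
#' score_well(integer(0), 0, 0)       # empty
score_well <- function(embryo_scores, n_embryos_found = length(embryo_scores),
                       n_dead_or_abnormal = 0L,
                       toxicity_rule = c("any", "majority")) {
  toxicity_rule <- match.arg(toxicity_rule)
  if (length(embryo_scores) > 0 &&
      (any(is.na(embryo_scores)) || !all(embryo_scores %in% 0:3))) {
    stop("embryo scores must be integers in 0..3")
  }
  if (length(embryo_scores) + n_dead_or_abnormal > n_embryos_found ||
      n_embryos_found > 3L) {
    stop("inconsistent embryo counts for well")
  }
  flag <- "ok"
  if (n_embryos_found == 0L) {
    flag <- "empty"
  } else if (n_dead_or_abnormal > 0L &&
             (toxicity_rule == "any" ||
              n_dead_or_abnormal > n_embryos_found / 2)) {
    flag <- "toxic"
  }
  s <- if (flag == "ok" && length(embryo_scores) > 0) {
    as.integer(sum(embryo_scores))
  } else {
    NA_integer_
  }
  structure(list(sum = s, flag = flag), class = "zf_well_score")
}

#' Assign a primary-screen category
#'
#' Maps a well sum (or flag) to the categories A-G: A-E by sum bins
#' (strongest rescue in A), F for toxic wells, G for empty wells.
#'
#' @param x A `"zf_well_score"`, or a plain sum in 0-9.
#' @param bins Sum bins; see [default_category_bins()].
#' @return A single character, one of `"A"`-`"G"`.
#' @export
categorize_primary <- function(x, bins = default_category_bins()) {
  validate_category_bins(bins)
  if (inherits(x, "zf_well_score")) {
    if (x$flag == "toxic") return("F")
    if (x$flag == "empty") return("G")
    x <- x$sum
  }
  if (is.na(x) || x < 0 || x > 9) stop("well sum out of range 0-9")
  for (nm in names(bins)) {
    if (x >= bins[[nm]][1] && x <= bins[[nm]][2]) return(nm)
  }
  stop("unreachable: bins validated to partition 0-9")
}

# Category of a continuous average score: integer bin upper edges act as
# inclusive cuts (A <= 2 < B <= 4 < C <= 6 < D <= 8 < E).
categorize_average <- function(avg, bins = default_category_bins()) {
  validate_category_bins(bins)
  uppers <- vapply(bins, `[`, numeric(1), 2L)
  nm <- names(bins)[which(avg <= uppers + 1e-9)[1]]
  if (is.na(nm)) stop("average out of range 0-9")
  nm
}

#' Hit selection across primary test and retests
#'
#' A compound is a confirmed hit when (1) the average of the three test sums
#' (primary + two retests, nine embryos total) falls in categories A-C and
#' (2) no individual test sum exceeds 7 (every single test must show at
#' least some rescue).
#'
#' @param primary_sum Primary screen well sum (0-9).
#' @param retest_sums Numeric vector of retest well sums (expected length 2).
#' @param bins Category bins for the average; see [default_category_bins()].
#' @return A list: `vcanb_average`, `is_hit`, `complete` (`FALSE` when fewer
#'   than three valid test sums were available; such records are never hits).
#' @export
#' @examples
#' select_hits(2, c(2, 2))  # average 2, hit
#' select_hits(0, c(0, 8))  # not a hit: an individual score exceeds 7
select_hits <- function(primary_sum, retest_sums,
                        bins = default_category_bins()) {
  sums <- c(primary_sum, retest_sums)
  if (length(sums) < 3L || anyNA(sums)) {
    return(list(vcanb_average = NA_real_, is_hit = FALSE, complete = FALSE))
  }
  if (any(sums < 0 | sums > 9)) stop("test sums must lie in 0-9")
  avg <- mean(sums)
  hit <- categorize_average(avg, bins) %in% c("A", "B", "C") && all(sums <= 7)
  list(vcanb_average = avg, is_hit = hit, complete = TRUE)
}

#' Counter-screen (mbp) classification
#'
#' Bins the counter-screen average (well sums over two repeats, six embryos;
#' for this marker 3 = wild-type-level expression restored) into three
#' classes: `rescue` (average above 3.5), `no_rescue` (above 1.5 up to and
#' including 3.5 -- expression as in untreated mutants), and `downregulated`
#' (1.5 or below -- the compound suppressed both markers, a transcription-
#' inhibitor signature treated as a false positive).
#'
#' @param mbp_average Numeric average in `[0, 9]`.
#' @return One of `"rescue"`, `"no_rescue"`, `"downregulated"`.
#' @export
classify_mbp <- function(mbp_average) {
  if (is.na(mbp_average) || mbp_average < 0 || mbp_average > 9) {
    stop("mbp average out of range 0-9")
  }
  if (mbp_average > 3.5) "rescue"
  else if (mbp_average > 1.5) "no_rescue"
  else "downregulated"
}

#' Allele-comparison mechanism classification
#'
#' Compounds that rescue the hypomorphic allele are re-screened on the
#' strong (truncating) allele, which cannot produce the receptor protein.
#' A compound that still rescues (score sum 0-7) must act downstream of the
#' receptor; one with no effect at all (sum 9) is a candidate for direct
#' receptor interaction; a partial effect (sum 8) or missing data (`"ND"`,
#' no data; `"DE"`, dead embryos) is inconclusive.
#'
#' @param fr24_sum A numeric score sum in 0-9, or one of the codes `"ND"`,
#'   `"DE"`.
#' @return One of `"downstream"`, `"receptor_candidate"`, `"inconclusive"`.
#' @export
#' @examples
#' classify_fr24(0)     # downstream
#' classify_fr24(9)     # receptor_candidate
#' classify_fr24("ND")  # inconclusive
classify_fr24 <- function(fr24_sum) {
  if (is.character(fr24_sum)) {
    code <- toupper(trimws(fr24_sum))
    if (code %in% c("ND", "DE")) return("inconclusive")
    num <- suppressWarnings(as.numeric(code))
    if (is.na(num)) stop("fr24 score must be 0-9, 'ND' or 'DE'")
    fr24_sum <- num
  }
  if (is.na(fr24_sum)) return("inconclusive")
  if (fr24_sum < 0 || fr24_sum > 9) stop("fr24 score out of range 0-9")
  if (fr24_sum <= 7) "downstream"
  else if (fr24_sum >= 9) "receptor_candidate"
  else "inconclusive"
}

#' Reconcile scores of a compound duplicated across libraries
#'
#' Bins the absolute difference of the two independent score averages into
#' the reporting bins `0` (identical), `1-2`, `3-6` and `7-9`, treating the
#' printed integer labels as inclusive upper edges.
#'
#' @param avg_a,avg_b Score averages on the 0-9 scale.
#' @return One of `"0"`, `"1-2"`, `"3-6"`, `"7-9"`.
#' @export
reconcile_duplicates <- function(avg_a, avg_b) {
  stopifnot(avg_a >= 0, avg_a <= 9, avg_b >= 0, avg_b <= 9)
  d <- abs(avg_a - avg_b)
  if (d == 0) "0"
  else if (d <= 2) "1-2"
  else if (d <= 6) "3-6"
  else "7-9"
}

#' Mechanism-class counts for a set of triage records
#'
#' Tallies the allele-comparison mechanism classes, overall and per library
#' (libraries identified by the first character of the plate id).
#'
#' @param records A data.frame with columns `mechanism_class` and `plate`
#'   (the plate column is optional; per-library tallies are skipped without
#'   it).
#' @return A list: `counts` (named integer vector over the three classes),
#'   `n` (total records), and `by_library` (table of library prefix by
#'   class, or `NULL`).
#' @export
mechanism_report <- function(records) {
  classes <- c("downstream", "receptor_candidate", "inconclusive")
  if (nrow(records) == 0L) {
    return(list(counts = stats::setNames(integer(3), classes), n = 0L,
                by_library = NULL))
  }
  stopifnot("mechanism_class" %in% names(records))
  mc <- factor(records$mechanism_class, levels = classes)
  if (anyNA(mc)) stop("unknown mechanism_class values present")
  counts <- table(mc)
  by_library <- NULL
  if ("plate" %in% names(records)) {
    by_library <- table(substr(as.character(records$plate), 1, 1), mc)
  }
  list(counts = stats::setNames(as.integer(counts), classes),
       n = nrow(records), by_library = by_library)
}
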