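#' Run the full triage pipeline over a well-results table
#'
#' Aggregates per-well screen results into one triage record per compound:
#' primary categorisation, hit confirmation across retests, counter-screen
#' classification for confirmed hits, and mechanism classification from the
#' strong-allele re-screen for counter-screen rescuers.
#'
#' The wells table uses one row per well with per-embryo scores packed as a
#' semicolon-separated list (see [read_wells()]). Assays are
#' `vcanb_tb233c` (primary marker, hypomorphic allele; replicate 1 is the
#' primary screen, replicates 2-3 the retests), `mbp_tb233c` (counter
#' screen, two replicates) and `vcanb_fr24` (strong-allele re-screen, one
#' well). Stages a compound never reached carry `NA`.
#'
#' @param wells Well-results data.frame with columns `compound_id`, `assay`,
#'   `replicate`, `embryo_scores` (semicolon-packed or a list column),
#'   `n_embryos_found`, `n_dead_or_abnormal`.
#' @param compounds Optional compound table supplying `plate`/`well`/`name`
#'   metadata for the report.
#' @param bins Primary category bins, see [default_category_bins()].
#' @param toxicity_rule Passed to [score_well()].
#' @return A data.frame of class `"zf_triage"`, one row per compound:
#'   `compound_id`, `plate`, `well`, `name`, `primary_sum`, `primary_flag`,
#'   `primary_category`, `retest_sums` (packed), `vcanb_average`, `is_hit`,
#'   `mbp_average`, `mbp_class`, `fr24_score` (number as character, or
#'   `"ND"`/`"DE"`), `mechanism_class`.
#' @export
triage_screen <- function(wells, compounds = NULL,
                          bins = default_category_bins(),
                          toxicity_rule = c("any", "majority")) {
  toxicity_rule <- match.arg(toxicity_rule)
  validate_category_bins(bins)
  req <- c("compound_id", "assay", "replicate", "embryo_scores",
           "n_embryos_found", "n_dead_or_abnormal")
  stopifnot(all(req %in% names(wells)))
  scores_list <- unpack_scores(wells$embryo_scores)

  ids <- unique(wells$compound_id)
  rows <- lapply(ids, function(id) {
    w <- which(wells$compound_id == id)
    triage_one(id, wells[w, , drop = FALSE], scores_list[w], bins,
               toxicity_rule)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(compounds)) {
    meta <- compounds[match(out$compound_id, compounds$compound_id),
                      intersect(c("plate", "well", "name"), names(compounds)),
                      drop = FALSE]
    out[names(meta)] <- meta
  }
  class(out) <- c("zf_triage", "data.frame")
  out
}

unpack_scores <- function(x) {
  if (is.list(x)) return(lapply(x, as.integer))
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(s) {
    s <- s[nzchar(trimws(s))]
    as.integer(s)
  })
}

score_assay_wells <- function(w, scores, rule) {
  lapply(seq_len(nrow(w)), function(i) {
    score_well(scores[[i]], w$n_embryos_found[i], w$n_dead_or_abnormal[i],
               toxicity_rule = rule)
  })
}

triage_one <- function(id, w, scores, bins, rule) {
  rec <- data.frame(
    compound_id = id, plate = NA_character_, well = NA_character_,
    name = NA_character_,
    primary_sum = NA_integer_, primary_flag = NA_character_,
    primary_category = NA_character_, retest_sums = NA_character_,
    vcanb_average = NA_real_, is_hit = FALSE,
    mbp_average = NA_real_, mbp_class = NA_character_,
    fr24_score = NA_character_, mechanism_class = NA_character_,
    stringsAsFactors = FALSE
  )

  prim <- w$assay == "vcanb_tb233c" & w$replicate == 1L
  if (!any(prim)) return(rec)
  ps <- score_assay_wells(w[prim, , drop = FALSE][1, , drop = FALSE],
                          scores[prim][1], rule)[[1]]
  rec$primary_sum <- ps$sum
  rec$primary_flag <- ps$flag
  rec$primary_category <- categorize_primary(ps, bins)
  if (!rec$primary_category %in% c("A", "B", "C")) return(rec)

  ret <- w$assay == "vcanb_tb233c" & w$replicate > 1L
  ret_scores <- score_assay_wells(w[ret, , drop = FALSE], scores[ret], rule)
  ret_sums <- vapply(ret_scores, function(s) {
    if (s$flag == "ok") as.numeric(s$sum) else NA_real_
  }, numeric(1))
  rec$retest_sums <- paste(ret_sums, collapse = ";")
  sel <- select_hits(ps$sum, ret_sums, bins)
  rec$vcanb_average <- sel$vcanb_average
  rec$is_hit <- sel$is_hit
  if (!sel$is_hit) return(rec)

  mbp <- w$assay == "mbp_tb233c"
  if (any(mbp)) {
    mbp_scores <- score_assay_wells(w[mbp, , drop = FALSE], scores[mbp], rule)
    sums <- vapply(mbp_scores, function(s) {
      if (s$flag == "ok") as.numeric(s$sum) else NA_real_
    }, numeric(1))
    if (!anyNA(sums) && length(sums) > 0) {
      rec$mbp_average <- mean(sums)
      rec$mbp_class <- classify_mbp(rec$mbp_average)
    }
  }
  if (is.na(rec$mbp_class) || rec$mbp_class != "rescue") return(rec)

  fr <- w$assay == "vcanb_fr24"
  if (!any(fr)) {
    rec$fr24_score <- "ND"
  } else {
    fs <- score_assay_wells(w[fr, , drop = FALSE][1, , drop = FALSE],
                            scores[fr][1], rule)[[1]]
    rec$fr24_score <- if (fs$flag == "empty") "ND"
      else if (fs$flag == "toxic") "DE"
      else as.character(fs$sum)
  }
  rec$mechanism_class <- classify_fr24(rec$fr24_score)
  rec
}

#' @export
print.zf_triage <- function(x, ...) {
  cat(sprintf("Screen triage: %d compounds, %d confirmed hits\n",
              nrow(x), sum(x$is_hit)))
  cats <- table(factor(x$primary_category, levels = LETTERS[1:7]))
  cat("Primary categories: ",
      paste(sprintf("%s=%d", names(cats), cats), collapse = " "), "\n")
  if (any(!is.na(x$mechanism_class))) {
    rep <- mechanism_report(x[!is.na(x$mechanism_class), , drop = FALSE])
    cat("Mechanism classes: ",
        paste(sprintf("%s=%d", names(rep$counts), rep$counts), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.zf_triage <- function(object, ...) {
  hits <- object[object$is_hit, , drop = FALSE]
  mbp <- table(factor(hits$mbp_class,
                      levels = c("rescue", "no_rescue", "downregulated")))
  structure(list(
    n = nrow(object),
    categories = table(factor(object$primary_category, levels = LETTERS[1:7])),
    n_hits = nrow(hits),
    mbp_classes = mbp,
    mechanism = mechanism_report(
      object[!is.na(object$mechanism_class), , drop = FALSE])
  ), class = "summary.zf_triage")
}

#' @export
print.summary.zf_triage <- function(x, ...) {
  cat(sprintf("%d compounds screened; %d confirmed hits\n", x$n, x$n_hits))
  cat("Primary categories:\n"); print(x$categories)
  cat("Counter-screen classes (hits):\n"); print(x$mbp_classes)
  cat("Mechanism classes:\n"); print(x$mechanism$counts)
  invisible(x)
}
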