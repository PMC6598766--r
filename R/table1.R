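#' Hit table of the published screen
#'
#' The packaged transcription of the published 41-compound hit table: the
#' compounds that rescued both markers in the hypomorphic allele, with their
#' plate/well ids, annotated activities, and the average scores from the
#' primary marker (nine embryos), the counter screen (six embryos) and the
#' strong-allele re-screen (three embryos; `ND` = no data, `DE` = dead
#' embryos). Plate ids prefixed `T` and `S` identify the two source
#' libraries.
#'
#' @return A data.frame with columns `row`, `plate`, `well`, `name`,
#'   `known_activity`, `vcanb_score` (numeric), `mbp_score` (numeric),
#'   `fr24_score` (character: a number or `ND`/`DE`).
#' @export
#' @examples
#' t1 <- screen_table1()
#' nrow(t1)  # 41
screen_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "zfscreen",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fr24_score = "character"))
  df$vcanb_score <- as.numeric(df$vcanb_score)
  df$mbp_score <- as.numeric(df$mbp_score)
  df
}
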