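# Internal OpenBabel plumbing shared by the chemistry functions.
#
# All structure handling goes through ChemmineOB (OpenBabel). Batch
# conversions carry a numeric title per molecule so that parse failures,
# which OpenBabel silently drops from its output, can be re-aligned with
# the input vector.

#' @importFrom ChemmineOB convertFormat forEachMol fingerprint_OB
NULL

parse_error <- function(smiles, msg = "unparseable SMILES") {
  structure(
    class = c("zfscreen_parse_error", "error", "condition"),
    list(message = sprintf("%s: %s", msg, paste(smiles, collapse = ", ")),
         call = sys.call(-1), smiles = smiles)
  )
}

#' @noRd
is_parse_error <- function(x) inherits(x, "zfscreen_parse_error")

# Batch SMILES -> canonical SMILES. Returns a character vector aligned with
# `smiles`; NA marks a parse failure. `neutralize` applies OpenBabel's charge
# neutralisation where valence permits.
ob_canonical <- function(smiles, neutralize = FALSE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  bad <- !nzchar(smiles) | is.na(smiles)
  out <- rep(NA_character_, length(smiles))
  idx <- which(!bad)
  if (length(idx) == 0L) return(out)
  src <- paste0(smiles[idx], " t", idx, collapse = "\n")
  res <- suppressWarnings(
    if (neutralize) {
      ChemmineOB::convertFormat(
        "SMI", "CAN", paste0(src, "\n"),
        options = data.frame(names = "neutralize", args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"))
    }
  )
  if (!nzchar(res)) return(out)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (f in fields) {
    if (length(f) >= 2L && grepl("^t[0-9]+$", f[[2L]])) {
      i <- as.integer(sub("^t", "", f[[2L]]))
      out[i] <- f[[1L]]
    }
  }
  out
}

# Batch SMILES -> InChIKey via the openbabel CLI (the in-process conversion
# drops SMILES stereo descriptors; the CLI handles them). Output is aligned
# by molecule title; NA marks parse failures.
ob_inchikey <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  idx <- which(!is.na(smiles) & nzchar(smiles))
  if (length(idx) == 0L) return(out)
  src <- tempfile(fileext = ".smi")
  on.exit(unlink(src))
  writeLines(paste0(smiles[idx], " t", idx), src)
  res <- suppressWarnings(
    system2("obabel", c("-ismi", src, "-oinchi", "-xK", "-xt", "-e"),
            stdout = TRUE, stderr = FALSE)
  )
  for (line in res) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) == 2L && grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", f[[1L]]) &&
        grepl("^t[0-9]+$", f[[2L]])) {
      out[as.integer(sub("^t", "", f[[2L]]))] <- f[[1L]]
    }
  }
  out
}

# Count heavy (non-hydrogen) atoms in a SMILES string by tokenising atom
# symbols. Used only to rank fragments of an already-validated molecule.
smiles_heavy_atoms <- function(smiles) {
  tok <- gregexpr("\\[[^]]*\\]|Cl|Br|Si|Se|As|[BCNOPSFI]|[bcnops]", smiles)[[1]]
  if (tok[1] == -1L) return(0L)
  m <- regmatches(smiles, gregexpr("\\[[^]]*\\]|Cl|Br|Si|Se|As|[BCNOPSFI]|[bcnops]", smiles))[[1]]
  sum(!grepl("^\\[H", m))
}

# Does a SMILES fragment contain carbon?
smiles_has_carbon <- function(smiles) {
  grepl("C(?![a-eg-z])|c|\\[C|\\[c", smiles, perl = TRUE)
}

# Evaluate a function over a seeded RNG substream without disturbing the
# caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
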