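#' Standardise a chemical structure
#'
#' Normalises a SMILES string before fingerprinting or scaffold analysis:
#' the largest organic fragment is kept (salts and counter-ions dropped),
#' charges are neutralised where valence permits, and the result is written
#' as a canonical SMILES. The procedure is idempotent: standardising a
#' standardised structure returns it unchanged.
#'
#' Fragment choice: among fragments containing carbon (all fragments, if
#' none contains carbon) the one with the most heavy atoms wins; ties are
#' broken by lexicographic order of the canonical fragment SMILES so the
#' result is deterministic.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as `smiles`.
#' @seealso [compute_fingerprint()], [bemis_murcko_scaffold()]
#' @export
#' @examples
#' standardize_structure("OCC")        # "CCO"
#' standardize_structure("CCO.Cl")     # "CCO" (largest organic fragment)
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  can <- ob_canonical(smiles, neutralize = TRUE)
  if (anyNA(can)) stop(parse_error(smiles[is.na(can)]))
  multi <- grepl(".", can, fixed = TRUE)
  if (any(multi)) {
    can[multi] <- vapply(can[multi], pick_fragment, character(1), USE.NAMES = FALSE)
    # re-canonicalise the chosen fragment so output is a single stable form
    re <- ob_canonical(can[multi], neutralize = TRUE)
    if (anyNA(re)) stop(parse_error(smiles[multi][is.na(re)]))
    can[multi] <- re
  }
  can
}

# Pick the largest organic fragment from a dot-separated canonical SMILES.
pick_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  organic <- vapply(frags, smiles_has_carbon, logical(1))
  if (any(organic)) frags <- frags[organic]
  sizes <- vapply(frags, smiles_heavy_atoms, integer(1))
  frags <- frags[sizes == max(sizes)]
  sort(frags)[1L]
}
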