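#' Extended-connectivity fingerprint of a structure
#'
#' Computes a binary Morgan/ECFP fingerprint. The default, radius 2 on 2048
#' bits, is the ECFP4 convention used throughout library comparison work.
#' OpenBabel enumerates circular substructures into a fixed 4096-bit space;
#' the result is folded (index modulo `n_bits`) onto the requested width.
#'
#' @param smiles A single standardised SMILES string (see
#'   [standardize_structure()]).
#' @param radius Morgan radius; radius `r` corresponds to ECFP`2r`.
#' @param n_bits Folded fingerprint width in bits.
#' @return An object of class `"zf_fingerprint"`: a list with `bits`
#'   (sorted 0-based indices of set bits), `n_bits` and `radius`.
#' @export
#' @examples
#' fp <- compute_fingerprint("c1ccccc1")
#' length(fp$bits) > 0
compute_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) == 1L,
            radius %in% 0:5, n_bits >= 2L)
  raw <- fingerprint_raw(smiles, radius)
  new_fingerprint(sort(unique(raw %% as.integer(n_bits))),
                  n_bits = as.integer(n_bits), radius = as.integer(radius))
}

new_fingerprint <- function(bits, n_bits, radius) {
  structure(list(bits = as.integer(bits), n_bits = n_bits, radius = radius),
            class = "zf_fingerprint")
}

#' @export
print.zf_fingerprint <- function(x, ...) {
  cat(sprintf("<ECFP%d fingerprint: %d/%d bits set>\n",
              2L * x$radius, length(x$bits), x$n_bits))
  invisible(x)
}

# Unfolded 0-based bit indices from OpenBabel's 4096-bit ECFP space.
fingerprint_raw <- function(smiles, radius = 2L) {
  mol <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                  error = function(e) stop(parse_error(smiles)))
  vec <- ChemmineOB::fingerprint_OB(mol, paste0("ECFP", 2L * radius))
  idx <- which(as.numeric(vec) != 0) - 1L
  if (length(idx) == 0L) stop(parse_error(smiles, "fingerprint computation failed"))
  as.integer(idx)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` on the set bits. Two empty fingerprints
#' have undefined similarity; it is defined here as 0 (with a warning) so
#' that similarity matrices stay total.
#'
#' @param a,b Objects of class `"zf_fingerprint"` with equal `n_bits`.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "zf_fingerprint"), inherits(b, "zf_fingerprint"))
  if (a$n_bits != b$n_bits) stop("fingerprints have different n_bits")
  ni <- length(intersect(a$bits, b$bits))
  nu <- length(union(a$bits, b$bits))
  if (nu == 0L) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  ni / nu
}

#' Pairwise Tanimoto similarity matrix for a compound library
#'
#' Standardises nothing: compounds are fingerprinted as given (use
#' [standardize_structure()] upstream). The result is symmetric with unit
#' diagonal and carries `compound_id`s as dimnames.
#'
#' @param compounds A compound table (see [compound_library()]) or a
#'   character vector of SMILES. A plain character vector is given ids
#'   `cmp1...cmpN` unless named.
#' @param radius,n_bits Fingerprint parameters, see [compute_fingerprint()].
#' @return A symmetric numeric matrix of class `"zf_simmat"`.
#' @export
similarity_matrix <- function(compounds, radius = 2L, n_bits = 2048L) {
  cmp <- as_compound_input(compounds)
  fps <- lapply(cmp$smiles, function(s) {
    tryCatch(compute_fingerprint(s, radius = radius, n_bits = n_bits),
             zfscreen_parse_error = function(e) NULL)
  })
  bad <- vapply(fps, is.null, logical(1))
  if (any(bad)) {
    stop(parse_error(cmp$compound_id[bad],
                     "unparseable compounds in similarity_matrix"))
  }
  n <- length(fps)
  # bit-incidence matrix; intersections via a single crossprod
  B <- matrix(0, n, n_bits)
  for (i in seq_len(n)) B[i, fps[[i]]$bits + 1L] <- 1
  inter <- tcrossprod(B)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  m <- ifelse(uni > 0, inter / uni, 0)
  diag(m) <- 1
  dimnames(m) <- list(cmp$compound_id, cmp$compound_id)
  class(m) <- c("zf_simmat", class(m))
  m
}

# Accept a compound table or a (possibly named) SMILES vector.
as_compound_input <- function(compounds) {
  if (is.data.frame(compounds)) {
    stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
    list(compound_id = as.character(compounds$compound_id),
         smiles = as.character(compounds$smiles))
  } else if (is.character(compounds)) {
    ids <- names(compounds)
    if (is.null(ids)) ids <- paste0("cmp", seq_along(compounds))
    list(compound_id = ids, smiles = unname(compounds))
  } else {
    stop("compounds must be a compound table or a character vector of SMILES")
  }
}

#' Write a similarity matrix as CSV
#'
#' @param m Matrix from [similarity_matrix()].
#' @param path Output file; compound ids become the header row and first
#'   column.
#' @export
write_similarity_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
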