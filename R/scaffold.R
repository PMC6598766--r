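#' Bemis-Murcko scaffold of a structure
#'
#' Reduces a molecule to its ring systems plus the linker atoms connecting
#' them, pruning all side chains. Terminal atoms attached to the retained
#' framework by a double or triple bond (e.g. a ring carbonyl oxygen) are
#' kept, following the convention of standard cheminformatics toolkits.
#' Acyclic molecules have no scaffold and return the empty string.
#'
#' @param smiles A single standardised SMILES string.
#' @return Canonical SMILES of the scaffold, or `""` for acyclic molecules.
#' @export
#' @examples
#' bemis_murcko_scaffold("Cc1ccccc1")  # "c1ccccc1"
#' bemis_murcko_scaffold("CCO")        # "" (acyclic)
bemis_murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(ob_canonical(smiles)[1])) stop(parse_error(smiles))
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  # drop explicit hydrogens from consideration
  sym <- sub("_.*$", "", rownames(ab))
  n_atoms <- nrow(ab)
  if (is.null(bb) || nrow(bb) == 0L) return("")
  edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  order_ <- as.integer(bb[, 3])

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  # ring atoms: endpoints of edges that lie on a cycle (non-bridges)
  bridges <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(nrow(edges)), bridges)
  ring_atoms <- unique(as.vector(edges[cyc_edges, , drop = FALSE]))
  ring_atoms <- setdiff(ring_atoms, which(sym == "H"))
  if (length(ring_atoms) == 0L) return("")

  # framework = rings + linkers: iteratively strip non-ring terminal atoms
  keep <- setdiff(seq_len(n_atoms), which(sym == "H"))
  repeat {
    sub_edges <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    deg <- tabulate(as.vector(sub_edges), nbins = n_atoms)
    prune <- setdiff(keep[deg[keep] <= 1L], ring_atoms)
    if (length(prune) == 0L) break
    keep <- setdiff(keep, prune)
  }

  # retain terminal atoms multiply-bonded to the framework (exocyclic =O etc.)
  repeat {
    extra <- integer(0)
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      if (order_[k] >= 2L) {
        if (a %in% keep && !(b %in% keep) && sym[b] != "H") extra <- c(extra, b)
        if (b %in% keep && !(a %in% keep) && sym[a] != "H") extra <- c(extra, a)
      }
    }
    extra <- setdiff(unique(extra), keep)
    if (length(extra) == 0L) break
    keep <- c(keep, extra)
  }

  sub <- ChemmineR::atomsubset(sdf, sort(keep))
  sset <- methods::new("SDFset", SDF = list(sub), ID = "scaffold")
  smi <- as.character(ChemmineR::sdf2smiles(sset))
  smi <- sub("\\s.*$", "", smi)
  out <- ob_canonical(smi)[1]
  if (is.na(out)) stop(parse_error(smiles, "scaffold extraction failed"))
  out
}

#' Scaffold composition of a compound library
#'
#' Tallies Bemis-Murcko scaffolds across a library: how many distinct
#' scaffolds, how many of them represent a single compound (singletons), and
#' how many compounds are acyclic (empty scaffold, excluded from the
#' scaffold count). Parse failures are counted and reported, not fatal.
#'
#' @param compounds A compound table or character vector of SMILES (see
#'   [similarity_matrix()] for the accepted forms).
#' @return An object of class `"zf_scaffold_summary"`: a list with
#'   `n_compounds`, `n_scaffolds`, `n_singleton_scaffolds`, `n_acyclic`,
#'   `n_parse_failed` and `scaffold_to_members` (named list mapping scaffold
#'   SMILES to member compound ids).
#' @export
scaffold_summary <- function(compounds) {
  cmp <- as_compound_input(compounds)
  n <- length(cmp$smiles)
  if (n == 0L) {
    return(structure(list(n_compounds = 0L, n_scaffolds = 0L,
                          n_singleton_scaffolds = 0L, n_acyclic = 0L,
                          n_parse_failed = 0L,
                          scaffold_to_members = list()),
                     class = "zf_scaffold_summary"))
  }
  sc <- vapply(cmp$smiles, function(s) {
    tryCatch(bemis_murcko_scaffold(s),
             zfscreen_parse_error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  failed <- is.na(sc)
  acyclic <- !failed & sc == ""
  cyclic <- !failed & !acyclic
  members <- split(cmp$compound_id[cyclic], sc[cyclic])
  members <- members[order(names(members))]
  structure(list(
    n_compounds = n,
    n_scaffolds = length(members),
    n_singleton_scaffolds = sum(lengths(members) == 1L),
    n_acyclic = sum(acyclic),
    n_parse_failed = sum(failed),
    scaffold_to_members = members
  ), class = "zf_scaffold_summary")
}

#' @export
print.zf_scaffold_summary <- function(x, ...) {
  cat(sprintf(
    "Scaffold summary: %d compounds, %d scaffolds (%d singletons), %d acyclic%s\n",
    x$n_compounds, x$n_scaffolds, x$n_singleton_scaffolds, x$n_acyclic,
    if (x$n_parse_failed > 0) sprintf(", %d parse failures", x$n_parse_failed) else ""
  ))
  invisible(x)
}

#' Write a scaffold summary to CSV and JSON
#'
#' @param x A `"zf_scaffold_summary"`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @export
write_scaffold_summary <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "zf_scaffold_summary"))
  if (!is.null(csv_path)) {
    df <- data.frame(
      scaffold = names(x$scaffold_to_members),
      n_members = lengths(x$scaffold_to_members),
      members = vapply(x$scaffold_to_members, paste, character(1), collapse = ";"),
      row.names = NULL
    )
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(x), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
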