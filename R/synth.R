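# Synthetic-screen generator: two overlapping compound libraries with
# planted scaffold families and activity classes, plus a simulator of the
# ordinal per-embryo scoring with noise and embryo death. Chemistry is
# template-grafted SMILES (substituents spliced into a core at a marked
# position), which keeps every structure valid and makes within-family
# similarity controllable without any generative model.

zf_classes <- c("downstream_agonist", "receptor_agonist", "ear_specific",
                "transcription_inhibitor", "inactive", "toxic")

# Per-embryo target scores by planted class and assay. vcanb: 0 = full
# rescue (suppression of the overexpressed marker), 3 = no effect. mbp:
# 3 = expression restored, 1 = mutant level, 0 = globally suppressed.
# fr24 re-screen reads vcanb in the strong allele.
zf_class_targets <- function() {
  rbind(
    downstream_agonist      = c(vcanb_tb233c = 0, mbp_tb233c = 3, vcanb_fr24 = 0),
    receptor_agonist        = c(vcanb_tb233c = 0, mbp_tb233c = 3, vcanb_fr24 = 3),
    ear_specific            = c(vcanb_tb233c = 0, mbp_tb233c = 1, vcanb_fr24 = 3),
    transcription_inhibitor = c(vcanb_tb233c = 0, mbp_tb233c = 0, vcanb_fr24 = 3),
    inactive                = c(vcanb_tb233c = 3, mbp_tb233c = 1, vcanb_fr24 = 3),
    toxic                   = c(vcanb_tb233c = 3, mbp_tb233c = 1, vcanb_fr24 = 3)
  )
}

#' Default planted scaffold families
#'
#' Each family is a core SMILES with a `{R}` attachment point and a pool of
#' substituents grafted into it, emulating the kinds of series found in
#' bioactive screening collections (dihydropyridines, xanthines, flavones,
#' quinolones, benzodiazepine-like and triterpenoid-like cores).
#'
#' @return A named list of `list(core, subs)` records.
#' @export
default_scaffold_families <- function() {
  subs_common <- c("C", "CC", "CCC", "CC(C)C", "CCCC", "OC", "OCC", "N(C)C",
                   "Cl", "F", "Br", "C#N", "C(F)(F)F", "CO", "CCO", "OC(C)C",
                   "N", "NC", "CCN", "O")
  list(
    dihydropyridine = list(
      core = "CCOC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1ccc({R})cc1",
      subs = subs_common),
    xanthine = list(
      core = "Cn1c(=O)c2c(ncn2{R})n(C)c1=O",
      subs = c("C", "CC", "CCC", "CCCC", "CC(C)C", "CCO", "CCN", "CCCO",
               "CC=C", "CCCC(C)C", "Cc1ccccc1", "CCc1ccccc1", "CCCN",
               "CC(C)O", "CCOC", "CCCC#N", "CC(C)CC", "CCCCC", "CCl", "CCF")),
    flavone = list(
      core = "O=c1cc(-c2ccc({R})cc2)oc2ccccc12",
      subs = subs_common),
    quinolone = list(
      core = "CCn1cc(C(=O)O)c(=O)c2cc({R})ccc21",
      subs = subs_common),
    benzodiazepinone = list(
      core = "O=C1CN=C(c2ccc({R})cc2)c2ccccc2N1",
      subs = subs_common),
    terpenoid = list(
      core = "CC1(C)CCC2(C(=O)OC{R})CCC3(C)C(=CC(=O)C4C5(C)CCC(O)C(C)(C)C5CCC43C)C12",
      subs = c("", "C", "CC", "CCC", "CC(C)C", "CCCC", "CCO", "CCCO", "CCN",
               "COC", "CCOC", "CC(C)O", "CCCC(C)C", "CCCCC", "CC=C", "CCC#N",
               "CCl", "CCF", "CBr", "CC(C)(C)C"))
  )
}

# Filler chemistry: two-point cores crossed with substituents give a large
# diverse singleton pool.
filler_cores <- function() {
  c("c1ccc({R1})c({R2})c1", "c1ccc(C({R1}){R2})cc1", "c1ccnc({R1})c1{R2}",
    "c1csc({R1})c1{R2}", "c1coc({R1})c1{R2}", "C1CCC({R1})C({R2})C1",
    "c1cnc({R1})nc1{R2}", "c1cc({R1})ccc1O{R2}", "c1cc({R1})ccc1N{R2}",
    "c1cc({R1})ccc1C(=O)O{R2}", "c1ccc2c(c1)cccc2{R1}",
    "c1ccc(-c2ccc({R1})cc2)cc1", "C1CN({R1})CCN1{R2}",
    "c1cc2ccccc2n1{R1}", "c1ccc(S(=O)(=O)N{R1})cc1",
    "c1ccc(C(=O)N{R1})cc1", "c1cc(O{R1})cc(O{R2})c1",
    "c1ccc(/C=C/{R1})cc1", "C1COC({R1})CN1{R2}", "c1cnn({R1})c1{R2}")
}

filler_subs <- function() {
  c("C", "CC", "CCC", "CCCC", "CC(C)C", "CCO", "CO", "OC", "N", "NC",
    "N(C)C", "Cl", "F", "Br", "C#N", "C(F)(F)F", "C(C)=O", "C(=O)OC",
    "c1ccccc1", "Cc1ccccc1", "CCN", "OCC", "CC(C)O", "CCCO", "CC=C")
}

graft <- function(core, r1, r2 = NULL) {
  s <- sub("{R}", r1, core, fixed = TRUE)
  s <- sub("{R1}", r1, s, fixed = TRUE)
  if (!is.null(r2)) s <- sub("{R2}", r2, s, fixed = TRUE)
  # unused second attachment point collapses to hydrogen
  gsub("\\(\\{R2\\}\\)|\\{R2\\}", "", s)
}

#' Configuration for the synthetic screen generator
#'
#' Defaults emulate the design of a two-library whole-organism screen:
#' libraries of 1000 and 2000 compounds with 5% of the first library also
#' present in the second, a 5% toxic fraction, about 4% of compounds active
#' in some class, and mild ordinal scoring noise with rare background
#' embryo death.
#'
#' @param n_compounds Integer vector of length 2: library sizes.
#' @param duplicate_fraction Fraction of the first library copied into the
#'   second (`round(duplicate_fraction * n_compounds[1])` duplicate pairs).
#' @param scaffold_families See [default_scaffold_families()].
#' @param class_proportions Named proportions over the six planted classes;
#'   must sum to 1.
#' @param sar_coherence Probability that a scaffold-family member carries
#'   its family's planted class rather than an independent draw.
#' @param noise Per-embryo probability that a score deviates by one unit
#'   from its class target (split evenly between -1 and +1, clamped to
#'   0-3).
#' @param death_prob Named per-class per-embryo death probabilities.
#' @param family_fraction Fraction of each library drawn from scaffold
#'   families rather than singleton fillers.
#' @param seed Integer master seed; all stages derive substreams from it.
#' @return A list of class `"zf_synth_config"`.
#' @export
synth_config <- function(n_compounds = c(1000L, 2000L),
                         duplicate_fraction = 0.05,
                         scaffold_families = default_scaffold_families(),
                         class_proportions = c(
                           downstream_agonist = 0.01, receptor_agonist = 0.01,
                           ear_specific = 0.01, transcription_inhibitor = 0.01,
                           inactive = 0.91, toxic = 0.05),
                         sar_coherence = 0.8,
                         noise = 0.15,
                         death_prob = c(
                           downstream_agonist = 0.005, receptor_agonist = 0.005,
                           ear_specific = 0.005, transcription_inhibitor = 0.005,
                           inactive = 0.005, toxic = 0.9),
                         family_fraction = 0.15,
                         seed = 1L) {
  stopifnot(length(n_compounds) == 2, all(n_compounds >= 10),
            duplicate_fraction >= 0, duplicate_fraction < 1,
            abs(sum(class_proportions) - 1) < 1e-8,
            setequal(names(class_proportions), zf_classes),
            setequal(names(death_prob), zf_classes),
            sar_coherence >= 0, sar_coherence <= 1,
            noise >= 0, noise < 1, seed == as.integer(seed),
            abs(seed) < 2^31 - 100)
  structure(list(
    n_compounds = as.integer(n_compounds),
    duplicate_fraction = duplicate_fraction,
    scaffold_families = scaffold_families,
    class_proportions = class_proportions[zf_classes],
    sar_coherence = sar_coherence,
    noise = noise,
    death_prob = death_prob[zf_classes],
    family_fraction = family_fraction,
    seed = as.integer(seed)
  ), class = "zf_synth_config")
}

#' Generate a synthetic two-library compound collection
#'
#' Builds both libraries by grafting substituents onto the configured
#' scaffold-family cores (guaranteeing structured within-family similarity)
#' and filling the remainder with diverse singletons; a configured fraction
#' of the first library reappears in the second under new plate/well ids.
#' Every generated SMILES is validated by parsing; the rare graft that fails
#' to parse is replaced by the next substituent and logged. Deterministic
#' under the config seed.
#'
#' @param cfg A [synth_config()].
#' @return A list: `compounds` (data.frame: `compound_id`, `library_id`,
#'   `plate`, `well`, `name`, `smiles`) and `truth` (class
#'   `"zf_ground_truth"`: `classes` data.frame mapping `compound_id` to
#'   planted `class` and `family`, plus `duplicates` data.frame of
#'   `id_a`/`id_b` pairs).
#' @export
generate_library <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "zf_synth_config"))
  with_seed(cfg$seed, {
    a <- build_one_library(cfg, "LIB1", "T", cfg$n_compounds[1])
    b <- build_one_library(cfg, "LIB2", "S", cfg$n_compounds[2])
    n_dup <- round(cfg$duplicate_fraction * cfg$n_compounds[1])
    duplicates <- data.frame(id_a = character(0), id_b = character(0),
                             stringsAsFactors = FALSE)
    if (n_dup > 0) {
      take <- sort(sample(seq_len(nrow(a$compounds)), n_dup))
      filler_rows <- which(b$truth$family == "filler")
      if (length(filler_rows) < n_dup) {
        stop("not enough filler compounds in library 2 to host duplicates")
      }
      put <- filler_rows[seq_len(n_dup)]
      b$compounds$smiles[put] <- a$compounds$smiles[take]
      b$compounds$name[put] <- a$compounds$name[take]
      b$truth$class[put] <- a$truth$class[take]
      b$truth$family[put] <- a$truth$family[take]
      duplicates <- data.frame(id_a = a$compounds$compound_id[take],
                               id_b = b$compounds$compound_id[put],
                               stringsAsFactors = FALSE)
    }
    compounds <- rbind(a$compounds, b$compounds)
    truth <- structure(list(
      classes = rbind(a$truth, b$truth),
      duplicates = duplicates,
      seed = cfg$seed
    ), class = "zf_ground_truth")
    list(compounds = compounds, truth = truth)
  })
}

# One library: family members first, then fillers, laid out on 80-well
# plates (rows A-H, columns 02-11).
build_one_library <- function(cfg, library_id, plate_prefix, n) {
  fam_defs <- cfg$scaffold_families
  n_family_total <- round(cfg$family_fraction * n)
  per_family <- if (length(fam_defs) > 0) {
    base <- n_family_total %/% length(fam_defs)
    extra <- n_family_total %% length(fam_defs)
    pmin(base + (seq_along(fam_defs) <= extra),
         vapply(fam_defs, function(f) length(f$subs), integer(1)))
  } else integer(0)

  smiles <- character(0); family <- character(0); name <- character(0)
  for (k in seq_along(fam_defs)) {
    f <- fam_defs[[k]]
    fname <- names(fam_defs)[k]
    subs <- sample(f$subs, per_family[k])
    cand <- vapply(subs, function(s) graft(f$core, s), character(1))
    ok <- !is.na(ob_canonical(cand))
    if (any(!ok)) { # swap failed grafts for unused substituents
      pool <- setdiff(f$subs, subs)
      for (i in which(!ok)) {
        for (alt in pool) {
          alt_s <- graft(f$core, alt)
          if (!is.na(ob_canonical(alt_s)[1])) {
            cand[i] <- alt_s; pool <- setdiff(pool, alt); ok[i] <- TRUE
            message(sprintf("family %s: substituent replaced after parse failure", fname))
            break
          }
        }
      }
      cand <- cand[ok]
    }
    smiles <- c(smiles, cand)
    family <- c(family, rep(fname, length(cand)))
    name <- c(name, paste0(toupper(fname), "-", seq_along(cand)))
  }

  n_fill <- n - length(smiles)
  combos <- expand.grid(core = filler_cores(), r1 = filler_subs(),
                        r2 = filler_subs(), stringsAsFactors = FALSE)
  # oversample: cores with one attachment point collapse their r2 variants
  pick <- sample(nrow(combos), min(n_fill * 2 + 200, nrow(combos)))
  fill <- vapply(seq_along(pick), function(i) {
    graft(combos$core[pick[i]], combos$r1[pick[i]], combos$r2[pick[i]])
  }, character(1))
  fill <- fill[!is.na(ob_canonical(fill))]
  fill <- fill[!duplicated(fill)]
  if (length(fill) < n_fill) stop("filler pool exhausted; reduce library size")
  fill <- fill[seq_len(n_fill)]
  smiles <- c(smiles, fill)
  family <- c(family, rep("filler", n_fill))
  name <- c(name, paste0("FIL-", seq_len(n_fill)))

  # planted classes: one draw per family, members inherit with
  # probability sar_coherence; fillers draw independently
  fam_names <- names(fam_defs)
  fam_class <- sample(zf_classes, length(fam_names), replace = TRUE,
                      prob = cfg$class_proportions)
  names(fam_class) <- fam_names
  cls <- character(length(smiles))
  for (i in seq_along(smiles)) {
    if (family[i] == "filler") {
      cls[i] <- sample(zf_classes, 1, prob = cfg$class_proportions)
    } else if (stats::runif(1) < cfg$sar_coherence) {
      cls[i] <- fam_class[[family[i]]]
    } else {
      cls[i] <- sample(zf_classes, 1, prob = cfg$class_proportions)
    }
  }

  ord <- sample(length(smiles))  # shuffle plate layout
  smiles <- smiles[ord]; family <- family[ord]; cls <- cls[ord]
  name <- name[ord]

  wells <- plate_positions(length(smiles), plate_prefix)
  compound_id <- paste(library_id, wells$plate, wells$well, sep = "_")
  list(
    compounds = data.frame(
      compound_id = compound_id, library_id = library_id,
      plate = wells$plate, well = wells$well, name = name, smiles = smiles,
      stringsAsFactors = FALSE),
    truth = data.frame(
      compound_id = compound_id, class = cls, family = family,
      stringsAsFactors = FALSE)
  )
}

# Sequential 80-well plate layout (compound columns 2-11 only).
plate_positions <- function(n, prefix) {
  rows <- LETTERS[1:8]; cols <- sprintf("%02d", 2:11)
  per_plate <- length(rows) * length(cols)
  idx <- seq_len(n) - 1L
  plate <- sprintf("%s%02d", prefix, idx %/% per_plate + 1L)
  within <- idx %% per_plate
  well <- paste0(rows[within %/% length(cols) + 1L],
                 cols[within %% length(cols) + 1L])
  list(plate = plate, well = well)
}

#' Simulate screen wells for a synthetic library
#'
#' Draws per-embryo ordinal scores from each compound's planted class
#' (targets in the man page of [synth_config()]) with the configured noise
#' and death probabilities, following the staged screen design: a primary
#' well for every compound, two retests for compounds whose primary well
#' lands in categories A-C, two counter-screen wells for confirmed hits, and
#' one strong-allele well for counter-screen rescuers. Three embryos per
#' well. Deterministic under the config seed.
#'
#' @param lib Output of [generate_library()] (or its `compounds` element).
#' @param truth The matching `"zf_ground_truth"` (optional if `lib` is the
#'   full [generate_library()] list).
#' @param cfg The [synth_config()] used.
#' @return A well-results data.frame as accepted by [triage_screen()].
#' @export
simulate_screen <- function(lib, truth = NULL, cfg = synth_config()) {
  if (is.list(lib) && !is.data.frame(lib) && is.null(truth)) {
    truth <- lib$truth; lib <- lib$compounds
  }
  stopifnot(inherits(truth, "zf_ground_truth"))
  cls <- truth$classes$class[match(lib$compound_id, truth$classes$compound_id)]
  if (anyNA(cls)) stop("ground truth does not cover all compounds")
  targets <- zf_class_targets()

  with_seed(cfg$seed + 1L, {
    rows <- vector("list", nrow(lib) * 6L)
    k <- 0L
    add_well <- function(id, assay, replicate, class) {
      target <- targets[class, assay]
      dead <- stats::rbinom(3L, 1L, cfg$death_prob[[class]])
      n_dead <- sum(dead)
      n_live <- 3L - n_dead
      scores <- integer(0)
      if (n_live > 0) {
        delta <- sample(c(-1L, 0L, 1L), n_live, replace = TRUE,
                        prob = c(cfg$noise / 2, 1 - cfg$noise, cfg$noise / 2))
        scores <- pmin(pmax(target + delta, 0L), 3L)
      }
      k <<- k + 1L
      rows[[k]] <<- data.frame(
        compound_id = id, assay = assay, replicate = replicate,
        concentration_uM = 25,
        embryo_scores = paste(scores, collapse = ";"),
        n_embryos_found = 3L, n_dead_or_abnormal = n_dead,
        stringsAsFactors = FALSE)
      score_well(scores, 3L, n_dead)
    }

    for (i in seq_len(nrow(lib))) {
      id <- lib$compound_id[i]; class <- cls[i]
      prim <- add_well(id, "vcanb_tb233c", 1L, class)
      if (!categorize_primary(prim) %in% c("A", "B", "C")) next
      r2 <- add_well(id, "vcanb_tb233c", 2L, class)
      r3 <- add_well(id, "vcanb_tb233c", 3L, class)
      rsums <- vapply(list(r2, r3), function(s) {
        if (s$flag == "ok") as.numeric(s$sum) else NA_real_
      }, numeric(1))
      sel <- select_hits(prim$sum, rsums)
      if (!sel$is_hit) next
      m1 <- add_well(id, "mbp_tb233c", 1L, class)
      m2 <- add_well(id, "mbp_tb233c", 2L, class)
      msums <- vapply(list(m1, m2), function(s) {
        if (s$flag == "ok") as.numeric(s$sum) else NA_real_
      }, numeric(1))
      if (anyNA(msums) || classify_mbp(mean(msums)) != "rescue") next
      add_well(id, "vcanb_fr24", 1L, class)
    }
    out <- do.call(rbind, rows[seq_len(k)])
    rownames(out) <- NULL
    out
  })
}

#' Recovery metrics of a triage run against planted ground truth
#'
#' Derives each compound's pipeline class from its triage record (toxic /
#' inactive / the four active classes via counter-screen and mechanism
#' calls) and confronts it with the planted class: confusion matrix, hit
#' recall per active class and pooled over the two agonist classes, hit
#' precision, and classification accuracy over non-toxic compounds.
#'
#' @param truth A `"zf_ground_truth"` from [generate_library()].
#' @param records A `"zf_triage"` from [triage_screen()].
#' @return A list of class `"zf_recovery"`: `confusion` (planted x
#'   predicted), `hit_recall` (named, per active class), `agonist_recall`
#'   (pooled over agonist-class compounds), `hit_precision`,
#'   `accuracy_nontoxic`, `n`.
#' @export
evaluate_recovery <- function(truth, records) {
  stopifnot(inherits(truth, "zf_ground_truth"))
  idx <- match(records$compound_id, truth$classes$compound_id)
  if (anyNA(idx)) stop("triage records contain compound ids absent from truth")
  planted <- truth$classes$class[idx]

  predicted <- ifelse(
    !is.na(records$primary_flag) & records$primary_flag == "toxic", "toxic",
    ifelse(!records$is_hit, "inactive",
      ifelse(is.na(records$mbp_class), "unclassified",
        ifelse(records$mbp_class == "downregulated", "transcription_inhibitor",
          ifelse(records$mbp_class == "no_rescue", "ear_specific",
            ifelse(is.na(records$mechanism_class), "unclassified",
              ifelse(records$mechanism_class == "downstream",
                     "downstream_agonist",
                ifelse(records$mechanism_class == "receptor_candidate",
                       "receptor_agonist", "unclassified"))))))))

  lev <- c(zf_classes, "unclassified")
  confusion <- table(planted = factor(planted, levels = zf_classes),
                     predicted = factor(predicted, levels = lev))
  actives <- c("downstream_agonist", "receptor_agonist", "ear_specific",
               "transcription_inhibitor")
  hit_recall <- vapply(actives, function(cl) {
    sel <- planted == cl
    if (!any(sel)) return(NA_real_)
    mean(records$is_hit[sel])
  }, numeric(1))
  hit_precision <- if (any(records$is_hit)) {
    mean(planted[records$is_hit] %in% actives)
  } else NA_real_
  agonists <- planted %in% c("downstream_agonist", "receptor_agonist")
  agonist_recall <- if (any(agonists)) mean(records$is_hit[agonists])
                    else NA_real_
  nontoxic <- planted != "toxic"
  structure(list(
    confusion = confusion,
    hit_recall = hit_recall,
    agonist_recall = agonist_recall,
    hit_precision = hit_precision,
    accuracy_nontoxic = mean(predicted[nontoxic] == planted[nontoxic]),
    n = nrow(records)
  ), class = "zf_recovery")
}

#' @export
print.zf_recovery <- function(x, ...) {
  cat(sprintf("Recovery over %d compounds: accuracy (non-toxic) %.3f\n",
              x$n, x$accuracy_nontoxic))
  cat("Hit recall: ",
      paste(sprintf("%s=%.2f", names(x$hit_recall), x$hit_recall),
            collapse = " "), "\n")
  cat(sprintf("Hit precision: %.3f\n", x$hit_precision))
  invisible(x)
}
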