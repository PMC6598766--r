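# Shared fixtures and independent oracles.

# Fifty diverse drug-like structures (common scaffold chemotypes plus a few
# near-duplicates and analogue series, so similarity values span [0, 1]).
fixture_smiles <- function() {
  c(
    caffeine      = "Cn1c(=O)c2c(ncn2C)n(C)c1=O",
    theophylline  = "Cn1c(=O)c2[nH]cnc2n(C)c1=O",
    ibmx          = "CC(C)Cn1c(=O)c2[nH]cnc2n(C)c1=O",
    aspirin       = "CC(=O)Oc1ccccc1C(=O)O",
    salicylate    = "OC(=O)c1ccccc1O",
    paracetamol   = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen     = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
    naproxen      = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
    benzene       = "c1ccccc1",
    toluene       = "Cc1ccccc1",
    ethylbenzene  = "CCc1ccccc1",
    phenol        = "Oc1ccccc1",
    aniline       = "Nc1ccccc1",
    pyridine      = "c1ccncc1",
    nicotinamide  = "NC(=O)c1cccnc1",
    quinoline     = "c1ccc2ncccc2c1",
    indole        = "c1ccc2[nH]ccc2c1",
    tryptamine    = "NCCc1c[nH]c2ccccc12",
    serotonin     = "NCCc1c[nH]c2ccc(O)cc12",
    naphthalene   = "c1ccc2ccccc2c1",
    anthracene    = "c1ccc2cc3ccccc3cc2c1",
    cyclohexane   = "C1CCCCC1",
    cyclohexanol  = "OC1CCCCC1",
    cyclohexanone = "O=C1CCCCC1",
    ethanol       = "CCO",
    glycerol      = "OCC(O)CO",
    glucose       = "OCC1OC(O)C(O)C(O)C1O",
    urea          = "NC(N)=O",
    nifedipine    = "COC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1ccccc1[N+](=O)[O-]",
    nitrendipine  = "CCOC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1cccc([N+](=O)[O-])c1",
    nimodipine    = "COCCOC(=O)C1=C(C)NC(C)=C(C(=O)OC(C)C)C1c1cccc([N+](=O)[O-])c1",
    dhp_plain     = "COC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1ccccc1",
    flavone       = "O=c1cc(-c2ccccc2)oc2ccccc12",
    chrysin       = "O=c1cc(-c2ccccc2)oc2cc(O)cc(O)c12",
    tangeretin    = "COc1cc2oc(-c3ccc(OC)cc3)cc(=O)c2c(OC)c1OC",
    progesterone  = "CC(=O)C1CCC2C1(C)CCC1C2CCC2=CC(=O)CCC12C",
    testosterone  = "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
    estradiol     = "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",
    diazepam      = "CN1c2ccc(Cl)cc2C(c2ccccc2)=NCC1=O",
    nordazepam    = "O=C1CN=C(c2ccccc2)c2cc(Cl)ccc2N1",
    ciprofloxacin = "O=C(O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O",
    norfloxacin   = "CCn1cc(C(=O)O)c(=O)c2cc(N3CCNCC3)c(F)cc21",
    sulfanilamide = "Nc1ccc(S(N)(=O)=O)cc1",
    benzamide     = "NC(=O)c1ccccc1",
    biphenyl      = "c1ccc(-c2ccccc2)cc1",
    stilbene      = "C(=C/c1ccccc1)\\c1ccccc1",
    imidazole     = "c1c[nH]cn1",
    histamine     = "NCCc1c[nH]cn1",
    furan         = "c1ccoc1",
    thiophene     = "c1ccsc1"
  )
}

# Independent O(n^2) Tanimoto oracle on explicit bit sets.
brute_tanimoto <- function(bits_a, bits_b) {
  u <- length(union(bits_a, bits_b))
  if (u == 0) return(0)
  length(intersect(bits_a, bits_b)) / u
}

brute_similarity_matrix <- function(fps) {
  n <- length(fps)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- if (i == j) 1 else brute_tanimoto(fps[[i]]$bits, fps[[j]]$bits)
    }
  }
  m
}

# Independent O(n^3) Lance-Williams Ward clustering (ward.D2 convention:
# update on squared distances, report sqrt heights).
ward_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  S <- d^2
  id <- -(seq_len(n))
  sizes <- rep(1L, n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    idx <- which(alive)
    for (a in idx) for (b in idx) {
      if (a < b && S[a, b] < bestv) { bestv <- S[a, b]; best <- c(a, b) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestv)
    merges[step, ] <- sort(c(id[i], id[j]))
    for (k in idx) {
      if (k != i && k != j) {
        S[i, k] <- S[k, i] <-
          ((sizes[i] + sizes[k]) * S[i, k] + (sizes[j] + sizes[k]) * S[j, k] -
             sizes[k] * S[i, j]) / (sizes[i] + sizes[j] + sizes[k])
      }
    }
    sizes[i] <- sizes[i] + sizes[j]
    alive[j] <- FALSE
    id[i] <- step
  }
  list(merge = merges, height = heights)
}

# Session-level cache so expensive fingerprints are computed once.
.fixture_cache <- new.env(parent = emptyenv())

fixture_fingerprints <- function() {
  if (is.null(.fixture_cache$fps)) {
    smis <- standardize_structure(fixture_smiles())
    .fixture_cache$smis <- smis
    .fixture_cache$fps <- lapply(smis, compute_fingerprint)
  }
  .fixture_cache$fps
}

fixture_standardized <- function() {
  fixture_fingerprints()
  .fixture_cache$smis
}

# Small zero-noise synthetic run shared across tests.
fixture_zero_noise_run <- function(n = c(120L, 160L), seed = 7L) {
  key <- paste0("run_", seed, "_", paste(n, collapse = "x"))
  if (is.null(.fixture_cache[[key]])) {
    cfg <- synth_config(
      n_compounds = n, noise = 0,
      death_prob = c(downstream_agonist = 0, receptor_agonist = 0,
                     ear_specific = 0, transcription_inhibitor = 0,
                     inactive = 0, toxic = 1),
      seed = seed)
    lib <- generate_library(cfg)
    wells <- simulate_screen(lib, cfg = cfg)
    tri <- triage_screen(wells, compounds = lib$compounds)
    .fixture_cache[[key]] <- list(cfg = cfg, lib = lib, wells = wells,
                                  triage = tri)
  }
  .fixture_cache[[key]]
}
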