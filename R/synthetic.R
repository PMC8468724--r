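# ---------------------------------------------------------------------------
# Seeded synthetic-data generators. Each generator is a pure function of its
# arguments (bit-identical output per seed) and returns, next to the data, a
# ground-truth ledger sufficient for the paired pipeline stage's recovery
# test. Deterministic "exact planting" modes exist alongside stochastic ones
# so recovery tests can be exact.
# ---------------------------------------------------------------------------

#' Curated toy SMILES library
#'
#' Chemically valid by construction: ring-scaffold templates crossed with a
#' small substituent set. Used as the structure source for synthetic
#' bioactivity tables and chemical-space tests.
#'
#' @param n number of distinct SMILES wanted (max 132).
#' @param seed RNG seed controlling which combinations are drawn.
#' @return character vector of `n` distinct SMILES.
#' @export
toy_smiles_library <- function(n, seed = 1L) {
  scaffolds <- c("c1ccc(%s)cc1",        # benzene
                 "c1ccnc(%s)c1",        # pyridine
                 "c1ccc2[nH]c(%s)cc2c1",# indole
                 "c1ccc2nc(%s)ccc2c1",  # quinoline
                 "C1CCN(%s)CC1",        # piperidine
                 "C1COCCN1%s",          # morpholine
                 "c1cnc(%s)nc1",        # pyrimidine
                 "c1csc(%s)c1",         # thiophene
                 "c1coc(%s)c1",         # furan
                 "C1CCC(%s)CC1",        # cyclohexane
                 "c1cc2ccccc2cc1%s",    # naphthalene
                 "C1CC1%s")             # cyclopropane
  subst <- c("C", "CC", "CCO", "N", "O", "Cl", "F", "C(=O)N", "C(=O)O",
             "OC", "C#N")
  all_smi <- as.vector(outer(scaffolds, subst,
                             function(s, r) sprintf(s, r)))
  if (n > length(all_smi))
    stop("library holds at most ", length(all_smi), " structures")
  .with_seed(seed, sample(all_smi, n))
}

#' Generate a raw bioactivity table with planted rule violations
#'
#' Produces clean records with activities drawn log-uniformly over
#' [1, 10^6] nM (expressed in a mix of convertible units), duplicate groups
#' with known minima, and one block of records per filter rule, each
#' violating exactly that rule.
#'
#' @param seed RNG seed.
#' @param n_clean number of clean singleton compounds.
#' @param dup_sizes integer vector: measurement count of each duplicate
#'   group (e.g. `c(2, 3, 2, 4, 2)` for 5 groups).
#' @param violations named integer vector of planted counts per rule; names
#'   from `empty_value`, `unparseable`, `relation_censored`, `type_excluded`,
#'   `empty_units`, `units_not_convertible`, `low_confidence`.
#' @param min_confidence the confidence threshold the table is built against.
#' @return list with `records` (raw table, shuffled) and `truth`: per-rule
#'   violation counts, `n_surviving` compounds after curation, `class_counts`
#'   and `dup_minima` (named planted minima, nM).
#' @export
gen_bioactivity_table <- function(seed = 1L, n_clean = 20,
                                  dup_sizes = c(2, 3, 2, 4, 2),
                                  violations = c(empty_value = 2,
                                                 unparseable = 1,
                                                 relation_censored = 3,
                                                 type_excluded = 2,
                                                 empty_units = 2,
                                                 units_not_convertible = 2,
                                                 low_confidence = 4),
                                  min_confidence = 8) {
  stopifnot(all(names(violations) %in% .filter_rules))
  .with_seed(seed, {
    n_groups <- length(dup_sizes)
    n_bad <- sum(violations)
    smi <- toy_smiles_library(n_clean + n_groups + n_bad, seed = seed + 1)
    units_pool <- c("nM", "uM", "µM", "mM", "pM", "M")
    mk_row <- function(id, s, act_nM, unit = sample(units_pool, 1),
                       relation = "=", type = sample(c("IC50", "Ki"), 1),
                       conf = sample(8:9, 1)) {
      val <- act_nM / .unit_factors[.normalise_unit(unit)]
      data.frame(compound_id = id, smiles = s, standard_type = type,
                 standard_relation = relation,
                 standard_value = sprintf("%.17g", val),
                 standard_units = unit, confidence_score = conf,
                 target_id = "T1", stringsAsFactors = FALSE)
    }
    rows <- list()
    planted_act <- numeric(0)
    # clean singletons
    for (i in seq_len(n_clean)) {
      act <- 10^runif(1, 0, 6)
      planted_act <- c(planted_act, act)
      rows[[length(rows) + 1L]] <- mk_row(sprintf("CLEAN%03d", i), smi[i], act)
    }
    # duplicate groups with known minima
    dup_minima <- numeric(0)
    for (g in seq_len(n_groups)) {
      s <- smi[n_clean + g]
      acts <- sort(10^runif(dup_sizes[g], 0, 6))
      dup_minima <- c(dup_minima, acts[1])
      names(dup_minima)[g] <- sprintf("DUP%02d", g)
      planted_act <- c(planted_act, acts[1])
      for (m in seq_along(acts)) {
        rows[[length(rows) + 1L]] <- mk_row(sprintf("DUP%02d_%d", g, m), s,
                                            acts[m])
      }
    }
    # violation blocks: each row violates exactly one rule
    bad_i <- 0L
    for (rule in names(violations)) {
      for (v in seq_len(violations[[rule]])) {
        bad_i <- bad_i + 1L
        r <- mk_row(sprintf("BAD_%s_%d", rule, v),
                    smi[n_clean + n_groups + bad_i], 10^runif(1, 0, 6))
        if (rule == "empty_value") r$standard_value <- ""
        if (rule == "unparseable") r$standard_value <- "n.d."
        if (rule == "relation_censored")
          r$standard_relation <- sample(c(">", ">="), 1)
        if (rule == "type_excluded")
          r$standard_type <- sample(c("FC", "Ratio"), 1)
        if (rule == "empty_units") r$standard_units <- ""
        if (rule == "units_not_convertible")
          r$standard_units <- sample(c("%", "/M/s", "hr"), 1)
        if (rule == "low_confidence")
          r$confidence_score <- sample(0:(min_confidence - 1), 1)
        rows[[length(rows) + 1L]] <- r
      }
    }
    records <- do.call(rbind, rows)
    records <- records[sample(nrow(records)), , drop = FALSE]
    rownames(records) <- NULL
    cls <- table(assign_activity_class(planted_act))
    list(records = records,
         truth = list(violations = structure(as.integer(violations),
                                             names = names(violations)),
                      n_surviving = as.integer(n_clean + n_groups),
                      class_counts = cls,
                      dup_minima = dup_minima))
  })
}

# exact E[Tanimoto] of a profile with hit prob p on the k reference residues
# and background rate q on the remaining n-k: sim = H/(k+B), H ~ Bin(k, p)
# independent of B ~ Bin(n-k, q)
.expected_plif_sim <- function(p, q, k, n_residues) {
  b <- 0:(n_residues - k)
  k * p * sum(stats::dbinom(b, n_residues - k, q) / (k + b))
}

#' Generate a synthetic residue-contact matrix with a planted class signal
#'
#' The X-ray reference ligand contacts residues 1..k. Every active reproduces
#' each reference contact with probability `p_active`, inactives with
#' `p_inactive` and moderates with their mean; every off-reference residue is
#' contacted with background probability `q`. Docking scores are drawn
#' independently of class (score ~ N(-8, 1)); heavy-atom counts uniform in
#' 15..40.
#'
#' @param seed RNG seed.
#' @param n_active,n_moderate,n_inactive class sizes.
#' @param n_residues residue universe size.
#' @param k number of reference contacts.
#' @param p_active,p_inactive reference-contact reproduction probabilities
#'   (requires `p_active >= p_inactive`).
#' @param q off-reference background contact rate.
#' @return list with `matrix` (a labelled [contact_matrix()]), `reference`
#'   (named binary profile) and `truth` (expected full-profile similarity per
#'   class, expected subset-restricted similarity = p, base active rate).
#' @export
gen_plif_matrix <- function(seed = 1L, n_active = 50, n_moderate = 50,
                            n_inactive = 100, n_residues = 200, k = 10,
                            p_active = 0.9, p_inactive = 0.3, q = 0.05) {
  stopifnot(k <= n_residues, p_active >= p_inactive,
            all(c(p_active, p_inactive, q) >= 0),
            all(c(p_active, p_inactive, q) <= 1))
  p_moderate <- (p_active + p_inactive) / 2
  .with_seed(seed, {
    residues <- sprintf("A:RES:%d", seq_len(n_residues))
    labels <- rep(c("active", "moderate", "inactive"),
                  c(n_active, n_moderate, n_inactive))
    p_of <- c(active = p_active, moderate = p_moderate,
              inactive = p_inactive)
    n <- length(labels)
    contacts <- matrix(0L, nrow = n, ncol = n_residues)
    for (i in seq_len(n)) {
      p <- p_of[labels[i]]
      contacts[i, seq_len(k)] <- stats::rbinom(k, 1, p)
      if (k < n_residues)
        contacts[i, (k + 1):n_residues] <- stats::rbinom(n_residues - k, 1, q)
    }
    cm <- contact_matrix(contacts,
                         compound_ids = sprintf("CPD%03d", seq_len(n)),
                         residues = residues,
                         docking_score = stats::rnorm(n, -8, 1),
                         n_heavy_atoms = sample(15:40, n, replace = TRUE),
                         labels = labels)
    reference <- as.integer(seq_len(n_residues) <= k)
    names(reference) <- residues
    truth <- list(
      expected_sim_full = vapply(p_of, .expected_plif_sim, numeric(1),
                                 q = q, k = k, n_residues = n_residues),
      expected_sim_subset = p_of,
      base_active_rate = n_active / n)
    list(matrix = cm, reference = reference, truth = truth)
  })
}

#' Generate a descriptor table with class-separated Gaussian features
#'
#' Five informative dimensions carry class means placed `separation` pooled
#' standard deviations apart (active at 0, moderate at `separation`, inactive
#' at `2 * separation`; unit SD); the remaining dimensions are pure noise.
#'
#' @param seed RNG seed.
#' @param n_active,n_moderate,n_inactive class sizes.
#' @param n_descriptors total feature count (default 200).
#' @param n_informative informative dimensions (default 5).
#' @param separation class-mean separation in pooled-SD units.
#' @return list with `data` (data.frame: `activity_class` + features),
#'   `compound_ids`, and `truth` (informative columns and class means).
#' @export
gen_descriptor_table <- function(seed = 1L, n_active = 200, n_moderate = 150,
                                 n_inactive = 150, n_descriptors = 200,
                                 n_informative = 5, separation = 2) {
  stopifnot(separation >= 0, n_informative <= n_descriptors)
  .with_seed(seed, {
    labels <- rep(c("active", "moderate", "inactive"),
                  c(n_active, n_moderate, n_inactive))
    n <- length(labels)
    shift <- c(active = 0, moderate = separation, inactive = 2 * separation)
    X <- matrix(stats::rnorm(n * n_descriptors), nrow = n)
    for (j in seq_len(n_informative)) {
      X[, j] <- X[, j] + shift[labels]
    }
    colnames(X) <- sprintf("D%03d", seq_len(n_descriptors))
    df <- data.frame(activity_class = factor(labels,
                                             levels = .activity_levels),
                     X, check.names = FALSE)
    list(data = df, compound_ids = sprintf("CPD%04d", seq_len(n)),
         truth = list(informative = colnames(X)[seq_len(n_informative)],
                      class_shift = shift))
  })
}

#' Generate an H-bond existence matrix with planted occupancies
#'
#' Deterministic mode plants exactly `round(occ * n_frames)` bonded frames
#' per residue, laid out from frame 1, so per-residue occupancies and the
#' >=1 / >=2 simultaneity fractions are exact and known in closed form.
#' Bernoulli mode draws frames independently at the stated rates.
#'
#' @param occupancies named vector of per-residue target occupancies in
#'   [0, 1] (names used as residue labels; default `R1`, `R2`, ...).
#' @param n_frames number of frames.
#' @param seed RNG seed (used in Bernoulli mode only).
#' @param mode `"deterministic"` (exact planting) or `"bernoulli"`.
#' @param spacing_ps frame spacing in ps (default 10).
#' @return list with `matrix` (an [hbond_matrix()]) and `truth`
#'   (`occupancy`, `frac_any`, `frac_two_residues`; exact in deterministic
#'   mode, expected values in Bernoulli mode).
#' @export
gen_hbond_matrix <- function(occupancies, n_frames, seed = 1L,
                             mode = c("deterministic", "bernoulli"),
                             spacing_ps = 10) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1, all(occupancies >= 0), all(occupancies <= 1))
  m <- length(occupancies)
  if (is.null(names(occupancies)))
    names(occupancies) <- paste0("R", seq_len(m))
  res <- names(occupancies)
  existence <- matrix(0L, nrow = m, ncol = n_frames)
  if (mode == "deterministic") {
    counts <- round(occupancies * n_frames)
    for (i in seq_len(m)) {
      if (counts[i] > 0) existence[i, seq_len(counts[i])] <- 1L
    }
    sorted <- sort(unname(counts), decreasing = TRUE)
    truth <- list(occupancy = counts / n_frames,
                  frac_any = if (m >= 1) sorted[1] / n_frames else 0,
                  frac_two_residues = if (m >= 2) sorted[2] / n_frames else 0)
  } else {
    existence <- .with_seed(seed, {
      t(vapply(seq_len(m), function(i)
        stats::rbinom(n_frames, 1, occupancies[i]), integer(n_frames)))
    })
    truth <- list(occupancy = occupancies,
                  frac_any = 1 - prod(1 - occupancies),
                  frac_two_residues = NA_real_)
  }
  bonds <- data.frame(donor = paste0("D", seq_len(m)),
                      hydrogen = paste0("H", seq_len(m)),
                      acceptor = paste0("A", seq_len(m)),
                      residue = res, stringsAsFactors = FALSE)
  hbm <- hbond_matrix(bonds, existence,
                      times = seq(0, by = spacing_ps,
                                  length.out = n_frames))
  list(matrix = hbm, truth = truth)
}

#' Generate a synthetic C-alpha trajectory with planted fluctuations
#'
#' Residue positions are fixed means (10 A apart on a line) plus isotropic
#' Gaussian jitter of standard deviation `sigma` per axis, so the expected
#' RMSF of every residue is `sigma * sqrt(3)`. Optionally a single-atom
#' ligand is planted whose minimum distance to the reference residue is
#' exactly 3 A in a chosen fraction of frames and 8 A otherwise, making
#' [fraction_within()] at the default 5 A cutoff recover `frac_within`
#' exactly.
#'
#' @param seed RNG seed.
#' @param n_residues number of C-alpha residues.
#' @param n_frames number of frames.
#' @param sigma per-axis jitter SD in Angstrom.
#' @param spacing_ps frame spacing in ps (default 10).
#' @param frac_within optional planted fraction of frames with ligand within
#'   5 A of residue 1 (rounded to a whole number of frames).
#' @return list with `trajectory`, and `truth` (`sigma`, `rmsf_expected`,
#'   `frac_within` actually planted).
#' @export
gen_trajectory <- function(seed = 1L, n_residues = 10, n_frames = 100,
                           sigma = 0.5, spacing_ps = 10,
                           frac_within = NULL) {
  stopifnot(n_frames >= 2, sigma >= 0)
  .with_seed(seed, {
    means <- cbind(10 * seq_len(n_residues), 0, 0)
    has_ligand <- !is.null(frac_within)
    n_atoms <- n_residues + has_ligand
    coords <- array(0, dim = c(n_frames, n_atoms, 3))
    for (f in seq_len(n_frames)) {
      jitter <- matrix(stats::rnorm(n_residues * 3, 0, sigma),
                       ncol = 3)
      coords[f, seq_len(n_residues), ] <- means + jitter
    }
    planted_frac <- NA_real_
    if (has_ligand) {
      n_close <- round(frac_within * n_frames)
      planted_frac <- n_close / n_frames
      offs <- c(rep(3, n_close), rep(8, n_frames - n_close))
      for (f in seq_len(n_frames)) {
        # offset from residue 1's jittered position along +y: exact distance
        coords[f, n_atoms, ] <- coords[f, 1, ] + c(0, offs[f], 0)
      }
    }
    atoms <- data.frame(
      atom_id = seq_len(n_atoms),
      residue_id = c(seq_len(n_residues), if (has_ligand) 9999L),
      residue_name = c(rep("ALA", n_residues), if (has_ligand) "LIG"),
      chain = c(rep("A", n_residues), if (has_ligand) "X"),
      element = "C",
      role = "none",
      ligand = c(rep(FALSE, n_residues), if (has_ligand) TRUE),
      bonded_to = NA, stringsAsFactors = FALSE)
    atoms$residue_name[1] <- "THR"
    traj <- trajectory(seq(0, by = spacing_ps, length.out = n_frames),
                       coords, atoms)
    list(trajectory = traj,
         truth = list(sigma = sigma, rmsf_expected = sigma * sqrt(3),
                      frac_within = planted_frac))
  })
}
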