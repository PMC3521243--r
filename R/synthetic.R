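# Synthetic fixture generator with planted ground truth. Emulates the five
# input dialects (domain annotations, activities, binding sites, curation
# lists, descriptors) so the whole pipeline is testable without database
# exports. Every generator is a pure function of its configuration and
# seed.

#' Synthetic data configuration
#'
#' Defaults encode the study conditions the generator emulates: about half
#' of all targets are multi-domain (`p_multidomain = 0.5`, matching the
#' observed 50.6% of human drug targets with more than one Pfam domain) and
#' family usage follows a discrete power law with exponent 2.07, the value
#' observed for proteome-wide Pfam family frequencies.
#'
#' @param n_targets Number of protein targets.
#' @param n_families Size of the family pool.
#' @param family_frequency_alpha Power-law exponent for family usage.
#' @param p_multidomain Probability a target carries more than one distinct
#'   family.
#' @param p_repeat Probability the planted family appears as two copies.
#' @param noise_fraction Fraction of binding residues planted outside the
#'   binding family (scalar, or one value per target).
#' @param k_binding Binding residues sampled inside the planted family.
#' @param n_compounds Size of the compound pool.
#' @param mean_qualifying Mean number of qualifying activities per target
#'   (at least one is always planted).
#' @param distractor_rates Named probabilities for the four distractor
#'   kinds (`assay`, `flagged`, `weak`, `wrong_type`) per target.
#' @param rng_seed Mandatory RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_targets = 200L, n_families = 30L,
                         family_frequency_alpha = 2.07,
                         p_multidomain = 0.5, p_repeat = 0.15,
                         noise_fraction = 0, k_binding = 10L,
                         n_compounds = 300L, mean_qualifying = 3,
                         distractor_rates = c(assay = 0.5, flagged = 0.5,
                                              weak = 0.5, wrong_type = 0.5),
                         rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory", call. = FALSE)
  stopifnot(n_targets >= 1, n_families >= 2, family_frequency_alpha > 1,
            p_multidomain >= 0, p_multidomain <= 1,
            p_repeat >= 0, p_repeat <= 1,
            all(noise_fraction >= 0), all(noise_fraction < 1),
            k_binding >= 1, all(distractor_rates >= 0),
            all(distractor_rates <= 1))
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic proteome with planted binding families
#'
#' Families get usage weights drawn from the discrete power law with the
#' configured exponent, so the realized family-frequency spectrum follows
#' the planted exponent at large `n_targets`. Each target carries one
#' distinct family, or two to three with probability `p_multidomain`; the
#' first family drawn is the planted ligand-binding family and may occur as
#' two copies. Domain intervals never overlap within a target (laid out
#' sequentially with gaps), and sequence lengths cover all intervals.
#'
#' @param config A [synth_config()].
#' @return A list: `targets` (`uniprot`, `sequence_length`, `species_tag`),
#'   `domains` (annotation table), `truth` (`uniprot`, `planted_family`,
#'   `n_families`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$rng_seed, {
    fams <- sprintf("F%04d", seq_len(config$n_families))
    w <- rzeta(config$n_families, config$family_frequency_alpha, 1L)

    # stage 1: architectures (distinct families per target)
    arch <- lapply(seq_len(config$n_targets), function(i) {
      nf <- if (stats::runif(1) < config$p_multidomain) sample(2:3, 1L) else 1L
      nf <- min(nf, config$n_families)
      fams[sample.int(config$n_families, nf, prob = w)]
    })
    # families that will be seeded: sole family of some target (every
    # target receives a qualifying activity downstream)
    seeds0 <- unique(unlist(arch[lengths(arch) == 1L]))

    dom_rows <- vector("list", config$n_targets)
    tgt_rows <- vector("list", config$n_targets)
    truth_rows <- vector("list", config$n_targets)
    for (i in seq_len(config$n_targets)) {
      acc <- sprintf("T%05d", i)
      tfams <- arch[[i]]
      # the planted binding family is the one the heuristic can recover:
      # the target's unique seed family when it has one, else its first
      sf <- intersect(tfams, seeds0)
      planted <- if (length(sf) == 1L) sf else tfams[1L]
      instances <- tfams
      if (stats::runif(1) < config$p_repeat) instances <- c(instances, planted)
      instances <- sample(instances)           # shuffle layout order
      pos <- 1L + sample.int(40L, 1L)
      starts <- integer(length(instances)); ends <- integer(length(instances))
      for (j in seq_along(instances)) {
        len <- sample(80:200, 1L)
        starts[j] <- pos
        ends[j] <- pos + len - 1L
        pos <- ends[j] + sample(10:50, 1L)
      }
      # generous undomained tail so binding-site noise placement (residues
      # outside the planted family) is always feasible
      seq_len_i <- pos + sample(60:120, 1L)
      dom_rows[[i]] <- data.frame(uniprot = acc, pfam = instances,
                                  start = starts, end = ends,
                                  stringsAsFactors = FALSE)
      tgt_rows[[i]] <- data.frame(uniprot = acc, sequence_length = seq_len_i,
                                  species_tag = "synthetic",
                                  stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(uniprot = acc, planted_family = planted,
                                    n_families = length(unique(tfams)),
                                    stringsAsFactors = FALSE)
    }
    list(targets = do.call(rbind, tgt_rows),
         domains = do.call(rbind, dom_rows),
         truth = do.call(rbind, truth_rows))
  })
}

#' Generate activities with planted qualifying records and distractors
#'
#' Every target receives at least one qualifying activity (binding assay
#' `B`, flags 0, allowed type, potency at or below 50 uM), so the expected
#' seed set equals the families of single-family targets by construction.
#' Distractor records violating exactly one filter dimension (wrong assay
#' type, flagged, weaker than threshold, disallowed activity type) are
#' added per target with the configured probabilities. The expected
#' mapping — the rows the three-case heuristic must emit — is derived from
#' the planted structure and returned as ground truth.
#'
#' @param proteome Output of [generate_proteome()].
#' @param config A [synth_config()].
#' @return A list: `activities` (activity table), `expected_seeds`
#'   (character vector), `expected_mapping` (mapping `data.frame`).
#' @export
generate_activities <- function(proteome, config) {
  stopifnot(inherits(config, "synth_config"))
  truth <- proteome$truth
  with_seed(config$rng_seed + 1L, {
    rows <- list()
    aid <- 0L
    add <- function(uniprot, assay, multi, complex, type, value, unit) {
      aid <<- aid + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        activity_id = as.character(aid),
        molregno = sprintf("C%05d", sample.int(config$n_compounds, 1L)),
        uniprot = uniprot, assay_type = assay,
        multi = multi, complex = complex, type = type,
        value = value, unit = unit, stringsAsFactors = FALSE)
      aid
    }
    qual_ids <- list()
    for (i in seq_len(nrow(truth))) {
      acc <- truth$uniprot[i]
      nq <- 1L + stats::rpois(1L, max(config$mean_qualifying - 1, 0))
      ids <- integer(nq)
      for (q in seq_len(nq)) {
        if (stats::runif(1) < 0.2) {                   # log-scale record
          ids[q] <- add(acc, "B", FALSE, FALSE, "pKd",
                        round(stats::runif(1, 4.31, 10), 3), "")
        } else {                                       # nM record <= 50 uM
          v <- round(10^stats::runif(1, -1, log10(50000)), 4)
          ids[q] <- add(acc, "B", FALSE, FALSE, "Ki", v, "nM")
        }
      }
      qual_ids[[acc]] <- ids
      r <- config$distractor_rates
      if (stats::runif(1) < r[["assay"]])
        add(acc, "F", FALSE, FALSE, "Ki", 10, "nM")
      if (stats::runif(1) < r[["flagged"]])
        add(acc, "B", TRUE, FALSE, "Ki", 10, "nM")
      if (stats::runif(1) < r[["weak"]])
        add(acc, "B", FALSE, FALSE, "Ki",
            round(stats::runif(1, 60, 1000), 2), "uM")
      if (stats::runif(1) < r[["wrong_type"]])
        add(acc, "B", FALSE, FALSE, "AC50", 10, "nM")
    }
    activities <- do.call(rbind, rows)

    # planted truth: seeds are the families of single-family targets;
    # a target maps iff it contains exactly one distinct seed family
    seeds <- sort(unique(truth$planted_family[truth$n_families == 1L]))
    fam_by_target <- lapply(split(proteome$domains$pfam,
                                  proteome$domains$uniprot), unique)
    exp_rows <- list()
    for (acc in truth$uniprot) {
      present <- intersect(fam_by_target[[acc]], seeds)
      if (length(present) != 1L) next
      ids <- qual_ids[[acc]]
      sel <- activities$activity_id %in% as.character(ids)
      exp_rows[[acc]] <- data.frame(activity = activities$activity_id[sel],
                                    domain = present,
                                    molregno = activities$molregno[sel],
                                    uniprot = acc,
                                    maptype = if (length(fam_by_target[[acc]]) == 1L)
                                      "single" else "multi",
                                    stringsAsFactors = FALSE)
    }
    expected <- if (length(exp_rows) > 0L) do.call(rbind, exp_rows) else
      data.frame(activity = character(0), domain = character(0),
                 molregno = character(0), uniprot = character(0),
                 maptype = character(0), stringsAsFactors = FALSE)
    expected <- expected[order(as.numeric(expected$activity)), , drop = FALSE]
    rownames(expected) <- NULL
    list(activities = activities, expected_seeds = seeds,
         expected_mapping = expected)
  })
}

#' Generate binding sites with controlled noise
#'
#' For each target, `k_binding` residues are sampled (without replacement)
#' inside the planted family's intervals and
#' `round(k * f / (1 - f))` residues outside them, so the fraction of
#' binding residues within the planted family is about `1 - f`. At
#' `noise_fraction = 0` every site lies fully within the planted family.
#'
#' @param proteome Output of [generate_proteome()].
#' @param config A [synth_config()]; `noise_fraction` may be a scalar or
#'   one value per target.
#' @return Binding-site `data.frame` with list-column `residues` and
#'   column `noise` recording each site's planted noise fraction.
#' @export
generate_binding_sites <- function(proteome, config) {
  stopifnot(inherits(config, "synth_config"))
  truth <- proteome$truth
  noise <- rep_len(config$noise_fraction, nrow(truth))
  with_seed(config$rng_seed + 2L, {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      acc <- truth$uniprot[i]
      dom <- proteome$domains[proteome$domains$uniprot == acc, , drop = FALSE]
      planted <- dom[dom$pfam == truth$planted_family[i], , drop = FALSE]
      inside_pool <- unlist(mapply(seq.int, planted$start, planted$end,
                                   SIMPLIFY = FALSE))
      k <- config$k_binding
      if (length(inside_pool) < k)
        stop(sprintf("planted family interval on %s shorter than k_binding", acc),
             call. = FALSE)
      f <- noise[i]
      m <- round(k * f / (1 - f))
      L <- proteome$targets$sequence_length[proteome$targets$uniprot == acc]
      outside_pool <- setdiff(seq_len(L), inside_pool)
      if (length(outside_pool) < m)
        stop(sprintf("not enough residues outside the planted family on %s", acc),
             call. = FALSE)
      res <- sort(c(sample(inside_pool, k),
                    if (m > 0L) sample(outside_pool, m)))
      rows[[i]] <- data.frame(uniprot = acc, source = "pdbe",
                              ligand = sprintf("L%02d", 1L + (i %% 90L)),
                              noise = f, stringsAsFactors = FALSE)
      rows[[i]]$residues <- list(res)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Draw a seeded discrete power-law sample
#'
#' Inverse-CDF draws from the zeta-normalized power law on
#' `{xmin, xmin + 1, ...}` under a fixed seed (see [rzeta()]).
#'
#' @param alpha Exponent (> 1).
#' @param xmin Lower support bound.
#' @param n Sample size.
#' @param seed RNG seed.
#' @return Integer-valued numeric vector.
#' @export
generate_powerlaw_sample <- function(alpha, xmin, n, seed) {
  with_seed(seed, rzeta(n, alpha, xmin))
}

#' Generate per-family Gaussian descriptor tables
#'
#' Draws multivariate Gaussian descriptor vectors per family (columns `mw`,
#' `alogp`, `psa`, `rtb`, `hbd`, `hba`), truncated at physical bounds: the
#' three count descriptors are rounded and clipped at zero, molecular
#' weight and polar surface area clipped at small positive values.
#'
#' @param families Character vector of family names.
#' @param means Named list: per family, a numeric 6-vector of descriptor
#'   means (order mw, alogp, psa, rtb, hbd, hba).
#' @param covariances A single 6x6 positive-semidefinite matrix, or a named
#'   list of per-family matrices.
#' @param n_per_family Compounds per family (scalar or per-family vector).
#' @param seed RNG seed.
#' @return A descriptor `data.frame` with an extra `family` column.
#' @export
generate_descriptors <- function(families, means, covariances, n_per_family,
                                 seed) {
  if (!all(families %in% names(means)))
    stop("means must be named for every family", call. = FALSE)
  get_cov <- function(f) if (is.list(covariances)) covariances[[f]] else covariances
  for (f in families) {
    S <- get_cov(f)
    if (is.null(S) || !is.matrix(S) || any(dim(S) != 6L) ||
        length(means[[f]]) != 6L)
      stop("dimension mismatch: means must be 6-vectors and covariances 6x6",
           call. = FALSE)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8)) stop("covariance not positive semi-definite",
                              call. = FALSE)
  }
  n_per_family <- rep_len(n_per_family, length(families))
  with_seed(seed, {
    out <- list()
    cid <- 0L
    for (i in seq_along(families)) {
      f <- families[i]
      m <- MASS::mvrnorm(n_per_family[i], means[[f]], get_cov(f))
      m <- matrix(m, ncol = 6L)
      colnames(m) <- c("mw", "alogp", "psa", "rtb", "hbd", "hba")
      df <- as.data.frame(m)
      df$mw <- pmax(df$mw, 50)
      df$psa <- pmax(df$psa, 0)
      for (col in c("rtb", "hbd", "hba")) df[[col]] <- pmax(round(df[[col]]), 0)
      df$molregno <- sprintf("D%06d", cid + seq_len(nrow(df)))
      cid <- cid + nrow(df)
      df$family <- f
      out[[f]] <- df[, c("molregno", "mw", "alogp", "psa", "rtb", "hbd",
                         "hba", "family")]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate the full fixture set
#'
#' Runs all generators under one configuration and, when `outdir` is given,
#' writes every table dialect plus the ground truth.
#'
#' @param config A [synth_config()].
#' @param outdir Optional output directory.
#' @return A list with `targets`, `domains`, `truth`, `activities`,
#'   `expected_seeds`, `expected_mapping`, `sites`.
#' @export
simulate_all <- function(config, outdir = NULL) {
  prot <- generate_proteome(config)
  act <- generate_activities(prot, config)
  sites <- generate_binding_sites(prot, config)
  res <- c(prot, act, list(sites = sites))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_domain_annotations(prot$domains, file.path(outdir, "domains.tsv"))
    write_tsv(prot$targets, file.path(outdir, "targets.tsv"))
    act2 <- act$activities
    write_activities(act2, file.path(outdir, "activities.tsv"))
    write_binding_sites(sites, file.path(outdir, "binding_sites.tsv"))
    write_tsv(prot$truth, file.path(outdir, "ground_truth_targets.tsv"))
    write_mappings(act$expected_mapping, file.path(outdir, "expected_mapping.tsv"))
    writeLines(act$expected_seeds, file.path(outdir, "expected_seeds.txt"))
  }
  res
}
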