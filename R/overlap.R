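# Validation machinery: compare annotated binding-site residues against
# Pfam-A domain boundaries. The central quantity is the fraction of binding
# residues lying within a family's intervals over all binding residues; a
# predicted domain is judged correct when this fraction is >= 0.5.

#' Is a residue inside a family's domain intervals?
#'
#' Union semantics over repeat copies: true iff `start <= residue <= end`
#' for any interval of that family.
#'
#' @param residue 1-based residue index.
#' @param hits Domain `data.frame` (columns `pfam`, `start`, `end`).
#' @param family Pfam family id.
#' @return Logical scalar.
#' @export
residue_in_family <- function(residue, hits, family) {
  stopifnot(residue >= 1L)
  h <- hits[hits$pfam == family, , drop = FALSE]
  any(h$start <= residue & residue <= h$end)
}

#' Overlap between a binding site and domain boundaries
#'
#' Counts binding residues inside vs outside domain intervals. With
#' `family` given, "inside" means inside that family's intervals (union over
#' copies); with `family = NULL`, inside any domain of the target. The
#' per-family share — the fraction of binding residues inside each family
#' present on the target — is always computed; shares need not sum to 1
#' (residues can fall outside every domain, or inside overlapping ones).
#'
#' @param residues Integer vector of binding-site residues (treated as a
#'   set; duplicates collapse).
#' @param domains Domain rows of the evaluated target.
#' @param family Optional family id restricting the "within" count.
#' @return A list of class `overlap_result`: `n_within`, `n_outside`,
#'   `fraction_within`, `ratio` (within/outside, `Inf` when all residues are
#'   within), `per_family_share`.
#' @export
compute_overlap <- function(residues, domains, family = NULL) {
  residues <- unique(as.integer(residues))
  if (length(residues) == 0L) stop("empty residue set", call. = FALSE)
  if (any(residues < 1L)) stop("residues must be >= 1", call. = FALSE)

  in_intervals <- function(starts, ends) {
    if (length(starts) == 0L) return(rep(FALSE, length(residues)))
    vapply(residues, function(r) any(starts <= r & r <= ends), logical(1))
  }
  fams <- unique(domains$pfam)
  shares <- vapply(fams, function(f) {
    h <- domains[domains$pfam == f, , drop = FALSE]
    mean(in_intervals(h$start, h$end))
  }, numeric(1))
  names(shares) <- fams

  if (is.null(family)) {
    within <- in_intervals(domains$start, domains$end)
  } else {
    h <- domains[domains$pfam == family, , drop = FALSE]
    within <- in_intervals(h$start, h$end)
  }
  n_within <- sum(within)
  n_outside <- length(residues) - n_within
  structure(list(n_within = n_within,
                 n_outside = n_outside,
                 fraction_within = n_within / length(residues),
                 ratio = if (n_outside == 0L) Inf else n_within / n_outside,
                 per_family_share = shares),
            class = "overlap_result")
}

#' Benchmark a predicted binding domain against an annotated site
#'
#' Applies the correctness rule: the prediction is `correct` when the
#' fraction of binding residues within the predicted family's intervals is
#' equal to or greater than 0.5, and `false` otherwise. The predicted
#' family must occur in the target's architecture — its absence signals an
#' upstream mapping bug and raises an error.
#'
#' @inheritParams compute_overlap
#' @param predicted_family The family the mapping assigned.
#' @return A list: `predicted_family`, `fraction_within`, `verdict`.
#' @export
benchmark_prediction <- function(residues, domains, predicted_family) {
  if (!predicted_family %in% domains$pfam)
    stop(sprintf("predicted family '%s' absent from target architecture",
                 predicted_family), call. = FALSE)
  ov <- compute_overlap(residues, domains, family = predicted_family)
  list(predicted_family = predicted_family,
       fraction_within = ov$fraction_within,
       verdict = if (ov$fraction_within >= 0.5) "correct" else "false")
}

#' Survival curve of within/outside binding ratios
#'
#' For ratios r_i = n_within/n_outside (with `Inf` when every residue lies
#' within a domain), computes the proportion of sites with ratio >= x over a
#' grid of x values. The default grid is the sorted unique finite ratios; at
#' the smallest observed ratio the proportion is 1. The all-within mass
#' (sites with infinite ratio) is reported separately as attribute
#' `p_all_within` so no arbitrary cap is imposed.
#'
#' @param ratios Numeric vector (may contain `Inf`), non-empty.
#' @param grid Optional evaluation grid; defaults to sorted unique finite
#'   ratios.
#' @return `data.frame` with columns `x` and `proportion` (non-increasing),
#'   attribute `p_all_within`.
#' @export
survival_curve <- function(ratios, grid = NULL) {
  if (length(ratios) == 0L) stop("empty ratio vector", call. = FALSE)
  if (any(is.na(ratios)) || any(ratios < 0)) stop("ratios must be non-negative",
                                                  call. = FALSE)
  if (is.null(grid)) grid <- sort(unique(ratios[is.finite(ratios)]))
  prop <- vapply(grid, function(x) mean(ratios >= x), numeric(1))
  out <- data.frame(x = grid, proportion = prop)
  attr(out, "p_all_within") <- mean(is.infinite(ratios))
  out
}

#' Fraction of a protein covered by Pfam domains
#'
#' Residues belonging to any Pfam domain (overlapping intervals merged
#' first) as a fraction of the protein's sequence length.
#'
#' @param domains Domain rows of one target.
#' @param sequence_length Protein length in residues (>= 1).
#' @return Numeric in `[0, 1]`.
#' @export
coverage_ratio <- function(domains, sequence_length) {
  if (missing(sequence_length) || is.na(sequence_length) || sequence_length < 1)
    stop("sequence_length must be known and >= 1", call. = FALSE)
  if (nrow(domains) == 0L) return(0)
  m <- merge_intervals(domains$start, domains$end)
  sum(m[, "end"] - m[, "start"] + 1L) / sequence_length
}

#' Detect ligand binding at a domain-domain interface
#'
#' A site is flagged as interface binding when at least `min_families`
#' distinct families each hold a per-family share of binding residues of at
#' least `min_share`. The defaults (0.30, 2) reflect the observed range of
#' per-domain ratios in curated interface examples; both are configurable.
#'
#' @inheritParams compute_overlap
#' @param min_share Minimum per-family share (default 0.30).
#' @param min_families Minimum number of families meeting it (default 2).
#' @return A list: `interface` (flag), `per_family_share`, `families`
#'   (the families meeting the share cutoff).
#' @export
detect_interface <- function(residues, domains, min_share = 0.30,
                             min_families = 2L) {
  ov <- compute_overlap(residues, domains)
  hit <- ov$per_family_share[ov$per_family_share >= min_share]
  list(interface = length(hit) >= min_families,
       per_family_share = ov$per_family_share,
       families = names(hit))
}

#' Benchmark a mapping table against binding-site annotations
#'
#' Joins mapping rows (one predicted family per target) with binding sites
#' by accession, applies [benchmark_prediction()] per site, and summarizes
#' percent correct split by `maptype`.
#'
#' @param mappings Mapping `data.frame` (columns `domain`, `uniprot`,
#'   `maptype`).
#' @param sites Binding sites from [read_binding_sites()].
#' @param domains Domain annotation `data.frame`.
#' @return A list: `verdicts` (one row per target/site pair with
#'   `fraction_within` and `verdict`) and `summary` (`maptype`, `n`,
#'   `pct_correct`).
#' @export
benchmark_mappings <- function(mappings, sites, domains) {
  pred <- unique(mappings[, c("uniprot", "domain", "maptype")])
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    acc <- sites$uniprot[i]
    p <- pred[pred$uniprot == acc, , drop = FALSE]
    if (nrow(p) == 0L) next
    dom <- domains[domains$uniprot == acc, , drop = FALSE]
    for (j in seq_len(nrow(p))) {
      b <- benchmark_prediction(sites$residues[[i]], dom, p$domain[j])
      rows[[length(rows) + 1L]] <- data.frame(
        uniprot = acc, source = sites$source[i],
        ligand = sites$ligand[i] %||% NA_character_,
        predicted_family = b$predicted_family, maptype = p$maptype[j],
        fraction_within = b$fraction_within, verdict = b$verdict,
        stringsAsFactors = FALSE)
    }
  }
  verdicts <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(uniprot = character(0), source = character(0),
               ligand = character(0), predicted_family = character(0),
               maptype = character(0), fraction_within = numeric(0),
               verdict = character(0), stringsAsFactors = FALSE)
  if (nrow(verdicts) > 0L) {
    sm <- lapply(split(verdicts, verdicts$maptype), function(d)
      data.frame(maptype = d$maptype[1L], n = nrow(d),
                 pct_correct = 100 * mean(d$verdict == "correct"),
                 stringsAsFactors = FALSE))
    summary <- do.call(rbind, sm)
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(maptype = character(0), n = integer(0),
                          pct_correct = numeric(0), stringsAsFactors = FALSE)
  }
  list(verdicts = verdicts, summary = summary)
}
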