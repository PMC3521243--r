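# The seed-domain heuristic. A Pfam-A family is a validated ligand-binding
# ("seed") domain when it occurs as the sole distinct family of some protein
# that has at least one qualifying activity (or when it is added by manual
# curation). Multi-domain targets are then classified by how many distinct
# seed families they contain: none -> no mapping; exactly one (any copy
# number) -> all qualifying activities map to that family; two or more ->
# conflict, no mapping is assigned.

#' Build the seed-domain set
#'
#' Seeds are the families of single-family targets (a target whose domain
#' rows all belong to one Pfam family, counting repeat copies as one) that
#' have at least one qualifying activity, plus any manual additions.
#' Targets on the exclusion list (typically protein fragments mis-annotated
#' as full-length targets) are removed before seeding. A manual addition
#' that is also data-derived keeps provenance `data_derived`.
#'
#' @param domains Domain annotation `data.frame`
#'   (see [read_domain_annotations()]).
#' @param qualifying Qualifying activities, the output of
#'   [filter_activities()].
#' @param manual_additions Character vector of family ids forced into the
#'   seed set (e.g. `"Pkinase_Tyr"`).
#' @param excluded_targets Character vector of accessions ignored entirely.
#' @return A `data.frame` with columns `family` and `provenance`
#'   (`data_derived`/`manual`), sorted by family.
#' @export
build_seed_set <- function(domains, qualifying,
                           manual_additions = character(0),
                           excluded_targets = character(0)) {
  dom <- domains[!domains$uniprot %in% excluded_targets, , drop = FALSE]
  act_targets <- unique(qualifying$uniprot[!qualifying$uniprot %in% excluded_targets])
  nfam <- tapply(dom$pfam, dom$uniprot, function(f) length(unique(f)))
  single <- names(nfam)[nfam == 1L]
  single <- intersect(single, act_targets)
  data_fams <- unique(dom$pfam[dom$uniprot %in% single])
  manual_only <- setdiff(manual_additions, data_fams)
  fams <- c(sort(data_fams), sort(manual_only))
  out <- data.frame(family = fams,
                    provenance = c(rep("data_derived", length(data_fams)),
                                   rep("manual", length(manual_only))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a target by its seed-domain content
#'
#' The three-case rule: a target containing no seed family is `no_seed`
#' (no mapping); exactly one distinct seed family — regardless of how many
#' copies of it — is `one_seed` and all qualifying activities are assigned
#' to that family; two or more distinct seed families is
#' `multi_seed_conflict` and no mapping is assigned. Targets with no domain
#' annotation at all classify as `no_seed`.
#'
#' @param families Character vector of the target's Pfam families (copies
#'   allowed).
#' @param seeds Seed-set `data.frame` from [build_seed_set()].
#' @return A list with `category` and `mapped_family` (non-`NA` only for
#'   `one_seed`).
#' @export
classify_target <- function(families, seeds) {
  present <- intersect(unique(families), seeds$family)
  if (length(present) == 0L)
    list(category = "no_seed", mapped_family = NA_character_)
  else if (length(present) == 1L)
    list(category = "one_seed", mapped_family = present)
  else
    list(category = "multi_seed_conflict", mapped_family = NA_character_)
}

#' Classify every target in a domain table
#'
#' @param domains Domain annotation `data.frame`.
#' @inheritParams classify_target
#' @return A `data.frame` with one row per target: `uniprot`, `category`,
#'   `mapped_family`, `n_families` (distinct families in the architecture).
#' @export
classify_targets <- function(domains, seeds) {
  accs <- unique(domains$uniprot)
  split_fams <- split(domains$pfam, domains$uniprot)[accs]
  cls <- lapply(split_fams, classify_target, seeds = seeds)
  data.frame(uniprot = accs,
             category = vapply(cls, `[[`, character(1), "category"),
             mapped_family = vapply(cls, `[[`, character(1), "mapped_family"),
             n_families = vapply(split_fams, function(f) length(unique(f)), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map qualifying activities to seed domains
#'
#' Emits one mapping row per qualifying activity whose target classifies
#' `one_seed`. `maptype` is `single` when the target's architecture has
#' exactly one distinct family and `multi` otherwise. Activities against
#' targets absent from the domain table are skipped with a warning;
#' activities against excluded targets are dropped silently (they were
#' removed from the analysis before seeding).
#'
#' @param domains Domain annotation `data.frame`.
#' @param seeds Seed set from [build_seed_set()].
#' @param qualifying Output of [filter_activities()].
#' @param excluded_targets Accessions removed by manual curation.
#' @return Mapping `data.frame` with columns `activity`, `domain`,
#'   `molregno`, `uniprot`, `maptype`, sorted by activity id.
#' @export
map_activities <- function(domains, seeds, qualifying,
                           excluded_targets = character(0)) {
  acts <- qualifying[!qualifying$uniprot %in% excluded_targets, , drop = FALSE]
  dom <- domains[!domains$uniprot %in% excluded_targets, , drop = FALSE]
  known <- unique(dom$uniprot)
  unknown <- !acts$uniprot %in% known
  if (any(unknown)) {
    lig_log("WARN", "map", sprintf("skipped %d activities on targets without domain annotation",
                                   sum(unknown)))
    warning(sprintf("skipped %d activities on unknown targets", sum(unknown)),
            call. = FALSE)
    acts <- acts[!unknown, , drop = FALSE]
  }
  cls <- classify_targets(dom, seeds)
  cls <- cls[cls$category == "one_seed", , drop = FALSE]
  idx <- match(acts$uniprot, cls$uniprot)
  keep <- !is.na(idx)
  acts <- acts[keep, , drop = FALSE]
  idx <- idx[keep]
  out <- data.frame(activity = acts$activity_id,
                    domain = cls$mapped_family[idx],
                    molregno = acts$molregno,
                    uniprot = acts$uniprot,
                    maptype = ifelse(cls$n_families[idx] == 1L, "single", "multi"),
                    stringsAsFactors = FALSE)
  num <- suppressWarnings(as.numeric(out$activity))
  o <- if (anyNA(num)) order(out$activity) else order(num)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report seed-domain co-occurrences and never-alone families
#'
#' Two views used for manual curation of the seed set. The pair table lists
#' every unordered pair of distinct seed families found on one target, with
#' the number of targets carrying that conflict (these targets classify
#' `multi_seed_conflict` and receive no mapping). The never-alone table
#' lists families that never occur as the sole distinct family of any
#' target — such families can never be seeded from data, however many
#' ligands they bind — with the number of targets containing them; families
#' at or above `min_count` targets are flagged as candidates for manual
#' seed review.
#'
#' @param domains Domain annotation `data.frame`.
#' @param seeds Seed set from [build_seed_set()].
#' @param min_count Target-count threshold flagging review candidates
#'   (default 100).
#' @return A list with `conflicts` (per conflicted target: `uniprot`,
#'   `conflict` — the co-occurring seed families, comma-joined), `pairs`
#'   (`family_a`, `family_b`, `n_targets`) and `never_alone` (`family`,
#'   `n_targets`, `candidate`), the latter sorted by descending target
#'   count.
#' @export
cooccurrence_report <- function(domains, seeds, min_count = 100L) {
  fam_by_target <- lapply(split(domains$pfam, domains$uniprot), unique)

  # per-target conflict rows: targets carrying >= 2 distinct seed families
  seed_sets <- lapply(fam_by_target, function(f) sort(intersect(f, seeds$family)))
  confl <- names(seed_sets)[vapply(seed_sets, length, integer(1)) >= 2L]
  conflicts <- data.frame(uniprot = confl,
                          conflict = vapply(seed_sets[confl], paste,
                                            character(1), collapse = ","),
                          stringsAsFactors = FALSE, row.names = NULL)

  # unordered pairs of co-occurring seed families
  pair_keys <- unlist(lapply(fam_by_target, function(f) {
    sf <- sort(intersect(f, seeds$family))
    if (length(sf) < 2L) return(character(0))
    cmb <- utils::combn(sf, 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = "\t")
  }), use.names = FALSE)
  if (length(pair_keys) > 0L) {
    tab <- sort(table(pair_keys), decreasing = TRUE)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    pairs <- data.frame(family_a = vapply(parts, `[[`, character(1), 1L),
                        family_b = vapply(parts, `[[`, character(1), 2L),
                        n_targets = as.integer(tab),
                        stringsAsFactors = FALSE, row.names = NULL)
  } else {
    pairs <- data.frame(family_a = character(0), family_b = character(0),
                        n_targets = integer(0), stringsAsFactors = FALSE)
  }

  # families never seen as a target's sole distinct family
  all_fams <- unique(domains$pfam)
  alone <- unique(unlist(fam_by_target[vapply(fam_by_target, length, integer(1)) == 1L],
                         use.names = FALSE))
  never <- setdiff(all_fams, alone)
  counts <- vapply(never, function(f)
    sum(vapply(fam_by_target, function(t) f %in% t, logical(1))), integer(1))
  never_alone <- data.frame(family = never, n_targets = counts,
                            candidate = counts >= min_count,
                            stringsAsFactors = FALSE, row.names = NULL)
  never_alone <- never_alone[order(-never_alone$n_targets, never_alone$family), ,
                             drop = FALSE]
  rownames(never_alone) <- NULL
  list(conflicts = conflicts, pairs = pairs, never_alone = never_alone)
}
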