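# The mapping heuristic: activity filter, seed set, three-case rule.

mk_act <- function(id, uniprot, type = "Ki", value = 10, unit = "nM",
                   assay = "B", multi = FALSE, complex = FALSE,
                   molregno = "C1") {
  data.frame(activity_id = as.character(id), molregno = molregno,
             uniprot = uniprot, assay_type = assay, multi = multi,
             complex = complex, type = type, value = value, unit = unit,
             stringsAsFactors = FALSE)
}

test_that("filter keeps records at least as potent as 50 uM, boundary inclusive", {
  acts <- rbind(
    mk_act(1, "T1", value = 10, unit = "nM"),          # strong -> keep
    mk_act(2, "T1", value = 50, unit = "uM"),          # boundary -> keep
    mk_act(3, "T1", value = 60, unit = "uM"),          # weak -> drop
    mk_act(4, "T1", type = "pKd", value = 6.0, unit = ""),  # 6 >= 4.301 -> keep
    mk_act(5, "T1", type = "pKd", value = 4.0, unit = ""))  # drop
  kept <- filter_activities(acts, verbose = FALSE)
  expect_equal(kept$activity_id, c("1", "2", "4"))
  rej <- attr(kept, "rejections")
  expect_equal(nrow(acts), nrow(kept) + sum(rej))      # no silent drops
})

test_that("filter unit conversion matches a by-hand molar oracle", {
  set.seed(42)
  units <- c("M", "mM", "uM", "nM", "pM")
  acts <- do.call(rbind, lapply(1:200, function(i) {
    u <- sample(units, 1)
    mk_act(i, "T1", value = round(10^runif(1, -3, 6), 4), unit = u)
  }))
  kept <- filter_activities(acts, verbose = FALSE)
  manual <- vapply(seq_len(nrow(acts)), function(i) {
    f <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[acts$unit[i]]]
    acts$value[i] * f <= 5e-5
  }, logical(1))
  expect_equal(kept$activity_id, acts$activity_id[manual])
})

test_that("filter rejects wrong assay type, flags, vocabulary, unknown units", {
  acts <- rbind(
    mk_act(1, "T1", assay = "F"),
    mk_act(2, "T1", multi = TRUE),
    mk_act(3, "T1", complex = TRUE),
    mk_act(4, "T1", type = "AC50"),
    mk_act(5, "T1", unit = "mg/L"),    # unsupported unit: reject, not crash
    mk_act(6, "T1"))
  kept <- filter_activities(acts, verbose = FALSE)
  expect_equal(kept$activity_id, "6")
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej[["unsupported_unit"]]), 1L)
})

test_that("seeding: single-family targets with a qualifying activity", {
  domains <- data.frame(
    uniprot = c("S1", "S2", "S2", "M1", "M1", "S3"),
    pfam = c("Trypsin", "Pkinase", "Pkinase", "A", "B", "Lonely"),
    start = c(1, 1, 200, 1, 100, 1), end = c(50, 150, 350, 90, 190, 50),
    stringsAsFactors = FALSE)
  qual <- rbind(mk_act(1, "S1"), mk_act(2, "S2"), mk_act(3, "M1"))
  seeds <- build_seed_set(domains, qual)
  # S1 single family; S2 two copies of one family counts as single;
  # M1 two families contributes nothing; S3 has no qualifying activity
  expect_setequal(seeds$family, c("Trypsin", "Pkinase"))
  expect_true(all(seeds$provenance == "data_derived"))
})

test_that("manual additions and excluded targets are honored", {
  domains <- data.frame(uniprot = c("S1", "F1"), pfam = c("Trypsin", "GAF"),
                        start = c(1, 1), end = c(50, 50),
                        stringsAsFactors = FALSE)
  qual <- rbind(mk_act(1, "S1"), mk_act(2, "F1"))
  seeds <- build_seed_set(domains, qual, manual_additions = "Pkinase_Tyr",
                          excluded_targets = "F1")
  expect_setequal(seeds$family, c("Trypsin", "Pkinase_Tyr"))
  expect_equal(seeds$provenance[seeds$family == "Pkinase_Tyr"], "manual")
  expect_false("GAF" %in% seeds$family)   # fragment excluded before seeding
  # manual addition colliding with a data-derived family: data_derived wins
  seeds2 <- build_seed_set(domains, qual, manual_additions = "Trypsin",
                           excluded_targets = "F1")
  expect_equal(seeds2$provenance[seeds2$family == "Trypsin"], "data_derived")
  # seed monotonicity: adding activities never removes a family
  seeds3 <- build_seed_set(domains, rbind(qual, mk_act(9, "S1")),
                           manual_additions = "Pkinase_Tyr",
                           excluded_targets = "F1")
  expect_true(all(seeds$family %in% seeds3$family))
})

test_that("three-case rule: no seed, one seed (any copies), conflict", {
  seeds <- data.frame(family = c("Pkinase", "SH2-like", "Trypsin"),
                      provenance = "data_derived", stringsAsFactors = FALSE)
  # the multi-domain kinase case: Pkinase seeded, companions not
  cl <- classify_target(c("Pkinase", "Pkinase_C", "PH"), seeds)
  expect_equal(cl$category, "one_seed")
  expect_equal(cl$mapped_family, "Pkinase")
  # copies of a non-seed family are irrelevant
  cl2 <- classify_target(c("fn3", "fn3", "SH2-like"), seeds)
  expect_equal(cl2$category, "one_seed")
  expect_equal(cl2$mapped_family, "SH2-like")
  # two distinct seed families: conflict, no mapping
  cl3 <- classify_target(c("Pkinase", "Trypsin"), seeds)
  expect_equal(cl3$category, "multi_seed_conflict")
  expect_true(is.na(cl3$mapped_family))
  # no seed at all
  expect_equal(classify_target(c("PH", "fn3"), seeds)$category, "no_seed")
})

test_that("map_activities fans out per activity and skips conflicts", {
  domains <- data.frame(
    uniprot = c("S1", "S2", "M1", "M1", "X1", "X1"),
    pfam = c("A", "B", "A", "Z", "A", "B"),
    start = c(1, 1, 1, 100, 1, 100), end = c(50, 50, 90, 190, 90, 190),
    stringsAsFactors = FALSE)
  qual <- rbind(mk_act(1, "S1"), mk_act(2, "S1"), mk_act(3, "S1"),
                mk_act(4, "M1"), mk_act(5, "X1"), mk_act(6, "S2"))
  seeds <- build_seed_set(domains, qual)
  expect_setequal(seeds$family, c("A", "B"))
  mp <- map_activities(domains, seeds, qual)
  # X1 holds both seed families -> conflict, activity 5 unmapped;
  # M1 holds seed A plus non-seed Z -> one_seed, maptype multi
  expect_equal(mp$activity, c("1", "2", "3", "4", "6"))
  expect_equal(mp$domain, c("A", "A", "A", "A", "B"))
  expect_equal(mp$maptype, c("single", "single", "single", "multi", "single"))
  # unknown target -> skipped with warning
  expect_warning(mp2 <- map_activities(domains, seeds,
                                       rbind(qual, mk_act(9, "NOPE"))),
                 "unknown")
  expect_equal(nrow(mp2), 5L)
  # soundness: every mapped domain is a seed present on its target
  for (i in seq_len(nrow(mp))) {
    expect_true(mp$domain[i] %in% seeds$family)
    expect_true(mp$domain[i] %in% domains$pfam[domains$uniprot == mp$uniprot[i]])
  }
})

test_that("mapping is deterministic: identical inputs, byte-identical output", {
  fx <- random_fixture(123)
  qual <- filter_activities(fx$activities, verbose = FALSE)
  seeds <- build_seed_set(fx$domains, qual)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_mappings(map_activities(fx$domains, seeds, qual), f1)
  write_mappings(map_activities(fx$domains, seeds, qual), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cooccurrence report: conflicts, pair counts, never-alone candidates", {
  # family X occurs only alongside Y, in 150 targets; Y also occurs alone
  domains <- do.call(rbind, c(
    lapply(1:150, function(i) data.frame(
      uniprot = sprintf("M%03d", i), pfam = c("X", "Y"),
      start = c(1, 100), end = c(90, 190), stringsAsFactors = FALSE)),
    list(data.frame(uniprot = "S1", pfam = "Y", start = 1, end = 90,
                    stringsAsFactors = FALSE))))
  qual <- mk_act(1, "S1")
  seeds <- build_seed_set(domains, qual)
  rep <- cooccurrence_report(domains, seeds, min_count = 100)
  expect_equal(rep$never_alone$family, "X")
  expect_true(rep$never_alone$candidate)
  expect_equal(rep$never_alone$n_targets, 150L)
  expect_equal(nrow(rep$conflicts), 0L)    # X is not a seed, no conflict
  # all-single-domain fixture: empty candidate list
  dsingle <- data.frame(uniprot = c("A", "B"), pfam = c("F1", "F2"),
                        start = 1, end = 50, stringsAsFactors = FALSE)
  rep2 <- cooccurrence_report(dsingle, seeds, min_count = 100)
  expect_equal(nrow(rep2$never_alone), 0L)
  expect_equal(nrow(rep2$pairs), 0L)
})

test_that("pair counts match a brute-force pair-counting oracle", {
  fx <- random_fixture(77, n_targets = 50)
  qual <- filter_activities(fx$activities, verbose = FALSE)
  seeds <- build_seed_set(fx$domains, qual)
  rep <- cooccurrence_report(fx$domains, seeds)
  # oracle: loop over targets, count unordered seed pairs
  counts <- new.env()
  for (acc in unique(fx$domains$uniprot)) {
    sf <- sort(intersect(unique(fx$domains$pfam[fx$domains$uniprot == acc]),
                         seeds$family))
    if (length(sf) < 2) next
    for (i in seq_len(length(sf) - 1)) for (j in (i + 1):length(sf)) {
      key <- paste(sf[i], sf[j])
      prev <- if (is.null(counts[[key]])) 0L else counts[[key]]
      counts[[key]] <- prev + 1L
    }
  }
  expect_equal(nrow(rep$pairs), length(ls(counts)))
  for (i in seq_len(nrow(rep$pairs))) {
    key <- paste(rep$pairs$family_a[i], rep$pairs$family_b[i])
    expect_equal(rep$pairs$n_targets[i], counts[[key]])
  }
})
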