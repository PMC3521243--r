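# Independent brute-force oracles. These re-derive the package's results
# by the most literal route possible (loops, enumeration, closed forms) and
# deliberately share no code with the implementation under test.

# --- brute-force re-derivation of the mapping heuristic ---------------------
# Literal per-record loops over the filter rules, the seeding rule, and the
# three-case classification.
oracle_qualifying <- function(acts, threshold_molar = 5e-5) {
  conc_types <- c("Ki", "Kd", "IC50", "EC50")
  log_types <- c("-Log Ki", "pKd", "pA2", "pI", "pKa")
  unit_f <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9, pM = 1e-12)
  keep <- logical(nrow(acts))
  for (i in seq_len(nrow(acts))) {
    a <- acts[i, ]
    if (a$assay_type != "B") next
    if (a$multi || a$complex) next
    if (a$type %in% conc_types) {
      if (!a$unit %in% names(unit_f)) next
      if (a$value * unit_f[[a$unit]] > threshold_molar) next
    } else if (a$type %in% log_types) {
      if (a$value < -log10(threshold_molar)) next
    } else next
    keep[i] <- TRUE
  }
  acts[keep, , drop = FALSE]
}

oracle_map <- function(domains, acts, manual = character(0),
                       excluded = character(0), threshold_molar = 5e-5) {
  qual <- oracle_qualifying(acts, threshold_molar)
  qual <- qual[!qual$uniprot %in% excluded, , drop = FALSE]
  dom <- domains[!domains$uniprot %in% excluded, , drop = FALSE]

  seeds <- character(0)
  for (acc in unique(dom$uniprot)) {
    fams <- unique(dom$pfam[dom$uniprot == acc])
    if (length(fams) == 1L && acc %in% qual$uniprot) seeds <- c(seeds, fams)
  }
  seeds <- sort(unique(c(seeds, manual)))

  rows <- list()
  for (i in seq_len(nrow(qual))) {
    acc <- qual$uniprot[i]
    fams <- unique(dom$pfam[dom$uniprot == acc])
    if (length(fams) == 0L) next
    sf <- fams[fams %in% seeds]
    if (length(sf) != 1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      activity = qual$activity_id[i], domain = sf,
      molregno = qual$molregno[i], uniprot = acc,
      maptype = if (length(fams) == 1L) "single" else "multi",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(activity = character(0), domain = character(0),
               molregno = character(0), uniprot = character(0),
               maptype = character(0), stringsAsFactors = FALSE)
  out <- out[order(as.numeric(out$activity)), , drop = FALSE]
  rownames(out) <- NULL
  list(seeds = seeds, mapping = out)
}

# --- random fixture for the heuristic oracle --------------------------------
random_fixture <- function(seed, n_targets = 60) {
  set.seed(seed)
  fams <- sprintf("FAM%02d", 1:12)
  dom_rows <- list(); act_rows <- list(); aid <- 0
  for (i in seq_len(n_targets)) {
    acc <- sprintf("P%04d", i)
    nf <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
    tf <- sample(fams, nf)
    inst <- c(tf, if (runif(1) < 0.2) tf[1])   # occasional repeat copy
    pos <- 10
    for (f in inst) {
      len <- sample(50:120, 1)
      dom_rows[[length(dom_rows) + 1]] <- data.frame(
        uniprot = acc, pfam = f, start = pos, end = pos + len - 1,
        stringsAsFactors = FALSE)
      pos <- pos + len + sample(5:30, 1)
    }
    for (k in seq_len(sample(0:4, 1))) {
      aid <- aid + 1
      kind <- sample(c("ok", "ok_log", "weak", "assay", "flag", "type",
                       "badunit"), 1)
      rec <- data.frame(activity_id = as.character(aid),
                        molregno = sprintf("C%03d", sample(1:80, 1)),
                        uniprot = acc, assay_type = "B", multi = FALSE,
                        complex = FALSE, type = "Ki", value = 10, unit = "nM",
                        stringsAsFactors = FALSE)
      if (kind == "ok") rec$value <- round(10^runif(1, 0, 4.69), 3)
      if (kind == "ok_log") { rec$type <- "pKd"; rec$value <- round(runif(1, 4.31, 9), 2); rec$unit <- "" }
      if (kind == "weak") { rec$value <- round(runif(1, 51, 500), 2); rec$unit <- "uM" }
      if (kind == "assay") rec$assay_type <- sample(c("F", "A"), 1)
      if (kind == "flag") rec$multi <- TRUE
      if (kind == "type") rec$type <- "AC50"
      if (kind == "badunit") rec$unit <- "mg/L"
      act_rows[[length(act_rows) + 1]] <- rec
    }
  }
  list(domains = do.call(rbind, dom_rows),
       activities = if (length(act_rows)) do.call(rbind, act_rows) else NULL)
}

# --- small numeric oracles --------------------------------------------------
# grid search MLE for alpha at fixed xmin: coarse pass over [1.01, 5],
# then a 1e-3 grid around the coarse optimum; zeta by direct summation
oracle_alpha_grid <- function(x, xmin) {
  tail <- x[x >= xmin]
  n <- length(tail); S <- sum(log(tail))
  ks <- xmin:(xmin + 200000)
  ll <- function(a) -n * log(sum(ks^(-a))) - a * S
  coarse <- seq(1.01, 5, by = 0.05)
  best <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(max(1.01, best - 0.06), min(5, best + 0.06), by = 1e-3)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# eigendecomposition PCA oracle
oracle_pca <- function(m) {
  e <- eigen(stats::cov(m), symmetric = TRUE)
  list(loadings = e$vectors, variance = e$values)
}

# interval union size by residue enumeration
oracle_union_size <- function(start, end) {
  length(unique(unlist(mapply(seq.int, start, end, SIMPLIFY = FALSE))))
}
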