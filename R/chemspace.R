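# Ligand chemical-space profiling on six basic molecular descriptors
# (molecular weight, ALogP, polar surface area, rotatable bonds, H-bond
# donors, H-bond acceptors): percentile trimming of outliers, centering and
# scaling to unit variance, pooled PCA, and per-family comparison of first
# principal component scores with Bonferroni-corrected Welch t-tests.

.descriptor_cols <- c("mw", "alogp", "psa", "rtb", "hbd", "hba")

#' Trim descriptor outliers by percentile
#'
#' Removes a compound when ANY of its six descriptor values falls strictly
#' below the `low_pct` percentile or strictly above the `high_pct`
#' percentile of that descriptor's distribution over the full input (one
#' pass; trimming is not iterated). Rows are the unit of removal because
#' PCA needs complete descriptor vectors. The defaults trim the extreme 1%
#' tails on each side.
#'
#' @param descriptors Descriptor `data.frame` (see [read_descriptors()]).
#' @param low_pct,high_pct Percentile cutoffs in `[0, 100]`.
#' @return The trimmed `data.frame`, with attribute `n_removed`.
#' @export
trim_outliers <- function(descriptors, low_pct = 1, high_pct = 99) {
  if (nrow(descriptors) == 0L) stop("empty descriptor table", call. = FALSE)
  stopifnot(low_pct < high_pct)
  drop <- rep(FALSE, nrow(descriptors))
  for (col in .descriptor_cols) {
    q <- stats::quantile(descriptors[[col]], c(low_pct, high_pct) / 100,
                         names = FALSE)
    drop <- drop | descriptors[[col]] < q[1] | descriptors[[col]] > q[2]
  }
  out <- descriptors[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Center and scale descriptors to unit variance
#'
#' Each descriptor column is mean-centered and divided by its sample
#' standard deviation (denominator `n - 1`), so every scaled column has
#' sd 1. The means and sds are recorded for the inverse transform.
#'
#' @param descriptors Descriptor `data.frame`.
#' @return A numeric matrix with attributes `center` and `scale` (named per
#'   descriptor) and rownames taken from `molregno`.
#' @export
scale_unit_variance <- function(descriptors) {
  m <- as.matrix(descriptors[, .descriptor_cols])
  sds <- apply(m, 2, stats::sd)
  zero <- .descriptor_cols[sds == 0 | !is.finite(sds)]
  if (length(zero) > 0L)
    stop(sprintf("zero-variance descriptor column(s): %s",
                 paste(zero, collapse = ", ")), call. = FALSE)
  centers <- colMeans(m)
  scaled <- sweep(sweep(m, 2, centers), 2, sds, "/")
  rownames(scaled) <- descriptors$molregno
  attr(scaled, "center") <- centers
  attr(scaled, "scale") <- sds
  scaled
}

#' Principal component analysis of the scaled descriptor matrix
#'
#' Thin wrapper around [stats::prcomp()] on the pre-scaled matrix (no
#' further centering or scaling), with a fixed sign convention: in each
#' loading column the largest-magnitude element is made positive, so
#' loadings are comparable across runs. Zero-variance trailing components
#' of rank-deficient input are kept and flagged.
#'
#' @param scaled Matrix from [scale_unit_variance()] (or any numeric
#'   matrix with observations in rows).
#' @return A list of class `pca_result`: `loadings` (columns PC1..),
#'   `explained_variance` (component variances, non-increasing), `scores`,
#'   `zero_variance` (logical per component).
#' @export
run_pca <- function(scaled) {
  if (nrow(scaled) < ncol(scaled) + 1L)
    lig_log("WARN", "chemspace", "fewer rows than descriptors + 1; PCA is rank deficient")
  pc <- stats::prcomp(scaled, center = FALSE, scale. = FALSE)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(loadings = load, explained_variance = ev, scores = scores,
                 zero_variance = ev < 1e-12),
            class = "pca_result")
}

#' Compare per-family PC1 distributions
#'
#' Splits first-principal-component scores by domain family and runs a
#' Welch two-sample t-test for every family pair; p-values are multiplied
#' by the number of pairs (Bonferroni) and capped at 1. Families with fewer
#' than `min_n` compounds are excluded with a warning.
#'
#' @param pca A `pca_result` from [run_pca()].
#' @param labels Named character vector or plain vector aligned with the
#'   score rows, giving each compound's family.
#' @param min_n Minimum family size (default 3).
#' @return A list: `pc1_by_family` (named list of score vectors),
#'   `tests` (`family_a`, `family_b`, `t`, `p_raw`, `p_bonferroni`),
#'   `summary` (per-family n, median and mean PC1).
#' @export
project_and_test <- function(pca, labels, min_n = 3L) {
  stopifnot(inherits(pca, "pca_result"))
  labels <- as.character(labels)
  if (length(labels) != nrow(pca$scores))
    stop("labels must align with score rows", call. = FALSE)
  pc1 <- split(pca$scores[, 1L], labels)
  small <- names(pc1)[vapply(pc1, length, integer(1)) < min_n]
  if (length(small) > 0L) {
    warning(sprintf("excluding families with < %d compounds: %s", min_n,
                    paste(small, collapse = ", ")), call. = FALSE)
    pc1 <- pc1[!names(pc1) %in% small]
  }
  fams <- sort(names(pc1))
  if (length(fams) < 2L) stop("need >= 2 families with enough compounds",
                              call. = FALSE)
  cmb <- utils::combn(fams, 2L)
  npairs <- ncol(cmb)
  tests <- do.call(rbind, lapply(seq_len(npairs), function(i) {
    a <- pc1[[cmb[1L, i]]]; b <- pc1[[cmb[2L, i]]]
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(family_a = cmb[1L, i], family_b = cmb[2L, i],
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_bonferroni = min(tt$p.value * npairs, 1),
               stringsAsFactors = FALSE)
  }))
  summary <- data.frame(family = fams,
                        n = vapply(pc1[fams], length, integer(1)),
                        median_pc1 = vapply(pc1[fams], stats::median, numeric(1)),
                        mean_pc1 = vapply(pc1[fams], mean, numeric(1)),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(pc1_by_family = pc1, tests = tests, summary = summary)
}

#' Run the full chemical-space pipeline
#'
#' Convenience wrapper: subset descriptors to mapped compounds of the
#' requested families, trim outliers, scale, run PCA, and compare PC1
#' distributions across families.
#'
#' @param descriptors Descriptor `data.frame`.
#' @param mappings Mapping `data.frame` (`domain`, `molregno`).
#' @param families Families to profile (default: all mapped families).
#' @param low_pct,high_pct Trimming percentiles.
#' @return A list: `pca`, `comparison`, `n_compounds`, `n_trimmed`.
#' @export
chemspace_profile <- function(descriptors, mappings, families = NULL,
                              low_pct = 1, high_pct = 99) {
  if (is.null(families)) families <- sort(unique(mappings$domain))
  mp <- unique(mappings[mappings$domain %in% families,
                        c("molregno", "domain")])
  dup <- duplicated(mp$molregno)   # a compound mapped to several families:
  if (any(dup)) {                  # keep the first family, note the rest
    lig_log("INFO", "chemspace",
            sprintf("%d compound(s) mapped to several families; first mapping kept",
                    length(unique(mp$molregno[dup]))))
    mp <- mp[!dup, , drop = FALSE]
  }
  desc <- descriptors[descriptors$molregno %in% mp$molregno, , drop = FALSE]
  if (nrow(desc) == 0L) stop("no descriptor rows for the mapped compounds",
                             call. = FALSE)
  trimmed <- trim_outliers(desc, low_pct, high_pct)
  scaled <- scale_unit_variance(trimmed)
  pca <- run_pca(scaled)
  labels <- mp$domain[match(trimmed$molregno, mp$molregno)]
  comparison <- project_and_test(pca, labels)
  list(pca = pca, comparison = comparison,
       n_compounds = nrow(trimmed), n_trimmed = attr(trimmed, "n_removed"))
}
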