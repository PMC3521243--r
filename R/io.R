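# Readers and writers for the flat-file dialects the tool consumes and
# produces. All files are UTF-8, tab-separated, with a header line. Readers
# are strict about required columns but tolerate (and ignore) extra columns;
# coordinates are 1-based inclusive throughout (Pfam/Uniprot convention).

read_tsv_table <- function(path, required, what = "table") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s %s: missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  df
}

# Parse a character column as integer; error names offending data lines
# (line 1 is the header, so data row i sits on file line i + 1).
parse_int_col <- function(x, col, path) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !(is.na(x) | x == ""))
  bad <- union(bad, which(is.na(x) | x == ""))
  if (length(bad) > 0L)
    stop(sprintf("%s: non-integer value in column '%s' at line(s) %s",
                 path, col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  v
}

parse_num_col <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which((is.na(v) | !is.finite(v)) )
  if (length(bad) > 0L)
    stop(sprintf("%s: unparseable value in column '%s' at line(s) %s",
                 path, col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  v
}

#' Read a Pfam-A domain annotation table
#'
#' Reads a tab-separated table with one row per domain instance on a protein.
#' Required columns are `uniprot` (protein accession), `pfam` (Pfam-A family
#' identifier), and `start`/`end` (1-based inclusive residue positions of the
#' domain on the Uniprot sequence). Extra columns are ignored; row order is
#' preserved; repeat domains (several copies of one family on one protein)
#' are kept as separate rows.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with columns `uniprot`, `pfam`, `start`, `end`.
#' @export
read_domain_annotations <- function(path) {
  df <- read_tsv_table(path, c("uniprot", "pfam", "start", "end"),
                       "domain annotation table")
  out <- data.frame(uniprot = df$uniprot, pfam = df$pfam,
                    start = parse_int_col(df$start, "start", path),
                    end = parse_int_col(df$end, "end", path),
                    stringsAsFactors = FALSE)
  bad <- which(out$start < 1L | out$end < out$start)
  if (length(bad) > 0L)
    stop(sprintf("%s: invalid domain boundaries (need 1 <= start <= end) at line(s) %s",
                 path, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  if (any(out$pfam == ""))
    stop(sprintf("%s: empty pfam family identifier at line(s) %s", path,
                 paste(which(out$pfam == "") + 1L, collapse = ", ")), call. = FALSE)
  out
}

#' Write a domain annotation table
#' @param domains A `data.frame` as returned by [read_domain_annotations()].
#' @param path Output path.
#' @export
write_domain_annotations <- function(domains, path) {
  write_tsv(domains[, c("uniprot", "pfam", "start", "end")], path)
}

#' Read a bioactivity table (ChEMBL-style export)
#'
#' Required columns: `activity_id`, `molregno` (compound id), `uniprot`
#' (target accession), `assay_type` (single-letter code), `multi` and
#' `complex` (0/1 flags for ambiguous multi-target and complex assays),
#' `type` (activity type, e.g. Ki, IC50, pKd), `value`, `unit` (concentration
#' unit, empty for log-scale types). Duplicated activity ids raise a warning
#' but all rows are kept; the reader never deduplicates.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with typed columns (`multi`/`complex` logical,
#'   `value` numeric).
#' @export
read_activities <- function(path) {
  req <- c("activity_id", "molregno", "uniprot", "assay_type",
           "multi", "complex", "type", "value", "unit")
  df <- read_tsv_table(path, req, "activity table")
  flag <- function(x, col) {
    ok <- x %in% c("0", "1")
    if (!all(ok))
      stop(sprintf("%s: flag column '%s' must be 0/1 at line(s) %s", path, col,
                   paste(which(!ok) + 1L, collapse = ", ")), call. = FALSE)
    x == "1"
  }
  out <- data.frame(activity_id = df$activity_id, molregno = df$molregno,
                    uniprot = df$uniprot, assay_type = df$assay_type,
                    multi = flag(df$multi, "multi"),
                    complex = flag(df$complex, "complex"),
                    type = df$type,
                    value = parse_num_col(df$value, "value", path),
                    unit = df$unit, stringsAsFactors = FALSE)
  dup <- duplicated(out$activity_id)
  if (any(dup)) {
    lig_log("WARN", "io", sprintf("duplicated activity_id(s) kept: %s",
                                  paste(unique(out$activity_id[dup]), collapse = ", ")))
    warning(sprintf("%s: duplicated activity_id(s): %s", path,
                    paste(unique(out$activity_id[dup]), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' @rdname read_activities
#' @param activities A `data.frame` of activities.
#' @export
write_activities <- function(activities, path) {
  df <- activities
  df$multi <- as.integer(df$multi)
  df$complex <- as.integer(df$complex)
  write_tsv(df[, c("activity_id", "molregno", "uniprot", "assay_type",
                   "multi", "complex", "type", "value", "unit")], path)
}

#' Read a binding-site annotation table
#'
#' Required columns: `uniprot`, `source` (one of `uniprot` — sparse expert
#' key residues — or `pdbe` — all ligand-contact residues), `residues`
#' (comma-separated 1-based residue indices in Uniprot coordinates).
#' An optional `ligand` column carries the PDB three-letter ligand code.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with a list-column `residues` of integer vectors.
#' @export
read_binding_sites <- function(path) {
  df <- read_tsv_table(path, c("uniprot", "source", "residues"),
                       "binding-site table")
  bad_src <- which(!df$source %in% c("uniprot", "pdbe"))
  if (length(bad_src) > 0L)
    stop(sprintf("%s: source must be 'uniprot' or 'pdbe' at line(s) %s", path,
                 paste(bad_src + 1L, collapse = ", ")), call. = FALSE)
  residues <- lapply(seq_len(nrow(df)), function(i) {
    parts <- strsplit(df$residues[i], ",", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    v <- suppressWarnings(as.integer(parts))
    if (length(v) == 0L || anyNA(v) || any(v < 1L))
      stop(sprintf("%s: invalid residue list at line %d", path, i + 1L),
           call. = FALSE)
    sort(unique(v))
  })
  out <- data.frame(uniprot = df$uniprot, source = df$source,
                    ligand = if ("ligand" %in% names(df)) df$ligand else NA_character_,
                    stringsAsFactors = FALSE)
  out$residues <- residues
  out
}

#' @rdname read_binding_sites
#' @param sites A `data.frame` of binding sites with list-column `residues`.
#' @export
write_binding_sites <- function(sites, path) {
  df <- data.frame(uniprot = sites$uniprot, source = sites$source,
                   ligand = sites$ligand %||% NA_character_,
                   residues = vapply(sites$residues, function(r)
                     paste(r, collapse = ","), character(1)),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a molecular descriptor table
#'
#' Required columns: `molregno` plus the six descriptors `mw` (molecular
#' weight, Da), `alogp` (Ghose-Crippen octanol/water partition estimate),
#' `psa` (polar surface area, A^2), `rtb` (rotatable bonds), `hbd`
#' (hydrogen-bond donors), `hba` (hydrogen-bond acceptors).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with numeric descriptor columns.
#' @export
read_descriptors <- function(path) {
  req <- c("molregno", "mw", "alogp", "psa", "rtb", "hbd", "hba")
  df <- read_tsv_table(path, req, "descriptor table")
  out <- data.frame(molregno = df$molregno, stringsAsFactors = FALSE)
  for (col in c("mw", "alogp", "psa", "rtb", "hbd", "hba"))
    out[[col]] <- parse_num_col(df[[col]], col, path)
  if (any(out$rtb < 0 | out$hbd < 0 | out$hba < 0))
    stop(sprintf("%s: count descriptors (rtb, hbd, hba) must be non-negative",
                 path), call. = FALSE)
  out
}

#' @rdname read_descriptors
#' @param descriptors A descriptor `data.frame`.
#' @export
write_descriptors <- function(descriptors, path) {
  write_tsv(descriptors[, c("molregno", "mw", "alogp", "psa", "rtb", "hbd", "hba")],
            path)
}

#' Write an activity-to-domain mapping table
#'
#' Emits the mapping dialect with header `activity`, `domain`, `molregno`,
#' `uniprot`, `maptype` (`single` for single-family targets, `multi`
#' otherwise). Rows are written sorted by `activity` (numerically when all
#' ids parse as numbers) so output is deterministic.
#'
#' @param rows A `data.frame` of mapping rows.
#' @param path Output path.
#' @export
write_mappings <- function(rows, path) {
  req <- c("activity", "domain", "molregno", "uniprot", "maptype")
  missing <- setdiff(req, names(rows))
  if (length(missing) > 0L)
    stop(sprintf("mapping table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  rows <- rows[, req, drop = FALSE]
  if (nrow(rows) > 0L) {
    num <- suppressWarnings(as.numeric(rows$activity))
    o <- if (anyNA(num)) order(rows$activity) else order(num)
    rows <- rows[o, , drop = FALSE]
  }
  write_tsv(rows, path)
}

#' @rdname write_mappings
#' @export
read_mappings <- function(path) {
  req <- c("activity", "domain", "molregno", "uniprot", "maptype")
  df <- read_tsv_table(path, req, "mapping table")
  df[, req, drop = FALSE]
}

#' Read or write a seed-domain list
#'
#' Two-column dialect: `family`, `provenance` (`data_derived` or `manual`).
#' @param seeds A seed-set `data.frame` from [build_seed_set()].
#' @param path File path.
#' @export
write_seed_set <- function(seeds, path) {
  write_tsv(seeds[, c("family", "provenance")], path)
}

#' @rdname write_seed_set
#' @export
read_seed_set <- function(path) {
  df <- read_tsv_table(path, c("family", "provenance"), "seed list")
  df[, c("family", "provenance")]
}

#' Read a one-identifier-per-line list
#'
#' Used for manual-curation inputs: excluded target accessions (protein
#' fragments mis-annotated as full-length targets) and forced seed families.
#' Blank lines and `#` comments are ignored; anything after whitespace on a
#' line is treated as annotation and dropped.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- vapply(strsplit(lines[lines != ""], "[ \t]+"), `[[`, character(1), 1L)
  unique(ids)
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write %s: %s", path, conditionMessage(e)), call. = FALSE)
  })
  invisible(ok)
}
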