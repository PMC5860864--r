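# Delimited-text interchange formats and JSON persistence. All tabular
# files are TSV with a header; structured results and references are
# versioned JSON documents.

mutation_table_cols <- c("patient_id", "assay", "well", "chrom", "pos",
                         "ref", "alt", "gene", "mutant_uids", "total_uids")

#' Read a mutation well table
#'
#' TSV with header `patient_id, assay, well, chrom, pos, ref, alt, gene,
#' mutant_uids, total_uids` (positions 1-based, hg19). Rows are validated:
#' malformed counts, `mutant_uids > total_uids` and duplicate
#' (patient, assay, well, position) rows are rejected with their line
#' numbers.
#'
#' @param path File path.
#' @return A validated data.frame with an added `key` and `maf` column.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(mutation_table_cols, names(df))
  if (length(missing) > 0) {
    stop("mutation table ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- !is.finite(df$mutant_uids) | !is.finite(df$total_uids) |
    df$mutant_uids < 0 | df$total_uids <= 0 | df$pos <= 0 |
    !df$well %in% c(1L, 2L)
  if (any(bad)) {
    stop("malformed row(s) at line(s): ",
         paste(utils::head(line[bad]), collapse = ", "), call. = FALSE)
  }
  over <- df$mutant_uids > df$total_uids
  if (any(over)) {
    stop("mutant_uids > total_uids at line(s): ",
         paste(utils::head(line[over]), collapse = ", "), call. = FALSE)
  }
  idc <- paste(df$patient_id, df$assay, df$well, df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(idc)) {
    stop("duplicate observation row(s) at line(s): ",
         paste(utils::head(line[duplicated(idc)]), collapse = ", "), call. = FALSE)
  }
  df$key <- mutation_key(df$chrom, df$pos, df$ref, df$alt)
  df$maf <- compute_maf(df$mutant_uids, df$total_uids)
  df
}

#' Write a mutation well table
#' @param obs Mutation well table data.frame.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(obs, path) {
  utils::write.table(obs[, mutation_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a locus count matrix
#'
#' TSV with columns `locus_id`, `chrom`, `arm`, then one integer column
#' per sample.
#'
#' @param path File path.
#' @return For the reader, a list with `counts` (loci x samples integer
#'   matrix) and `arm_map` (data.frame `locus_id`, `chrom`, `arm`).
#' @export
read_locus_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("locus_id", "chrom", "arm")
  if (!all(needed %in% names(df))) {
    stop("locus matrix ", path, " lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  samples <- setdiff(names(df), needed)
  counts <- as.matrix(df[, samples, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$locus_id
  list(counts = counts, arm_map = df[, needed])
}

#' @rdname read_locus_matrix
#' @param counts Loci x samples matrix.
#' @param arm_map Locus-to-arm map covering the rownames of `counts`.
#' @export
write_locus_matrix <- function(counts, arm_map, path) {
  i <- match(rownames(counts), arm_map$locus_id)
  if (anyNA(i)) stop("counts contain loci absent from arm_map", call. = FALSE)
  df <- cbind(arm_map[i, c("locus_id", "chrom", "arm")],
              as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like panel interval file
#'
#' BED intervals are 0-based half-open; they are converted to 1-based
#' inclusive coordinates, so the interval `[1295227, 1295228)` covers the
#' 1-based position 1295228.
#'
#' @param path BED file (3+ columns: chrom, start, end, optional name).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @export
read_panel_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs >= 3 columns", call. = FALSE)
  out <- data.frame(chrom = df[[1]], start = df[[2]] + 1L, end = df[[3]],
                    name = if (ncol(df) >= 4) df[[4]] else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$end < out$start)) stop("empty or inverted BED interval", call. = FALSE)
  out
}

#' Persist / restore a calibrated control reference
#'
#' Single versioned JSON document holding the per-mutation summaries, the
#' pooled null, both thresholds and calibration provenance.
#'
#' @param reference A `control_reference`.
#' @param path File path.
#' @return The path (writer, invisibly) or the restored reference (reader).
#' @export
save_control_reference <- function(reference, path) {
  stopifnot(inherits(reference, "control_reference"))
  doc <- list(format = "uroseek_control_reference", version = "1.0",
              keys = reference$keys, pooled_null = reference$pooled_null,
              fallback = reference$fallback,
              t_diff = reference$t_diff, t_z = reference$t_z,
              n_controls = reference$n_controls,
              calibration = if (is.null(reference$calibration)) NULL else
                list(n_urines = reference$calibration$n_urines,
                     n_exceeding = reference$calibration$n_exceeding,
                     max_z = as.list(reference$calibration$max_z)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_control_reference
#' @export
load_control_reference <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "uroseek_control_reference")) {
    stop("not a control reference document: ", path, call. = FALSE)
  }
  calib <- NULL
  if (!is.null(doc$calibration)) {
    calib <- list(n_urines = doc$calibration$n_urines,
                  n_exceeding = doc$calibration$n_exceeding,
                  max_z = unlist(doc$calibration$max_z))
  }
  structure(list(keys = as.data.frame(doc$keys, stringsAsFactors = FALSE),
                 pooled_null = doc$pooled_null,
                 fallback = doc$fallback,
                 t_diff = doc$t_diff %||% NA_real_,
                 t_z = doc$t_z %||% NA_real_,
                 n_controls = doc$n_controls,
                 calibration = calib),
            class = "control_reference")
}

#' Write a cohort bundle to a directory
#'
#' Emits the clinical sheet, truth table, mutation well table, tumor
#' mutation list and locus count matrix as TSV files, all reproducible
#' from the configuration seed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "uroseek_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(cohort$clinical, "clinical_sheet.tsv")
  w(cohort$truth, "truth_table.tsv")
  write_mutation_table(cohort$mutations, file.path(dir, "mutation_wells.tsv"))
  if (!is.null(cohort$tumor_mutations)) w(cohort$tumor_mutations, "tumor_mutations.tsv")
  write_locus_matrix(cohort$loci, cohort$config$arm_map,
                     file.path(dir, "locus_counts.tsv"))
  invisible(dir)
}
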