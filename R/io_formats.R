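#' Column-name dialect for GDC MAF exports
#'
#' Maps the pipeline's canonical mutation-table field names to the column
#' names found in MAF files exported from the GDC portal. Pass a modified
#' copy to [read_mutations()] to load tables with other headers.
#'
#' @return Named list mapping canonical field names (`sample_id`, `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `ref_count`, `alt_count`,
#'   `polyphen_class`, `gene`) to file column names.
#' @export
gdc_maf_dialect <- function() {
  list(
    sample_id      = "Tumor_Sample_Barcode",
    chrom          = "Chromosome",
    pos            = "Start_Position",
    ref_allele     = "Reference_Allele",
    alt_allele     = "Tumor_Seq_Allele2",
    ref_count      = "t_ref_count",
    alt_count      = "t_alt_count",
    polyphen_class = "PolyPhen",
    gene           = "Hugo_Symbol"
  )
}

#' Identity dialect for the package's own mutation TSVs
#'
#' @return Named list mapping each canonical field name to itself.
#' @export
plain_dialect <- function() {
  fields <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
              "ref_count", "alt_count", "polyphen_class", "gene")
  stats::setNames(as.list(fields), fields)
}

# PolyPhen annotations arrive either as bare class labels or as
# "probably_damaging(0.98)"-style strings; anything unrecognised is "unknown".
normalize_polyphen <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("unknown", length(x))
  out[grepl("probably[ _]damaging", x)] <- "probably_damaging"
  out[grepl("possibly[ _]damaging", x)] <- "possibly_damaging"
  out[grepl("benign", x)] <- "benign"
  out
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""), quote = "")
}

# Coerce a character column to numeric; values that are present but do not
# parse raise an error naming the offending line (header is line 1).
parse_numeric_column <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "." & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("unparsable value '%s' in column '%s' at line %d",
                 x[bad[1]], column, bad[1] + 1L), call. = FALSE)
  }
  out[!is.na(x) & x == "."] <- NA_real_
  out
}

check_columns <- function(df, required, path) {
  missing <- setdiff(unlist(required), names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a somatic mutation table
#'
#' Loads a MAF-like tab-separated table of somatic point mutations. Rows that
#' are not single-nucleotide substitutions (multi-base or "-" alleles, or
#' identical ref/alt), or that lack read counts, are dropped and tallied in a
#' skip report rather than raising an error; unparsable count values are a
#' hard error naming the line.
#'
#' @param path Path to a tab-separated mutation table with a header row.
#' @param dialect Named list mapping canonical field names to the file's
#'   column names; see [gdc_maf_dialect()] (the default) and
#'   [plain_dialect()]. The `gene` entry is optional in the file.
#' @return A list with components `mutations` (data frame with columns
#'   `sample_id`, `chrom`, `pos`, `ref_allele`, `alt_allele`, `ref_count`,
#'   `alt_count`, `polyphen_class`, `gene`) and `skip_report` (named integer
#'   vector with counts for `non_snv`, `ref_equals_alt`, `missing_counts`,
#'   `bad_position`).
#' @export
read_mutations <- function(path, dialect = gdc_maf_dialect()) {
  raw <- read_tsv_raw(path)
  required <- dialect[setdiff(names(dialect), "gene")]
  check_columns(raw, required, path)

  df <- data.frame(
    sample_id  = as.character(raw[[dialect$sample_id]]),
    chrom      = as.character(raw[[dialect$chrom]]),
    pos        = parse_numeric_column(raw[[dialect$pos]], dialect$pos),
    ref_allele = toupper(as.character(raw[[dialect$ref_allele]])),
    alt_allele = toupper(as.character(raw[[dialect$alt_allele]])),
    ref_count  = parse_numeric_column(raw[[dialect$ref_count]], dialect$ref_count),
    alt_count  = parse_numeric_column(raw[[dialect$alt_count]], dialect$alt_count),
    polyphen_class = normalize_polyphen(raw[[dialect$polyphen_class]]),
    stringsAsFactors = FALSE
  )
  df$gene <- if (!is.null(dialect$gene) && dialect$gene %in% names(raw)) {
    as.character(raw[[dialect$gene]])
  } else {
    NA_character_
  }

  bases <- c("A", "C", "G", "T")
  is_snv <- df$ref_allele %in% bases & df$alt_allele %in% bases
  same   <- is_snv & df$ref_allele == df$alt_allele
  no_cnt <- is.na(df$ref_count) | is.na(df$alt_count) |
    df$ref_count < 0 | df$alt_count < 0
  bad_pos <- is.na(df$pos) | df$pos < 1

  skip <- c(
    non_snv        = sum(!is_snv),
    ref_equals_alt = sum(same),
    missing_counts = sum(is_snv & !same & no_cnt),
    bad_position   = sum(is_snv & !same & !no_cnt & bad_pos)
  )
  keep <- is_snv & !same & !no_cnt & !bad_pos
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$pos <- as.integer(out$pos)
  out$ref_count <- as.integer(out$ref_count)
  out$alt_count <- as.integer(out$alt_count)
  list(mutations = out, skip_report = skip)
}

#' Read a copy-number segment table
#'
#' Loads a SEG-format tab-separated file (columns `ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`). Coordinates are 1-based inclusive.
#' Segments of a sample may overlap; no merging is performed.
#'
#' @param path Path to the SEG file.
#' @return Data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `num_probes`, `segment_mean`.
#' @export
read_segments <- function(path) {
  raw <- read_tsv_raw(path)
  cols <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  check_columns(raw, cols, path)
  df <- data.frame(
    sample_id    = as.character(raw[["ID"]]),
    chrom        = as.character(raw[["chrom"]]),
    start        = parse_numeric_column(raw[["loc.start"]], "loc.start"),
    end          = parse_numeric_column(raw[["loc.end"]], "loc.end"),
    num_probes   = parse_numeric_column(raw[["num.mark"]], "num.mark"),
    segment_mean = parse_numeric_column(raw[["seg.mean"]], "seg.mean"),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad) > 0) {
    stop(sprintf("invalid segment interval at line %d (start > end or missing)",
                 bad[1] + 1L), call. = FALSE)
  }
  bad <- which(is.na(df$num_probes) | df$num_probes < 1)
  if (length(bad) > 0) {
    stop(sprintf("num.mark must be a positive integer at line %d", bad[1] + 1L),
         call. = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$num_probes <- as.integer(df$num_probes)
  df
}

#' Read a per-sample clinical table
#'
#' Loads a tab-separated clinical table keyed by `sample_id`. Required
#' columns: `sample_id`, `cancer_type`, `purity`, `survival_days`, `event`.
#' Optional columns (`age`, `gender`, `stage`, `smoking`, `subtype`) are kept
#' as `NA` when absent or empty, never zero-filled.
#'
#' @param path Path to the clinical TSV.
#' @return Data frame with one row per sample.
#' @export
read_clinical <- function(path) {
  raw <- read_tsv_raw(path)
  required <- c("sample_id", "cancer_type", "purity", "survival_days", "event")
  check_columns(raw, required, path)
  df <- data.frame(
    sample_id     = as.character(raw[["sample_id"]]),
    cancer_type   = as.character(raw[["cancer_type"]]),
    purity        = parse_numeric_column(raw[["purity"]], "purity"),
    survival_days = parse_numeric_column(raw[["survival_days"]], "survival_days"),
    event         = parse_numeric_column(raw[["event"]], "event"),
    stringsAsFactors = FALSE
  )
  for (opt in c("age", "gender", "stage", "smoking", "subtype")) {
    if (opt %in% names(raw)) {
      df[[opt]] <- if (opt == "age") {
        parse_numeric_column(raw[[opt]], opt)
      } else {
        as.character(raw[[opt]])
      }
    } else {
      df[[opt]] <- if (opt == "age") NA_real_ else NA_character_
    }
  }
  dup <- duplicated(df$sample_id)
  if (any(dup)) {
    stop("duplicate sample_id in clinical table: ",
         paste(unique(df$sample_id[dup]), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(df$purity) & (df$purity <= 0 | df$purity > 1))
  if (length(bad) > 0) {
    stop(sprintf("purity must lie in (0, 1]; offending sample '%s' (%.3f)",
                 df$sample_id[bad[1]], df$purity[bad[1]]), call. = FALSE)
  }
  bad <- which(!is.na(df$survival_days) & df$survival_days < 0)
  if (length(bad) > 0) {
    stop("survival_days must be non-negative; offending sample: ",
         df$sample_id[bad[1]], call. = FALSE)
  }
  bad <- which(!is.na(df$event) & !(df$event %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("event must be 0 (censored) or 1 (death); offending sample: ",
         df$sample_id[bad[1]], call. = FALSE)
  }
  df
}

#' Write a mutation table in a given dialect
#'
#' Inverse of [read_mutations()]: writing then re-reading a validated table
#' reproduces the records exactly.
#'
#' @param mutations Data frame as returned in `read_mutations()$mutations`.
#' @param path Output file path.
#' @param dialect Column-name dialect, as for [read_mutations()].
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path, dialect = gdc_maf_dialect()) {
  out <- mutations[, c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
                       "ref_count", "alt_count", "polyphen_class", "gene")]
  names(out) <- unlist(dialect[names(out)])
  write_tsv(out, path)
}

#' Write a copy-number segment table in SEG format
#'
#' @param segments Data frame as returned by [read_segments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- segments[, c("sample_id", "chrom", "start", "end", "num_probes",
                      "segment_mean")]
  names(out) <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  write_tsv(out, path)
}

#' Write a clinical table
#'
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  write_tsv(clinical, path)
}

#' Write a tab-separated table
#'
#' Plain TSV writer used for all pipeline report tables.
#'
#' @param df Data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
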