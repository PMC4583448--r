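#' Construct a biomarker table
#'
#' The central data container: `m` biomarker concentrations measured on `n`
#' subjects split into two clinical groups, gingivitis (label `-1`) and
#' periodontitis (label `+1`). Raw tables hold strictly positive
#' concentrations (pg/mL scale); [log_normalize()] converts them to
#' per-marker z-scores of the natural-log values.
#'
#' @param X numeric `m x n` matrix, markers in rows, samples in columns.
#' @param sample_ids character vector of `n` unique sample identifiers.
#' @param marker_names character vector of `m >= 2` unique marker names.
#' @param labels integer vector of length `n` over `{-1, +1}`:
#'   `-1` = gingivitis, `+1` = periodontitis.
#' @param normalized logical; `FALSE` for raw concentrations.
#'
#' @return An object of class `biomarker_table`: a list with elements
#'   `X`, `sample_ids`, `marker_names`, `labels`, `normalized`.
#' @export
biomarker_table <- function(X, sample_ids, marker_names, labels,
                            normalized = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  m <- nrow(X)
  n <- ncol(X)
  if (m < 2L)
    stop("m >= 2 required: pairwise voting is undefined for fewer than 2 markers")
  if (length(sample_ids) != n)
    stop("length(sample_ids) must equal ncol(X)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(marker_names) != m)
    stop("length(marker_names) must equal nrow(X)")
  if (anyDuplicated(marker_names))
    stop("duplicate marker names")
  if (anyNA(X))
    stop("missing values in the marker matrix are not allowed")
  labels <- as.integer(labels)
  if (length(labels) != n || !all(labels %in% c(-1L, 1L)))
    stop("labels must be a length-n vector over {-1, +1}")
  if (sum(labels == -1L) < 2L || sum(labels == 1L) < 2L)
    stop("each clinical group must contain at least 2 samples")
  if (!normalized && any(X <= 0)) {
    bad <- which(X <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive concentration at marker '%s', sample '%s'",
                 marker_names[bad[1L]], sample_ids[bad[2L]]))
  }
  dimnames(X) <- list(marker_names, sample_ids)
  structure(list(X = X,
                 sample_ids = as.character(sample_ids),
                 marker_names = as.character(marker_names),
                 labels = labels,
                 normalized = isTRUE(normalized)),
            class = "biomarker_table")
}

#' @export
print.biomarker_table <- function(x, ...) {
  cat(sprintf("biomarker_table: %d markers x %d samples (%s)\n",
              nrow(x$X), ncol(x$X),
              if (x$normalized) "log z-scores" else "raw concentrations"))
  cat(sprintf("  gingivitis (-1): %d   periodontitis (+1): %d\n",
              sum(x$labels == -1L), sum(x$labels == 1L)))
  cat("  markers: ", paste(x$marker_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a biomarker table from delimited text
#'
#' Expects a header row and one row per subject: a `sample_id` column, either
#' a `group` column (`-1`/`+1` or `gingivitis`/`periodontitis`) or the three
#' clinical parameter columns `bop_pct`, `ppd4_pct`, `cal2_any` from which the
#' label is derived via [assign_clinical_label()], then one numeric column per
#' marker. Rows whose clinical presentation matches neither case definition
#' are excluded with a message.
#'
#' @param path file path; lines starting with `#` are skipped.
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A raw-scale [biomarker_table()].
#' @export
read_biomarker_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 25L)
    hdr <- hdr[!startsWith(hdr, "#")][1L]
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("input must contain a 'sample_id' column")
  clin_cols <- c("bop_pct", "ppd4_pct", "cal2_any")
  has_clin <- all(clin_cols %in% names(df))
  has_group <- "group" %in% names(df)
  if (!has_group && !has_clin)
    stop("input must contain either a 'group' column or the clinical ",
         "parameter columns bop_pct, ppd4_pct, cal2_any")
  if (has_group) {
    labels <- parse_group_label(df$group)
  } else {
    labels <- vapply(seq_len(nrow(df)), function(i) {
      assign_clinical_label(clinical_record(
        df$sample_id[i], df$bop_pct[i], df$ppd4_pct[i],
        as.logical(df$cal2_any[i])))
    }, numeric(1))
    drop <- is.na(labels)
    if (any(drop)) {
      message("excluding ", sum(drop),
              " sample(s) with indeterminate clinical presentation: ",
              paste(df$sample_id[drop], collapse = ", "))
      df <- df[!drop, , drop = FALSE]
      labels <- labels[!drop]
    }
  }
  meta <- c("sample_id", "group", clin_cols)
  marker_names <- setdiff(names(df), meta)
  if (length(marker_names) < 2L)
    stop("m >= 2 required: found ", length(marker_names), " marker column(s)")
  Xdf <- df[marker_names]
  for (mn in marker_names) {
    v <- suppressWarnings(as.numeric(Xdf[[mn]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in marker column '%s' (row %d)",
                   mn, which(is.na(v))[1L]))
    Xdf[[mn]] <- v
  }
  biomarker_table(t(as.matrix(Xdf)), df$sample_id, marker_names, labels,
                  normalized = FALSE)
}

parse_group_label <- function(g) {
  if (is.numeric(g)) {
    if (!all(g %in% c(-1, 1))) stop("numeric 'group' must be -1 or +1")
    return(as.integer(g))
  }
  g <- tolower(trimws(as.character(g)))
  out <- ifelse(g %in% c("-1", "g", "gin", "gingivitis"), -1L,
         ifelse(g %in% c("1", "+1", "p", "per", "periodontitis"), 1L, NA_integer_))
  if (anyNA(out))
    stop("unrecognized group value(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "))
  out
}

#' Write a biomarker table to delimited text
#'
#' Inverse of [read_biomarker_table()]: one row per subject with `sample_id`,
#' `group`, and one column per marker. Normalized tables are flagged with a
#' leading `#` comment line so they are not mistaken for raw concentrations.
#'
#' @param table a [biomarker_table()].
#' @param path output file path.
#' @param sep field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_biomarker_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "biomarker_table"))
  df <- data.frame(sample_id = table$sample_ids,
                   group = table$labels,
                   t(table$X),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (table$normalized)
    writeLines("# normalized: per-marker z-scores of natural-log values", con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clinical record for periodontal case definition
#'
#' Full-mouth periodontal examination summary used to assign the clinical
#' group: percent of sites bleeding on probing (BOP), percent of sites with
#' probing pocket depth (PPD) of at least 4 mm, and whether any site shows
#' clinical attachment level (CAL) loss of at least 2 mm.
#'
#' @param sample_id subject identifier.
#' @param bop_pct percent of sites with bleeding on probing, in `[0, 100]`.
#' @param ppd4_pct percent of sites with PPD >= 4 mm, in `[0, 100]`.
#' @param cal2_any logical: any site with CAL >= 2 mm.
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(sample_id, bop_pct, ppd4_pct, cal2_any) {
  if (is.na(bop_pct) || bop_pct < 0 || bop_pct > 100)
    stop("bop_pct must be in [0, 100]")
  if (is.na(ppd4_pct) || ppd4_pct < 0 || ppd4_pct > 100)
    stop("ppd4_pct must be in [0, 100]")
  if (is.na(cal2_any)) stop("cal2_any must be TRUE or FALSE")
  structure(list(sample_id = as.character(sample_id),
                 bop_pct = as.numeric(bop_pct),
                 ppd4_pct = as.numeric(ppd4_pct),
                 cal2_any = isTRUE(cal2_any)),
            class = "clinical_record")
}

#' Assign the clinical group from periodontal parameters
#'
#' Applies the case definitions: gingivitis (`-1`) requires BOP at >= 20% of
#' sites, < 10% of sites with PPD >= 4 mm, and no site with CAL >= 2 mm;
#' periodontitis (`+1`) requires BOP at > 20% of sites, > 10% of sites with
#' PPD >= 4 mm, and CAL >= 2 mm at some site. Presentations matching neither
#' definition (including boundary values such as exactly 10% PPD >= 4 mm
#' sites with CAL loss) are indeterminate and return `NA`; they are excluded
#' from analysis, never coerced into a group.
#'
#' @param rec a [clinical_record()].
#' @return `-1`, `+1`, or `NA` (indeterminate).
#' @export
assign_clinical_label <- function(rec) {
  stopifnot(inherits(rec, "clinical_record"))
  if (rec$bop_pct >= 20 && rec$ppd4_pct < 10 && !rec$cal2_any) return(-1)
  if (rec$bop_pct > 20 && rec$ppd4_pct > 10 && rec$cal2_any) return(1)
  NA_real_
}

#' Log-transform and z-normalize a biomarker table
#'
#' Replaces each marker row by z-scores of its natural-log concentrations,
#' computed over all `n` samples jointly (the normalization precedes the
#' cross-validation loop, so it is global, not per training fold). The sample
#' standard deviation uses the `n - 1` denominator.
#'
#' @param table a raw-scale [biomarker_table()] (all values > 0).
#' @return The table with `X` replaced by per-marker log z-scores and
#'   `normalized = TRUE`.
#' @export
log_normalize <- function(table) {
  stopifnot(inherits(table, "biomarker_table"))
  if (table$normalized)
    stop("table is already normalized")
  if (any(table$X <= 0))
    stop("log_normalize requires strictly positive concentrations")
  L <- log(table$X)
  mu <- rowMeans(L)
  sdv <- apply(L, 1L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance marker(s): ",
         paste(table$marker_names[sdv == 0], collapse = ", "))
  table$X <- (L - mu) / sdv
  table$normalized <- TRUE
  table
}
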