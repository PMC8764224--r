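#' @keywords internal
"_PACKAGE"

#' Treatment arms, timepoints, biofluids and assay platforms
#'
#' Controlled vocabularies used throughout the package. The four treatment
#' arms are a saline placebo infusion (SAL), a combined GLP-1/oxyntomodulin/PYY
#' infusion (GOP), a very low-calorie diet (VLCD) and Roux-en-Y gastric bypass
#' (RYGB). Samples are paired per subject at baseline and 4 weeks, in plasma
#' and/or urine, measured on one of several LC-MS or NMR assay platforms.
#'
#' @name vocabularies
#' @keywords internal
NULL

study_groups <- function() c("SAL", "GOP", "VLCD", "RYGB")
study_timepoints <- function() c("baseline", "week4")
study_biofluids <- function() c("plasma", "urine")
study_platforms <- function() {
  c("lipidRPCpos", "lipidRPCneg", "HILICpos", "SmMolRPCpos", "SmMolRPCneg",
    "NMR1D", "NMRCPMG", "IVDr_SmMol", "IVDr_lipoprotein")
}

#' Assemble a validated metabolomic study object
#'
#' Bundles an intensity matrix with its sample metadata, feature annotation
#' and (optionally) per-subject clinical deltas into a `metabo_study` object,
#' the container consumed by every analysis stage. The sample table, not the
#' row order of the matrix, is authoritative: rows are reordered canonically
#' by (subject, timepoint, biofluid) on construction.
#'
#' @param values numeric matrix of raw intensities, samples in rows and
#'   features in columns; all present values must be strictly positive (a log
#'   transform must be defined). `NA` marks missing measurements.
#' @param samples data.frame with columns `sample_id`, `subject_id`, `group`
#'   (one of SAL/GOP/VLCD/RYGB), `timepoint` (baseline/week4) and `biofluid`
#'   (plasma/urine), one row per row of `values`.
#' @param features data.frame with columns `feature_id`, `platform`,
#'   `metabolite_class`, optional `lipid_name` (shorthand such as
#'   `"PC(16:0/20:4)"`) and logical `annotated`. Lipid names are parsed on
#'   construction; unparseable names are kept with a warning and no
#'   descriptor.
#' @param clinical optional data.frame with one row per subject: `subject_id`
#'   plus baseline-to-week-4 deltas `delta_weight` (kg),
#'   `delta_fasting_glucose` (mmol/L), `delta_fasting_insulin`,
#'   `delta_triglycerides` (mmol/L), `delta_total_cholesterol` (mmol/L).
#'
#' @return An object of class `metabo_study`: a list with elements `values`,
#'   `samples`, `features`, `clinical` and `lipids` (named list of parsed
#'   [lipid descriptors][parse_lipid_name], one entry per feature, `NULL`
#'   where no shorthand was given or parseable).
#' @export
metabo_study <- function(values, samples, features, clinical = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)

  required_s <- c("sample_id", "subject_id", "group", "timepoint", "biofluid")
  missing_s <- setdiff(required_s, names(samples))
  if (length(missing_s)) {
    stop("sample table lacks column(s): ", paste(missing_s, collapse = ", "))
  }
  if (!"feature_id" %in% names(features)) {
    stop("feature table lacks column 'feature_id'")
  }
  if (!"platform" %in% names(features)) features$platform <- "HILICpos"
  if (!"metabolite_class" %in% names(features)) features$metabolite_class <- "other"
  if (!"annotated" %in% names(features)) {
    features$annotated <- !is.na(features$metabolite_class) &
      features$metabolite_class != "other"
  }
  if (!"lipid_name" %in% names(features)) features$lipid_name <- NA_character_

  if (nrow(samples) != nrow(values)) {
    stop("sample table has ", nrow(samples), " rows but the intensity matrix has ",
         nrow(values))
  }
  if (nrow(features) != ncol(values)) {
    stop("feature table has ", nrow(features), " rows but the intensity matrix has ",
         ncol(values), " columns")
  }

  bad_group <- setdiff(unique(samples$group), study_groups())
  if (length(bad_group)) {
    stop("unknown treatment group label(s): ", paste(bad_group, collapse = ", "))
  }
  bad_tp <- setdiff(unique(samples$timepoint), study_timepoints())
  if (length(bad_tp)) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "))
  }
  bad_bf <- setdiff(unique(samples$biofluid), study_biofluids())
  if (length(bad_bf)) {
    stop("unknown biofluid label(s): ", paste(bad_bf, collapse = ", "))
  }

  key <- paste(samples$subject_id, samples$timepoint, samples$biofluid, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- samples[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (subject, timepoint, biofluid): (",
         dup$subject_id, ", ", dup$timepoint, ", ", dup$biofluid, ")")
  }
  grp_per_subj <- tapply(samples$group, samples$subject_id,
                         function(g) length(unique(g)))
  if (any(grp_per_subj > 1L)) {
    stop("subject(s) assigned to more than one group: ",
         paste(names(grp_per_subj)[grp_per_subj > 1L], collapse = ", "))
  }

  nonpos <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(nonpos)) {
    stop("nonpositive intensity for feature '",
         features$feature_id[nonpos[1L, 2L]], "' in sample '",
         samples$sample_id[nonpos[1L, 1L]], "' (value ",
         values[nonpos[1L, , drop = FALSE]], "); intensities must be > 0")
  }

  ord <- order(samples$subject_id, match(samples$timepoint, study_timepoints()),
               samples$biofluid)
  samples <- samples[ord, , drop = FALSE]
  values <- values[ord, , drop = FALSE]
  rownames(samples) <- NULL
  dimnames(values) <- list(samples$sample_id, features$feature_id)

  # flag subjects missing the week-4 pair rather than refusing them
  pair_n <- with(samples, tapply(timepoint, paste(subject_id, biofluid, sep = "\r"),
                                 function(x) length(unique(x))))
  if (any(pair_n < 2L)) {
    warning(sum(pair_n < 2L), " subject-biofluid pair(s) lack one timepoint")
  }

  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(clinical)) {
      stop("clinical table lacks column 'subject_id'")
    }
    if (anyDuplicated(clinical$subject_id)) {
      stop("clinical table must have one row per subject")
    }
  }

  lipids <- lapply(seq_len(nrow(features)), function(i) {
    nm <- features$lipid_name[i]
    if (is.na(nm) || !nzchar(nm)) return(NULL)
    parse_lipid_name(nm, feature_id = features$feature_id[i])
  })
  names(lipids) <- features$feature_id

  structure(
    list(values = values, samples = samples, features = features,
         clinical = clinical, lipids = lipids),
    class = "metabo_study"
  )
}

#' @export
print.metabo_study <- function(x, ...) {
  cat("metabo_study: ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  tab <- table(x$samples$group[!duplicated(x$samples$subject_id)])
  cat("  subjects: ", length(unique(x$samples$subject_id)),
      " | groups: ", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n", sep = "")
  cat("  biofluids: ", paste(unique(x$samples$biofluid), collapse = ", "),
      " | platforms: ", length(unique(x$features$platform)), "\n", sep = "")
  cat("  clinical table: ", if (is.null(x$clinical)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Read a study from CSV tables
#'
#' Reads the wide feature table (first column `sample_id`, remaining columns
#' one per feature), the sample metadata table, the feature annotation table
#' and, optionally, the clinical delta table, and assembles a validated
#' [metabo_study()]. Tab-delimited files are accepted; the delimiter is
#' sniffed from the header line unless given.
#'
#' @param feature_csv,sample_csv,annotation_csv,clinical_csv file paths;
#'   `clinical_csv` may be `NULL`.
#' @param delim field delimiter; `NULL` (default) sniffs `,` vs tab.
#' @return A `metabo_study`.
#' @export
read_study <- function(feature_csv, sample_csv, annotation_csv,
                       clinical_csv = NULL, delim = NULL) {
  for (f in c(feature_csv, sample_csv, annotation_csv, clinical_csv)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  sniff <- function(path) {
    if (!is.null(delim)) return(delim)
    hdr <- readLines(path, n = 1L)
    if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  rd <- function(path) {
    utils::read.csv(path, sep = sniff(path), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  wide <- rd(feature_csv)
  if (names(wide)[1L] != "sample_id") {
    stop("feature table must have 'sample_id' as its first column")
  }
  samples <- rd(sample_csv)
  idx <- match(wide$sample_id, samples$sample_id)
  if (anyNA(idx)) {
    stop("sample id(s) in the feature table absent from the sample table: ",
         paste(utils::head(wide$sample_id[is.na(idx)], 3L), collapse = ", "))
  }
  values <- as.matrix(wide[, -1L, drop = FALSE])
  features <- rd(annotation_csv)
  miss <- setdiff(colnames(values), features$feature_id)
  if (length(miss)) {
    stop("feature(s) lacking annotation rows: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  }
  features <- features[match(colnames(values), features$feature_id), ,
                       drop = FALSE]
  clinical <- if (!is.null(clinical_csv)) rd(clinical_csv) else NULL
  metabo_study(values, samples[idx, , drop = FALSE], features, clinical)
}

#' Write a study to CSV tables
#'
#' Inverse of [read_study()]: writes `features.csv` (wide intensity table),
#' `samples.csv`, `annotation.csv` and, when present, `clinical.csv` into
#' `dir`. `read_study(write_study(x))` round-trips values bit-exactly for
#' finite intensities.
#'
#' @param x a `metabo_study`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study <- function(x, dir) {
  stopifnot(inherits(x, "metabo_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(features = file.path(dir, "features.csv"),
             samples = file.path(dir, "samples.csv"),
             annotation = file.path(dir, "annotation.csv"))
  # full "%.17g" precision so numeric values survive the round trip bit-exactly
  vchar <- apply(x$values, 2L, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- NA_character_
    out
  })
  wide <- data.frame(sample_id = x$samples$sample_id, vchar,
                     check.names = FALSE)
  utils::write.csv(wide, paths[["features"]], row.names = FALSE, quote = 1L)
  utils::write.csv(x$samples, paths[["samples"]], row.names = FALSE)
  utils::write.csv(x$features, paths[["annotation"]], row.names = FALSE)
  if (!is.null(x$clinical)) {
    paths <- c(paths, clinical = file.path(dir, "clinical.csv"))
    utils::write.csv(x$clinical, paths[["clinical"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Impute missing intensities by half the per-feature minimum
#'
#' Optional pre-step replacing `NA` intensities (never zeros, which are
#' rejected at validation) by half the smallest observed value of that
#' feature, a conventional detection-limit proxy.
#'
#' @param x a `metabo_study`.
#' @return The study with missing values filled in.
#' @export
impute_half_min <- function(x) {
  stopifnot(inherits(x, "metabo_study"))
  v <- x$values
  for (j in seq_len(ncol(v))) {
    nas <- is.na(v[, j])
    if (any(nas)) {
      if (all(nas)) stop("feature '", colnames(v)[j], "' has no observed values")
      v[nas, j] <- min(v[!nas, j]) / 2
    }
  }
  x$values <- v
  x
}
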