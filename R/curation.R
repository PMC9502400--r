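# Bioactivity curation: replicate aggregation, activity labeling and
# train/test assembly.
#
# The raw input is a table of single measurements (one row per assay record):
# compound_id, smiles, endpoint (KI or IC50), relation (EQ/GT/LT), value_nM,
# source_id. Curation standardizes structures, deduplicates by canonical
# SMILES, reconciles replicate Ki measurements, labels compounds by potency
# thresholds (active at Ki <= 1 uM, inactive at Ki >= 5 uM, in-between
# removed), and assembles a training set (Ki data minus a random holdout) and
# an external test set (the holdout plus IC50-measured compounds not already
# in training).

#' Aggregate replicate potency measurements
#'
#' Reconciles repeated potency measurements of one compound into a single
#' value. One value is returned as is; two values are averaged; with three or
#' more, values deviating by more than `max_dev` (default 25%) from the mean
#' of all values are discarded and the mean of the survivors is recomputed
#' once. The deviation filter is a single pass by default; `iterate = TRUE`
#' repeats discard-and-recompute until no value is removed.
#'
#' @param values numeric vector of potencies (nM), all strictly positive.
#' @param max_dev maximum tolerated relative deviation from the mean
#'   (strictly greater deviations are discarded). Default 0.25.
#' @param iterate repeat the filter to convergence instead of one pass.
#' @return list with `potency` (nM), `n_used`, `n_discarded`.
#' @examples
#' aggregate_replicates(c(100, 200))       # potency 150
#' aggregate_replicates(c(100, 100, 200))  # 200 discarded, potency 100
#' @export
aggregate_replicates <- function(values, max_dev = 0.25, iterate = FALSE) {
  if (length(values) == 0) .stopf("no replicate values supplied")
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0)) {
    .stopf("replicate potencies must be finite and strictly positive")
  }
  n <- length(values)
  if (n <= 2) {
    return(list(potency = mean(values), n_used = n, n_discarded = 0L))
  }
  kept <- values
  repeat {
    m <- mean(kept)
    # boundary deviations (exactly max_dev) are kept; epsilon guards the
    # comparison against floating-point noise in the mean
    keep <- abs(kept - m) / m <= max_dev * (1 + 1e-9)
    if (!any(keep)) {
      .stopf("irreconcilable replicates: all %d values deviate by more than %g%% from their mean",
             length(kept), 100 * max_dev)
    }
    if (all(keep) || !iterate) {
      kept <- kept[keep]
      break
    }
    kept <- kept[keep]
  }
  list(potency = mean(kept),
       n_used = length(kept),
       n_discarded = n - length(kept))
}

#' Label a compound by potency thresholds
#'
#' Applies the two-threshold activity scheme: potency at or below
#' `active_max` (1 uM) is ACTIVE, at or above `inactive_min` (5 uM) is
#' INACTIVE, and the band in between is EXCLUDED (such compounds are removed
#' from model datasets). Both boundaries are inclusive.
#'
#' @param potency_nM numeric vector of potencies in nanomolar.
#' @param active_max,inactive_min class thresholds in nM.
#' @return character vector in `{"ACTIVE", "INACTIVE", "EXCLUDED"}`.
#' @export
label_activity <- function(potency_nM, active_max = 1000, inactive_min = 5000) {
  if (!is.numeric(potency_nM) || any(!is.finite(potency_nM)) || any(potency_nM <= 0)) {
    .stopf("potencies must be finite and strictly positive")
  }
  ifelse(potency_nM <= active_max, "ACTIVE",
         ifelse(potency_nM >= inactive_min, "INACTIVE", "EXCLUDED"))
}

#' Read a bioactivity record table
#'
#' Reads a delimited text export with columns `compound_id`, `smiles`,
#' `endpoint` (KI/IC50), `relation` (EQ/GT/LT), `value_nM`, `source_id`.
#'
#' @param path file path of a CSV (or TSV with `sep = "\t"`).
#' @param sep field separator.
#' @return data.frame of bioactivity records.
#' @export
read_bioactivity_csv <- function(path, sep = ",") {
  rec <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  .validate_records(rec)
}

.validate_records <- function(records) {
  need <- c("compound_id", "smiles", "endpoint", "relation", "value_nM", "source_id")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    .stopf("record table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  records$endpoint <- toupper(records$endpoint)
  records$relation <- toupper(records$relation)
  if (!all(records$endpoint %in% c("KI", "IC50"))) {
    .stopf("endpoint must be KI or IC50")
  }
  if (!all(records$relation %in% c("EQ", "GT", "LT"))) {
    .stopf("relation must be EQ, GT or LT")
  }
  if (any(!is.finite(records$value_nM)) || any(records$value_nM <= 0)) {
    .stopf("value_nM must be finite and strictly positive")
  }
  records
}

# Curate one endpoint's records into one row per canonical SMILES.
# Returns a data.frame; irreconcilable-replicate compounds are dropped with
# a warning.
.curate_group <- function(records, max_dev) {
  smi <- unique(records$canonical_smiles)
  rows <- vector("list", length(smi))
  dropped <- character(0)
  for (i in seq_along(smi)) {
    rec <- records[records$canonical_smiles == smi[i], , drop = FALSE]
    agg <- tryCatch(aggregate_replicates(rec$value_nM, max_dev = max_dev),
                    error = function(e) NULL)
    if (is.null(agg)) {
      dropped <- c(dropped, smi[i])
      next
    }
    rows[[i]] <- data.frame(
      canonical_smiles = smi[i],
      potency_nM = agg$potency,
      n_replicates_used = agg$n_used,
      n_replicates_discarded = agg$n_discarded,
      compound_ids = paste(unique(rec$compound_id), collapse = ";"),
      source_ids = paste(unique(rec$source_id), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  if (length(dropped)) {
    .warnf("dropped %d compound(s) with irreconcilable replicates", length(dropped))
  }
  do.call(rbind, rows[!vapply(rows, is.null, FALSE)])
}

#' Assemble training and test sets from raw bioactivity records
#'
#' Runs the full curation pipeline: structure standardization, deduplication
#' by canonical SMILES, replicate aggregation of Ki values, optional
#' source-document filtering, potency labeling, and removal of the excluded
#' potency band. A seeded random holdout of `holdout_n` labeled Ki compounds
#' is moved from the training pool into the external test set; the test set
#' additionally receives IC50-measured compounds not already present in
#' training, labeled by the same thresholds, plus any Ki compounds rejected
#' by the source filter.
#'
#' @param records bioactivity record data.frame
#'   (see [read_bioactivity_csv()]).
#' @param holdout_n number of labeled Ki compounds moved to the test set.
#' @param seed integer seed controlling the holdout draw.
#' @param source_filter optional character vector of `source_id`s; a compound
#'   stays in the training pool only if at least one of its Ki records comes
#'   from these sources. Filtered-out compounds join the test set.
#' @param max_dev replicate-deviation discard threshold
#'   (see [aggregate_replicates()]).
#' @return an object of class `vs_datasets`: list with `training` and `test`
#'   data.frames (columns `canonical_smiles`, `potency_nM`, `label`,
#'   `n_replicates_used`, `n_replicates_discarded`, `endpoint`), the `seed`,
#'   and a `summary` of curation counts.
#' @export
build_datasets <- function(records, holdout_n = 100, seed = 1,
                           source_filter = NULL, max_dev = 0.25) {
  records <- .validate_records(records)
  if (nrow(records) == 0) .stopf("no records supplied")

  # Standardize each distinct raw SMILES once.
  raw <- unique(records$smiles)
  std <- standardize_structure(raw, on_error = "na")
  n_bad <- sum(is.na(std))
  if (n_bad > 0) {
    .warnf("dropped %d unparseable or empty structure(s)", n_bad)
  }
  records$canonical_smiles <- std[match(records$smiles, raw)]
  records <- records[!is.na(records$canonical_smiles), , drop = FALSE]

  # Censored measurements cannot enter an arithmetic mean.
  records <- records[records$relation == "EQ", , drop = FALSE]
  if (nrow(records) == 0) .stopf("no usable (uncensored, parseable) records")

  ki <- .curate_group(records[records$endpoint == "KI", , drop = FALSE], max_dev)
  if (is.null(ki) || nrow(ki) == 0) .stopf("no Ki compounds after curation")
  n_ki_unique <- nrow(ki)

  # Source filter: compounds with no Ki record from an accepted source leave
  # the training pool but remain available for the external test set.
  filtered_out <- NULL
  if (!is.null(source_filter)) {
    in_filter <- vapply(strsplit(ki$source_ids, ";", fixed = TRUE),
                        function(s) any(s %in% source_filter), FALSE)
    filtered_out <- ki[!in_filter, , drop = FALSE]
    ki <- ki[in_filter, , drop = FALSE]
  }

  finish <- function(df, endpoint) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df$label <- label_activity(df$potency_nM)
    df <- df[df$label != "EXCLUDED", , drop = FALSE]
    if (nrow(df) == 0) return(NULL)
    df$endpoint <- endpoint
    df[, c("canonical_smiles", "potency_nM", "label",
           "n_replicates_used", "n_replicates_discarded", "endpoint")]
  }

  ki_pre <- ki
  ki_lab <- finish(ki, "KI")
  if (is.null(ki_lab)) .stopf("no labeled Ki compounds after thresholding")
  n_active <- sum(ki_lab$label == "ACTIVE")
  n_inactive <- sum(ki_lab$label == "INACTIVE")

  if (holdout_n >= nrow(ki_lab)) {
    .stopf("holdout_n (%d) must be smaller than the number of labeled Ki compounds (%d)",
           holdout_n, nrow(ki_lab))
  }
  hold_idx <- if (holdout_n > 0) {
    .with_seed(seed, sample.int(nrow(ki_lab), holdout_n))
  } else {
    integer(0)
  }
  training <- ki_lab[setdiff(seq_len(nrow(ki_lab)), hold_idx), , drop = FALSE]
  test <- ki_lab[hold_idx, , drop = FALSE]

  # Source-filtered Ki compounds enrich the test set.
  test <- rbind(test, finish(filtered_out, "KI"))

  # IC50-measured compounds not already used for training.
  ic50 <- .curate_group(records[records$endpoint == "IC50", , drop = FALSE], max_dev)
  n_ic50 <- if (is.null(ic50)) 0L else nrow(ic50)
  ic50_lab <- finish(ic50, "IC50")
  if (!is.null(ic50_lab)) {
    ic50_lab <- ic50_lab[!(ic50_lab$canonical_smiles %in% training$canonical_smiles), , drop = FALSE]
    ic50_lab <- ic50_lab[!(ic50_lab$canonical_smiles %in% test$canonical_smiles), , drop = FALSE]
    test <- rbind(test, ic50_lab)
  }
  rownames(training) <- rownames(test) <- NULL

  structure(list(
    training = training,
    test = test,
    seed = as.integer(seed),
    summary = list(
      n_ki_unique = n_ki_unique,
      n_ki_after_source_filter = nrow(ki_pre),
      n_active_ki = n_active,
      n_inactive_ki = n_inactive,
      n_ic50_unique = n_ic50,
      n_training = nrow(training),
      n_test = nrow(test)
    )
  ), class = "vs_datasets")
}

#' @export
print.vs_datasets <- function(x, ...) {
  s <- x$summary
  cat("Curated virtual-screening datasets\n")
  cat(sprintf("  unique Ki compounds:     %d (%d active / %d inactive after thresholding)\n",
              s$n_ki_unique, s$n_active_ki, s$n_inactive_ki))
  cat(sprintf("  training set:            %d compounds (%d active / %d inactive)\n",
              nrow(x$training),
              sum(x$training$label == "ACTIVE"),
              sum(x$training$label == "INACTIVE")))
  cat(sprintf("  external test set:       %d compounds (%d active / %d inactive)\n",
              nrow(x$test),
              sum(x$test$label == "ACTIVE"),
              sum(x$test$label == "INACTIVE")))
  cat(sprintf("  holdout seed:            %d\n", x$seed))
  invisible(x)
}

#' Write curated datasets to disk
#'
#' Writes `training.csv` and `test.csv` plus a JSON manifest recording the
#' holdout seed, curation summary and set membership.
#'
#' @param datasets a `vs_datasets` object from [build_datasets()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_datasets <- function(datasets, dir) {
  stopifnot(inherits(datasets, "vs_datasets"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(datasets$training, file.path(dir, "training.csv"), row.names = FALSE)
  utils::write.csv(datasets$test, file.path(dir, "test.csv"), row.names = FALSE)
  manifest <- list(
    seed = datasets$seed,
    summary = datasets$summary,
    training = datasets$training$canonical_smiles,
    test = datasets$test$canonical_smiles
  )
  path <- file.path(dir, "split_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
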