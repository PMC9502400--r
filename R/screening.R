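# Library screening: score a candidate library with a fitted model (or
# consensus), retain the top-scoring compounds, and cluster the hits for
# structural diversity.

#' Screen a compound library
#'
#' Passes a SMILES library through the same structure standardizer used for
#' model training, featurizes it with the model's fingerprint family and
#' parameters, scores every valid compound, and retains hits. `"max_ps"`
#' retention keeps all compounds tied (within `tie_tol`) at the library's
#' maximum probability score; `"ps_at_least"` keeps compounds with
#' `ps >= threshold`. Hits are ranked by descending PS, ties broken by input
#' order.
#'
#' @param model a fitted `vs_model` or `vs_consensus`.
#' @param library character vector of SMILES (need not be standardized).
#' @param retention `"max_ps"` (default) or `"ps_at_least"`.
#' @param threshold PS cutoff for `"ps_at_least"` retention.
#' @param tie_tol numeric tolerance for the maximum-PS tie.
#' @return object of class `vs_hits`: data.frame with `canonical_smiles`,
#'   `ps` and `rank`, plus a `summary` attribute (library size, number of
#'   valid structures, number of hits, maximum PS).
#' @export
screen_library <- function(model, library, retention = c("max_ps", "ps_at_least"),
                           threshold = 0.5, tie_tol = 1e-9) {
  retention <- match.arg(retention)
  if (!inherits(model, "vs_model") && !inherits(model, "vs_consensus")) {
    .stopf("'model' must be a vs_model or vs_consensus")
  }
  if (!is.character(library) || length(library) == 0) {
    .stopf("'library' must be a non-empty character vector of SMILES")
  }
  std <- standardize_structure(library, on_error = "na")
  valid <- !is.na(std)
  if (!any(valid)) .stopf("no valid molecules in the library after standardization")
  if (any(!valid)) {
    .warnf("dropped %d structure(s) that failed standardization", sum(!valid))
  }
  smiles <- std[valid]

  ps <- if (inherits(model, "vs_consensus")) {
    fps <- lapply(model$models, function(m) {
      .featurize_for(m, smiles)
    })
    predict(model, fps)$ps
  } else {
    predict(model, .featurize_for(model, smiles))
  }

  keep <- if (retention == "max_ps") {
    ps >= max(ps) - tie_tol
  } else {
    ps >= threshold
  }
  ord <- order(-ps[keep], seq_along(ps)[keep])
  hits <- data.frame(
    canonical_smiles = smiles[keep][ord],
    ps = ps[keep][ord],
    stringsAsFactors = FALSE
  )
  hits$rank <- seq_len(nrow(hits))
  structure(hits,
            summary = list(library_size = length(library),
                           n_valid = length(smiles),
                           n_hits = nrow(hits),
                           max_ps = max(ps),
                           retention = retention,
                           threshold = if (retention == "ps_at_least") threshold else NA_real_),
            class = c("vs_hits", "data.frame"))
}

# Fingerprint a set of standardized SMILES with a model's stored
# fingerprint family/parameters (Morgan defaults when untagged).
.featurize_for <- function(model, smiles) {
  fam <- model$fingerprint$family
  prm <- model$fingerprint$params
  if (is.null(fam)) fam <- "morgan"
  fingerprint_matrix(smiles, fam,
                     radius = if (!is.null(prm$radius)) prm$radius else 2L,
                     n_bits = if (!is.null(prm$n_bits)) prm$n_bits else 2048L)
}

#' @export
print.vs_hits <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Screening hits: %d of %d valid compounds (library size %d)\n",
              s$n_hits, s$n_valid, s$library_size))
  cat(sprintf("  retention: %s%s; maximum PS %.3f\n", s$retention,
              if (!is.na(s$threshold)) sprintf(" (threshold %.2f)", s$threshold) else "",
              s$max_ps))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Diversity-cluster screening hits
#'
#' Deterministic leader clustering on Morgan-fingerprint Tanimoto
#' similarity: hits are visited in rank order; a hit joins the first cluster
#' whose leader is at least `similarity_cutoff` similar, otherwise it founds
#' a new cluster. Cluster leaders are the structural representatives one
#' would carry forward to visual inspection and purchase.
#'
#' @param hits a `vs_hits` object from [screen_library()].
#' @param similarity_cutoff Tanimoto similarity in `[0, 1]` (default 0.7)
#'   above which two hits are considered structurally redundant.
#' @return the `vs_hits` object with an added `cluster_id` column and a
#'   `representatives` attribute (the leaders' canonical SMILES).
#' @export
diversity_filter <- function(hits, similarity_cutoff = 0.7) {
  if (!inherits(hits, "vs_hits") || nrow(hits) == 0) {
    .stopf("'hits' must be a non-empty vs_hits object")
  }
  if (similarity_cutoff < 0 || similarity_cutoff > 1) {
    .stopf("similarity_cutoff must lie in [0, 1]")
  }
  fp <- fingerprint_matrix(hits$canonical_smiles, "morgan")
  K <- tanimoto_kernel_matrix(fp)
  leaders <- integer(0)
  cluster <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    joined <- FALSE
    for (ci in seq_along(leaders)) {
      if (K[i, leaders[ci]] >= similarity_cutoff) {
        cluster[i] <- ci
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      leaders <- c(leaders, i)
      cluster[i] <- length(leaders)
    }
  }
  hits$cluster_id <- cluster
  attr(hits, "representatives") <- hits$canonical_smiles[leaders]
  attr(hits, "leader_rows") <- leaders
  hits
}
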