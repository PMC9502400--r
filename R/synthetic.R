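# Synthetic ChEMBL-like benchmark.
#
# Generates bioactivity record tables and screening libraries with a hidden,
# learnable structure-activity rule, so the curation -> fingerprint -> model
# -> screening pipeline can be exercised end to end without any download.
# Compounds are scaffold x substituent decorations; a compound matching the
# pharmacophore rule (by default: it carries a sulfonamide substituent) draws
# its true Ki from the potent mode of a bimodal log-normal distribution, all
# others from the weak mode. Replicate measurements add multiplicative
# log-normal noise with occasional multiplicative outliers, a fraction of
# compounds is reported as IC50 instead of Ki, a few records are censored
# (relation GT), and some raw SMILES are written as salts or charged forms
# to exercise the standardizer.

.DEFAULT_SCAFFOLDS <- c(
  "c1cc({R1})ccc1{R2}",
  "c1cc({R1})cc({R2})c1",
  "c1cc({R1})cnc1{R2}",
  "c1csc({R1})c1{R2}",
  "c1coc({R1})c1{R2}",
  "C1CC({R1})CCC1{R2}",
  "C1CN({R1})CCN1{R2}",
  "c1ccc2c(c1)cc({R1})n2{R2}",
  "c1ccc(c(c1){R2}){R1}",
  "C1CC({R1})N(C1)C(=O){R2}"
)

.DEFAULT_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "C(C)C", "CCCC", "OC", "OCC", "N(C)C", "NC",
  "F", "Cl", "Br", "C#N", "C(=O)C", "C(=O)OC", "C(=O)O", "C(F)(F)F",
  "CO", "CCO", "CCN", "C=C", "OC(F)F", "CC#N", "C(C)(C)C"
)

.DEFAULT_PHARM_SUBSTITUENTS <- c(
  "S(=O)(=O)N", "S(=O)(=O)NC", "S(=O)(=O)N(C)C",
  "CS(=O)(=O)N", "S(=O)(=O)NCC", "CCS(=O)(=O)N"
)

#' Specify a synthetic screening benchmark
#'
#' Collects the generator parameters: chemical space (scaffold templates
#' with `{R1}`/`{R2}` attachment points and substituent fragments), the
#' hidden pharmacophore rule, the bimodal potency distribution, replicate
#' noise, and data-quality nuisances (outliers, censored records, salt
#' spellings, IC50-measured compounds).
#'
#' @param n_compounds number of compounds to sample from the enumerable
#'   scaffold-by-substituent space.
#' @param scaffolds SMILES templates containing `{R1}` and `{R2}`.
#' @param substituents plain substituent fragments (usable at both points).
#' @param pharm_substituents rule-carrying fragments (R1 position); the
#'   default set carries a sulfonamide group.
#' @param pharmacophore_rule substructure written as a SMILES fragment whose
#'   literal presence in a generated SMILES marks a rule match.
#' @param active_fraction_target fraction of sampled compounds matching the
#'   rule.
#' @param ki_active_mu,ki_inactive_mu medians (nM) of the potent and weak
#'   true-Ki modes; must sit on the proper sides of the 1 uM / 5 uM labels.
#' @param ki_spread_log10 standard deviation (log10 units) of each true-Ki
#'   mode; controls how much the bimodal distribution straddles the
#'   labeling thresholds.
#' @param noise_sigma_log10 replicate measurement noise (log10 units).
#' @param outlier_rate probability that a replicate is multiplied by a
#'   factor drawn uniformly from `[3, 10]`.
#' @param replicate_dist probabilities of 1..4 replicate measurements.
#' @param ic50_fraction fraction of compounds measured as IC50 (these feed
#'   the external test set).
#' @param censored_rate probability that a record is censored (relation GT).
#' @param salt_rate probability that a record's SMILES is spelled as a salt
#'   or charged form.
#' @param seed master seed of the generator.
#' @return object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_compounds = 600L,
                           scaffolds = .DEFAULT_SCAFFOLDS,
                           substituents = .DEFAULT_SUBSTITUENTS,
                           pharm_substituents = .DEFAULT_PHARM_SUBSTITUENTS,
                           pharmacophore_rule = "S(=O)(=O)N",
                           active_fraction_target = 0.35,
                           ki_active_mu = 100,
                           ki_inactive_mu = 50000,
                           ki_spread_log10 = 0.6,
                           noise_sigma_log10 = 0.1,
                           outlier_rate = 0.05,
                           replicate_dist = c(0.4, 0.3, 0.2, 0.1),
                           ic50_fraction = 0.15,
                           censored_rate = 0.03,
                           salt_rate = 0.10,
                           seed = 7L) {
  stopifnot(length(replicate_dist) == 4, all(replicate_dist >= 0))
  rates <- c(active_fraction_target, outlier_rate, ic50_fraction,
             censored_rate, salt_rate)
  if (any(rates < 0 | rates > 1)) .stopf("all rates must lie in [0, 1]")
  if (active_fraction_target <= 0 || active_fraction_target >= 1) {
    .stopf("active_fraction_target must lie strictly inside (0, 1)")
  }
  if (!(ki_active_mu <= 1000 && ki_inactive_mu >= 5000)) {
    .stopf("ki_active_mu must be <= 1000 nM and ki_inactive_mu >= 5000 nM so the hidden rule aligns with the labeling thresholds")
  }
  structure(list(
    n_compounds = as.integer(n_compounds),
    scaffolds = scaffolds,
    substituents = substituents,
    pharm_substituents = pharm_substituents,
    pharmacophore_rule = pharmacophore_rule,
    active_fraction_target = active_fraction_target,
    ki_active_mu = ki_active_mu,
    ki_inactive_mu = ki_inactive_mu,
    ki_spread_log10 = ki_spread_log10,
    noise_sigma_log10 = noise_sigma_log10,
    outlier_rate = outlier_rate,
    replicate_dist = replicate_dist / sum(replicate_dist),
    ic50_fraction = ic50_fraction,
    censored_rate = censored_rate,
    salt_rate = salt_rate,
    seed = as.integer(seed)
  ), class = "benchmark_spec")
}

.decorate <- function(scaffold, r1, r2) {
  unlist(Map(function(s, a, b) {
    gsub("{R2}", b, gsub("{R1}", a, s, fixed = TRUE), fixed = TRUE)
  }, scaffold, r1, r2, USE.NAMES = FALSE))
}

#' Enumerate and sample a synthetic compound library
#'
#' Enumerates all scaffold x R1 x R2 decorations (R1 drawn from plain plus
#' rule-carrying substituents, R2 from plain substituents) and samples
#' `n_compounds` distinct members without replacement, hitting the rule-match
#' quota `round(n * active_fraction_target)` exactly.
#'
#' @param spec a [benchmark_spec()].
#' @param n override of `spec$n_compounds`.
#' @param seed override of `spec$seed` (e.g. to draw an independent
#'   screening library from the same chemical space).
#' @return data.frame with `compound_id`, `smiles` and the hidden
#'   `rule_match` flag.
#' @export
generate_library <- function(spec, n = spec$n_compounds, seed = spec$seed) {
  stopifnot(inherits(spec, "benchmark_spec"))
  n <- as.integer(n)
  if (n == 0) {
    return(data.frame(compound_id = character(0), smiles = character(0),
                      rule_match = logical(0), stringsAsFactors = FALSE))
  }
  r1 <- c(spec$substituents, spec$pharm_substituents)
  space <- expand.grid(s = seq_along(spec$scaffolds),
                       a = seq_along(r1),
                       b = seq_along(spec$substituents))
  smiles <- .decorate(spec$scaffolds[space$s], r1[space$a],
                      spec$substituents[space$b])
  match_rule <- grepl(spec$pharmacophore_rule, smiles, fixed = TRUE)
  n_match <- round(n * spec$active_fraction_target)
  pool_m <- which(match_rule)
  pool_o <- which(!match_rule)
  if (n_match > length(pool_m) || (n - n_match) > length(pool_o)) {
    .stopf("requested %d compounds exceed the enumerable space (%d rule-matching, %d others)",
           n, length(pool_m), length(pool_o))
  }
  idx <- .with_seed(seed, {
    sel <- c(sample(pool_m, n_match), sample(pool_o, n - n_match))
    sample(sel)  # shuffle so rule matches are not clustered by position
  })
  data.frame(
    compound_id = sprintf("SYN%05d", seq_len(n)),
    smiles = smiles[idx],
    rule_match = match_rule[idx],
    stringsAsFactors = FALSE
  )
}

# Bioactivity of one compound: the true Ki plus the raw replicate records.
# Deterministic given (spec$seed, compound index).
.assign_one <- function(smiles, rule_match, idx, spec) {
  .with_seed(.child_seed(spec$seed, 7000L + idx), {
    mu <- if (rule_match) spec$ki_active_mu else spec$ki_inactive_mu
    true_ki <- 10^(log10(mu) + stats::rnorm(1, 0, spec$ki_spread_log10))
    endpoint <- if (stats::runif(1) < spec$ic50_fraction) "IC50" else "KI"
    n_rep <- sample(1:4, 1, prob = spec$replicate_dist)
    values <- true_ki * 10^stats::rnorm(n_rep, 0, spec$noise_sigma_log10)
    is_out <- stats::runif(n_rep) < spec$outlier_rate
    values[is_out] <- values[is_out] * stats::runif(sum(is_out), 3, 10)
    relation <- ifelse(stats::runif(n_rep) < spec$censored_rate, "GT", "EQ")
    raw <- smiles
    if (stats::runif(1) < spec$salt_rate) {
      # terminal carboxylic acids become sodium carboxylates, everything else
      # an HCl salt; the acid pattern must not match esters (C(=O)OC)
      acid <- "C\\(=O\\)O(?=\\)|$)"
      raw <- if (grepl(acid, smiles, perl = TRUE)) {
        paste0(sub(acid, "C(=O)[O-]", smiles, perl = TRUE), ".[Na+]")
      } else {
        paste0(smiles, ".Cl")
      }
    }
    source_id <- ifelse(stats::runif(n_rep) < 0.97, "SRC-MAIN", "SRC-ALT")
    list(
      true_ki = true_ki,
      records = data.frame(
        compound_id = sprintf("SYN%05d", idx),
        smiles = raw,
        endpoint = endpoint,
        relation = relation,
        value_nM = values,
        source_id = source_id,
        stringsAsFactors = FALSE
      )
    )
  })
}

.compound_index <- function(compound_id) {
  as.integer(sub("^SYN", "", compound_id))
}

#' Simulate bioactivity records for generated compounds
#'
#' Draws each compound's true Ki from the potency mode selected by its
#' hidden rule flag, then emits 1-4 replicate measurement records with
#' multiplicative noise, occasional outliers, censoring and salt spellings
#' (see [benchmark_spec()]). Records are deterministic per compound given
#' the spec seed.
#'
#' @param compounds data.frame from [generate_library()].
#' @param spec the [benchmark_spec()].
#' @return data.frame of bioactivity records in the curation input schema.
#' @export
assign_bioactivity <- function(compounds, spec) {
  stopifnot(inherits(spec, "benchmark_spec"),
            all(c("compound_id", "smiles", "rule_match") %in% names(compounds)))
  out <- lapply(seq_len(nrow(compounds)), function(i) {
    .assign_one(compounds$smiles[i], compounds$rule_match[i],
                .compound_index(compounds$compound_id[i]), spec)$records
  })
  do.call(rbind, out)
}

#' Build the full synthetic benchmark
#'
#' Generates the compound library, simulates its bioactivity records, and
#' returns both the raw record table (curation input schema) and the hidden
#' truth table used by parameter-recovery tests.
#'
#' @param spec a [benchmark_spec()] (defaults to the standard benchmark).
#' @return object of class `vs_benchmark`: list with `records`, `truth`
#'   (compound_id, smiles, rule_match, true_ki_nM, true_label), the `spec`,
#'   and a `summary` with the realized rule-match and active fractions.
#' @export
make_benchmark <- function(spec = benchmark_spec()) {
  lib <- generate_library(spec)
  assigned <- lapply(seq_len(nrow(lib)), function(i) {
    .assign_one(lib$smiles[i], lib$rule_match[i],
                .compound_index(lib$compound_id[i]), spec)
  })
  records <- do.call(rbind, lapply(assigned, `[[`, "records"))
  truth <- data.frame(
    compound_id = lib$compound_id,
    smiles = lib$smiles,
    rule_match = lib$rule_match,
    true_ki_nM = vapply(assigned, `[[`, 0, "true_ki"),
    stringsAsFactors = FALSE
  )
  truth$true_label <- label_activity(truth$true_ki_nM)
  structure(list(
    records = records,
    truth = truth,
    spec = spec,
    summary = list(
      n_compounds = nrow(lib),
      n_records = nrow(records),
      rule_match_fraction = mean(truth$rule_match),
      active_fraction = mean(truth$true_label == "ACTIVE")
    )
  ), class = "vs_benchmark")
}

#' @export
print.vs_benchmark <- function(x, ...) {
  s <- x$summary
  cat("Synthetic screening benchmark\n")
  cat(sprintf("  %d compounds, %d raw records (seed %d)\n",
              s$n_compounds, s$n_records, x$spec$seed))
  cat(sprintf("  rule-match fraction %.3f; true-active fraction %.3f\n",
              s$rule_match_fraction, s$active_fraction))
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Writes `records.csv` (curation input schema), `truth.csv` and
#' `spec.json`.
#'
#' @param benchmark a `vs_benchmark` from [make_benchmark()].
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "vs_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(benchmark$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(benchmark$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(benchmark$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
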