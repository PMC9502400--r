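# Structure standardization, replicate aggregation, labeling and dataset
# assembly.

test_that("standardization canonicalizes, strips salts and neutralizes", {
  expect_identical(standardize_structure("CCO"), "CCO")
  expect_identical(standardize_structure("CC(=O)[O-].[Na+]"), "CC(=O)O")
  # same molecule, different spellings -> one canonical form
  expect_identical(standardize_structure("OCC"), standardize_structure("CCO"))
  expect_identical(standardize_structure("C1=CC=CC=C1"),
                   standardize_structure("c1ccccc1"))
  # idempotent
  s <- standardize_structure("CC(=O)[O-].[Na+]")
  expect_identical(standardize_structure(s), s)
  # amine hydrochloride loses its counterion
  expect_identical(standardize_structure("CC[NH3+].[Cl-]"),
                   standardize_structure("CCN"))
})

test_that("standardization rejects unusable structures", {
  expect_error(standardize_structure("C1CC"), "invalid structure")
  expect_error(standardize_structure(""), "invalid structure")
  expect_error(standardize_structure("[Na+].[Cl-]"), "no organic fragment")
  out <- standardize_structure(c("CCO", "C1CC"), on_error = "na")
  expect_identical(out[1], "CCO")
  expect_true(is.na(out[2]))
  expect_identical(attr(out, "reason")[2], "invalid structure")
})

test_that("replicate aggregation follows the one-pass 25% discard rule", {
  expect_equal(aggregate_replicates(100),
               list(potency = 100, n_used = 1L, n_discarded = 0L))
  # two values: plain mean, no filtering
  expect_equal(aggregate_replicates(c(100, 200))$potency, 150)
  expect_equal(aggregate_replicates(c(100, 200))$n_discarded, 0L)
  # three values: 200 deviates 50% from mean 133.3 and is discarded; the
  # 100s deviate exactly 25% and are kept; recomputed mean is 100
  agg <- aggregate_replicates(c(100, 100, 200))
  expect_equal(agg$potency, 100)
  expect_equal(agg$n_used, 2L)
  expect_equal(agg$n_discarded, 1L)
  # all within 25%: everything kept
  expect_equal(aggregate_replicates(c(100, 104, 96)),
               list(potency = 100, n_used = 3L, n_discarded = 0L))
})

test_that("replicate aggregation rejects degenerate input", {
  expect_error(aggregate_replicates(numeric(0)))
  expect_error(aggregate_replicates(c(100, -5)))
  expect_error(aggregate_replicates(c(1, 1, 100, 100)), "irreconcilable")
})

test_that("aggregation is permutation-invariant, scale-equivariant and in-range", {
  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(1:6, 1)
      v <- 10^runif(n, 0, 4)
      a <- tryCatch(aggregate_replicates(v), error = function(e) NULL)
      b <- tryCatch(aggregate_replicates(v[sample.int(length(v))]),
                    error = function(e) NULL)
      if (is.null(a)) {
        expect_null(b)
        next
      }
      expect_equal(a$potency, b$potency)
      expect_equal(a$n_used, b$n_used)
      # scale equivariance
      k <- runif(1, 0.1, 10)
      a_scaled <- aggregate_replicates(k * v)
      expect_equal(a_scaled$potency, k * a$potency)
      # output within the input range
      expect_gte(a$potency, min(v))
      expect_lte(a$potency, max(v))
    }
  })
})

test_that("activity labeling applies inclusive 1 uM / 5 uM thresholds", {
  expect_identical(label_activity(1000), "ACTIVE")
  expect_identical(label_activity(5000), "INACTIVE")
  expect_identical(label_activity(2500), "EXCLUDED")
  expect_identical(label_activity(c(999.9, 1000.1, 4999.9, 5000.1)),
                   c("ACTIVE", "EXCLUDED", "EXCLUDED", "INACTIVE"))
  expect_error(label_activity(0))
  expect_error(label_activity(-10))
})

make_records <- function(compound_id, smiles, endpoint = "KI",
                         relation = "EQ", value_nM, source_id = "SRC-A") {
  data.frame(compound_id = compound_id, smiles = smiles, endpoint = endpoint,
             relation = relation, value_nM = value_nM, source_id = source_id,
             stringsAsFactors = FALSE)
}

test_that("dataset assembly deduplicates by canonical SMILES and averages", {
  # two spellings of ethanol with Ki 100 and 200 -> one compound at 150
  rec <- rbind(
    make_records("a", "OCC", value_nM = 100),
    make_records("b", "CCO", value_nM = 200),
    make_records(c("c", "d"), "c1ccccc1O", value_nM = c(8000, 8000))
  )
  ds <- build_datasets(rec, holdout_n = 0, seed = 1)
  etoh <- ds$training[ds$training$canonical_smiles == "CCO", ]
  expect_equal(nrow(etoh), 1)
  expect_equal(etoh$potency_nM, 150)
  expect_equal(etoh$n_replicates_used, 2L)
  expect_identical(etoh$label, "ACTIVE")
})

test_that("a compound measured as both Ki and IC50 stays in training only", {
  rec <- rbind(
    make_records("a", "CCO", value_nM = 100),
    make_records("a2", "CCO", endpoint = "IC50", value_nM = 120),
    make_records("b", "CCCCO", value_nM = 200),
    make_records("c", "CCCO", endpoint = "IC50", value_nM = 50000)
  )
  ds <- build_datasets(rec, holdout_n = 0, seed = 1)
  expect_true("CCO" %in% ds$training$canonical_smiles)
  expect_false("CCO" %in% ds$test$canonical_smiles)
  # the IC50-only compound lands in the test set
  expect_true("CCCO" %in% ds$test$canonical_smiles)
  expect_length(intersect(ds$training$canonical_smiles,
                          ds$test$canonical_smiles), 0)
})

test_that("censored records and the excluded band are removed", {
  rec <- rbind(
    make_records("a", "CCO", value_nM = 100),
    make_records("b", "CCCO", relation = "GT", value_nM = 10000),
    make_records("c", "CCCCO", value_nM = 2500)
  )
  ds <- build_datasets(rec, holdout_n = 0, seed = 1)
  all_smiles <- c(ds$training$canonical_smiles, ds$test$canonical_smiles)
  expect_identical(all_smiles, "CCO")
  expect_false(any(c(ds$training$label, ds$test$label) == "EXCLUDED"))
})

test_that("the source filter moves foreign compounds to the test set", {
  rec <- rbind(
    make_records("a", "CCO", value_nM = 100, source_id = "MAIN"),
    make_records("b", "CCCO", value_nM = 200, source_id = "OTHER"),
    make_records("c", "CCCCO", value_nM = 50000, source_id = "MAIN")
  )
  ds <- build_datasets(rec, holdout_n = 0, seed = 1, source_filter = "MAIN")
  expect_setequal(ds$training$canonical_smiles, c("CCO", "CCCCO"))
  expect_identical(ds$test$canonical_smiles, "CCCO")
})

test_that("dataset assembly is deterministic and the holdout is validated", {
  bench <- small_benchmark()
  ds1 <- suppressWarnings(build_datasets(bench$records, holdout_n = 20, seed = 7))
  ds2 <- suppressWarnings(build_datasets(bench$records, holdout_n = 20, seed = 7))
  expect_identical(ds1$training, ds2$training)
  expect_identical(ds1$test, ds2$test)
  ds3 <- suppressWarnings(build_datasets(bench$records, holdout_n = 20, seed = 8))
  expect_false(identical(ds1$test$canonical_smiles, ds3$test$canonical_smiles))
  # label <-> potency invariant holds everywhere
  both <- rbind(ds1$training, ds1$test)
  expect_identical(both$label, label_activity(both$potency_nM))
  expect_length(intersect(ds1$training$canonical_smiles,
                          ds1$test$canonical_smiles), 0)
  expect_error(suppressWarnings(build_datasets(bench$records, holdout_n = 1e6)),
               "holdout_n")
})

test_that("curated datasets round-trip to disk with a manifest", {
  rec <- rbind(make_records("a", "CCO", value_nM = 100),
               make_records("b", "CCCO", value_nM = 50000))
  ds <- build_datasets(rec, holdout_n = 0, seed = 1)
  dir <- withr::local_tempdir()
  path <- write_datasets(ds, dir)
  expect_true(file.exists(file.path(dir, "training.csv")))
  manifest <- jsonlite::read_json(path)
  expect_equal(manifest$seed, 1)
  expect_equal(length(manifest$training), nrow(ds$training))
})
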